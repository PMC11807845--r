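#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-exposure and per-method seeds so batch runs are reproducible and
# independent of processing order.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(x)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Combine a base seed with a string or integer offset, staying below 2^31.
derive_seed <- function(seed, offset) {
  if (is.character(offset)) offset <- stable_hash(offset)
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
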