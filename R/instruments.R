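#' Pairwise LD matrix
#'
#' Container for squared correlations (r-squared) between variants, used by
#' the greedy clumping step. The matrix must be symmetric with unit diagonal
#' and entries in \[0, 1\].
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param variant_ids character vector of ids, one per matrix row.
#' @param positions base-pair positions aligned to `variant_ids` (1-based).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids, positions = NULL) {
  r2 <- as.matrix(r2)
  m <- length(variant_ids)
  if (nrow(r2) != m || ncol(r2) != m)
    stop_input("r2 must be a ", m, "x", m, " matrix to match variant_ids")
  if (max(abs(r2 - t(r2))) > 1e-8) stop_input("r2 matrix is not symmetric")
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop_input("r2 entries outside [0, 1]")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop_input("r2 diagonal must equal 1")
  r2 <- pmin(pmax(r2, 0), 1)
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2,
                 positions = positions), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("LD matrix over", length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Read an LD matrix from a square delimited file
#'
#' Expects a header row of variant ids and an id column, with squared
#' correlations in the body.
#'
#' @param path file path.
#' @param sep field separator; default tab.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  ld_matrix(as.matrix(raw), variant_ids = rownames(raw))
}

#' Squared-correlation LD from a genotype dosage panel
#'
#' Computes pairwise Pearson correlation squared across samples from a
#' sample-by-variant dosage table (delimited file with a header of variant
#' ids, or a numeric matrix).
#'
#' @param dosages numeric matrix (samples x variants) or path to a delimited
#'   file with variant ids as the header.
#' @param sep field separator when `dosages` is a path.
#' @return An `ld_matrix` object.
#' @export
ld_from_dosages <- function(dosages, sep = "\t") {
  if (is.character(dosages))
    dosages <- as.matrix(utils::read.delim(dosages, sep = sep, header = TRUE,
                                           check.names = FALSE))
  r <- stats::cor(dosages)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  ld_matrix(r * r, variant_ids = colnames(dosages))
}

#' Select candidate instruments by association p-value
#'
#' Returns the variant ids whose exposure p-value falls strictly below the
#' threshold, ordered by ascending p-value with ties broken by chromosome,
#' position and id. The forward screen uses 5e-6 and the reverse-causation
#' stage the genome-wide 5e-8.
#'
#' @param stats a [sumstats] object.
#' @param threshold p-value cutoff in (0, 1).
#' @return character vector of variant ids (possibly empty).
#' @export
select_by_pvalue <- function(stats, threshold = 5e-6) {
  stopifnot(inherits(stats, "sumstats"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_input("threshold must be in (0, 1)")
  rec <- stats$records
  hit <- rec[rec$pvalue < threshold, , drop = FALSE]
  hit <- hit[order(hit$pvalue, hit$chromosome, hit$position, hit$variant_id), ,
             drop = FALSE]
  hit$variant_id
}

#' Greedy LD clumping of candidate instruments
#'
#' Sweeps candidates by ascending p-value, keeping a variant only if no
#' previously kept variant on the same chromosome lies within the window and
#' exceeds the r-squared ceiling with it. Cross-chromosome pairs are never
#' clumped. The output order is the keep order; the result does not depend on
#' the order of `candidates` because ranking is re-derived from p-values.
#'
#' @param candidates character vector of variant ids (must be present in both
#'   `ld` and `stats`).
#' @param ld an [ld_matrix].
#' @param stats the exposure [sumstats] providing p-values and coordinates.
#' @param window_kb clumping window in kilobases (default 10000).
#' @param r2_max maximum tolerated squared correlation (default 0.001).
#' @return character vector of retained variant ids.
#' @export
ld_clump <- function(candidates, ld, stats, window_kb = 10000,
                     r2_max = 0.001) {
  stopifnot(inherits(ld, "ld_matrix"), inherits(stats, "sumstats"))
  if (!length(candidates)) return(character())
  if (window_kb <= 0) stop_input("window_kb must be positive")
  if (r2_max < 0 || r2_max > 1) stop_input("r2_max must be in [0, 1]")
  missing_ld <- setdiff(candidates, ld$variant_ids)
  if (length(missing_ld))
    stop_input("candidate(s) missing from LD matrix: ",
               paste(utils::head(missing_ld, 5), collapse = ", "))
  rec <- stats$records
  idx <- match(candidates, rec$variant_id)
  if (anyNA(idx))
    stop_input("candidate(s) missing from summary statistics: ",
               paste(utils::head(candidates[is.na(idx)], 5), collapse = ", "))
  ord <- order(rec$pvalue[idx], rec$chromosome[idx], rec$position[idx],
               rec$variant_id[idx])
  cand <- candidates[ord]
  chr <- rec$chromosome[idx][ord]
  pos <- rec$position[idx][ord]
  window_bp <- window_kb * 1000

  kept <- integer(0)
  for (i in seq_along(cand)) {
    ok <- TRUE
    for (j in kept) {
      if (chr[j] == chr[i] && abs(pos[j] - pos[i]) <= window_bp &&
          ld$r2[cand[j], cand[i]] > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  cand[kept]
}

#' Proportion of exposure variance explained by one variant
#'
#' Computes R-squared = beta^2 / (beta^2 + se^2 * n), the standard
#' summary-statistic approximation for the variance in the exposure explained
#' by a single variant (the allele-frequency factor 2*EAF*(1-EAF) cancels
#' exactly between numerator and denominator).
#'
#' @param beta per-allele effect size (vectorized).
#' @param se standard error of `beta`, positive.
#' @param n sample size, positive.
#' @return numeric vector of R-squared values in \[0, 1).
#' @export
variance_explained <- function(beta, se, n) {
  if (any(is.na(n))) stop_input("sample size n is missing")
  if (any(se <= 0) || any(n <= 0)) stop_input("se and n must be positive")
  beta^2 / (beta^2 + se^2 * n)
}

#' Instrument F-statistic
#'
#' F = \[(N - K - 1) / K\] * R^2 / (1 - R^2). A variant with F below 10 is
#' conventionally flagged as a weak instrument. Per-SNP strength uses K = 1;
#' the aggregate strength of an instrument set uses K equal to the number of
#' instruments and their combined R-squared.
#'
#' @param r_squared variance explained, in \[0, 1).
#' @param n sample size; must exceed `k + 1`.
#' @param k number of instruments in the model (default 1).
#' @return numeric vector of F-statistics.
#' @export
f_statistic <- function(r_squared, n, k = 1) {
  if (any(r_squared < 0 | r_squared >= 1))
    stop_input("r_squared must be in [0, 1)")
  if (any(n <= k + 1)) stop_input("n must exceed k + 1")
  ((n - k - 1) / k) * r_squared / (1 - r_squared)
}

#' Per-variant and aggregate instrument strength
#'
#' Tabulates R-squared and the F-statistic for each instrument (K = 1) and,
#' as attributes, the aggregate R-squared (sum over instruments) and the
#' aggregate F computed with K equal to the instrument count.
#'
#' @param stats exposure [sumstats].
#' @param variant_ids instruments to assess.
#' @return data.frame with columns `variant_id`, `r_squared`, `f_stat`, `k`
#'   and a logical `weak` flag (F < 10); attributes `aggregate_r2` and
#'   `aggregate_f`.
#' @export
instrument_strength <- function(stats, variant_ids) {
  stopifnot(inherits(stats, "sumstats"))
  rec <- stats$records
  idx <- match(variant_ids, rec$variant_id)
  if (anyNA(idx))
    stop_input("variant(s) absent from summary statistics: ",
               paste(utils::head(variant_ids[is.na(idx)], 5), collapse = ", "))
  r2 <- variance_explained(rec$beta[idx], rec$se[idx], rec$n[idx])
  f1 <- f_statistic(r2, rec$n[idx], k = 1)
  out <- data.frame(variant_id = rec$variant_id[idx], r_squared = r2,
                    f_stat = f1, k = 1L, weak = f1 < 10,
                    stringsAsFactors = FALSE)
  k <- length(variant_ids)
  agg_r2 <- min(sum(r2), 1 - 1e-12)
  n_agg <- stats::median(rec$n[idx])
  attr(out, "aggregate_r2") <- agg_r2
  attr(out, "aggregate_f") <- if (n_agg > k + 1)
    f_statistic(agg_r2, n_agg, k = k) else NA_real_
  out
}
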