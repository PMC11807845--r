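#' GWAS summary statistics container
#'
#' Builds a validated set of per-variant association records for one trait.
#' Each record carries the variant identifier, coordinates, effect and other
#' alleles, the effect-allele frequency (EAF), the per-allele effect size
#' (beta), its standard error, the association p-value and the sample size.
#' Rows violating the record invariants (identical alleles, non-ACGT alleles,
#' non-positive standard error, frequency outside \[0, 1\], p-value outside
#' (0, 1\], non-positive position or sample size, duplicated variant id) are
#' dropped and tallied in the load report rather than raising an error.
#'
#' @param data data.frame with (a superset of) the canonical columns
#'   `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`. `eaf` and `n` may be missing or `NA`;
#'   a missing `n` falls back to `default_n`.
#' @param trait_id character scalar naming the trait (e.g. a GWAS Catalog
#'   accession).
#' @param default_n optional fallback sample size used where a record's `n`
#'   is missing.
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `records` (data.frame in canonical column order), `default_n` and
#'   `load_report` (data.frame of reason/count pairs for dropped rows).
#' @examples
#' ss <- sumstats(data.frame(
#'   variant_id = "rs1", chromosome = "1", position = 1000L,
#'   effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = 0.05, se = 0.008, pvalue = 4e-10, n = 26333L), "trait")
#' ss
#' @export
sumstats <- function(data, trait_id, default_n = NULL) {
  stopifnot(is.data.frame(data), is.character(trait_id), length(trait_id) == 1L)
  canonical <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "eaf", "beta", "se", "pvalue", "n")
  for (col in c("eaf", "n")) if (!col %in% names(data)) data[[col]] <- NA_real_
  missing_cols <- setdiff(canonical, names(data))
  if (length(missing_cols))
    stop_input("missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  df <- data[canonical]
  df$variant_id    <- as.character(df$variant_id)
  df$chromosome    <- as.character(df$chromosome)
  df$position      <- as.integer(df$position)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele  <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.numeric(df$n)
  if (!is.null(default_n)) df$n[is.na(df$n)] <- as.numeric(default_n)

  drop_reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    drop_reason[bad & is.na(drop_reason)] <<- reason
  }
  acgt <- c("A", "C", "G", "T")
  flag(is.na(df$variant_id) | df$variant_id == "", "missing_id")
  flag(!(df$effect_allele %in% acgt) | !(df$other_allele %in% acgt),
       "invalid_allele")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(is.na(df$beta) | !is.finite(df$beta), "missing_beta")
  flag(is.na(df$se) | df$se <= 0, "invalid_se")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "invalid_eaf")
  flag(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "invalid_pvalue")
  flag(is.na(df$position) | df$position < 1, "invalid_position")
  flag(!is.na(df$n) & df$n <= 0, "invalid_n")
  flag(duplicated(df$variant_id), "duplicate_id")

  dropped <- drop_reason[!is.na(drop_reason)]
  report <- if (length(dropped)) {
    tab <- table(dropped)
    data.frame(reason = names(tab), count = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  records <- df[is.na(drop_reason), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(trait_id = trait_id, records = records,
                 default_n = default_n, load_report = report),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for trait '", x$trait_id, "': ",
      nrow(x$records), " variants\n", sep = "")
  if (nrow(x$load_report)) {
    cat("Dropped rows at load:\n")
    print(x$load_report, row.names = FALSE)
  }
  invisible(x)
}

#' @export
nvariants <- function(x) UseMethod("nvariants")

#' @export
nvariants.sumstats <- function(x) nrow(x$records)

canonical_columns <- function() {
  c("variant_id", "chromosome", "position", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pvalue", "n")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing delimited file into a [sumstats] object. Foreign
#' column layouts (e.g. PLINK-style `SNP/CHR/BP/A1/A2/FRQ/BETA/SE/P/N` or
#' GWAS-SSF exports) are mapped onto the canonical columns through a
#' `dialect`: a named character vector or list whose names are the canonical
#' fields and whose values are the source header names, or the path to a YAML
#' file holding that mapping.
#'
#' @param path file path of a delimited text file with a header row.
#' @param trait_id trait identifier; defaults to the file name without
#'   extension.
#' @param dialect optional column mapping (named vector/list or YAML path).
#' @param sep field separator; default tab.
#' @param default_n optional fallback sample size.
#' @return A [sumstats] object; rows failing validation are counted in its
#'   `load_report`.
#' @seealso [write_sumstats()]
#' @export
read_sumstats <- function(path, trait_id = NULL, dialect = NULL, sep = "\t",
                          default_n = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        stop_input("empty file: ", path)
      stop(e)
    })
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop_input("empty file: ", path)
  if (!is.null(dialect)) {
    if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
      dialect <- yaml::read_yaml(dialect)
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), canonical_columns())
    if (length(unknown))
      stop_input("dialect maps unknown canonical field(s): ",
                 paste(unknown, collapse = ", "))
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop_input("dialect names source column(s) absent from file: ",
                 paste(missing_src, collapse = ", "))
    for (canon in names(dialect)) {
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  mandatory <- setdiff(canonical_columns(), c("eaf", "n"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop_input("missing mandatory column(s): ",
               paste(missing_cols, collapse = ", "),
               " (provide a dialect mapping?)")
  sumstats(raw, trait_id %||% sub("\\.[^.]*$", "", basename(path)),
           default_n = default_n)
}

#' Write GWAS summary statistics to a canonical delimited file
#'
#' Writes the canonical tab-delimited layout
#' (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`) at full numeric precision, so that
#' `read_sumstats(write_sumstats(x))` reproduces `x` field for field.
#'
#' @param stats a [sumstats] object.
#' @param path destination file path.
#' @param sep field separator; default tab.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path, sep = "\t") {
  stopifnot(inherits(stats, "sumstats"))
  df <- stats$records
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- vapply(df[[col]], function(v)
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = NA,
                                     trim = TRUE), character(1))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_input("cannot write to '", path, "': ",
                              conditionMessage(ok))
  invisible(path)
}
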