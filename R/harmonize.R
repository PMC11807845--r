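ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a variant palindromic (A/T or C/G)?
#'
#' Palindromic variants carry the same allele pair on both strands, so their
#' strand cannot be resolved from the alleles alone; the screening pipeline
#' removes them unconditionally during harmonization.
#'
#' @param effect_allele,other_allele allele characters over A/C/G/T
#'   (vectorized).
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(ALLELE_COMPLEMENT[toupper(effect_allele)] == toupper(other_allele))
}

#' Harmonize exposure and outcome effects onto a shared effect-allele frame
#'
#' For each instrument present in both traits the outcome association is
#' re-expressed relative to the exposure's effect allele: aligned alleles are
#' copied, swapped effect/other alleles negate the outcome beta, and
#' complementary (strand-flipped) alleles are complemented before applying the
#' same rules. Palindromic variants (A/T or C/G) are removed unconditionally
#' -- no allele-frequency rescue is attempted -- and instruments absent from
#' the outcome or with irreconcilable alleles are dropped with audit reason
#' codes. Variant matching is by `variant_id`; chromosome/position
#' disagreements between the two traits are tallied in the
#' `coordinate_mismatches` attribute, not treated as fatal.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param instrument_ids character vector of variant ids, a subset of the
#'   exposure's variants (typically the output of [select_by_pvalue()] and
#'   [ld_clump()]).
#' @return An object of class `harmonized_set`: a list with `exposure_id`,
#'   `outcome_id`, `data` (one row per retained instrument: `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`) and `dropped` (data.frame of `variant_id`, `reason` with
#'   reasons from `palindromic`, `missing_in_outcome`, `allele_mismatch`).
#' @examples
#' ex <- sumstats(data.frame(variant_id = "rs1", chromosome = "1",
#'   position = 100L, effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = 0.1, se = 0.01, pvalue = 1e-8, n = 10000), "exp")
#' out <- sumstats(data.frame(variant_id = "rs1", chromosome = "1",
#'   position = 100L, effect_allele = "G", other_allele = "A", eaf = 0.7,
#'   beta = -0.05, se = 0.02, pvalue = 0.01, n = 20000), "out")
#' harmonize(ex, out, "rs1")$data$beta_outcome  # +0.05: alleles were swapped
#' @export
harmonize <- function(exposure, outcome, instrument_ids) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (length(instrument_ids) == 0L)
    stop_input("instrument_ids is empty")
  instrument_ids <- as.character(instrument_ids)
  ex <- exposure$records
  absent <- setdiff(instrument_ids, ex$variant_id)
  if (length(absent))
    stop_input("instrument id(s) absent from exposure: ",
               paste(utils::head(absent, 5), collapse = ", "))
  ex <- ex[match(instrument_ids, ex$variant_id), , drop = FALSE]
  out <- outcome$records

  n <- nrow(ex)
  keep <- logical(n)
  reason <- rep(NA_character_, n)
  beta_out <- se_out <- rep(NA_real_, n)
  coord_mismatch <- 0L

  out_idx <- match(ex$variant_id, out$variant_id)
  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    if (isTRUE(is_palindromic(ea_x, oa_x))) { reason[i] <- "palindromic"; next }
    j <- out_idx[i]
    if (is.na(j)) { reason[i] <- "missing_in_outcome"; next }
    ea_y <- out$effect_allele[j]; oa_y <- out$other_allele[j]
    if (isTRUE(is_palindromic(ea_y, oa_y))) { reason[i] <- "palindromic"; next }
    if (!identical(out$chromosome[j], ex$chromosome[i]) ||
        !identical(out$position[j], ex$position[i]))
      coord_mismatch <- coord_mismatch + 1L
    b <- out$beta[j]
    if (ea_y == ea_x && oa_y == oa_x) {
      # already aligned
    } else if (ea_y == oa_x && oa_y == ea_x) {
      b <- -b
    } else {
      # try the complementary strand
      ea_c <- unname(ALLELE_COMPLEMENT[ea_y])
      oa_c <- unname(ALLELE_COMPLEMENT[oa_y])
      if (ea_c == ea_x && oa_c == oa_x) {
        # strand flip only; effect allele unchanged in meaning
      } else if (ea_c == oa_x && oa_c == ea_x) {
        b <- -b
      } else {
        reason[i] <- "allele_mismatch"; next
      }
    }
    keep[i] <- TRUE
    beta_out[i] <- b
    se_out[i] <- out$se[j]
  }

  data <- data.frame(
    variant_id = ex$variant_id[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_out[keep],
    se_outcome = se_out[keep],
    eaf_exposure = ex$eaf[keep],
    stringsAsFactors = FALSE)
  dropped <- data.frame(variant_id = ex$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(exposure_id = exposure$trait_id,
                 outcome_id = outcome$trait_id,
                 data = data, dropped = dropped),
            class = "harmonized_set",
            coordinate_mismatches = coord_mismatch)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", x$exposure_id, " -> ", x$outcome_id,
      "\n  instruments retained: ", nrow(x$data),
      "; dropped: ", nrow(x$dropped), "\n", sep = "")
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat("  drop reasons: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Internal: build a harmonized_set directly from aligned effect vectors.
# Used by simulations, tests and examples that start from effect pairs.
#' Construct a harmonized set from aligned effect vectors
#'
#' Convenience constructor for analyses that already have exposure and
#' outcome effects on a shared effect-allele frame (e.g. simulation output or
#' published per-SNP tables).
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome numeric vectors of
#'   equal length; standard errors must be positive.
#' @param variant_id optional ids (defaults to `snp_1 ... snp_K`).
#' @param eaf_exposure optional exposure effect-allele frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, variant_id = NULL, eaf_exposure = NULL,
                           exposure_id = "exposure", outcome_id = "outcome") {
  k <- length(beta_exposure)
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k, all(se_exposure > 0), all(se_outcome > 0))
  data <- data.frame(
    variant_id = variant_id %||% paste0("snp_", seq_len(k)),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    eaf_exposure = if (is.null(eaf_exposure)) NA_real_ else
      as.numeric(eaf_exposure),
    stringsAsFactors = FALSE)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 data = data,
                 dropped = data.frame(variant_id = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)),
            class = "harmonized_set",
            coordinate_mismatches = 0L)
}
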