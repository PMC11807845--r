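# Forward and reverse screening of many exposures against one outcome.

#' Screening configuration
#'
#' Bundles the thresholds and knobs of the screening pipeline. Defaults
#' follow the forward screen: candidate instruments at p < 5e-6, clumping
#' window 10,000 kb at r-squared < 0.001, weak-instrument exclusion at
#' F < 10, all decision tests at the 0.05 level, and a stricter genome-wide
#' 5e-8 instrument threshold for the reverse-causation stage.
#'
#' @param exposure_p_threshold instrument p-value cutoff for the forward
#'   screen.
#' @param reverse_p_threshold instrument cutoff for the reverse stage.
#' @param clump_window_kb clumping window in kilobases.
#' @param clump_r2 clumping r-squared ceiling.
#' @param ivw_screen_alpha IVW significance level of the first screening
#'   step.
#' @param q_alpha heterogeneity rejection level.
#' @param intercept_alpha Egger-intercept rejection level.
#' @param f_min weak-instrument F cutoff (set to 0 to disable the filter).
#' @param heterogeneity_methods which Q tests can exclude an exposure:
#'   `c("ivw", "egger")` (either test, the default) or `"ivw"` only.
#' @param loo_check apply the leave-one-out stability rule.
#' @param fdr apply Benjamini-Hochberg correction to the IVW screening
#'   p-values across exposures (off by default; the screen uses raw p).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param seed base integer seed; per-exposure seeds are derived from it by
#'   a stable hash of the exposure id.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(exposure_p_threshold = 5e-6,
                             reverse_p_threshold = 5e-8,
                             clump_window_kb = 10000, clump_r2 = 0.001,
                             ivw_screen_alpha = 0.05, q_alpha = 0.05,
                             intercept_alpha = 0.05, f_min = 10,
                             heterogeneity_methods = c("ivw", "egger"),
                             loo_check = TRUE, fdr = FALSE,
                             n_boot = 500, seed = 1) {
  cfg <- list(exposure_p_threshold = exposure_p_threshold,
              reverse_p_threshold = reverse_p_threshold,
              clump_window_kb = clump_window_kb, clump_r2 = clump_r2,
              ivw_screen_alpha = ivw_screen_alpha, q_alpha = q_alpha,
              intercept_alpha = intercept_alpha, f_min = f_min,
              heterogeneity_methods = match.arg(heterogeneity_methods,
                                                c("ivw", "egger"),
                                                several.ok = TRUE),
              loo_check = isTRUE(loo_check), fdr = isTRUE(fdr),
              n_boot = as.integer(n_boot), seed = as.integer(seed))
  probs <- c(exposure_p_threshold = exposure_p_threshold,
             reverse_p_threshold = reverse_p_threshold,
             ivw_screen_alpha = ivw_screen_alpha, q_alpha = q_alpha,
             intercept_alpha = intercept_alpha)
  bad <- names(probs)[probs <= 0 | probs >= 1]
  if (length(bad))
    stop_input("configuration value(s) outside (0, 1): ",
               paste(bad, collapse = ", "))
  if (clump_window_kb <= 0 || clump_r2 < 0 || clump_r2 > 1)
    stop_input("invalid clumping parameters")
  structure(cfg, class = "screening_config")
}

#' @export
print.screening_config <- function(x, ...) {
  cat("MR screening configuration:\n")
  cat(sprintf("  instrument p < %g (forward), p < %g (reverse)\n",
              x$exposure_p_threshold, x$reverse_p_threshold))
  cat(sprintf("  clumping: window %g kb, r2 < %g; weak-instrument F < %g\n",
              x$clump_window_kb, x$clump_r2, x$f_min))
  cat(sprintf("  alphas: IVW %g, Q %g (%s), intercept %g; LOO check %s\n",
              x$ivw_screen_alpha, x$q_alpha,
              paste(x$heterogeneity_methods, collapse = "/"),
              x$intercept_alpha, x$loo_check))
  invisible(x)
}

#' Are the five odds-ratio directions consistent?
#'
#' An exposure passes the direction screen only when all five estimators
#' place the odds ratio strictly on the same side of 1; any OR exactly equal
#' to 1, or a mix of directions, fails the screen.
#'
#' @param estimates either a numeric vector of exactly five odds ratios, an
#'   `mr_fit` with five estimates, or a list of five `mr_estimate` objects.
#' @return logical scalar.
#' @examples
#' direction_consistent(c(1.15, 1.25, 1.24, 1.30, 1.27))  # TRUE
#' direction_consistent(c(0.95, 1.07, 1.12, 1.03, 1.00))  # FALSE
#' @export
direction_consistent <- function(estimates) {
  or_values <- if (is.numeric(estimates)) {
    estimates
  } else if (inherits(estimates, "mr_fit")) {
    estimates$estimates$or_value
  } else if (is.list(estimates)) {
    vapply(estimates, function(e) e$or_value, numeric(1))
  } else stop_input("cannot extract odds ratios from 'estimates'")
  if (length(or_values) != 5L)
    stop_input("direction consistency needs exactly 5 estimates; got ",
               length(or_values))
  if (anyNA(or_values)) return(FALSE)
  all(or_values > 1) || all(or_values < 1)
}

SCREEN_REASONS <- c("ivw_not_significant", "direction_inconsistent",
                    "heterogeneity", "pleiotropy", "loo_unstable",
                    "too_few_instruments")

#' Screen one exposure against the outcome
#'
#' Runs the full per-exposure pipeline: instrument selection by p-value,
#' greedy LD clumping, weak-instrument (F < 10) exclusion, allele
#' harmonization with palindrome removal, the five estimators, and the
#' sensitivity battery. The sequential decision rule then excludes the
#' exposure at the first failing step: IVW not significant, inconsistent OR
#' directions, heterogeneity (Cochran's Q for IVW or Egger), directional
#' pleiotropy (Egger intercept), or leave-one-out instability; otherwise the
#' exposure is retained and classed as a risk factor (all five ORs > 1) or
#' protective (all five ORs < 1). Fewer than three usable instruments yields
#' an excluded record with reason `too_few_instruments`, not an error, so
#' batch runs always complete.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param ld an [ld_matrix] covering the exposure's candidate variants.
#' @param cfg a [screening_config].
#' @param seed optional integer overriding the seed derived from
#'   `cfg$seed` and the exposure id.
#' @return An object of class `exposure_screen` carrying the decision, the
#'   ordered reason codes, the effect class, and every intermediate artifact
#'   (instrument lists, strength table, harmonized set, `mr_fit`,
#'   heterogeneity/pleiotropy/leave-one-out results).
#' @export
screen_exposure <- function(exposure, outcome, ld, cfg = screening_config(),
                            seed = NULL) {
  stopifnot(inherits(cfg, "screening_config"))
  seed <- seed %||% derive_seed(cfg$seed, exposure$trait_id)
  rec <- list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
              seed = seed, decision = "excluded", reasons = character(),
              effect_class = "none", fit = NULL, heterogeneity = NULL,
              pleiotropy = NULL, loo = NULL, harmonized = NULL,
              strength = NULL)
  class(rec) <- "exposure_screen"

  candidates <- select_by_pvalue(exposure, cfg$exposure_p_threshold)
  rec$n_candidates <- length(candidates)
  if (length(candidates) < 3) {
    rec$reasons <- "too_few_instruments"
    return(rec)
  }
  clumped <- ld_clump(candidates, ld, exposure,
                      window_kb = cfg$clump_window_kb, r2_max = cfg$clump_r2)
  rec$n_clumped <- length(clumped)
  if (cfg$f_min > 0) {
    strength <- instrument_strength(exposure, clumped)
    rec$strength <- strength
    kept <- strength$variant_id[strength$f_stat >= cfg$f_min]
    rec$n_weak_dropped <- length(clumped) - length(kept)
  } else kept <- clumped
  if (length(kept) < 3) {
    rec$reasons <- "too_few_instruments"
    return(rec)
  }
  h <- harmonize(exposure, outcome, kept)
  rec$harmonized <- h
  if (nrow(h$data) < 3) {
    rec$reasons <- "too_few_instruments"
    return(rec)
  }

  fit <- mr_fit(h, seed = seed, n_boot = cfg$n_boot)
  rec$fit <- fit
  het <- rbind(as.data.frame(cochran_q(h, "ivw")),
               as.data.frame(cochran_q(h, "egger")))
  rec$heterogeneity <- het
  rec$pleiotropy <- egger_intercept_test(h, alpha = cfg$intercept_alpha)
  rec$loo <- leave_one_out(h, alpha = cfg$ivw_screen_alpha)

  if (length(fit$failures) || nrow(fit$estimates) != 5L) {
    rec$reasons <- "too_few_instruments"
    return(rec)
  }
  ivw_row <- fit$estimates[fit$estimates$method == "ivw", ]
  het_sel <- het[het$method %in% cfg$heterogeneity_methods, ]
  rec$reasons <- if (ivw_row$pvalue >= cfg$ivw_screen_alpha) {
    "ivw_not_significant"
  } else if (!direction_consistent(fit)) {
    "direction_inconsistent"
  } else if (any(het_sel$pvalue < cfg$q_alpha)) {
    "heterogeneity"
  } else if (rec$pleiotropy$pvalue < cfg$intercept_alpha) {
    "pleiotropy"
  } else if (cfg$loo_check && !rec$loo$stable) {
    "loo_unstable"
  } else character()

  if (!length(rec$reasons)) {
    rec$decision <- "retained"
    ors <- fit$estimates$or_value
    rec$effect_class <- if (all(ors > 1)) "risk"
      else if (all(ors < 1)) "protective" else "none"
  }
  rec
}

#' @export
print.exposure_screen <- function(x, ...) {
  cat("Exposure screen: ", x$exposure_id, " -> ", x$outcome_id, ": ",
      x$decision,
      if (length(x$reasons)) paste0(" (", x$reasons, ")") else
        paste0(" [", x$effect_class, "]"),
      "\n", sep = "")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Screen many exposures against one outcome
#'
#' Applies [screen_exposure()] independently to each exposure; results do
#' not depend on the exposure order because each exposure's seed is derived
#' from the base seed and a stable hash of its trait id. With `cfg$fdr` the
#' first-step IVW p-values are Benjamini-Hochberg adjusted across exposures
#' before the significance rule is applied (off by default).
#'
#' @param exposures non-empty list of [sumstats] objects.
#' @param outcome the outcome [sumstats].
#' @param ld an [ld_matrix], or a named list of matrices keyed by exposure
#'   trait id.
#' @param cfg a [screening_config].
#' @return An object of class `mr_screen`: list of `exposure_screen` records
#'   plus a summary of decisions and exclusion reasons.
#' @export
screen_many <- function(exposures, outcome, ld, cfg = screening_config()) {
  if (!length(exposures)) stop_input("no exposures supplied")
  records <- lapply(exposures, function(ex) {
    ld_ex <- if (inherits(ld, "ld_matrix")) ld else {
      m <- ld[[ex$trait_id]]
      if (is.null(m)) stop_input("no LD matrix for exposure ", ex$trait_id)
      m
    }
    screen_exposure(ex, outcome, ld_ex, cfg)
  })
  names(records) <- vapply(records, `[[`, character(1), "exposure_id")

  if (cfg$fdr) {
    ivw_p <- vapply(records, function(r) {
      if (is.null(r$fit)) NA_real_ else
        r$fit$estimates$pvalue[r$fit$estimates$method == "ivw"]
    }, numeric(1))
    adj <- stats::p.adjust(ivw_p, method = "BH")
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (!is.na(adj[i]) && identical(r$reasons, character()) &&
          adj[i] >= cfg$ivw_screen_alpha) {
        r$decision <- "excluded"; r$reasons <- "ivw_not_significant"
        r$effect_class <- "none"; records[[i]] <- r
      }
    }
  }

  decisions <- vapply(records, `[[`, character(1), "decision")
  reasons <- unlist(lapply(records, `[[`, "reasons"))
  structure(list(records = records, cfg = cfg,
                 summary = list(
                   n = length(records),
                   retained = sum(decisions == "retained"),
                   excluded = sum(decisions == "excluded"),
                   by_reason = table(factor(reasons,
                                            levels = SCREEN_REASONS)))),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  s <- x$summary
  cat("MR screen over", s$n, "exposures:", s$retained, "retained,",
      s$excluded, "excluded\n")
  tab <- s$by_reason[s$by_reason > 0]
  if (length(tab)) {
    cat("Exclusion reasons:\n")
    for (r in names(tab)) cat(sprintf("  %-24s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Reverse-causation screen
#'
#' Re-runs the screening machinery with the outcome trait as the exposure
#' against each forward-significant target, using the stricter genome-wide
#' instrument threshold (`cfg$reverse_p_threshold`). A target is declared
#' reverse-null when the reverse IVW p-value is at least 0.05 (or no usable
#' instrument set exists).
#'
#' @param outcome_as_exposure the original outcome [sumstats], now treated
#'   as exposure.
#' @param targets non-empty list of [sumstats] objects (the retained forward
#'   exposures).
#' @param ld an [ld_matrix] for the outcome trait's variants.
#' @param cfg a [screening_config].
#' @return An `mr_screen` object whose records carry an extra logical
#'   `reverse_null` field.
#' @export
reverse_screen <- function(outcome_as_exposure, targets, ld,
                           cfg = screening_config()) {
  if (!length(targets)) stop_input("no reverse-stage targets supplied")
  cfg_rev <- cfg
  cfg_rev$exposure_p_threshold <- cfg$reverse_p_threshold
  records <- lapply(targets, function(tg) {
    r <- screen_exposure(outcome_as_exposure, tg, ld, cfg_rev,
                         seed = derive_seed(cfg$seed,
                                            paste0("reverse:", tg$trait_id)))
    ivw_p <- if (is.null(r$fit)) NA_real_ else
      r$fit$estimates$pvalue[r$fit$estimates$method == "ivw"]
    r$reverse_null <- is.na(ivw_p) || ivw_p >= 0.05
    r
  })
  names(records) <- vapply(targets, `[[`, character(1), "trait_id")
  decisions <- vapply(records, `[[`, character(1), "decision")
  reasons <- unlist(lapply(records, `[[`, "reasons"))
  structure(list(records = records, cfg = cfg_rev,
                 summary = list(
                   n = length(records),
                   retained = sum(decisions == "retained"),
                   excluded = sum(decisions == "excluded"),
                   reverse_null = sum(vapply(records, `[[`, logical(1),
                                             "reverse_null")),
                   by_reason = table(factor(reasons,
                                            levels = SCREEN_REASONS)))),
            class = "mr_screen")
}

#' Long-format estimate table for a screen
#'
#' One row per exposure and method with the odds ratio and its support
#' columns, mirroring the layout of published multi-exposure MR tables
#' (id.exposure, outcome, exposure, method, or).
#'
#' @param x an `mr_screen` or a single `exposure_screen`/`mr_fit`.
#' @param exposure_labels optional named character vector mapping exposure
#'   ids to descriptive names.
#' @return data.frame with columns `id.exposure`, `outcome`, `exposure`,
#'   `method`, `or`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `n_snp`.
#' @export
mr_table <- function(x, exposure_labels = NULL) {
  records <- if (inherits(x, "mr_screen")) x$records
    else if (inherits(x, "exposure_screen")) list(x)
    else if (inherits(x, "mr_fit")) {
      est <- x$estimates
      return(data.frame(id.exposure = x$harmonized$exposure_id,
                        outcome = x$harmonized$outcome_id,
                        exposure = x$harmonized$exposure_id,
                        method = est$method, or = est$or_value,
                        beta = est$beta, se = est$se, ci_low = est$ci_low,
                        ci_high = est$ci_high, pvalue = est$pvalue,
                        n_snp = est$n_snp, stringsAsFactors = FALSE))
    } else stop_input("unsupported input to mr_table")
  out <- lapply(records, function(r) {
    if (is.null(r$fit)) return(NULL)
    est <- r$fit$estimates
    label <- if (!is.null(exposure_labels) &&
                 r$exposure_id %in% names(exposure_labels))
      exposure_labels[[r$exposure_id]] else r$exposure_id
    data.frame(id.exposure = r$exposure_id, outcome = r$outcome_id,
               exposure = label, method = est$method, or = est$or_value,
               beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pvalue = est$pvalue,
               n_snp = est$n_snp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Forest-plot data for screened exposures
#'
#' Per-exposure, per-method point estimates with 95% interval bounds on the
#' odds-ratio scale, in plotting order.
#'
#' @param x an `mr_screen`.
#' @return data.frame with `id.exposure`, `method`, `or`, `or_low`,
#'   `or_high`, `pvalue`, `decision`.
#' @export
mr_forest_data <- function(x) {
  stopifnot(inherits(x, "mr_screen"))
  out <- lapply(x$records, function(r) {
    if (is.null(r$fit)) return(NULL)
    est <- r$fit$estimates
    data.frame(id.exposure = r$exposure_id, method = est$method,
               or = est$or_value, or_low = exp(est$ci_low),
               or_high = exp(est$ci_high), pvalue = est$pvalue,
               decision = r$decision, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Circle-plot data: per-method p-values across all exposures
#'
#' Wide table with one row per exposure and one column of p-values per
#' method, plus a significance flag at the screening alpha, the layout used
#' by circular overview plots of many-exposure screens.
#'
#' @param x an `mr_screen`.
#' @param alpha significance threshold for the flag columns.
#' @return data.frame.
#' @export
mr_circle_data <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "mr_screen"))
  rows <- lapply(x$records, function(r) {
    p <- stats::setNames(rep(NA_real_, length(MR_METHODS)), MR_METHODS)
    if (!is.null(r$fit))
      p[r$fit$estimates$method] <- r$fit$estimates$pvalue
    cbind(data.frame(id.exposure = r$exposure_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(p)),
          data.frame(ivw_significant = !is.na(p[["ivw"]]) &
                       p[["ivw"]] < alpha))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
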