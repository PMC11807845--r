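# Heterogeneity, pleiotropy and leave-one-out diagnostics for one
# exposure-outcome instrument set.

#' Cochran's Q heterogeneity test
#'
#' For the IVW model, Q = sum w_j (ratio_j - beta_fixed)^2 with K - 1 degrees
#' of freedom; for MR-Egger, the Rucker Q' of weighted squared residuals
#' about the fitted line with K - 2 degrees of freedom. The p-value is the
#' upper tail of the corresponding chi-square distribution.
#'
#' @param h a `harmonized_set` (K >= 2 for ivw, K >= 3 for egger).
#' @param method `"ivw"` or `"egger"`.
#' @return An object of class `heterogeneity_result` with fields `method`,
#'   `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, method = c("ivw", "egger")) {
  method <- match.arg(method)
  if (method == "ivw") {
    w <- wald_ratios(h)
    if (nrow(w) < 2)
      stop_input("Cochran's Q (ivw) requires at least 2 instruments")
    core <- ivw_core(w$ratio, w$weight, "fixed")
    q <- core$q; df <- core$q_df
  } else {
    if (nrow(h$data) < 3)
      stop_input("Cochran's Q (egger) requires at least 3 instruments")
    core <- egger_core(h)
    q <- core$q; df <- core$q_df
  }
  structure(list(method = method, q = q, df = df,
                 pvalue = stats::pchisq(q, df = df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %.4f on %d df, p = %.4g\n",
              x$method, x$q, x$df, x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.heterogeneity_result <- function(x, ...) {
  data.frame(method = x$method, q = x$q, df = x$df, pvalue = x$pvalue,
             stringsAsFactors = FALSE)
}

#' MR-Egger intercept test of directional pleiotropy
#'
#' Reports the Egger regression intercept, its (heterogeneity-scaled)
#' standard error and the two-sided test of a zero intercept. An intercept
#' p-value below `alpha` flags directional horizontal pleiotropy.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param alpha flag threshold (default 0.05).
#' @param dist reference distribution, `"normal"` (default) or `"t"`.
#' @return An object of class `pleiotropy_result` with fields `intercept`,
#'   `se`, `pvalue` and logical `pleiotropic`.
#' @export
egger_intercept_test <- function(h, alpha = 0.05, dist = c("normal", "t")) {
  dist <- match.arg(dist)
  if (nrow(h$data) < 3)
    stop_input("Egger intercept test requires at least 3 instruments")
  est <- mr_egger(h, dist = dist)
  structure(list(intercept = est$egger_intercept,
                 se = est$egger_intercept_se,
                 pvalue = est$egger_intercept_p,
                 pleiotropic = est$egger_intercept_p < alpha),
            class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("Egger intercept: %.4f (SE %.4f), p = %.4g%s\n",
              x$intercept, x$se, x$pvalue,
              if (x$pleiotropic) " [directional pleiotropy flagged]" else ""))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate K times, each time omitting one instrument,
#' alongside the all-SNP estimate. The stability flag is true when every
#' subset estimate has the same sign as the all-SNP estimate and matches its
#' significance at `alpha` -- i.e. no single variant drives the result.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param model IVW model passed to [mr_ivw()].
#' @param alpha significance level for the stability criterion.
#' @return An object of class `loo_table`: list with `table` (one row per
#'   omitted variant: `dropped_variant_id`, `ivw_beta`, `ivw_se`, `ivw_p`),
#'   `all_snp` (the full-set IVW row) and logical `stable`.
#' @export
leave_one_out <- function(h, model = "auto", alpha = 0.05) {
  k <- nrow(h$data)
  if (k < 3) stop_input("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(h, model = model)
  rows <- lapply(seq_len(k), function(j) {
    hj <- h
    hj$data <- h$data[-j, , drop = FALSE]
    e <- mr_ivw(hj, model = model)
    data.frame(dropped_variant_id = h$data$variant_id[j], ivw_beta = e$beta,
               ivw_se = e$se, ivw_p = e$pvalue, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  all_row <- data.frame(dropped_variant_id = "All", ivw_beta = full$beta,
                        ivw_se = full$se, ivw_p = full$pvalue,
                        stringsAsFactors = FALSE)
  stable <- all(sign(tab$ivw_beta) == sign(full$beta)) &&
    all((tab$ivw_p < alpha) == (full$pvalue < alpha))
  structure(list(table = tab, all_snp = all_row, stable = stable,
                 alpha = alpha), class = "loo_table")
}

#' @export
print.loo_table <- function(x, digits = 4, ...) {
  cat("Leave-one-out IVW analysis (", nrow(x$table), " instruments), ",
      if (x$stable) "stable" else "UNSTABLE", "\n", sep = "")
  df <- rbind(x$table, x$all_snp)
  df[-1] <- lapply(df[-1], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.loo_table <- function(x, ...) rbind(x$table, x$all_snp)
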