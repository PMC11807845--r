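# Five two-sample MR estimators on a harmonized instrument set.
#
# All estimators work from per-variant Wald ratios beta_outcome/beta_exposure
# with first-order standard errors se_outcome/|beta_exposure|; the outcome is
# assumed to be on a log-odds scale, so exp(beta) is an odds ratio.

CI_Z <- 1.96  # 95% interval multiplier

#' Per-variant Wald ratio estimates
#'
#' ratio = beta_outcome / beta_exposure, with first-order standard error
#' se_outcome / |beta_exposure| and inverse-variance weight 1 / ratio_se^2.
#' Rows with a zero exposure effect cannot form a ratio and are excluded;
#' their ids are recorded in the `excluded` attribute.
#'
#' @param h a `harmonized_set`.
#' @return data.frame with columns `variant_id`, `ratio`, `ratio_se`,
#'   `weight`, one row per usable instrument in input order.
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  d <- h$data
  usable <- d$beta_exposure != 0
  out <- data.frame(
    variant_id = d$variant_id[usable],
    ratio = d$beta_outcome[usable] / d$beta_exposure[usable],
    ratio_se = d$se_outcome[usable] / abs(d$beta_exposure[usable]),
    stringsAsFactors = FALSE)
  out$weight <- 1 / out$ratio_se^2
  attr(out, "excluded") <- d$variant_id[!usable]
  out
}

new_mr_estimate <- function(method, beta, se, pvalue, n_snp,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_,
                            model = NA_character_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
                 or_value = exp(beta), pvalue = pvalue, n_snp = n_snp,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_p = egger_intercept_p,
                 model = model),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: beta = %.4f (SE %.4f), OR = %.4f [%.4f, %.4f], p = %.3g, nSNP = %d\n",
    x$method, x$beta, x$se, x$or_value, exp(x$ci_low), exp(x$ci_high),
    x$pvalue, x$n_snp))
  if (x$method == "egger")
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, or_value = x$or_value, pvalue = x$pvalue,
             n_snp = x$n_snp, egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_p = x$egger_intercept_p,
             stringsAsFactors = FALSE)
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# Internal IVW workhorse shared by the estimator, Cochran's Q and
# leave-one-out: returns the fixed-effect weighted mean, its SE, Q and the
# model actually applied.
ivw_core <- function(ratio, weight, model = "auto") {
  k <- length(ratio)
  sw <- sum(weight)
  beta <- sum(weight * ratio) / sw
  se_fixed <- sqrt(1 / sw)
  q <- sum(weight * (ratio - beta)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  scale <- max(1, sqrt(q / (k - 1)))
  applied <- switch(model,
                    fixed = "fixed",
                    random = "random",
                    auto = if (q_p >= 0.05) "fixed" else "random")
  se <- if (applied == "random") se_fixed * scale else se_fixed
  list(beta = beta, se = se, se_fixed = se_fixed, q = q, q_df = k - 1,
       q_p = q_p, model = applied)
}

#' Inverse-variance weighted estimator
#'
#' Meta-analyses the per-variant Wald ratios with inverse-variance weights:
#' beta = sum(w * ratio) / sum(w). The fixed-effect SE is (sum w)^(-1/2); the
#' multiplicative random-effects SE scales it by max(1, sqrt(Q / (K - 1)))
#' where Q is Cochran's statistic. `model = "auto"` (the default) uses the
#' fixed-effect model when the Q test p-value is at least 0.05 and the
#' random-effects model otherwise. Requires at least two instruments; a
#' single instrument's Wald ratio should be reported directly instead.
#'
#' @param h a `harmonized_set`.
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return An `mr_estimate` with method `"ivw"`; the model actually applied
#'   is stored in its `model` field.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  w <- wald_ratios(h)
  if (nrow(w) < 2)
    stop_input("IVW requires at least 2 instruments; got ", nrow(w))
  core <- ivw_core(w$ratio, w$weight, model)
  new_mr_estimate("ivw", core$beta, core$se,
                  two_sided_p(core$beta / core$se), nrow(w),
                  model = core$model)
}

# Internal Egger workhorse: weighted least squares of beta_outcome on
# beta_exposure with a free intercept, rows oriented to beta_exposure >= 0,
# weights 1/se_outcome^2. Returns slope/intercept with SEs scaled by
# max(1, sqrt(Q'/(K-2))) (Rucker heterogeneity about the fitted line).
egger_core <- function(h) {
  d <- h$data
  flip <- d$beta_exposure < 0
  x <- ifelse(flip, -d$beta_exposure, d$beta_exposure)
  y <- ifelse(flip, -d$beta_outcome, d$beta_outcome)
  w <- 1 / d$se_outcome^2
  k <- length(x)
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= 0) stop_input("exposure effects are constant; Egger slope and ",
                           "intercept are not separable")
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  resid <- y - intercept - slope * x
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (k - 2)))
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sw / det) * scale,
       intercept_se = sqrt(sxx / det) * scale,
       q = q, q_df = k - 2, x = x, y = y, w = w, scale = scale)
}

#' MR-Egger regression estimator
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights 1/se_outcome^2), after orienting every instrument so
#' its exposure effect is non-negative. The slope estimates the causal
#' effect; a non-zero intercept indicates directional horizontal pleiotropy.
#' Slope and intercept SEs carry a multiplicative heterogeneity scaling
#' floored at 1, max(1, sqrt(Q' / (K - 2))). P-values use the standard
#' normal by default; set `dist = "t"` for the t reference with K - 2 df.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param dist reference distribution for p-values: `"normal"` (default) or
#'   `"t"`.
#' @return An `mr_estimate` with method `"egger"`, including the intercept
#'   estimate, its SE and p-value.
#' @export
mr_egger <- function(h, dist = c("normal", "t")) {
  dist <- match.arg(dist)
  if (nrow(h$data) < 3)
    stop_input("MR-Egger requires at least 3 instruments; got ", nrow(h$data))
  core <- egger_core(h)
  pfun <- if (dist == "t")
    function(z) 2 * stats::pt(-abs(z), df = core$q_df)
  else two_sided_p
  new_mr_estimate("egger", core$slope, core$slope_se,
                  pfun(core$slope / core$slope_se), nrow(h$data),
                  egger_intercept = core$intercept,
                  egger_intercept_se = core$intercept_se,
                  egger_intercept_p = pfun(core$intercept / core$intercept_se))
}

# Weighted median of ratio estimates: order ascending, form the
# half-weight-corrected cumulative weights, and interpolate linearly where
# they cross one half. Equal weights and odd K reduce to the sample median.
weighted_median_raw <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  if (any(s == 0.5)) return(r[which(s == 0.5)[1]])
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

boot_se <- function(ratio, ratio_se, n_boot, seed, statistic) {
  k <- length(ratio)
  with_seed(seed, {
    draws <- matrix(stats::rnorm(k * n_boot, mean = ratio, sd = ratio_se),
                    nrow = k)
    stats::sd(apply(draws, 2, statistic))
  })
}

#' Weighted median estimator
#'
#' Orders the Wald ratios and takes the value at which the cumulative
#' normalized inverse-variance weight crosses one half, interpolating
#' linearly between the bracketing ratios. Consistent when at least half the
#' weight comes from valid instruments. The SE comes from a parametric
#' bootstrap: each ratio is resampled from Normal(ratio_j, ratio_se_j), the
#' median is recomputed, and the SE is the standard deviation across
#' replicates.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  w <- wald_ratios(h)
  if (nrow(w) < 3)
    stop_input("weighted median requires at least 3 instruments; got ",
               nrow(w))
  beta <- weighted_median_raw(w$ratio, w$weight)
  se <- boot_se(w$ratio, w$ratio_se, n_boot, seed,
                function(r) weighted_median_raw(r, w$weight))
  new_mr_estimate("weighted_median", beta, se, two_sided_p(beta / se),
                  nrow(w))
}

# Kernel-mode of the ratio estimates: weighted Gaussian kernel density on a
# fixed 512-point grid spanning the ratios +- 3 bandwidths; bandwidth is a
# modified Silverman rule 0.9 * min(sd, mad) * K^(-1/5) (falling back to the
# sd when the mad degenerates to zero), times a user factor.
mode_bandwidth <- function(ratio, bandwidth_factor) {
  s <- stats::sd(ratio)
  m <- stats::mad(ratio)
  base <- 0.9 * min(s, if (m > 0) m else s) * length(ratio)^(-1 / 5)
  bandwidth_factor * base
}

mode_raw <- function(ratio, weight, bandwidth_factor = 1) {
  bw <- mode_bandwidth(ratio, bandwidth_factor)
  if (!is.finite(bw) || bw <= 0) {
    # all ratios (effectively) identical: the mode is that common value
    tab <- table(ratio)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512)
  wn <- weight / sum(weight)
  dens <- colSums(wn * stats::dnorm(outer(ratio, grid, "-") / bw)) / bw
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' Estimates the causal effect as the mode of the kernel-smoothed empirical
#' density of the Wald ratios: Gaussian kernel, bandwidth from a modified
#' Silverman rule times `bandwidth_factor`, argmax taken on a 512-point grid
#' spanning the ratios plus/minus three bandwidths. The simple mode weights
#' every ratio equally; the weighted mode uses inverse-variance weights. SEs
#' come from the same parametric bootstrap as the weighted median.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param weighted use inverse-variance weights in the density (`TRUE`) or
#'   equal weights (`FALSE`).
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  w <- wald_ratios(h)
  if (nrow(w) < 3)
    stop_input("mode estimator requires at least 3 instruments; got ",
               nrow(w))
  wt <- if (weighted) w$weight else rep(1, nrow(w))
  beta <- mode_raw(w$ratio, wt, bandwidth_factor)
  se <- boot_se(w$ratio, w$ratio_se, n_boot, seed,
                function(r) mode_raw(r, wt, bandwidth_factor))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, two_sided_p(beta / se), nrow(w))
}

MR_METHODS <- c("ivw", "egger", "simple_mode", "weighted_median",
                "weighted_mode")

#' Fit the five two-sample MR estimators
#'
#' The central fitting function: runs the inverse-variance weighted,
#' MR-Egger, simple mode, weighted median and weighted mode estimators on one
#' harmonized exposure-outcome instrument set and returns them as a classed
#' model object with `print`, `summary`, `coef`, `confint` and `plot`
#' methods. Stochastic components (the bootstrap SEs) are seeded per method
#' by a stable hash of the method name combined with `seed`, so a fit is
#' byte-identical across runs and does not depend on which methods are
#' requested. A method that fails (e.g. too few instruments) is recorded in
#' `$failures` rather than silently omitted.
#'
#' @param h a `harmonized_set` (at least 3 instruments for the full set of
#'   methods).
#' @param methods subset of `c("ivw", "egger", "simple_mode",
#'   "weighted_median", "weighted_mode")`, fitted in that canonical order.
#' @param seed integer seed governing all bootstrap randomness.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param ivw_model IVW model selection: `"auto"`, `"fixed"` or `"random"`.
#' @param bandwidth_factor bandwidth multiplier for the mode estimators.
#' @param egger_dist reference distribution for Egger p-values.
#' @return An object of class `mr_fit`: list with `estimates` (data.frame,
#'   one row per successful method), `failures` (named list of error
#'   messages), `harmonized` (the input set) and `seed`.
#' @examples
#' h <- harmonized_set(beta_exposure = c(0.1, 0.12, 0.08, 0.11),
#'                     se_exposure = rep(0.01, 4),
#'                     beta_outcome = c(0.021, 0.025, 0.015, 0.022),
#'                     se_outcome = rep(0.01, 4))
#' fit <- mr_fit(h, seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(h, methods = MR_METHODS, seed = 1, n_boot = 1000,
                   ivw_model = "auto", bandwidth_factor = 1,
                   egger_dist = "normal") {
  stopifnot(inherits(h, "harmonized_set"))
  methods <- match.arg(methods, MR_METHODS, several.ok = TRUE)
  methods <- MR_METHODS[MR_METHODS %in% methods]  # canonical order
  estimates <- list()
  failures <- list()
  for (m in methods) {
    mseed <- derive_seed(seed, m)
    res <- tryCatch(switch(m,
      ivw = mr_ivw(h, model = ivw_model),
      egger = mr_egger(h, dist = egger_dist),
      simple_mode = mr_mode(h, weighted = FALSE,
                            bandwidth_factor = bandwidth_factor,
                            n_boot = n_boot, seed = mseed),
      weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = mseed),
      weighted_mode = mr_mode(h, weighted = TRUE,
                              bandwidth_factor = bandwidth_factor,
                              n_boot = n_boot, seed = mseed)),
      error = function(e) e)
    if (inherits(res, "error")) failures[[m]] <- conditionMessage(res)
    else estimates[[m]] <- res
  }
  est_df <- if (length(estimates))
    do.call(rbind, lapply(estimates, as.data.frame)) else
    as.data.frame(new_mr_estimate("ivw", NA_real_, NA_real_, NA_real_,
                                  0L))[0, ]
  rownames(est_df) <- NULL
  structure(list(estimates = est_df, failures = failures, harmonized = h,
                 seed = seed, objects = estimates),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit: ", x$harmonized$exposure_id, " -> ",
      x$harmonized$outcome_id, " (", nrow(x$harmonized$data),
      " instruments)\n", sep = "")
  df <- x$estimates[c("method", "beta", "se", "or_value", "ci_low",
                      "ci_high", "pvalue", "n_snp")]
  df[-1] <- lapply(df[-1], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  if (length(x$failures))
    cat("Failed methods:",
        paste(names(x$failures), unlist(x$failures), sep = ": ",
              collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$estimates$beta - z * object$estimates$se,
               object$estimates$beta + z * object$estimates$se)
  dimnames(out) <- list(object$estimates$method,
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               " %"))
  out
}

#' Sensitivity summary of an MR fit
#'
#' Augments the estimate table with heterogeneity (Cochran's Q for IVW and
#' Egger), the Egger intercept test of directional pleiotropy, and the
#' leave-one-out stability flag.
#'
#' @param object an `mr_fit`.
#' @param ... unused.
#' @return An object of class `summary.mr_fit`.
#' @export
summary.mr_fit <- function(object, ...) {
  h <- object$harmonized
  k <- nrow(h$data)
  het <- if (k >= 2)
    rbind(as.data.frame(cochran_q(h, "ivw")),
          if (k >= 3) as.data.frame(cochran_q(h, "egger"))) else NULL
  pleio <- if (k >= 3) egger_intercept_test(h) else NULL
  loo <- if (k >= 3) leave_one_out(h) else NULL
  structure(list(fit = object, heterogeneity = het, pleiotropy = pleio,
                 loo = loo), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$heterogeneity)) {
    cat("\nHeterogeneity (Cochran's Q):\n")
    print(x$heterogeneity, row.names = FALSE)
  }
  if (!is.null(x$pleiotropy)) {
    cat(sprintf("\nEgger intercept: %.4f (SE %.4f), p = %.3g\n",
                x$pleiotropy$intercept, x$pleiotropy$se, x$pleiotropy$pvalue))
  }
  if (!is.null(x$loo))
    cat("Leave-one-out stable:", x$loo$stable, "\n")
  invisible(x)
}

#' Scatter plot of instrument effects with fitted method lines
#'
#' Plots per-variant exposure effects against outcome effects (oriented to
#' non-negative exposure effects) with one fitted line per estimator: slope
#' through the origin for IVW, median, and mode methods; slope plus intercept
#' for MR-Egger.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot()].
#' @return The plotted per-variant data, invisibly (see
#'   [mr_scatter_data()]).
#' @export
plot.mr_fit <- function(x, ...) {
  sc <- mr_scatter_data(x)
  d <- sc$points
  graphics::plot(d$beta_exposure, d$beta_outcome,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::arrows(d$beta_exposure, d$beta_outcome - d$se_outcome,
                   d$beta_exposure, d$beta_outcome + d$se_outcome,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  for (i in seq_len(nrow(sc$lines)))
    graphics::abline(sc$lines$intercept[i], sc$lines$slope[i], col = i + 1)
  graphics::legend("topleft", legend = sc$lines$method,
                   col = seq_len(nrow(sc$lines)) + 1, lty = 1, cex = 0.8)
  invisible(sc)
}

#' Tabular data behind the MR scatter plot
#'
#' @param fit an `mr_fit`.
#' @return list with `points` (oriented per-variant effects and SEs) and
#'   `lines` (per-method slope and intercept).
#' @export
mr_scatter_data <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  d <- fit$harmonized$data
  flip <- d$beta_exposure < 0
  pts <- data.frame(variant_id = d$variant_id,
                    beta_exposure = ifelse(flip, -d$beta_exposure,
                                           d$beta_exposure),
                    beta_outcome = ifelse(flip, -d$beta_outcome,
                                          d$beta_outcome),
                    se_exposure = d$se_exposure,
                    se_outcome = d$se_outcome, stringsAsFactors = FALSE)
  est <- fit$estimates
  lines <- data.frame(method = est$method, slope = est$beta,
                      intercept = ifelse(est$method == "egger",
                                         est$egger_intercept, 0),
                      stringsAsFactors = FALSE)
  list(points = pts, lines = lines)
}
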