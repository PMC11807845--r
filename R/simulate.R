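# Synthetic paired GWAS summary statistics with known causal structure.
#
# The generator works on the z-score scale: a variant tagging an index
# variant at correlation r inherits r times its noncentrality, which is the
# exact marginal relation for standardized genotypes and makes LD clumping
# meaningful. Observed noise is correlated within LD blocks (AR(1)) and
# independent between the exposure and outcome samples (two-sample design).

#' Simulation configuration
#'
#' Defines the conditions of a synthetic two-sample MR study. Variants are
#' organized into LD blocks with AR(1) correlation `ld_rho`; the first
#' variant of each of the first `n_instruments` blocks is a true instrument
#' with exposure effect drawn from Normal(`gamma_mean`, `gamma_sd`^2). A
#' fraction `prop_invalid` of instruments receives a direct (pleiotropic)
#' outcome effect drawn from Normal(`alpha_mean`, `alpha_sd`^2); `alpha_mean
#' = 0` gives balanced pleiotropy, non-zero values directional pleiotropy,
#' and the draws are independent of instrument strength (InSIDE holds unless
#' `pleiotropy_correlated` is set). Per-variant standard errors follow
#' 1/sqrt(2 N eaf (1-eaf)) with eaf ~ Uniform(0.05, 0.95). A non-zero
#' `reverse_theta` plants instruments for the outcome (in the last blocks)
#' whose effects propagate back to the exposure. Allele frames are perturbed
#' with palindromic variants (probability `p_palindromic`) and swapped
#' outcome allele order (probability `p_allele_swap`) to exercise
#' harmonization.
#'
#' @param m_variants total variants (default 240).
#' @param n_blocks LD blocks (default 30); must be at least `n_instruments`
#'   (twice that when `reverse_theta` is non-zero).
#' @param ld_rho within-block AR(1) correlation in \[0, 1) (default 0.8).
#' @param n_exposure,n_outcome GWAS sample sizes (default 30000 each, so the
#'   first-order Wald-ratio SE is accurate for moderate causal effects).
#' @param theta true causal effect of exposure on outcome (log-odds per
#'   exposure SD; default 0).
#' @param n_instruments number of true instruments (default 30).
#' @param gamma_mean,gamma_sd instrument effect distribution (defaults 0.08
#'   and 0.04: per-SNP F-statistics mostly in the tens to low hundreds, with
#'   enough spread for Egger's slope and intercept to be separable).
#' @param prop_invalid fraction of instruments with a direct outcome effect.
#' @param alpha_mean,alpha_sd pleiotropic direct-effect distribution
#'   (defaults 0 and 0.01).
#' @param reverse_theta true outcome-to-exposure effect (default 0).
#' @param p_palindromic probability a variant is A/T or C/G (default 0.05).
#' @param p_allele_swap probability the outcome lists the alleles in swapped
#'   order (default 0.2).
#' @param pleiotropy_correlated if `TRUE`, pleiotropic effects are
#'   proportional in sign to instrument strength, violating InSIDE (stress
#'   test; default `FALSE`).
#' @param seed integer seed.
#' @return An object of class `sim_config` (validated list of the above).
#' @export
sim_config <- function(m_variants = 240, n_blocks = 30, ld_rho = 0.8,
                       n_exposure = 30000, n_outcome = 30000, theta = 0,
                       n_instruments = 30, gamma_mean = 0.08,
                       gamma_sd = 0.04, prop_invalid = 0, alpha_mean = 0,
                       alpha_sd = 0.01, reverse_theta = 0,
                       p_palindromic = 0.05, p_allele_swap = 0.2,
                       pleiotropy_correlated = FALSE, seed = 1) {
  cfg <- as.list(environment())
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(m_variants >= 1, "m_variants must be >= 1")
  chk(n_blocks >= 1 && n_blocks <= m_variants,
      "n_blocks must be in [1, m_variants]")
  chk(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0, 1)")
  chk(n_exposure > 1 && n_outcome > 1, "sample sizes must exceed 1")
  chk(n_instruments >= 1 && n_instruments <= m_variants,
      "n_instruments must be in [1, m_variants]")
  chk(n_instruments <= n_blocks,
      "n_instruments must not exceed n_blocks (one instrument per block)")
  chk(reverse_theta == 0 || 2 * n_instruments <= n_blocks,
      "bidirectional simulation needs n_blocks >= 2 * n_instruments")
  chk(prop_invalid >= 0 && prop_invalid <= 1,
      "prop_invalid must be in [0, 1]")
  chk(gamma_sd >= 0 && alpha_sd >= 0, "effect SDs must be non-negative")
  chk(p_palindromic >= 0 && p_palindromic <= 1,
      "p_palindromic must be in [0, 1]")
  chk(p_allele_swap >= 0 && p_allele_swap <= 1,
      "p_allele_swap must be in [0, 1]")
  if (length(problems))
    stop_input("invalid simulation configuration:\n  ",
               paste(problems, collapse = "\n  "))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation: %d variants in %d AR(1) blocks (rho = %g), theta = %g\n",
    x$m_variants, x$n_blocks, x$ld_rho, x$theta))
  cat(sprintf(
    "  %d instruments, gamma ~ N(%g, %g^2), %.0f%% invalid (alpha ~ N(%g, %g^2))\n",
    x$n_instruments, x$gamma_mean, x$gamma_sd, 100 * x$prop_invalid,
    x$alpha_mean, x$alpha_sd))
  invisible(x)
}

NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                         "G","A", "G","T", "T","C", "T","G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                    ncol = 2, byrow = TRUE)

#' Simulate one exposure/outcome summary-statistics pair
#'
#' Generates GWAS summary statistics for an exposure and an outcome with the
#' causal structure described in [sim_config()], plus the LD matrix and the
#' generating truth. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param id_prefix prefix for variant ids (default `"rs"`), letting batch
#'   simulations keep disjoint variant namespaces.
#' @param exposure_id,outcome_id trait labels.
#' @return An object of class `mr_simulation`: list with `exposure` and
#'   `outcome` ([sumstats]), `ld` ([ld_matrix]) and `truth` (list with
#'   `theta`, `instrument_ids`, `invalid_ids`, `alpha_by_id`, `gamma_by_id`,
#'   `reverse_theta`, `outcome_instrument_ids`).
#' @export
simulate_pair <- function(cfg, id_prefix = "rs", exposure_id = "exposure",
                          outcome_id = "outcome") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$m_variants
    block <- sort(rep_len(seq_len(cfg$n_blocks), m))
    offset <- stats::ave(seq_len(m), block, FUN = seq_along) - 1L
    chr <- as.character(((block - 1L) %% 22L) + 1L)
    slot <- (block - 1L) %/% 22L
    pos <- slot * 20000000L + offset * 10000L + 1L
    ids <- sprintf("%s%04d", id_prefix, seq_len(m))

    eaf <- stats::runif(m, 0.05, 0.95)
    se_x <- 1 / sqrt(2 * cfg$n_exposure * eaf * (1 - eaf))
    se_y <- 1 / sqrt(2 * cfg$n_outcome * eaf * (1 - eaf))

    # exposure instruments: first variant of the first n_instruments blocks
    inst_block <- seq_len(cfg$n_instruments)
    inst_idx <- match(inst_block, block)
    gamma <- stats::rnorm(cfg$n_instruments, cfg$gamma_mean, cfg$gamma_sd)
    n_inv <- round(cfg$prop_invalid * cfg$n_instruments)
    inv_sel <- if (n_inv > 0) sample(cfg$n_instruments, n_inv) else integer()
    alpha <- numeric(cfg$n_instruments)
    if (n_inv > 0) {
      a <- stats::rnorm(n_inv, cfg$alpha_mean, cfg$alpha_sd)
      if (cfg$pleiotropy_correlated)
        a <- abs(a) * sign(gamma[inv_sel] - cfg$gamma_mean)
      alpha[inv_sel] <- a
    }

    # outcome instruments (reverse direction), placed in the last blocks
    rev_block <- if (cfg$reverse_theta != 0)
      seq(cfg$n_blocks - cfg$n_instruments + 1L, cfg$n_blocks) else integer()
    rev_idx <- match(rev_block, block)
    gamma_rev <- if (length(rev_block))
      stats::rnorm(length(rev_block), cfg$gamma_mean, cfg$gamma_sd) else
      numeric()

    # noncentrality (z-scale) per variant: tags inherit r times the index ncp
    r_to_index <- cfg$ld_rho^offset
    ncp_x <- numeric(m); ncp_y <- numeric(m)
    for (b in seq_along(inst_block)) {
      in_b <- block == inst_block[b]
      i <- inst_idx[b]
      ncp_x[in_b] <- r_to_index[in_b] * gamma[b] / se_x[i]
      ncp_y[in_b] <- r_to_index[in_b] *
        (cfg$theta * gamma[b] + alpha[b]) / se_y[i]
    }
    for (b in seq_along(rev_block)) {
      in_b <- block == rev_block[b]
      i <- rev_idx[b]
      ncp_y[in_b] <- ncp_y[in_b] + r_to_index[in_b] * gamma_rev[b] / se_y[i]
      ncp_x[in_b] <- ncp_x[in_b] +
        r_to_index[in_b] * cfg$reverse_theta * gamma_rev[b] / se_x[i]
    }

    # within-block correlated noise, independent between the two samples
    chol_cache <- list()
    block_chol <- function(size) {
      key <- as.character(size)
      if (is.null(chol_cache[[key]])) {
        R <- cfg$ld_rho^abs(outer(seq_len(size), seq_len(size), "-"))
        chol_cache[[key]] <<- chol(R)
      }
      chol_cache[[key]]
    }
    z_x <- numeric(m); z_y <- numeric(m)
    for (b in seq_len(cfg$n_blocks)) {
      in_b <- which(block == b)
      U <- block_chol(length(in_b))
      z_x[in_b] <- ncp_x[in_b] + crossprod(U, stats::rnorm(length(in_b)))
      z_y[in_b] <- ncp_y[in_b] + crossprod(U, stats::rnorm(length(in_b)))
    }
    beta_x <- z_x * se_x
    beta_y <- z_y * se_y

    # allele frames
    pal <- stats::runif(m) < cfg$p_palindromic
    pal_idx <- sample.int(4L, m, replace = TRUE)
    np_idx <- sample.int(8L, m, replace = TRUE)
    ea <- ifelse(pal, PAL_PAIRS[pal_idx, 1], NONPAL_PAIRS[np_idx, 1])
    oa <- ifelse(pal, PAL_PAIRS[pal_idx, 2], NONPAL_PAIRS[np_idx, 2])

    swap <- stats::runif(m) < cfg$p_allele_swap
    ea_y <- ifelse(swap, oa, ea)
    oa_y <- ifelse(swap, ea, oa)
    beta_y_out <- ifelse(swap, -beta_y, beta_y)
    eaf_y <- ifelse(swap, 1 - eaf, eaf)

    exposure <- sumstats(data.frame(
      variant_id = ids, chromosome = chr, position = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta_x,
      se = se_x, pvalue = pmax(two_sided_p(z_x), 1e-320),
      n = cfg$n_exposure, stringsAsFactors = FALSE), exposure_id)
    outcome <- sumstats(data.frame(
      variant_id = ids, chromosome = chr, position = pos,
      effect_allele = ea_y, other_allele = oa_y, eaf = eaf_y,
      beta = beta_y_out, se = se_y,
      pvalue = pmax(two_sided_p(z_y), 1e-320),
      n = cfg$n_outcome, stringsAsFactors = FALSE), outcome_id)

    r2 <- matrix(0, m, m)
    for (b in seq_len(cfg$n_blocks)) {
      in_b <- which(block == b)
      r <- cfg$ld_rho^abs(outer(offset[in_b], offset[in_b], "-"))
      r2[in_b, in_b] <- r * r
    }
    diag(r2) <- 1
    ld <- ld_matrix(r2, ids, positions = pos)

    truth <- list(theta = cfg$theta,
                  instrument_ids = ids[inst_idx],
                  invalid_ids = ids[inst_idx][inv_sel],
                  alpha_by_id = stats::setNames(alpha, ids[inst_idx]),
                  gamma_by_id = stats::setNames(gamma, ids[inst_idx]),
                  reverse_theta = cfg$reverse_theta,
                  outcome_instrument_ids = ids[rev_idx])
    structure(list(exposure = exposure, outcome = outcome, ld = ld,
                   truth = truth, cfg = cfg), class = "mr_simulation")
  })
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat("Simulated summary-statistics pair: theta =", x$truth$theta, "with",
      length(x$truth$instrument_ids), "instruments (",
      length(x$truth$invalid_ids), "invalid )\n")
  invisible(x)
}

#' Simulate a batch of exposures sharing one outcome
#'
#' Builds `n_exposures` independent exposure panels (disjoint variant
#' namespaces) against a single concatenated outcome trait, with per-exposure
#' true causal effects given by `theta`. Used to exercise [screen_many()]
#' with planted effects among nulls.
#'
#' @param n_exposures number of exposures.
#' @param theta numeric vector of true effects, recycled to `n_exposures`.
#' @param cfg base [sim_config()]; each exposure uses a seed derived from
#'   `cfg$seed` and its id.
#' @param outcome_id label for the shared outcome trait.
#' @return list with `exposures` (list of [sumstats]), `outcome`
#'   ([sumstats]), `ld` (named list of [ld_matrix]) and `truth` (named list
#'   per exposure).
#' @export
simulate_batch <- function(n_exposures, theta = 0, cfg = sim_config(),
                           outcome_id = "outcome") {
  stopifnot(n_exposures >= 1)
  theta <- rep_len(theta, n_exposures)
  exposure_ids <- sprintf("EXP%03d", seq_len(n_exposures))
  sims <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    cfg_i <- cfg
    cfg_i$theta <- theta[i]
    cfg_i$seed <- derive_seed(cfg$seed, exposure_ids[i])
    sims[[i]] <- simulate_pair(cfg_i, id_prefix = sprintf("e%03d_v", i),
                               exposure_id = exposure_ids[i],
                               outcome_id = outcome_id)
  }
  outcome_records <- do.call(rbind, lapply(sims, function(s)
    s$outcome$records))
  outcome <- sumstats(outcome_records, outcome_id)
  list(exposures = lapply(sims, `[[`, "exposure"),
       outcome = outcome,
       ld = stats::setNames(lapply(sims, `[[`, "ld"), exposure_ids),
       truth = stats::setNames(lapply(sims, `[[`, "truth"), exposure_ids))
}

#' Monte-Carlo recovery experiment
#'
#' Repeats the simulate -> select -> clump -> filter -> harmonize ->
#' estimate pipeline `n_reps` times with per-replicate derived seeds and
#' aggregates, per estimator: mean estimate, bias, RMSE, empirical SE, mean
#' model SE, 95% CI coverage of the true effect, and rejection rate at the
#' 0.05 level. Per-replicate heterogeneity and Egger-intercept diagnostics
#' are kept in `$diagnostics` so calibration of the Q and intercept tests
#' can be assessed from the same object.
#'
#' @param cfg a [sim_config()] defining the study conditions.
#' @param n_reps number of replicates (>= 1).
#' @param methods estimators to run (default all five).
#' @param n_boot bootstrap replicates for median/mode SEs; default 200,
#'   enough for stable SEs at Monte-Carlo scale.
#' @param p_threshold instrument selection threshold (default 5e-6).
#' @param f_min weak-instrument cutoff applied after clumping.
#' @return An object of class `mr_recovery`: list with `summary` (one row
#'   per method), `reps` (long per-replicate estimates), `diagnostics`
#'   (per-replicate Q and intercept tests) and `n_failed` (replicates with
#'   fewer than 3 usable instruments).
#' @export
recovery_experiment <- function(cfg, n_reps, methods = MR_METHODS,
                                n_boot = 200, p_threshold = 5e-6,
                                f_min = 10) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  reps <- vector("list", n_reps)
  diags <- vector("list", n_reps)
  n_failed <- 0L
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(cfg$seed, paste0("rep", i))
    cfg_i <- cfg
    cfg_i$seed <- rep_seed
    sim <- simulate_pair(cfg_i)
    ids <- select_by_pvalue(sim$exposure, p_threshold)
    if (length(ids) >= 1) {
      ids <- ld_clump(ids, sim$ld, sim$exposure)
      if (f_min > 0) {
        st <- instrument_strength(sim$exposure, ids)
        ids <- st$variant_id[st$f_stat >= f_min]
      }
    }
    h <- if (length(ids) >= 1)
      tryCatch(harmonize(sim$exposure, sim$outcome, ids),
               error = function(e) NULL) else NULL
    if (is.null(h) || nrow(h$data) < 3) { n_failed <- n_failed + 1L; next }
    fit <- mr_fit(h, methods = methods, seed = rep_seed, n_boot = n_boot)
    est <- fit$estimates
    if (!nrow(est)) { n_failed <- n_failed + 1L; next }
    est$rep <- i
    est$covered <- est$ci_low <= cfg$theta & cfg$theta <= est$ci_high
    est$reject <- est$pvalue < 0.05
    reps[[i]] <- est
    q1 <- cochran_q(h, "ivw")
    q2 <- cochran_q(h, "egger")
    pl <- egger_intercept_test(h)
    diags[[i]] <- data.frame(rep = i, k = nrow(h$data),
                             q_ivw = q1$q, q_ivw_df = q1$df,
                             q_ivw_p = q1$pvalue,
                             q_egger = q2$q, q_egger_p = q2$pvalue,
                             egger_intercept = pl$intercept,
                             egger_intercept_p = pl$pvalue)
  }
  reps_df <- do.call(rbind, reps)
  diags_df <- do.call(rbind, diags)
  summary_df <- if (!is.null(reps_df)) {
    do.call(rbind, lapply(split(reps_df, reps_df$method), function(d) {
      data.frame(method = d$method[1],
                 n_reps = nrow(d),
                 mean_estimate = mean(d$beta),
                 bias = mean(d$beta) - cfg$theta,
                 rmse = sqrt(mean((d$beta - cfg$theta)^2)),
                 empirical_se = stats::sd(d$beta),
                 mean_se = mean(d$se),
                 coverage = mean(d$covered),
                 rejection_rate = mean(d$reject),
                 mean_k = mean(d$n_snp),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (!is.null(summary_df)) {
    summary_df <- summary_df[order(match(summary_df$method, MR_METHODS)), ]
    rownames(summary_df) <- NULL
  }
  structure(list(summary = summary_df, reps = reps_df,
                 diagnostics = diags_df, truth_theta = cfg$theta,
                 n_reps = n_reps, n_failed = n_failed, cfg = cfg),
            class = "mr_recovery")
}

#' @export
print.mr_recovery <- function(x, digits = 4, ...) {
  cat("Recovery experiment:", x$n_reps, "replicates, true theta =",
      x$truth_theta, "\n")
  if (x$n_failed) cat(" ", x$n_failed, "replicates lacked instruments\n")
  if (!is.null(x$summary)) {
    df <- x$summary
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
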