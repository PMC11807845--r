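test_that("Wald ratios follow their closed form and sign symmetry", {
  h <- harmonized_set(beta_exposure = c(1, 2), se_exposure = c(0.1, 0.1),
                      beta_outcome = c(0.5, 1.2), se_outcome = c(0.1, 0.2))
  w <- wald_ratios(h)
  expect_equal(w$ratio, c(0.5, 0.6))
  expect_equal(w$ratio_se, c(0.1, 0.1))
  expect_equal(w$weight, c(100, 100))

  h_neg <- harmonized_set(-c(1, 2), c(0.1, 0.1), -c(0.5, 1.2), c(0.1, 0.2))
  expect_equal(wald_ratios(h_neg)$ratio, w$ratio)

  h0 <- harmonized_set(c(1, 0), c(0.1, 0.1), c(0.5, 0.2), c(0.1, 0.1))
  w0 <- wald_ratios(h0)
  expect_equal(nrow(w0), 1L)
  expect_equal(attr(w0, "excluded"), "snp_2")
})

test_that("IVW is the inverse-variance weighted mean with the stated SEs", {
  h <- harmonized_set(c(1, 2), c(0.1, 0.1), c(0.5, 1.2), c(0.1, 0.2))
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$beta, 0.55)
  expect_equal(est$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(est$or_value, exp(0.55), tolerance = 1e-12)
  expect_equal(est$ci_low, 0.55 - 1.96 * est$se)

  # identical ratios: Q = 0, fixed and random coincide
  h_eq <- harmonized_set(c(1, 1, 1), rep(0.1, 3), c(0.4, 0.4, 0.4),
                         rep(0.1, 3))
  expect_equal(mr_ivw(h_eq, "fixed")$beta, 0.4)
  expect_equal(mr_ivw(h_eq, "random")$se, mr_ivw(h_eq, "fixed")$se)

  # a single instrument is a contract violation, not a silent fallback
  h1 <- harmonized_set(1, 0.1, 0.5, 0.1)
  expect_error(mr_ivw(h1), "at least 2")
  expect_equal(wald_ratios(h1)$ratio, 0.5)
})

test_that("IVW equals the zero-intercept weighted regression slope", {
  for (seed in 1:20) {
    h <- random_hset(k = sample(5:30, 1), seed = seed)
    est <- mr_ivw(h, model = "fixed")
    d <- h$data
    fitlm <- lm(beta_outcome ~ beta_exposure - 1, data = d,
                weights = 1 / d$se_outcome^2)
    expect_equal(est$beta, unname(coef(fitlm)), tolerance = 1e-10)
    w <- wald_ratios(h)
    expect_equal(est$beta, oracle_ivw(w$ratio, w$weight)$beta,
                 tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact line and is orientation invariant", {
  h <- harmonized_set(c(1, 2, 3), rep(0.1, 3), c(0.3, 0.5, 0.7), rep(0.1, 3))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(cochran_q(h, "egger")$q, 0, tolerance = 1e-18)

  # flipping the sign of any (bx, by) pair changes nothing but the
  # intercept's sign is preserved by the bx >= 0 orientation
  h_flip <- harmonized_set(c(1, -2, 3), rep(0.1, 3), c(0.3, -0.5, 0.7),
                           rep(0.1, 3))
  est_flip <- mr_egger(h_flip)
  expect_equal(est_flip$beta, est$beta, tolerance = 1e-12)
  expect_equal(est_flip$egger_intercept, est$egger_intercept,
               tolerance = 1e-12)

  expect_error(mr_egger(harmonized_set(c(1, 2), c(.1, .1), c(.1, .2),
                                       c(.1, .1))), "at least 3")
  # constant exposure effects leave slope/intercept inseparable
  expect_error(mr_egger(harmonized_set(c(1, 1, 1), rep(.1, 3),
                                       c(.1, .2, .3), rep(.1, 3))),
               "separable")
})

test_that("Egger intercept recovers planted directional pleiotropy", {
  cfg <- sim_config(n_instruments = 100, n_blocks = 100, m_variants = 400,
                    theta = 0.1, prop_invalid = 1, alpha_mean = 0.05,
                    alpha_sd = 0.01, p_palindromic = 0, seed = 21)
  sim <- simulate_pair(cfg)
  h <- harmonize(sim$exposure, sim$outcome, sim$truth$instrument_ids)
  est <- mr_egger(h)
  expect_equal(est$egger_intercept, 0.05, tolerance = 0.35)
  expect_lt(est$egger_intercept_p, 0.05)
})

test_that("weighted median matches the cumulative-weight oracle", {
  h <- harmonized_set(c(1, 1, 1), rep(0.1, 3), c(0.4, 0.5, 0.9), rep(0.1, 3))
  est <- mr_weighted_median(h, n_boot = 100, seed = 5)
  expect_equal(est$beta, 0.5)  # ordinary median under equal weights

  # unequal weights: interpolate the half-weight crossing
  ratio <- c(0.4, 0.5, 0.9)
  weight <- c(1, 1, 8)
  got <- mrscreen:::weighted_median_raw(ratio, weight)
  expect_equal(got, oracle_weighted_median(ratio, weight), tolerance = 1e-12)

  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:25, 1)
    r <- rnorm(k); w <- runif(k, 0.1, 10)
    expect_equal(mrscreen:::weighted_median_raw(r, w),
                 oracle_weighted_median(r, w), tolerance = 1e-12)
    if (k %% 2 == 1)
      expect_equal(mrscreen:::weighted_median_raw(r, rep(1, k)), median(r))
  }

  # determinism: same seed, same bootstrap SE
  e1 <- mr_weighted_median(h, n_boot = 200, seed = 11)
  e2 <- mr_weighted_median(h, n_boot = 200, seed = 11)
  e3 <- mr_weighted_median(h, n_boot = 2000, seed = 99)
  expect_identical(e1$se, e2$se)
  expect_equal(e1$se, e3$se, tolerance = 0.5)  # Monte-Carlo agreement
})

test_that("mode estimators find the majority cluster", {
  h <- harmonized_set(rep(1, 4), rep(0.1, 4), c(0.5, 0.5, 0.5, 2.0),
                      rep(0.1, 4))
  est <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 3)
  expect_equal(est$beta, 0.5, tolerance = 0.05)

  # fine-grid brute-force oracle at the same bandwidth
  bw <- mrscreen:::mode_bandwidth(c(0.5, 0.5, 0.5, 2.0), 1)
  expect_equal(est$beta,
               oracle_mode(c(0.5, 0.5, 0.5, 2.0), rep(1, 4), bw),
               tolerance = 0.01)

  # all ratios equal: the estimate is that value for any bandwidth
  h_eq <- harmonized_set(rep(1, 3), rep(0.1, 3), rep(0.7, 3), rep(0.1, 3))
  for (bf in c(0.3, 1, 3))
    expect_equal(mr_mode(h_eq, bandwidth_factor = bf, n_boot = 10,
                         seed = 1)$beta, 0.7)

  # equal weights make the weighted and simple modes coincide
  h2 <- harmonized_set(rep(1, 5), rep(0.1, 5), c(0.2, 0.25, 0.3, 0.31, 0.9),
                       rep(0.1, 5))
  expect_equal(mr_mode(h2, weighted = TRUE, n_boot = 10, seed = 1)$beta,
               mr_mode(h2, weighted = FALSE, n_boot = 10, seed = 1)$beta)
})

test_that("mr_fit runs the five methods in canonical order, reproducibly", {
  h <- random_hset(12, seed = 77, theta = 0.15)
  fit1 <- mr_fit(h, seed = 42, n_boot = 100)
  fit2 <- mr_fit(h, seed = 42, n_boot = 100)
  expect_identical(fit1$estimates, fit2$estimates)
  expect_equal(fit1$estimates$method,
               c("ivw", "egger", "simple_mode", "weighted_median",
                 "weighted_mode"))
  expect_equal(fit1$estimates$or_value, exp(fit1$estimates$beta),
               tolerance = 1e-12)
  expect_true(all(fit1$estimates$ci_low < fit1$estimates$ci_high))

  # a fit on a method subset reproduces the full fit's rows (seeds are
  # derived per method, not from the call sequence)
  fit_sub <- mr_fit(h, methods = c("weighted_median"), seed = 42,
                    n_boot = 100)
  expect_identical(
    fit_sub$estimates,
    fit1$estimates[fit1$estimates$method == "weighted_median", ],
    ignore_attr = TRUE)

  expect_named(coef(fit1), fit1$estimates$method)
  ci <- confint(fit1)
  expect_equal(unname(ci[, 1]), fit1$estimates$beta -
                 qnorm(0.975) * fit1$estimates$se, tolerance = 1e-12)

  # failures are recorded, not silently dropped
  h2 <- harmonized_set(c(1, 2), c(.1, .1), c(.2, .5), c(.1, .1))
  fit_small <- mr_fit(h2, seed = 1, n_boot = 10)
  expect_equal(sort(names(fit_small$failures)),
               sort(c("egger", "simple_mode", "weighted_median",
                      "weighted_mode")))
  expect_equal(fit_small$estimates$method, "ivw")
})

test_that("null and causal simulations are recovered with the right sign", {
  # theta = 0: all five estimates within 3 SE of zero
  sim0 <- simulate_pair(sim_config(theta = 0, n_instruments = 50,
                                   n_blocks = 50, m_variants = 300,
                                   p_palindromic = 0, seed = 8))
  h0 <- harmonize(sim0$exposure, sim0$outcome, sim0$truth$instrument_ids)
  fit0 <- mr_fit(h0, seed = 2, n_boot = 200)
  expect_true(all(abs(fit0$estimates$beta) < 3 * fit0$estimates$se))

  # theta = 0.2: all five odds ratios exceed 1
  sim1 <- simulate_pair(sim_config(theta = 0.2, n_instruments = 50,
                                   n_blocks = 50, m_variants = 300,
                                   p_palindromic = 0, seed = 9))
  h1 <- harmonize(sim1$exposure, sim1$outcome, sim1$truth$instrument_ids)
  fit1 <- mr_fit(h1, seed = 2, n_boot = 200)
  expect_true(all(fit1$estimates$or_value > 1))
})

test_that("scatter data exposes oriented points and per-method lines", {
  h <- random_hset(8, seed = 3)
  fit <- mr_fit(h, seed = 1, n_boot = 50)
  sc <- mr_scatter_data(fit)
  expect_true(all(sc$points$beta_exposure >= 0))
  expect_equal(nrow(sc$lines), 5L)
  expect_equal(sc$lines$intercept[sc$lines$method != "egger"], rep(0, 4))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); on.exit(grDevices::dev.off(), add = TRUE)
  expect_no_error(plot(fit))
})
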