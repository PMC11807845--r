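# Independent oracle implementations and fixture builders used across the
# suite. These deliberately avoid the package's internal code paths.

# Build a small sumstats data.frame with sensible defaults.
toy_records <- function(variant_id, beta, se, pvalue,
                        chromosome = "1",
                        position = seq_along(variant_id) * 1000L,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, n = 20000) {
  data.frame(variant_id = variant_id, chromosome = chromosome,
             position = position, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

# Random harmonized instrument set (valid instruments, no pleiotropy).
random_hset <- function(k, seed, theta = 0.1) {
  set.seed(seed)
  bx <- rnorm(k, 0.1, 0.03)
  sx <- runif(k, 0.005, 0.02)
  sy <- runif(k, 0.005, 0.02)
  by <- theta * bx + rnorm(k, 0, sy)
  harmonized_set(bx, sx, by, sy)
}

# Weighted-median oracle: explicit scan of the half-weight crossing.
oracle_weighted_median <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  for (i in seq_along(s)) {
    if (s[i] == 0.5) return(r[i])
    if (i > 1 && s[i - 1] < 0.5 && s[i] > 0.5)
      return(r[i - 1] + (r[i] - r[i - 1]) * (0.5 - s[i - 1]) /
               (s[i] - s[i - 1]))
  }
  stop("oracle failed")
}

# Kernel-mode oracle: brute-force density maximization on a very fine grid.
oracle_mode <- function(ratio, weight, bw, n_grid = 20001) {
  wn <- weight / sum(weight)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g)
    sum(wn * exp(-0.5 * ((g - ratio) / bw)^2)), numeric(1))
  grid[which.max(dens)]
}

# IVW oracle: plain weighted mean of ratios.
oracle_ivw <- function(ratio, weight) {
  list(beta = sum(weight * ratio) / sum(weight),
       se_fixed = sqrt(1 / sum(weight)))
}
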