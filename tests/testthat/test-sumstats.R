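test_that("well-formed rows load as-is and invalid rows are counted", {
  df <- toy_records(c("rs1", "rs2", "rs3"), beta = c(0.05, -0.02, 0.1),
                    se = c(0.008, 0.01, 0.02), pvalue = c(4e-10, 0.05, 1e-6))
  ss <- sumstats(df, "trait")
  expect_s3_class(ss, "sumstats")
  expect_equal(nvariants(ss), 3L)
  expect_equal(ss$records$beta, df$beta)
  expect_equal(nrow(ss$load_report), 0L)

  df$se[2] <- 0
  ss2 <- sumstats(df, "trait")
  expect_equal(nvariants(ss2), 2L)
  expect_equal(ss2$load_report$reason, "invalid_se")
  expect_equal(ss2$load_report$count, 1L)

  df$variant_id[3] <- "rs1"
  ss3 <- sumstats(df, "trait")
  expect_true("duplicate_id" %in% ss3$load_report$reason)
})

test_that("missing mandatory columns and empty files raise clear errors", {
  df <- toy_records("rs1", 0.1, 0.01, 1e-5)
  expect_error(sumstats(df[setdiff(names(df), "beta")], "t"),
               "mandatory column")
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  expect_error(read_sumstats(path), "empty")
})

test_that("write/read round-trip is the identity at full precision", {
  set.seed(4)
  df <- toy_records(sprintf("rs%d", 1:20), beta = rnorm(20, 0, 0.05),
                    se = runif(20, 1e-4, 0.02),
                    pvalue = 10^runif(20, -30, -0.001),
                    eaf = runif(20), n = sample(1e4:1e6, 20))
  df$eaf[1] <- 1 / 3  # non-terminating decimal exercises precision
  ss <- sumstats(df, "trait")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path, trait_id = "trait")
  expect_equal(back$records, ss$records, tolerance = 1e-14)
  expect_true(abs(back$records$eaf[1] - 1 / 3) < 1e-12)
})

test_that("empty record sets write a header-only file", {
  ss <- sumstats(toy_records(character(), numeric(), numeric(), numeric(),
                             chromosome = character(),
                             position = integer(),
                             effect_allele = character(),
                             other_allele = character(),
                             eaf = numeric(), n = numeric()), "empty")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^variant_id\t")
})

test_that("dialect mapping reproduces a canonical-column load", {
  set.seed(9)
  df <- toy_records(sprintf("rs%d", 1:5), beta = rnorm(5, 0, 0.05),
                    se = runif(5, 0.005, 0.02), pvalue = runif(5, 1e-8, 0.9),
                    eaf = runif(5), n = 15000)
  ss <- sumstats(df, "trait")
  canon <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, canon)

  foreign <- df
  names(foreign) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE",
                      "P", "N")
  fpath <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(format(foreign, digits = 17, trim = TRUE,
                            scientific = NA),
                     fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  dialect <- c(variant_id = "SNP", chromosome = "CHR", position = "BP",
               effect_allele = "A1", other_allele = "A2", eaf = "FRQ",
               beta = "BETA", se = "SE", pvalue = "P", n = "N")
  got <- read_sumstats(fpath, trait_id = "trait", dialect = dialect)
  want <- read_sumstats(canon, trait_id = "trait")
  expect_equal(got$records, want$records, tolerance = 1e-12)

  # dialect as a YAML file behaves identically
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(as.list(dialect), ypath)
  got_yaml <- read_sumstats(fpath, trait_id = "trait", dialect = ypath)
  expect_equal(got_yaml$records, want$records, tolerance = 1e-12)

  expect_error(read_sumstats(fpath, trait_id = "trait"), "mandatory")
})

test_that("harmonization aligns, flips and drops as the allele frames demand", {
  ex <- sumstats(toy_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                             beta = rep(0.10, 5), se = rep(0.01, 5),
                             pvalue = rep(1e-8, 5)), "exp")
  out_df <- toy_records(c("rs1", "rs2", "rs4", "rs5"),
                        beta = c(-0.05, -0.05, 0.02, 0.03),
                        se = rep(0.02, 4), pvalue = rep(0.01, 4))
  out_df$effect_allele <- c("A", "G", "T", "C")
  out_df$other_allele <- c("G", "A", "C", "T")
  out <- sumstats(out_df, "out")

  h <- harmonize(ex, out, c("rs1", "rs2", "rs3", "rs4", "rs5"))
  d <- h$data
  # rs1 aligned: beta unchanged; rs2 swapped: sign flips
  expect_equal(d$beta_outcome[d$variant_id == "rs1"], -0.05)
  expect_equal(d$beta_outcome[d$variant_id == "rs2"], +0.05)
  # rs4: outcome on opposite strand (T/C vs A/G) -> complement aligns, copy
  expect_equal(d$beta_outcome[d$variant_id == "rs4"], 0.02)
  # rs5: complement gives G/A = swapped -> sign flip
  expect_equal(d$beta_outcome[d$variant_id == "rs5"], -0.03)
  expect_equal(h$dropped$reason[h$dropped$variant_id == "rs3"],
               "missing_in_outcome")
})

test_that("palindromic variants never reach the harmonized rows", {
  ex_df <- toy_records(c("rs1", "rs2"), beta = c(0.1, 0.1),
                       se = c(0.01, 0.01), pvalue = c(1e-8, 1e-8))
  ex_df$effect_allele <- c("A", "C")
  ex_df$other_allele <- c("T", "G")
  ex <- sumstats(ex_df, "exp")
  out <- sumstats(ex_df, "out")
  h <- harmonize(ex, out, c("rs1", "rs2"))
  expect_equal(nrow(h$data), 0L)
  expect_equal(h$dropped$reason, c("palindromic", "palindromic"))

  # property: no A/T or C/G pair survives harmonization of generated data
  sim <- simulate_pair(sim_config(p_palindromic = 0.5, seed = 31))
  h2 <- harmonize(sim$exposure, sim$outcome, sim$truth$instrument_ids)
  rec <- sim$exposure$records
  kept <- rec[match(h2$data$variant_id, rec$variant_id), ]
  expect_false(any(is_palindromic(kept$effect_allele, kept$other_allele)))
})

test_that("harmonization is idempotent and invariant to outcome label flips", {
  sim <- simulate_pair(sim_config(seed = 7, p_allele_swap = 0.5))
  ids <- sim$truth$instrument_ids
  h <- harmonize(sim$exposure, sim$outcome, ids)

  # already-aligned pair: harmonizing the exposure against itself keeps betas
  h_self <- harmonize(sim$exposure, sim$exposure, ids)
  expect_equal(h_self$data$beta_outcome, h_self$data$beta_exposure)

  # flip all outcome allele labels and negate betas: same harmonized rows
  flipped <- sim$outcome
  rec <- flipped$records
  tmp <- rec$effect_allele
  rec$effect_allele <- rec$other_allele
  rec$other_allele <- tmp
  rec$beta <- -rec$beta
  rec$eaf <- 1 - rec$eaf
  flipped$records <- rec
  h_flip <- harmonize(sim$exposure, flipped, ids)
  expect_equal(h_flip$data, h$data, tolerance = 1e-15)

  expect_error(harmonize(sim$exposure, sim$outcome, character()), "empty")
})
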