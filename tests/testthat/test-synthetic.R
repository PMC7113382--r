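small_config <- function(n_timepoints = 64, ...) {
  cohort_config(n_per_group = c(IC = 2, HC = 2), n_regions = 20,
                network_sizes = c(DMN = 6, SN = 4, FPN = 4),
                n_timepoints = n_timepoints, ...)
}

test_that("the same seed reproduces a cohort bit for bit", {
  cfg <- small_config(seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$timeseries, c2$timeseries)
  # and the same subject seed reproduces a single series
  p <- c1$parcels
  x1 <- simulate_subject_timeseries(cfg, p, "HC", 123)
  x2 <- simulate_subject_timeseries(cfg, p, "HC", 123)
  expect_identical(x1, x2)
})

test_that("different seeds change realizations but not planted parameters", {
  c1 <- generate_cohort(small_config(seed = 1), timeseries = FALSE)
  c2 <- generate_cohort(small_config(seed = 2), timeseries = FALSE)
  expect_false(isTRUE(all.equal(c1$manifest$stroop, c2$manifest$stroop)))
  expect_identical(c1$ground_truth$indirect_effects,
                   c2$ground_truth$indirect_effects)
})

test_that("uncorrelated configurations produce near-zero empirical correlations", {
  cfg <- cohort_config(n_per_group = c(IC = 1, HC = 1), n_regions = 20,
                       network_sizes = c(DMN = 6, SN = 4, FPN = 4),
                       n_timepoints = 500,
                       rho_within = c(IC = 0, HC = 0), rho_between = 0,
                       seed = 4)
  p <- make_parcel_table(20, c(DMN = 6, SN = 4, FPN = 4))
  x <- simulate_subject_timeseries(cfg, p, "HC", 77)
  r <- cor(x)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)
})

test_that("within-network correlation approaches its target at large T", {
  cfg <- cohort_config(n_per_group = c(IC = 1, HC = 1), n_regions = 30,
                       network_sizes = c(DMN = 10, SN = 4, FPN = 4),
                       n_timepoints = 4096,
                       rho_within = c(IC = 0.35, HC = 0.6),
                       seed = 5)
  p <- make_parcel_table(30, c(DMN = 10, SN = 4, FPN = 4))
  x <- simulate_subject_timeseries(cfg, p, "HC", 3)
  dmn <- which(p$network == "DMN")
  r <- cor(x[, dmn])
  expect_lt(abs(mean(r[upper.tri(r)]) - 0.6), 0.05)
})

test_that("the planted band carries the dominant share of signal power", {
  cfg <- small_config(n_timepoints = 512, seed = 6)
  p <- make_parcel_table(20, c(DMN = 6, SN = 4, FPN = 4))
  x <- simulate_subject_timeseries(cfg, p, "IC", 8)
  band <- band_for_level(cfg$tr_seconds, cfg$band_level)
  spec <- Mod(mvfft(x))^2
  freqs <- (0:(nrow(x) - 1)) / (nrow(x) * cfg$tr_seconds)
  freqs <- pmin(freqs, 1 / cfg$tr_seconds - freqs)
  in_band <- freqs >= band$f_low & freqs <= band$f_high
  share <- sum(spec[in_band, ]) / sum(spec)
  expect_gt(share, 0.4)
})

test_that("a non-positive-definite block covariance is rejected before sampling", {
  cfg <- small_config(rho_within = c(IC = 0, HC = 0), rho_between = -0.5)
  p <- make_parcel_table(20, c(DMN = 6, SN = 4, FPN = 4))
  expect_error(simulate_subject_timeseries(cfg, p, "IC", 1),
               "not positive definite")
})

test_that("cognitive scores follow the planted structural model exactly", {
  cfg <- small_config(score_noise_sd = 0,
                      path_coeffs = list(s1 = c(b = 0, c = -0.5)))
  g <- c(0, 1, 1, 0)
  eff <- c(0.2, -0.1, 0.4, 0)
  sc <- simulate_cognition(cfg, g, eff, seed = 1)
  expect_equal(sc$s1, -0.5 * g)

  cfg2 <- small_config(a = -0.5,
                       path_coeffs = list(s1 = c(b = 0.4, c = 0)))
  gt <- generate_cohort(cfg2, timeseries = FALSE)$ground_truth
  expect_equal(unname(gt$indirect_effects["s1"]), -0.5 * 0.4)

  s1 <- simulate_cognition(cfg, g, eff, seed = 10)
  s2 <- simulate_cognition(cfg, g, eff, seed = 10)
  expect_identical(s1, s2)
})

test_that("cohorts have the configured group structure and artifacts", {
  cfg <- cohort_config(n_per_group = c(IC = 30, HC = 27), n_regions = 12,
                       network_sizes = c(DMN = 4, SN = 2, FPN = 2),
                       n_timepoints = 64, seed = 2)
  coh <- generate_cohort(cfg, timeseries = FALSE)
  expect_equal(nrow(coh$manifest), 57)
  expect_equal(as.vector(table(coh$manifest$group)[c("IC", "HC")]), c(30, 27))
  expect_true(all(coh$manifest$age >= 12 & coh$manifest$age <= 17))
  expect_true(all(coh$manifest$other_substance_months[
    coh$manifest$group == "HC"] == 0))

  sm <- generate_cohort(small_config(seed = 3))
  expect_equal(length(sm$timeseries), 4)
  expect_equal(dim(sm$timeseries[[1]]), c(64, 20))
  d <- withr::local_tempdir()
  write_cohort(sm, d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  expect_true(file.exists(file.path(d, "parcels.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  expect_equal(length(list.files(file.path(d, "timeseries"))), 4)
})

test_that("the planted indirect effect is recovered by the mediation machinery", {
  # construct-level recovery: group -> efficiency construct -> mediated score
  hits <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_per_group = c(IC = 200, HC = 200), n_regions = 12,
                         network_sizes = c(DMN = 4, SN = 2, FPN = 2),
                         n_timepoints = 64, a = -0.5,
                         path_coeffs = list(stroop = c(b = 0.4, c = 0)),
                         seed = 1000 + s)
    coh <- generate_cohort(cfg, timeseries = FALSE)
    dat <- data.frame(group = as.integer(coh$manifest$group == "IC"),
                      eff = coh$ground_truth$efficiency_construct,
                      stroop = coh$manifest$stroop)
    spec <- path_model_spec(c("group -> eff", "eff -> stroop",
                              "group -> stroop"))
    ie <- indirect_effect(spec, dat, c("group", "eff", "stroop"),
                          n_boot = 400, seed = s)
    if (ie$ci_low <= -0.2 && -0.2 <= ie$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
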