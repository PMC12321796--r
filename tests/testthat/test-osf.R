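test_that("band powers count the dyadic grid bins correctly", {
  freqs <- default_freqs()
  flat <- rep(1, 47)
  expect_equal(band_power(flat, freqs, "delta"), 8)
  expect_equal(band_power(flat, freqs, "beta"), 19)
  expect_equal(band_power(flat, freqs, "theta"), 10)
  expect_equal(band_power(flat, freqs, "alpha"), 10)
  expect_equal(band_power(rep(0, 47), freqs, "delta"), 0)
  expect_error(band_power(flat, freqs, c(25, 30)), "outside")
})

test_that("band edges are half-open and tile the grid", {
  freqs <- default_freqs()
  counts <- vapply(band_defs(), function(b)
    sum(freqs >= b[1] & freqs < b[2]), numeric(1))
  expect_equal(sum(counts), 47)
  flat <- rep(1, 47)
  rps <- vapply(names(band_defs()), function(b)
    relative_power(flat, freqs, b), numeric(1))
  expect_equal(sum(rps), 1, tolerance = 1e-12)
  expect_equal(unname(rps["delta"]), 8 / 47, tolerance = 1e-12)
})

test_that("power ratios follow the bin-count oracle and guard zero denominators", {
  freqs <- default_freqs()
  flat <- rep(1, 47)
  expect_equal(power_ratio(flat, freqs, "theta", "beta"), 10 / 19,
               tolerance = 1e-12)
  expect_equal(power_ratio(flat, freqs, "alpha", "alpha"), 1)
  only_delta <- ifelse(freqs < 4, 1, 0)
  expect_error(power_ratio(only_delta, freqs, "delta", "theta"),
               "zero denominator")
})

test_that("PR and RP are invariant to global rescaling of the spectrum", {
  freqs <- default_freqs()
  set.seed(2)
  psd <- exp(1 - log(freqs) + rnorm(47, 0, 0.3))
  for (kappa in c(0.1, 7)) {
    expect_equal(power_ratio(kappa * psd, freqs, "theta", "beta"),
                 power_ratio(psd, freqs, "theta", "beta"), tolerance = 1e-12)
    expect_equal(relative_power(kappa * psd, freqs, "alpha"),
                 relative_power(psd, freqs, "alpha"), tolerance = 1e-12)
  }
  # all power in one alpha bin
  spike <- rep(0, 47); spike[which(freqs >= 8 & freqs < 12)[1]] <- 5
  spike <- spike + 1e-12
  expect_equal(relative_power(spike, freqs, "alpha"), 1, tolerance = 1e-9)
})

test_that("the OSF table has 13 canonical features with valid ranges", {
  expect_length(osf_feature_names(), 13L)
  expect_equal(as.vector(table(osf_feature_groups())[c("AP", "PP", "PR", "RP")]),
               c(2L, 3L, 4L, 4L))
  cohort <- make_cohort(cohort_config(n = 6L, seed = 23L))
  models <- fit_cohort_spectra(cohort$spectra)
  osf <- build_osf_table(models, cohort$spectra)
  expect_equal(dim(osf), c(6L, 18L, 13L))
  expect_true(all(is.finite(osf)))
  rp <- osf[, , 10:13]
  expect_true(all(rp > 0 & rp < 1))
  expect_equal(apply(osf[, , 10:13], c(1, 2), sum),
               matrix(1, 6, 18), tolerance = 1e-12, ignore_attr = TRUE)
  pr <- osf[, , 6:9]
  expect_true(all(pr > 0))
})

test_that("single-subject tables keep shape and constant cohorts zero variance", {
  cohort <- make_cohort(cohort_config(n = 1L, seed = 2L))
  models <- fit_cohort_spectra(cohort$spectra)
  expect_equal(dim(build_osf_table(models, cohort$spectra)), c(1L, 18L, 13L))
  # identical spectra across subjects -> zero feature variance
  sp <- cohort$spectra
  vals <- array(rep(sp$values[1, , ], each = 3), dim = c(3, 18, 47))
  trip <- power_spectra(vals, sp$grid, sp$channels, scale = "log")
  m3 <- fit_cohort_spectra(trip)
  osf3 <- build_osf_table(m3, trip)
  expect_equal(max(apply(osf3, c(2, 3), sd)), 0, tolerance = 1e-10)
})

test_that("aperiodic feature columns track the generator ground truth", {
  cohort <- make_cohort(cohort_config(n = 40L, seed = 29L))
  models <- fit_cohort_spectra(cohort$spectra)
  osf <- build_osf_table(models, cohort$spectra)
  expect_gt(cor(as.vector(osf[, , 1]), as.vector(cohort$truth$chi)), 0.95)
  # the offset truth carries per-channel spatial variation of similar size
  # to its fit noise, so its recovery ceiling sits slightly lower
  expect_gt(cor(as.vector(osf[, , 2]), as.vector(cohort$truth$b)), 0.9)
})

test_that("feature-age correlations behave as Pearson r with region means", {
  cohort <- make_cohort(cohort_config(n = 30L, seed = 3L))
  models <- fit_cohort_spectra(cohort$spectra)
  osf <- build_osf_table(models, cohort$spectra)
  ages <- cohort$meta$age
  # plant a feature exactly equal to age
  osf[, , 4] <- matrix(ages, 30L, 18L)
  imp <- pcc_importance(osf, ages)
  expect_equal(unname(imp$pcc[, 4]), rep(1, 18L), tolerance = 1e-12)
  # region aggregation is the mean over member electrodes
  regions <- channel_regions()
  frontal <- names(regions)[regions == "frontal"]
  expect_equal(unname(imp$region_pcc["frontal", 1]),
               mean(imp$pcc[frontal, 1]), tolerance = 1e-12)
  expect_true(all(abs(imp$pcc) <= 1 + 1e-12))
})

test_that("planted linear feature matches the closed-form correlation", {
  set.seed(55)
  n <- 500L
  ages <- runif(n, 5, 95)
  cohort <- make_cohort(cohort_config(n = 3L, seed = 1L))
  models <- fit_cohort_spectra(cohort$spectra)
  osf_small <- build_osf_table(models, cohort$spectra)
  osf <- array(rnorm(n * 18 * 13), dim = c(n, 18, 13),
               dimnames = list(NULL, dimnames(osf_small)[[2]],
                               dimnames(osf_small)[[3]]))
  class(osf) <- "osf_table"
  attr(osf, "feature_names") <- osf_feature_names()
  attr(osf, "groups") <- osf_feature_groups()
  osf[, 1, 1] <- 0.5 * ages + rnorm(n)
  imp <- suppressWarnings(pcc_importance(osf, ages))
  analytic <- 0.5 * sd(ages) / sqrt(0.25 * var(ages) + 1)
  expect_lt(abs(imp$pcc[1, 1] - analytic), 0.05)
})
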