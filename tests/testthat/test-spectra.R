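test_that("default grid has 47 dyadic bins matching the printed range", {
  g <- frequency_grid()
  expect_equal(g$n_bins, 47L)
  expect_equal(g$step_hz, 100 / 256)
  expect_equal(g$freqs[1L], 1.171875)
  expect_equal(g$freqs[47L], 19.140625)
  expect_true(all(diff(g$freqs) > 0))
  expect_error(frequency_grid(step_hz = 0), "positive")
  expect_error(frequency_grid(n_bins = 1), "n_bins")
})

test_that("channel sets and regions partition the montage", {
  ch <- eeg_channels()
  expect_length(ch, 18L)
  expect_false("Pz" %in% ch)
  expect_true("Pz" %in% eeg_channels("raw"))
  reg <- channel_regions()
  expect_setequal(names(reg), ch)
  counts <- as.vector(table(reg)[c("frontal", "central", "parietal",
                                   "occipital", "temporal")])
  expect_equal(counts, c(7L, 3L, 2L, 2L, 4L))
})

test_that("TSV round-trip is lossless and incomplete grids error", {
  psd <- tiny_psd()
  f <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_spectra(psd, f, meta_path = mf)
  back <- read_spectra(f, mf, scale = "linear")
  expect_equal(back$values, psd$values, tolerance = 1e-12)
  expect_equal(back$grid$freqs, psd$grid$freqs, tolerance = 1e-12)
  expect_equal(back$meta$subject_id, psd$meta$subject_id)
  # drop one row -> incomplete grid error
  tab <- read.table(f, header = TRUE, sep = "\t")
  write.table(tab[-5, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spectra(f, scale = "linear"), "incomplete grid")
  # non-numeric power
  tab$value <- as.character(tab$value); tab$value[2] <- "oops"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spectra(f, scale = "linear"), "non-numeric")
})

test_that("generated cohorts have the documented shape and round-trip", {
  cohort <- make_cohort(cohort_config(n = 10L, seed = 3L))
  expect_equal(dim(cohort$spectra$values), c(10L, 18L, 47L))
  f <- tempfile(fileext = ".tsv")
  write_spectra(cohort$spectra, f)
  back <- read_spectra(f, scale = "log")
  expect_equal(back$values, cohort$spectra$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("diagonal extraction recovers target powers from cross-spectra", {
  g <- frequency_grid(2, 1, 3L)
  # identity cross-spectrum -> unit powers
  ident <- array(0i, dim = c(1L, 2L, 2L, 3L))
  for (f in 1:3) ident[1, , , f] <- diag(2) + 0i
  cs <- cross_spectra(ident, g, c("C3", "C4"))
  expect_equal(unname(diagonal_power(cs)$values[1, , ]),
               matrix(1, 2, 3))
  # rank-1 v v^H with v = (1, 2i) -> diagonal (1, 4)
  v <- c(1 + 0i, 2i)
  r1 <- array(0i, dim = c(1L, 2L, 2L, 3L))
  for (f in 1:3) r1[1, , , f] <- v %*% Conj(t(v))
  cs1 <- cross_spectra(r1, g, c("C3", "C4"))
  expect_equal(unname(diagonal_power(cs1)$values[1, , 1]), c(1, 4))
  # generator-built cross-spectra recover the cohort's linear powers
  cfg <- cohort_config(n = 2L, seed = 11L)
  cs2 <- make_cross_spectra(cfg)
  lin <- exp(make_cohort(cfg)$spectra$values)
  expect_equal(diagonal_power(cs2)$values[, 1:18, ], lin, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("average reference projects out the common mode and drops Pz", {
  g <- frequency_grid(2, 1, 2L)
  n <- 3L
  ident <- array(0i, dim = c(1L, n, n, 2L))
  for (f in 1:2) ident[1, , , f] <- diag(n) + 0i
  cs <- cross_spectra(ident, g, c("C3", "C4", "Pz"))
  ref <- average_reference(cs, drop = "Pz")
  # H I H = H has diagonal 1 - 1/n
  expect_equal(Re(ref$values[1, 1, 1, 1]), 2 / 3, tolerance = 1e-12)
  expect_equal(ref$channels, c("C3", "C4"))
  # constant-signal cross-spectrum is annihilated
  const <- array(1 + 0i, dim = c(1L, n, n, 2L))
  csc <- cross_spectra(const, g, c("C3", "C4", "Pz"))
  expect_equal(max(Mod(average_reference(csc, "Pz")$values)), 0,
               tolerance = 1e-12)
  expect_error(average_reference(cs, drop = "Oz"), "not among")
})

test_that("referenced cross-spectra are rank deficient by one", {
  cs <- make_cross_spectra(cohort_config(n = 2L, seed = 13L))
  ref <- average_reference(cs, drop = "Pz")
  # rank of the full 18x18 referenced slice (before dropping it would be 18
  # channels from 19): dropping a row/column of a rank-18 matrix keeps rank
  # <= 18; verify the undropped 19-channel projection has a null vector
  n <- length(cs$channels)
  H <- diag(n) - matrix(1 / n, n, n)
  S <- H %*% cs$values[1, , , 5] %*% H
  ev <- sort(abs(eigen(S, only.values = TRUE)$values))
  expect_lt(ev[1L], 1e-10 * ev[n])
})

test_that("referencing then diagonal differs from the row-mean shortcut", {
  # guards a known shortcut bug: subtracting channel-mean power is NOT the
  # diagonal of H S H for correlated channels
  set.seed(42)
  n <- 4L
  M <- matrix(rnorm(n * n) + 1i * rnorm(n * n), n)
  S <- M %*% Conj(t(M))
  H <- diag(n) - matrix(1 / n, n, n)
  proper <- Re(diag(H %*% S %*% H))
  shortcut <- Re(diag(S)) - mean(Re(diag(S)))
  expect_gt(max(abs(proper - shortcut)), 1e-3)
})

test_that("global scale correction centers each subject and is offset-invariant", {
  psd <- tiny_psd(scale = "linear")
  lg <- log_transform(psd)
  corr <- global_scale_correct(lg)
  expect_equal(apply(corr$values, 1L, mean), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # adding a per-subject offset changes nothing after correction
  shifted <- lg
  shifted$values[1, , ] <- shifted$values[1, , ] + 5
  expect_equal(global_scale_correct(shifted)$values, corr$values,
               tolerance = 1e-12)
  expect_error(global_scale_correct(psd), "log")
  # constant subject maps to all zeros
  flat <- power_spectra(array(3, dim = c(1, 2, 3)), frequency_grid(2, 1, 3),
                        c("A", "B"), scale = "log")
  expect_equal(max(abs(global_scale_correct(flat)$values)), 0)
})

test_that("cohort-scale correction leaves per-subject means below 1e-12", {
  cohort <- make_cohort(cohort_config(n = 15L, seed = 5L))
  corr <- global_scale_correct(cohort$spectra)
  expect_lt(max(abs(apply(corr$values, 1L, mean))), 1e-12)
})
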