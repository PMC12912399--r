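# MAE, windowed PCC, masked-spectrum SNR, overall score, acceptance rate,
# Bland-Altman.

test_that("MAE matches hand-computed examples", {
  t <- 0:2
  expect_equal(hr_mae(make_paired(t, c(70, 72, 74), c(70, 72, 74))), 0)
  expect_equal(hr_mae(make_paired(t, c(70, 72, 74), c(68, 72, 70))), 2)
  expect_equal(hr_mae(make_paired(t, c(70, 72, 74) + 5, c(70, 72, 74))), 5)
  expect_error(hr_mae(make_paired(numeric(0), numeric(0), numeric(0))),
               "empty")
})

test_that("MAE translation shift is bounded by the offset", {
  set.seed(4)
  est <- runif(50, 60, 100)
  ref <- runif(50, 60, 100)
  base <- hr_mae(make_paired(1:50, est, ref))
  for (c0 in c(0.5, 3, 10)) {
    shifted <- hr_mae(make_paired(1:50, est + c0, ref))
    expect_lte(shifted, base + c0)
    expect_gte(shifted, base - c0)
  }
  # when the estimate never undershoots, the shift is exact
  est_hi <- ref + runif(50, 0, 5)
  expect_equal(hr_mae(make_paired(1:50, est_hi + 2, ref)),
               hr_mae(make_paired(1:50, est_hi, ref)) + 2)
})

test_that("windowed PCC reproduces perfect and hand-built correlations", {
  x <- rep(c(1, 2, 3, 4), 2)
  expect_equal(as.numeric(windowed_pcc(x, x, fps = 1, window_s = 4,
                                       overlap_s = 0)), 1)
  expect_equal(as.numeric(windowed_pcc(x, -x, fps = 1, window_s = 4,
                                       overlap_s = 0)), -1)
  # segment 1 exactly linear (r = 1), segment 2 r = cor oracle
  y <- c(2, 4, 6, 8, 1, 1, 3, 3)
  expected <- (1 + cor(c(1, 2, 3, 4), c(1, 1, 3, 3))) / 2
  expect_equal(as.numeric(windowed_pcc(x, y, fps = 1, window_s = 4,
                                       overlap_s = 0)),
               expected, tolerance = 1e-12)
})

test_that("windowed PCC equals the covariance-form oracle on random data", {
  set.seed(8)
  fps <- 10
  x <- rnorm(200)
  y <- 0.4 * x + rnorm(200)
  got <- as.numeric(windowed_pcc(x, y, fps, window_s = 6, overlap_s = 5))
  starts <- seq(1, 200 - 60 + 1, by = 10)
  oracle <- mean(vapply(starts, function(s) {
    cor(x[s:(s + 59)], y[s:(s + 59)])
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("windowed PCC is invariant to positive affine rescaling", {
  set.seed(9)
  x <- rnorm(120)
  y <- rnorm(120)
  base <- as.numeric(windowed_pcc(x, y, fps = 10))
  expect_equal(as.numeric(windowed_pcc(3 * x + 7, y, fps = 10)), base,
               tolerance = 1e-10)
  expect_equal(as.numeric(windowed_pcc(x, 0.2 * y - 4, fps = 10)), base,
               tolerance = 1e-10)
})

test_that("zero-variance segments are excluded and counted", {
  x <- c(rep(1, 40), rnorm(40))
  y <- rnorm(80)
  r <- windowed_pcc(x, y, fps = 10, window_s = 4, overlap_s = 0)
  expect_equal(attr(r, "excluded"), 1L)
  expect_warning(windowed_pcc(rep(1, 80), y, fps = 10, window_s = 4,
                              overlap_s = 0), "zero variance")
})

test_that("SNR hits the clamp bounds for pure in/out-of-mask tones", {
  fps <- 30
  t <- (0:179) / fps # exactly one 6 s segment; bin width 10 BPM
  x_in <- sin(2 * pi * 1 * t)
  expect_equal(as.numeric(spectral_snr(x_in, fps, ref_bpm = 60)), 60)
  x_out <- sin(2 * pi * 3.5 * t)
  expect_equal(as.numeric(spectral_snr(x_out, fps, ref_bpm = 60)), -60)
})

test_that("two-tone SNR matches the Parseval closed form", {
  fps <- 30
  t <- (0:179) / fps
  x <- 2 * sin(2 * pi * 1 * t) + 1 * sin(2 * pi * 3.5 * t)
  got <- as.numeric(spectral_snr(x, fps, ref_bpm = 60))
  expect_equal(got, 10 * log10(4), tolerance = 0.1)
})

test_that("SNR decreases as out-of-mask amplitude grows", {
  fps <- 30
  t <- (0:179) / fps
  snrs <- vapply(c(0.5, 1, 2, 4), function(b) {
    x <- 2 * sin(2 * pi * 1 * t) + b * sin(2 * pi * 3.5 * t)
    as.numeric(spectral_snr(x, fps, ref_bpm = 60))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("the harmonic lobe is part of the mask", {
  fps <- 30
  t <- (0:179) / fps
  # fundamental plus first harmonic: both inside the mask
  x <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 2 * t)
  expect_equal(as.numeric(spectral_snr(x, fps, ref_bpm = 60)), 60)
})

test_that("overall score matches its boundary and midpoint examples", {
  tab <- tibble::tibble(roi_index = 1:3, mae = c(2, 4, 6),
                        pcc = c(0.9, 0.5, 0.1), snr = c(6, 0, -6))
  sc <- overall_score(tab)
  expect_equal(sc$os, c(1, 0.5, 0))
})

test_that("overall score is invariant to affine rescaling of one metric", {
  set.seed(10)
  tab <- tibble::tibble(roi_index = 1:6, mae = runif(6, 1, 8),
                        pcc = runif(6, -0.2, 0.9), snr = runif(6, -10, 10))
  base <- overall_score(tab)$os
  tab2 <- tab
  tab2$snr <- 3 * tab$snr + 100
  expect_equal(overall_score(tab2)$os, base, tolerance = 1e-12)
})

test_that("a constant metric contributes a neutral 0.5 component", {
  tab <- tibble::tibble(roi_index = 1:3, mae = c(1, 1, 1),
                        pcc = c(0.9, 0.5, 0.1), snr = c(6, 0, -6))
  sc <- overall_score(tab)
  expect_equal(sc$mae_score, rep(0.5, 3))
  expect_equal(sc$os, (0.5 + c(1, 0.5, 0) + c(1, 0.5, 0)) / 3)
  expect_error(overall_score(tab[1, ]), "at least 2")
})

test_that("acceptance rate counts windows by their MAE threshold", {
  t <- seq(0, 100, by = 1)
  ref <- rep(70, length(t))
  offs <- c(5, 12, 8, 20)[pmin(floor(t / 25) + 1, 4)]
  p <- make_paired(t, ref + offs, ref)
  a <- acceptance_rate(p)
  expect_equal(as.numeric(a), 0.5)
  expect_equal(attr(a, "n_windows"), 4L)
  expect_equal(as.numeric(acceptance_rate(make_paired(t, ref, ref))), 1)
  expect_equal(as.numeric(acceptance_rate(make_paired(t, ref + 50, ref))), 0)
  expect_error(acceptance_rate(make_paired(0:10, rep(70, 11), rep(70, 11))),
               "span")
})

test_that("a window MAE of exactly 10 BPM is acceptable", {
  t <- seq(0, 50, by = 1)
  ref <- rep(70, length(t))
  p <- make_paired(t, ref + 10, ref)
  expect_equal(as.numeric(acceptance_rate(p)), 1)
})

test_that("Bland-Altman reproduces hand-computed agreement limits", {
  t <- seq(0, 50, by = 1)
  ref <- rep(70, length(t))
  ident <- bland_altman(make_paired(t, ref, ref))
  expect_equal(c(ident$mean_diff, ident$loa_lower, ident$loa_upper),
               c(0, 0, 0))
  # window differences +2 and -2: bias 0, limits +-1.96 * sd(c(2, -2))
  est <- ref + ifelse(t < 25, 2, -2)
  ba <- bland_altman(make_paired(t, est, ref))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_upper, 1.96 * sd(c(2, -2)), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -1.96 * sd(c(2, -2)), tolerance = 1e-12)
  # constant offset: zero spread
  ba5 <- bland_altman(make_paired(t, ref + 5, ref))
  expect_equal(c(ba5$mean_diff, ba5$loa_lower, ba5$loa_upper), c(5, 5, 5))
  expect_error(bland_altman(make_paired(0:26, rep(70, 27), rep(70, 27))),
               "at least 2")
})

test_that("tidiers expose Bland-Altman windows and summary", {
  t <- seq(0, 50, by = 1)
  ref <- rep(70, length(t))
  ba <- bland_altman(make_paired(t, ref + 3, ref))
  expect_equal(nrow(tidy(ba)), 2L)
  g <- glance(ba)
  expect_equal(g$mean_diff, 3)
  expect_s3_class(autoplot(ba), "ggplot")
})
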