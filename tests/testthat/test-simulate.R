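# Synthetic pulse, trace, and study generation.

test_that("the simulated contact PPG peaks at the configured rate", {
  cfg <- sim_config(seed = 1, fps = 30, duration = 30, hr = 72)
  gt <- simulate_pulse(cfg)
  expect_equal(oracle_peak_hz(gt$ppg$value, 60), 1.2, tolerance = 2 / 30)
  expect_true(all(gt$hr$bpm == 72))
  expect_equal(nrow(gt$ppg), 30 * 60 + 1)
})

test_that("harmonic_ratio = 0 gives a single-tone spectrum", {
  cfg <- sim_config(seed = 1, fps = 30, duration = 30, hr = 72,
                    harmonic_ratio = 0)
  gt <- simulate_pulse(cfg)
  x <- gt$ppg$value - mean(gt$ppg$value)
  p <- Mod(stats::fft(x)[2:(length(x) %/% 2)])^2
  fund <- max(p)
  p_sorted <- sort(p, decreasing = TRUE)
  # exclude leakage right next to the fundamental
  f_hz <- (seq_along(p)) * 60 / length(x)
  away <- abs(f_hz - 1.2) > 0.3
  expect_lt(max(p[away]) / fund, 0.01)
})

test_that("generation is a pure function of the configuration", {
  cfg <- sim_config(seed = 33, fps = 20, duration = 10, noise_sd = 2,
                    burst_rate = 0.5)
  a <- simulate_traces(cfg)
  b <- simulate_traces(cfg)
  expect_identical(a$traces, b$traces)
  c2 <- simulate_traces(sim_config(seed = 34, fps = 20, duration = 10,
                                   noise_sd = 2, burst_rate = 0.5))
  expect_false(identical(a$traces$R, c2$traces$R))
})

test_that("trajectories outside 48-180 BPM are rejected", {
  expect_error(sim_config(hr = 40), "48-180")
  expect_error(sim_config(hr = tibble::tibble(time_s = c(0, 10),
                                              bpm = c(70, 200))), "48-180")
  expect_error(sim_config(fps = 5), "fps")
})

test_that("trace samples stay on the 0-255 scale and cover 28 ROIs", {
  cfg <- sim_config(seed = 2, fps = 20, duration = 10, noise_sd = 5,
                    burst_rate = 1, burst_amplitude = 50)
  tr <- simulate_traces(cfg)$traces
  expect_setequal(unique(tr$roi_index), 1:28)
  for (ch in c("R", "G", "B")) {
    expect_true(all(tr[[ch]] >= 0 & tr[[ch]] <= 255))
  }
})

test_that("noise-free traces recover ground truth HR for all methods", {
  cfg <- sim_config(seed = 5, fps = 20, duration = 30, hr = 84,
                    noise_sd = 0, drift_amplitude = 0, burst_rate = 0)
  sim <- simulate_traces(cfg)
  for (k in c(4, 22)) {
    tk <- sim$traces[sim$traces$roi_index == k, ]
    attr(tk, "fps") <- 20
    for (m in c("CHROM", "POS", "LGI", "OMIT")) {
      h <- estimate_hr(tk, m)
      expect_true(all(abs(h$bpm - 84) <= 1),
                  label = paste("ROI", k, m))
    }
  }
})

test_that("a zero-amplitude ROI scores worst", {
  amps <- default_roi_amplitudes()
  amps["7"] <- 0
  cfg <- sim_config(seed = 6, fps = 20, duration = 30, amplitudes = amps,
                    noise_sd = 1)
  sim <- simulate_traces(cfg)
  sub <- sim$traces[sim$traces$roi_index %in% c(4, 7, 22), ]
  attr(sub, "fps") <- 20
  rec <- evaluate_traces(sub, reference_hr = sim$hr,
                         reference_ppg = sim$ppg, fps = 20,
                         methods = "OMIT")
  agg <- dplyr::summarise(dplyr::group_by(rec, roi_index),
                          mae = median(mae), pcc = median(pcc),
                          snr = median(snr))
  sc <- overall_score(agg)
  expect_equal(sc$roi_index[which.min(sc$os)], 7L)
  expect_lt(sc$snr[sc$roi_index == 7], sc$snr[sc$roi_index == 4])
})

test_that("clean simulated cPPG reproduces the trajectory through welch_hr", {
  hr <- tibble::tibble(time_s = c(0, 20, 20.001, 40), bpm = c(66, 66, 90, 90))
  cfg <- sim_config(seed = 7, fps = 20, duration = 40, hr = hr)
  gt <- simulate_pulse(cfg)
  est <- welch_hr(tibble::tibble(time_s = gt$ppg$time_s,
                                 value = gt$ppg$value), fps = 60)
  ref <- stats::approx(hr$time_s, hr$bpm, xout = est$time_s)$y
  away <- abs(est$time_s - 20) > 3
  expect_true(all(abs(est$bpm - ref)[away] <= 1))
})

test_that("the study generator is deterministic and labelled", {
  s1 <- simulate_study(n_participants = 2, duration = 30, seed = 4)
  s2 <- simulate_study(n_participants = 2, duration = 30, seed = 4)
  expect_identical(s1$traces[[1]], s2$traces[[1]])
  expect_equal(nrow(s1), 4L) # 2 participants x 2 activities
  expect_setequal(s1$activity, c("resting", "talking"))
  # per-participant HR trajectories stay in range
  for (i in seq_len(nrow(s1))) {
    expect_true(all(s1$hr[[i]]$bpm >= 48 & s1$hr[[i]]$bpm <= 180))
  }
})
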