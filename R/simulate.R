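# Synthetic study generator: quasi-periodic pulse waveform with a first
# harmonic and a drifting rate, per-ROI pulse amplitudes, white noise,
# illumination drift, motion-artifact bursts, ground truth sampled at a
# different rate than the video, and optional rendered frames.

#' Default per-ROI pulsatile amplitudes
#'
#' Relative pulsatile strength of each facial region, graded so that the
#' regions with the richest superficial perfusion -- glabella (4), medial
#' forehead (1), lateral foreheads (2, 3), malars (22, 23) and upper nasal
#' dorsum (5) -- carry the strongest pulse, the glabella strongest of all.
#' Units are intensity counts on the 0-255 scale per unit pulse waveform.
#'
#' @return A named numeric vector of length 28 (names = ROI indices).
#' @export
default_roi_amplitudes <- function() {
  amp <- c(
    `1` = 2.6, `2` = 2.4, `3` = 2.4, `4` = 3.0, `5` = 2.0,
    `6` = 1.0, `7` = 0.9, `8` = 0.85, `9` = 0.85, `10` = 0.95,
    `11` = 0.8, `12` = 0.8, `13` = 0.75, `14` = 0.75, `15` = 0.7,
    `16` = 0.65, `17` = 0.65, `18` = 0.7, `19` = 0.7, `20` = 0.6,
    `21` = 0.6, `22` = 2.2, `23` = 2.2, `24` = 0.55, `25` = 0.55,
    `26` = 0.5, `27` = 0.45, `28` = 0.45
  )
  amp
}

#' Simulation configuration
#'
#' Bundles all generator parameters. The pulse waveform is
#' `p(t) = sin(phi(t)) + harmonic_ratio * sin(2 phi(t))` with
#' `phi'(t) = 2 pi HR(t) / 60`, where the heart-rate trajectory `HR(t)` is
#' piecewise linear within 48-180 BPM. ROI traces are
#' `baseline + amplitude_k * p(t) * channel_gains + white noise
#'  + illumination drift + motion bursts`, clipped to the 0-255 scale.
#'
#' @param seed Integer seed; every generator operation is a pure function of
#'   the configuration including this seed.
#' @param fps Video frame rate in Hz (> 8).
#' @param duration Recording length in seconds (use >= 30 s for
#'   full-pipeline work so at least one 25 s acceptance window exists).
#' @param hr Heart-rate trajectory: a single BPM value or a tibble
#'   (`time_s`, `bpm`) defining a piecewise-linear trajectory; all values
#'   must lie in 48-180 BPM.
#' @param harmonic_ratio Amplitude of the first harmonic relative to the
#'   fundamental.
#' @param amplitudes Named per-ROI pulsatile amplitudes (intensity counts);
#'   see [default_roi_amplitudes()].
#' @param baseline Baseline skin color triplet (R, G, B).
#' @param channel_gains Relative pulse strength per channel;
#'   green-dominant by default, reflecting that the green channel carries
#'   the strongest cardiac signal.
#' @param noise_sd White-noise standard deviation (intensity counts).
#' @param drift_amplitude,drift_period_s Illumination drift: a slow sinusoid
#'   of this amplitude and period added equally to all channels.
#' @param burst_rate,burst_amplitude Motion artifacts: Poisson-timed
#'   transients (rate per second) with exponentially decaying shape and this
#'   peak amplitude, added to all channels.
#' @param gt_rate Sampling rate (Hz) of the ground-truth contact PPG and HR
#'   series (different from `fps` to exercise alignment).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, fps = 30, duration = 60, hr = 72,
                       harmonic_ratio = 0.3,
                       amplitudes = default_roi_amplitudes(),
                       baseline = c(R = 160, G = 110, B = 95),
                       channel_gains = c(R = 0.4, G = 1.0, B = 0.6),
                       noise_sd = 1, drift_amplitude = 2,
                       drift_period_s = 20, burst_rate = 0.05,
                       burst_amplitude = 5, gt_rate = 60) {
  if (fps <= 8) stop("fps must exceed 8 Hz", call. = FALSE)
  stopifnot(duration > 0, gt_rate > 0, harmonic_ratio >= 0,
            all(amplitudes >= 0), noise_sd >= 0, drift_amplitude >= 0,
            drift_period_s > 0, burst_rate >= 0, burst_amplitude >= 0)
  if (is.numeric(hr) && is.null(dim(hr)) && length(hr) == 1L) {
    hr <- tibble::tibble(time_s = c(0, duration), bpm = c(hr, hr))
  }
  stopifnot(is.data.frame(hr), all(c("time_s", "bpm") %in% names(hr)))
  if (any(hr$bpm < 48 | hr$bpm > 180)) {
    stop("heart-rate trajectory must stay within 48-180 BPM", call. = FALSE)
  }
  if (length(amplitudes) != 28L) {
    stop("amplitudes must provide 28 per-ROI values", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), fps = fps, duration = duration, hr = hr,
    harmonic_ratio = harmonic_ratio, amplitudes = amplitudes,
    baseline = baseline, channel_gains = channel_gains, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
    burst_rate = burst_rate, burst_amplitude = burst_amplitude,
    gt_rate = gt_rate
  ), class = "sim_config")
}

# phase-integrated pulse waveform on an arbitrary time grid
.pulse_on_grid <- function(config, rate) {
  t <- seq(0, config$duration, by = 1 / rate)
  bpm <- stats::approx(config$hr$time_s, config$hr$bpm, xout = t,
                       rule = 2)$y
  phi <- 2 * pi * cumsum(bpm / 60) / rate
  value <- sin(phi) + config$harmonic_ratio * sin(2 * phi)
  tibble::tibble(time_s = t, value = value, bpm = bpm)
}

#' Simulate the contact-PPG ground truth
#'
#' Generates the quasi-periodic pulse waveform and HR series at the
#' ground-truth rate (`gt_rate`, default 60 Hz), emulating a fingertip
#' pulse-oximeter recording.
#'
#' @param config A [sim_config()].
#' @return A list with `ppg` (tibble `time_s`, `value`) and `hr` (tibble
#'   `time_s`, `bpm`), both sampled at `config$gt_rate`.
#' @export
simulate_pulse <- function(config) {
  g <- .pulse_on_grid(config, config$gt_rate)
  list(ppg = g[, c("time_s", "value")],
       hr = tibble::tibble(time_s = g$time_s, bpm = g$bpm))
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate 28 per-ROI RGB traces with ground truth
#'
#' Embeds the configured pulse waveform into each ROI's mean-RGB trace with
#' the ROI's pulsatile amplitude and green-dominant channel gains, then adds
#' white noise (independent per ROI and channel), a shared illumination
#' drift (equal across channels and ROIs), and motion-artifact bursts at
#' Poisson times (correlated across channels; per-ROI severity varies).
#' Values are clipped to the 0-255 scale. Deterministic given the
#' configuration (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list: `traces` (long tibble `roi_index`, `roi_name`, `frame`,
#'   `time_s`, `R`, `G`, `B`, `valid`, attribute `fps`), `pulse` (waveform on
#'   the video grid), `ppg` and `hr` (ground truth at `gt_rate`), and
#'   `config`.
#' @export
simulate_traces <- function(config) {
  gt <- simulate_pulse(config)
  vid <- .pulse_on_grid(config, config$fps)
  n <- nrow(vid)
  rois <- roi_table()
  amps <- config$amplitudes[as.character(rois$roi_index)]
  out <- with_seed(config$seed, {
    drift <- config$drift_amplitude *
      sin(2 * pi * vid$time_s / config$drift_period_s + stats::runif(1, 0, 2 * pi))
    burst <- numeric(n)
    n_burst <- stats::rpois(1, config$burst_rate * config$duration)
    if (n_burst > 0) {
      times <- stats::runif(n_burst, 0, config$duration)
      signs <- sample(c(-1, 1), n_burst, replace = TRUE)
      for (b in seq_len(n_burst)) {
        dt <- vid$time_s - times[b]
        on <- dt >= 0 & dt < 2
        burst[on] <- burst[on] +
          signs[b] * config$burst_amplitude * exp(-dt[on] / 0.3)
      }
    }
    roi_burst_scale <- stats::runif(28, 0.5, 1.5)
    purrr::map(seq_len(28), function(k) {
      p <- amps[k] * vid$value
      common <- drift + roi_burst_scale[k] * burst
      tibble::tibble(
        roi_index = rois$roi_index[k],
        roi_name = rois$roi_name[k],
        frame = seq_len(n) - 1L,
        time_s = vid$time_s,
        R = pmin(pmax(config$baseline[["R"]] + config$channel_gains[["R"]] * p +
                        stats::rnorm(n, 0, config$noise_sd) + common, 0), 255),
        G = pmin(pmax(config$baseline[["G"]] + config$channel_gains[["G"]] * p +
                        stats::rnorm(n, 0, config$noise_sd) + common, 0), 255),
        B = pmin(pmax(config$baseline[["B"]] + config$channel_gains[["B"]] * p +
                        stats::rnorm(n, 0, config$noise_sd) + common, 0), 255),
        valid = TRUE
      )
    })
  })
  traces <- dplyr::bind_rows(out)
  attr(traces, "fps") <- config$fps
  list(traces = traces, pulse = vid[, c("time_s", "value")],
       ppg = gt$ppg, hr = gt$hr, config = config)
}

#' Default synthetic study activities
#'
#' Two acquisition regimes: `resting` (low noise, rare motion bursts,
#' emulating a still subject / cognitive-task recording) and `talking`
#' (stronger noise, faster illumination drift, frequent motion bursts,
#' emulating a motion recording).
#'
#' @return A tibble of per-activity noise parameters.
#' @export
default_activities <- function() {
  tibble::tibble(
    activity = c("resting", "talking"),
    noise_sd = c(1.0, 2.5),
    drift_amplitude = c(2, 3),
    drift_period_s = c(20, 15),
    burst_rate = c(0.02, 0.15),
    burst_amplitude = c(4, 8)
  )
}

#' Simulate a multi-participant study
#'
#' Generates one recording (28 ROI traces + ground truth) per participant
#' and activity. Each participant receives a random baseline heart rate
#' (uniform 55-95 BPM) with a slow linear drift of up to +-6 BPM across the
#' recording; activities differ in their noise regime. Deterministic given
#' `seed`.
#'
#' @param n_participants Number of participants.
#' @param activities A tibble as returned by [default_activities()].
#' @param fps,duration,gt_rate,amplitudes,harmonic_ratio Passed to
#'   [sim_config()] (study defaults: 20 Hz video, 30 s recordings, 60 Hz
#'   ground truth).
#' @param seed Study seed.
#' @return A `synthetic_study` tibble with one row per participant x
#'   activity and list-columns `traces`, `ppg`, `hr`, `config`.
#' @export
simulate_study <- function(n_participants = 6,
                           activities = default_activities(),
                           fps = 20, duration = 30, gt_rate = 60,
                           amplitudes = default_roi_amplitudes(),
                           harmonic_ratio = 0.3, seed = 1L) {
  draws <- with_seed(seed, {
    list(
      base = stats::runif(n_participants, 55, 95),
      drift = stats::runif(n_participants, -6, 6),
      sub_seed = matrix(sample.int(.Machine$integer.max - 1L,
                                   n_participants * nrow(activities)),
                        n_participants, nrow(activities))
    )
  })
  rows <- list()
  for (p in seq_len(n_participants)) {
    bpm0 <- draws$base[p]
    bpm1 <- min(max(bpm0 + draws$drift[p], 48), 180)
    hr <- tibble::tibble(time_s = c(0, duration), bpm = c(bpm0, bpm1))
    for (a in seq_len(nrow(activities))) {
      cfg <- sim_config(
        seed = draws$sub_seed[p, a], fps = fps, duration = duration,
        hr = hr, harmonic_ratio = harmonic_ratio, amplitudes = amplitudes,
        noise_sd = activities$noise_sd[a],
        drift_amplitude = activities$drift_amplitude[a],
        drift_period_s = activities$drift_period_s[a],
        burst_rate = activities$burst_rate[a],
        burst_amplitude = activities$burst_amplitude[a],
        gt_rate = gt_rate
      )
      sim <- simulate_traces(cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = p,
        activity = activities$activity[a],
        traces = list(sim$traces),
        ppg = list(sim$ppg),
        hr = list(sim$hr),
        config = list(cfg)
      )
    }
  }
  study <- dplyr::bind_rows(rows)
  attr(study, "fps") <- fps
  attr(study, "seed") <- seed
  class(study) <- c("synthetic_study", class(study))
  study
}

#' Render synthetic frames and landmark files
#'
#' Paints each ROI polygon's interior with that ROI's simulated color for
#' the frame on a textured background, using the synthetic landmark template
#' ([landmark_template()]); optional rigid per-frame jitter of all landmarks
#' (and therefore of the painted polygons) emulates head motion. The emitted
#' landmark list matches the painted frames, so extraction round-trips the
#' generating traces.
#'
#' @param config A [sim_config()] (short durations are fine here).
#' @param width,height Frame size in pixels.
#' @param jitter_sd Standard deviation (pixels) of random rigid per-frame
#'   translation; 0 for a static face.
#' @param offsets Optional n x 2 matrix of explicit per-frame (dx, dy)
#'   translations, overriding `jitter_sd` (e.g. to push the face off-frame).
#' @return A list: `frames` (list of `height x width x 3` arrays),
#'   `landmarks` (list of 468 x 2 matrices), `traces` and ground truth as in
#'   [simulate_traces()], and `config`.
#' @export
render_frames <- function(config, width = 200, height = 200, jitter_sd = 0,
                          offsets = NULL) {
  sim <- simulate_traces(config)
  traces <- sim$traces
  n <- max(traces$frame) + 1L
  base <- landmark_template(width, height)
  if (is.null(offsets)) {
    offsets <- with_seed(config$seed + 1L, {
      if (jitter_sd > 0) matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
      else matrix(0, n, 2)
    })
  }
  stopifnot(nrow(offsets) == n)
  rois <- roi_table()
  # background texture, fixed across frames
  bg <- with_seed(config$seed + 2L, {
    array(stats::runif(height * width * 3, 40, 80), c(height, width, 3))
  })
  trace_mat <- array(NA_real_, c(28, n, 3))
  for (k in 1:28) {
    tk <- traces[traces$roi_index == k, ]
    trace_mat[k, , ] <- cbind(tk$R, tk$G, tk$B)
  }
  frames <- vector("list", n)
  landmarks <- vector("list", n)
  for (i in seq_len(n)) {
    lm <- cbind(base[, 1] + offsets[i, 1], base[, 2] + offsets[i, 2])
    fr <- bg
    for (k in 1:28) {
      mask <- roi_polygon_mask(lm, rois[k, ], height, width)
      if (attr(mask, "pixel_count") > 0L) {
        for (ch in 1:3) {
          plane <- fr[, , ch]
          plane[mask] <- trace_mat[k, i, ch]
          fr[, , ch] <- plane
        }
      }
    }
    frames[[i]] <- fr
    landmarks[[i]] <- lm
  }
  list(frames = frames, landmarks = landmarks, traces = traces,
       ppg = sim$ppg, hr = sim$hr, config = config)
}
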