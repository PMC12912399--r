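# Two-phase evaluation pipeline: (1) raw signal extraction -- frames +
# landmarks -> 28 mean-RGB traces; (2) HR estimation and scoring -- traces +
# ground truth -> pulse signals, HR series, metric records, rankings. The
# phases are separate so extraction outputs can be reused across method
# choices.

#' Pipeline configuration defaults
#'
#' All defaults equal the pipeline's canonical constants: a 6th-order
#' 0.65-4 Hz Butterworth bandpass, 6 s Welch windows with 5 s overlap, 25 s
#' acceptance windows with a 10 BPM threshold, +-12 BPM SNR mask lobes, and
#' all four rPPG methods.
#'
#' @param ... Named overrides of any default.
#' @return A named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band = c(0.65, 4),
    filter_order = 6,
    window_s = 6,
    overlap_s = 5,
    chrom_window_s = 1.6,
    grid_bpm = 0.1,
    max_invalid = 0.2,
    max_gap_s = 1,
    snr_tolerance_bpm = 12,
    snr_clamp = c(-60, 60),
    acceptance_window_s = 25,
    acceptance_threshold_bpm = 10,
    methods = c("CHROM", "POS", "LGI", "OMIT"),
    method_mode = "mean",
    renormalize = FALSE,
    top_gap = 0.3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg
}

#' Echo a configuration to an output directory
#'
#' Writes the fully resolved configuration as `config.json` so a run can be
#' reproduced from its own output.
#'
#' @param config A list (e.g. [pipeline_config()]).
#' @param dir Output directory.
#' @return The path written, invisibly.
#' @export
echo_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Extraction phase: frames + landmarks -> 28 trace CSV files
#'
#' Runs [extract_rgb_traces()] and writes one CSV per ROI
#' (`trace_rXX.csv`), plus a JSON run log with the frame count and per-ROI
#' invalid-sample counts. Output files are written atomically (via a
#' temporary name) so a failing run leaves no partial outputs.
#'
#' @param frames List of `H x W x 3` arrays, or `NULL` if `landmarks_path`
#'   points at a landmark file and `frames` are supplied some other way.
#' @param landmarks List of 468 x 2 matrices, or a path to a JSON-lines
#'   landmark file.
#' @param fps Frame rate (Hz).
#' @param dir Output directory.
#' @return Invisibly, the written trace paths.
#' @export
run_extraction <- function(frames, landmarks, fps, dir) {
  if (is.character(landmarks)) {
    if (!file.exists(landmarks)) {
      stop("landmark file not found: ", landmarks, call. = FALSE)
    }
    landmarks <- read_landmarks_jsonl(landmarks)
  }
  traces <- extract_rgb_traces(frames, landmarks, fps)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rois <- roi_table()
  tmp <- character(0)
  paths <- character(0)
  for (k in rois$roi_index) {
    tk <- traces[traces$roi_index == k, ]
    path <- file.path(dir, sprintf("trace_r%02d.csv", k))
    tmp_path <- paste0(path, ".tmp")
    write_trace_csv(tk, tmp_path)
    tmp <- c(tmp, tmp_path)
    paths <- c(paths, path)
  }
  file.rename(tmp, paths)
  log <- list(
    n_frames = length(frames),
    fps = fps,
    invalid_samples = stats::setNames(
      as.list(tapply(!traces$valid, traces$roi_index, sum)),
      sprintf("roi_%02d", rois$roi_index)
    )
  )
  jsonlite::write_json(log, file.path(dir, "extraction_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# per-segment reference HR (median of the reference series inside each
# PCC/SNR segment) on the shared segment grid of one recording
.segment_reference <- function(n, fps, t0, reference_hr, cfg) {
  seg <- metric_segments(n, fps, cfg$window_s, cfg$overlap_s)
  vapply(seg$starts, function(s) {
    t_lo <- t0 + (s - 1L) / fps
    t_hi <- t_lo + cfg$window_s
    inwin <- reference_hr$time_s >= t_lo & reference_hr$time_s <= t_hi
    if (any(inwin)) stats::median(reference_hr$bpm[inwin])
    else stats::approx(reference_hr$time_s, reference_hr$bpm,
                       xout = (t_lo + t_hi) / 2, rule = 2)$y
  }, numeric(1))
}

# full single-trace pipeline: trace -> pulse -> bandpass -> HR series
.trace_to_hr <- function(trace, method, fps, cfg) {
  pulse <- apply_rppg(trace, method, window_seconds = cfg$chrom_window_s,
                      max_gap_s = cfg$max_gap_s)
  filt <- bandpass_filter(pulse, fps = fps, low = cfg$band[1],
                          high = cfg$band[2], order = cfg$filter_order)
  hr <- welch_hr(filt, fps = fps, window_s = cfg$window_s,
                 overlap_s = cfg$overlap_s, band = cfg$band,
                 grid_bpm = cfg$grid_bpm, max_invalid = cfg$max_invalid)
  list(pulse = filt, hr = hr)
}

#' Estimate HR from one trace
#'
#' Convenience wrapper running conversion, bandpass, and spectral HR
#' estimation for a single ROI trace.
#'
#' @param trace A trace tibble.
#' @param method rPPG method tag.
#' @param fps Frame rate; from the trace's attribute when `NULL`.
#' @param config A [pipeline_config()].
#' @return An `hr_series` tibble.
#' @export
estimate_hr <- function(trace, method = "POS", fps = NULL,
                        config = pipeline_config()) {
  if (is.null(fps)) fps <- trace_fps(trace)
  .trace_to_hr(trace, method, fps, config)$hr
}

#' Evaluation phase for a single recording
#'
#' Runs every requested rPPG method over every ROI trace of one recording
#' and computes the three metrics against ground truth: MAE of the aligned
#' HR series, windowed PCC between the bandpassed pulse and the reference
#' contact PPG (interpolated onto the video grid and identically
#' bandpassed), and the masked-spectrum SNR around the aligned reference HR.
#' Never re-extracts traces.
#'
#' @param traces Long trace tibble (28 ROIs) from [extract_rgb_traces()] or
#'   [simulate_traces()].
#' @param reference_hr Ground-truth HR tibble (`time_s`, `bpm`); if `NULL`,
#'   it is derived from `reference_ppg` with the same spectral estimator.
#' @param reference_ppg Ground-truth contact PPG tibble (`time_s`, `value`),
#'   required for the PCC metric.
#' @param fps Video frame rate; inferred when `NULL`.
#' @param methods Subset of the four method tags.
#' @param config A [pipeline_config()].
#' @param activity,participant Labels attached to the records.
#' @return A metric-record tibble: one row per ROI x method with columns
#'   `roi_index`, `roi_name`, `activity`, `participant`, `method`, `mae`,
#'   `pcc`, `snr`, `n_windows`.
#' @export
evaluate_traces <- function(traces, reference_hr = NULL,
                            reference_ppg = NULL, fps = NULL,
                            methods = rppg_methods(),
                            config = pipeline_config(),
                            activity = NA_character_,
                            participant = NA_integer_) {
  if (is.null(fps)) fps <- trace_fps(traces)
  methods <- match.arg(methods, rppg_methods(), several.ok = TRUE)
  if (is.null(reference_hr)) {
    if (is.null(reference_ppg)) {
      stop("need reference_hr or reference_ppg", call. = FALSE)
    }
    gt_rate <- 1 / stats::median(diff(reference_ppg$time_s))
    reference_hr <- welch_hr(
      tibble::tibble(time_s = reference_ppg$time_s,
                     value = reference_ppg$value),
      fps = gt_rate, window_s = config$window_s,
      overlap_s = config$overlap_s, band = config$band,
      grid_bpm = config$grid_bpm
    )
  }
  # reference cPPG on the video grid, identically bandpassed, for PCC
  ref_on_grid <- NULL
  roi_ids <- unique(traces$roi_index)
  t_grid <- traces$time_s[traces$roi_index == roi_ids[1]]
  if (!is.null(reference_ppg)) {
    y <- stats::approx(reference_ppg$time_s, reference_ppg$value,
                       xout = t_grid, rule = 2)$y
    ref_on_grid <- bandpass_filter(
      tibble::tibble(time_s = t_grid, value = y, valid = TRUE), fps = fps,
      low = config$band[1], high = config$band[2],
      order = config$filter_order
    )$value
  }
  # the PCC/SNR segment grid is shared by every ROI x method of this
  # recording, so the per-segment reference HR is computed once
  seg_ref <- .segment_reference(length(t_grid), fps, t_grid[1], reference_hr,
                                config)
  nm <- length(roi_ids) * length(methods)
  rec <- list(
    roi_index = integer(nm), roi_name = character(nm), mae = numeric(nm),
    pcc = numeric(nm), snr = numeric(nm), n_windows = integer(nm)
  )
  n <- length(t_grid)
  # pass 1: convert + bandpass every ROI x method into signal columns
  pulses <- matrix(0, n, nm)
  pvalid <- matrix(TRUE, n, nm)
  r <- 0L
  row_sets <- split(seq_len(nrow(traces)), traces$roi_index)
  for (k in roi_ids) {
    ri <- row_sets[[as.character(k)]]
    tk <- tibble::new_tibble(
      list(time_s = traces$time_s[ri], R = traces$R[ri], G = traces$G[ri],
           B = traces$B[ri], valid = traces$valid[ri],
           roi_name = traces$roi_name[ri]),
      nrow = length(ri)
    )
    attr(tk, "fps") <- fps
    for (m in methods) {
      pulse <- apply_rppg(tk, m, window_seconds = config$chrom_window_s,
                          max_gap_s = config$max_gap_s)
      filt <- bandpass_filter(pulse, fps = fps, low = config$band[1],
                              high = config$band[2],
                              order = config$filter_order)
      r <- r + 1L
      pulses[, r] <- filt$value
      pvalid[, r] <- filt$valid
      rec$roi_index[r] <- k
      rec$roi_name[r] <- tk$roi_name[1]
    }
  }
  # pass 2: one batched spectral-peak search over all signals
  bw <- batch_welch(pulses, pvalid, fps, window_s = config$window_s,
                    overlap_s = config$overlap_s, band = config$band,
                    grid_bpm = config$grid_bpm,
                    max_invalid = config$max_invalid)
  for (r in seq_len(nm)) {
    keep <- bw$keep[, r]
    hr <- tibble::new_tibble(
      list(time_s = (t_grid[1] + bw$time_s)[keep], bpm = bw$bpm[keep, r]),
      nrow = sum(keep)
    )
    paired <- align_hr(hr, reference_hr)
    rec$mae[r] <- hr_mae(paired)
    rec$pcc[r] <- if (is.null(ref_on_grid)) NA_real_ else {
      as.numeric(windowed_pcc(pulses[, r], ref_on_grid, fps,
                              window_s = config$window_s,
                              overlap_s = config$overlap_s))
    }
    rec$snr[r] <- as.numeric(spectral_snr(
      pulses[, r], fps, seg_ref,
      window_s = config$window_s, overlap_s = config$overlap_s,
      tol_bpm = config$snr_tolerance_bpm, clamp = config$snr_clamp
    ))
    rec$n_windows[r] <- nrow(paired)
  }
  tibble::tibble(
    roi_index = rec$roi_index, roi_name = rec$roi_name,
    activity = activity, participant = participant,
    method = rep(methods, times = length(roi_ids)),
    mae = rec$mae, pcc = rec$pcc, snr = rec$snr,
    n_windows = rec$n_windows
  )
}

#' Evaluation phase for a whole study
#'
#' Maps [evaluate_traces()] over every participant x activity recording of
#' a [simulate_study()] result (or any tibble with the same list-columns).
#'
#' @param study A `synthetic_study` tibble.
#' @param methods Subset of the four method tags.
#' @param config A [pipeline_config()].
#' @return A metric-record tibble (rows = ROI x method x participant x
#'   activity).
#' @export
evaluate_study <- function(study, methods = rppg_methods(),
                           config = pipeline_config()) {
  rows <- purrr::map(seq_len(nrow(study)), function(i) {
    evaluate_traces(
      study$traces[[i]], reference_hr = study$hr[[i]],
      reference_ppg = study$ppg[[i]],
      fps = study$config[[i]]$fps, methods = methods, config = config,
      activity = study$activity[i], participant = study$participant[i]
    )
  })
  dplyr::bind_rows(rows)
}
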