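# Evaluation metrics: MAE on aligned HR pairs, windowed Pearson correlation
# between estimated pulse and reference contact PPG, masked-spectrum SNR,
# the min-max normalized per-ROI overall score, the 25 s acceptance rate,
# and Bland-Altman agreement statistics.

#' Mean absolute error of an aligned HR pair
#'
#' `MAE = mean(|estimate - reference|)` in BPM.
#'
#' @param pair A `paired_hr` tibble from [align_hr()] (columns `estimate`,
#'   `reference`).
#' @return MAE in BPM.
#' @export
hr_mae <- function(pair) {
  if (nrow(pair) == 0) stop("empty HR pair", call. = FALSE)
  mean(abs(pair$estimate - pair$reference))
}

# shared segmentation used by the PCC and SNR metrics (same 6 s / 5 s-overlap
# grid as the HR stage)
metric_segments <- function(n, fps, window_s, overlap_s) {
  l <- as.integer(round(window_s * fps))
  hop <- max(1L, as.integer(round((window_s - overlap_s) * fps)))
  list(starts = window_starts(n, l, hop), l = l)
}

#' Windowed Pearson correlation between pulse and reference signals
#'
#' Segments both signals into sliding windows and returns the mean of the
#' per-segment Pearson correlation coefficients, computed with the
#' sums-of-products form
#' `(m Sxy - Sx Sy) / (sqrt(m Sxx - Sx^2) sqrt(m Syy - Sy^2))`.
#' Segments in which either signal has zero variance are excluded; their
#' count is returned in the `excluded` attribute.
#'
#' @param x,y Numeric vectors of equal length on a shared time grid
#'   (estimated rPPG signal and reference contact PPG).
#' @param fps Sampling rate (Hz).
#' @param window_s,overlap_s Segment length and overlap in seconds.
#' @return Mean per-segment correlation in `[-1, 1]`, with attributes
#'   `n_segments` and `excluded`.
#' @export
windowed_pcc <- function(x, y, fps, window_s = 6, overlap_s = 5) {
  stopifnot(length(x) == length(y))
  seg <- metric_segments(length(x), fps, window_s, overlap_s)
  m <- seg$l
  idx <- outer(0:(m - 1L), seg$starts, "+")
  Xs <- matrix(x[idx], m)
  Ys <- matrix(y[idx], m)
  sx <- colSums(Xs); sy <- colSums(Ys)
  vx <- m * colSums(Xs * Xs) - sx * sx
  vy <- m * colSums(Ys * Ys) - sy * sy
  r <- ifelse(vx <= 0 | vy <= 0, NA_real_,
              (m * colSums(Xs * Ys) - sx * sy) / (sqrt(vx) * sqrt(vy)))
  excluded <- sum(is.na(r))
  if (excluded == length(r)) {
    warning("all segments had zero variance; PCC undefined")
    out <- NA_real_
  } else {
    out <- mean(r, na.rm = TRUE)
  }
  attr(out, "n_segments") <- length(r)
  attr(out, "excluded") <- excluded
  out
}

#' Masked-spectrum signal-to-noise ratio
#'
#' Per segment, the FFT power of the estimated pulse is split by a binary
#' frequency mask that keeps bins within `tol_bpm` (default +-12 BPM) of the
#' reference heart rate and of its first harmonic (twice the rate); the
#' segment SNR is `10 log10(in-mask power / out-of-mask power)`, clamped to
#' `clamp` dB, and the returned value is the mean over segments.
#'
#' @param x Numeric pulse signal.
#' @param fps Sampling rate (Hz).
#' @param ref_bpm Reference heart rate: a single value, one value per
#'   segment, or an HR series tibble (`time_s`, `bpm`) from which each
#'   segment's reference is taken as the median over the segment's time span
#'   (`t0` gives the time of the first sample).
#' @param window_s,overlap_s Segment length and overlap in seconds.
#' @param tol_bpm Half-width of the mask lobes in BPM.
#' @param clamp Two-element dB range to which segment SNRs are clamped.
#' @param t0 Time of `x[1]` in seconds (used only with an HR-series
#'   `ref_bpm`).
#' @return Mean segment SNR in dB, with attribute `n_segments`.
#' @export
spectral_snr <- function(x, fps, ref_bpm, window_s = 6, overlap_s = 5,
                         tol_bpm = 12, clamp = c(-60, 60), t0 = 0) {
  seg <- metric_segments(length(x), fps, window_s, overlap_s)
  l <- seg$l
  nseg <- length(seg$starts)
  if (is.data.frame(ref_bpm)) {
    ref <- vapply(seg$starts, function(s) {
      t_lo <- t0 + (s - 1L) / fps
      t_hi <- t_lo + window_s
      inwin <- ref_bpm$time_s >= t_lo & ref_bpm$time_s <= t_hi
      if (any(inwin)) stats::median(ref_bpm$bpm[inwin])
      else stats::approx(ref_bpm$time_s, ref_bpm$bpm,
                         xout = (t_lo + t_hi) / 2, rule = 2)$y
    }, numeric(1))
  } else if (length(ref_bpm) == 1L) {
    ref <- rep(ref_bpm, nseg)
  } else {
    stopifnot(length(ref_bpm) == nseg)
    ref <- ref_bpm
  }
  freq_bpm <- (1:(l %/% 2)) * fps / l * 60
  idx <- outer(0:(l - 1L), seg$starts, "+")
  V <- matrix(x[idx], l)
  V <- V - rep(colMeans(V), each = l)
  P <- Mod(stats::mvfft(V)[2:(l %/% 2 + 1L), , drop = FALSE])^2
  snrs <- numeric(nseg)
  for (j in seq_len(nseg)) {
    p <- P[, j]
    total <- sum(p)
    if (total <= 0) stop("segment ", j, " has zero power", call. = FALSE)
    mask <- abs(freq_bpm - ref[j]) <= tol_bpm |
      abs(freq_bpm - 2 * ref[j]) <= tol_bpm
    num <- sum(p[mask])
    den <- max(sum(p[!mask]), 1e-12 * total)
    snrs[j] <- min(max(10 * log10(num / den), clamp[1]), clamp[2])
  }
  out <- mean(snrs)
  attr(out, "n_segments") <- nseg
  out
}

#' Per-ROI overall score for one activity
#'
#' Combines aggregated MAE, PCC and SNR into the composite overall score
#' `OS_k = (1/3) [ (MAE_max - MAE_k)/(MAE_max - MAE_min)
#'               + (PCC_k - PCC_min)/(PCC_max - PCC_min)
#'               + (SNR_k - SNR_min)/(SNR_max - SNR_min) ]`,
#' where min/max run over the ROIs in `table`. Lower MAE and higher PCC/SNR
#' are better, so OS lies in `[0, 1]` with 1 for an ROI that is best in all
#' three metrics. If a metric is constant across ROIs its normalized
#' component is set to 0.5 for every ROI (neutral contribution).
#'
#' @param table A tibble with one row per ROI and columns `mae`, `pcc`,
#'   `snr` (already aggregated over participants, e.g. medians).
#' @param renormalize If `TRUE`, the OS column is additionally min-max
#'   rescaled to span exactly `[0, 1]` across ROIs.
#' @return `table` with added columns `mae_score`, `pcc_score`, `snr_score`
#'   and `os`.
#' @examples
#' overall_score(tibble::tibble(
#'   roi_index = 1:3, mae = c(2, 4, 6), pcc = c(.9, .5, .1),
#'   snr = c(6, 0, -6)
#' ))
#' @export
overall_score <- function(table, renormalize = FALSE) {
  stopifnot(all(c("mae", "pcc", "snr") %in% names(table)))
  if (nrow(table) < 2) {
    stop("overall score needs at least 2 ROIs", call. = FALSE)
  }
  minmax <- function(v, higher_better) {
    lo <- min(v); hi <- max(v)
    if (!is.finite(lo) || !is.finite(hi)) {
      stop("non-finite aggregated metric", call. = FALSE)
    }
    if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
      return(rep(0.5, length(v)))
    }
    if (higher_better) (v - lo) / (hi - lo) else (hi - v) / (hi - lo)
  }
  out <- table
  out$mae_score <- minmax(table$mae, FALSE)
  out$pcc_score <- minmax(table$pcc, TRUE)
  out$snr_score <- minmax(table$snr, TRUE)
  out$os <- (out$mae_score + out$pcc_score + out$snr_score) / 3
  if (renormalize) {
    lo <- min(out$os); hi <- max(out$os)
    out$os <- if (hi - lo < .Machine$double.eps) rep(0.5, nrow(out))
    else (out$os - lo) / (hi - lo)
  }
  out
}

# consecutive non-overlapping window assignment over a paired series;
# returns NULL-free list(window id per row, complete window ids)
.acceptance_windows <- function(pair, window_s) {
  t0 <- min(pair$time_s)
  span <- max(pair$time_s) - t0
  if (span < window_s) {
    stop("paired series spans ", signif(span, 4), " s < one ", window_s,
         " s window", call. = FALSE)
  }
  w <- floor((pair$time_s - t0) / window_s)
  complete <- 0:(floor(span / window_s) - 1L)
  list(w = w, complete = complete)
}

#' Acceptance rate of an HR measurement series
#'
#' Partitions an aligned HR pair into consecutive non-overlapping windows
#' (default 25 s; a trailing partial window is ignored); a window is
#' acceptable when its MAE is at most `threshold_bpm` (default 10 BPM). The
#' acceptance rate is the ratio of acceptable windows to total windows.
#'
#' @param pair A `paired_hr` tibble.
#' @param window_s Window length in seconds.
#' @param threshold_bpm Acceptability threshold on the window MAE.
#' @return The acceptance rate in `[0, 1]`, with attributes `n_windows` and
#'   `n_acceptable`.
#' @export
acceptance_rate <- function(pair, window_s = 25, threshold_bpm = 10) {
  aw <- .acceptance_windows(pair, window_s)
  maes <- vapply(aw$complete, function(k) {
    hr_mae(pair[aw$w == k, ])
  }, numeric(1))
  out <- mean(maes <= threshold_bpm)
  attr(out, "n_windows") <- length(maes)
  attr(out, "n_acceptable") <- sum(maes <= threshold_bpm)
  out
}

#' Bland-Altman agreement of windowed HR measurements
#'
#' Summarizes agreement between estimated and reference HR. The paired
#' series is cut into consecutive non-overlapping windows (default 25 s);
#' each window contributes one measurement pair (its mean estimate and mean
#' reference). Reported are the mean difference (bias) and the limits of
#' agreement `bias +- 1.96 SD` of the window differences.
#'
#' @param pair A `paired_hr` tibble spanning at least two windows.
#' @param window_s Window length in seconds.
#' @return A `bland_altman` object: list with `windows` (tibble of
#'   `window`, `time_s`, `mean_bpm`, `diff_bpm`), `mean_diff`, `loa_lower`,
#'   `loa_upper`, `n`.
#' @export
bland_altman <- function(pair, window_s = 25) {
  aw <- .acceptance_windows(pair, window_s)
  if (length(aw$complete) < 2) {
    stop("Bland-Altman needs at least 2 complete windows", call. = FALSE)
  }
  rows <- lapply(aw$complete, function(k) {
    p <- pair[aw$w == k, ]
    tibble::tibble(
      window = k,
      time_s = mean(p$time_s),
      mean_bpm = mean((p$estimate + p$reference) / 2),
      diff_bpm = mean(p$estimate) - mean(p$reference)
    )
  })
  windows <- dplyr::bind_rows(rows)
  d <- windows$diff_bpm
  sdd <- stats::sd(d)
  out <- list(
    windows = windows,
    mean_diff = mean(d),
    loa_lower = mean(d) - 1.96 * sdd,
    loa_upper = mean(d) + 1.96 * sdd,
    n = length(d)
  )
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (", x$n, " windows)\n", sep = "")
  cat(sprintf("  bias: %.3f BPM\n  limits of agreement: [%.3f, %.3f] BPM\n",
              x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Write Bland-Altman results
#'
#' Writes the per-window differences as CSV
#' (`window_center_s,mean_bpm,diff_bpm`) and a JSON summary (`mean_diff`,
#' `loa_low`, `loa_high`, and `acceptance_rate` when supplied).
#'
#' @param ba A `bland_altman` object.
#' @param csv_path,json_path Output paths (`NULL` to skip either file).
#' @param acceptance Optional acceptance rate to embed in the summary.
#' @return Invisibly, the summary list.
#' @export
write_bland_altman <- function(ba, csv_path = NULL, json_path = NULL,
                               acceptance = NULL) {
  if (!is.null(csv_path)) {
    df <- tibble::tibble(window_center_s = ba$windows$time_s,
                         mean_bpm = ba$windows$mean_bpm,
                         diff_bpm = ba$windows$diff_bpm)
    readr::write_csv(df, csv_path)
  }
  summary <- list(mean_diff = ba$mean_diff, loa_low = ba$loa_lower,
                  loa_high = ba$loa_upper)
  if (!is.null(acceptance)) summary$acceptance_rate <- as.numeric(acceptance)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
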