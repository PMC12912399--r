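# Heart-rate estimation: zero-phase Butterworth bandpass, windowed spectral
# peak search (Welch-style single-segment Hann periodogram with a fine
# zero-padded frequency grid), and linear-interpolation alignment of
# estimated and reference HR series.

# cache of band-restricted DFT matrices, keyed by (l, nfft, klo, khi)
.dft_cache <- new.env(parent = emptyenv())

#' Zero-phase Butterworth bandpass filter
#'
#' Filters each valid segment of a pulse signal forward and backward
#' (zero-phase) with a Butterworth bandpass. `order` is the bandpass order:
#' the default 6 corresponds to a 3rd-order prototype applied to the
#' 0.65-4 Hz band (39-240 BPM).
#'
#' @param pulse A pulse tibble (`time_s`, `value`, `valid`) from
#'   [apply_rppg()], or any tibble with those columns.
#' @param fps Sampling rate (Hz); taken from the `fps` attribute when `NULL`.
#' @param low,high Band edges in Hz.
#' @param order Bandpass filter order (even).
#' @return The input tibble with `value` replaced by the filtered signal.
#'   Valid runs too short to filter (<= 3 x order samples) are marked
#'   invalid.
#' @export
bandpass_filter <- function(pulse, fps = NULL, low = 0.65, high = 4,
                            order = 6) {
  if (is.null(fps)) fps <- trace_fps(pulse)
  if (fps <= 2 * high) {
    stop("sampling rate ", fps, " Hz cannot represent the ", high,
         " Hz cutoff (need fps > ", 2 * high, " Hz)", call. = FALSE)
  }
  stopifnot(order %% 2 == 0, low > 0, high > low)
  bf <- signal::butter(order / 2, c(low, high) / (fps / 2), type = "pass")
  valid <- if ("valid" %in% names(pulse)) pulse$valid else rep(TRUE, nrow(pulse))
  x <- pulse$value
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    if (length(idx) <= 3L * order) {
      valid[idx] <- FALSE
      x[idx] <- 0
      next
    }
    x[idx] <- signal::filtfilt(bf, x[idx])
  }
  out <- pulse
  out$value <- x
  out$valid <- valid
  attr(out, "fps") <- fps
  out
}

# Sliding-window start indices (1-based) for window length l and hop h over n
# samples. Errors if the signal is shorter than one window.
window_starts <- function(n, l, hop) {
  if (n < l) stop("signal shorter than one analysis window", call. = FALSE)
  seq(1L, n - l + 1L, by = hop)
}

# Batched spectral peak search over many equal-length signals (columns of
# `values`): windows of all signals are stacked into one matrix so the band
# DFT runs as a single large product. Same core math as welch_hr().
batch_welch <- function(values, valid, fps, window_s = 6, overlap_s = 5,
                        band = c(0.65, 4), grid_bpm = 0.1,
                        max_invalid = 0.2) {
  n <- nrow(values)
  S <- ncol(values)
  l <- as.integer(round(window_s * fps))
  hop <- max(1L, as.integer(round((window_s - overlap_s) * fps)))
  starts <- window_starts(n, l, hop)
  W <- length(starts)
  idx <- outer(0:(l - 1L), starts, "+") # l x W, within one signal
  big_idx <- as.vector(idx) + rep((seq_len(S) - 1L) * n, each = l * W)
  X <- matrix(values[big_idx], l, W * S)
  X <- X - rep(colMeans(X), each = l)
  op <- band_dft(l, fps, band, grid_bpm)
  peak <- cpp_band_peak(op$M, X)
  bpm <- matrix(op$bpm[peak], W, S)
  bad <- matrix(colMeans(matrix((!valid)[big_idx], l, W * S)), W, S)
  list(
    time_s = (starts - 1L) / fps + window_s / 2,
    bpm = bpm,
    keep = bad <= max_invalid
  )
}

# Band-restricted zero-padded Hann periodogram operator. Returns list(bpm,
# M) where M is a (2K x l) matrix; for a detrended window x, the spectral
# power on the grid is (M x)[1:K]^2 + (M x)[K + 1:K]^2 and bpm are the grid
# frequencies in beats per minute.
band_dft <- function(l, fps, band, grid_bpm) {
  nfft <- as.integer(ceiling(fps * 60 / grid_bpm))
  klo <- as.integer(ceiling(band[1] * nfft / fps))
  khi <- as.integer(floor(band[2] * nfft / fps))
  key <- paste(l, nfft, klo, khi, sep = "_")
  hit <- .dft_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- klo:khi
  tt <- 0:(l - 1L)
  ang <- outer(k, tt) * (2 * pi / nfft)
  h <- hann_window(l)
  M <- rbind(cos(ang) * rep(h, each = length(k)),
             sin(ang) * rep(h, each = length(k)))
  res <- list(bpm = k * fps / nfft * 60, M = M, K = length(k))
  .dft_cache[[key]] <- res
  res
}

#' Sliding-window spectral heart-rate estimation
#'
#' Estimates heart rate on sliding windows by locating the peak of the
#' window's power spectral density inside the analysis band. Each window is
#' mean-detrended, Hann-tapered, and evaluated on a zero-padded frequency
#' grid no coarser than `grid_bpm` (default 0.1 BPM); the estimate is 60
#' times the peak frequency and the timestamp is the window center.
#'
#' @param pulse A pulse tibble (`time_s`, `value`, optional `valid`).
#' @param fps Sampling rate (Hz); from the `fps` attribute when `NULL`.
#' @param window_s,overlap_s Window length and overlap in seconds (defaults
#'   6 and 5, i.e. a 1 s hop).
#' @param band Analysis band in Hz; the default 0.65-4 Hz spans 39-240 BPM.
#' @param grid_bpm Maximum frequency-grid spacing, in BPM.
#' @param max_invalid Windows whose invalid-sample fraction exceeds this are
#'   dropped.
#' @return An `hr_series` tibble (`time_s`, `bpm`) with attributes
#'   `window_s` and `overlap_s`.
#' @examples
#' t <- seq(0, 30, by = 1 / 30)
#' pulse <- tibble::tibble(time_s = t, value = sin(2 * pi * 1.2 * t))
#' welch_hr(pulse, fps = 30) # 72 BPM in every window
#' @export
welch_hr <- function(pulse, fps = NULL, window_s = 6, overlap_s = 5,
                     band = c(0.65, 4), grid_bpm = 0.1, max_invalid = 0.2) {
  if (is.null(fps)) fps <- trace_fps(pulse)
  stopifnot(window_s > overlap_s, overlap_s >= 0)
  x <- pulse$value
  n <- length(x)
  valid <- if ("valid" %in% names(pulse)) pulse$valid else rep(TRUE, n)
  l <- as.integer(round(window_s * fps))
  hop <- max(1L, as.integer(round((window_s - overlap_s) * fps)))
  starts <- window_starts(n, l, hop)
  idx <- outer(0:(l - 1L), starts, "+")
  X <- matrix(x[idx], l, length(starts))
  X <- X - rep(colMeans(X), each = l)
  bad_frac <- colMeans(matrix(!valid[idx], l, length(starts)))
  op <- band_dft(l, fps, band, grid_bpm)
  peak <- cpp_band_peak(op$M, X)
  keep <- bad_frac <= max_invalid
  t0 <- pulse$time_s[1]
  out <- tibble::new_tibble(list(
    time_s = (t0 + (starts - 1L) / fps + window_s / 2)[keep],
    bpm = op$bpm[peak][keep]
  ), nrow = sum(keep))
  attr(out, "window_s") <- window_s
  attr(out, "overlap_s") <- overlap_s
  class(out) <- c("hr_series", class(out))
  out
}

#' Align an estimated HR series with a reference series
#'
#' Linearly interpolates the reference values onto the estimate's
#' timestamps. Estimate points outside the reference time span are dropped.
#'
#' @param estimate,reference Tibbles with columns `time_s` and `bpm` (at
#'   least 2 points each).
#' @return A `paired_hr` tibble with columns `time_s`, `estimate`,
#'   `reference`.
#' @export
align_hr <- function(estimate, reference) {
  stopifnot(nrow(estimate) >= 2, nrow(reference) >= 2)
  lo <- min(reference$time_s)
  hi <- max(reference$time_s)
  keep <- estimate$time_s >= lo & estimate$time_s <= hi
  if (!any(keep)) {
    stop("estimate span [", min(estimate$time_s), ", ", max(estimate$time_s),
         "] s and reference span [", lo, ", ", hi, "] s are disjoint",
         call. = FALSE)
  }
  t_est <- estimate$time_s[keep]
  ref <- stats::approx(reference$time_s, reference$bpm, xout = t_est)$y
  out <- tibble::new_tibble(
    list(time_s = t_est, estimate = estimate$bpm[keep], reference = ref),
    nrow = length(t_est)
  )
  class(out) <- c("paired_hr", class(out))
  out
}

#' Read / write HR series CSV files
#'
#' Columns `time_s,bpm,source` with `source` one of `estimate`, `reference`.
#'
#' @param estimate,reference `hr_series` tibbles (reference may be `NULL`).
#' @param path File path.
#' @return `write_hr_csv()` returns `path` invisibly; `read_hr_csv()` a
#'   tibble with a `source` column.
#' @export
write_hr_csv <- function(estimate, path, reference = NULL) {
  df <- dplyr::mutate(estimate[, c("time_s", "bpm")], source = "estimate")
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(
      df,
      dplyr::mutate(reference[, c("time_s", "bpm")], source = "reference")
    )
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(time_s = "d", bpm = "d",
                                          source = "c"))
}
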