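# Independent oracles and small fixture builders shared across tests.

# Brute-force even-odd point-in-polygon: scalar loop over every pixel center
# of the frame, one ray-crossing count per point. Independent of the
# package's vectorized, bounding-box-limited rasterizer.
oracle_mask <- function(vx, vy, height, width) {
  m <- matrix(FALSE, height, width)
  nv <- length(vx)
  for (i in seq_len(height)) {
    py <- i - 0.5
    for (j in seq_len(width)) {
      px <- j - 0.5
      crossings <- 0L
      for (e in seq_len(nv)) {
        x1 <- vx[e]; y1 <- vy[e]
        x2 <- vx[e %% nv + 1L]; y2 <- vy[e %% nv + 1L]
        if ((y1 <= py && py < y2) || (y2 <= py && py < y1)) {
          xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
          if (px < xint) crossings <- crossings + 1L
        }
      }
      m[i, j] <- crossings %% 2L == 1L
    }
  }
  m
}

# Dominant positive-frequency spectral peak (Hz) of a signal: plain FFT
# argmax, no windowing or padding.
oracle_peak_hz <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x)[2:(n %/% 2 + 1L)])^2
  which.max(p) * fs / n
}

# Synthetic dichromatic RGB trace: baseline triplet plus a sinusoidal pulse
# with per-channel gains and optional white noise.
dichromatic_trace <- function(freq_hz, fps = 30, duration = 30,
                              baseline = c(180, 120, 100),
                              gains = c(0.3, 0.7, 0.4), noise_sd = 0,
                              seed = NULL) {
  t <- seq(0, duration, by = 1 / fps)
  p <- sin(2 * pi * freq_hz * t)
  if (!is.null(seed)) set.seed(seed)
  noise <- function() if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  tr <- tibble::tibble(
    frame = seq_along(t) - 1L,
    time_s = t,
    R = baseline[1] + gains[1] * p + noise(),
    G = baseline[2] + gains[2] * p + noise(),
    B = baseline[3] + gains[3] * p + noise(),
    valid = TRUE
  )
  attr(tr, "fps") <- fps
  tr
}

# paired HR helper with explicit estimate/reference vectors
make_paired <- function(time_s, estimate, reference) {
  tibble::tibble(time_s = time_s, estimate = estimate,
                 reference = reference)
}

# uniform-color frame stack
constant_frames <- function(n, height, width, rgb = c(128, 128, 128)) {
  fr <- array(0, c(height, width, 3))
  for (ch in 1:3) fr[, , ch] <- rgb[ch]
  replicate(n, fr, simplify = FALSE)
}

# frozen md5 of the canonical ROI-table serialization
ROI_TABLE_MD5 <- "4d8afe65715196b710478b2c4c1b19bd"

roi_table_checksum <- function(tab) {
  canon <- paste(tab$roi_index, tab$roi_name,
                 vapply(tab$keypoints, paste, "", collapse = ","),
                 sep = ";", collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}
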