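# RGB-trace -> pulse-signal conversion.
#
# Four classic algorithms are implemented on the 3 x N channel matrix:
#   CHROM - chrominance combination X = 3Rn - 2Gn, Y = 1.5Rn + Gn - 1.5Bn on
#           temporally normalized channels, combined as X - (sd(X)/sd(Y)) Y,
#           computed on 1.6 s Hann-weighted half-overlapping windows and
#           overlap-added.
#   POS   - projection of window-normalized channels onto the plane
#           orthogonal to the skin tone, rows (0, 1, -1) and (-2, 1, 1),
#           alpha-tuned and overlap-added with a one-sample stride.
#   LGI   - projection I - u u' with u the leading left singular vector of
#           the channel matrix; the pulse is the second projected component.
#   OMIT  - thin QR of the channel matrix (Householder); P = I - q1 q1' from
#           the first orthonormal column; pulse = second row of P C.
#
# Temporal normalization divides by the within-window channel mean, which
# makes the downstream heart-rate estimate invariant to a global gain on the
# trace. Standard-deviation ratios with a denominator below 1e-12 use
# alpha = 0 so constant channels cannot produce NaN.

rppg_methods <- function() c("CHROM", "POS", "LGI", "OMIT")

#' Convert a mean RGB trace into a pulse signal
#'
#' Applies one of the four supported rPPG algorithms to a mean RGB trace.
#' Invalid samples are linearly interpolated when the gap is at most
#' `max_gap_s` seconds; longer gaps split the trace into segments that are
#' converted independently (gap samples stay invalid, value 0). The returned
#' signal is zero-mean per segment.
#'
#' @param trace A trace tibble with columns `time_s`, `R`, `G`, `B`, `valid`
#'   (see [extract_rgb_trace()], [simulate_traces()]).
#' @param method One of `"CHROM"`, `"POS"`, `"LGI"`, `"OMIT"`.
#' @param window_seconds Sub-window length (s) for the CHROM/POS overlap-add
#'   stage; LGI and OMIT operate on whole segments.
#' @param max_gap_s Longest invalid gap (s) bridged by linear interpolation.
#' @return A pulse tibble with columns `time_s`, `value`, `valid`, `method`
#'   and attribute `fps`.
#' @examples
#' cfg <- sim_config(duration = 12, fps = 20)
#' tr <- simulate_traces(cfg)$traces
#' glab <- dplyr::filter(tr, roi_index == 4)
#' pulse <- apply_rppg(glab, "POS")
#' @export
apply_rppg <- function(trace, method = c("CHROM", "POS", "LGI", "OMIT"),
                       window_seconds = 1.6, max_gap_s = 1) {
  method <- match.arg(method)
  fps <- trace_fps(trace)
  stopifnot(fps > 0)
  n <- nrow(trace)
  valid <- trace$valid
  if (!any(valid)) stop("trace has no valid samples", call. = FALSE)

  C <- t(as.matrix(trace[, c("R", "G", "B")]))
  # interpolate short invalid gaps; identify processing segments split by
  # gaps longer than max_gap_s (and by leading/trailing invalid runs)
  seg <- fill_gaps(C, valid, fps, max_gap_s)
  C <- seg$C
  values <- numeric(n)
  out_valid <- logical(n)
  l <- max(2L, round(window_seconds * fps))
  for (s in seg$segments) {
    idx <- s[1]:s[2]
    ns <- length(idx)
    min_len <- if (method %in% c("CHROM", "POS")) l else 4L
    if (ns < min_len) next
    Cs <- C[, idx, drop = FALSE]
    v <- switch(method,
      CHROM = chrom_pulse(Cs, l),
      POS = pos_pulse(Cs, l),
      LGI = lgi_pulse(Cs),
      OMIT = omit_pulse(Cs)
    )
    values[idx] <- v - mean(v)
    out_valid[idx] <- seg$filled_valid[idx]
  }
  if (!any(out_valid)) {
    stop("no trace segment holds a full ", signif(window_seconds, 3),
         " s processing window of valid samples", call. = FALSE)
  }
  out <- tibble::new_tibble(
    list(time_s = trace$time_s, value = values, valid = out_valid,
         method = rep(method, n)),
    nrow = n
  )
  attr(out, "fps") <- fps
  class(out) <- c("rppg_pulse", class(out))
  out
}

# Linear interpolation across invalid gaps <= max_gap_s; longer gaps (and
# untouched leading/trailing invalid runs) delimit independent segments.
fill_gaps <- function(C, valid, fps, max_gap_s) {
  n <- ncol(C)
  filled <- valid
  if (any(!valid)) {
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i]) next
      internal <- i > 1L && i < length(r$values)
      if (internal && r$lengths[i] / fps <= max_gap_s) {
        gap <- starts[i]:ends[i]
        x0 <- starts[i] - 1L
        x1 <- ends[i] + 1L
        w <- (gap - x0) / (x1 - x0)
        for (ch in 1:3) C[ch, gap] <- (1 - w) * C[ch, x0] + w * C[ch, x1]
        filled[gap] <- TRUE
      }
    }
  }
  r2 <- rle(filled)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  segments <- lapply(which(r2$values), function(i) c(starts[i], ends[i]))
  list(C = C, segments = segments, filled_valid = filled)
}

hann_window <- function(l) 0.5 - 0.5 * cos(2 * pi * (0:(l - 1)) / l)

safe_ratio <- function(a, b) ifelse(b < 1e-12, 0, a / b)

chrom_pulse <- function(C, l) {
  n <- ncol(C)
  if (l %% 2L == 1L) l <- l + 1L
  l <- min(l, n)
  hop <- l %/% 2L
  starts <- unique(c(seq(1L, n - l + 1L, by = hop), n - l + 1L))
  h <- hann_window(l)
  out <- numeric(n)
  for (s in starts) {
    idx <- s:(s + l - 1L)
    Cw <- C[, idx, drop = FALSE]
    mu <- rowMeans(Cw)
    mu[mu == 0] <- 1
    Cn <- Cw / mu
    Xs <- 3 * Cn[1, ] - 2 * Cn[2, ]
    Ys <- 1.5 * Cn[1, ] + Cn[2, ] - 1.5 * Cn[3, ]
    alpha <- safe_ratio(stats::sd(Xs), stats::sd(Ys))
    S <- Xs - alpha * Ys
    out[idx] <- out[idx] + h * (S - mean(S))
  }
  out
}

pos_pulse <- function(C, l) {
  n <- ncol(C)
  l <- min(l, n)
  starts <- 1L:(n - l + 1L)
  idx <- outer(0:(l - 1L), starts, "+") # l x W sample indices
  W <- length(starts)
  Rw <- matrix(C[1, idx], l, W)
  Gw <- matrix(C[2, idx], l, W)
  Bw <- matrix(C[3, idx], l, W)
  norm_w <- function(M) {
    mu <- colMeans(M)
    mu[mu == 0] <- 1
    M / rep(mu, each = l)
  }
  Rn <- norm_w(Rw); Gn <- norm_w(Gw); Bn <- norm_w(Bw)
  S1 <- Gn - Bn
  S2 <- -2 * Rn + Gn + Bn
  sd_col <- function(M) {
    m <- colMeans(M)
    sqrt(pmax(colMeans(M * M) - m * m, 0))
  }
  alpha <- safe_ratio(sd_col(S1), sd_col(S2))
  H <- S1 + rep(alpha, each = l) * S2
  H <- H - rep(colMeans(H), each = l)
  out <- numeric(n)
  for (j in seq_len(l)) {
    pos <- starts + j - 1L
    out[pos] <- out[pos] + H[j, ]
  }
  out
}

lgi_pulse <- function(C) {
  e <- eigen(tcrossprod(C), symmetric = TRUE)
  u <- e$vectors[, 1]
  P <- diag(3) - tcrossprod(u)
  (P %*% C)[2, ]
}

omit_pulse <- function(C) {
  q1 <- qr.Q(qr(C))[, 1]
  P <- diag(3) - tcrossprod(q1)
  (P %*% C)[2, ]
}

#' Write a pulse signal to CSV
#'
#' Columns `time_s,value,method`.
#' @param pulse A pulse tibble from [apply_rppg()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(pulse, path) {
  readr::write_csv(pulse[, c("time_s", "value", "method")], path)
  invisible(path)
}
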