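# Polygon rasterization for ROI masks.
#
# Coordinate convention: landmarks are pixel coordinates with the origin at
# the top-left pixel's corner, x rightward and y downward; pixel (row i,
# col j) (1-based in R) has center (j - 0.5, i - 0.5). A pixel belongs to the
# mask iff its center lies inside the closed polygon under the even-odd rule.

# Even-odd (crossing-number parity) point-in-polygon test, vectorized over
# points. px, py: point coordinates; vx, vy: polygon vertices in order.
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

#' Rasterize an ROI polygon into a pixel mask
#'
#' Connects the ROI's keypoints in their listed order, closes the loop, and
#' marks every pixel whose center lies inside the polygon (even-odd fill
#' rule). The polygon is implicitly clipped to the frame: pixels outside the
#' `height` x `width` grid simply do not exist. Landmarks may lie outside the
#' frame bounds.
#'
#' @param landmarks A 468 x 2 numeric matrix of (x, y) pixel coordinates,
#'   indexed by face-mesh keypoint serial number + 1. Origin at the top-left
#'   pixel corner; pixel (i, j) has center (j - 0.5, i - 0.5).
#' @param roi An ROI selector accepted by [roi_get()], or a one-row tibble
#'   from [roi_table()].
#' @param height,width Frame dimensions in pixels (>= 1).
#' @return A logical `height` x `width` matrix with attribute `pixel_count`.
#' @examples
#' lm <- landmark_template(width = 64, height = 64)
#' m <- roi_polygon_mask(lm, "glabella", 64, 64)
#' attr(m, "pixel_count")
#' @export
roi_polygon_mask <- function(landmarks, roi, height, width) {
  stopifnot(height >= 1, width >= 1)
  landmarks <- validate_landmarks(landmarks)
  if (is.data.frame(roi)) {
    kp <- roi$keypoints[[1]]
  } else {
    kp <- roi_get(roi)$keypoints[[1]]
  }
  if (any(kp < 0L | kp > 467L)) {
    stop("ROI keypoint index outside 0-467", call. = FALSE)
  }
  vx <- landmarks[kp + 1L, 1L]
  vy <- landmarks[kp + 1L, 2L]
  mask <- matrix(FALSE, nrow = height, ncol = width)
  # restrict the test to the polygon's bounding box (padded one pixel)
  jlo <- max(1L, as.integer(floor(min(vx))))
  jhi <- min(width, as.integer(ceiling(max(vx)) + 1L))
  ilo <- max(1L, as.integer(floor(min(vy))))
  ihi <- min(height, as.integer(ceiling(max(vy)) + 1L))
  if (jlo <= jhi && ilo <= ihi) {
    jj <- jlo:jhi
    ii <- ilo:ihi
    px <- rep(jj - 0.5, each = length(ii))
    py <- rep(ii - 0.5, times = length(jj))
    inside <- .points_in_polygon(px, py, vx, vy)
    mask[ii, jj] <- inside
  }
  attr(mask, "pixel_count") <- sum(mask)
  mask
}

# Check / coerce a landmark set: 468 finite (x, y) rows.
validate_landmarks <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != 468L || ncol(landmarks) < 2L) {
    stop("landmarks must be a 468 x 2 matrix of (x, y) coordinates",
         call. = FALSE)
  }
  landmarks <- landmarks[, 1:2, drop = FALSE]
  if (!all(is.finite(landmarks))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  landmarks
}
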