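# A synthetic 468-point face-mesh landmark template.
#
# This is a hand-built schematic face layout, NOT the canonical face-mesh
# geometry: only plausibility matters here. Every keypoint referenced by the
# 28 ROI polygons is placed so that each polygon is simple (non
# self-intersecting) with nonzero area, laid out anatomically (forehead rows,
# nose column, cheeks, chin). Coordinates are authored for the midline and
# the left half; right-side keypoints are mirror images. The mirror pairs
# were derived from the order correspondence of the left/right ROI keypoint
# lists. Mesh indices not used by any ROI are distributed along a face
# outline ellipse. All coordinates live in the unit square (x right, y down)
# and are scaled by the requested frame size.

# midline keypoints: index = normalized (x, y)
.tpl_mid <- list(
  `10`  = c(0.500, 0.060),
  `151` = c(0.500, 0.140),
  `8`   = c(0.500, 0.220),
  `197` = c(0.500, 0.300),
  `5`   = c(0.500, 0.380),
  `4`   = c(0.500, 0.420),
  `1`   = c(0.500, 0.450),
  `2`   = c(0.500, 0.480),
  `0`   = c(0.500, 0.520),
  `18`  = c(0.500, 0.620),
  `152` = c(0.500, 0.720)
)

# left-side keypoints and their right-side mirror indices: left_index =
# c(x, y, right_index)
.tpl_left <- list(
  `109` = c(0.440, 0.070, 338), `108` = c(0.440, 0.130, 337),
  `67`  = c(0.380, 0.075, 297), `103` = c(0.320, 0.090, 332),
  `104` = c(0.310, 0.150, 333), `105` = c(0.360, 0.165, 334),
  `66`  = c(0.410, 0.170, 296), `107` = c(0.440, 0.180, 336),
  `55`  = c(0.460, 0.215, 285), `193` = c(0.465, 0.250, 417),
  `122` = c(0.465, 0.280, 351), `196` = c(0.470, 0.300, 419),
  `3`   = c(0.470, 0.345, 248), `51`  = c(0.475, 0.375, 281),
  `45`  = c(0.470, 0.410, 275), `44`  = c(0.480, 0.455, 274),
  `134` = c(0.450, 0.430, 363), `220` = c(0.455, 0.445, 440),
  `237` = c(0.460, 0.455, 457), `131` = c(0.430, 0.420, 360),
  `49`  = c(0.415, 0.440, 279), `102` = c(0.420, 0.465, 331),
  `64`  = c(0.435, 0.475, 294), `219` = c(0.450, 0.475, 439),
  `218` = c(0.455, 0.465, 438), `217` = c(0.450, 0.370, 437),
  `126` = c(0.435, 0.395, 355), `209` = c(0.430, 0.410, 429),
  `188` = c(0.460, 0.315, 412), `114` = c(0.440, 0.345, 343),
  `236` = c(0.468, 0.345, 456), `97`  = c(0.470, 0.485, 326),
  `167` = c(0.475, 0.510, 393), `37`  = c(0.480, 0.525, 267),
  `165` = c(0.445, 0.500, 391), `185` = c(0.430, 0.525, 409),
  `40`  = c(0.445, 0.535, 270), `39`  = c(0.465, 0.535, 269),
  `98`  = c(0.445, 0.480, 327), `203` = c(0.410, 0.490, 423),
  `186` = c(0.420, 0.515, 410), `54`  = c(0.300, 0.100, 284),
  `21`  = c(0.260, 0.130, 251), `162` = c(0.240, 0.180, 389),
  `127` = c(0.240, 0.250, 356), `116` = c(0.270, 0.300, 345),
  `143` = c(0.285, 0.260, 372), `156` = c(0.295, 0.210, 383),
  `70`  = c(0.310, 0.170, 300), `63`  = c(0.315, 0.130, 293),
  `68`  = c(0.320, 0.105, 298), `100` = c(0.400, 0.365, 329),
  `118` = c(0.360, 0.345, 347), `117` = c(0.310, 0.330, 346),
  `123` = c(0.280, 0.340, 352), `147` = c(0.300, 0.390, 376),
  `187` = c(0.330, 0.430, 411), `205` = c(0.370, 0.460, 425),
  `129` = c(0.430, 0.460, 358), `177` = c(0.280, 0.440, 401),
  `215` = c(0.290, 0.490, 435), `138` = c(0.300, 0.530, 367),
  `172` = c(0.315, 0.565, 397), `136` = c(0.345, 0.590, 365),
  `135` = c(0.375, 0.585, 364), `212` = c(0.410, 0.555, 432),
  `206` = c(0.415, 0.500, 426), `57`  = c(0.440, 0.565, 287),
  `210` = c(0.400, 0.585, 430), `169` = c(0.400, 0.625, 394),
  `150` = c(0.410, 0.660, 379), `149` = c(0.420, 0.695, 378),
  `204` = c(0.440, 0.630, 424), `43`  = c(0.450, 0.590, 273),
  `83`  = c(0.465, 0.625, 313), `182` = c(0.440, 0.635, 406),
  `194` = c(0.425, 0.650, 418), `32`  = c(0.420, 0.665, 262),
  `140` = c(0.430, 0.685, 369), `176` = c(0.450, 0.700, 400),
  `148` = c(0.470, 0.715, 377)
)

# Normalized 468 x 2 coordinate matrix (unit square), built once at load.
.build_template <- function() {
  pts <- matrix(NA_real_, nrow = 468, ncol = 2)
  for (k in names(.tpl_mid)) {
    pts[as.integer(k) + 1L, ] <- .tpl_mid[[k]]
  }
  for (k in names(.tpl_left)) {
    v <- .tpl_left[[k]]
    pts[as.integer(k) + 1L, ] <- v[1:2]
    pts[as.integer(v[3]) + 1L, ] <- c(1 - v[1], v[2])
  }
  # remaining (unused-by-ROI) indices: spread along a face-outline ellipse
  free <- which(is.na(pts[, 1]))
  th <- 2 * pi * (seq_along(free) - 1) / length(free)
  pts[free, 1] <- 0.5 + 0.30 * cos(th)
  pts[free, 2] <- 0.40 + 0.36 * sin(th)
  pts
}

.template_norm <- .build_template()

#' Synthetic face-mesh landmark template
#'
#' A schematic, hand-built 468-point landmark layout in which every shipped
#' ROI polygon is simple and has nonzero area. It is synthetic -- a plausible
#' face-shaped stand-in for real face-mesh detector output -- and exists so
#' that rendering and extraction can be exercised without any detector or
#' video data.
#'
#' @param width,height Frame size in pixels the template should span; the
#'   normalized unit-square layout is scaled by these factors.
#' @param dx,dy Optional rigid translation (pixels), e.g. head-motion jitter.
#' @return A 468 x 2 numeric matrix of (x, y) pixel coordinates.
#' @examples
#' lm <- landmark_template(160, 160)
#' @export
landmark_template <- function(width = 1, height = 1, dx = 0, dy = 0) {
  pts <- .template_norm
  cbind(pts[, 1] * width + dx, pts[, 2] * height + dy)
}
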