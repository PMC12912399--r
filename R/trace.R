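# Mean-RGB trace extraction: per frame and ROI, the arithmetic mean of each
# color channel over the ROI's polygon mask.

#' Extract a mean RGB trace for one ROI
#'
#' For every frame, rasterizes the ROI polygon from that frame's landmarks
#' and averages the red, green and blue channels over the mask. Frames whose
#' mask is empty (e.g. the face moved off-frame) are marked invalid and carry
#' placeholder `NA` samples.
#'
#' @param frames A list of `height x width x 3` numeric arrays on the 0-255
#'   intensity scale (R, G, B planes).
#' @param landmarks A list of 468 x 2 landmark matrices, one per frame (see
#'   [roi_polygon_mask()] for the coordinate convention).
#' @param roi ROI selector accepted by [roi_get()].
#' @param fps Frame rate in Hz (> 0).
#' @return An `rppg_trace` tibble with columns `frame` (0-based), `time_s`,
#'   `R`, `G`, `B`, `valid`, and attribute `fps`.
#' @export
extract_rgb_trace <- function(frames, landmarks, roi, fps) {
  stopifnot(fps > 0)
  if (length(frames) != length(landmarks)) {
    stop("frame count (", length(frames), ") and landmark-frame count (",
         length(landmarks), ") differ", call. = FALSE)
  }
  roi_row <- if (is.data.frame(roi)) roi else roi_get(roi)
  n <- length(frames)
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  valid <- logical(n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    mask <- roi_polygon_mask(landmarks[[i]], roi_row, dim(fr)[1], dim(fr)[2])
    if (attr(mask, "pixel_count") > 0L) {
      out[i, ] <- c(mean(fr[, , 1][mask]), mean(fr[, , 2][mask]),
                    mean(fr[, , 3][mask]))
      valid[i] <- TRUE
    }
  }
  new_trace(
    tibble::tibble(
      frame = seq_len(n) - 1L,
      time_s = (seq_len(n) - 1L) / fps,
      R = out[, 1], G = out[, 2], B = out[, 3],
      valid = valid
    ),
    fps = fps,
    roi_index = roi_row$roi_index, roi_name = roi_row$roi_name
  )
}

#' Extract mean RGB traces for all 28 ROIs
#'
#' @inheritParams extract_rgb_trace
#' @param rois ROI definition table, by default [roi_table()].
#' @return A long tibble: one [extract_rgb_trace()] result per ROI, stacked,
#'   with `roi_index` and `roi_name` columns; attribute `fps`.
#' @export
extract_rgb_traces <- function(frames, landmarks, fps, rois = roi_table()) {
  out <- purrr::map(seq_len(nrow(rois)), function(i) {
    tr <- extract_rgb_trace(frames, landmarks, rois[i, ], fps)
    tr$roi_index <- rois$roi_index[i]
    tr$roi_name <- rois$roi_name[i]
    tr
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::relocate(res, "roi_index", "roi_name")
  attr(res, "fps") <- fps
  res
}

# trace constructor: tibble + fps (+ roi identity) metadata
new_trace <- function(df, fps, roi_index = NA_integer_, roi_name = NA_character_) {
  attr(df, "fps") <- fps
  attr(df, "roi_index") <- roi_index
  attr(df, "roi_name") <- roi_name
  class(df) <- c("rppg_trace", class(df))
  df
}

#' Frame rate of a trace or pulse tibble
#'
#' Returns the `fps` attribute if present, otherwise infers it from the
#' median spacing of `time_s`.
#'
#' @param x A tibble with a `time_s` column.
#' @return Frames per second (Hz).
#' @export
trace_fps <- function(x) {
  fps <- attr(x, "fps")
  if (!is.null(fps)) return(fps)
  dt <- stats::median(diff(sort(unique(x$time_s))))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer frame rate", call. = FALSE)
  1 / dt
}

#' Read / write trace CSV files
#'
#' Traces are stored as CSV with header `frame,time_s,R,G,B,valid`
#' (`time_s = frame / fps`).
#'
#' @param trace A trace tibble from [extract_rgb_trace()] or
#'   [simulate_traces()].
#' @param path File path.
#' @param fps Frame rate used to restore the `fps` attribute on read; if
#'   `NULL` it is inferred from `time_s`.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a trace tibble.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace[, c("frame", "time_s", "R", "G", "B", "valid")], path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, fps = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          frame = "i", time_s = "d", R = "d", G = "d",
                          B = "d", valid = "l"
                        ))
  if (is.null(fps)) fps <- 1 / stats::median(diff(df$time_s))
  new_trace(tibble::as_tibble(df), fps = fps)
}

#' Read / write face-mesh landmark files (JSON lines)
#'
#' One JSON object per frame: `{"frame": int, "points": [[x, y], ...]}` with
#' exactly 468 points.
#'
#' @param landmarks A list of 468 x 2 matrices.
#' @param path File path.
#' @return `write_landmarks_jsonl()` returns `path` invisibly;
#'   `read_landmarks_jsonl()` returns a list of 468 x 2 matrices.
#' @export
write_landmarks_jsonl <- function(landmarks, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(landmarks)) {
    m <- validate_landmarks(landmarks[[i]])
    writeLines(jsonlite::toJSON(
      list(frame = i - 1L, points = unname(m)),
      auto_unbox = TRUE, digits = NA
    ), con)
  }
  invisible(path)
}

#' @rdname write_landmarks_jsonl
#' @export
read_landmarks_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    m <- rec$points
    if (is.null(dim(m)) || nrow(m) != 468L) {
      stop("landmark record ", i, " in ", path,
           " does not contain 468 points", call. = FALSE)
    }
    out[[i]] <- validate_landmarks(m)
  }
  out
}
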