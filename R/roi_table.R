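# The 28 anatomically defined facial ROIs, each an ordered keypoint polygon in
# the 468-point face-mesh index convention (indices 0-467).
.roi_keypoints <- list(
  `1`  = c(10, 109, 108, 151, 337, 338),
  `2`  = c(67, 103, 104, 105, 66, 107, 108, 109),
  `3`  = c(297, 338, 337, 336, 296, 334, 333, 332),
  `4`  = c(151, 108, 107, 55, 8, 285, 336, 337),
  `5`  = c(8, 55, 193, 122, 196, 197, 419, 351, 417, 285),
  `6`  = c(197, 196, 3, 51, 5, 281, 248, 419),
  `7`  = c(4, 45, 134, 220, 237, 44, 1, 274, 457, 440, 363, 275),
  `8`  = c(134, 131, 49, 102, 64, 219, 218, 237, 220),
  `9`  = c(363, 440, 457, 438, 439, 294, 331, 279, 360),
  `10` = c(5, 51, 45, 4, 275, 281),
  `11` = c(3, 217, 126, 209, 131, 134),
  `12` = c(248, 363, 360, 429, 355, 437),
  `13` = c(188, 114, 217, 236, 196),
  `14` = c(412, 419, 456, 437, 343),
  `15` = c(2, 97, 167, 37, 0, 267, 393, 326),
  `16` = c(97, 165, 185, 40, 39, 37, 167),
  `17` = c(326, 393, 267, 269, 270, 409, 391),
  `18` = c(97, 98, 203, 186, 185, 165),
  `19` = c(326, 391, 409, 410, 423, 327),
  `20` = c(54, 21, 162, 127, 116, 143, 156, 70, 63, 68),
  `21` = c(284, 298, 293, 300, 383, 372, 345, 356, 389, 251),
  `22` = c(126, 100, 118, 117, 116, 123, 147, 187, 205, 203, 129, 209),
  `23` = c(355, 429, 358, 423, 425, 411, 376, 352, 345, 346, 347, 329),
  `24` = c(203, 205, 187, 147, 177, 215, 138, 172, 136, 135, 212, 186, 206),
  `25` = c(423, 426, 410, 432, 364, 365, 397, 367, 435, 401, 376, 411, 425),
  `26` = c(18, 83, 182, 194, 32, 140, 176, 148, 152, 377, 400, 369, 262, 418, 406, 313),
  `27` = c(57, 212, 210, 169, 150, 149, 176, 140, 204, 43),
  `28` = c(287, 273, 424, 369, 400, 378, 379, 394, 430, 432)
)

.roi_names <- c(
  "medial forehead", "left lateral forehead", "right lateral forehead",
  "glabella", "upper nasal dorsum", "lower nasal dorsum", "soft triangle",
  "left ala", "right ala", "nasal tip", "left lower nasal sidewall",
  "right lower nasal sidewall", "left mid nasal sidewall",
  "right mid nasal sidewall", "philtrum", "left upper lip", "right upper lip",
  "left nasolabial fold", "right nasolabial fold", "left temporal",
  "right temporal", "left malar", "right malar", "left lower cheek",
  "right lower cheek", "chin", "left marionette fold", "right marionette fold"
)

#' The 28 facial regions of interest
#'
#' Returns the shipped table of 28 anatomically defined facial regions used
#' for camera-based pulse extraction. Each region is an ordered list of
#' keypoint indices in the 468-point face-mesh convention (serial numbers
#' 0-467); connecting the keypoints in order and closing the loop yields the
#' region's polygon. The set covers the forehead (medial, lateral, glabella),
#' the nose (dorsum, sidewalls, alae, tip, soft triangle), the perioral area
#' (philtrum, upper lip, nasolabial and marionette folds), cheeks (malar,
#' lower cheek), temples, and chin.
#'
#' @return A tibble with 28 rows and columns `roi_index` (1-28), `roi_name`,
#'   and `keypoints` (list-column of integer vectors).
#' @examples
#' roi_table()
#' roi_table()$keypoints[[4]] # the glabella polygon
#' @export
roi_table <- function() {
  tibble::tibble(
    roi_index = seq_along(.roi_names),
    roi_name = .roi_names,
    keypoints = lapply(.roi_keypoints, as.integer)
  )
}

#' Look up a single ROI definition
#'
#' @param roi An `roi_index` (1-28) or exact `roi_name`.
#' @return A one-row tibble as in [roi_table()].
#' @examples
#' roi_get("glabella")
#' @export
roi_get <- function(roi) {
  tab <- roi_table()
  if (is.numeric(roi)) {
    out <- tab[tab$roi_index == as.integer(roi), ]
  } else {
    out <- tab[tab$roi_name == roi, ]
  }
  if (nrow(out) != 1L) {
    stop("unknown ROI: ", roi, call. = FALSE)
  }
  out
}

#' Export the ROI table as JSON
#'
#' Writes the 28 ROI definitions as a JSON array of
#' `{"index": k, "name": str, "keypoints": [int, ...]}` objects.
#'
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly), or a JSON string when `path` is `NULL`.
#' @export
roi_table_json <- function(path = NULL) {
  tab <- roi_table()
  obj <- lapply(seq_len(nrow(tab)), function(i) {
    list(index = tab$roi_index[i], name = tab$roi_name[i],
         keypoints = tab$keypoints[[i]])
  })
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
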