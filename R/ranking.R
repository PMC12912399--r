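# ROI ranking: per-activity median aggregation over participants, overall
# scores, summation across activities, descending ranking, and report export.

#' Aggregate metric records and rank the ROIs
#'
#' For each activity (and rPPG method), the per-participant MAE/PCC/SNR
#' records are aggregated to their median per ROI and converted to overall
#' scores with [overall_score()]. Per-method overall scores are then either
#' averaged across methods (`method_mode = "mean"`, the default) or kept
#' separate (`"per_method"`, returning one ranking per method). Each ROI's
#' overall scores are summed across activities and the ROIs are ranked in
#' descending order of the sum; ties break by lower aggregated MAE, then by
#' ROI index. ROIs missing any (ROI, activity) cell are excluded with a
#' warning.
#'
#' A "top group" is flagged as the largest ranking prefix that is separated
#' from the rest by a summed-OS gap larger than `top_gap`; this formalizes
#' the visual identification of a leading cluster and is advisory only.
#'
#' @param records A tibble of metric records with columns `roi_index`,
#'   `roi_name`, `activity`, `participant`, `method`, `mae`, `pcc`, `snr`
#'   (see [evaluate_study()]).
#' @param method_mode `"mean"` (average OS across rPPG methods) or
#'   `"per_method"`.
#' @param renormalize Passed to [overall_score()].
#' @param top_gap Summed-OS gap that delimits the top group.
#' @return A `roi_ranking` object (or a named list of them when
#'   `method_mode = "per_method"`): list with `ranking` (tibble `rank`,
#'   `roi_index`, `roi_name`, one `os_<activity>` column per activity,
#'   `os_sum`, `mae_agg`, `top_group`), `os` (long per-activity score
#'   table), `activities`, `method_mode`, `top_gap`.
#' @export
rank_rois <- function(records, method_mode = c("mean", "per_method"),
                      renormalize = FALSE, top_gap = 0.3) {
  method_mode <- match.arg(method_mode)
  needed <- c("roi_index", "roi_name", "activity", "participant", "method",
              "mae", "pcc", "snr")
  stopifnot(all(needed %in% names(records)))
  activities <- unique(records$activity)

  # drop ROIs with missing (roi, activity) cells
  cells <- dplyr::distinct(records, .data$roi_index, .data$activity)
  counts <- dplyr::count(cells, .data$roi_index)
  incomplete <- counts$roi_index[counts$n < length(activities)]
  if (length(incomplete) > 0) {
    warning("excluding ROI(s) with missing activity cells: ",
            paste(incomplete, collapse = ", "))
    records <- records[!records$roi_index %in% incomplete, ]
  }

  med <- records |>
    dplyr::group_by(.data$activity, .data$method, .data$roi_index,
                    .data$roi_name) |>
    dplyr::summarise(mae = stats::median(.data$mae),
                     pcc = stats::median(.data$pcc),
                     snr = stats::median(.data$snr), .groups = "drop")

  scored <- med |>
    dplyr::group_by(.data$activity, .data$method) |>
    dplyr::group_modify(~ overall_score(.x, renormalize = renormalize)) |>
    dplyr::ungroup()

  if (method_mode == "per_method") {
    out <- lapply(split(scored, scored$method), function(sc) {
      .build_ranking(sc, activities, "per_method", top_gap)
    })
    return(out)
  }
  pooled <- scored |>
    dplyr::group_by(.data$activity, .data$roi_index, .data$roi_name) |>
    dplyr::summarise(os = mean(.data$os), mae = mean(.data$mae),
                     pcc = mean(.data$pcc), snr = mean(.data$snr),
                     .groups = "drop")
  .build_ranking(pooled, activities, "mean", top_gap)
}

.build_ranking <- function(scored, activities, method_mode, top_gap) {
  sums <- scored |>
    dplyr::group_by(.data$roi_index, .data$roi_name) |>
    dplyr::summarise(os_sum = sum(.data$os), mae_agg = mean(.data$mae),
                     .groups = "drop")
  wide <- scored |>
    dplyr::select("roi_index", "activity", "os") |>
    tidyr::pivot_wider(names_from = "activity", values_from = "os",
                       names_prefix = "os_")
  ranking <- dplyr::left_join(sums, wide, by = "roi_index") |>
    dplyr::arrange(dplyr::desc(.data$os_sum), .data$mae_agg,
                   .data$roi_index) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank", "roi_index", "roi_name",
                    dplyr::starts_with("os_"), "os_sum", "mae_agg")
  gaps <- -diff(ranking$os_sum)
  cut <- which(gaps > top_gap)
  top_n <- if (length(cut) > 0) max(cut) else 0L
  ranking$top_group <- ranking$rank <= top_n
  structure(list(
    ranking = ranking, os = scored, activities = activities,
    method_mode = method_mode, top_gap = top_gap
  ), class = "roi_ranking")
}

#' @export
print.roi_ranking <- function(x, n = 10, ...) {
  cat("ROI ranking over", length(x$activities), "activities (",
      x$method_mode, "across methods )\n")
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' Export a ranking report
#'
#' Writes `ranking.csv` (rank, ROI, per-activity OS, sum),
#' `ranking_metadata.json` (activities, method combination mode, top-group
#' threshold and membership) and, optionally, a stacked-bar figure
#' `ranking_os.png`. Output is deterministic for identical inputs.
#'
#' @param result A `roi_ranking` from [rank_rois()].
#' @param dir Output directory (created if needed).
#' @param figure Write the stacked-bar PNG?
#' @return Invisibly, the paths written.
#' @export
export_roi_report <- function(result, dir, figure = TRUE) {
  stopifnot(inherits(result, "roi_ranking"))
  if (nrow(result$ranking) == 0) stop("empty ranking result", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "ranking.csv")
  readr::write_csv(result$ranking, csv)
  meta <- file.path(dir, "ranking_metadata.json")
  jsonlite::write_json(list(
    activities = result$activities,
    method_mode = result$method_mode,
    top_gap = result$top_gap,
    top_group = result$ranking$roi_index[result$ranking$top_group],
    n_rois = nrow(result$ranking)
  ), meta, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, meta)
  if (figure) {
    fig <- file.path(dir, "ranking_os.png")
    ggplot2::ggsave(fig, ggplot2::autoplot(result),
                    width = 7, height = 6, dpi = 120)
    paths <- c(paths, fig)
  }
  invisible(paths)
}

#' Write metric records to CSV
#'
#' Columns `roi_index,roi_name,activity,participant,method,mae,pcc,snr`.
#'
#' @param records Metric record tibble from [evaluate_study()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  cols <- c("roi_index", "roi_name", "activity", "participant", "method",
            "mae", "pcc", "snr")
  readr::write_csv(records[, cols], path)
  invisible(path)
}
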