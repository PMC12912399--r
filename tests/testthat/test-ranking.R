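# Aggregation, overall-score ranking, and report export.

# metric records with prescribed per-ROI quality, one participant
records_from_scores <- function(mae, pcc, snr, activities = "a",
                                methods = "OMIT", participants = 1) {
  n <- length(mae)
  grid <- expand.grid(roi = seq_len(n), activity = activities,
                      method = methods, participant = participants,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    roi_index = grid$roi,
    roi_name = paste0("roi", grid$roi),
    activity = grid$activity,
    participant = grid$participant,
    method = grid$method,
    mae = mae[grid$roi],
    pcc = pcc[grid$roi],
    snr = snr[grid$roi]
  )
}

test_that("a single activity ranks ROIs by their overall score", {
  rec <- records_from_scores(mae = c(1, 3, 5), pcc = c(0.9, 0.5, 0.1),
                             snr = c(10, 0, -10))
  rk <- rank_rois(rec)
  expect_equal(rk$ranking$roi_index, c(1L, 2L, 3L))
  expect_equal(rk$ranking$os_sum, c(1, 0.5, 0))
})

test_that("an everywhere-dominant ROI attains the theoretical maximum", {
  set.seed(15)
  acts <- c("a1", "a2", "a3", "a4")
  mae <- c(1, 4, 6, 9)
  pcc <- c(0.95, 0.6, 0.3, 0.05)
  snr <- c(12, 4, -2, -9)
  rec <- records_from_scores(mae, pcc, snr, activities = acts)
  rk <- rank_rois(rec)
  expect_equal(rk$ranking$roi_index[1], 1L)
  expect_equal(rk$ranking$os_sum[1], 4)
  expect_lte(max(rk$ranking$os_sum), length(acts))
})

test_that("ties break by aggregated MAE then ROI index", {
  # MAE and PCC components cancel exactly: both ROIs score OS = 0.5,
  # so the lower-MAE ROI must rank first
  rec <- records_from_scores(mae = c(3, 1), pcc = c(0.8, 0.2),
                             snr = c(1, 1))
  rk <- rank_rois(rec)
  expect_equal(rk$ranking$os_sum, c(0.5, 0.5))
  expect_equal(rk$ranking$roi_index, c(2L, 1L))
  # fully degenerate metrics: equal OS and MAE, order falls back to index
  rec2 <- records_from_scores(mae = c(2, 2, 2), pcc = c(0.5, 0.5, 0.5),
                              snr = c(1, 1, 1))
  rk2 <- rank_rois(rec2)
  expect_equal(rk2$ranking$roi_index, 1:3)
  expect_false(any(rk2$ranking$top_group))
})

test_that("missing activity cells exclude the ROI with a warning", {
  rec <- records_from_scores(mae = c(1, 2, 3), pcc = c(0.9, 0.5, 0.2),
                             snr = c(5, 0, -5), activities = c("a1", "a2"))
  rec <- rec[!(rec$roi_index == 2 & rec$activity == "a2"), ]
  expect_warning(rk <- rank_rois(rec), "missing activity")
  expect_setequal(rk$ranking$roi_index, c(1L, 3L))
})

test_that("per-method mode returns one ranking per method", {
  rec <- records_from_scores(mae = c(1, 2, 3), pcc = c(0.9, 0.5, 0.2),
                             snr = c(5, 0, -5),
                             methods = c("POS", "OMIT"))
  out <- rank_rois(rec, method_mode = "per_method")
  expect_setequal(names(out), c("POS", "OMIT"))
  expect_s3_class(out$POS, "roi_ranking")
})

test_that("median aggregation over participants feeds the scores", {
  rec <- records_from_scores(mae = c(1, 5), pcc = c(0.9, 0.1),
                             snr = c(5, -5), participants = 1:3)
  # corrupt one participant of ROI 1 badly; the median shrugs it off
  rec$mae[rec$roi_index == 1 & rec$participant == 2] <- 50
  rk <- rank_rois(rec)
  expect_equal(rk$ranking$roi_index[1], 1L)
})

test_that("rank order is stable under a common shift of every metric", {
  set.seed(16)
  mae <- runif(6, 1, 9)
  pcc <- runif(6, 0, 0.9)
  snr <- runif(6, -8, 8)
  base <- rank_rois(records_from_scores(mae, pcc, snr))
  shifted <- rank_rois(records_from_scores(mae + 5, pcc, snr))
  expect_equal(shifted$ranking$roi_index, base$ranking$roi_index)
})

test_that("graded amplitudes yield amplitude-ordered rankings", {
  rhos <- vapply(1:3, function(s) {
    amps <- default_roi_amplitudes()
    keep <- c(4, 1, 22, 6, 15, 20, 26, 28)
    study <- simulate_study(n_participants = 2, seed = 40 + s)
    recs <- dplyr::bind_rows(lapply(seq_len(nrow(study)), function(i) {
      tr <- study$traces[[i]]
      sub <- tr[tr$roi_index %in% keep, ]
      attr(sub, "fps") <- 20
      evaluate_traces(sub, reference_hr = study$hr[[i]],
                      reference_ppg = study$ppg[[i]], fps = 20,
                      methods = "OMIT", activity = study$activity[i],
                      participant = study$participant[i])
    }))
    rk <- rank_rois(recs)
    amp_order <- amps[as.character(rk$ranking$roi_index)]
    cor(rk$ranking$rank, rank(-amp_order), method = "spearman")
  }, numeric(1))
  expect_gte(median(rhos), 0.9)
})

test_that("report export is deterministic and complete", {
  rec <- records_from_scores(mae = runif(28, 1, 9), pcc = runif(28, 0, 0.9),
                             snr = runif(28, -8, 8),
                             activities = c("a1", "a2"))
  rk <- rank_rois(rec)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_roi_report(rk, d1, figure = FALSE)
  export_roi_report(rk, d2, figure = FALSE)
  csv1 <- readLines(file.path(d1, "ranking.csv"))
  csv2 <- readLines(file.path(d2, "ranking.csv"))
  expect_identical(csv1, csv2)
  expect_equal(length(csv1) - 1L, 28L)
  meta <- jsonlite::fromJSON(file.path(d1, "ranking_metadata.json"))
  expect_equal(meta$method_mode, "mean")
  expect_setequal(meta$activities, c("a1", "a2"))
})

test_that("ranking tidiers summarize the result", {
  rec <- records_from_scores(mae = c(1, 2, 3), pcc = c(0.9, 0.5, 0.2),
                             snr = c(5, 0, -5))
  rk <- rank_rois(rec)
  expect_equal(nrow(tidy(rk)), 3L)
  g <- glance(rk)
  expect_equal(g$top_roi_index, 1L)
  expect_equal(g$n_activities, 1L)
  expect_s3_class(autoplot(rk), "ggplot")
})
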