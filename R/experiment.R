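# Leave-one-site-out experiment harness: ties gold-standard construction,
# training with augmentation, threshold tuning, ROI prediction, matching,
# the extended confusion matrix and the cohort statistics into one seeded,
# reproducible protocol.

#' Experiment configuration
#'
#' @param train A [train_config()] (its seed is re-derived per fold).
#' @param val_fraction Fraction of training-site ROIs held out as the
#'   threshold-tuning / early-stopping validation set (never test-site
#'   data).
#' @param threshold_search List with `k`, `rounds`, `shrink` for
#'   [tune_threshold()].
#' @param radius_um Matching radius for evaluation.
#' @param visual `NULL`, or a list of arguments for
#'   [simulate_visual_estimates()] (e.g. `list(n_evaluators = 13)`) to
#'   add simulated pathologist estimates to the report.
#' @param seed Master seed.
#' @export
experiment_config <- function(train = desk_train_config(),
                              val_fraction = 0.25,
                              threshold_search = list(k = 11, rounds = 3,
                                                      shrink = 0.5),
                              radius_um = 4,
                              visual = list(n_evaluators = 13),
                              seed = 1) {
  stopifnot(inherits(train, "train_config"),
            val_fraction > 0, val_fraction < 1)
  structure(list(train = train, val_fraction = val_fraction,
                 threshold_search = threshold_search,
                 radius_um = radius_um, visual = visual,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Attach gold standards to every cohort ROI
#'
#' Runs the three simulated annotators of each ROI through
#' [build_gold_standard()] and stores the result (and the gold TCR) on
#' the ROI.
#'
#' @param cohort A `cohort` object.
#' @return The cohort with `gold` and `tcr_gs` on each ROI.
#' @export
attach_gold_standards <- function(cohort) {
  cohort$rois <- lapply(cohort$rois, function(roi) {
    roi$gold <- build_gold_standard(roi$annotators[[1]],
                                    roi$annotators[[2]],
                                    roi$annotators[[3]])
    roi$tcr_gs <- tryCatch(tcr_gold_standard(roi$gold),
                           error = function(e) NA_real_)
    roi
  })
  cohort
}

# Rolling polynomial hash over the serialized object; a compact
# dependency-free fingerprint for embedding configs in reports.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 5381; h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 33554393
    h2 <- (h2 * 31 + b) %% 33554467
  }
  sprintf("%07x%07x", h1, h2)
}

#' Run the leave-one-site-out experiment
#'
#' For every fold (each site once as the test site): trains a model on
#' the other sites' ROIs with gold-standard labels, tunes the detection
#' threshold on held-out validation ROIs from the training sites,
#' predicts the test ROIs, matches detections to gold cells within the
#' matching radius, and accumulates per-ROI confusions, detection F1 and
#' AI TCR. Pools the Table-style confusion matrix and computes the
#' cohort statistics (optionally against simulated visual estimates).
#' Fully deterministic given the cohort and config.
#'
#' @param cohort A `cohort` (gold standards are attached if missing).
#' @param cfg An [experiment_config()].
#' @return An `experiment_report` list; see Details in the vignette.
#' @export
run_experiment <- function(cohort, cfg = experiment_config()) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(cohort$rois[[1]]$gold))
    cohort <- attach_gold_standards(cohort)
  folds <- loso_folds(cohort)
  site_of <- cohort_site_ids(cohort)
  fold_out <- list()
  roi_rows <- list()
  confs <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    tr_idx <- which(site_of %in% fold$train_sites)
    te_idx <- which(site_of == fold$test_site)
    if (!length(tr_idx) || !length(te_idx))
      stop("fold ", fi, " has no data for ", fold$test_site)
    n_val <- max(1L, floor(length(tr_idx) * cfg$val_fraction))
    val_idx <- tr_idx[seq(length(tr_idx) - n_val + 1L, length(tr_idx))]
    fit_idx <- setdiff(tr_idx, val_idx)
    if (!length(fit_idx)) stop("fold ", fi, ": no training ROIs left")
    tcfg <- cfg$train
    tcfg$seed <- derive_seed(cfg$seed, fi)
    fit <- train_density_model(cohort$rois[fit_idx],
                               cohort$rois[val_idx], tcfg)
    ts <- cfg$threshold_search
    tune <- tune_threshold(fit$model, cohort$rois[val_idx],
                           patch_px = tcfg$patch_px, k = ts$k,
                           rounds = ts$rounds, shrink = ts$shrink,
                           radius_um = cfg$radius_um)
    for (i in te_idx) {
      roi <- cohort$rois[[i]]
      det <- predict_roi(fit$model, roi$image, tune$best_threshold,
                         roi$mpp, tcfg$patch_px)
      m <- match_points(det, roi$gold$cells, radius_um = cfg$radius_um)
      cf <- extended_confusion(m, det$class, roi$gold$cells$label)
      confs[[length(confs) + 1]] <- cf
      ai <- tryCatch(tcr_ai(det, roi$gold, m), error = function(e)
        NA_real_)
      roi_rows[[length(roi_rows) + 1]] <- data.frame(
        roi_id = roi$roi_id, site_id = roi$site_id, fold = fi,
        tcr_true = roi$tcr_true, tcr_gs = roi$tcr_gs, tcr_ai = ai,
        detection_f1 = detection_f1(m), n_detections = nrow(det),
        stringsAsFactors = FALSE)
    }
    fold_out[[fi]] <- list(test_site = fold$test_site,
                           threshold = tune$best_threshold,
                           val_f1 = tune$best_f1,
                           history = fit$history,
                           best_epoch = fit$best_epoch)
  }
  rois <- do.call(rbind, roi_rows)
  pooled <- pool_confusions(confs)
  metrics <- list(
    matched_only = as.list(sens_spec(pooled, "matched_only")),
    all_cells = as.list(sens_spec(pooled, "all_cells")),
    roi_level = roi_level_sens_spec(confs)[c("sensitivity",
                                             "specificity")],
    mean_detection_f1 = mean(rois$detection_f1))
  records <- tcr_records(rois$roi_id, rois$site_id, rois$tcr_gs,
                         rois$tcr_ai)
  stats <- list(mae_ai = mae_ai(records)$overall)
  if (!is.null(cfg$visual)) {
    vargs <- utils::modifyList(
      list(tcr_gs = rois$tcr_gs, site = rois$site_id,
           seed = derive_seed(cfg$seed, 999L)),
      cfg$visual)
    est <- do.call(simulate_visual_estimates, vargs)
    long <- do.call(rbind, lapply(seq_len(ncol(est)), function(j)
      tcr_records(rois$roi_id, rois$site_id, rois$tcr_gs, rois$tcr_ai,
                  evaluator = colnames(est)[j], estimate = est[, j])))
    records <- long
    mv <- mae_visual(records)
    ma <- mae_ai(records)
    common <- intersect(mv$per_roi$roi_id, ma$per_roi$roi_id)
    ai_err <- ma$per_roi$error[match(common, ma$per_roi$roi_id)]
    pv_err <- mv$per_roi$error[match(common, mv$per_roi$roi_id)]
    stats <- list(
      mae_visual = mv$overall, mae_ai = ma$overall,
      signed_rank = paired_signed_rank(ai_err, pv_err),
      kendall = error_correlation(ai_err, pv_err),
      site = site_report(records))
  }
  structure(list(folds = fold_out, rois = rois, confusion = pooled,
                 metrics = metrics, records = records, stats = stats,
                 config = cfg, seed = cfg$seed,
                 config_hash = config_hash(cfg)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Leave-one-site-out experiment:", length(x$folds), "folds,",
      nrow(x$rois), "test ROIs\n")
  cat(sprintf("  detection F1 (mean over ROIs): %.3f\n",
              x$metrics$mean_detection_f1))
  cat(sprintf("  matched-only SEN/SPE: %.1f%% / %.1f%%\n",
              100 * x$metrics$matched_only$sensitivity,
              100 * x$metrics$matched_only$specificity))
  cat(sprintf("  MAE(AI): %.1f", x$stats$mae_ai))
  if (!is.null(x$stats$mae_visual))
    cat(sprintf("   MAE(visual): %.1f", x$stats$mae_visual))
  cat("\n")
  invisible(x)
}

#' Write an experiment report to a directory
#'
#' Emits the pooled confusion CSV (Table-4 layout), a metrics YAML, the
#' per-ROI results CSV, the per-site MAE grid CSV (Table-6 layout) and a
#' per-site MAE bar chart PNG.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_confusion(report$confusion, file.path(dir, "confusion.csv"))
  utils::write.csv(report$rois, file.path(dir, "rois.csv"),
                   row.names = FALSE)
  met <- report$metrics
  met$thresholds <- lapply(report$folds, function(f)
    list(test_site = f$test_site, threshold = f$threshold,
         val_f1 = f$val_f1))
  met$mae_ai <- report$stats$mae_ai
  met$seed <- report$seed
  met$config_hash <- report$config_hash
  yaml::write_yaml(met, file.path(dir, "metrics.yaml"))
  if (!is.null(report$stats$site)) {
    utils::write.csv(report$stats$site$grid,
                     file.path(dir, "site_mae_grid.csv"))
    grDevices::png(file.path(dir, "site_mae.png"), width = 720,
                   height = 480)
    g <- report$stats$site$grid
    graphics::barplot(t(g), beside = TRUE, ylab = "MAE (pp)",
                      xlab = "site", legend.text = colnames(g),
                      main = "Per-site TCR error by evaluator")
    grDevices::dev.off()
  }
  invisible(dir)
}
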