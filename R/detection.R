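# From density maps to classified cell detections: max-combined detection
# map, strict 8-neighbor peak detection with a tuned cutoff threshold,
# softmax classification from the per-map values at each peak, and
# ROI-scale prediction by overlapping patch tiling.

#' Combine the normal and tumor maps into a detection map
#'
#' @param pair List with matrices `normal` and `tumor`.
#' @return Pointwise maximum of the two maps.
#' @export
combine_maps <- function(pair) {
  stopifnot(all(dim(pair$normal) == dim(pair$tumor)))
  pmax(pair$normal, pair$tumor)
}

#' Detect peaks on a detection map
#'
#' A pixel is a peak when its value is strictly higher than all eight
#' neighbors (plateaus are not peaks) and at least `threshold`. Pixel
#' centers are converted to microns.
#'
#' @param map Numeric matrix.
#' @param threshold Cutoff in \[0,1\].
#' @param mpp Microns per pixel.
#' @return `data.frame` with `x_um`, `y_um`, `peak_value`, and the pixel
#'   indices `row`, `col`.
#' @export
detect_peaks <- function(map, threshold, mpp) {
  stopifnot(threshold >= 0)
  h <- nrow(map); w <- ncol(map)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- map
  is_peak <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(h + 1) + dr, 2:(w + 1) + dc]
    is_peak <- is_peak & (map > nb)
  }
  is_peak <- is_peak & (map >= threshold)
  idx <- which(is_peak, arr.ind = TRUE)
  data.frame(x_um = (idx[, 2] - 0.5) * mpp,
             y_um = (idx[, 1] - 0.5) * mpp,
             peak_value = map[idx],
             row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}

#' Classify detected peaks from the two density maps
#'
#' Reads the (normal, tumor) map values at each peak pixel and applies a
#' softmax; the predicted class is the argmax, with exact ties broken
#' toward non-tumor.
#'
#' @param peaks Output of [detect_peaks()].
#' @param pair List with matrices `normal` and `tumor`.
#' @param mpp Microns per pixel (kept for interface symmetry; peak
#'   coordinates are already in microns).
#' @return `data.frame` with `x_um`, `y_um`, `class` ("t"/"n"),
#'   `peak_value`, `score_t`, `score_n`.
#' @export
classify_detections <- function(peaks, pair, mpp = NULL) {
  if (nrow(peaks) == 0)
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      class = character(), peak_value = numeric(),
                      score_t = numeric(), score_n = numeric(),
                      stringsAsFactors = FALSE))
  vn <- pair$normal[cbind(peaks$row, peaks$col)]
  vt <- pair$tumor[cbind(peaks$row, peaks$col)]
  m <- pmax(vn, vt)
  en <- exp(vn - m); et <- exp(vt - m)
  z <- en + et
  data.frame(x_um = peaks$x_um, y_um = peaks$y_um,
             class = ifelse(vt > vn, "t", "n"),   # ties -> "n"
             peak_value = peaks$peak_value,
             score_t = et / z, score_n = en / z,
             stringsAsFactors = FALSE)
}

#' Predict cell detections for a whole ROI
#'
#' Tiles the ROI into overlapping patches, runs the model in evaluation
#' mode, averages the density maps over overlaps, max-combines, detects
#' and classifies peaks, and removes duplicate detections near patch
#' seams by non-maximum suppression within `nms_radius_um`.
#'
#' @param model A trained `unet_model`.
#' @param image RGB array at least as large as `patch_px`.
#' @param threshold Detection threshold.
#' @param mpp Microns per pixel.
#' @param patch_px Patch side the model was trained with.
#' @param overlap_px Patch overlap (default a quarter of the patch).
#' @param nms_radius_um Duplicate-suppression radius.
#' @return Detections `data.frame` as in [classify_detections()].
#' @export
predict_roi <- function(model, image, threshold, mpp, patch_px,
                        overlap_px = NULL, nms_radius_um = 2) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < patch_px || w < patch_px)
    stop("ROI must be at least the patch size")
  if (is.null(overlap_px))
    overlap_px <- min(50L, patch_px %/% 4L)
  stride <- max(1L, patch_px - as.integer(overlap_px))
  starts <- function(n) {
    s <- unique(c(seq(1L, max(1L, n - patch_px + 1L), by = stride),
                  n - patch_px + 1L))
    s[s >= 1L]
  }
  acc_n <- matrix(0, h, w); acc_t <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (r0 in starts(h)) for (c0 in starts(w)) {
    rr <- r0:(r0 + patch_px - 1L); cc <- c0:(c0 + patch_px - 1L)
    maps <- unet_predict_patch(model, image[rr, cc, , drop = FALSE])
    acc_n[rr, cc] <- acc_n[rr, cc] + maps$normal
    acc_t[rr, cc] <- acc_t[rr, cc] + maps$tumor
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  pair <- list(normal = acc_n / cnt, tumor = acc_t / cnt)
  peaks <- detect_peaks(combine_maps(pair), threshold, mpp)
  det <- classify_detections(peaks, pair)
  nms_points(det, nms_radius_um)
}

# keep the strongest detection within radius_um (greedy by peak value;
# ties by scan order for determinism)
nms_points <- function(det, radius_um) {
  if (nrow(det) <= 1) return(det)
  ord <- order(-det$peak_value, det$y_um, det$x_um)
  keep <- logical(nrow(det))
  for (i in ord) {
    ki <- which(keep)
    if (!length(ki) ||
        min((det$x_um[ki] - det$x_um[i])^2 +
            (det$y_um[ki] - det$y_um[i])^2) > radius_um^2)
      keep[i] <- TRUE
  }
  out <- det[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tune the detection threshold by sequential domain reduction
#'
#' Evaluates the class-agnostic detection F1 (4-micron bipartite matching
#' against gold-standard cells, pooled over the validation ROIs) on a
#' grid of `k` thresholds over the current domain, then shrinks the
#' domain around the argmax by `shrink` and repeats for `rounds` rounds.
#' Deterministic given its inputs. Local maxima and their map values are
#' extracted once per ROI at threshold 0 and filtered per candidate
#' threshold, which is equivalent to re-running the peak detector.
#'
#' @param model Trained `unet_model`.
#' @param val_rois List of ROIs (with `image`, `mpp`, and `gold` or
#'   `truth` annotations).
#' @param patch_px Patch size for [predict_roi()] tiling.
#' @param k Grid points per round.
#' @param rounds Number of domain-reduction rounds.
#' @param shrink Domain shrink factor per round.
#' @param radius_um Matching radius.
#' @param include_icells Count indistinguishable gold cells on the label
#'   side of the detection F1 (default TRUE; they are matchable).
#' @return List with `best_threshold`, `best_f1`, and `search_trace`
#'   (data.frame `threshold`, `f1` with `k * rounds` rows).
#' @export
tune_threshold <- function(model, val_rois, patch_px, k = 11, rounds = 3,
                           shrink = 0.5, radius_um = 4,
                           include_icells = TRUE) {
  if (!length(val_rois)) stop("validation set is empty")
  # all candidate peaks once per ROI (threshold 0)
  cand <- lapply(val_rois, function(roi) {
    det <- predict_roi(model, roi$image, threshold = 0, mpp = roi$mpp,
                       patch_px = patch_px)
    ann <- roi$gold$cells %||% roi$truth
    if (!include_icells) ann <- ann[ann$label != "i", , drop = FALSE]
    list(det = det, labels = ann)
  })
  eval_f1 <- function(th) {
    tp <- 0; fp <- 0; fn <- 0
    for (cn in cand) {
      det <- cn$det[cn$det$peak_value >= th, , drop = FALSE]
      m <- match_points(det, cn$labels, radius_um = radius_um)
      tp <- tp + nrow(m$pairs)
      fp <- fp + length(m$unmatched_pred)
      fn <- fn + length(m$unmatched_label)
    }
    if (tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  sr <- domain_reduce(eval_f1, 0, 1, k = k, rounds = rounds,
                      shrink = shrink)
  list(best_threshold = sr$best_x, best_f1 = sr$best_y,
       search_trace = data.frame(threshold = sr$trace$x,
                                 f1 = sr$trace$y))
}

# Sequential domain reduction: evaluate f on a k-point grid, shrink the
# domain around the argmax by `shrink`, repeat. Ties go to the lowest
# grid point. Deterministic; trace has k * rounds rows.
domain_reduce <- function(f, lo, hi, k = 11, rounds = 3, shrink = 0.5) {
  trace <- data.frame(x = numeric(), y = numeric())
  best_x <- NA_real_; best_y <- -Inf
  lo0 <- lo; hi0 <- hi
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = k)
    ys <- vapply(grid, f, 0)
    trace <- rbind(trace, data.frame(x = grid, y = ys))
    arg <- grid[which.max(ys)]
    if (max(ys) > best_y) {
      best_y <- max(ys); best_x <- arg
    }
    half <- (hi - lo) * shrink / 2
    lo <- max(lo0, arg - half); hi <- min(hi0, arg + half)
  }
  list(best_x = best_x, best_y = best_y, trace = trace)
}

#' AI-predicted TCR from matched detections
#'
#' `100 * tCells_AI / (tCells_AI + nCells_AI)` where tCells_AI are
#' detections classified tumor AND matched to gold tumor cells, and
#' nCells_AI detections classified non-tumor AND matched to gold
#' non-tumor cells. Predictions matched to indistinguishable cells are
#' discarded, mirroring how pathologists exclude them from visual
#' estimates.
#'
#' @param detections Detections `data.frame` (with `class`).
#' @param gold A `gold_standard` object (or data.frame of cells).
#' @param match Result of [match_points()] for (detections, gold cells).
#' @return TCR percentage.
#' @export
tcr_ai <- function(detections, gold, match) {
  cells <- if (inherits(gold, "gold_standard")) gold$cells else gold
  if (nrow(match$pairs) == 0)
    stop("undefined TCR: no matched predictions")
  pc <- detections$class[match$pairs$pred]
  lc <- cells$label[match$pairs$label]
  t_ai <- sum(pc == "t" & lc == "t")
  n_ai <- sum(pc == "n" & lc == "n")
  if (t_ai + n_ai == 0)
    stop("undefined TCR: no class-concordant matched predictions ",
         "outside iCells")
  100 * t_ai / (t_ai + n_ai)
}

#' Unmatched-inclusive predicted TCR
#'
#' Deployment-mode TCR using every detection regardless of matching
#' (no gold standard needed): percentage of detections classified tumor.
#' This is NOT the matched definition used in the evaluation protocol;
#' prefer [tcr_ai()] whenever gold labels exist.
#'
#' @param detections Detections `data.frame`.
#' @export
tcr_predictions <- function(detections) {
  if (nrow(detections) == 0)
    stop("undefined TCR: no detections")
  100 * sum(detections$class == "t") / nrow(detections)
}

#' Write detections as CSV
#'
#' Columns `x_um,y_um,class,peak_value,score_t,score_n`.
#' @param detections Detections `data.frame`.
#' @param path Output path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(
    detections[, c("x_um", "y_um", "class", "peak_value", "score_t",
                   "score_n")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
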