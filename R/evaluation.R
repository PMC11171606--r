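# Evaluation protocol: optimal bipartite matching of predicted cells to
# gold-standard cells within 4 microns, the extended confusion matrix
# (matched label x prediction counts plus unmatched rows/columns,
# including the indistinguishable label), and the derived sensitivity /
# specificity and detection-F1 metrics.

#' Match predictions to labels by optimal bipartite matching
#'
#' Maximum-cardinality matching among prediction-label pairs within
#' `radius_um` of each other, minimizing total distance among all
#' maximum-cardinality matchings. Solved as a linear sum assignment on an
#' augmented square cost matrix (dummy rows/columns carry the unmatched
#' penalty; pairs beyond the radius are forbidden). Deterministic.
#'
#' @param pred,labels `data.frame`s with `x_um`, `y_um` (possibly empty).
#' @param radius_um Matching radius in microns.
#' @return List with `pairs` (data.frame `pred`, `label`, `dist_um`),
#'   `unmatched_pred` and `unmatched_label` (integer index vectors).
#' @export
match_points <- function(pred, labels, radius_um = 4) {
  np <- nrow(pred); nl <- nrow(labels)
  empty <- list(pairs = data.frame(pred = integer(), label = integer(),
                                   dist_um = numeric()),
                unmatched_pred = seq_len(np),
                unmatched_label = seq_len(nl))
  if (np == 0 || nl == 0) return(empty)
  dx <- outer(pred$x_um, labels$x_um, "-")
  dy <- outer(pred$y_um, labels$y_um, "-")
  d <- sqrt(dx * dx + dy * dy)
  U <- 1e5           # cost of leaving one point unmatched
  n <- np + nl
  cost <- matrix(0, n, n)
  cost[seq_len(np), seq_len(nl)] <- ifelse(d <= radius_um, d, 3 * U)
  cost[seq_len(np), nl + seq_len(np)] <- U        # pred -> dummy
  cost[np + seq_len(nl), seq_len(nl)] <- U        # dummy -> label
  assign <- solve_lsap_cpp(cost)
  pi <- seq_len(np)
  li <- assign[seq_len(np)]
  ok <- li <= nl & d[cbind(pi, pmin(li, nl))] <= radius_um
  pairs <- data.frame(pred = pi[ok], label = li[ok],
                      dist_um = d[cbind(pi[ok], li[ok])])
  list(pairs = pairs,
       unmatched_pred = setdiff(seq_len(np), pairs$pred),
       unmatched_label = setdiff(seq_len(nl), pairs$label))
}

#' Class-agnostic detection F1
#'
#' `2 * pairs / (2 * pairs + unmatched_predictions + unmatched_labels)`.
#'
#' @param match Result of [match_points()].
#' @export
detection_f1 <- function(match) {
  tp <- nrow(match$pairs)
  denom <- 2 * tp + length(match$unmatched_pred) +
    length(match$unmatched_label)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Extended confusion matrix
#'
#' Tallies matched pairs by gold label (n / t / i) against predicted
#' class (n / t), plus unmatched labels per class (ULN, ULT, ULI) and
#' unmatched predictions per class (UPN, UPT). Cell names follow the
#' label-then-prediction convention: `TN` is a tumor label predicted
#' non-tumor.
#'
#' @param match Result of [match_points()].
#' @param pred_class Character vector of predicted classes ("t"/"n"),
#'   one per prediction.
#' @param label_class Character vector of gold labels ("t"/"n"/"i"),
#'   one per label.
#' @return An `extended_confusion` object (named integer list).
#' @export
extended_confusion <- function(match, pred_class, label_class) {
  cnt <- function(lc, pc)
    sum(label_class[match$pairs$label] == lc &
        pred_class[match$pairs$pred] == pc)
  conf <- list(
    NN = cnt("n", "n"), NT = cnt("n", "t"),
    TN = cnt("t", "n"), TT = cnt("t", "t"),
    IN = cnt("i", "n"), IT = cnt("i", "t"),
    ULN = sum(label_class[match$unmatched_label] == "n"),
    ULT = sum(label_class[match$unmatched_label] == "t"),
    ULI = sum(label_class[match$unmatched_label] == "i"),
    UPN = sum(pred_class[match$unmatched_pred] == "n"),
    UPT = sum(pred_class[match$unmatched_pred] == "t"))
  structure(lapply(conf, as.integer), class = "extended_confusion")
}

#' Build an extended confusion object from raw counts
#'
#' @param NN,NT,TN,TT,IN,IT Matched label x prediction counts.
#' @param ULN,ULT,ULI Unmatched labels per class.
#' @param UPN,UPT Unmatched predictions per class.
#' @export
confusion_counts <- function(NN = 0, NT = 0, TN = 0, TT = 0, IN = 0,
                             IT = 0, ULN = 0, ULT = 0, ULI = 0, UPN = 0,
                             UPT = 0) {
  x <- list(NN = NN, NT = NT, TN = TN, TT = TT, IN = IN, IT = IT,
            ULN = ULN, ULT = ULT, ULI = ULI, UPN = UPN, UPT = UPT)
  stopifnot(all(unlist(x) >= 0))
  structure(lapply(x, as.integer), class = "extended_confusion")
}

#' Sum extended confusions (e.g. pooling ROIs)
#' @param ... `extended_confusion` objects or a list of them.
#' @export
pool_confusions <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "extended_confusion"))
    xs <- xs[[1]]
  out <- Reduce(function(a, b) Map(`+`, a, b), xs)
  structure(out, class = "extended_confusion")
}

#' @export
print.extended_confusion <- function(x, ...) {
  m <- confusion_as_matrix(x)
  print(m)
  invisible(x)
}

confusion_as_matrix <- function(conf) {
  m <- rbind(
    `Label Non-Tumor` = c(conf$NN, conf$NT, conf$ULN),
    `Label Tumor` = c(conf$TN, conf$TT, conf$ULT),
    `Label Indistinguishable` = c(conf$IN, conf$IT, conf$ULI),
    `Unmatched Predictions` = c(conf$UPN, conf$UPT, NA))
  colnames(m) <- c("Prediction Non-Tumor", "Prediction Tumor",
                   "Unmatched Label")
  m
}

#' Write an extended confusion as CSV (matrix layout)
#' @param conf An `extended_confusion`.
#' @param path Output path.
#' @export
write_confusion <- function(conf, path) {
  utils::write.csv(confusion_as_matrix(conf), path, na = "")
  invisible(path)
}

#' Sensitivity and specificity from an extended confusion
#'
#' `matched_only` uses the matched cells: SEN = TT / (TT + TN),
#' SPE = NN / (NN + NT). `all_cells` additionally charges unmatched
#' labels as misses: SEN = TT / (TT + TN + ULT),
#' SPE = NN / (NN + NT + ULN).
#'
#' @param conf An `extended_confusion`.
#' @param mode `"matched_only"` or `"all_cells"`.
#' @param metric Which metric(s) to compute; a metric whose denominator
#'   is zero raises an undefined-metric error, so requesting a single
#'   metric keeps the other's degeneracy from blocking it.
#' @return Named numeric vector with the requested metric(s), as
#'   proportions in \[0,1\].
#' @export
sens_spec <- function(conf, mode = c("matched_only", "all_cells"),
                      metric = c("both", "sensitivity", "specificity")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  sden <- conf$TT + conf$TN + if (mode == "all_cells") conf$ULT else 0
  pden <- conf$NN + conf$NT + if (mode == "all_cells") conf$ULN else 0
  out <- c()
  if (metric %in% c("both", "sensitivity")) {
    if (sden == 0)
      stop("undefined metric: zero denominator in ", mode,
           " sensitivity")
    out <- c(out, sensitivity = conf$TT / sden)
  }
  if (metric %in% c("both", "specificity")) {
    if (pden == 0)
      stop("undefined metric: zero denominator in ", mode,
           " specificity")
    out <- c(out, specificity = conf$NN / pden)
  }
  out
}

#' ROI-level mean sensitivity and specificity
#'
#' Unweighted mean of matched-only sensitivity/specificity over ROIs;
#' ROIs where either metric is undefined are excluded and reported.
#'
#' @param confs List of per-ROI `extended_confusion` objects.
#' @return List with `sensitivity`, `specificity`, `n_used`, `excluded`
#'   (indices of excluded ROIs).
#' @export
roi_level_sens_spec <- function(confs) {
  vals <- lapply(confs, function(cf)
    tryCatch(sens_spec(cf, "matched_only"), error = function(e) NULL))
  ok <- !vapply(vals, is.null, TRUE)
  if (!any(ok)) stop("no ROI with defined metrics")
  if (any(!ok))
    warning(sum(!ok), " ROI(s) with undefined metrics excluded")
  m <- do.call(rbind, vals[ok])
  list(sensitivity = mean(m[, "sensitivity"]),
       specificity = mean(m[, "specificity"]),
       n_used = sum(ok), excluded = which(!ok))
}
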