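#' Tumor content ratio from cell counts
#'
#' TCR is the percentage of tumor cells among tumor plus non-tumor cells.
#' Indistinguishable cells are excluded by the caller before counting.
#'
#' @param tumor_count,nontumor_count Non-negative integer counts.
#' @return TCR as a percentage in \[0, 100\].
#' @examples
#' tcr(30, 10)  # 75
#' @export
tcr <- function(tumor_count, nontumor_count) {
  stopifnot(tumor_count >= 0, nontumor_count >= 0)
  if (tumor_count + nontumor_count == 0)
    stop("undefined TCR: no tumor or non-tumor cells")
  100 * tumor_count / (tumor_count + nontumor_count)
}

# Scan order used everywhere a deterministic cell ordering is needed:
# row-major over the tile (increasing y, then increasing x), ties broken by
# original row index (order() is stable).
scan_order <- function(ann) order(ann$y_um, ann$x_um)

#' Group three annotators' cells by proximity
#'
#' Greedy distance grouping of the point annotations of three annotators
#' of the same region. Annotators are processed in a fixed order and each
#' annotator's cells in row-major scan order; for each not-yet-consumed
#' seed cell, the nearest not-yet-consumed cell of each *other* annotator
#' within `radius_um` is pulled into the group (ties at equal distance go
#' to the cell with the lower scan index). Consumed cells are never
#' reused; cells left over become 1-member groups. Every input cell
#' therefore appears in exactly one group.
#'
#' @param a1,a2,a3 Annotation `data.frame`s in the same coordinate frame.
#' @param radius_um Grouping radius in microns (default 4).
#' @return A list of groups; each group is a list with `members`
#'   (data.frame with columns `annotator`, `x_um`, `y_um`, `label`) and
#'   `position`, the centroid of the members in microns.
#' @export
group_annotations <- function(a1, a2, a3, radius_um = 4) {
  sets <- list(a1, a2, a3)
  cells <- do.call(rbind, lapply(seq_along(sets), function(a) {
    s <- sets[[a]]
    if (is.null(s) || nrow(s) == 0) return(NULL)
    data.frame(annotator = a, x_um = s$x_um, y_um = s$y_um,
               label = s$label, stringsAsFactors = FALSE)
  }))
  if (is.null(cells) || nrow(cells) == 0) return(list())
  # scan-order rank within each annotator
  ord <- unlist(lapply(1:3, function(a) {
    idx <- which(cells$annotator == a)
    idx[scan_order(cells[idx, ])]
  }))
  consumed <- logical(nrow(cells))
  groups <- list()
  for (i in ord) {
    if (consumed[i]) next
    consumed[i] <- TRUE
    member_idx <- i
    for (b in setdiff(1:3, cells$annotator[i])) {
      cand <- which(cells$annotator == b & !consumed)
      if (!length(cand)) next
      d <- sqrt((cells$x_um[cand] - cells$x_um[i])^2 +
                (cells$y_um[cand] - cells$y_um[i])^2)
      ok <- d <= radius_um
      if (!any(ok)) next
      cand <- cand[ok]; d <- d[ok]
      # nearest; ties broken by scan rank (cand is already index-ordered,
      # so rank by scan position among candidates)
      rank_in_scan <- match(cand, ord)
      pick <- cand[order(d, rank_in_scan)[1]]
      consumed[pick] <- TRUE
      member_idx <- c(member_idx, pick)
    }
    members <- cells[member_idx, c("annotator", "x_um", "y_um", "label")]
    rownames(members) <- NULL
    groups[[length(groups) + 1]] <- list(
      members = members,
      position = c(x_um = mean(members$x_um), y_um = mean(members$y_um)))
  }
  groups
}

#' Majority aggregation of a match group's labels
#'
#' Implements the three-annotator majority rule: unanimous groups keep
#' their label; a 2-vs-1 majority wins; three mutually different labels
#' (n, t, i) resolve to `"i"`; two-member groups keep the label if equal
#' and resolve to `"i"` otherwise; single-member groups are discarded.
#'
#' @param labels Character vector of 1-3 labels from distinct annotators.
#' @return The final label (`"t"`, `"n"`, `"i"`) or `"discard"`.
#' @export
aggregate_label <- function(labels) {
  m <- length(labels)
  if (m < 1 || m > 3)
    stop("a match group must have 1-3 members, got ", m)
  bad <- setdiff(unique(labels), c("t", "n", "i"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (m == 1) return("discard")
  tab <- table(labels)
  if (length(tab) == 1) return(names(tab))           # full agreement
  if (m == 2) return("i")                            # 2 members, unequal
  if (max(tab) == 2) return(names(tab)[which.max(tab)])  # 2-vs-1 majority
  "i"                                                # n, t, i all different
}

#' Build the gold standard from three annotators
#'
#' Distance-groups the three annotation sets (see [group_annotations()]),
#' aggregates each group's labels by majority rule (see
#' [aggregate_label()]) and tallies the result. Single-member groups are
#' discarded and counted separately; they never enter the TCR.
#'
#' @inheritParams group_annotations
#' @return An object of class `gold_standard`: a list with `cells`
#'   (data.frame `x_um`, `y_um`, `label`, `n_annotators`), counts
#'   `n_tumor`, `n_nontumor`, `n_indist`, and `discarded`.
#' @export
build_gold_standard <- function(a1, a2, a3, radius_um = 4) {
  groups <- group_annotations(a1, a2, a3, radius_um = radius_um)
  rows <- list(); discarded <- 0L
  for (g in groups) {
    lab <- aggregate_label(g$members$label)
    if (identical(lab, "discard")) {
      discarded <- discarded + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      x_um = g$position[["x_um"]], y_um = g$position[["y_um"]],
      label = lab, n_annotators = nrow(g$members),
      stringsAsFactors = FALSE)
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(), y_um = numeric(), label = character(),
               n_annotators = integer(), stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 n_tumor = sum(cells$label == "t"),
                 n_nontumor = sum(cells$label == "n"),
                 n_indist = sum(cells$label == "i"),
                 discarded = discarded),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("Gold standard:", nrow(x$cells), "cells (",
      x$n_tumor, "t /", x$n_nontumor, "n /", x$n_indist, "i ),",
      x$discarded, "singleton(s) discarded\n")
  if (x$n_tumor + x$n_nontumor > 0)
    cat(sprintf("TCR(GS) = %.1f%%\n", tcr(x$n_tumor, x$n_nontumor)))
  invisible(x)
}

#' Gold-standard TCR
#'
#' @param gs A `gold_standard` object.
#' @return TCR percentage computed from the gold-standard tumor and
#'   non-tumor counts (indistinguishable cells excluded).
#' @export
tcr_gold_standard <- function(gs) {
  stopifnot(inherits(gs, "gold_standard"))
  tcr(gs$n_tumor, gs$n_nontumor)
}
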