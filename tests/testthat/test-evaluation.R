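test_that("bipartite matching handles coincident points and prefers
           cardinality over greedy nearest-first", {
  p <- data.frame(x_um = 5, y_um = 5)
  m <- match_points(p, p)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$dist_um, 0)
  # one prediction equidistant (3 um) from two labels; the second
  # prediction can only reach one of them: both must be matched
  pred <- data.frame(x_um = c(0, 6), y_um = c(0, 0))
  labs <- data.frame(x_um = c(3, 0), y_um = c(0, 3))
  m2 <- match_points(pred, labs)
  expect_equal(nrow(m2$pairs), 2)
  expect_length(m2$unmatched_pred, 0)
  expect_length(m2$unmatched_label, 0)
  # empty sides
  e <- match_points(pred[0, ], labs)
  expect_equal(nrow(e$pairs), 0)
  expect_equal(e$unmatched_label, 1:2)
})

test_that("matching equals the exhaustive oracle on random small
           instances and conserves points", {
  set.seed(6)
  for (rep in 1:12) {
    np <- sample(0:8, 1); nl <- sample(0:8, 1)
    pred <- data.frame(x_um = runif(np, 0, 20), y_um = runif(np, 0, 20))
    labs <- data.frame(x_um = runif(nl, 0, 20), y_um = runif(nl, 0, 20))
    m <- match_points(pred, labs)
    o <- enum_match(pred, labs)
    expect_equal(nrow(m$pairs), max(o$n, 0))
    if (nrow(m$pairs) > 0)
      expect_equal(sum(m$pairs$dist_um), o$dist, tolerance = 1e-9)
    # conservation
    expect_equal(nrow(m$pairs) + length(m$unmatched_pred), np)
    expect_equal(nrow(m$pairs) + length(m$unmatched_label), nl)
    if (nrow(m$pairs)) expect_true(all(m$pairs$dist_um <= 4))
  }
})

test_that("detection F1 follows its closed form", {
  m <- list(pairs = data.frame(pred = 1:3, label = 1:3,
                               dist_um = c(0, 1, 2)),
            unmatched_pred = 4L, unmatched_label = 4L)
  expect_equal(detection_f1(m), 0.75)
  m0 <- list(pairs = data.frame(pred = integer(), label = integer(),
                                dist_um = numeric()),
             unmatched_pred = 1:3, unmatched_label = 1:2)
  expect_equal(detection_f1(m0), 0)
  mperf <- list(pairs = data.frame(pred = 1:5, label = 1:5,
                                   dist_um = numeric(5)),
                unmatched_pred = integer(), unmatched_label = integer())
  expect_equal(detection_f1(mperf), 1)
})

test_that("the extended confusion tallies matched and unmatched cells
           and conserves marginals", {
  # constructed miniature with every category populated
  labs <- annotation_set(
    x_um = c(1, 2, 3, 4, 5, 6, 20, 21, 22),
    y_um = rep(1, 9),
    label = c("n", "n", "t", "t", "i", "i", "n", "t", "i"))
  pred <- data.frame(
    x_um = c(1, 2, 3, 4, 5, 6, 30, 31),
    y_um = rep(1, 8),
    class = c("n", "t", "n", "t", "n", "t", "n", "t"))
  m <- match_points(pred, labs)
  cf <- extended_confusion(m, pred$class, labs$label)
  expect_equal(cf$NN, 1); expect_equal(cf$NT, 1)
  expect_equal(cf$TN, 1); expect_equal(cf$TT, 1)
  expect_equal(cf$IN, 1); expect_equal(cf$IT, 1)
  expect_equal(cf$ULN, 1); expect_equal(cf$ULT, 1); expect_equal(cf$ULI, 1)
  expect_equal(cf$UPN, 1); expect_equal(cf$UPT, 1)
  # marginal conservation mirrors the published table layout
  expect_equal(cf$NN + cf$NT + cf$ULN, sum(labs$label == "n"))
  expect_equal(cf$TN + cf$TT + cf$ULT, sum(labs$label == "t"))
  expect_equal(cf$IN + cf$IT + cf$ULI, sum(labs$label == "i"))
  expect_equal(cf$UPN + cf$UPT, length(m$unmatched_pred))
  # perfect prediction: zeros off the diagonal and no unmatched
  mperf <- match_points(pred[1:2, ], labs[1:2, ])
  cperf <- extended_confusion(mperf, c("n", "n"), c("n", "n"))
  expect_equal(cperf$NN, 2)
  expect_equal(sum(unlist(cperf)) - cperf$NN, 0)
  # no predictions at all
  mnone <- match_points(pred[0, ], labs)
  cnone <- extended_confusion(mnone, character(), labs$label)
  expect_equal(cnone$ULN, 3); expect_equal(cnone$ULT, 3)
  expect_equal(cnone$ULI, 3)
  expect_equal(cnone$NN + cnone$NT + cnone$TT + cnone$TN, 0)
})

test_that("sensitivity and specificity derive from the confusion in
           both modes with undefined-metric errors", {
  cf <- published_confusion()
  ms <- sens_spec(cf, "matched_only")
  expect_equal(unname(ms["sensitivity"]), 17174 / (17174 + 3171))
  expect_equal(unname(ms["specificity"]), 10762 / (10762 + 2044))
  ac <- sens_spec(cf, "all_cells")
  expect_equal(unname(ac["sensitivity"]), 17174 / (17174 + 3171 + 1644))
  expect_equal(unname(ac["specificity"]), 10762 / (10762 + 2044 + 1408))
  # all-cells metrics never exceed matched-only when unmatched exist
  expect_true(all(ac <= ms))
  cf5 <- confusion_counts(TT = 5)
  expect_equal(unname(sens_spec(cf5, "matched_only",
                                metric = "sensitivity")), 1.0)
  expect_error(sens_spec(cf5, "matched_only", metric = "specificity"),
               "undefined metric")
  expect_error(sens_spec(confusion_counts(TT = 0, TN = 0, NN = 3)),
               "undefined metric")
})

test_that("ROI-level metrics average matched-only values and report
           exclusions", {
  cf <- confusion_counts(NN = 8, NT = 2, TN = 1, TT = 9)
  same <- roi_level_sens_spec(list(cf, cf, cf))
  one <- sens_spec(cf, "matched_only")
  expect_equal(same$sensitivity, unname(one["sensitivity"]))
  expect_equal(same$specificity, unname(one["specificity"]))
  # two ROIs with sensitivities 1.0 and 0.5 average to 0.75
  c1 <- confusion_counts(TT = 4, TN = 0, NN = 4, NT = 0)
  c2 <- confusion_counts(TT = 2, TN = 2, NN = 3, NT = 1)
  two <- roi_level_sens_spec(list(c1, c2))
  expect_equal(two$sensitivity, 0.75)
  # pooled vs per-ROI means differ on a size-heterogeneous fixture
  h1 <- confusion_counts(TT = 9, TN = 1, NN = 8, NT = 2)
  h2 <- confusion_counts(TT = 1, TN = 3, NN = 1, NT = 1)
  per_roi <- roi_level_sens_spec(list(h1, h2))
  pooled <- sens_spec(pool_confusions(list(h1, h2)), "matched_only")
  expect_equal(per_roi$sensitivity, (0.9 + 0.25) / 2)
  expect_equal(unname(pooled["sensitivity"]), 10 / 14)
  expect_false(isTRUE(all.equal(unname(pooled["sensitivity"]),
                                per_roi$sensitivity)))
  # undefined ROIs are excluded with a warning
  cbad <- confusion_counts(NN = 5)
  expect_warning(mix <- roi_level_sens_spec(list(c1, cbad)),
                 "excluded")
  expect_equal(mix$n_used, 1)
  expect_equal(mix$excluded, 2L)
})
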