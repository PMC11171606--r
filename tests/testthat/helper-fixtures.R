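# Shared fixtures. Heavy objects (trained models) are built once per test
# run and cached in this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A synthetic ROI in the list form the training/prediction code expects.
mk_roi <- function(seed, n_tumor = 20, n_nontumor = 15, n_indist = 4,
                   size = 128, cluster_strength = 0.7) {
  tl <- generate_tile(tile_spec(size, size, n_tumor = n_tumor,
                                n_nontumor = n_nontumor,
                                n_indist = n_indist,
                                cluster_strength = cluster_strength,
                                seed = seed))
  tt <- sum(tl$annotations$label == "t")
  tn <- sum(tl$annotations$label == "n")
  list(image = tl$image, truth = tl$annotations,
       mpp = tl$spec$microns_per_px,
       tcr_true = if (tt + tn > 0) tcr(tt, tn) else NA_real_)
}

# Desk-scale trained model shared by the detection / density-model /
# acceptance tests: 6 training tiles, 2 validation, 3 held-out test
# tiles, no augmentation (parameter recovery of the detector itself).
desk_fit <- function() fixture("desk_fit", {
  set.seed(41)
  train_rois <- lapply(1:6, function(i)
    mk_roi(100 + i, sample(10:35, 1), sample(8:25, 1)))
  val_rois <- lapply(1:2, function(i) mk_roi(200 + i, 22, 16))
  test_rois <- lapply(1:3, function(i)
    mk_roi(300 + i, sample(10:35, 1), sample(8:25, 1)))
  cfg <- desk_train_config(augment = FALSE, max_epochs = 10, seed = 11)
  fit <- train_density_model(train_rois, val_rois, cfg)
  tune <- tune_threshold(fit$model, val_rois, patch_px = cfg$patch_px)
  list(fit = fit, tune = tune, cfg = cfg, train_rois = train_rois,
       val_rois = val_rois, test_rois = test_rois)
})

# Exhaustive maximum-cardinality / minimum-distance matching oracle for
# small instances (recursion over predictions).
enum_match <- function(pred, labels, radius_um = 4) {
  np <- nrow(pred); nl <- nrow(labels)
  if (np == 0 || nl == 0) return(list(n = 0L, dist = 0))
  dmat <- sqrt(outer(pred$x_um, labels$x_um, "-")^2 +
               outer(pred$y_um, labels$y_um, "-")^2)
  best <- list(n = -1L, dist = Inf)
  rec <- function(i, used, n, s) {
    if (i > np) {
      if (n > best$n || (n == best$n && s < best$dist - 1e-12))
        best <<- list(n = n, dist = s)
      return()
    }
    rec(i + 1L, used, n, s)
    for (j in seq_len(nl)) {
      if (!used[j] && dmat[i, j] <= radius_um) {
        used[j] <- TRUE
        rec(i + 1L, used, n + 1L, s + dmat[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nl), 0L, 0)
  best
}

# Augmentation-robustness experiment: train on one site, evaluate the
# per-site TCR error across stain-shifted sites, with and without
# augmentation; repeated over seeds. Returns a data.frame of SDIs.
aug_sdi_replicates <- function(n_rep = 3) fixture("aug_sdi", {
  profiles <- list(
    sA = site_profile("sA"),
    sB = site_profile("sB", he_shift = c(0, 0.10)),
    sC = site_profile("sC", gamma = 1.6),
    sD = site_profile("sD", he_shift = c(0.10, 0),
                      rgb_shift = c(-0.08, -0.02, 0.02),
                      brightness = -0.05))
  shifted_roi <- function(seed, prof) {
    roi <- mk_roi(seed, n_tumor = sample(10:30, 1),
                  n_nontumor = sample(8:22, 1))
    roi$image <- apply_site_profile(roi$image, prof)
    roi
  }
  site_sdi <- function(rep_seed, augment) {
    set.seed(rep_seed)
    train_rois <- lapply(1:4, function(i)
      shifted_roi(rep_seed * 1000 + i, profiles$sA))
    val_rois <- lapply(5:6, function(i)
      shifted_roi(rep_seed * 1000 + i, profiles$sA))
    test_rois <- list()
    for (s in names(profiles)) {
      for (i in 1:3)
        test_rois[[paste0(s, i)]] <-
          c(shifted_roi(rep_seed * 1000 + 100 + match(s,
              names(profiles)) * 10 + i, profiles[[s]]),
            list(site = s))
    }
    cfg <- desk_train_config(max_epochs = 6, examples_per_epoch = 200,
                             augment = augment, seed = rep_seed)
    fit <- train_density_model(train_rois, val_rois, cfg)
    tune <- tune_threshold(fit$model, val_rois, patch_px = cfg$patch_px)
    errs <- vapply(test_rois, function(roi) {
      det <- predict_roi(fit$model, roi$image, tune$best_threshold,
                         roi$mpp, cfg$patch_px)
      ai <- tryCatch({
        m <- match_points(det, roi$truth)
        tcr_ai(det, roi$truth, m)
      }, error = function(e) NA_real_)
      if (is.na(ai)) 50 else abs(ai - roi$tcr_true)
    }, 0)
    site_of <- vapply(test_rois, `[[`, "", "site")
    sdi(tapply(errs, site_of, mean))
  }
  do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(replicate = r,
               sdi_augmented = site_sdi(70 + r, TRUE),
               sdi_plain = site_sdi(70 + r, FALSE))))
})

# All permutations of 1..n as a matrix (n! rows).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# The published pooled cell-level confusion counts used as a worked
# example throughout the evaluation tests.
published_confusion <- function() {
  confusion_counts(NN = 10762, NT = 2044, TN = 3171, TT = 17174,
                   IN = 2541, IT = 1535, ULN = 1408, ULT = 1644,
                   ULI = 664, UPN = 1678, UPT = 1430)
}

# Published per-site MAE grid (13 pathologists + AI across 4 sites).
published_site_mae <- function() {
  path <- system.file("extdata", "published_site_mae.csv",
                      package = "cellularity")
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}
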