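#' Multi-site synthetic cohort configuration
#'
#' Describes a synthetic cohort: at least two sites with their staining
#' profiles, the number of tiles per site, per-tile cell count ranges,
#' and the three simulated annotators whose noisy point sets feed the
#' gold-standard aggregation. Everything downstream (ROI seeds, per-tile
#' counts, annotator seeds) is derived deterministically from `seed`.
#'
#' @param sites List of [site_profile()] objects (>= 2).
#' @param tiles_per_site Number of tiles (ROIs) generated per site.
#' @param tile List of tile parameters: `width_px`, `height_px`,
#'   `microns_per_px`, `cluster_strength`, and integer ranges
#'   `n_tumor`, `n_nontumor`, `n_indist` (length-2 lo/hi).
#' @param annotators List of three [annotator_noise()] templates (their
#'   seeds are re-derived per ROI).
#' @param seed Integer master seed.
#' @export
cohort_config <- function(sites, tiles_per_site = 10,
                          tile = list(width_px = 128, height_px = 128,
                                      microns_per_px = 0.6667,
                                      cluster_strength = 0.7,
                                      n_tumor = c(8, 40),
                                      n_nontumor = c(6, 30),
                                      n_indist = c(2, 8)),
                          annotators = list(annotator_noise(),
                                            annotator_noise(),
                                            annotator_noise()),
                          seed = 1) {
  if (length(sites) < 2) stop("a cohort needs at least 2 sites")
  stopifnot(all(vapply(sites, inherits, TRUE, "site_profile")),
            length(annotators) == 3, tiles_per_site >= 1)
  structure(list(sites = sites, tiles_per_site = as.integer(tiles_per_site),
                 tile = tile, annotators = annotators,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic integer seed stream, kept below 2^31 and exact in doubles
derive_seed <- function(seed, i) {
  ((seed %% 94906265) * 22695477 + 1013904223 + i * 7919) %% 2147483647
}

#' Generate a synthetic multi-site cohort
#'
#' Generates `tiles_per_site` tiles per site, applies each site's stain
#' profile to the imagery, simulates the three annotators on the true
#' cell points, and (when `dir` is given) writes a `site/ROI` directory
#' tree with PNG images, truth/annotator CSVs and a YAML manifest that
#' supports leave-one-site-out partitioning. With `dir = NULL` the same
#' cohort is returned fully in memory.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory, or `NULL` for in-memory only.
#' @return A `cohort` object: list with `rois` (each with `roi_id`,
#'   `site_id`, `image`, `truth`, `annotators`, `seed`, `mpp`,
#'   `tcr_true`), `sites`, `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  tl <- config$tile
  draws <- withr::with_seed(config$seed, {
    n <- length(config$sites) * config$tiles_per_site
    data.frame(
      n_tumor = sample(tl$n_tumor[1]:tl$n_tumor[2], n, replace = TRUE),
      n_nontumor = sample(tl$n_nontumor[1]:tl$n_nontumor[2], n,
                          replace = TRUE),
      n_indist = sample(tl$n_indist[1]:tl$n_indist[2], n, replace = TRUE))
  })
  rois <- list()
  g <- 0L
  for (si in seq_along(config$sites)) {
    prof <- config$sites[[si]]
    for (ti in seq_len(config$tiles_per_site)) {
      g <- g + 1L
      roi_seed <- derive_seed(config$seed, g)
      spec <- tile_spec(width_px = tl$width_px, height_px = tl$height_px,
                        microns_per_px = tl$microns_per_px,
                        n_tumor = draws$n_tumor[g],
                        n_nontumor = draws$n_nontumor[g],
                        n_indist = draws$n_indist[g],
                        cluster_strength = tl$cluster_strength,
                        seed = roi_seed)
      tile <- generate_tile(spec)
      img <- apply_site_profile(tile$image, prof)
      anns <- lapply(1:3, function(a) {
        tmpl <- config$annotators[[a]]
        nz <- annotator_noise(tmpl$jitter_sigma_um, tmpl$miss_prob,
                              tmpl$flip_prob, tmpl$to_indist_prob,
                              seed = derive_seed(roi_seed, a))
        simulate_annotator(tile$annotations, nz)
      })
      tt <- sum(tile$annotations$label == "t")
      tn <- sum(tile$annotations$label == "n")
      rois[[g]] <- list(
        roi_id = sprintf("%s_roi%02d", prof$site_id, ti),
        site_id = prof$site_id, image = img,
        truth = tile$annotations, annotators = anns,
        seed = roi_seed, mpp = tl$microns_per_px,
        tcr_true = if (tt + tn > 0) tcr(tt, tn) else NA_real_)
    }
  }
  cohort <- structure(list(rois = rois, sites = config$sites,
                           config = config),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create cohort directory: ", dir)
  man_sites <- list()
  for (prof in cohort$sites) {
    site_rois <- list()
    for (roi in cohort$rois) {
      if (roi$site_id != prof$site_id) next
      rd <- file.path(dir, prof$site_id, roi$roi_id)
      dir.create(rd, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(roi$image, file.path(rd, "image.png"))
      write_annotations(roi$truth, file.path(rd, "truth.csv"))
      for (a in 1:3)
        write_annotations(roi$annotators[[a]],
                          file.path(rd, sprintf("annotator_%d.csv", a)))
      site_rois[[length(site_rois) + 1]] <- list(
        roi_id = roi$roi_id,
        dir = file.path(prof$site_id, roi$roi_id),
        seed = roi$seed, microns_per_px = roi$mpp)
    }
    man_sites[[length(man_sites) + 1]] <- list(
      site_id = prof$site_id,
      profile = unclass(prof), rois = site_rois)
  }
  manifest <- list(seed = cohort$config$seed, sites = man_sites)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [generate_cohort()]
#'
#' @param dir Cohort directory containing `manifest.yaml`.
#' @return A `cohort` object (without the generating config).
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  rois <- list(); sites <- list()
  for (s in manifest$sites) {
    p <- s$profile
    sites[[length(sites) + 1]] <-
      site_profile(p$site_id, unlist(p$he_shift), unlist(p$rgb_shift),
                   p$gamma, p$brightness)
    for (r in s$rois) {
      rd <- file.path(dir, r$dir)
      truth <- read_annotations(file.path(rd, "truth.csv"))
      tt <- sum(truth$label == "t"); tn <- sum(truth$label == "n")
      rois[[length(rois) + 1]] <- list(
        roi_id = r$roi_id, site_id = s$site_id,
        image = png::readPNG(file.path(rd, "image.png")),
        truth = truth,
        annotators = lapply(1:3, function(a)
          read_annotations(file.path(rd, sprintf("annotator_%d.csv", a)))),
        seed = r$seed, mpp = r$microns_per_px,
        tcr_true = if (tt + tn > 0) tcr(tt, tn) else NA_real_)
    }
  }
  structure(list(rois = rois, sites = sites, manifest = manifest),
            class = "cohort")
}

#' Leave-one-site-out folds
#'
#' @param cohort A `cohort` object.
#' @return A list of folds, each with `test_site` and `train_sites`;
#'   every site appears exactly once as the test site.
#' @export
loso_folds <- function(cohort) {
  ids <- vapply(cohort$sites, function(s) s$site_id, "")
  lapply(ids, function(s) list(test_site = s,
                               train_sites = setdiff(ids, s)))
}

cohort_site_ids <- function(cohort)
  vapply(cohort$rois, function(r) r$site_id, "")
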