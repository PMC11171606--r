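test_that("tile generation is deterministic and honors its spec", {
  sp <- tile_spec(n_tumor = 30, n_nontumor = 10, n_indist = 0, seed = 42)
  t1 <- generate_tile(sp)
  t2 <- generate_tile(sp)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$annotations, t2$annotations)
  expect_equal(dim(t1$image), c(128, 128, 3))
  expect_equal(nrow(t1$annotations), 40)
  expect_equal(sum(t1$annotations$label == "t"), 30)
  # exact TCR forced by the counts
  expect_equal(tcr(sum(t1$annotations$label == "t"),
                   sum(t1$annotations$label == "n")), 75.0)
  # minimum center spacing
  expect_gte(min(dist(t1$annotations[, c("x_um", "y_um")])), 3)
  # all points inside the tile
  side <- 128 * sp$microns_per_px
  expect_true(all(t1$annotations$x_um > 0 & t1$annotations$x_um < side))
  expect_true(all(t1$annotations$y_um > 0 & t1$annotations$y_um < side))
})

test_that("empty tile and infeasible counts behave as specified", {
  t0 <- generate_tile(tile_spec(n_tumor = 0, n_nontumor = 0,
                                n_indist = 0, seed = 1))
  expect_equal(nrow(t0$annotations), 0)
  expect_true(all(is.finite(t0$image)))
  expect_error(generate_tile(tile_spec(32, 32, n_tumor = 5000,
                                       n_nontumor = 0, n_indist = 0,
                                       seed = 1)),
               "capacity|cannot place")
})

test_that("tumor nuclei are larger, darker and more clustered than
           non-tumor nuclei", {
  tl <- generate_tile(tile_spec(192, 192, n_tumor = 40, n_nontumor = 40,
                                n_indist = 0, seed = 7))
  ann <- tl$annotations
  mpp <- tl$spec$microns_per_px
  # sample the image at nucleus centers: tumor centers must be darker
  px_val <- function(rows) {
    r <- pmin(pmax(round(rows$y_um / mpp + 0.5), 1), 192)
    c <- pmin(pmax(round(rows$x_um / mpp + 0.5), 1), 192)
    mean(tl$image[cbind(r, c, 1)] + tl$image[cbind(r, c, 2)] +
           tl$image[cbind(r, c, 3)])
  }
  expect_lt(px_val(ann[ann$label == "t", ]), px_val(ann[ann$label == "n", ]))
  # clustering: mean nearest-neighbor distance smaller for tumor
  nnd <- function(rows) {
    d <- as.matrix(dist(rows[, c("x_um", "y_um")]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nnd(ann[ann$label == "t", ]), nnd(ann[ann$label == "n", ]))
})

test_that("simulated annotators respect their noise model", {
  tl <- generate_tile(tile_spec(seed = 5))
  truth <- tl$annotations
  # identity noise returns the truth up to ordering
  a0 <- simulate_annotator(truth, annotator_noise(0, 0, 0, 0, seed = 3))
  expect_equal(nrow(a0), nrow(truth))
  o1 <- order(a0$x_um, a0$y_um); o2 <- order(truth$x_um, truth$y_um)
  expect_equal(a0[o1, ], truth[o2, ], ignore_attr = TRUE)
  # miss everything
  a1 <- simulate_annotator(truth, annotator_noise(0, 1, 0, 0, seed = 3))
  expect_equal(nrow(a1), 0)
  # binomial retention on a large point set
  big <- annotation_set(runif(10000, 0, 1000), runif(10000, 0, 1000),
                        sample(c("t", "n"), 10000, replace = TRUE))
  kept <- nrow(simulate_annotator(big, annotator_noise(0, 0.1, 0, 0,
                                                       seed = 9)))
  sd3 <- 3 * sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(kept - 9000), sd3)
})

test_that("site profiles are deterministic photometric transforms", {
  tl <- generate_tile(tile_spec(seed = 11))
  img <- tl$image
  # neutral profile is the identity
  expect_equal(apply_site_profile(img, site_profile("X")), img)
  # gamma-only profile equals standalone gamma correction
  p24 <- site_profile("G", gamma = 2.4)
  expect_equal(apply_site_profile(img, p24), adjust_gamma(img, 2.4))
  # distinct profiles differ; rgb shifts move channel means as signed
  pa <- site_profile("A", rgb_shift = c(0.05, -0.03, 0))
  pb <- site_profile("B", rgb_shift = c(-0.05, 0.04, 0.02))
  ia <- apply_site_profile(img, pa)
  ib <- apply_site_profile(img, pb)
  expect_false(identical(ia, ib))
  expect_gt(mean(ia[, , 1]), mean(img[, , 1]))
  expect_lt(mean(ia[, , 2]), mean(img[, , 2]))
  expect_lt(mean(ib[, , 1]), mean(img[, , 1]))
})

test_that("cohort generation writes a reproducible site/ROI tree with
           leave-one-site-out folds", {
  cfg <- cohort_config(
    sites = list(site_profile("sA"), site_profile("sB", gamma = 1.3)),
    tiles_per_site = 2,
    tile = list(width_px = 64, height_px = 64, microns_per_px = 0.6667,
                cluster_strength = 0.5, n_tumor = c(5, 10),
                n_nontumor = c(4, 8), n_indist = c(1, 2)),
    seed = 21)
  d1 <- file.path(tempdir(), "cohort1")
  unlink(d1, recursive = TRUE)
  co <- generate_cohort(cfg, d1)
  expect_length(co$rois, 4)
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  roi_dirs <- list.dirs(d1, recursive = TRUE)
  expect_length(grep("roi", basename(roi_dirs)), 4)
  # round trip through disk
  back <- read_cohort(d1)
  expect_length(back$rois, 4)
  expect_equal(back$rois[[1]]$truth, co$rois[[1]]$truth)
  expect_equal(back$rois[[1]]$image, co$rois[[1]]$image,
               tolerance = 1 / 255)
  # regeneration is reproducible
  co2 <- generate_cohort(cfg)
  expect_identical(co$rois[[3]]$image, co2$rois[[3]]$image)
  expect_identical(co$rois[[3]]$annotators, co2$rois[[3]]$annotators)
  # folds: every site once as test, test disjoint from train
  folds <- loso_folds(co)
  expect_equal(sort(vapply(folds, `[[`, "", "test_site")),
               c("sA", "sB"))
  for (f in folds)
    expect_length(intersect(f$test_site, f$train_sites), 0)
  expect_error(cohort_config(sites = list(site_profile("one"))),
               "at least 2")
})

test_that("annotation CSV and GeoJSON round trips preserve cells", {
  ann <- annotation_set(c(1.5, 20.25), c(3, 40), c("t", "i"))
  p <- tempfile(fileext = ".csv")
  write_annotations(ann, p)
  expect_equal(read_annotations(p), ann)
  gj <- jsonlite::fromJSON(annotations_to_geojson(ann),
                           simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_equal(gj$features[[2]]$properties$label, "i")
  expect_error(annotation_set(1, 1, "x"), "unknown cell labels")
})
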