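test_that("target rendering draws unit-amplitude max-combined peaks", {
  mpp <- 0.6667
  z <- render_targets(annotation_set(), 32, 32, mpp)
  expect_equal(z$normal, matrix(0, 32, 32))
  expect_equal(z$tumor, matrix(0, 32, 32))
  # one tumor cell at the center of a pixel: unit peak there, normal
  # map untouched
  ctr <- annotation_set((16 - 0.5) * mpp, (16 - 0.5) * mpp, "t")
  m <- render_targets(ctr, 32, 32, mpp, sigma_px = 3)
  expect_equal(m$tumor[16, 16], 1.0)
  expect_equal(max(m$tumor), 1.0)
  expect_equal(m$normal, matrix(0, 32, 32))
  # i-cells are rendered in neither map
  mi <- render_targets(annotation_set(10, 10, "i"), 32, 32, mpp)
  expect_equal(max(mi$tumor), 0)
  expect_equal(max(mi$normal), 0)
})

test_that("overlapping peaks max-combine and match direct evaluation", {
  mpp <- 1
  ann <- annotation_set(c(15.5, 16.5), c(15.5, 15.5), c("t", "t"))
  m <- render_targets(ann, 32, 32, mpp, sigma_px = 3,
                      trunc_sigma = Inf)
  expect_lte(max(m$tumor), 1.0)
  # direct evaluation of max of the two Gaussians on the pixel grid
  direct <- matrix(0, 32, 32)
  for (r in 1:32) for (c in 1:32) {
    px <- (c - 0.5); py <- (r - 0.5)
    g1 <- exp(-((px - 15.5)^2 + (py - 15.5)^2) / 18)
    g2 <- exp(-((px - 16.5)^2 + (py - 15.5)^2) / 18)
    direct[r, c] <- max(g1, g2)
  }
  expect_equal(m$tumor, direct, tolerance = 1e-12)
  # default truncation at 4 SD deviates by at most exp(-8)
  m4 <- render_targets(ann, 32, 32, mpp, sigma_px = 3)
  expect_lt(max(abs(m4$tumor - direct)), exp(-8) + 1e-12)
})

test_that("single-peak map integral approximates 2*pi*sigma^2", {
  mpp <- 1
  ann <- annotation_set(31.5, 31.5, "n")
  m <- render_targets(ann, 64, 64, mpp, sigma_px = 3)
  expect_equal(sum(m$normal), 2 * pi * 9, tolerance = 0.01)
})

test_that("BCE-with-logits matches its closed forms and brute-force sum", {
  x <- array(0, c(4, 4, 2, 1))
  y <- array(0.5, c(4, 4, 2, 1))
  expect_equal(bce_loss(x, y), log(2))
  # zero loss iff sigmoid(x) = y with y in {0,1}
  x2 <- array(c(-50, 50), c(2, 1, 1, 1))
  y2 <- array(c(0, 1), c(2, 1, 1, 1))
  expect_lt(bce_loss(x2, y2), 1e-10)
  # gradient vanishes at y = sigmoid(x)
  set.seed(5)
  x3 <- array(rnorm(16), c(4, 4, 1, 1))
  expect_lt(max(abs(cellularity:::bce_grad(x3, plogis(x3)))), 1e-12)
  # random 4x4 instance against the naive per-pixel sum
  x4 <- array(rnorm(32), c(4, 4, 2, 1))
  y4 <- array(runif(32), c(4, 4, 2, 1))
  p <- plogis(x4)
  naive <- -mean(y4 * log(p) + (1 - y4) * log(1 - p))
  expect_equal(bce_loss(x4, y4), naive, tolerance = 1e-6)
  expect_gte(bce_loss(x4, y4), 0)
  expect_error(bce_loss(x4, y4 + 2), "\\[0, 1\\]")
})

test_that("network outputs are finite sigmoid maps, identical for
           duplicated batch items in eval mode", {
  model <- unet_init(base_ch = 4, depth = 2, seed = 8)
  img <- generate_tile(tile_spec(32, 32, n_tumor = 4, n_nontumor = 3,
                                 n_indist = 0, seed = 2))$image
  maps <- unet_predict_patch(model, img)
  expect_true(all(is.finite(maps$normal)) && all(is.finite(maps$tumor)))
  expect_true(all(maps$normal >= 0 & maps$normal <= 1))
  expect_true(all(maps$tumor >= 0 & maps$tumor <= 1))
  x <- array(0, c(32, 32, 3, 2))
  x[, , , 1] <- img; x[, , , 2] <- img
  out <- cellularity:::unet_forward(model, x, training = FALSE)
  expect_identical(out$logits[, , , 1], out$logits[, , , 2])
  expect_error(cellularity:::unet_forward(model, array(0, c(30, 30, 3, 1)),
                                          training = FALSE))
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(3)
  model <- unet_init(base_ch = 2, depth = 2, seed = 5)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  fw <- cellularity:::unet_forward(model, x, training = TRUE)
  loss0 <- bce_loss(fw$logits, y)
  g <- cellularity:::unet_backward(model, fw$cache,
                                   cellularity:::bce_grad(fw$logits, y))
  for (nm in sample(names(model$params), 8)) {
    i <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    m2 <- model
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    l2 <- bce_loss(cellularity:::unet_forward(m2, x,
                                              training = TRUE)$logits, y)
    expect_equal((l2 - loss0) / eps, g[[nm]][i], tolerance = 1e-3,
                 label = nm)
  }
})

test_that("training improves the loss, returns the best checkpoint and
           respects patience", {
  dk <- desk_fit()
  h <- dk$fit$history
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_equal(dk$fit$best_epoch, which.min(h$val_loss))
  # the returned model is the best-validation checkpoint
  vs <- lapply(dk$val_rois, cellularity:::val_patches, patch_px = 64,
               sigma_px = 3)
  vl <- cellularity:::validation_loss(dk$fit$model, do.call(c, vs))
  expect_equal(vl, min(h$val_loss), tolerance = 1e-10)
  # patience 0 stops after the first non-improving epoch
  cfg0 <- desk_train_config(max_epochs = 6, patience_epochs = 0,
                            examples_per_epoch = 16, base_ch = 2,
                            learning_rate = 0.5, augment = FALSE,
                            seed = 2)
  fit0 <- train_density_model(dk$train_rois[1:2], dk$val_rois[1], cfg0)
  h0 <- fit0$history
  worse <- which(diff(h0$val_loss) >= 0)
  if (length(worse))
    expect_equal(nrow(h0), worse[1] + 1)
  # a trained model's tumor map peaks above the tuned threshold at a
  # rendered tumor nucleus
  roi <- dk$test_rois[[1]]
  maps <- cellularity:::unet_predict_patch(
    dk$fit$model, roi$image[1:64, 1:64, , drop = FALSE])
  tcells <- roi$truth[roi$truth$label == "t", ]
  inside <- tcells$x_um < 64 * roi$mpp & tcells$y_um < 64 * roi$mpp
  if (any(inside)) {
    k <- which(inside)[1]
    r <- round(tcells$y_um[k] / roi$mpp + 0.5)
    c <- round(tcells$x_um[k] / roi$mpp + 0.5)
    expect_gt(maps$tumor[r, c], dk$tune$best_threshold)
  }
})

test_that("checkpoints round-trip through the text format", {
  dk <- desk_fit()
  p <- tempfile(fileext = ".json")
  save_checkpoint(dk$fit, p)
  m2 <- load_checkpoint(p)
  img <- dk$test_rois[[1]]$image[1:64, 1:64, , drop = FALSE]
  expect_equal(unet_predict_patch(m2, img),
               unet_predict_patch(dk$fit$model, img), tolerance = 1e-12)
})
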