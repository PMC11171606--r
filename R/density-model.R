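# Two-output density-map regressor: a compact U-Net that maps an RGB
# patch to a 'normal' and a 'tumor' cell density map. Targets are
# unit-amplitude Gaussians drawn at annotated cell centers (max-combined
# where peaks overlap); the network is trained with sigmoid + binary
# cross-entropy. Convolution / batch-norm / pooling kernels live in
# compiled code; the layer graph, backward orchestration and Adam updates
# are here.

#' Render target density maps from point annotations
#'
#' Draws a unit-amplitude isotropic Gaussian of SD `sigma_px` at every
#' tumor cell (into the tumor map) and every non-tumor cell (into the
#' normal map). Overlapping peaks are combined with the pointwise max, so
#' values stay in \[0,1\]. Indistinguishable cells are rendered in
#' neither map: they act as unannotated background during training, just
#' as they are excluded from TCR.
#'
#' @param ann Annotation `data.frame` (coordinates in microns within the
#'   patch).
#' @param height_px,width_px Patch geometry.
#' @param mpp Microns per pixel.
#' @param sigma_px Gaussian SD in pixels.
#' @param trunc_sigma Support radius of each peak in SDs (peaks are
#'   rendered inside a `trunc_sigma * sigma_px` box; `Inf` renders on
#'   the full patch).
#' @return List with matrices `normal` and `tumor` (height x width).
#' @export
render_targets <- function(ann, height_px, width_px, mpp, sigma_px = 3,
                           trunc_sigma = 4) {
  stopifnot(sigma_px > 0)
  maps <- list(normal = matrix(0, height_px, width_px),
               tumor = matrix(0, height_px, width_px))
  if (nrow(ann) == 0) return(maps)
  ext <- min(ceiling(trunc_sigma * sigma_px), max(height_px, width_px))
  for (k in seq_len(nrow(ann))) {
    lab <- ann$label[k]
    if (lab == "i") next
    tgt <- if (lab == "t") "tumor" else "normal"
    c0 <- ann$x_um[k] / mpp + 0.5
    r0 <- ann$y_um[k] / mpp + 0.5
    rr <- max(1L, floor(r0 - ext)):min(height_px, ceiling(r0 + ext))
    cc <- max(1L, floor(c0 - ext)):min(width_px, ceiling(c0 + ext))
    if (!length(rr) || !length(cc)) next
    g <- exp(-(outer((rr - r0)^2, (cc - c0)^2, "+")) / (2 * sigma_px^2))
    maps[[tgt]][rr, cc] <- pmax(maps[[tgt]][rr, cc], g)
  }
  maps
}

#' Initialize the density-map U-Net
#'
#' An encoder-decoder fully convolutional network with skip connections:
#' `depth` encoder stages of two 3x3 conv + batch-norm + ReLU layers with
#' 2x2 max pooling, a bottleneck, and mirrored decoder stages using
#' nearest-neighbor upsampling and channel concatenation. Zero-padded
#' convolutions keep every map the size of the input, so the two output
#' channels (normal, tumor logits) are spatially registered to the patch.
#' Channel widths double per stage from `base_ch`.
#'
#' @param in_ch Input channels (3 for RGB).
#' @param base_ch Channels of the first stage.
#' @param depth Number of pooling stages.
#' @param out_ch Output channels (2: normal and tumor).
#' @param seed Optional seed for weight initialization.
#' @return A `unet_model` object.
#' @export
unet_init <- function(in_ch = 3, base_ch = 8, depth = 2, out_ch = 2,
                      seed = NULL) {
  build <- function() {
    P <- list(); S <- list()
    add_conv <- function(nm, k, ci, co) {
      P[[paste0(nm, ".w")]] <<- array(
        stats::rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))),
        c(k, k, ci, co))
      P[[paste0(nm, ".b")]] <<- numeric(co)
    }
    add_bn <- function(nm, c) {
      P[[paste0(nm, ".gamma")]] <<- rep(1, c)
      P[[paste0(nm, ".beta")]] <<- numeric(c)
      S[[paste0(nm, ".rm")]] <<- numeric(c)
      S[[paste0(nm, ".rv")]] <<- rep(1, c)
    }
    ch <- function(d) base_ch * 2L^(d - 1L)
    for (d in seq_len(depth)) {
      ci <- if (d == 1) in_ch else ch(d - 1)
      add_conv(sprintf("enc%d.conv1", d), 3, ci, ch(d))
      add_bn(sprintf("enc%d.bn1", d), ch(d))
      add_conv(sprintf("enc%d.conv2", d), 3, ch(d), ch(d))
      add_bn(sprintf("enc%d.bn2", d), ch(d))
    }
    add_conv("bott.conv1", 3, ch(depth), ch(depth + 1))
    add_bn("bott.bn1", ch(depth + 1))
    add_conv("bott.conv2", 3, ch(depth + 1), ch(depth + 1))
    add_bn("bott.bn2", ch(depth + 1))
    for (d in depth:1) {
      up_ci <- ch(d + 1)
      add_conv(sprintf("dec%d.conv1", d), 3, up_ci + ch(d), ch(d))
      add_bn(sprintf("dec%d.bn1", d), ch(d))
      add_conv(sprintf("dec%d.conv2", d), 3, ch(d), ch(d))
      add_bn(sprintf("dec%d.bn2", d), ch(d))
    }
    add_conv("head", 1, ch(1), out_ch)
    list(P = P, S = S)
  }
  ps <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  structure(list(params = ps$P, stats = ps$S, in_ch = in_ch,
                 base_ch = base_ch, depth = depth, out_ch = out_ch),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "U-Net density regressor: depth %d, base %d channels, %d parameters\n",
    x$depth, x$base_ch, np))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `unet_model`.
#' @export
unet_n_params <- function(model) sum(vapply(model$params, length, 0L))

# Forward pass. x: (H, W, C, B). Returns list(logits, cache, stats);
# cache holds everything the backward pass needs and is NULL in eval mode.
unet_forward <- function(model, x, training = FALSE) {
  P <- model$params
  env <- new.env(parent = emptyenv())
  env$S <- model$stats
  env$cache <- list()
  conv_f <- function(nm, x) {
    if (training) env$cache[[paste0(nm, ".x")]] <- x
    conv2d_forward_cpp(x, P[[paste0(nm, ".w")]], P[[paste0(nm, ".b")]])
  }
  bn_f <- function(nm, x) {
    r <- bn_forward_cpp(x, P[[paste0(nm, ".gamma")]],
                        P[[paste0(nm, ".beta")]],
                        env$S[[paste0(nm, ".rm")]],
                        env$S[[paste0(nm, ".rv")]],
                        training, 1e-5, 0.1)
    if (training) {
      env$S[[paste0(nm, ".rm")]] <- r$running_mean
      env$S[[paste0(nm, ".rv")]] <- r$running_var
      env$cache[[paste0(nm, ".x")]] <- x
      env$cache[[paste0(nm, ".mean")]] <- r$mean
      env$cache[[paste0(nm, ".invstd")]] <- r$invstd
    }
    r$y
  }
  # a stage is conv-bn-relu twice, e.g. enc1.conv1/bn1 then enc1.conv2/bn2
  stage <- function(prefix, x) {
    cbr_named(prefix, 2, cbr_named(prefix, 1, x))
  }
  cbr_named <- function(prefix, j, x) {
    h <- bn_f(sprintf("%s.bn%d", prefix, j),
              conv_f(sprintf("%s.conv%d", prefix, j), x))
    if (training) env$cache[[sprintf("%s.mask%d", prefix, j)]] <- h > 0
    pmax(h, 0)
  }
  skips <- vector("list", model$depth)
  h <- x
  for (d in seq_len(model$depth)) {
    h <- stage(sprintf("enc%d", d), h)
    skips[[d]] <- h
    mp <- maxpool2_forward_cpp(h)
    if (training) {
      env$cache[[sprintf("pool%d.idx", d)]] <- mp$idx
      env$cache[[sprintf("pool%d.xdim", d)]] <- dim(h)
    }
    h <- mp$y
  }
  h <- stage("bott", h)
  for (d in model$depth:1) {
    up <- upsample2_forward_cpp(h)
    h <- abind4(up, skips[[d]])
    if (training)
      env$cache[[sprintf("cat%d.split", d)]] <- dim(up)[3]
    h <- stage(sprintf("dec%d", d), h)
  }
  logits <- conv_f("head", h)
  list(logits = logits, cache = if (training) env$cache else NULL,
       stats = env$S)
}

# concatenate two (H, W, C, B) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backward pass; returns gradients named like the parameters.
unet_backward <- function(model, cache, dlogits) {
  P <- model$params
  G <- list()
  conv_b <- function(nm, dy) {
    r <- conv2d_backward_cpp(cache[[paste0(nm, ".x")]],
                             P[[paste0(nm, ".w")]], dy)
    G[[paste0(nm, ".w")]] <<- r$dw
    G[[paste0(nm, ".b")]] <<- r$db
    r$dx
  }
  bn_b <- function(nm, dy) {
    r <- bn_backward_cpp(cache[[paste0(nm, ".x")]],
                         P[[paste0(nm, ".gamma")]],
                         cache[[paste0(nm, ".mean")]],
                         cache[[paste0(nm, ".invstd")]], dy)
    G[[paste0(nm, ".gamma")]] <<- r$dgamma
    G[[paste0(nm, ".beta")]] <<- r$dbeta
    r$dx
  }
  cbr_b <- function(prefix, j, dy) {
    dy <- dy * cache[[sprintf("%s.mask%d", prefix, j)]]
    conv_b(sprintf("%s.conv%d", prefix, j),
           bn_b(sprintf("%s.bn%d", prefix, j), dy))
  }
  stage_b <- function(prefix, dy) cbr_b(prefix, 1, cbr_b(prefix, 2, dy))
  dh <- conv_b("head", dlogits)
  dskips <- vector("list", model$depth)
  for (d in seq_len(model$depth)) {
    dh <- stage_b(sprintf("dec%d", d), dh)
    nup <- cache[[sprintf("cat%d.split", d)]]
    dup <- dh[, , seq_len(nup), , drop = FALSE]
    dskips[[d]] <- dh[, , -seq_len(nup), , drop = FALSE]
    dh <- upsample2_backward_cpp(dup)
  }
  dh <- stage_b("bott", dh)
  for (d in model$depth:1) {
    dh <- maxpool2_backward_cpp(cache[[sprintf("pool%d.idx", d)]], dh,
                                cache[[sprintf("pool%d.xdim", d)]])
    dh <- dh + dskips[[d]]
    dh <- stage_b(sprintf("enc%d", d), dh)
  }
  G
}

#' Binary cross-entropy loss with logits
#'
#' Numerically stabilized BCE combined with a sigmoid layer:
#' `-(1/N) * sum(y * log(sigmoid(x)) + (1 - y) * log(1 - sigmoid(x)))`
#' where N is the total number of elements (pixels times maps).
#'
#' @param logits Numeric array of pre-sigmoid outputs.
#' @param target Array of the same shape with values in \[0,1\].
#' @return Scalar loss.
#' @export
bce_loss <- function(logits, target) {
  if (any(target < 0 | target > 1)) stop("targets must lie in [0, 1]")
  stopifnot(length(logits) == length(target))
  mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
}

bce_grad <- function(logits, target) {
  g <- (stats::plogis(logits) - target) / length(logits)
  dim(g) <- dim(logits)
  g
}

#' Run the network on a single patch
#'
#' Evaluation-mode forward pass returning the two sigmoid density maps.
#'
#' @param model A trained `unet_model`.
#' @param patch RGB array (patch_px x patch_px x 3).
#' @return List with matrices `normal` and `tumor`, values in \[0,1\].
#' @export
unet_predict_patch <- function(model, patch) {
  d <- dim(patch)
  x <- array(patch, c(d[1], d[2], d[3], 1))
  out <- unet_forward(model, x, training = FALSE)
  p <- stats::plogis(out$logits)
  list(normal = matrix(p[, , 1, 1], d[1], d[2]),
       tumor = matrix(p[, , 2, 1], d[1], d[2]))
}
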