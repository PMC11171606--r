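#' Training configuration
#'
#' Defaults mirror the full-scale protocol: 300 px patches, 4000 examples
#' per epoch, Adam at learning rate 1e-4, early stopping when validation
#' loss fails to improve for 4 epochs, convergence expected within ~50
#' epochs. [desk_train_config()] provides a scaled-down preset (smaller
#' patches, wider learning rate, fewer examples) suitable for seeded
#' CPU-scale experiments on synthetic tiles.
#'
#' @param patch_px Square patch side in pixels.
#' @param examples_per_epoch Patches sampled per epoch.
#' @param batch_size Minibatch size.
#' @param patience_epochs Early-stopping patience; 0 stops at the first
#'   non-improving epoch.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Epoch budget.
#' @param target_sigma_px Gaussian SD of the target peaks, in pixels
#'   (must stay well below the 4-micron matching radius).
#' @param base_ch,depth Network width/depth (see [unet_init()]).
#' @param augment Apply a random augmentation spec to every patch.
#' @param seed Integer seed funnelling all training randomness.
#' @export
train_config <- function(patch_px = 300, examples_per_epoch = 4000,
                         batch_size = 8, patience_epochs = 4,
                         learning_rate = 1e-4, max_epochs = 50,
                         target_sigma_px = 3, base_ch = 16, depth = 2,
                         augment = TRUE, seed = 1) {
  stopifnot(patch_px > 0, examples_per_epoch > 0, batch_size > 0,
            patience_epochs >= 0, learning_rate > 0, max_epochs > 0,
            target_sigma_px > 0, base_ch > 0, depth > 0)
  if (patch_px %% 2^depth != 0)
    stop("patch_px must be divisible by 2^depth")
  structure(list(patch_px = as.integer(patch_px),
                 examples_per_epoch = as.integer(examples_per_epoch),
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 target_sigma_px = target_sigma_px,
                 base_ch = as.integer(base_ch), depth = as.integer(depth),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' @param ... Overrides passed to [train_config()].
#' @rdname train_config
#' @export
desk_train_config <- function(...) {
  defaults <- list(patch_px = 64, examples_per_epoch = 240, batch_size = 8,
                   patience_epochs = 3, learning_rate = 1e-3,
                   max_epochs = 10, target_sigma_px = 3, base_ch = 8,
                   depth = 2, augment = TRUE, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Extract a training example: random patch from a random ROI, optional
# augmentation, rendered target maps. Uses the current RNG stream.
sample_patch <- function(rois, patch_px, sigma_px, augment) {
  roi <- rois[[sample.int(length(rois), 1)]]
  h <- dim(roi$image)[1]; w <- dim(roi$image)[2]
  if (h < patch_px || w < patch_px)
    stop("ROI smaller than the training patch")
  r0 <- sample.int(h - patch_px + 1L, 1) - 1L
  c0 <- sample.int(w - patch_px + 1L, 1) - 1L
  img <- roi$image[r0 + seq_len(patch_px), c0 + seq_len(patch_px), ,
                   drop = FALSE]
  mpp <- roi$mpp
  ann <- roi$gold$cells %||% roi$truth
  x0 <- c0 * mpp; y0 <- r0 * mpp
  side <- patch_px * mpp
  sel <- ann$x_um > x0 & ann$x_um <= x0 + side &
         ann$y_um > y0 & ann$y_um <= y0 + side
  local_ann <- ann[sel, , drop = FALSE]
  local_ann$x_um <- local_ann$x_um - x0
  local_ann$y_um <- local_ann$y_um - y0
  if (augment)
    img <- apply_augmentation_spec(img, sample_augmentation_spec())
  tg <- render_targets(local_ann, patch_px, patch_px, mpp, sigma_px)
  list(x = img, y_normal = tg$normal, y_tumor = tg$tumor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic non-overlapping patch tiling of an ROI for validation
val_patches <- function(roi, patch_px, sigma_px) {
  h <- dim(roi$image)[1]; w <- dim(roi$image)[2]
  starts <- function(n) {
    if (n == patch_px) return(0L)
    seq(0L, n - patch_px, by = patch_px)
  }
  out <- list()
  ann <- roi$gold$cells %||% roi$truth
  for (r0 in starts(h)) for (c0 in starts(w)) {
    img <- roi$image[r0 + seq_len(patch_px), c0 + seq_len(patch_px), ,
                     drop = FALSE]
    mpp <- roi$mpp
    x0 <- c0 * mpp; y0 <- r0 * mpp; side <- patch_px * mpp
    sel <- ann$x_um > x0 & ann$x_um <= x0 + side &
           ann$y_um > y0 & ann$y_um <= y0 + side
    la <- ann[sel, , drop = FALSE]
    la$x_um <- la$x_um - x0; la$y_um <- la$y_um - y0
    tg <- render_targets(la, patch_px, patch_px, mpp, sigma_px)
    out[[length(out) + 1]] <- list(x = img, y_normal = tg$normal,
                                   y_tumor = tg$tumor)
  }
  out
}

examples_to_batch <- function(examples) {
  B <- length(examples)
  p <- dim(examples[[1]]$x)[1]
  x <- array(0, c(p, p, 3, B))
  y <- array(0, c(p, p, 2, B))
  for (b in seq_len(B)) {
    x[, , , b] <- examples[[b]]$x
    y[, , 1, b] <- examples[[b]]$y_normal
    y[, , 2, b] <- examples[[b]]$y_tumor
  }
  list(x = x, y = y)
}

#' Train the density-map model
#'
#' Per epoch, samples `examples_per_epoch` random patches from the
#' training ROIs (one freshly sampled augmentation spec per patch when
#' augmentation is on), optimizes the sigmoid/BCE loss with Adam, then
#' measures the loss on a deterministic tiling of the validation ROIs.
#' Training stops when the validation loss has not improved for
#' `patience_epochs` epochs or at `max_epochs`; the returned model is the
#' one with the best validation loss. All randomness runs through
#' `cfg$seed`.
#'
#' ROIs are lists with `image` (h x w x 3 array), `mpp`, and annotations
#' in either `gold` (a `gold_standard`, preferred) or `truth`.
#'
#' @param train_rois,val_rois Non-empty lists of ROIs.
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint), `history` (data.frame
#'   `epoch`, `train_loss`, `val_loss`), `stopped_epoch`, `best_epoch`.
#' @export
train_density_model <- function(train_rois, val_rois, cfg) {
  stopifnot(inherits(cfg, "train_config"),
            length(train_rois) > 0, length(val_rois) > 0)
  withr::with_seed(cfg$seed, {
    model <- unet_init(in_ch = 3, base_ch = cfg$base_ch, depth = cfg$depth,
                       out_ch = 2)
    opt <- adam_init(model$params)
    vsets <- lapply(val_rois, val_patches, patch_px = cfg$patch_px,
                    sigma_px = cfg$target_sigma_px)
    vsets <- do.call(c, vsets)
    steps <- max(1L, ceiling(cfg$examples_per_epoch / cfg$batch_size))
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best_val <- Inf; best_model <- model; best_epoch <- 0L
    bad_epochs <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      tl <- 0
      for (s in seq_len(steps)) {
        ex <- lapply(seq_len(cfg$batch_size), function(i)
          sample_patch(train_rois, cfg$patch_px, cfg$target_sigma_px,
                       cfg$augment))
        ba <- examples_to_batch(ex)
        fw <- unet_forward(model, ba$x, training = TRUE)
        model$stats <- fw$stats
        loss <- bce_loss(fw$logits, ba$y)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch, ", step ", s,
               " (lr = ", cfg$learning_rate, ")")
        grads <- unet_backward(model, fw$cache, bce_grad(fw$logits, ba$y))
        up <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- up$params
        opt <- up$state
        tl <- tl + loss
      }
      vl <- validation_loss(model, vsets)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = tl / steps,
                                  val_loss = vl))
      if (vl < best_val) {
        best_val <- vl; best_model <- model; best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > cfg$patience_epochs) break
      }
    }
    list(model = best_model, history = history,
         stopped_epoch = nrow(history), best_epoch = best_epoch,
         config = cfg)
  })
}

validation_loss <- function(model, vsets) {
  if (!length(vsets)) return(NA_real_)
  tot <- 0
  for (ex in vsets) {
    ba <- examples_to_batch(list(ex))
    fw <- unet_forward(model, ba$x, training = FALSE)
    tot <- tot + bce_loss(fw$logits, ba$y)
  }
  tot / length(vsets)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain YAML+CSV-free single RDS-like text format:
#' parameters are serialized with [jsonlite] (lossless doubles), so
#' checkpoints are text files that survive source-only distribution.
#'
#' @param fit Result of [train_density_model()] or a `unet_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "unet_model")) fit else fit$model
  obj <- list(meta = list(in_ch = model$in_ch, base_ch = model$base_ch,
                          depth = model$depth, out_ch = model$out_ch),
              dims = lapply(model$params, function(p)
                as.integer(dim(p) %||% length(p))),
              params = lapply(model$params, as.numeric),
              stats = lapply(model$stats, as.numeric))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  model <- unet_init(obj$meta$in_ch, obj$meta$base_ch, obj$meta$depth,
                     obj$meta$out_ch, seed = 0)
  for (nm in names(model$params)) {
    p <- obj$params[[nm]]
    d <- obj$dims[[nm]]
    if (length(d) > 1) dim(p) <- d
    model$params[[nm]] <- p
  }
  for (nm in names(model$stats)) model$stats[[nm]] <- obj$stats[[nm]]
  model
}
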