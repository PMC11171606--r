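# Photometric augmentation operators and the three-branch sampler used
# during training: one color branch (H&E stain shift or RGB shift), one
# tone branch (gamma or brightness/contrast/saturation), one focus branch
# (blur, sharpen, or nothing). All operators preserve image geometry, so
# point annotations remain valid unchanged.

AUG_RANGES <- list(
  he_delta = c(-0.16, 0.16),
  rgb_delta = c(-0.12, 0.12),
  gamma = c(0.4, 1.5),
  brightness_delta = c(-0.15, 0),
  contrast_factor = c(0.70, 1.30),
  saturation_factor = c(0.70, 1.30),
  blur_sigma = c(0.3, 0.5),          # discrete choice
  sharpen_intensity = c(1.0, 1.2)
)

#' Sample a random augmentation specification
#'
#' Draws one choice per branch with equal probability (HE vs RGB color
#' shift; gamma vs brightness/contrast/saturation; blur vs sharpen vs
#' nothing) and every parameter uniformly within its range. Uses the
#' current R RNG stream, so seed the caller for reproducibility.
#'
#' @return An `augmentation_spec` list.
#' @export
sample_augmentation_spec <- function() {
  r <- AUG_RANGES
  structure(list(
    color_branch = sample(c("HE", "RGB"), 1),
    tone_branch = sample(c("GAMMA", "BCS"), 1),
    focus_branch = sample(c("BLUR", "SHARPEN", "NONE"), 1),
    he_delta = stats::runif(2, r$he_delta[1], r$he_delta[2]),
    rgb_delta = stats::runif(3, r$rgb_delta[1], r$rgb_delta[2]),
    gamma = stats::runif(1, r$gamma[1], r$gamma[2]),
    brightness_delta = stats::runif(1, r$brightness_delta[1],
                                    r$brightness_delta[2]),
    contrast_factor = stats::runif(1, r$contrast_factor[1],
                                   r$contrast_factor[2]),
    saturation_factor = stats::runif(1, r$saturation_factor[1],
                                     r$saturation_factor[2]),
    blur_sigma = sample(r$blur_sigma, 1),
    sharpen_intensity = stats::runif(1, r$sharpen_intensity[1],
                                     r$sharpen_intensity[2])),
    class = "augmentation_spec")
}

#' Neutral (identity) augmentation specification
#' @export
neutral_augmentation_spec <- function() {
  structure(list(color_branch = "RGB", tone_branch = "GAMMA",
                 focus_branch = "NONE",
                 he_delta = c(0, 0), rgb_delta = c(0, 0, 0), gamma = 1,
                 brightness_delta = 0, contrast_factor = 1,
                 saturation_factor = 1, blur_sigma = 0.3,
                 sharpen_intensity = 1),
            class = "augmentation_spec")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Elementary photometric operators
#'
#' Geometry-preserving image operators on RGB arrays with values in
#' \[0,1\]: additive RGB shift (fractions of the channel range), gamma
#' correction, additive brightness, contrast about mid-gray, saturation
#' toward per-pixel luminance, separable Gaussian blur with replicate
#' padding, and unsharp-mask sharpening.
#'
#' @param img RGB array (h x w x 3).
#' @param delta,g,factor,sigma,intensity Operator parameters.
#' @name photometric-ops
NULL

#' @rdname photometric-ops
#' @export
rgb_shift <- function(img, delta) {
  stopifnot(length(delta) == 3)
  for (ch in 1:3) img[, , ch] <- img[, , ch] + delta[ch]
  clip01(img)
}

#' @rdname photometric-ops
#' @export
adjust_gamma <- function(img, g) {
  stopifnot(g > 0)
  clip01(img)^g
}

#' @rdname photometric-ops
#' @export
adjust_brightness <- function(img, delta) clip01(img + delta)

#' @rdname photometric-ops
#' @export
adjust_contrast <- function(img, factor) clip01((img - 0.5) * factor + 0.5)

#' @rdname photometric-ops
#' @export
adjust_saturation <- function(img, factor) {
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  for (ch in 1:3) img[, , ch] <- lum + (img[, , ch] - lum) * factor
  clip01(img)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

convolve_sep <- function(m, k) {
  # separable 1-D convolution along rows then columns, replicate padding
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(h) + (j - 1L - r), 1L), h)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  m2 <- matrix(0, h, w)
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(w) + (j - 1L - r), 1L), w)
    m2 <- m2 + k[j] * out[, idx, drop = FALSE]
  }
  m2
}

#' @rdname photometric-ops
#' @export
gaussian_blur <- function(img, sigma) {
  k <- gauss_kernel_1d(sigma)
  if (length(dim(img)) == 2) return(convolve_sep(img, k))
  for (ch in seq_len(dim(img)[3]))
    img[, , ch] <- convolve_sep(img[, , ch], k)
  img
}

#' @rdname photometric-ops
#' @export
sharpen <- function(img, intensity) {
  clip01(img + intensity * (img - gaussian_blur(img, 1.0)))
}

#' Apply an augmentation specification to an image
#'
#' Deterministic application order: color branch, then tone branch, then
#' focus branch. Annotation coordinates are untouched (all operators are
#' geometry-preserving).
#'
#' @param img RGB array.
#' @param spec An `augmentation_spec`.
#' @return Augmented image, intensities clipped to \[0,1\].
#' @export
apply_augmentation_spec <- function(img, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  img <- switch(spec$color_branch,
                HE = he_shift(img, spec$he_delta),
                RGB = rgb_shift(img, spec$rgb_delta))
  img <- switch(spec$tone_branch,
                GAMMA = adjust_gamma(img, spec$gamma),
                BCS = adjust_saturation(
                  adjust_contrast(
                    adjust_brightness(img, spec$brightness_delta),
                    spec$contrast_factor),
                  spec$saturation_factor))
  img <- switch(spec$focus_branch,
                BLUR = gaussian_blur(img, spec$blur_sigma),
                SHARPEN = sharpen(img, spec$sharpen_intensity),
                NONE = img)
  clip01(img)
}

#' Serialize / deserialize an augmentation spec as YAML
#'
#' @param spec An `augmentation_spec`.
#' @param text YAML string from `augmentation_spec_to_yaml()`.
#' @export
augmentation_spec_to_yaml <- function(spec) {
  yaml::as.yaml(unclass(spec), precision = 15)
}

#' @rdname augmentation_spec_to_yaml
#' @export
augmentation_spec_from_yaml <- function(text) {
  structure(yaml::yaml.load(text), class = "augmentation_spec")
}
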