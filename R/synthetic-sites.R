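#' Site staining / imaging profile
#'
#' A deterministic per-site color transform emulating inter-institution
#' variation in staining chemistry and scanner processing: a fixed shift
#' along the H&E stain axes, an RGB offset, a gamma correction and a
#' brightness offset, applied in that order. Annotation coordinates are
#' unchanged by design (the transform is purely photometric).
#'
#' @param site_id Site identifier string.
#' @param he_shift Length-2 shift along the H and E stain axes (fraction
#'   of the stain channel range).
#' @param rgb_shift Length-3 additive RGB shift (fraction of range).
#' @param gamma Positive gamma exponent.
#' @param brightness Additive brightness offset (fraction of range).
#' @export
site_profile <- function(site_id, he_shift = c(0, 0),
                         rgb_shift = c(0, 0, 0), gamma = 1,
                         brightness = 0) {
  stopifnot(gamma > 0, length(he_shift) == 2, length(rgb_shift) == 3)
  structure(list(site_id = as.character(site_id), he_shift = he_shift,
                 rgb_shift = rgb_shift, gamma = gamma,
                 brightness = brightness),
            class = "site_profile")
}

#' Apply a site profile to an image
#'
#' @param img RGB array (h x w x 3).
#' @param profile A [site_profile()].
#' @return The transformed image.
#' @export
apply_site_profile <- function(img, profile) {
  stopifnot(inherits(profile, "site_profile"))
  if (any(profile$he_shift != 0))
    img <- he_shift(img, profile$he_shift)
  if (any(profile$rgb_shift != 0))
    img <- rgb_shift(img, profile$rgb_shift)
  if (profile$gamma != 1)
    img <- adjust_gamma(img, profile$gamma)
  if (profile$brightness != 0)
    img <- adjust_brightness(img, profile$brightness)
  clip01(img)
}
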