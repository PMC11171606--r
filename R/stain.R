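# Color deconvolution in optical-density space with the standard
# hematoxylin / eosin stain vectors (Ruifrok & Johnston); the residual
# axis completes an invertible basis. OD is base-10: od = -log10(I),
# intensities in (0, 1].

#' Default H&E stain basis
#'
#' A 3x3 matrix whose rows are the unit optical-density vectors of
#' hematoxylin, eosin, and a residual axis orthogonal to both.
#'
#' @return Matrix with rows `H`, `E`, `R` and columns `R`, `G`, `B`.
#' @export
he_stain_basis <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- rbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)),
             R = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

# Nominal full range of a stain-concentration channel, in OD units
# (log10(256), the OD of the darkest representable 8-bit intensity).
# "Fractions of range" for H&E shifts are fractions of this constant.
OD_RANGE <- log10(256)

rgb_to_od <- function(img) -log10(pmax(img, 1 / 255))

od_to_rgb <- function(od) pmin(pmax(10^(-od), 0), 1)

#' Shift an image along the H and E stain axes
#'
#' Converts the image to optical density, projects it onto the H&E stain
#' basis, adds `delta * OD range` to the hematoxylin and eosin
#' concentration channels, and reconstructs RGB with clipping. A zero
#' delta round-trips the image up to quantization.
#'
#' @param img RGB array (h x w x 3, values in \[0,1\]).
#' @param delta Length-2 numeric: shift of the H and E channels as a
#'   fraction of the stain channel range.
#' @param basis Stain basis matrix (rows H, E, residual).
#' @return The shifted RGB image.
#' @export
he_shift <- function(img, delta, basis = he_stain_basis()) {
  stopifnot(length(delta) == 2)
  d <- dim(img)
  od <- matrix(rgb_to_od(img), ncol = 3)     # pixels x 3 (RGB planes)
  conc <- od %*% solve(basis)                # pixels x 3 (H, E, residual)
  conc[, 1] <- conc[, 1] + delta[1] * OD_RANGE
  conc[, 2] <- conc[, 2] + delta[2] * OD_RANGE
  array(od_to_rgb(conc %*% basis), d)
}

#' Stain concentration channels of an image
#'
#' @inheritParams he_shift
#' @return Array h x w x 3 of H, E and residual concentrations (OD units).
#' @export
stain_concentrations <- function(img, basis = he_stain_basis()) {
  d <- dim(img)
  od <- matrix(rgb_to_od(img), ncol = 3)
  array(od %*% solve(basis), d)
}
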