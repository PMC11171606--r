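#' Specification of a synthetic H&E-like tile
#'
#' Describes a seeded, fully reproducible synthetic tile: two
#' morphologically distinct cell classes (tumor nuclei are larger, darker
#' and more elongated; non-tumor nuclei smaller and rounder) plus
#' intermediate-looking indistinguishable cells, on a textured eosin-like
#' background. Nucleus centers are kept at least `min_spacing_um` apart by
#' rejection sampling so that 4-micron point matching is unambiguous.
#'
#' @param width_px,height_px Tile size in pixels.
#' @param microns_per_px Pixel pitch in microns (default 0.6667, the 15x
#'   magnification used throughout).
#' @param n_tumor,n_nontumor,n_indist Cell counts per class.
#' @param cluster_strength Fraction in \[0,1\] of tumor cells drawn near
#'   cluster centers rather than uniformly (tumor nuclei cluster into
#'   nests; non-tumor cells are dispersed).
#' @param min_spacing_um Minimum distance between nucleus centers.
#' @param seed Integer seed; identical specs give bit-identical tiles.
#' @return A `tile_spec` list.
#' @export
tile_spec <- function(width_px = 128, height_px = 128,
                      microns_per_px = 0.6667,
                      n_tumor = 25, n_nontumor = 15, n_indist = 5,
                      cluster_strength = 0.7, min_spacing_um = 3,
                      seed = 1) {
  stopifnot(width_px > 0, height_px > 0, microns_per_px > 0,
            n_tumor >= 0, n_nontumor >= 0, n_indist >= 0,
            cluster_strength >= 0, cluster_strength <= 1,
            min_spacing_um >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_px = microns_per_px,
                 n_tumor = as.integer(n_tumor),
                 n_nontumor = as.integer(n_nontumor),
                 n_indist = as.integer(n_indist),
                 cluster_strength = cluster_strength,
                 min_spacing_um = min_spacing_um,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

# Smooth value-noise field (random coarse grid, bilinear upsampling); a
# cheap stand-in for the low-frequency texture of an eosin background.
value_noise <- function(h, w, cell = 16, amplitude = 1) {
  gh <- ceiling(h / cell) + 1L
  gw <- ceiling(w / cell) + 1L
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  r <- (seq_len(h) - 1) / cell
  cc <- (seq_len(w) - 1) / cell
  r0 <- pmin(floor(r), gh - 2); c0 <- pmin(floor(cc), gw - 2)
  fr <- r - r0; fc <- cc - c0
  # smoothstep for C1 continuity
  fr <- fr * fr * (3 - 2 * fr); fc <- fc * fc * (3 - 2 * fc)
  a <- g[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  b <- g[cbind(rep(r0 + 2, w), rep(c0 + 1, each = h))]
  d <- g[cbind(rep(r0 + 1, w), rep(c0 + 2, each = h))]
  e <- g[cbind(rep(r0 + 2, w), rep(c0 + 2, each = h))]
  m <- (a * (1 - fr) + b * fr) * (1 - rep(fc, each = h)) +
       (d * (1 - fr) + e * fr) * rep(fc, each = h)
  amplitude * matrix(m, h, w)
}

# Anti-aliased filled ellipse composited onto img (h x w x 3, values 0-1).
draw_nucleus <- function(img, x_um, y_um, a_um, b_um, theta, color, mpp) {
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- a_um / mpp + 1.5
  c0 <- x_um / mpp + 0.5; r0 <- y_um / mpp + 0.5
  rr <- max(1L, floor(r0 - half)):min(h, ceiling(r0 + half))
  cc <- max(1L, floor(c0 - half)):min(w, ceiling(c0 + half))
  if (!length(rr) || !length(cc)) return(img)
  px <- (rep(cc, each = length(rr)) - 0.5) * mpp - x_um
  py <- (rep(rr, times = length(cc)) - 0.5) * mpp - y_um
  u <- (cos(theta) * px + sin(theta) * py) / a_um
  v <- (-sin(theta) * px + cos(theta) * py) / b_um
  d <- sqrt(u * u + v * v)
  # soft edge roughly one pixel wide, in units of the semi-major axis
  alpha <- pmin(1, pmax(0, (1 - d) * a_um / (0.75 * mpp)))
  if (!any(alpha > 0)) return(img)
  am <- matrix(alpha, length(rr), length(cc))
  # slight radial shading: darker core, lighter rim
  shade <- matrix(1 - 0.25 * pmin(d, 1)^2, length(rr), length(cc))
  for (ch in 1:3) {
    sub <- img[rr, cc, ch]
    img[rr, cc, ch] <- sub * (1 - am) + (color[ch] * shade) * am
  }
  img
}

# Per-class nucleus morphology; tumor nuclei are large, dark and
# elongated, non-tumor small and round, indistinguishable in between.
nucleus_params <- function(label) {
  switch(label,
    t = list(a = stats::runif(1, 2.6, 3.6),
             aspect = stats::runif(1, 0.55, 0.85),
             color = c(0.30, 0.16, 0.45) + stats::rnorm(3, 0, 0.03)),
    n = list(a = stats::runif(1, 1.3, 1.9),
             aspect = stats::runif(1, 0.85, 1.0),
             color = c(0.46, 0.30, 0.58) + stats::rnorm(3, 0, 0.03)),
    i = list(a = stats::runif(1, 1.9, 2.6),
             aspect = stats::runif(1, 0.70, 0.95),
             color = c(0.38, 0.23, 0.52) + stats::rnorm(3, 0, 0.03)))
}

#' Generate a synthetic H&E-like tile with ground-truth cell points
#'
#' Renders the tile described by `spec` and returns both the RGB image and
#' the exact cell-center annotations. The same `spec` (including its seed)
#' always produces a bit-identical image and identical point list. The
#' true TCR of the tile is `100 * n_tumor / (n_tumor + n_nontumor)` by
#' construction.
#'
#' @param spec A [tile_spec()].
#' @return A list with `image` (array height x width x 3, values in
#'   \[0,1\]), `annotations` (annotation `data.frame`), and `spec`.
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  withr::with_seed(spec$seed, generate_tile_impl(spec))
}

generate_tile_impl <- function(spec) {
  h <- spec$height_px; w <- spec$width_px; mpp <- spec$microns_per_px
  w_um <- w * mpp; h_um <- h * mpp
  margin <- 2.5
  if (w_um <= 2 * margin || h_um <= 2 * margin)
    stop("tile too small for the placement margin")
  n_total <- spec$n_tumor + spec$n_nontumor + spec$n_indist
  # crude capacity guard before attempting rejection sampling
  cap <- floor((w_um - 2 * margin) * (h_um - 2 * margin) /
                 (0.5 * spec$min_spacing_um^2))
  if (n_total > cap)
    stop("requested ", n_total, " cells exceed tile capacity (~", cap,
         ") under the ", spec$min_spacing_um, " um minimum spacing")

  pts <- matrix(numeric(0), ncol = 2)
  labels <- character(0)
  place <- function(n, label, sampler) {
    placed <- 0L; fails <- 0L
    while (placed < n) {
      p <- sampler()
      ok <- p[1] >= margin && p[1] <= w_um - margin &&
            p[2] >= margin && p[2] <= h_um - margin &&
            (nrow(pts) == 0 ||
             min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >=
               spec$min_spacing_um^2)
      if (ok) {
        pts <<- rbind(pts, p)
        labels <<- c(labels, label)
        placed <- placed + 1L
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails > 2000)
          stop("cannot place ", n, " '", label, "' cells under the ",
               spec$min_spacing_um, " um minimum spacing")
      }
    }
  }
  unif <- function() c(stats::runif(1, margin, w_um - margin),
                       stats::runif(1, margin, h_um - margin))
  if (spec$n_tumor > 0) {
    n_centers <- max(1L, ceiling(spec$n_tumor / 12))
    centers <- cbind(stats::runif(n_centers, margin, w_um - margin),
                     stats::runif(n_centers, margin, h_um - margin))
    tumor_sampler <- function() {
      if (stats::runif(1) < spec$cluster_strength) {
        ctr <- centers[sample.int(n_centers, 1), ]
        ctr + stats::rnorm(2, 0, 8)
      } else unif()
    }
    place(spec$n_tumor, "t", tumor_sampler)
  }
  place(spec$n_nontumor, "n", unif)
  place(spec$n_indist, "i", unif)

  # background: pale eosin wash with smooth texture
  img <- array(0, c(h, w, 3))
  base <- c(0.91, 0.84, 0.89)
  tex <- value_noise(h, w, cell = 16, amplitude = 0.030)
  fine <- value_noise(h, w, cell = 5, amplitude = 0.015)
  for (ch in 1:3) img[, , ch] <- base[ch] + tex + fine
  # render in scan order for determinism
  if (n_total > 0) {
    ord <- order(pts[, 2], pts[, 1])
    for (k in ord) {
      p <- nucleus_params(labels[k])
      img <- draw_nucleus(img, pts[k, 1], pts[k, 2], p$a, p$a * p$aspect,
                          stats::runif(1, 0, pi),
                          pmin(pmax(p$color, 0), 1), mpp)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  ann <- if (n_total > 0)
    annotation_set(pts[, 1], pts[, 2], labels)
  else annotation_set()
  list(image = img, annotations = ann, spec = spec)
}
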