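#' Annotator noise model
#'
#' Describes one simulated annotator of a tile: each true cell is missed
#' independently with `miss_prob`; surviving points are jittered by an
#' isotropic Gaussian of `jitter_sigma_um`; a point's label is set to
#' `"i"` with `to_indist_prob`, otherwise flipped t<->n with `flip_prob`.
#' The output row order is randomized under the seed.
#'
#' @param jitter_sigma_um Positional jitter SD in microns.
#' @param miss_prob,flip_prob,to_indist_prob Probabilities in \[0,1\].
#' @param seed Integer seed.
#' @export
annotator_noise <- function(jitter_sigma_um = 0.5, miss_prob = 0.03,
                            flip_prob = 0.05, to_indist_prob = 0.05,
                            seed = 1) {
  stopifnot(jitter_sigma_um >= 0,
            miss_prob >= 0, miss_prob <= 1,
            flip_prob >= 0, flip_prob <= 1,
            to_indist_prob >= 0, to_indist_prob <= 1)
  structure(list(jitter_sigma_um = jitter_sigma_um, miss_prob = miss_prob,
                 flip_prob = flip_prob, to_indist_prob = to_indist_prob,
                 seed = as.integer(seed)),
            class = "annotator_noise")
}

#' Simulate a noisy annotator
#'
#' @param truth Ground-truth annotation `data.frame`.
#' @param noise An [annotator_noise()].
#' @return A new annotation `data.frame` (order randomized).
#' @export
simulate_annotator <- function(truth, noise) {
  stopifnot(inherits(noise, "annotator_noise"))
  withr::with_seed(noise$seed, {
    n <- nrow(truth)
    if (n == 0) return(annotation_set())
    keep <- stats::runif(n) >= noise$miss_prob
    out <- truth[keep, , drop = FALSE]
    m <- nrow(out)
    if (m == 0) return(annotation_set())
    out$x_um <- out$x_um + stats::rnorm(m, 0, noise$jitter_sigma_um)
    out$y_um <- out$y_um + stats::rnorm(m, 0, noise$jitter_sigma_um)
    u <- stats::runif(m)
    to_i <- u < noise$to_indist_prob
    flip <- !to_i & u < noise$to_indist_prob + noise$flip_prob
    out$label[to_i] <- "i"
    out$label[flip & out$label == "t"] <- "N"   # temp to avoid double swap
    out$label[flip & out$label == "n"] <- "t"
    out$label[out$label == "N"] <- "n"
    out <- out[sample.int(m), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate pathologists' visual TCR estimates
#'
#' Emulates a panel of evaluators giving coarse visual estimates of the
#' gold-standard TCR: each evaluator has a global bias, a per-site bias
#' (visual estimation is site-dependent), and per-ROI noise; estimates
#' are rounded to 5% increments and clamped to \[0, 100\].
#'
#' @param tcr_gs Numeric vector of gold-standard TCRs (percent).
#' @param site Character/factor vector of site ids, same length.
#' @param n_evaluators Number of simulated evaluators.
#' @param evaluator_bias_sd,site_bias_sd,estimate_sd Noise SDs in
#'   percentage points.
#' @param seed Integer seed.
#' @return A matrix (length(tcr_gs) x n_evaluators) of estimates.
#' @export
simulate_visual_estimates <- function(tcr_gs, site,
                                      n_evaluators = 13,
                                      evaluator_bias_sd = 6,
                                      site_bias_sd = 6,
                                      estimate_sd = 11,
                                      seed = 1) {
  stopifnot(length(site) == length(tcr_gs))
  withr::with_seed(seed, {
    sites <- unique(as.character(site))
    bias_e <- stats::rnorm(n_evaluators, 0, evaluator_bias_sd)
    bias_es <- matrix(stats::rnorm(n_evaluators * length(sites), 0,
                                   site_bias_sd),
                      length(sites), n_evaluators,
                      dimnames = list(sites, NULL))
    est <- sapply(seq_len(n_evaluators), function(j) {
      raw <- tcr_gs + bias_e[j] + bias_es[as.character(site), j] +
        stats::rnorm(length(tcr_gs), 0, estimate_sd)
      pmin(100, pmax(0, 5 * round(raw / 5)))
    })
    est <- matrix(est, nrow = length(tcr_gs))
    colnames(est) <- sprintf("P%02d", seq_len(n_evaluators))
    est
  })
}
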