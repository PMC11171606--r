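# Cohort-level statistics: mean absolute errors of visual estimates and
# AI predictions against the gold-standard TCR, the site dependency
# index, a Wilcoxon signed-rank comparison of paired per-ROI errors, and
# Kendall's tau correlation of the error profiles.

#' Assemble cohort TCR records
#'
#' The long record format used by the cohort statistics: one row per
#' (ROI, evaluator) visual estimate, with the ROI's site, gold-standard
#' TCR and (repeated) AI TCR. `tcr_ai` and `estimate` may be NA.
#'
#' @param roi_id,site_id Character vectors.
#' @param tcr_gs,tcr_ai Percentages in \[0,100\].
#' @param evaluator Evaluator id for the visual estimate.
#' @param estimate Visual estimate (percent, 5% increments).
#' @export
tcr_records <- function(roi_id, site_id, tcr_gs, tcr_ai = NA_real_,
                        evaluator = NA_character_,
                        estimate = NA_real_) {
  df <- data.frame(roi_id = as.character(roi_id),
                   site_id = as.character(site_id),
                   tcr_gs = tcr_gs, tcr_ai = tcr_ai,
                   evaluator = as.character(evaluator),
                   estimate = estimate, stringsAsFactors = FALSE)
  rng <- range(c(df$tcr_gs, df$tcr_ai, df$estimate), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100)
    stop("TCR values must lie in [0, 100]")
  df
}

roi_table <- function(records) {
  u <- !duplicated(records$roi_id)
  records[u, c("roi_id", "site_id", "tcr_gs", "tcr_ai")]
}

#' Mean absolute error of visual estimates
#'
#' Per ROI, the mean over available evaluators of
#' `|estimate - TCR_GS|`; the overall MAE is the mean over ROIs. ROIs
#' without any estimate are excluded with a warning. With
#' `per_roi_sum = TRUE` the per-ROI errors are summed over evaluators
#' instead of averaged (the literal unnormalized form).
#'
#' @param records Long records from [tcr_records()].
#' @param per_roi_sum Use the unnormalized per-ROI sum.
#' @return List with `overall` and `per_roi` (data.frame `roi_id`,
#'   `site_id`, `error`, `n_evaluators`).
#' @export
mae_visual <- function(records, per_roi_sum = FALSE) {
  has_est <- !is.na(records$estimate)
  ids <- unique(records$roi_id)
  per <- lapply(ids, function(id) {
    rows <- records[records$roi_id == id & has_est, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    err <- abs(rows$estimate - rows$tcr_gs)
    data.frame(roi_id = id, site_id = rows$site_id[1],
               error = if (per_roi_sum) sum(err) else mean(err),
               n_evaluators = nrow(rows), stringsAsFactors = FALSE)
  })
  drop <- vapply(per, is.null, TRUE)
  if (any(drop))
    warning(sum(drop), " ROI(s) without visual estimates excluded")
  per <- do.call(rbind, per[!drop])
  if (is.null(per)) stop("no ROI with visual estimates")
  list(overall = mean(per$error), per_roi = per)
}

#' Mean absolute error of the AI prediction
#'
#' Mean over ROIs of `|TCR_AI - TCR_GS|`.
#'
#' @param records Long records from [tcr_records()] (one AI value per
#'   ROI; rows are deduplicated by `roi_id`).
#' @return List with `overall` and `per_roi` (data.frame `roi_id`,
#'   `site_id`, `error`).
#' @export
mae_ai <- function(records) {
  rt <- roi_table(records)
  rt <- rt[!is.na(rt$tcr_ai), , drop = FALSE]
  if (nrow(rt) == 0) stop("no ROI with an AI TCR")
  per <- data.frame(roi_id = rt$roi_id, site_id = rt$site_id,
                    error = abs(rt$tcr_ai - rt$tcr_gs),
                    stringsAsFactors = FALSE)
  list(overall = mean(per$error), per_roi = per)
}

#' Site dependency index
#'
#' The difference between an evaluator's largest and smallest per-site
#' mean absolute error; missing sites are ignored. Lower means more
#' robust across institutions.
#'
#' @param per_site_errors Named numeric vector of per-site MAEs.
#' @return max - min over available sites.
#' @export
sdi <- function(per_site_errors) {
  v <- per_site_errors[!is.na(per_site_errors)]
  if (length(v) < 2)
    stop("SDI needs MAEs from at least 2 sites")
  max(v) - min(v)
}

#' Wilcoxon signed-rank test for paired errors
#'
#' Two-sided signed-rank test on paired differences `x - y`. Zero
#' differences are handled by Pratt's method (zeros participate in the
#' ranking, then drop from the statistic). The exact distribution is
#' used when there are no zeros and no ties and n <= 25; otherwise a
#' normal approximation with tie/zero corrections and continuity
#' correction.
#'
#' @param x,y Paired numeric vectors (equal length).
#' @return List with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n` (non-zero pairs) and `method`.
#' @export
paired_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n_all <- length(d)
  zeros <- d == 0
  if (all(zeros))
    return(list(statistic = 0, p.value = 1, n = 0L,
                method = "all differences zero"))
  r <- rank(abs(d))               # Pratt: zeros keep their ranks
  V <- sum(r[d > 0])
  nz <- sum(!zeros)
  if (nz <= 25) {
    # exact conditional distribution of V given the observed (possibly
    # tied) ranks: convolve the +rank/0 generating functions over the
    # non-zero ranks; ranks doubled so average ranks become integers
    r2 <- round(2 * r[!zeros])
    probs <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), probs)
      length(probs) <- length(shifted)
      probs[is.na(probs)] <- 0
      probs <- (probs + shifted) / 2
    }
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):length(probs)])
    p <- 2 * min(p_le, p_ge)
    return(list(statistic = V, p.value = min(1, p), n = nz,
                method = "exact signed rank (Pratt zeros)"))
  }
  n <- n_all
  z0 <- sum(zeros)
  mu <- n * (n + 1) / 4 - z0 * (z0 + 1) / 4
  tie_tab <- table(r[!zeros])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    z0 * (z0 + 1) * (2 * z0 + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  list(statistic = V, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       n = nz, method = "normal approximation (Pratt zeros)")
}

#' Kendall's tau correlation of paired error profiles
#'
#' Tau-b with tie correction and a two-sided p-value, via
#' [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors (length >= 3).
#' @return List with `tau` and `p.value`.
#' @export
error_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p.value = ct$p.value)
}

#' Per-site error table, SDI column and pathologist summaries
#'
#' Builds the evaluator x site MAE grid (the AI is one more evaluator
#' column named `"AI"`), the per-evaluator SDI, and the per-site
#' mean +/- SD of the pathologists' MAEs (sample SD; the AI column is
#' excluded from the summaries). Evaluators observed at fewer than two
#' sites get an NA SDI with a warning.
#'
#' @param records Long records from [tcr_records()].
#' @return List with `grid` (matrix site x evaluator), `sdi` (named
#'   vector per evaluator), `site_mean`, `site_sd` (named vectors per
#'   site, pathologists only).
#' @export
site_report <- function(records) {
  sites <- unique(records$site_id)
  evals <- unique(records$evaluator[!is.na(records$estimate)])
  grid <- matrix(NA_real_, length(sites), length(evals) + 1,
                 dimnames = list(sites, c(evals, "AI")))
  for (s in sites) {
    for (e in evals) {
      rows <- records$site_id == s & records$evaluator == e &
        !is.na(records$estimate)
      if (any(rows))
        grid[s, e] <- mean(abs(records$estimate[rows] -
                                 records$tcr_gs[rows]))
    }
    rt <- roi_table(records)
    rs <- rt$site_id == s & !is.na(rt$tcr_ai)
    if (any(rs))
      grid[s, "AI"] <- mean(abs(rt$tcr_ai[rs] - rt$tcr_gs[rs]))
  }
  sdis <- apply(grid, 2, function(col) {
    if (sum(!is.na(col)) < 2) return(NA_real_)
    sdi(col)
  })
  if (any(is.na(sdis)))
    warning("evaluator(s) with fewer than 2 sites: SDI undefined for ",
            paste(names(sdis)[is.na(sdis)], collapse = ", "))
  path_grid <- grid[, colnames(grid) != "AI", drop = FALSE]
  list(grid = grid, sdi = sdis,
       site_mean = apply(path_grid, 1, mean, na.rm = TRUE),
       site_sd = apply(path_grid, 1, stats::sd, na.rm = TRUE))
}
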