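test_that("visual MAE averages over evaluators then ROIs", {
  rec <- tcr_records(rep("r1", 2), rep("A", 2), tcr_gs = 65,
                     evaluator = c("P01", "P02"), estimate = c(60, 70))
  expect_equal(mae_visual(rec)$overall, 5.0)
  # all estimates equal the gold standard
  rec0 <- tcr_records(c("r1", "r2"), c("A", "B"), c(40, 80),
                      evaluator = "P01", estimate = c(40, 80))
  expect_equal(mae_visual(rec0)$overall, 0.0)
  # the literal unnormalized per-ROI sum is available behind the flag
  expect_equal(mae_visual(rec, per_roi_sum = TRUE)$overall, 10.0)
  # ROIs without estimates are excluded with a warning
  rec2 <- rbind(rec, tcr_records("r2", "A", 50))
  expect_warning(out <- mae_visual(rec2), "excluded")
  expect_equal(out$overall, 5.0)
})

test_that("a constant estimator bias shows up as the visual MAE and
           vanishes as noise goes to zero", {
  set.seed(33)
  gs <- runif(60, 20, 80)
  for (b in c(8, 0)) {
    est <- pmin(100, pmax(0, gs + b))
    rec <- tcr_records(sprintf("r%02d", 1:60), "A", gs,
                       evaluator = "P01", estimate = est)
    expect_equal(mae_visual(rec)$overall, b, tolerance = 1e-9)
  }
})

test_that("AI MAE reproduces the published single-ROI spot checks", {
  expect_equal(mae_ai(tcr_records("r1", "A", tcr_gs = 82.5,
                                  tcr_ai = 84.6))$overall,
               2.1, tolerance = 1e-9)
  expect_equal(mae_ai(tcr_records("r1", "A", tcr_gs = 66.3,
                                  tcr_ai = 33.0))$overall,
               33.3, tolerance = 1e-9)
  expect_equal(mae_ai(tcr_records("r1", "A", tcr_gs = 50,
                                  tcr_ai = 50))$overall, 0)
  expect_error(mae_ai(tcr_records("r1", "A", 50)), "no ROI")
})

test_that("the site dependency index is max minus min and is
           shift-invariant", {
  e01 <- c(A = 18.2, B = 13.6, C = 9.2, D = 10.2)
  expect_equal(sdi(e01), 9.0)
  ai <- c(A = 8.9, B = 10.6, C = 8.9, D = 15.2)
  expect_equal(sdi(ai), 6.3)
  expect_equal(sdi(e01 + 7), sdi(e01))
  expect_lte(sdi(e01), max(e01))
  expect_error(sdi(c(A = 5)), "at least 2")
  # missing sites are ignored
  expect_equal(sdi(c(A = 10, B = NA, C = 4)), 6)
})

test_that("the signed-rank test matches exact enumeration for small n
           and handles zeros by Pratt's method", {
  # identical arrays: all differences zero
  expect_equal(paired_signed_rank(1:8, 1:8)$p.value, 1.0)
  # shifted pair without ties in |d|: compare with the classic exact
  # distribution
  x <- c(5, 3, 8, 1, 9, 2, 11, 4, 6, 10)
  y <- x - c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) / 100
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(paired_signed_rank(x, y)$p.value, ref$p.value)
  # enumeration oracle (2^n sign assignments) incl. ties and zeros
  enum_p <- function(d) {
    r <- rank(abs(d))
    nzi <- which(d != 0)
    V <- sum(r[d > 0])
    n <- length(nzi)
    Vs <- vapply(0:(2^n - 1), function(m) {
      s <- as.integer(intToBits(m))[seq_len(n)]
      sum(r[nzi][s == 1])
    }, 0)
    min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  }
  set.seed(17)
  for (rep in 1:6) {
    d <- sample(-4:4, 9, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    expect_equal(paired_signed_rank(d, rep(0, 9))$p.value, enum_p(d),
                 label = paste(d, collapse = ","))
  }
  # (1..10) vs (2..11): constant difference of -1, fully tied
  expect_equal(paired_signed_rank(1:10, 2:11)$p.value,
               enum_p(rep(-1, 10)))
})

test_that("a cohort where one error profile stochastically dominates is
           detected by the signed-rank test", {
  # error magnitudes mirror the synthetic generator's conditions:
  # AI errors of a few points, visual errors in the low teens
  set.seed(29)
  rejections <- vapply(1:40, function(i) {
    ai <- abs(rnorm(41, 0, 3))
    pv <- abs(rnorm(41, 0, 14))
    paired_signed_rank(ai, pv)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})

test_that("Kendall correlation matches the brute-force pair count and
           permutation p-value", {
  expect_equal(error_correlation(1:6, 2 * (1:6))$tau, 1.0)
  expect_equal(error_correlation(1:6, rev(1:6))$tau, -1.0)
  set.seed(19)
  x <- c(3.2, 1.5, 4.8, 2.2, 5.9)
  y <- c(2.1, 0.7, 3.3, 4.0, 5.2)
  res <- error_correlation(x, y)
  # brute-force concordant/discordant count
  cd <- 0
  for (i in 1:4) for (j in (i + 1):5)
    cd <- cd + sign(x[i] - x[j]) * sign(y[i] - y[j])
  expect_equal(res$tau, cd / choose(5, 2))
  # permutation distribution over all 5! orderings
  taus <- apply(all_perms(5), 1, function(p) {
    s <- 0
    for (i in 1:4) for (j in (i + 1):5)
      s <- s + sign(x[i] - x[j]) * sign(y[p[i]] - y[p[j]])
    s / choose(5, 2)
  })
  expect_equal(res$p.value, mean(abs(taus) >= abs(res$tau) - 1e-12))
})

test_that("the site report reproduces the published grid summaries", {
  grid <- published_site_mae()
  sdis <- apply(grid, 2, function(col) sdi(col))
  expect_equal(unname(sdis["E01"]), 9.0)
  expect_equal(unname(sdis["AI"]), 6.3)
  path_sdis <- sdis[names(sdis) != "AI"]
  expect_equal(round(mean(path_sdis), 1), 9.5)
  expect_equal(round(mean(grid["A", colnames(grid) != "AI"]), 1), 18.5)
  expect_equal(round(sd(grid["A", colnames(grid) != "AI"]), 1), 4.0)
})

test_that("site_report builds the evaluator-by-site grid from long
           records and flags single-site evaluators", {
  rec <- rbind(
    tcr_records(c("r1", "r2"), c("A", "B"), c(50, 70), c(55, 70),
                evaluator = "P01", estimate = c(60, 75)),
    tcr_records(c("r1", "r2"), c("A", "B"), c(50, 70), c(55, 70),
                evaluator = "P02", estimate = c(40, 80)))
  rep <- site_report(rec)
  expect_equal(rep$grid["A", "P01"], 10)
  expect_equal(rep$grid["B", "P02"], 10)
  expect_equal(rep$grid["A", "AI"], 5)
  expect_equal(unname(rep$sdi["P01"]), 5)
  expect_equal(unname(rep$site_mean["A"]), 10)
  # one evaluator seen at a single site only
  rec2 <- rbind(rec,
                tcr_records("r1", "A", 50, 55, evaluator = "P03",
                            estimate = 45))
  expect_warning(rep2 <- site_report(rec2), "SDI undefined")
  expect_true(is.na(rep2$sdi["P03"]))
})
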