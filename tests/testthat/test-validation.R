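make_sample <- function(n_neg = 70, n_pos = 30, fpr = 0, fnr = 0, seed = 1) {
  set.seed(seed)
  n <- n_neg + n_pos
  truth <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                      pdl1_intensity = rep(c(0L, 1L), c(n_neg, n_pos)))
  pred_bin <- truth$pdl1_intensity
  neg <- which(truth$pdl1_intensity == 0)
  pos <- which(truth$pdl1_intensity == 1)
  flipn <- head(neg, round(fpr * length(neg)))
  flipp <- head(pos, round(fnr * length(pos)))
  pred_bin[flipn] <- 1; pred_bin[flipp] <- 0
  pred <- data.frame(x = truth$x, y = truth$y, pdl1_bin = pred_bin)
  list(pred = pred, truth = truth)
}

test_that("cell-level metrics follow their definitions exactly", {
  perfect <- make_sample(70, 30, seed = 2)
  m <- cell_level_metrics(list(perfect))
  expect_equal(m$per_sample$identification_rate, 1)
  expect_equal(m$per_sample$false_positive_rate, 0)
  expect_equal(m$per_sample$false_negative_rate, 0)
  expect_equal(m$cohort_pass_fraction, 1)

  ## 15% of true negatives called positive -> FPR 0.15, sample fails
  s <- make_sample(100, 30, fpr = 0.15, seed = 3)
  m2 <- cell_level_metrics(list(s))
  expect_equal(m2$per_sample$false_positive_rate, 0.15)
  expect_equal(m2$fpr_pass_fraction, 0)
  expect_equal(m2$cohort_pass_fraction, 0)

  ## zero-cell samples are dropped with a warning
  empty <- list(pred = s$pred[0, ], truth = s$truth[0, ])
  expect_warning(m3 <- cell_level_metrics(list(perfect, empty)),
                 "zero true cells")
  expect_equal(nrow(m3$per_sample), 1)
})

test_that("accuracy concordance counts same-side-of-cutoff samples", {
  expect_equal(accuracy_concordance(c(0, 5, 60), c(0, 5, 60))$bin_concordance_fraction, 1)
  a <- accuracy_concordance(c(0.5, 10), c(1.5, 10))
  expect_equal(a$bin_concordance_fraction, 0.5)  # 0.5 vs 1.5 straddles 1%
  expect_false(a$pass)
  expect_error(accuracy_concordance(1:3, 1:2), "length")
})

test_that("ICC handles zero-variance and boundary tables by the formula", {
  ## identical repeats, varying samples: all variance is inter-sample
  tab <- matrix(rep(c(10, 40, 70, 90), 3), ncol = 3)
  r <- icc_precision(tab)
  expect_equal(r$icc, 1)
  expect_equal(unname(r$proportions["repeat"] + r$proportions["residual"]), 0)
  expect_equal(r$reliability, "excellent")
  expect_false(r$degenerate)

  ## fully constant table is degenerate, ICC 1 by convention
  rd <- icc_precision(matrix(5, 4, 3))
  expect_true(rd$degenerate)
  expect_equal(rd$icc, 1)

  ## constructed two-component table: repeat+residual = 40% of variance
  ## simulated at large n so the method-of-moments recovers the ratio
  set.seed(9)
  n <- 2000; k <- 3
  tabb <- outer(rnorm(n, 0, sqrt(60)), rep(1, k)) +
    matrix(rnorm(n * k, 0, sqrt(40)), n, k)
  rb <- icc_precision(tabb)
  expect_equal(rb$icc, 0.6, tolerance = 0.03)
  expect_error(icc_precision(matrix(1, 1, 3)), ">= 2")
})

test_that("ICC recovers generating variance ratios (analytic oracle)", {
  ## generating components 90/5/5 -> ICC 0.90; with only k = 3 repeat
  ## levels any single table realizes a noisy repeat component, so the
  ## estimator is checked on its mean over replicate tables
  set.seed(21)
  res <- replicate(40, {
    n <- 500; k <- 3
    tab <- outer(rnorm(n, 0, sqrt(90)), rep(1, k)) +
      outer(rep(1, n), rnorm(k, 0, sqrt(5))) +
      matrix(rnorm(n * k, 0, sqrt(5)), n, k)
    r <- icc_precision(tab)
    c(icc = r$icc, sum = sum(r$proportions),
      resid = unname(r$proportions["residual"]))
  })
  expect_lt(abs(mean(res["icc", ]) - 0.90), 0.02)
  expect_equal(unname(res["sum", ]), rep(1, 40), tolerance = 1e-9)
  expect_lt(abs(mean(res["resid", ]) - 0.05), 0.01)
})

test_that("ICC variance decomposition agrees with a REML mixed-model fit", {
  skip_if_not_installed("lme4")
  set.seed(33)
  n <- 120; k <- 3
  tab <- outer(rnorm(n, 0, sqrt(80)), rep(1, k)) +
    outer(rep(1, n), rnorm(k, 0, sqrt(6))) +
    matrix(rnorm(n * k, 0, sqrt(10)), n, k)
  ours <- icc_precision(tab)
  long <- data.frame(y = as.numeric(tab), s = factor(rep(1:n, k)),
                     r = factor(rep(1:k, each = n)))
  fit <- lme4::lmer(y ~ (1 | s) + (1 | r), data = long)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vtot <- sum(vc$vcov)
  icc_reml <- vc$vcov[vc$grp == "s"] / vtot
  expect_equal(ours$icc, icc_reml, tolerance = 0.03)
})

test_that("simulation CI is deterministic, sane, and (1,1) when exact", {
  tab <- matrix(rep(c(10, 40, 70, 90), 3), ncol = 3) # zero repeat/residual
  r <- icc_precision(tab, n_sim = 50, seed = 4)
  expect_equal(r$ci95, c(1, 1))
  expect_true(r$pass)

  set.seed(77)
  tab2 <- outer(rnorm(30, 0, 9), rep(1, 3)) + matrix(rnorm(90, 0, 3), 30, 3)
  a <- icc_precision(tab2, n_sim = 300, seed = 5)
  b <- icc_precision(tab2, n_sim = 300, seed = 5)
  expect_identical(a$ci95, b$ci95)
  expect_true(a$ci95[1] <= a$icc && a$icc <= a$ci95[2])
  expect_equal(a$n_simulations, 300L)
})

test_that("simulation CI covers the generating ICC (coverage study)", {
  ## generating components 80/6/10 -> ICC 0.833; check percentile CI covers
  ## it in most meta-replicates at a small design
  set.seed(55)
  icc_gen <- 80 / 96
  hits <- vapply(1:25, function(b) {
    tab <- outer(rnorm(40, 0, sqrt(80)), rep(1, 3)) +
      outer(rep(1, 40), rnorm(3, 0, sqrt(6))) +
      matrix(rnorm(120, 0, sqrt(10)), 40, 3)
    r <- icc_precision(tab, n_sim = 120, seed = b)
    r$ci95[1] <= icc_gen && icc_gen <= r$ci95[2]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Bonferroni-corrected Pearson concordance reports and decides", {
  x <- seq(0, 100, length.out = 20)
  res <- pearson_concordance(list(d_vs_m = list(x = x, y = x)),
                             n_comparisons = 3)
  expect_equal(res$alpha_reported, 0.017)
  expect_equal(res$alpha_corrected, 0.05 / 3)
  expect_equal(res$pairs$pearson_r, 1.0)
  expect_true(res$pairs$significant)
  expect_error(pearson_concordance(list(p = list(x = 1:2, y = 1:2))), ">= 3")
})

test_that("null concordance rarely reaches Bonferroni significance", {
  set.seed(66)
  sig <- vapply(1:40, function(i) {
    res <- pearson_concordance(list(p = list(x = rnorm(100), y = rnorm(100))),
                               n_comparisons = 3)
    res$pairs$significant
  }, logical(1))
  expect_lte(mean(sig), 0.05)
})

test_that("average percent error is exact signed arithmetic", {
  expect_equal(average_percent_error(197, 200), -1.5)
  expect_equal(average_percent_error(c(10, 20), c(10, 20)), 0)
  expect_warning(ape <- average_percent_error(c(10, 5), c(10, 0)),
                 "zero truth")
  expect_equal(ape, 0)
  expect_error(average_percent_error(c(1, 2), c(0, 0)), "all-zero|all truth")
})

test_that("validation report assembles rows, fails on bad metrics, round-trips", {
  perfect <- make_sample(70, 30, seed = 2)
  cm <- cell_level_metrics(list(perfect))
  acc <- accuracy_concordance(c(0, 5, 60), c(0, 6, 55))
  prec <- icc_precision(matrix(rep(c(10, 40, 70, 90), 3), ncol = 3),
                        n_sim = 50, seed = 1)
  rep <- validation_report(cm, acc, prec)
  expect_equal(nrow(rep$rows), 4)
  expect_true(all(rep$rows$pass))
  expect_length(rep$missing_inputs, 0)

  ## forced FPR 0.2 fails the specificity row
  bad <- make_sample(100, 30, fpr = 0.2, seed = 3)
  repb <- validation_report(cell_level_metrics(list(bad)), acc, prec)
  expect_false(repb$rows$pass[repb$rows$parameter == "Analytical Specificity"])

  ## partial report lists missing inputs
  repp <- validation_report(accuracy = acc)
  expect_setequal(repp$missing_inputs, c("cell_metrics", "precision"))
  expect_equal(nrow(repp$rows), 1)

  path <- file.path(tempdir(), "report.json")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  expect_equal(back$rows$pass, rep$rows$pass)
  expect_equal(back$rows$observed, rep$rows$observed, tolerance = 1e-12)
})

test_that("both ICC formula readings are reported and ordered", {
  set.seed(14)
  tab <- outer(rnorm(50, 0, 8), rep(1, 3)) + outer(rep(1, 50), c(-2, 0, 2)) +
    matrix(rnorm(150, 0, 3), 50, 3)
  a <- icc_precision(tab)
  expect_equal(a$icc, a$icc_printed)
  ## dropping only the repeat share can never give a smaller value
  expect_gte(a$icc_prose, a$icc_printed)
  b <- icc_precision(tab, variant = "prose")
  expect_equal(b$icc, b$icc_prose)
  expect_equal(b$icc_printed, a$icc_printed)
})
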