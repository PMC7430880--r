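# contrasting-groups standard setting: intersection cutoff, error rates,
# model methods, three-group report

test_that("equal-sigma cutoff is the exact midpoint; order and scale are enforced", {
  expect_equal(as.numeric(intersect_cutoff(group_gaussian(40, 10),
                                           group_gaussian(60, 10))), 50)
  expect_error(intersect_cutoff(group_gaussian(60, 10), group_gaussian(40, 10)),
               "expected order")
  expect_error(group_gaussian(50, 0), "sigma")
})

test_that("unequal-sigma cutoff matches the grid-search FP+FN minimizer", {
  # worked pair: minimizer near 68.5
  c1 <- as.numeric(intersect_cutoff(group_gaussian(55, 12), group_gaussian(80, 8)))
  expect_equal(c1, grid_cutoff(55, 12, 80, 8), tolerance = 1e-3)
  expect_equal(c1, 68.48, tolerance = 0.01)

  set.seed(11)
  for (i in 1:60) {
    mu_lo <- runif(1, 10, 60); mu_hi <- mu_lo + runif(1, 3, 40)
    s_lo <- runif(1, 2, 15); s_hi <- runif(1, 2, 15)
    cut <- as.numeric(intersect_cutoff(group_gaussian(mu_lo, s_lo),
                                       group_gaussian(mu_hi, s_hi)))
    expect_lt(abs(cut - grid_cutoff(mu_lo, s_lo, mu_hi, s_hi)), 1e-3)
    expect_gt(cut, mu_lo); expect_lt(cut, mu_hi)
  }
})

test_that("theoretical rates are normal tails with the stated pass rule", {
  lo <- group_gaussian(40, 10); hi <- group_gaussian(70, 8)
  r <- theoretical_rates(50, lo, hi)
  expect_equal(r[["fp"]], 1 - pnorm(1))       # P(lo >= 50)
  expect_equal(theoretical_rates(hi$mu, lo, hi)[["fn"]], 0.5)
  # the intersection minimizes total error locally
  cut <- as.numeric(intersect_cutoff(lo, hi))
  tot <- function(c) sum(theoretical_rates(c, lo, hi))
  expect_lte(tot(cut), tot(cut + 0.5))
  expect_lte(tot(cut), tot(cut - 0.5))
  # monotonicity: fp decreasing, fn increasing in the cutoff
  cs <- seq(20, 90, by = 5)
  fps <- vapply(cs, function(c) theoretical_rates(c, lo, hi)[["fp"]], numeric(1))
  fns <- vapply(cs, function(c) theoretical_rates(c, lo, hi)[["fn"]], numeric(1))
  expect_true(all(diff(fps) < 0))
  expect_true(all(diff(fns) > 0))
})

test_that("absolute rates are empirical fractions consistent with theory", {
  expect_equal(absolute_rates(50, c(10, 20), c(60, 70)), c(fp = 0, fn = 0))
  expect_equal(absolute_rates(70, c(60, 80), c(75, 85))[["fp"]], 0.5)
  expect_error(absolute_rates(50, numeric(0), 1), "nonempty")
  set.seed(12)
  lo <- group_gaussian(45, 9); hi <- group_gaussian(72, 7)
  cut <- as.numeric(intersect_cutoff(lo, hi))
  ab <- absolute_rates(cut, rnorm(1e5, lo$mu, lo$sigma),
                       rnorm(1e5, hi$mu, hi$sigma))
  th <- theoretical_rates(cut, lo, hi)
  expect_lt(abs(ab[["fp"]] - th[["fp"]]), 0.01)
  expect_lt(abs(ab[["fn"]] - th[["fn"]]), 0.01)
})

test_that("contrast_groups fits Gaussians by sample mean/sd and classifies", {
  set.seed(13)
  scores <- c(rnorm(30, 30, 5), rnorm(15, 80, 5))
  groups <- rep(c("novice", "robotic"), c(30, 15))
  fit <- contrast_groups(scores, groups, lo = "novice", hi = "robotic")
  expect_s3_class(fit, "contrast_cutoff")
  expect_equal(fit$lo$mu, mean(scores[1:30]))
  expect_equal(fit$hi$sigma, sd(scores[31:45]))
  expect_equal(fit$cutoff, 55, tolerance = 3)
  expect_lt(fit$fp_theoretical + fit$fn_theoretical +
              fit$fp_absolute + fit$fn_absolute, 0.04)
  # overlapping groups: total theoretical error approaches 1
  set.seed(14)
  s2 <- rnorm(60, 50, 10)
  g2 <- rep(c("novice", "robotic"), 30)
  f2 <- contrast_groups(s2, g2)  # sample means happen to be ordered
  expect_gt(f2$fp_theoretical + f2$fn_theoretical, 0.85)

  # formula interface and methods
  df <- data.frame(score = scores, group = groups)
  ff <- contrast_groups(score ~ group, data = df)
  expect_equal(ff$cutoff, fit$cutoff)
  expect_named(coef(fit), c("cutoff", "fp_theoretical", "fn_theoretical",
                            "fp_absolute", "fn_absolute"))
  expect_equal(as.character(predict(fit, c(fit$cutoff - 1, fit$cutoff))),
               c("fail", "pass"))  # boundary passes
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(nrow(sim), 100)
  expect_output(print(summary(fit)), "Cutoff")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("cutoff is affine-equivariant and rates are invariant", {
  set.seed(15)
  scores <- c(rnorm(25, 40, 8), rnorm(12, 70, 12))
  groups <- rep(c("novice", "robotic"), c(25, 12))
  f <- contrast_groups(scores, groups)
  g <- contrast_groups(scores * 2.5 + 7, groups)
  expect_equal(g$cutoff, f$cutoff * 2.5 + 7, tolerance = 1e-8)
  expect_equal(coef(g)[-1], coef(f)[-1], tolerance = 1e-8)
})

test_that("three_group_report flags unordered pairs instead of aborting", {
  set.seed(16)
  tbl <- data.frame(
    participant_id = sprintf("p%02d", 1:60),
    group = rep(c("novice", "laparoscopic", "robotic"), each = 20),
    total_time = c(rnorm(20, 60, 6), rnorm(20, 40, 6), rnorm(20, 20, 6)))
  co <- wide_cohort(tbl)
  cs <- composite_scores(co, "task1", "total_time")
  rep3 <- three_group_report(cs)
  expect_named(rep3, c("novice_vs_robotic", "laparoscopic_vs_robotic",
                       "novice_vs_laparoscopic"))
  expect_true(all(vapply(rep3, inherits, logical(1), "contrast_cutoff")))
  # cutoffs increase with the lower group's mean
  expect_lt(rep3$novice_vs_robotic$cutoff, rep3$laparoscopic_vs_robotic$cutoff)

  # laparoscopic mean above robotic: that pair flagged, others returned
  tbl2 <- tbl
  tbl2$total_time[21:40] <- rnorm(20, 10, 4)  # laparoscopic fastest
  cs2 <- composite_scores(wide_cohort(tbl2), "task1", "total_time")
  rep2 <- three_group_report(cs2)
  expect_s3_class(rep2$novice_vs_robotic, "contrast_cutoff")
  expect_s3_class(rep2$laparoscopic_vs_robotic, "skipped_cutoff")

  # all groups identical: every pair flagged
  tbl3 <- tbl; tbl3$total_time <- rep(c(30, 31, 32, 33, 34), 12)
  cs3 <- composite_scores(wide_cohort(tbl3), "task1", "total_time")
  rep3i <- three_group_report(cs3)
  expect_true(all(vapply(rep3i, inherits, logical(1), "skipped_cutoff")))
})
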