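# summary-statistic t-tests, Levene gate, normality check, construct and
# content screening, parameter selection

test_that("summary t-tests match record-level t.test on moment-matched data", {
  expect_equal(student_t_summary(5, 1, 10, 5, 1, 12)$t, 0)
  expect_equal(student_t_summary(5, 1, 10, 5, 1, 12)$p, 1)
  expect_equal(welch_t_summary(5, 1, 10, 5, 1, 12)$p, 1)
  expect_error(student_t_summary(1, 0, 10, 2, 0, 12), "degenerate")
  expect_error(welch_t_summary(5, 1, 1, 5, 1, 12), "n >= 2")

  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.2, 4); s2 <- runif(1, 0.2, 4)
    x <- moment_match(n1, m1, s1); y <- moment_match(n2, m2, s2)
    st <- student_t_summary(m1, s1, n1, m2, s2, n2)
    we <- welch_t_summary(m1, s1, n1, m2, s2, n2)
    rt <- t.test(x, y, var.equal = TRUE)
    rw <- t.test(x, y)
    expect_equal(st$t, unname(rt$statistic), tolerance = 1e-10)
    expect_equal(st$p, rt$p.value, tolerance = 1e-10)
    expect_equal(we$t, unname(rw$statistic), tolerance = 1e-10)
    expect_equal(we$df, unname(rw$parameter), tolerance = 1e-10)
    expect_equal(we$p, rw$p.value, tolerance = 1e-10)
  }
})

test_that("mean-centered Levene test matches independent computations", {
  x <- c(1, 2, 3, 4); y <- c(10, 20, 30, 40)
  lev <- levene_test(x, y)
  # direct formula evaluation
  z1 <- abs(x - mean(x)); z2 <- abs(y - mean(y))
  zb <- mean(c(z1, z2))
  f_direct <- (6 / 1) * (4 * (mean(z1) - zb)^2 + 4 * (mean(z2) - zb)^2) /
    (sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2))
  expect_equal(lev$statistic, f_direct, tolerance = 1e-12)
  expect_equal(lev$p, pf(f_direct, 1, 6, lower.tail = FALSE), tolerance = 1e-12)

  expect_equal(levene_test(x, x)$statistic, 0)
  expect_equal(levene_test(x, x)$p, 1)
  expect_equal(levene_test(rep(2, 5), rep(7, 4))$statistic, 0)
  expect_error(levene_test(1, y), "n >= 2")

  skip_if_not_installed("car")
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    ours <- levene_test(a, b)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(length(a), length(b)))),
                           center = mean)
    expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("normality check flags skew, passes normal data, rejects tiny n", {
  expect_error(normality_check(c(1, 2)), "n >= 3")
  set.seed(4)
  hits <- mean(replicate(100, normality_check(exp(rnorm(200))) < 0.05))
  expect_gte(hits, 0.95)
  # calibration: under normal data the p-value is uniform
  set.seed(5)
  rate <- mean(replicate(1000, normality_check(rnorm(50)) < 0.05))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("compare_groups gates Student/Welch, reports advantage, errors on empty groups", {
  co <- toy_cohort(list(novice = c(10, 12, 14, 16), laparoscopic = c(9, 11, 13, 15),
                        robotic = c(5, 6, 7, 8)), metric = "total_time")
  res <- compare_groups(co, "task1", "total_time")
  expect_s3_class(res, "construct_result")
  # total_time is lower_better: robotic (lowest mean) has the advantage
  expect_equal(unname(res$advantage["robotic_vs_novice"]), "robotic")
  expect_true(res$tests$robotic_vs_novice$method %in% c("student", "welch"))
  # gated choice agrees with the Levene p attached to the report
  for (cn in names(res$tests)) {
    t <- res$tests[[cn]]
    expect_equal(t$method, if (t$levene_p >= 0.05) "student" else "welch")
    # both forms always computed and logged
    expect_equal(t$student$method, "student")
    expect_equal(t$welch$method, "welch")
  }
  co2 <- toy_cohort(list(novice = c(10, 12), robotic = c(5, 6)))
  expect_error(compare_groups(co2, "task1", "total_time"), "laparoscopic")
})

test_that("summary-based and record-based screens agree on moment-matched records", {
  set.seed(6)
  vals <- list(novice = moment_match(29, 597, 225),
               laparoscopic = moment_match(26, 475, 219),
               robotic = moment_match(15, 265, 92))
  co <- toy_cohort(vals, metric = "total_time")
  rec <- compare_groups(co, "task1", "total_time")
  summ <- data.frame(task = "task1", metric = "total_time",
                     group = names(vals),
                     mean = c(597, 475, 265), sd = c(225, 219, 92),
                     n = c(29, 26, 15))
  sb <- screen_summaries(summ, "task1")[["total_time"]]
  for (cn in c("robotic_vs_novice", "laparoscopic_vs_novice", "robotic_vs_laparoscopic")) {
    expect_equal(rec$tests[[cn]]$welch$t, sb$tests[[cn]]$welch$t, tolerance = 1e-10)
    expect_equal(rec$tests[[cn]]$student$p, sb$tests[[cn]]$student$p, tolerance = 1e-10)
  }
})

test_that("likert_content aggregates domains and applies the strict 3.5 threshold", {
  mk_likert <- function(scores_by_group) do.call(rbind, lapply(
    names(scores_by_group), function(g) {
      s <- scores_by_group[[g]]
      data.frame(participant_id = sprintf("%s_%02d", g, seq_along(s)),
                 group = g, task = "task1", domain = "realism",
                 item = "q1", score = s, stringsAsFactors = FALSE)
    }))
  base <- data.frame(participant_id = "novice_01", group = "novice",
                     task = "task1", metric = "total_time", value = 1)
  co <- cohort_table(base, likert = mk_likert(list(
    novice = c(5L, 5L), laparoscopic = c(5L, 5L), robotic = c(5L, 5L))))
  res <- likert_content(co, "task1")[["realism"]]
  expect_equal(res$total_mean, 5)
  expect_true(res$positive)

  co35 <- cohort_table(base, likert = mk_likert(list(
    novice = c(3L, 4L), laparoscopic = c(3L, 4L), robotic = c(3L, 4L))))
  res35 <- likert_content(co35, "task1")[["realism"]]
  expect_equal(res35$total_mean, 3.5)
  expect_false(res35$positive)  # boundary is not positive
})

test_that("selection rule reproduces the published composite parameter sets", {
  # task 1: eight metrics significant robotic-vs-novice with robotic advantage
  res1 <- screen_summaries(task_fixture("task1"), "task1")
  expect_equal(select_construct_parameters(res1), paper_composites()$task1)

  # task 2: five metrics (needle precision is not significant when recomputed
  # from the rounded summaries)
  res2 <- screen_summaries(task_fixture("task2"), "task2")
  expect_equal(select_construct_parameters(res2), paper_composites()$task2)

  # task 3 (pooled-variance form): the published four; times_out_of_view and
  # distance_scope_tissue stay out (novice advantage / ambiguous direction)
  res3 <- screen_summaries(task_fixture("task3"), "task3", method = "student")
  expect_equal(select_construct_parameters(res3), paper_composites()$task3)
  expect_true(res3$times_out_of_view$significant_rvn)
  expect_equal(unname(res3$times_out_of_view$advantage["robotic_vs_novice"]),
               "novice")

  # overrides: include/exclude adjust the set, unknown names error
  expect_equal(select_construct_parameters(res2, exclude = "total_time"),
               setdiff(paper_composites()$task2, "total_time"))
  expect_true("needle_precision" %in%
                select_construct_parameters(res2, include = "needle_precision"))
  expect_error(select_construct_parameters(res2, exclude = "warp_factor"),
               "unknown metric")
})
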