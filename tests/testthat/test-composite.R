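# min-max normalization, composite aggregation, sensitivity weighting

test_that("normalization bounds, direction and clipping follow the contract", {
  tbl <- data.frame(participant_id = c("n1", "n2", "r1"),
                    group = c("novice", "novice", "robotic"),
                    total_time = c(2, 4, 6), needle_precision = c(10, 30, 50))
  co <- wide_cohort(tbl)
  map <- fit_normalization(co, "task1", c("total_time", "needle_precision"))
  expect_equal(map$min[map$metric == "total_time"], 2)
  expect_equal(map$max[map$metric == "total_time"], 6)

  # higher_better: min -> 0, max -> 100; lower_better reversed
  expect_equal(normalize_value(c(10, 30, 50), "needle_precision", map),
               c(0, 50, 100))
  expect_equal(normalize_value(c(2, 4, 6), "total_time", map), c(100, 50, 0))
  # out-of-range values clip to the bounds
  expect_equal(normalize_value(7, "total_time", map), 0)
  expect_equal(normalize_value(60, "needle_precision", map), 100)
  expect_error(normalize_value(1, "warp_factor", map), "absent")

  tbl$needle_precision <- 30
  expect_error(fit_normalization(wide_cohort(tbl), "task1",
                                 c("total_time", "needle_precision")),
               "ZeroRange.*needle_precision")

  # refit after adding an out-of-range participant moves only that metric
  tbl2 <- data.frame(participant_id = c("n1", "n2", "r1", "x9"),
                     group = c("novice", "novice", "robotic", "robotic"),
                     total_time = c(2, 4, 6, 9), needle_precision = c(10, 30, 50, 20))
  map2 <- fit_normalization(wide_cohort(tbl2), "task1",
                            c("total_time", "needle_precision"))
  expect_equal(map2$max[map2$metric == "total_time"], 9)
  expect_equal(map2[map2$metric == "needle_precision", c("min", "max")],
               map[map$metric == "needle_precision", c("min", "max")],
               ignore_attr = TRUE)
})

test_that("composites live on 0-100, honor weights, and drop incomplete participants", {
  tbl <- data.frame(participant_id = c("n1", "n2", "n3", "r1", "r2"),
                    group = c(rep("novice", 3), rep("robotic", 2)),
                    total_time = c(60, 50, 40, 20, 10),
                    needle_precision = c(10, 20, 30, 50, 40),
                    movements_left = c(9, 7, 5, 3, 1))
  co <- wide_cohort(tbl)

  # single lower_better metric: participant at min -> 100, at max -> 0
  cs1 <- composite_scores(co, "task1", "total_time")
  expect_equal(cs1$composite[cs1$participant_id == "r2"], 100)
  expect_equal(cs1$composite[cs1$participant_id == "n1"], 0)
  expect_true(all(cs1$composite >= 0 & cs1$composite <= 100))

  # doubling a weight equals counting the metric twice in a plain mean
  mets <- c("total_time", "needle_precision", "movements_left")
  map <- fit_normalization(co, "task1", mets)
  z <- vapply(mets, function(mm)
    normalize_value(tbl[[mm]], mm, map), numeric(nrow(tbl)))
  manual <- rowMeans(cbind(z[, 1], z[, 1], z[, 2], z[, 3]))
  cs2 <- composite_scores(co, "task1", mets, weights = c(2, 1, 1))
  expect_equal(cs2$composite[match(tbl$participant_id, cs2$participant_id)],
               manual)

  # group summaries computed on composites
  gs <- attr(cs2, "group_summaries")
  expect_equal(gs$novice[["n"]], 3)
  expect_equal(gs$robotic[["mean"]],
               mean(cs2$composite[cs2$group == "robotic"]))

  # participant missing a selected metric is dropped with a warning
  tbl_missing <- tbl
  extra <- data.frame(participant_id = "n4", group = "novice", task = "task1",
                      metric = "total_time", value = 55)
  co_m <- cohort_table(rbind(wide_cohort(tbl_missing)$metrics, extra))
  expect_warning(cs3 <- composite_scores(co_m, "task1", mets), "dropping 1")
  expect_false("n4" %in% cs3$participant_id)
})

test_that("composites are invariant to affine metric rescaling and participant order", {
  set.seed(8)
  co <- generate_cohort(task_fixture("task1"), seed = 8, demographics = FALSE)
  mets <- paper_composites()$task1
  base <- composite_scores(co, "task1", mets)

  co2 <- co
  sel <- co2$metrics$metric == "total_time"
  co2$metrics$value[sel] <- co2$metrics$value[sel] * 3.7 + 12  # unit change
  resc <- composite_scores(co2, "task1", mets)
  expect_equal(base$composite, resc$composite, tolerance = 1e-12)

  co3 <- co
  set.seed(9)
  co3$metrics <- co3$metrics[sample(nrow(co3$metrics)), ]
  perm <- composite_scores(co3, "task1", mets)
  expect_equal(perm$composite[match(base$participant_id, perm$participant_id)],
               base$composite, tolerance = 1e-12)
})

test_that("sensitivity weights extremize group separation over the simplex", {
  # two metrics, one with zero group separation
  set.seed(10)
  tbl <- data.frame(
    participant_id = sprintf("p%02d", 1:30),
    group = rep(c("novice", "robotic"), each = 15),
    total_time = c(rnorm(15, 60, 5), rnorm(15, 20, 5)),
    needle_precision = rnorm(30, 50, 8))
  co <- wide_cohort(tbl)
  mets <- c("total_time", "needle_precision")

  expect_equal(as.numeric(sensitivity_weights(co, "task1", mets, "uniform")),
               c(1, 1))
  best <- sensitivity_weights(co, "task1", mets, "best_case")
  expect_gt(best[["total_time"]], 0.95)  # nearly all weight on the separator

  # grid-search oracle on the 1-simplex
  map <- fit_normalization(co, "task1", mets)
  z <- vapply(mets, function(mm) normalize_value(tbl[[mm]], mm, map),
              numeric(nrow(tbl)))
  sep <- function(w1) {
    cmp <- z %*% c(w1, 1 - w1)
    lo <- cmp[tbl$group == "novice"]; hi <- cmp[tbl$group == "robotic"]
    sp <- sqrt((14 * var(lo) + 14 * var(hi)) / 28)
    (mean(hi) - mean(lo)) / sp
  }
  grid <- seq(0, 1, by = 1e-3)
  oracle_best <- max(vapply(grid, sep, numeric(1)))
  expect_equal(attr(best, "separation"), oracle_best, tolerance = 1e-3)

  worst <- sensitivity_weights(co, "task1", mets, "worst_case")
  uni <- sensitivity_weights(co, "task1", mets, "uniform")
  expect_gte(attr(best, "separation"), attr(uni, "separation"))
  expect_gte(attr(uni, "separation"), attr(worst, "separation"))
  expect_error(sensitivity_weights(co, "task1", character(0)), "empty")
})
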