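# Construct- and content-validity screening: two-sample t-tests from summary
# statistics or records, a variance-homogeneity gate, Likert domain
# aggregation, and the rule selecting composite-eligible metrics.

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided independent-samples t-test directly from group
#' means, SDs and sizes, in the pooled-variance (Student) or
#' Welch-Satterthwaite form. This is the workhorse for screening published
#' summary tables where raw records are unavailable.
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @param var_equal pooled-variance form? (`FALSE` gives Welch.)
#' @return object of class `test_report`: list with `t`, `df`, `p`, `method`
#'   and the input summaries.
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2 (got %d, %d)", n1, n2)
  if (s1 < 0 || s2 < 0) stopf("SDs must be nonnegative")
  if (s1 == 0 && s2 == 0 && m1 == m2) {
    # identical degenerate groups: no evidence of a difference
    rep <- list(t = 0, df = n1 + n2 - 2, p = 1,
                method = if (var_equal) "student" else "welch")
  } else if (s1 == 0 && s2 == 0) {
    stopf("degenerate input: both SDs are zero with different means")
  } else if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    t <- (m1 - m2) / se
    rep <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), method = "student")
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    t <- (m1 - m2) / se
    rep <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), method = "welch")
  }
  rep$summary1 <- c(mean = m1, sd = s1, n = n1)
  rep$summary2 <- c(mean = m2, sd = s2, n = n2)
  class(rep) <- "test_report"
  rep
}

#' @rdname t_test_summary
#' @export
student_t_summary <- function(m1, s1, n1, m2, s2, n2)
  t_test_summary(m1, s1, n1, m2, s2, n2, var_equal = TRUE)

#' @rdname t_test_summary
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2)
  t_test_summary(m1, s1, n1, m2, s2, n2, var_equal = FALSE)

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  if (!is.null(x$levene_p))
    cat(sprintf("  variance-homogeneity (Levene) p = %.4g\n", x$levene_p))
  invisible(x)
}

#' Mean-centered Levene test for variance homogeneity
#'
#' One-way ANOVA F-test on the absolute deviations from the group means,
#' used as the gate choosing between the pooled-variance and Welch forms of
#' the two-sample t-test (the convention of mainstream statistical software).
#'
#' @param x,y numeric samples, each of length `>= 2`.
#' @return list with `statistic`, `df` (length 2) and `p`.
#' @export
levene_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs n >= 2")
  z <- list(abs(x - mean(x)), abs(y - mean(y)))
  ni <- lengths(z)
  N <- sum(ni)
  k <- 2L
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(ni * zbar_i) / N
  num <- sum(ni * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), numeric(1))) / (N - k)
  if (den == 0) {
    stat <- if (num == 0) 0 else Inf
    p <- if (num == 0) 1 else 0
  } else {
    stat <- num / den
    p <- stats::pf(stat, k - 1, N - k, lower.tail = FALSE)
  }
  list(statistic = stat, df = c(k - 1, N - k), p = p)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper used in the screening log. The screen reports this p-value but
#' does not change the test pathway on its outcome: the published analysis
#' applies t-tests throughout, so the check is informational.
#'
#' @param x numeric sample of length `>= 3`.
#' @return Shapiro-Wilk p-value.
#' @export
normality_check <- function(x) {
  if (length(x) < 3) stopf("normality check needs n >= 3 (got %d)", length(x))
  if (stats::sd(x) == 0) return(NA_real_)  # degenerate: normality undefined
  stats::shapiro.test(x)$p.value
}

# gated record-level two-sample test: Levene at alpha decides Student vs
# Welch; the chosen test is computed from the sample moments so that
# summary-based and record-based pathways agree exactly
gated_t_test <- function(x, y, alpha = 0.05) {
  lev <- levene_test(x, y)
  var_equal <- lev$p >= alpha
  rep <- t_test_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y),
                        var_equal = var_equal)
  rep$levene_p <- lev$p
  rep
}

contrast_names <- function() c("robotic_vs_novice", "laparoscopic_vs_novice",
                               "robotic_vs_laparoscopic")

contrast_pairs <- function() list(
  robotic_vs_novice = c("robotic", "novice"),
  laparoscopic_vs_novice = c("laparoscopic", "novice"),
  robotic_vs_laparoscopic = c("robotic", "laparoscopic"))

better_group <- function(mean_a, mean_b, label_a, label_b, direction) {
  if (is.na(direction) || mean_a == mean_b) return(NA_character_)
  hi_is_better <- direction == "higher_better"
  if ((mean_a > mean_b) == hi_is_better) label_a else label_b
}

#' Pairwise construct screening of one metric
#'
#' Runs the three pairwise contrasts (robotic vs novice, laparoscopic vs
#' novice, robotic vs laparoscopic) for one task metric on record-level data.
#' Each contrast is a two-sided independent t-test gated by a mean-centered
#' Levene test at `alpha`: pooled-variance when homogeneity is not rejected,
#' Welch otherwise. The direction-aware "advantage" (which group performed
#' better) is derived from the group means and the metric's registry
#' direction; it is undefined for ties and for `ambiguous` metrics.
#'
#' @param cohort a `cohort_table`.
#' @param task,metric which metric to screen.
#' @param alpha two-sided significance level (default 0.05).
#' @return object of class `construct_result`.
#' @export
compare_groups <- function(cohort, task, metric, alpha = 0.05) {
  m <- cohort$metrics
  sub <- m[m$task == task & m$metric == metric, ]
  if (!nrow(sub)) stopf("no records for metric '%s' in task '%s'", metric, task)
  vals <- split(sub$value, factor(sub$group, levels = group_levels()))
  sizes <- lengths(vals)
  empty <- names(sizes)[sizes == 0]
  if (length(empty))
    stopf("group '%s' has no records for metric '%s' (task %s)",
          empty[1], metric, task)
  if (any(sizes < 2))
    stopf("contrasted groups need n >= 2 for metric '%s'", metric)
  reg <- cohort$registry
  dir <- reg$direction[reg$task == task & reg$metric == metric]
  tests <- list()
  advantage <- character(0)
  for (cn in contrast_names()) {
    pair <- contrast_pairs()[[cn]]
    x <- vals[[pair[1]]]
    y <- vals[[pair[2]]]
    rep <- gated_t_test(x, y, alpha = alpha)
    rep$student <- student_t_summary(mean(x), stats::sd(x), length(x),
                                     mean(y), stats::sd(y), length(y))
    rep$welch <- welch_t_summary(mean(x), stats::sd(x), length(x),
                                 mean(y), stats::sd(y), length(y))
    rep$normality_p <- c(
      if (length(x) >= 3) normality_check(x) else NA_real_,
      if (length(y) >= 3) normality_check(y) else NA_real_)
    tests[[cn]] <- rep
    advantage[cn] <- better_group(mean(x), mean(y), pair[1], pair[2], dir)
  }
  res <- list(metric = metric, task = task, direction = dir, alpha = alpha,
              group_means = vapply(vals, mean, numeric(1)),
              group_sds = vapply(vals, stats::sd, numeric(1)),
              group_n = sizes, tests = tests, advantage = advantage,
              significant_rvn = tests$robotic_vs_novice$p < alpha)
  class(res) <- "construct_result"
  res
}

#' @export
print.construct_result <- function(x, ...) {
  cat(sprintf("Construct screen: %s / %s (direction: %s)\n",
              x$task, x$metric, x$direction))
  for (cn in names(x$tests)) {
    t <- x$tests[[cn]]
    cat(sprintf("  %-24s p = %-8.4g (%s)  advantage: %s\n", cn, t$p,
                t$method, ifelse(is.na(x$advantage[cn]), "-", x$advantage[cn])))
  }
  invisible(x)
}

#' Screen every metric of a task
#'
#' @param cohort a `cohort_table`.
#' @param task task identifier.
#' @param alpha significance level.
#' @return list of [compare_groups()] results in registry order.
#' @export
screen_task <- function(cohort, task, alpha = 0.05) {
  reg <- cohort$registry
  mets <- reg$metric[reg$task == task]
  mets <- mets[mets %in% cohort$metrics$metric[cohort$metrics$task == task]]
  if (!length(mets)) stopf("no metrics recorded for task '%s'", task)
  out <- lapply(mets, function(mm) compare_groups(cohort, task, mm, alpha))
  names(out) <- mets
  out
}

#' Screen a task from published summary statistics
#'
#' Same contrasts as [screen_task()] but computed from `(mean, sd, n)` rows,
#' for re-analysis of printed tables without raw records. With no record-level
#' data to run the variance-homogeneity gate on, the Welch form is used by
#' default (conservative); both forms are attached to each report.
#'
#' @param summaries summary data frame (see [load_summary_fixture()]).
#' @param task task identifier.
#' @param registry metric registry supplying benefit directions.
#' @param alpha significance level.
#' @param method `"welch"` (default) or `"student"`.
#' @return list of `construct_result` objects in registry order.
#' @export
screen_summaries <- function(summaries, task, registry = default_registry(),
                             alpha = 0.05, method = c("welch", "student")) {
  method <- match.arg(method)
  sub <- summaries[summaries$task == task & summaries$group %in% group_levels(), ]
  if (!nrow(sub)) stopf("no summary rows for task '%s'", task)
  reg <- registry[registry$task == task, ]
  mets <- reg$metric[reg$metric %in% sub$metric]
  out <- lapply(mets, function(mm) {
    srows <- sub[sub$metric == mm, ]
    g <- function(lbl) srows[srows$group == lbl, ]
    dir <- reg$direction[reg$metric == mm]
    tests <- list()
    advantage <- character(0)
    for (cn in contrast_names()) {
      pair <- contrast_pairs()[[cn]]
      a <- g(pair[1]); b <- g(pair[2])
      if (nrow(a) != 1 || nrow(b) != 1)
        stopf("missing summary for metric '%s', contrast %s", mm, cn)
      rep <- t_test_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n,
                            var_equal = method == "student")
      rep$student <- student_t_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
      rep$welch <- welch_t_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
      tests[[cn]] <- rep
      advantage[cn] <- better_group(a$mean, b$mean, pair[1], pair[2], dir)
    }
    means <- vapply(group_levels(), function(lbl) g(lbl)$mean, numeric(1))
    sds <- vapply(group_levels(), function(lbl) g(lbl)$sd, numeric(1))
    ns <- vapply(group_levels(), function(lbl) as.integer(g(lbl)$n), integer(1))
    res <- list(metric = mm, task = task, direction = dir, alpha = alpha,
                group_means = means, group_sds = sds, group_n = ns,
                tests = tests, advantage = advantage,
                significant_rvn = tests$robotic_vs_novice$p < alpha)
    class(res) <- "construct_result"
    res
  })
  names(out) <- mets
  out
}

#' Flatten construct results to a table
#'
#' @param results list of `construct_result` objects.
#' @return data frame, one row per metric, mirroring the published layout
#'   (group means/SDs and the three pairwise p-values).
#' @export
construct_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(task = r$task, metric = r$metric, direction = r$direction,
               mean_robotic = r$group_means[["robotic"]],
               sd_robotic = r$group_sds[["robotic"]],
               mean_laparoscopic = r$group_means[["laparoscopic"]],
               sd_laparoscopic = r$group_sds[["laparoscopic"]],
               mean_novice = r$group_means[["novice"]],
               sd_novice = r$group_sds[["novice"]],
               p_robotic_vs_novice = r$tests$robotic_vs_novice$p,
               p_laparoscopic_vs_novice = r$tests$laparoscopic_vs_novice$p,
               p_robotic_vs_laparoscopic = r$tests$robotic_vs_laparoscopic$p,
               significant_rvn = r$significant_rvn,
               advantage_rvn = r$advantage[["robotic_vs_novice"]],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Content-validity aggregation of Likert domains
#'
#' For each questionnaire domain (realism, didactic value, usability) of a
#' task: per-participant domain mean over items, per-group mean/SD, pooled
#' total-group mean, a positivity flag (total mean strictly above the 3.5
#' neutral-to-positive threshold; the boundary is not positive), and the three
#' pairwise group contrasts tested as in [compare_groups()].
#'
#' @param cohort a `cohort_table` carrying Likert responses.
#' @param task task identifier.
#' @param alpha significance level for the pairwise contrasts.
#' @return list of `content_result` objects, one per domain present.
#' @export
likert_content <- function(cohort, task, alpha = 0.05) {
  lk <- cohort$likert
  if (is.null(lk)) stopf("cohort carries no Likert responses")
  lk <- lk[lk$task == task, ]
  if (!nrow(lk)) stopf("no Likert responses for task '%s'", task)
  doms <- likert_domains()[likert_domains() %in% lk$domain]
  out <- lapply(doms, function(dm) {
    sub <- lk[lk$domain == dm, ]
    if (!nrow(sub)) stopf("domain '%s' has zero items", dm)
    per <- stats::aggregate(score ~ participant_id + group, data = sub, FUN = mean)
    vals <- split(per$score, factor(per$group, levels = group_levels()))
    tests <- list()
    for (cn in contrast_names()) {
      pair <- contrast_pairs()[[cn]]
      if (length(vals[[pair[1]]]) >= 2 && length(vals[[pair[2]]]) >= 2)
        tests[[cn]] <- gated_t_test(vals[[pair[1]]], vals[[pair[2]]], alpha)
    }
    total_mean <- mean(per$score)
    res <- list(task = task, domain = dm,
                group_means = vapply(vals, mean, numeric(1)),
                group_sds = vapply(vals, stats::sd, numeric(1)),
                group_n = lengths(vals), total_mean = total_mean,
                positive = total_mean > 3.5,
                pairwise_p = vapply(tests, function(t) t$p, numeric(1)))
    class(res) <- "content_result"
    res
  })
  names(out) <- doms
  out
}

#' @export
print.content_result <- function(x, ...) {
  cat(sprintf("Content: %s / %s — total mean %.2f (%s)\n", x$task, x$domain,
              x$total_mean, if (x$positive) "positive" else "not positive"))
  invisible(x)
}

#' Select composite-eligible construct parameters
#'
#' Implements the published inclusion rule: a metric enters the composite when
#' its robotic-vs-novice contrast is significant AND the robotic group is the
#' better performer under the metric's benefit direction (metrics on which
#' novices outperformed experts are excluded) AND the direction is not
#' `ambiguous`. Explicit `include`/`exclude` overrides adjust the set;
#' ordering follows the registry.
#'
#' @param results list of `construct_result` objects for one task.
#' @param registry metric registry (ordering and direction source).
#' @param include,exclude character vectors of metric names forced in or out.
#' @return character vector of selected metric names, in registry order.
#' @export
select_construct_parameters <- function(results, registry = default_registry(),
                                        include = NULL, exclude = NULL) {
  task <- unique(vapply(results, function(r) r$task, character(1)))
  if (length(task) != 1) stopf("results must cover exactly one task")
  reg <- registry[registry$task == task, ]
  unknown <- setdiff(c(include, exclude), reg$metric)
  if (length(unknown))
    stopf("override names unknown metric '%s' for task '%s'", unknown[1], task)
  picked <- vapply(results, function(r) {
    isTRUE(r$significant_rvn) &&
      identical(r$advantage[["robotic_vs_novice"]], "robotic") &&
      r$direction != "ambiguous"
  }, logical(1))
  sel <- vapply(results[picked], function(r) r$metric, character(1))
  sel <- union(setdiff(sel, exclude), include)
  reg$metric[reg$metric %in% sel]
}
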