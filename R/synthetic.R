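# Synthetic cohort generation from published per-group summary statistics.
#
# Performance metrics are drawn from a normal location-scale model truncated
# at zero by rejection, so the pre-truncation location and scale equal the
# published mean and SD (the truncation bias is negligible when mean/sd is
# large, which holds for nearly every metric here). Count-valued metrics are
# rounded to the nearest integer after truncation. Likert scores are rounded,
# clipped normal draws on the 1-5 scale.

#' Draw synthetic values for one metric
#'
#' Samples `n` values from N(mean, sd) truncated at zero by rejection; the
#' location/scale parameters are the published group mean and SD. Count-valued
#' metrics are rounded to the nearest integer after truncation.
#'
#' @param mean target (pre-truncation) mean.
#' @param sd target (pre-truncation) standard deviation, `>= 0`.
#' @param n number of draws.
#' @param count_valued round draws to integers?
#' @return numeric vector of `n` nonnegative values.
#' @details Uses the current RNG state; seed with [set.seed()] or use
#'   [generate_cohort()] for keyed substreams.
#' @export
sample_metric <- function(mean, sd, n, count_valued = FALSE) {
  if (sd < 0) stopf("sd must be nonnegative (got %g)", sd)
  if (n < 1) stopf("n must be >= 1")
  if (sd == 0) {
    if (mean < 0) stopf("degenerate draw with negative mean %g", mean)
    out <- rep(mean, n)
    return(if (count_valued) round(out) else out)
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n, 2 * (n - length(out))), mean, sd)
    out <- c(out, draw[draw >= 0])
  }
  out <- out[seq_len(n)]
  if (count_valued) out <- round(out)
  out
}

#' Draw synthetic Likert scores
#'
#' Normal draws rounded to the nearest integer and clipped to the 1-5 scale;
#' the simplest mechanism consistent with a published mean and SD of opinion
#' scores. At moderate SD the clipping shifts the mean by well under 0.05.
#'
#' @param mean target mean opinion score, in `[1, 5]`.
#' @param sd target standard deviation, `>= 0`.
#' @param n number of scores.
#' @return integer vector with values in 1..5.
#' @export
generate_likert <- function(mean, sd, n) {
  if (mean < 1 || mean > 5)
    stopf("Likert mean must lie in [1, 5] (got %g)", mean)
  if (sd < 0) stopf("sd must be nonnegative (got %g)", sd)
  raw <- if (sd == 0) rep(mean, n) else stats::rnorm(n, mean, sd)
  as.integer(pmin(5, pmax(1, round(raw))))
}

group_sizes_from_summaries <- function(summaries, task) {
  sub <- summaries[summaries$task == task & summaries$group %in% group_levels(), ]
  vapply(group_levels(), function(g) {
    ns <- sub$n[sub$group == g]
    if (!length(ns)) 0L else as.integer(max(ns))
  }, integer(1))
}

#' Generate a synthetic cohort from group summaries
#'
#' Builds a full participant cohort whose per-group, per-metric distributions
#' match the supplied summary rows (`task,metric,group,mean,sd,n`): empirical
#' group means and SDs converge to the summaries as group sizes grow. One
#' global seed is expanded into per-`(task, metric, group)` substreams by
#' stable string hashing, so adding or removing a metric leaves all other
#' draws unchanged and identical inputs give bitwise-identical cohorts.
#'
#' @param summaries data frame of group summaries (see
#'   [load_summary_fixture()]); rows with group `"total"` are ignored.
#' @param group_sizes named integer vector (`novice`, `laparoscopic`,
#'   `robotic`) or a list of such vectors keyed by task. Defaults to the `n`
#'   column of the summaries per task, which reproduces the study's per-task
#'   group sizes including the task2 data loss (14/26/28).
#' @param registry metric registry; metrics with unit `"count"` are rounded.
#' @param seed integer seed controlling all draws.
#' @param likert_summaries optional Likert summary rows (same columns, metric
#'   = domain name) used to attach one questionnaire response per participant,
#'   task and domain.
#' @param demographics attach simple synthetic demographics (age and advanced
#'   robotic procedure counts mirroring the study's distribution)?
#' @return a [cohort_table()].
#' @export
generate_cohort <- function(summaries, group_sizes = NULL,
                            registry = default_registry(), seed = 1L,
                            likert_summaries = NULL, demographics = TRUE) {
  summaries <- summaries[summaries$group %in% group_levels(), ]
  if (!nrow(summaries)) stopf("no usable summary rows")
  tasks <- unique(summaries$task)
  known <- paste(registry$task, registry$metric)

  # participant ids are stable per group across tasks; per-task subsets take
  # the first n_task participants of each group (mirrors per-task data loss)
  max_sizes <- vapply(group_levels(), function(g) {
    n <- 0L
    for (tk in tasks) {
      sz <- if (is.list(group_sizes)) group_sizes[[tk]]
            else if (!is.null(group_sizes)) group_sizes
            else group_sizes_from_summaries(summaries, tk)
      n <- max(n, as.integer(sz[[g]]))
    }
    n
  }, integer(1))
  ids <- lapply(group_levels(), function(g)
    sprintf("%s_%02d", g, seq_len(max_sizes[[g]])))
  names(ids) <- group_levels()

  rows <- vector("list", 0)
  for (tk in tasks) {
    sz <- if (is.list(group_sizes)) group_sizes[[tk]]
          else if (!is.null(group_sizes)) group_sizes
          else group_sizes_from_summaries(summaries, tk)
    reg_tk <- registry[registry$task == tk, ]
    sub <- summaries[summaries$task == tk, ]
    for (mi in seq_len(nrow(reg_tk))) {
      met <- reg_tk$metric[mi]
      if (!met %in% sub$metric) next
      count_valued <- identical(reg_tk$unit[mi], "count")
      for (g in group_levels()) {
        n_g <- as.integer(sz[[g]])
        if (is.na(n_g) || n_g < 1) next
        srow <- sub[sub$metric == met & sub$group == g, ]
        if (nrow(srow) != 1)
          stopf("missing summary for metric '%s', group '%s' (task %s)",
                met, g, tk)
        vals <- with_substream(seed, paste(tk, met, g, sep = "/"),
                               sample_metric(srow$mean, srow$sd, n_g, count_valued))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[[g]][seq_len(n_g)], group = g, task = tk,
          metric = met, value = vals, stringsAsFactors = FALSE)
      }
    }
    missing <- setdiff(sub$metric, reg_tk$metric)
    if (length(missing))
      stopf("summary metric '%s' (task %s) not present in the registry",
            missing[1], tk)
  }
  metrics <- do.call(rbind, rows)

  likert <- NULL
  if (!is.null(likert_summaries)) {
    lk <- likert_summaries[likert_summaries$group %in% group_levels(), ]
    lrows <- vector("list", 0)
    for (ri in seq_len(nrow(lk))) {
      tk <- lk$task[ri]; dom <- lk$metric[ri]; g <- lk$group[ri]
      n_g <- max_sizes[[g]]
      if (n_g < 1) next
      sc <- with_substream(seed, paste("likert", tk, dom, g, sep = "/"),
                           generate_likert(lk$mean[ri], lk$sd[ri], n_g))
      lrows[[length(lrows) + 1L]] <- data.frame(
        participant_id = ids[[g]], group = g, task = tk, domain = dom,
        item = "overall", score = sc, stringsAsFactors = FALSE)
    }
    likert <- do.call(rbind, lrows)
  }

  demo <- NULL
  if (isTRUE(demographics)) {
    # age means/SDs and the split of advanced robotic procedure experience
    # follow the study's demographics table
    age_par <- list(novice = c(24, 2.4), laparoscopic = c(35, 5.5),
                    robotic = c(43, 10.8))
    drows <- lapply(group_levels(), function(g) {
      n_g <- max_sizes[[g]]
      if (n_g < 1) return(NULL)
      age <- with_substream(seed, paste("demo/age", g, sep = "/"),
                            round(sample_metric(age_par[[g]][1], age_par[[g]][2], n_g)))
      adv <- rep(0L, n_g)
      if (g == "robotic") {
        # 7 of 15 robotic participants report > 50 advanced procedures
        k <- round(n_g * 7 / 15)
        adv <- with_substream(seed, "demo/advanced", {
          hi <- sample(51:100, k, replace = TRUE)
          lo <- sample(0:20, n_g - k, replace = TRUE)
          sample(c(hi, lo))
        })
      }
      data.frame(participant_id = ids[[g]], group = g, age = age,
                 advanced_procedures = as.integer(adv), stringsAsFactors = FALSE)
    })
    demo <- do.call(rbind, drows)
  }

  cohort_table(metrics, registry = registry, likert = likert,
               demographics = demo)
}
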