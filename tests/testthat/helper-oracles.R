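# shared oracles and fixture builders

# sample with exactly the requested mean and sd (ddof = 1)
moment_match <- function(n, mean, sd) {
  x <- seq_len(n) + stats::rnorm(n)
  as.numeric(scale(x)) * sd + mean
}

# grid-search minimizer of theoretical FP + FN over [mu_lo, mu_hi];
# independent of the analytic intersection path. FP + FN is unimodal between
# the means, so staged refinement reaches the global minimizer.
grid_cutoff <- function(mu_lo, s_lo, mu_hi, s_hi, final_step = 1e-5) {
  tot <- function(c) pnorm(c, mu_lo, s_lo, lower.tail = FALSE) + pnorm(c, mu_hi, s_hi)
  lo <- mu_lo; hi <- mu_hi
  step <- (hi - lo) / 1000
  while (step > final_step) {
    g <- seq(lo, hi, by = step)
    i <- which.min(tot(g))
    lo <- g[max(1, i - 1)]
    hi <- g[min(length(g), i + 1)]
    step <- (hi - lo) / 1000
  }
  g <- seq(lo, hi, by = final_step)
  g[which.min(tot(g))]
}

# small record-level cohort from per-group value lists for one metric
toy_cohort <- function(values, task = "task1", metric = "total_time",
                       registry = default_registry()) {
  rows <- do.call(rbind, lapply(names(values), function(g) {
    v <- values[[g]]
    data.frame(participant_id = sprintf("%s_%02d", g, seq_along(v)),
               group = g, task = task, metric = metric, value = v,
               stringsAsFactors = FALSE)
  }))
  cohort_table(rows, registry = registry)
}

# cohort with several metrics: `tbl` is data.frame(participant_id, group)
# plus one column per metric
wide_cohort <- function(tbl, task = "task1", registry = default_registry()) {
  mets <- setdiff(names(tbl), c("participant_id", "group"))
  rows <- do.call(rbind, lapply(mets, function(mm)
    data.frame(participant_id = tbl$participant_id, group = tbl$group,
               task = task, metric = mm, value = tbl[[mm]],
               stringsAsFactors = FALSE)))
  cohort_table(rows, registry = registry)
}

paper_composites <- function() list(
  task1 = c("path_length_left", "path_length_right", "movements_left",
            "movements_right", "inaccurate_punctures", "instrument_collisions",
            "needle_precision", "total_time"),
  task2 = c("entrance_exit_points", "dropped_needles", "unnecessary_piercing",
            "suture_breakage", "total_time"),
  task3 = c("path_length_left", "instrument_collisions",
            "precise_needle_passages", "total_time"))

task_fixture <- function(task) {
  f <- c(task1 = "table4_task1.csv", task2 = "table5_task2.csv",
         task3 = "table6_task3.csv")
  load_summary_fixture(simval_fixture(f[[task]]))
}
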