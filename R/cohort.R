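# Cohort data model and I/O: metric registry, long-format participant tables,
# Likert responses and published group-summary fixtures.

#' Experience group labels
#'
#' The three experience groups, ordered by expected proficiency on a robotic
#' simulator: medical-background novices, laparoscopically experienced
#' surgeons without robotic experience, and robotically experienced surgeons.
#'
#' @return character vector of the three ordered labels.
#' @export
group_levels <- function() c("novice", "laparoscopic", "robotic")

likert_domains <- function() c("realism", "didactic_value", "usability")

#' Define a performance metric
#'
#' @param task task identifier (e.g. `"task1"`).
#' @param metric metric name, unique within a task.
#' @param domain one of `"movement"`, `"safety"`, `"task_specific"`.
#' @param direction benefit direction: `"lower_better"`, `"higher_better"` or
#'   `"ambiguous"` (ambiguous metrics are never auto-selected for composites).
#' @param unit measurement unit (`"mm"`, `"count"`, `"seconds"`, `"percent"`).
#'   Metrics with unit `"count"` are treated as count-valued by the generator.
#' @return one-row data frame usable as a registry row.
#' @export
metric_definition <- function(task, metric, domain, direction, unit) {
  domain <- match.arg(domain, c("movement", "safety", "task_specific"))
  direction <- match.arg(direction, c("lower_better", "higher_better", "ambiguous"))
  if (!nzchar(unit)) stopf("metric '%s': unit must be nonempty", metric)
  data.frame(task = task, metric = metric, domain = domain,
             direction = direction, unit = unit, stringsAsFactors = FALSE)
}

#' Default metric registry for the three advanced suturing tasks
#'
#' Metric vocabulary, domain and benefit direction for the tilted-plane needle
#' transfer (task1), intracorporal suturing (task2) and anastomosis needle
#' transfer (task3) tasks. Distance between scope and tissue, and times out of
#' view on task3, are flagged `ambiguous`: experts work closer to the tissue
#' and accept more out-of-view instrument time, so neither end is
#' unambiguously "better" and such metrics require an explicit override to
#' enter a composite.
#'
#' @return data frame with columns `task`, `metric`, `domain`, `direction`,
#'   `unit`.
#' @export
default_registry <- function() {
  rows <- list(
    # task 1: tilted plane needle transfer
    metric_definition("task1", "path_length_left", "movement", "lower_better", "mm"),
    metric_definition("task1", "path_length_right", "movement", "lower_better", "mm"),
    metric_definition("task1", "movements_left", "movement", "lower_better", "count"),
    metric_definition("task1", "movements_right", "movement", "lower_better", "count"),
    metric_definition("task1", "inaccurate_punctures", "safety", "lower_better", "count"),
    metric_definition("task1", "instrument_collisions", "safety", "lower_better", "count"),
    metric_definition("task1", "times_out_of_view", "safety", "lower_better", "count"),
    metric_definition("task1", "needle_precision", "task_specific", "higher_better", "percent"),
    metric_definition("task1", "total_errors", "task_specific", "lower_better", "count"),
    metric_definition("task1", "total_time", "task_specific", "lower_better", "seconds"),
    # task 2: intracorporal suturing
    metric_definition("task2", "entrance_exit_points", "movement", "lower_better", "count"),
    metric_definition("task2", "dropped_needles", "safety", "lower_better", "count"),
    metric_definition("task2", "unnecessary_piercing", "safety", "lower_better", "count"),
    metric_definition("task2", "needle_out_of_view", "safety", "lower_better", "count"),
    metric_definition("task2", "suture_breakage", "safety", "lower_better", "count"),
    metric_definition("task2", "total_knots", "task_specific", "higher_better", "count"),
    metric_definition("task2", "surgeon_knots", "task_specific", "higher_better", "count"),
    metric_definition("task2", "needle_precision", "task_specific", "higher_better", "percent"),
    metric_definition("task2", "total_time", "task_specific", "lower_better", "seconds"),
    # task 3: anastomosis needle transfer (vaginal cuff closure)
    metric_definition("task3", "path_length_left", "movement", "lower_better", "mm"),
    metric_definition("task3", "path_length_right", "movement", "lower_better", "mm"),
    metric_definition("task3", "movements_left", "movement", "lower_better", "count"),
    metric_definition("task3", "movements_right", "movement", "lower_better", "count"),
    metric_definition("task3", "entrance_exit_points", "movement", "lower_better", "count"),
    metric_definition("task3", "distance_scope_tissue", "movement", "ambiguous", "mm"),
    metric_definition("task3", "instrument_collisions", "safety", "lower_better", "count"),
    metric_definition("task3", "times_out_of_view", "safety", "ambiguous", "count"),
    metric_definition("task3", "unnecessary_piercing", "safety", "lower_better", "count"),
    metric_definition("task3", "suture_breakage", "safety", "lower_better", "count"),
    # the anastomosis task requires a fixed set of transfers, so fewer
    # (precise) passages means fewer redo attempts; the expert group records
    # fewer of both, and the composite treats fewer as better
    metric_definition("task3", "precise_needle_passages", "task_specific", "lower_better", "count"),
    metric_definition("task3", "needle_passages", "task_specific", "lower_better", "count"),
    metric_definition("task3", "total_time", "task_specific", "lower_better", "seconds")
  )
  reg <- do.call(rbind, rows)
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  need <- c("task", "metric", "domain", "direction", "unit")
  if (!all(need %in% names(registry)))
    stopf("registry must have columns: %s", paste(need, collapse = ", "))
  key <- paste(registry$task, registry$metric)
  if (anyDuplicated(key))
    stopf("duplicate metric definition: %s", key[duplicated(key)][1])
  bad <- !registry$direction %in% c("lower_better", "higher_better", "ambiguous")
  if (any(bad))
    stopf("invalid direction '%s' for metric '%s'",
          registry$direction[bad][1], registry$metric[bad][1])
  invisible(registry)
}

normalize_group <- function(x, allow_total = FALSE) {
  g <- tolower(trimws(as.character(x)))
  allowed <- group_levels()
  if (allow_total) allowed <- c(allowed, "total")
  bad <- !g %in% allowed
  if (any(bad))
    stopf("unknown group label '%s'; allowed labels: %s",
          unique(g[bad])[1], paste(allowed, collapse = ", "))
  g
}

#' Construct a validated cohort table
#'
#' A cohort table bundles long-format performance records, optional Likert
#' questionnaire responses and optional demographics with the metric registry
#' they are validated against.
#'
#' @param metrics data frame with columns `participant_id`, `group`, `task`,
#'   `metric`, `value` (nonnegative).
#' @param registry metric registry (see [default_registry()]).
#' @param likert optional data frame with columns `participant_id`, `group`,
#'   `task`, `domain`, `item`, `score` (integers 1-5).
#' @param demographics optional data frame with `participant_id`, `group` and
#'   free-form descriptor columns (age, advanced procedure counts, ...).
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(metrics, registry = default_registry(),
                         likert = NULL, demographics = NULL) {
  validate_registry(registry)
  need <- c("participant_id", "group", "task", "metric", "value")
  if (!all(need %in% names(metrics)))
    stopf("cohort metrics need columns: %s", paste(need, collapse = ", "))
  metrics$group <- normalize_group(metrics$group)
  metrics$value <- as.numeric(metrics$value)
  if (anyNA(metrics$value))
    stopf("non-numeric metric value at row %s", which(is.na(metrics$value))[1])
  if (any(metrics$value < 0))
    stopf("negative metric value for metric '%s' (participant %s)",
          metrics$metric[metrics$value < 0][1],
          metrics$participant_id[metrics$value < 0][1])
  known <- paste(registry$task, registry$metric)
  seen <- paste(metrics$task, metrics$metric)
  if (any(!seen %in% known))
    stopf("metric '%s' (task '%s') not present in the registry",
          metrics$metric[!seen %in% known][1], metrics$task[!seen %in% known][1])
  if (!is.null(likert)) likert <- validate_likert(likert)
  if (!is.null(demographics))
    demographics$group <- normalize_group(demographics$group)
  obj <- list(metrics = metrics, likert = likert,
              demographics = demographics, registry = registry)
  class(obj) <- "cohort_table"
  obj
}

validate_likert <- function(likert) {
  need <- c("participant_id", "group", "task", "domain", "item", "score")
  if (!all(need %in% names(likert)))
    stopf("likert table needs columns: %s", paste(need, collapse = ", "))
  likert$group <- normalize_group(likert$group)
  bad <- !likert$score %in% 1:5
  if (any(bad))
    stopf("Likert score %s outside 1..5 (participant %s)",
          likert$score[bad][1], likert$participant_id[bad][1])
  bad_dom <- !likert$domain %in% likert_domains()
  if (any(bad_dom))
    stopf("unknown Likert domain '%s'; allowed: %s",
          unique(likert$domain[bad_dom])[1],
          paste(likert_domains(), collapse = ", "))
  likert
}

#' @export
print.cohort_table <- function(x, ...) {
  np <- length(unique(x$metrics$participant_id))
  tasks <- sort(unique(x$metrics$task))
  cat(sprintf("Cohort table: %d participants, %d tasks, %d metric rows\n",
              np, length(tasks), nrow(x$metrics)))
  for (tk in tasks) {
    sub <- x$metrics[x$metrics$task == tk, ]
    sizes <- tapply(sub$participant_id, sub$group,
                    function(p) length(unique(p)))
    sizes <- sizes[group_levels()]
    cat(sprintf("  %s: n = %s (novice/laparoscopic/robotic), %d metrics\n",
                tk, paste(ifelse(is.na(sizes), 0, sizes), collapse = "/"),
                length(unique(sub$metric))))
  }
  if (!is.null(x$likert))
    cat(sprintf("  Likert responses: %d rows\n", nrow(x$likert)))
  invisible(x)
}

#' Group sizes of a cohort
#'
#' @param cohort a `cohort_table`.
#' @param task optional task; if omitted, sizes over all tasks.
#' @return named integer vector over the three group labels.
#' @export
group_sizes <- function(cohort, task = NULL) {
  m <- cohort$metrics
  if (!is.null(task)) m <- m[m$task == task, ]
  out <- vapply(group_levels(), function(g)
    length(unique(m$participant_id[m$group == g])), integer(1))
  out
}

#' Read a long-format cohort CSV
#'
#' Expects a header `participant_id,group,task,metric,value`. Group labels are
#' normalized case-insensitively; rows with metrics missing from the registry,
#' unknown group labels or negative values are rejected with an informative
#' error.
#'
#' @param path CSV file path.
#' @param registry metric registry used for validation.
#' @return a [cohort_table()].
#' @export
load_cohort <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stopf("malformed cohort CSV '%s': %s", path, conditionMessage(e)))
  need <- c("participant_id", "group", "task", "metric", "value")
  if (!all(need %in% names(df)))
    stopf("cohort CSV '%s' must have header: %s", path, paste(need, collapse = ","))
  suppressWarnings(v <- as.numeric(df$value))
  if (anyNA(v))
    stopf("malformed cohort CSV '%s': non-numeric value at data line %d",
          path, which(is.na(v))[1])
  df$value <- v
  cohort_table(df, registry = registry)
}

#' Write a cohort's performance records to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f))` reproduces the
#' metric records of `x`.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("participant_id", "group", "task", "metric", "value")
  utils::write.csv(cohort$metrics[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Likert response CSV
#'
#' Expects header `participant_id,group,task,domain,item,score` with integer
#' scores on the 1-5 scale.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
load_likert <- function(path) {
  if (!file.exists(path)) stopf("likert file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_likert(df)
}

#' Read a group-summary fixture
#'
#' Fixtures carry published per-group summary statistics, one row per
#' `(task, metric, group)` with columns `task,metric,group,mean,sd,n`. The
#' packaged fixtures (`table3_likert.csv`, `table4_task1.csv`,
#' `table5_task2.csv`, `table6_task3.csv`, via [simval_fixture()]) transcribe
#' the study's questionnaire and performance tables; Likert fixtures may carry
#' additional pooled rows with group `"total"`.
#'
#' @param path CSV file path.
#' @return data frame of validated group summaries.
#' @export
load_summary_fixture <- function(path) {
  if (!file.exists(path)) stopf("summary fixture not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task", "metric", "group", "mean", "sd", "n")
  if (!all(need %in% names(df)))
    stopf("summary fixture '%s' must have columns: %s", path,
          paste(need, collapse = ","))
  df$group <- normalize_group(df$group, allow_total = TRUE)
  if (any(df$sd < 0))
    stopf("summary fixture '%s': negative sd for metric '%s'",
          path, df$metric[df$sd < 0][1])
  if (any(df$n < 2))
    stopf("summary fixture '%s': n < 2 for metric '%s'",
          path, df$metric[df$n < 2][1])
  df
}

#' Path to a packaged summary fixture
#'
#' @param name fixture file name, e.g. `"table4_task1.csv"`; with no argument,
#'   lists the available fixtures.
#' @return file path (or vector of available names).
#' @export
simval_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "simvalid")
  if (is.null(name)) return(list.files(dir, pattern = "\\.csv$"))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stopf("no packaged fixture '%s'; available: %s", name,
          paste(list.files(dir, pattern = "\\.csv$"), collapse = ", "))
  path
}
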