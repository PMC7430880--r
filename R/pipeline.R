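# End-to-end orchestration: (generate | load) -> content + construct screen ->
# parameter selection -> composite -> pairwise cutoffs -> report.

#' Build a pipeline configuration
#'
#' @param tasks tasks to analyse.
#' @param alpha two-sided significance level in (0, 1).
#' @param seed integer seed driving all synthetic draws.
#' @param fixtures named list `task -> summary fixture path`; defaults to the
#'   packaged transcriptions of the study's performance tables.
#' @param likert_fixture path to the Likert summary fixture (or `NULL` to skip
#'   the content section).
#' @param cohort optional path to a long-format cohort CSV to load instead of
#'   generating one from the fixtures.
#' @param sizes optional group sizes passed to [generate_cohort()].
#' @param registry metric registry data frame or CSV path
#'   (`task,metric,domain,direction,unit`).
#' @param overrides named list `task -> list(include=, exclude=)` adjusting
#'   the selected parameter sets.
#' @param scenario composite weighting scenario (see [sensitivity_weights()]).
#' @param outdir optional output directory for [write_report()].
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(tasks = c("task1", "task2", "task3"),
                            alpha = 0.05, seed = 1L,
                            fixtures = NULL, likert_fixture = NULL,
                            cohort = NULL, sizes = NULL,
                            registry = NULL, overrides = list(),
                            scenario = "uniform", outdir = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (is.null(fixtures)) {
    defaults <- c(task1 = "table4_task1.csv", task2 = "table5_task2.csv",
                  task3 = "table6_task3.csv")
    fixtures <- lapply(defaults[tasks[tasks %in% names(defaults)]], simval_fixture)
  }
  if (is.null(likert_fixture) && is.null(cohort))
    likert_fixture <- simval_fixture("table3_likert.csv")
  if (is.character(registry)) {
    if (!file.exists(registry)) stopf("registry file not found: %s", registry)
    registry <- validate_registry(utils::read.csv(registry, stringsAsFactors = FALSE))
  }
  if (is.null(registry)) registry <- default_registry()
  for (p in c(unlist(fixtures), likert_fixture, cohort))
    if (!is.null(p) && !file.exists(p)) stopf("referenced file not found: %s", p)
  bad <- setdiff(names(overrides), tasks)
  if (length(bad)) stopf("override for unknown task '%s'", bad[1])
  structure(list(tasks = tasks, alpha = alpha, seed = as.integer(seed),
                 fixtures = fixtures, likert_fixture = likert_fixture,
                 cohort = cohort, sizes = sizes, registry = registry,
                 overrides = overrides,
                 scenario = match.arg(scenario,
                                      c("uniform", "best_case", "worst_case")),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments (`tasks`, `alpha`,
#' `seed`, `fixtures`, `likert_fixture`, `cohort`, `sizes`, `registry`,
#' `overrides`, `scenario`, `outdir`).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(pipeline_config)))
  do.call(pipeline_config, cfg[keep])
}

config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x$registry <- NULL
  sprintf("%08x", fnv1a32(paste(deparse(x), collapse = "")))
}

pipeline_cohort <- function(config) {
  if (!is.null(config$cohort))
    return(load_cohort(config$cohort, registry = config$registry))
  summaries <- do.call(rbind, lapply(unname(config$fixtures), load_summary_fixture))
  lk <- if (!is.null(config$likert_fixture))
    load_summary_fixture(config$likert_fixture) else NULL
  generate_cohort(summaries, group_sizes = config$sizes,
                  registry = config$registry, seed = config$seed,
                  likert_summaries = lk)
}

content_table <- function(content_results) {
  do.call(rbind, lapply(content_results, function(r) {
    data.frame(task = r$task, domain = r$domain,
               mean_robotic = r$group_means[["robotic"]],
               sd_robotic = r$group_sds[["robotic"]],
               mean_laparoscopic = r$group_means[["laparoscopic"]],
               sd_laparoscopic = r$group_sds[["laparoscopic"]],
               mean_novice = r$group_means[["novice"]],
               sd_novice = r$group_sds[["novice"]],
               total_mean = r$total_mean, positive = r$positive,
               p_robotic_vs_novice = r$pairwise_p[["robotic_vs_novice"]],
               p_laparoscopic_vs_novice = r$pairwise_p[["laparoscopic_vs_novice"]],
               p_robotic_vs_laparoscopic = r$pairwise_p[["robotic_vs_laparoscopic"]],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

cutoff_table <- function(report) {
  do.call(rbind, lapply(names(report), function(nm) {
    r <- report[[nm]]
    if (inherits(r, "skipped_cutoff")) {
      data.frame(contrast = nm, computable = FALSE, cutoff = NA_real_,
                 fp_theoretical = NA_real_, fn_theoretical = NA_real_,
                 fp_absolute = NA_real_, fn_absolute = NA_real_,
                 method = NA_character_, reason = r$reason,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(contrast = nm, computable = TRUE, cutoff = r$cutoff,
                 fp_theoretical = r$fp_theoretical,
                 fn_theoretical = r$fn_theoretical,
                 fp_absolute = r$fp_absolute, fn_absolute = r$fn_absolute,
                 method = r$method, reason = "", stringsAsFactors = FALSE)
    }
  }))
}

#' Run the full validity-evidence pipeline
#'
#' Executes, per task: construct screening of every registry metric, selection
#' of composite-eligible parameters (with any configured overrides), composite
#' scoring, and pairwise contrasting-groups cutoffs; plus Likert content
#' aggregation when questionnaire data is present. Deterministic given the
#' configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `cohort_table` (overrides the config's
#'   cohort source; used by [run_subgroup()]).
#' @return object of class `validity_report`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) cohort <- pipeline_cohort(config)
  message(sprintf("[cohort] %d participants, %d metric rows (%.2fs)",
                  length(unique(cohort$metrics$participant_id)),
                  nrow(cohort$metrics), proc.time()[["elapsed"]] - t0))
  notes <- character(0)
  content <- NULL
  if (!is.null(cohort$likert)) {
    cres <- unlist(lapply(intersect(config$tasks, unique(cohort$likert$task)),
                          function(tk) likert_content(cohort, tk, config$alpha)),
                   recursive = FALSE)
    content <- content_table(cres)
  }
  tasks <- list()
  for (tk in config$tasks) {
    t1 <- proc.time()[["elapsed"]]
    screen <- screen_task(cohort, tk, alpha = config$alpha)
    ov <- config$overrides[[tk]]
    selected <- select_construct_parameters(screen, config$registry,
                                            include = ov$include,
                                            exclude = ov$exclude)
    if (!is.null(ov))
      notes <- c(notes, sprintf(
        "%s: selection overrides applied (include: %s; exclude: %s)", tk,
        paste(ov$include, collapse = ", "), paste(ov$exclude, collapse = ", ")))
    task_out <- list(selected = selected, construct = construct_table(screen))
    if (length(selected)) {
      weights <- if (config$scenario == "uniform") NULL else
        sensitivity_weights(cohort, tk, selected, scenario = config$scenario)
      dropped <- withCallingHandlers(
        {
          comp <- composite_scores(cohort, tk, selected, weights = weights)
          character(0)
        },
        warning = function(w) {
          notes <<- c(notes, sprintf("%s: %s", tk, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      gs <- attr(comp, "group_summaries")
      task_out$composite <- data.frame(
        group = names(gs),
        mean = vapply(gs, `[[`, numeric(1), "mean"),
        sd = vapply(gs, `[[`, numeric(1), "sd"),
        n = vapply(gs, `[[`, numeric(1), "n"),
        row.names = NULL, stringsAsFactors = FALSE)
      task_out$weights <- as.list(attr(comp, "weights"))
      task_out$scores <- as.data.frame(comp)
      task_out$cutoffs <- cutoff_table(three_group_report(comp))
    } else {
      notes <- c(notes, sprintf("%s: no construct parameters selected", tk))
    }
    tasks[[tk]] <- task_out
    message(sprintf("[%s] %d metrics screened, %d selected (%.2fs)", tk,
                    length(screen), length(selected),
                    proc.time()[["elapsed"]] - t1))
  }
  report <- list(
    provenance = list(seed = config$seed, alpha = config$alpha,
                      scenario = config$scenario,
                      config_hash = config_hash(config),
                      package = as.character(utils::packageVersion("simvalid"))),
    content = content, tasks = tasks, notes = notes)
  class(report) <- "validity_report"
  validate_report(report)
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Subgroup re-analysis
#'
#' Re-runs the pipeline with participants restricted by a predicate on the
#' demographics table (for example, robotic-experienced participants with more
#' than 50 advanced procedures) and reports how the selected parameter set
#' changes per task relative to the full cohort.
#'
#' @param config a [pipeline_config()].
#' @param filter function taking the demographics data frame and returning a
#'   logical keep-vector (one value per participant).
#' @return a `validity_report` with an extra `subgroup` element holding the
#'   per-task selection deltas and filtered group sizes.
#' @export
run_subgroup <- function(config, filter) {
  cohort <- pipeline_cohort(config)
  if (is.null(cohort$demographics))
    stopf("subgroup analysis needs a demographics table")
  keep <- filter(cohort$demographics)
  if (!is.logical(keep) || length(keep) != nrow(cohort$demographics))
    stopf("filter must return one logical per participant")
  ids <- cohort$demographics$participant_id[keep]
  if (!length(ids)) stopf("filter matches no participants")
  sub <- cohort
  sub$metrics <- sub$metrics[sub$metrics$participant_id %in% ids, ]
  if (!is.null(sub$likert))
    sub$likert <- sub$likert[sub$likert$participant_id %in% ids, ]
  sub$demographics <- sub$demographics[keep, ]
  for (tk in config$tasks) {
    sz <- group_sizes(sub, tk)
    if (any(sz < 2))
      stopf("filter leaves fewer than 2 participants in group '%s' (task %s)",
            names(sz)[sz < 2][1], tk)
  }
  full <- run_pipeline(config, cohort = cohort)
  filtered <- run_pipeline(config, cohort = sub)
  filtered$subgroup <- list(
    kept = length(ids),
    group_sizes = as.list(group_sizes(sub)),
    selection_delta = lapply(config$tasks, function(tk) {
      a <- full$tasks[[tk]]$selected
      b <- filtered$tasks[[tk]]$selected
      list(full = a, subgroup = b,
           gained = setdiff(b, a), lost = setdiff(a, b))
    }) |> stats::setNames(config$tasks))
  filtered
}

# minimal structural schema check against the packaged schema file
validate_report <- function(report) {
  schema_path <- system.file("schema", "report_schema.json", package = "simvalid")
  schema <- jsonlite::fromJSON(schema_path)
  missing <- setdiff(schema$required, names(report))
  if (length(missing))
    stopf("report fails schema: missing section '%s'", missing[1])
  for (tk in names(report$tasks)) {
    miss <- setdiff(schema$task_required, names(report$tasks[[tk]]))
    ok_empty <- !length(report$tasks[[tk]]$selected) &&
      all(miss %in% schema$task_optional_when_empty)
    if (length(miss) && !ok_empty)
      stopf("report fails schema: task '%s' missing '%s'", tk, miss[1])
  }
  invisible(report)
}

md_table <- function(df, digits = 3) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = digits, format = "g") else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Write a validity report to disk
#'
#' Emits `report.json` (full report), `report.md` (tables laid out like the
#' published ones: content means, construct p-values, composite group
#' summaries, cutoffs with FP/FN) and per-task CSVs.
#'
#' @param report a `validity_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  md <- c("# Validity evidence report", "",
          sprintf("Seed %d, alpha %g, scenario %s, config %s.",
                  report$provenance$seed, report$provenance$alpha,
                  report$provenance$scenario, report$provenance$config_hash), "")
  if (!is.null(report$content)) {
    md <- c(md, "## Content validity (Likert domains)", "",
            md_table(report$content), "")
    utils::write.csv(report$content, file.path(dir, "content.csv"),
                     row.names = FALSE)
  }
  for (tk in names(report$tasks)) {
    t <- report$tasks[[tk]]
    md <- c(md, sprintf("## %s", tk), "",
            sprintf("Selected parameters: %s",
                    if (length(t$selected)) paste(t$selected, collapse = ", ")
                    else "(none)"), "",
            "### Construct screening", "", md_table(t$construct), "")
    utils::write.csv(t$construct, file.path(dir, sprintf("construct_%s.csv", tk)),
                     row.names = FALSE)
    if (!is.null(t$composite)) {
      md <- c(md, "### Composite scores", "", md_table(t$composite), "",
              "### Pass/fail cutoffs", "", md_table(t$cutoffs), "")
      utils::write.csv(t$scores, file.path(dir, sprintf("composite_%s.csv", tk)),
                       row.names = FALSE)
      utils::write.csv(t$cutoffs, file.path(dir, sprintf("cutoffs_%s.csv", tk)),
                       row.names = FALSE)
    }
  }
  if (length(report$notes))
    md <- c(md, "## Notes", "", paste0("- ", report$notes), "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Validity report (seed %d, alpha %g)\n",
              x$provenance$seed, x$provenance$alpha))
  if (!is.null(x$content)) {
    pos <- x$content[x$content$positive, ]
    cat(sprintf("  content: %d/%d task-domains rated positive (> 3.5)\n",
                nrow(pos), nrow(x$content)))
  }
  for (tk in names(x$tasks)) {
    t <- x$tasks[[tk]]
    cat(sprintf("  %s: %d parameters selected", tk, length(t$selected)))
    if (!is.null(t$cutoffs)) {
      nr <- t$cutoffs[t$cutoffs$contrast == "novice_vs_robotic", ]
      if (nrow(nr) && isTRUE(nr$computable))
        cat(sprintf("; novice-vs-robotic cutoff %.1f (FP %.0f%%, FN %.0f%%)",
                    nr$cutoff, 100 * nr$fp_theoretical, 100 * nr$fn_theoretical))
    }
    cat("\n")
  }
  if (length(x$notes)) cat(sprintf("  notes: %d\n", length(x$notes)))
  invisible(x)
}
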