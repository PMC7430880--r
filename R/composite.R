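# Direction-aware min-max normalization to the 0-100 scale and per-participant
# composite scores with group summaries.

#' Fit a 0-100 normalization map
#'
#' Computes per-metric min/max bounds over ALL participants of a task (all
#' three groups pooled), so every group lives on one comparable 0-100 axis.
#' Benefit direction comes from the cohort's registry: for `lower_better`
#' metrics the minimum maps to 100, for `higher_better` the maximum does.
#'
#' @param cohort a `cohort_table`.
#' @param task task identifier.
#' @param metrics character vector of metric names to include.
#' @return object of class `normalization_map` (data frame with `metric`,
#'   `min`, `max`, `direction`).
#' @export
fit_normalization <- function(cohort, task, metrics) {
  if (!length(metrics)) stopf("no metrics to normalize")
  m <- cohort$metrics
  reg <- cohort$registry
  rows <- lapply(metrics, function(mm) {
    v <- m$value[m$task == task & m$metric == mm]
    if (length(v) < 2) stopf("metric '%s' observed for < 2 participants", mm)
    lo <- min(v); hi <- max(v)
    if (hi <= lo)
      stopf("ZeroRange: metric '%s' is constant over the pooled cohort", mm)
    dir <- reg$direction[reg$task == task & reg$metric == mm]
    if (!length(dir)) stopf("metric '%s' absent from the registry", mm)
    data.frame(metric = mm, min = lo, max = hi, direction = dir,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  attr(map, "task") <- task
  class(map) <- c("normalization_map", "data.frame")
  map
}

#' Normalize raw metric values to 0-100
#'
#' `higher_better`: `100 (v - min) / (max - min)`; `lower_better`:
#' `100 (max - v) / (max - min)`. Values outside the fitted bounds (possible
#' when a map is reused on new data) are clipped so scores stay in `[0, 100]`.
#'
#' @param value numeric vector of raw values.
#' @param metric metric name present in the map.
#' @param map a fitted [fit_normalization()] map.
#' @return numeric vector in `[0, 100]`.
#' @export
normalize_value <- function(value, metric, map) {
  row <- map[map$metric == metric, ]
  if (nrow(row) != 1) stopf("metric '%s' absent from the normalization map", metric)
  v <- pmin(row$max, pmax(row$min, value))
  z <- (v - row$min) / (row$max - row$min)
  if (row$direction == "lower_better") z <- 1 - z
  100 * z
}

#' Apply a normalization map to new data
#'
#' @param object a `normalization_map`.
#' @param newdata data frame with columns `metric` and `value`.
#' @param ... unused.
#' @return `newdata` with a `score` column on the 0-100 scale.
#' @export
predict.normalization_map <- function(object, newdata, ...) {
  newdata$score <- vapply(seq_len(nrow(newdata)), function(i)
    normalize_value(newdata$value[i], newdata$metric[i], object), numeric(1))
  newdata
}

#' Per-participant composite scores
#'
#' Each participant's composite is the (weighted) mean of their normalized
#' metric scores; the result lives on the same 0-100 scale, 100 meaning the
#' favorable bound of every included metric. Participants missing any selected
#' metric for the task are dropped with a warning (never imputed). Group
#' mean/SD/n are computed on the composites.
#'
#' @param cohort a `cohort_table`.
#' @param task task identifier.
#' @param metrics metric names to include (e.g. from
#'   [select_construct_parameters()]).
#' @param weights optional nonnegative weights, named by metric or in
#'   `metrics` order; default equal weights.
#' @param map optional pre-fitted normalization map; default fits on `cohort`.
#' @return object of class `composite_set`: data frame `participant_id`,
#'   `group`, `composite`, with the map, weights and group summaries attached
#'   as attributes.
#' @export
composite_scores <- function(cohort, task, metrics, weights = NULL, map = NULL) {
  if (!length(metrics)) stopf("composite needs a nonempty metric set")
  if (is.null(weights)) weights <- rep(1, length(metrics))
  if (!is.null(names(weights))) weights <- weights[metrics]
  if (length(weights) != length(metrics) || anyNA(weights))
    stopf("weights must cover every included metric")
  if (any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be nonnegative with positive sum")
  if (is.null(map)) map <- fit_normalization(cohort, task, metrics)
  m <- cohort$metrics
  sub <- m[m$task == task & m$metric %in% metrics, ]
  wide <- stats::reshape(sub[, c("participant_id", "group", "metric", "value")],
                         idvar = c("participant_id", "group"),
                         timevar = "metric", direction = "wide")
  cols <- paste0("value.", metrics)
  complete <- stats::complete.cases(wide[, cols, drop = FALSE])
  if (any(!complete)) {
    warnf("dropping %d participant(s) missing a selected metric for %s",
          sum(!complete), task)
    wide <- wide[complete, ]
  }
  scores <- vapply(seq_along(metrics), function(j)
    normalize_value(wide[[cols[j]]], metrics[j], map),
    numeric(nrow(wide)))
  scores <- matrix(scores, nrow = nrow(wide))
  composite <- as.numeric(scores %*% weights) / sum(weights)
  out <- data.frame(participant_id = wide$participant_id, group = wide$group,
                    composite = composite, stringsAsFactors = FALSE)
  out <- out[order(match(out$group, group_levels()), out$participant_id), ]
  rownames(out) <- NULL
  gs <- lapply(split(out$composite, factor(out$group, levels = group_levels())),
               function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  structure(out, task = task, metrics = metrics,
            weights = stats::setNames(weights, metrics), map = map,
            group_summaries = gs, class = c("composite_set", "data.frame"))
}

#' @export
print.composite_set <- function(x, ...) {
  cat(sprintf("Composite scores (%s): %d participants, %d metrics\n",
              attr(x, "task"), nrow(x), length(attr(x, "metrics"))))
  gs <- attr(x, "group_summaries")
  for (g in names(gs))
    cat(sprintf("  %-13s mean %5.1f  sd %5.1f  n %2d\n", g,
                gs[[g]]["mean"], gs[[g]]["sd"], gs[[g]]["n"]))
  invisible(x)
}

# standardized mean difference of weighted composites between two groups
composite_separation <- function(score_matrix, groups, weights,
                                 contrast = c("novice", "robotic")) {
  comp <- as.numeric(score_matrix %*% weights) / sum(weights)
  lo <- comp[groups == contrast[1]]
  hi <- comp[groups == contrast[2]]
  sp <- sqrt(((length(lo) - 1) * stats::var(lo) + (length(hi) - 1) * stats::var(hi)) /
               (length(lo) + length(hi) - 2))
  if (sp == 0) return(0)
  (mean(hi) - mean(lo)) / sp
}

#' Best/worst-case sensitivity weights
#'
#' Formalizes the "weigh the included parameters in a best/worst case
#' scenario" sensitivity analysis as extremization of the contrasted groups'
#' standardized mean difference of composites over the weight simplex:
#' `best_case` maximizes the separation, `worst_case` minimizes it, `uniform`
#' returns equal weights. The search runs a multi-start Nelder-Mead on a
#' softmax parameterization of the simplex.
#'
#' @param cohort a `cohort_table`.
#' @param task task identifier.
#' @param metrics nonempty metric set.
#' @param scenario `"uniform"`, `"best_case"` or `"worst_case"`.
#' @param contrast the two groups whose separation is extremized (low, high).
#' @return named weight vector (all 1 for uniform; summing to 1 otherwise),
#'   with the achieved separation in attribute `"separation"`.
#' @export
sensitivity_weights <- function(cohort, task, metrics,
                                scenario = c("uniform", "best_case", "worst_case"),
                                contrast = c("novice", "robotic")) {
  scenario <- match.arg(scenario)
  if (!length(metrics)) stopf("empty metric set")
  map <- fit_normalization(cohort, task, metrics)
  m <- cohort$metrics
  sub <- m[m$task == task & m$metric %in% metrics, ]
  wide <- stats::reshape(sub[, c("participant_id", "group", "metric", "value")],
                         idvar = c("participant_id", "group"),
                         timevar = "metric", direction = "wide")
  cols <- paste0("value.", metrics)
  wide <- wide[stats::complete.cases(wide[, cols, drop = FALSE]), ]
  scorem <- vapply(seq_along(metrics), function(j)
    normalize_value(wide[[cols[j]]], metrics[j], map), numeric(nrow(wide)))
  scorem <- matrix(scorem, nrow = nrow(wide))
  sep_of <- function(w) composite_separation(scorem, wide$group, w, contrast)
  if (scenario == "uniform") {
    w <- stats::setNames(rep(1, length(metrics)), metrics)
    return(structure(w, separation = sep_of(w)))
  }
  sign <- if (scenario == "best_case") -1 else 1
  k <- length(metrics)
  obj <- function(theta) sign * sep_of(exp(theta - max(theta)))
  starts <- c(list(rep(0, k)),
              lapply(seq_len(k), function(j) { th <- rep(-3, k); th[j] <- 3; th }))
  best <- NULL
  for (th0 in starts) {
    fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- exp(best$par - max(best$par))
  w <- stats::setNames(w / sum(w), metrics)
  structure(w, separation = sep_of(w))
}
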