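# Contrasting-groups standard setting: the pass/fail cutoff is the point
# where the fitted normal densities of a less-experienced and a
# more-experienced group's composite scores cross, which is exactly the
# minimizer of the total theoretical misclassification (FP + FN). The pass
# rule is composite >= cutoff (the boundary passes).

#' Fitted group Gaussian
#'
#' @param mu composite mean (0-100 scale).
#' @param sigma composite SD, `> 0`.
#' @param n group size.
#' @param label group label.
#' @return object of class `group_gaussian`.
#' @export
group_gaussian <- function(mu, sigma, n = NA_integer_, label = NA_character_) {
  if (!is.finite(mu)) stopf("mu must be finite")
  if (!is.finite(sigma) || sigma <= 0)
    stopf("sigma must be > 0 (got %s); a zero-SD group cannot be contrasted — inspect the composite scores", format(sigma))
  structure(list(mu = mu, sigma = sigma, n = n, label = label),
            class = "group_gaussian")
}

as_gaussian <- function(x) {
  if (inherits(x, "group_gaussian")) return(x)
  group_gaussian(x$mu, x$sigma, if (!is.null(x$n)) x$n else NA_integer_,
                 if (!is.null(x$label)) x$label else NA_character_)
}

#' Density-intersection cutoff between two group Gaussians
#'
#' Returns the score at which the two fitted normal densities are equal,
#' taken strictly between the group means: the midpoint when the SDs are
#' equal, otherwise the between-means root of the quadratic obtained by
#' equating the log-densities. This point minimizes the total theoretical
#' error FP + FN. A numeric minimization of FP + FN over the between-means
#' interval backs up numerically degenerate cases.
#'
#' @param lo `group_gaussian` of the less-experienced group (lower mean).
#' @param hi `group_gaussian` of the more-experienced group (higher mean).
#' @return the cutoff score, with attribute `"method"` (`analytic_intersection`
#'   or `numeric`).
#' @export
intersect_cutoff <- function(lo, hi) {
  lo <- as_gaussian(lo); hi <- as_gaussian(hi)
  if (lo$mu >= hi$mu)
    stopf("groups are not separated in the expected order (lo mean %.3f >= hi mean %.3f)",
          lo$mu, hi$mu)
  s1 <- lo$sigma; s2 <- hi$sigma; m1 <- lo$mu; m2 <- hi$mu
  if (isTRUE(all.equal(s1, s2))) {
    return(structure((m1 + m2) / 2, method = "analytic_intersection"))
  }
  # equate log densities: quadratic a c^2 + b c + d = 0
  a <- 1 / s2^2 - 1 / s1^2
  b <- -2 * (m2 / s2^2 - m1 / s1^2)
  d <- m2^2 / s2^2 - m1^2 / s1^2 - 2 * log(s1 / s2)
  disc <- b^2 - 4 * a * d
  roots <- if (disc >= 0) (-b + c(-1, 1) * sqrt(disc)) / (2 * a) else numeric(0)
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 1 && is.finite(inside))
    return(structure(inside, method = "analytic_intersection"))
  # numeric fallback: FP + FN is unimodal between the means
  tot <- function(c) {
    r <- theoretical_rates(c, lo, hi)
    r[["fp"]] + r[["fn"]]
  }
  opt <- stats::optimize(tot, interval = c(m1, m2), tol = 1e-9)
  structure(opt$minimum, method = "numeric")
}

#' Theoretical false-positive and false-negative rates
#'
#' Under the fitted Gaussians and the pass rule "composite >= cutoff":
#' FP is the probability that a member of the less-experienced group scores at
#' or above the cutoff (an unready trainee passes); FN the probability that a
#' member of the more-experienced group scores below it.
#'
#' @param cutoff pass/fail score.
#' @param lo,hi `group_gaussian` objects (less/more experienced).
#' @return named vector `c(fp, fn)` of rates in `[0, 1]`.
#' @export
theoretical_rates <- function(cutoff, lo, hi) {
  lo <- as_gaussian(lo); hi <- as_gaussian(hi)
  c(fp = stats::pnorm(cutoff, lo$mu, lo$sigma, lower.tail = FALSE),
    fn = stats::pnorm(cutoff, hi$mu, hi$sigma))
}

#' Empirical (absolute) false-positive and false-negative rates
#'
#' Same quantities as [theoretical_rates()] but computed as empirical
#' fractions of the observed composite scores.
#'
#' @param cutoff pass/fail score.
#' @param lo_scores,hi_scores observed composites of the two groups.
#' @return named vector `c(fp, fn)`.
#' @export
absolute_rates <- function(cutoff, lo_scores, hi_scores) {
  if (!length(lo_scores) || !length(hi_scores))
    stopf("absolute rates need nonempty score samples")
  c(fp = mean(lo_scores >= cutoff), fn = mean(hi_scores < cutoff))
}

#' Contrasting-groups standard setting
#'
#' Fits normal distributions (sample mean, sample SD) to the composite scores
#' of a less-experienced and a more-experienced group, places the pass/fail
#' cutoff at the intersection of the two densities, and reports theoretical
#' (fitted-Gaussian tail) and absolute (empirical fraction) false-positive and
#' false-negative rates.
#'
#' @param x composite scores: a numeric vector (with `groups`), a
#'   [composite_scores()] result, or a formula `score ~ group` with `data`.
#' @param ... passed to methods.
#' @return object of class `contrast_cutoff` with `print`, `summary`, `coef`,
#'   `predict`, `plot` and `simulate` methods.
#' @examples
#' set.seed(1)
#' scores <- c(rnorm(30, 45, 10), rnorm(15, 75, 8))
#' groups <- rep(c("novice", "robotic"), c(30, 15))
#' fit <- contrast_groups(scores, groups, lo = "novice", hi = "robotic")
#' coef(fit)
#' predict(fit, c(40, 70, 90))
#' @export
contrast_groups <- function(x, ...) UseMethod("contrast_groups")

#' @rdname contrast_groups
#' @param groups group label per score.
#' @param lo,hi labels of the less- and more-experienced contrasted groups.
#' @export
contrast_groups.default <- function(x, groups, lo = "novice", hi = "robotic", ...) {
  lo_scores <- x[groups == lo]
  hi_scores <- x[groups == hi]
  if (length(lo_scores) < 2 || length(hi_scores) < 2)
    stopf("both contrasted groups need n >= 2 (got %d '%s', %d '%s')",
          length(lo_scores), lo, length(hi_scores), hi)
  g_lo <- group_gaussian(mean(lo_scores), stats::sd(lo_scores),
                         length(lo_scores), lo)
  g_hi <- group_gaussian(mean(hi_scores), stats::sd(hi_scores),
                         length(hi_scores), hi)
  cutoff <- intersect_cutoff(g_lo, g_hi)
  th <- theoretical_rates(cutoff, g_lo, g_hi)
  ab <- absolute_rates(cutoff, lo_scores, hi_scores)
  structure(list(cutoff = as.numeric(cutoff),
                 method = attr(cutoff, "method"),
                 fp_theoretical = th[["fp"]], fn_theoretical = th[["fn"]],
                 fp_absolute = ab[["fp"]], fn_absolute = ab[["fn"]],
                 lo = g_lo, hi = g_hi,
                 scores = list(lo = lo_scores, hi = hi_scores),
                 contrast = c(lo = lo, hi = hi), call = match.call()),
            class = "contrast_cutoff")
}

#' @rdname contrast_groups
#' @export
contrast_groups.composite_set <- function(x, lo = "novice", hi = "robotic", ...) {
  contrast_groups(x$composite, x$group, lo = lo, hi = hi)
}

#' @rdname contrast_groups
#' @param data data frame for the formula interface (`score ~ group`).
#' @export
contrast_groups.formula <- function(x, data, lo = "novice", hi = "robotic", ...) {
  mf <- stats::model.frame(x, data)
  contrast_groups(mf[[1]], as.character(mf[[2]]), lo = lo, hi = hi)
}

#' @export
print.contrast_cutoff <- function(x, digits = 2, ...) {
  cat("Contrasting-groups standard setting\n")
  cat(sprintf("  contrast: %s (n=%d) vs %s (n=%d)\n",
              x$contrast[["lo"]], x$lo$n, x$contrast[["hi"]], x$hi$n))
  cat(sprintf("  pass/fail cutoff: %.*f (pass if composite >= cutoff; %s)\n",
              digits, x$cutoff, x$method))
  cat(sprintf("  theoretical FP %.1f%%, FN %.1f%%; absolute FP %.1f%%, FN %.1f%%\n",
              100 * x$fp_theoretical, 100 * x$fn_theoretical,
              100 * x$fp_absolute, 100 * x$fn_absolute))
  invisible(x)
}

#' @export
coef.contrast_cutoff <- function(object, ...) {
  c(cutoff = object$cutoff,
    fp_theoretical = object$fp_theoretical,
    fn_theoretical = object$fn_theoretical,
    fp_absolute = object$fp_absolute,
    fn_absolute = object$fn_absolute)
}

#' @export
summary.contrast_cutoff <- function(object, ...) {
  out <- list(coef = coef(object),
              groups = data.frame(
                group = c(object$contrast[["lo"]], object$contrast[["hi"]]),
                mean = c(object$lo$mu, object$hi$mu),
                sd = c(object$lo$sigma, object$hi$sigma),
                n = c(object$lo$n, object$hi$n)),
              method = object$method)
  class(out) <- "summary.contrast_cutoff"
  out
}

#' @export
print.summary.contrast_cutoff <- function(x, ...) {
  cat("Contrasting-groups standard setting\n\nFitted group Gaussians:\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("\nCutoff %.3f (%s)\n", x$coef[["cutoff"]], x$method))
  cat(sprintf("Theoretical FP/FN: %.3f / %.3f\nAbsolute    FP/FN: %.3f / %.3f\n",
              x$coef[["fp_theoretical"]], x$coef[["fn_theoretical"]],
              x$coef[["fp_absolute"]], x$coef[["fn_absolute"]]))
  invisible(x)
}

#' Classify scores against a fitted cutoff
#'
#' @param object a `contrast_cutoff`.
#' @param newdata numeric composite scores; defaults to the training scores.
#' @param ... unused.
#' @return factor with levels `fail`, `pass` (pass when score >= cutoff).
#' @export
predict.contrast_cutoff <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- c(object$scores$lo, object$scores$hi)
  factor(ifelse(newdata >= object$cutoff, "pass", "fail"),
         levels = c("fail", "pass"))
}

#' Simulate composite scores from the fitted group Gaussians
#'
#' @param object a `contrast_cutoff`.
#' @param nsim draws per group.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with columns `group` and `composite`.
#' @export
simulate.contrast_cutoff <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    group = rep(c(object$contrast[["lo"]], object$contrast[["hi"]]), each = nsim),
    composite = c(stats::rnorm(nsim, object$lo$mu, object$lo$sigma),
                  stats::rnorm(nsim, object$hi$mu, object$hi$sigma)),
    stringsAsFactors = FALSE)
}

#' Plot the fitted densities and cutoff
#'
#' @param x a `contrast_cutoff`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.contrast_cutoff <- function(x, ...) {
  rng <- range(x$lo$mu - 3.5 * x$lo$sigma, x$hi$mu + 3.5 * x$hi$sigma, 0, 100)
  xs <- seq(rng[1], rng[2], length.out = 400)
  d_lo <- stats::dnorm(xs, x$lo$mu, x$lo$sigma)
  d_hi <- stats::dnorm(xs, x$hi$mu, x$hi$sigma)
  graphics::plot(xs, d_lo, type = "l", col = "firebrick", lwd = 2,
                 xlab = "composite score", ylab = "density",
                 ylim = c(0, max(d_lo, d_hi)), ...)
  graphics::lines(xs, d_hi, col = "steelblue", lwd = 2)
  graphics::abline(v = x$cutoff, lty = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(x$contrast[["lo"]], x$contrast[["hi"]]))
  graphics::mtext(sprintf("cutoff %.1f", x$cutoff), side = 3, line = 0.2)
  invisible(x)
}

#' Pairwise cutoffs over the three experience groups
#'
#' Computes contrasting-groups cutoffs for novice-vs-robotic and
#' laparoscopic-vs-robotic, plus novice-vs-laparoscopic when the ordered
#' separation holds. A pair whose group means are not in the expected order is
#' flagged not-computable rather than aborting the report.
#'
#' @param composites a [composite_scores()] result covering all three groups.
#' @return object of class `cutoff_report`: named list per pair, each either a
#'   `contrast_cutoff` or a not-computable flag with the reason.
#' @export
three_group_report <- function(composites) {
  pairs <- list(novice_vs_robotic = c("novice", "robotic"),
                laparoscopic_vs_robotic = c("laparoscopic", "robotic"),
                novice_vs_laparoscopic = c("novice", "laparoscopic"))
  out <- lapply(pairs, function(p) {
    tryCatch(contrast_groups(composites, lo = p[1], hi = p[2]),
             error = function(e) structure(
               list(computable = FALSE, contrast = c(lo = p[1], hi = p[2]),
                    reason = conditionMessage(e)),
               class = "skipped_cutoff"))
  })
  structure(out, task = attr(composites, "task"), class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("Pairwise contrasting-groups cutoffs (%s)\n",
              attr(x, "task")))
  for (nm in names(x)) {
    if (inherits(x[[nm]], "skipped_cutoff")) {
      cat(sprintf("  %-24s not computable: %s\n", nm, x[[nm]]$reason))
    } else {
      cat(sprintf("  %-24s cutoff %5.1f  FP %4.1f%%  FN %4.1f%%\n", nm,
                  x[[nm]]$cutoff, 100 * x[[nm]]$fp_theoretical,
                  100 * x[[nm]]$fn_theoretical))
    }
  }
  invisible(x)
}
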