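#' ROC curve, AUC with DeLong confidence interval, and Youden cutoff
#'
#' Evaluates a candidate biomarker against case/control status under the
#' convention that larger values are more disease-like: a sample is called
#' positive when its value is `>=` the cutoff. The curve is traversed at
#' every observed value as a candidate cutoff (plus a cutoff above the
#' maximum, giving the (0, 0) corner). The AUC is computed from midranks,
#' which equals both the trapezoid area under the empirical curve and the
#' Mann–Whitney probability `U / (n1 * n2)` with ties counted one half.
#' The confidence interval uses DeLong's placement-value variance on the
#' probit-free (Wald) scale, truncated to `[0, 1]`.
#'
#' @param case_values,control_values Numeric vectors, at least one finite
#'   value each.
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @return An object of class `roc_result` with elements `points` (tibble:
#'   `cutoff`, `sensitivity`, `specificity`), `auc`, `conf_low`,
#'   `conf_high`, `conf_level`, `youden` (list: `cutoff`, `j`), `n_case`,
#'   `n_control`. Use [tidy()] for the points, [glance()] for the summary.
#' @examples
#' r <- roc_auc(c(3, 4), c(1, 2))
#' glance(r)  # AUC 1, J = 1 at cutoff 3
#' @export
roc_auc <- function(case_values, control_values, conf_level = 0.95) {
  case_values <- case_values[is.finite(case_values)]
  control_values <- control_values[is.finite(control_values)]
  if (length(case_values) == 0L || length(control_values) == 0L) {
    data_error("both groups need at least one finite value")
  }
  check_number(conf_level, "conf_level", min = 0.5, max = 1 - 1e-12)
  n1 <- length(case_values)
  n0 <- length(control_values)

  cutoffs <- sort(unique(c(case_values, control_values)))
  sens <- vapply(cutoffs, function(cc) mean(case_values >= cc), numeric(1))
  spec <- vapply(cutoffs, function(cc) mean(control_values < cc), numeric(1))
  points <- tibble(
    cutoff = c(cutoffs, Inf),
    sensitivity = c(sens, 0),
    specificity = c(spec, 1)
  )

  # midrank AUC == trapezoid area == Mann-Whitney with ties counted 1/2
  r <- rank(c(case_values, control_values))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placement values
  v10 <- vapply(case_values, function(x)
    mean((control_values < x) + 0.5 * (control_values == x)), numeric(1))
  v01 <- vapply(control_values, function(y)
    mean((case_values > y) + 0.5 * (case_values == y)), numeric(1))
  v1 <- if (n1 > 1L) var(v10) else 0  # singleton group: no between-subject
  v0 <- if (n0 > 1L) var(v01) else 0  # variance component is estimable
  auc_var <- v1 / n1 + v0 / n0
  z <- qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(auc_var, 0))

  j_all <- points$sensitivity + points$specificity - 1
  j_best <- max(j_all[is.finite(points$cutoff)])
  best_cut <- min(points$cutoff[is.finite(points$cutoff) &
                                  j_all >= j_best - 1e-12])

  structure(list(
    points = points,
    auc = auc,
    conf_low = max(0, auc - half),
    conf_high = min(1, auc + half),
    conf_level = conf_level,
    youden = list(cutoff = best_cut, j = j_best),
    n_case = n1,
    n_control = n0
  ), class = "roc_result")
}

#' Youden-index optimal cutoff
#'
#' Returns the cutoff maximizing `J = sensitivity + specificity - 1`; when
#' several cutoffs tie, the smallest is returned so the choice is
#' deterministic. The maximal `J` is attached as attribute `"j"`.
#'
#' @param roc An object from [roc_auc()].
#' @return The optimal cutoff (numeric scalar).
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result")) {
    data_error("`roc` must come from roc_auc()")
  }
  structure(roc$youden$cutoff, j = roc$youden$j)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: %d cases vs %d controls\nAUC %.3f (%d%% CI %.3f-%.3f)\n",
    x$n_case, x$n_control, x$auc, round(100 * x$conf_level),
    x$conf_low, x$conf_high))
  cat(sprintf("Youden cutoff %g (J = %.3f)\n",
              x$youden$cutoff, x$youden$j))
  invisible(x)
}

#' @rdname roc_auc
#' @param x An `roc_result` object.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname roc_auc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, conf_low = x$conf_low, conf_high = x$conf_high,
         youden_cutoff = x$youden$cutoff, j = x$youden$j,
         n_case = x$n_case, n_control = x$n_control)
}

#' Fraction of values above a cutoff (over-expression rate)
#'
#' @param values Numeric vector (non-empty; `NA` dropped with a warning).
#' @param cutoff Finite cutoff; values strictly above it count.
#' @return A one-row tibble: `rate`, `n_above`, `n_total`.
#' @examples
#' overexpression_rate(c(0.5, 2, 3), 1)  # 2 of 3
#' @export
overexpression_rate <- function(values, cutoff) {
  check_number(cutoff, "cutoff")
  if (anyNA(values)) {
    warn("dropping missing values")
    values <- values[!is.na(values)]
  }
  if (length(values) == 0L) data_error("`values` is empty")
  tibble(rate = mean(values > cutoff),
         n_above = sum(values > cutoff),
         n_total = length(values))
}

#' Dichotomize at the median
#'
#' Splits a cohort into `"high"` (strictly above the median) and `"low"`
#' (at or below) groups; ties at the median go to the low group, so
#' `n_low >= n_high`. Group sizes are attached as attribute `"sizes"`.
#'
#' @param values Numeric vector, length >= 2 (`NA` allowed, stays `NA`).
#' @return A factor with levels `low`, `high`.
#' @export
dichotomize_median <- function(values) {
  if (sum(!is.na(values)) < 2L) {
    data_error("need at least 2 non-missing values")
  }
  m <- median(values, na.rm = TRUE)
  g <- factor(ifelse(values > m, "high", "low"), levels = c("low", "high"))
  if (all(g[!is.na(g)] == "low")) {
    warn("all values at or below the median; `high` group is empty")
  }
  structure(g, sizes = table(g))
}
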