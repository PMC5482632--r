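#' Kaplan-Meier relapse-free survival
#'
#' Product-limit estimate of relapse-free survival (RFS) with Greenwood
#' variance and log-log transformed confidence limits, fitted through the
#' survival package. By default both relapse and death in remission count
#' as RFS events (event-free duration from first remission); set
#' `rfs_events = "relapse"` for the relapse-only reading.
#'
#' @param records A data frame with columns `time` (months, positive) and
#'   `event` (one of `"relapse"`, `"death"`, `"censored"`).
#' @param rfs_events Event codes counted as failures (default
#'   `c("relapse", "death")`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `km_fit`; [tidy()] gives the step table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`), [glance()] the sample/event counts.
#' @examples
#' rec <- tibble::tibble(time = c(1, 2, 3),
#'                       event = c("censored", "relapse", "relapse"))
#' tidy(km_fit(rec))
#' @export
km_fit <- function(records, rfs_events = c("relapse", "death"),
                   conf_level = 0.95) {
  records <- check_records(records)
  rfs_events <- match.arg(rfs_events, c("relapse", "death"),
                          several.ok = TRUE)
  status <- as.integer(records$event %in% rfs_events)
  sf <- survival::survfit(
    survival::Surv(records$time, status) ~ 1,
    conf.type = "log-log", conf.int = conf_level)
  steps <- tibble(
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    estimate = sf$surv,
    std_error = sf$surv * sf$std.err,  # survfit std.err is on log scale
    conf_low = sf$lower,
    conf_high = sf$upper
  )
  structure(list(steps = steps, rfs_events = rfs_events,
                 n = length(status), n_event = sum(status),
                 conf_level = conf_level, survfit = sf),
            class = "km_fit")
}

#' @rdname km_fit
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @rdname km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event,
         rfs_events = paste(x$rfs_events, collapse = "+"),
         conf_level = x$conf_level)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d subjects, %d events (%s)\n",
              x$n, x$n_event, paste(x$rfs_events, collapse = "+")))
  invisible(x)
}

#' Log-rank test between groups
#'
#' @param records A data frame with `time`, `event`, and a grouping
#'   column.
#' @param group Name of the grouping column (default `"group"`).
#' @param rfs_events Event codes counted as failures.
#' @return A one-row tibble: `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank <- function(records, group = "group",
                    rfs_events = c("relapse", "death")) {
  records <- check_records(records, require_cols = c("time", "event", group))
  rfs_events <- match.arg(rfs_events, c("relapse", "death"),
                          several.ok = TRUE)
  g <- factor(records[[group]])
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    data_error("need at least 2 non-empty groups")
  }
  status <- as.integer(records$event %in% rfs_events)
  if (sum(status) == 0L) data_error("no events observed")
  sd_fit <- survival::survdiff(survival::Surv(records$time, status) ~ g)
  df <- nlevels(g) - 1L
  tibble(statistic = sd_fit$chisq, df = df,
         p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

#' Cumulative incidence functions under competing risks
#'
#' Aalen-Johansen estimates of the cumulative incidence of relapse and of
#' death in remission, computed with `cmprsk::cuminc()`. At every time,
#' `CIF_relapse + CIF_death + event-free survival = 1`.
#'
#' @param records A data frame with `time` and `event`.
#' @return An object of class `cif_fit`; [tidy()] gives `cause`, `time`,
#'   `estimate`, `variance`.
#' @export
cif_fit <- function(records) {
  records <- check_records(records)
  if (all(records$event == "censored")) {
    # no failures of either cause: both CIFs are identically zero
    empty <- tibble(cause = character(), time = numeric(),
                    estimate = numeric(), variance = numeric())
    return(structure(list(steps = empty, n = nrow(records), cuminc = NULL),
                     class = "cif_fit"))
  }
  ci <- cmprsk::cuminc(ftime = records$time,
                       fstatus = as.character(records$event),
                       cencode = "censored")
  steps <- purrr::imap(ci, function(comp, nm) {
    if (!is.list(comp) || is.null(comp$time)) return(NULL)
    cause <- sub("^1 ", "", nm)
    tibble(cause = cause, time = comp$time, estimate = comp$est,
           variance = comp$var)
  }) |>
    dplyr::bind_rows()
  structure(list(steps = steps, n = nrow(records), cuminc = ci),
            class = "cif_fit")
}

#' @rdname cif_fit
#' @param x A `cif_fit` object.
#' @param ... Unused.
#' @export
tidy.cif_fit <- function(x, ...) x$steps

#' @export
print.cif_fit <- function(x, ...) {
  cat(sprintf("Aalen-Johansen cumulative incidence: %d subjects, causes %s\n",
              x$n, paste(unique(x$steps$cause), collapse = ", ")))
  invisible(x)
}

#' Gray's test for equality of cumulative incidence functions
#'
#' Compares the relapse (and death) cumulative incidence between groups
#' accounting for the competing cause, via `cmprsk::cuminc()`.
#'
#' @param records A data frame with `time`, `event`, and a grouping column.
#' @param group Name of the grouping column.
#' @return A tibble with one row per cause: `cause`, `statistic`, `df`,
#'   `p_value`.
#' @export
gray_test <- function(records, group = "group") {
  records <- check_records(records, require_cols = c("time", "event", group))
  g <- factor(records[[group]])
  if (nlevels(g) < 2L || any(table(g) == 0L)) {
    data_error("Gray's test needs at least 2 non-empty groups")
  }
  if (!any(records$event == "relapse")) {
    data_error("no relapse events observed")
  }
  ci <- cmprsk::cuminc(ftime = records$time,
                       fstatus = as.character(records$event),
                       group = g, cencode = "censored")
  tst <- ci$Tests
  tibble(cause = rownames(tst), statistic = tst[, "stat"],
         df = tst[, "df"], p_value = tst[, "pv"])
}

#' Evaluate a survival or cumulative-incidence fit at a time point
#'
#' Reads the step function of a [km_fit()] or [cif_fit()] at `t` (default
#' 60 months, i.e. the 5-year estimate). A `t` beyond the last observed
#' time carries the last value forward with a warning.
#'
#' @param fit A `km_fit` or `cif_fit`.
#' @param t Time in months.
#' @param cause For `cif_fit`: which cause (default `"relapse"`).
#' @return A one-row tibble: `time`, `estimate` and, where available,
#'   `conf_low`/`conf_high` (KM) or `variance` (CIF).
#' @export
point_estimate_at <- function(fit, t = 60, cause = "relapse") {
  check_number(t, "t", min = 0)
  if (inherits(fit, "km_fit")) {
    steps <- fit$steps
    if (t > max(steps$time)) {
      warn(sprintf("t = %g beyond last observed time %g; carrying forward",
                   t, max(steps$time)))
    }
    i <- findInterval(t, steps$time)
    if (i == 0L) {
      return(tibble(time = t, estimate = 1, conf_low = 1, conf_high = 1))
    }
    tibble(time = t, estimate = steps$estimate[i],
           conf_low = steps$conf_low[i], conf_high = steps$conf_high[i])
  } else if (inherits(fit, "cif_fit")) {
    steps <- dplyr::filter(fit$steps, .data$cause == !!cause)
    if (nrow(steps) == 0L) {
      return(tibble(time = t, estimate = 0, variance = 0))
    }
    if (t > max(steps$time)) {
      warn(sprintf("t = %g beyond last observed time %g; carrying forward",
                   t, max(steps$time)))
    }
    i <- findInterval(t, steps$time)
    if (i == 0L) return(tibble(time = t, estimate = 0, variance = 0))
    tibble(time = t, estimate = steps$estimate[i],
           variance = steps$variance[i])
  } else {
    data_error("`fit` must be a km_fit or cif_fit")
  }
}
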