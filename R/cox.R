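#' Cox proportional-hazards model for relapse outcomes
#'
#' Fits a Cox model by partial likelihood with the Efron tie correction
#' (through `survival::coxph()`), either for the cause-specific relapse
#' hazard — competing deaths in remission censored at their death time —
#' or for relapse-free survival, where relapse and (by default) death both
#' count as events.
#'
#' @param records A data frame with `time`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names; each must
#'   have nonzero variance.
#' @param outcome `"relapse"` (cause-specific hazard of relapse, the CIR
#'   model) or `"rfs"` (relapse-free survival).
#' @param rfs_events Event codes counted as failures when
#'   `outcome = "rfs"`.
#' @param ties Tie-handling method passed to `coxph` (default `"efron"`).
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @return An object of class `cox_fit`; [tidy()] gives per-covariate
#'   `term`, `estimate` (log hazard), `hr`, `std_error`, `conf_low`,
#'   `conf_high` (HR scale) and `p_value`; [glance()] gives counts,
#'   log-likelihoods and the convergence flag. Non-convergence or a
#'   monotone likelihood (perfect separation) is flagged with a warning,
#'   never returned silently.
#' @export
cox_fit <- function(records, covariates, outcome = c("relapse", "rfs"),
                    rfs_events = c("relapse", "death"), ties = "efron",
                    conf_level = 0.95) {
  outcome <- match.arg(outcome)
  if (length(covariates) == 0L) data_error("no covariates supplied")
  records <- check_records(records,
                           require_cols = c("time", "event", covariates))
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(factor(v))
      records[[cv]] <- v - min(v)
    }
    if (isTRUE(sd(records[[cv]], na.rm = TRUE) == 0)) {
      data_error(sprintf("covariate `%s` is constant", cv))
    }
  }
  status <- if (outcome == "relapse") {
    as.integer(records$event == "relapse")
  } else {
    rfs_events <- match.arg(rfs_events, c("relapse", "death"),
                            several.ok = TRUE)
    as.integer(records$event %in% rfs_events)
  }
  if (sum(status) == 0L) data_error("no events observed for this outcome")

  fml <- stats::as.formula(paste(
    "survival::Surv(time, .status) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  dat <- dplyr::mutate(records, .status = status)

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) converged <- FALSE
  if (!converged) {
    warn("Cox fit did not converge cleanly (possible monotone likelihood)")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  tidy_tbl <- tibble(
    term = names(beta),
    estimate = unname(beta),
    hr = exp(unname(beta)),
    std_error = unname(se),
    conf_low = exp(unname(beta) - z * unname(se)),
    conf_high = exp(unname(beta) + z * unname(se)),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se)))
  )
  structure(list(
    tidy = tidy_tbl,
    loglik = fit$loglik[2L],
    loglik_null = fit$loglik[1L],
    n = fit$n, n_event = fit$nevent,
    outcome = outcome, ties = ties, conf_level = conf_level,
    converged = converged, coxph = fit
  ), class = "cox_fit")
}

#' @rdname cox_fit
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @export
tidy.cox_fit <- function(x, ...) x$tidy

#' @rdname cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, outcome = x$outcome,
         loglik = x$loglik, loglik_null = x$loglik_null,
         converged = x$converged)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s outcome, %s ties): %d subjects, %d events\n",
              x$outcome, x$ties, x$n, x$n_event))
  print(x$tidy)
  invisible(x)
}

#' Backward elimination of Cox covariates
#'
#' Starting from the full model, repeatedly drops the single covariate
#' with the largest Wald p-value among those exceeding `keep_alpha`
#' (default 0.1) and refits, until every remaining covariate has
#' `p <= keep_alpha` or none remain. The full elimination trace is
#' returned alongside the final fit.
#'
#' @inheritParams cox_fit
#' @param keep_alpha Retention threshold on the Wald p-value.
#' @return A list of class `cox_elimination`: `fit` (the final
#'   [cox_fit()], or `NULL` if every covariate was eliminated),
#'   `covariates` (those retained), and `trace` (tibble: `step`,
#'   `dropped`, `p_value`).
#' @export
backward_eliminate <- function(records, covariates, keep_alpha = 0.1,
                               outcome = c("relapse", "rfs"),
                               rfs_events = c("relapse", "death"),
                               ties = "efron") {
  check_number(keep_alpha, "keep_alpha", min = 1e-12, max = 1 - 1e-12)
  outcome <- match.arg(outcome)
  remaining <- covariates
  trace <- tibble(step = integer(), dropped = character(),
                  p_value = numeric())
  fit <- NULL
  step <- 0L
  while (length(remaining) > 0L) {
    fit <- cox_fit(records, remaining, outcome = outcome,
                   rfs_events = rfs_events, ties = ties)
    worst <- dplyr::slice_max(fit$tidy, .data$p_value, n = 1L,
                              with_ties = FALSE)
    if (worst$p_value <= keep_alpha) break
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble(
      step = step, dropped = worst$term, p_value = worst$p_value))
    remaining <- setdiff(remaining, worst$term)
    fit <- NULL
  }
  structure(list(fit = fit, covariates = remaining, trace = trace),
            class = "cox_elimination")
}

#' @export
print.cox_elimination <- function(x, ...) {
  if (nrow(x$trace) > 0L) {
    cat("Eliminated:", paste(x$trace$dropped, collapse = ", "), "\n")
  } else {
    cat("No covariates eliminated\n")
  }
  if (is.null(x$fit)) cat("Final model: empty\n") else print(x$fit)
  invisible(x)
}
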