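#' Relative expression by the 2^-ddCt method
#'
#' Computes per-sample relative expression from qPCR threshold cycles:
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt - mean(dCt_calibrator)`,
#' relative level `2^-ddCt`. The calibrator baseline is the mean `dCt`
#' over the samples flagged as calibrators (typically the normal
#' controls). Replicate wells of the same sample are averaged at the Ct
#' level before any difference is taken.
#'
#' @param records A data frame with columns `sample_id`, `target_ct`,
#'   `reference_ct` and logical `calibrator` (one row per well; replicate
#'   wells share a `sample_id`).
#' @return A tibble, one row per sample: `sample_id`, `target_ct`,
#'   `reference_ct` (well means), `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`, `calibrator`.
#' @examples
#' ddct(tibble::tibble(
#'   sample_id = c("p1", "n1"),
#'   target_ct = c(25, 28), reference_ct = c(20, 20),
#'   calibrator = c(FALSE, TRUE)))  # rel_expr 8 for p1
#' @export
ddct <- function(records) {
  need <- c("sample_id", "target_ct", "reference_ct", "calibrator")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    data_error(paste0("`records` needs columns: ",
                      paste(need, collapse = ", ")))
  }
  if (any(!is.finite(records$target_ct)) ||
      any(!is.finite(records$reference_ct))) {
    data_error("Ct values must be finite (reference Ct required per well)")
  }
  if (any(records$target_ct <= 0) || any(records$reference_ct <= 0)) {
    data_error("Ct values must be positive")
  }
  per_sample <- records |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      target_ct = mean(.data$target_ct),
      reference_ct = mean(.data$reference_ct),
      calibrator = any(.data$calibrator),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_ct = .data$target_ct - .data$reference_ct)
  if (!any(per_sample$calibrator)) {
    data_error("no calibrator samples present")
  }
  base <- mean(per_sample$delta_ct[per_sample$calibrator])
  per_sample |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - base,
      rel_expr = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::select("sample_id", "target_ct", "reference_ct", "delta_ct",
                  "delta_delta_ct", "rel_expr", "calibrator")
}

#' Standard curve and amplification efficiency
#'
#' Least-squares line of Ct against log10 template quantity over a
#' dilution series. The amplification efficiency is
#' `E = 10^(-1/slope) - 1`; perfect doubling chemistry has slope
#' -3.3219 (= -1/log10(2)) and `E = 1`.
#'
#' @param data A data frame with the dilution series.
#' @param log10_quantity,ct Column names (strings) of the log10 quantity
#'   and Ct values.
#' @return A one-row tibble of class `std_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`.
#' @examples
#' std_curve(tibble::tibble(q = 5:1, ct = 20 + 3.3219 * (5 - 5:1)),
#'           log10_quantity = "q", ct = "ct")
#' @export
std_curve <- function(data, log10_quantity = "log10_quantity", ct = "ct") {
  if (!is.data.frame(data) ||
      !all(c(log10_quantity, ct) %in% names(data))) {
    data_error("columns not found in `data`")
  }
  q <- data[[log10_quantity]]
  y <- data[[ct]]
  keep <- is.finite(q) & is.finite(y)
  q <- q[keep]; y <- y[keep]
  if (length(q) < 3L) data_error("need at least 3 dilution points")
  if (sd(q) == 0) data_error("zero variance in log10 quantity")
  fit <- lm(y ~ q)
  slope <- unname(coef(fit)[2L])
  if (slope >= 0) {
    warn("non-negative slope: not a valid dilution series")
  }
  r2 <- if (sd(y) == 0) 1 else stats::cor(q, y)^2
  out <- tibble(
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n_points = length(q)
  )
  class(out) <- c("std_curve", class(out))
  out
}

#' Interpolate template quantity from a standard curve
#'
#' Inverts the standard curve: `quantity = 10^((ct - intercept) / slope)`.
#'
#' @param curve A [std_curve()] result.
#' @param ct Numeric vector of observed Ct values.
#' @return Estimated quantities (same length as `ct`).
#' @export
std_curve_quantify <- function(curve, ct) {
  if (!inherits(curve, "std_curve")) {
    data_error("`curve` must come from std_curve()")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Copy-number ratio as a percentage
#'
#' Absolute quantification route: target copies relative to a reference
#' gene's copies, times 100 (the percent scale used for transcript
#' levels normalized to a housekeeping control).
#'
#' @param copies_target Non-negative copy numbers.
#' @param copies_reference Strictly positive copy numbers.
#' @return `100 * copies_target / copies_reference`, vectorized.
#' @export
copy_ratio <- function(copies_target, copies_reference) {
  if (any(!is.finite(copies_reference)) || any(copies_reference <= 0)) {
    data_error("reference copies must be positive")
  }
  if (any(is.finite(copies_target) & copies_target < 0)) {
    data_error("target copies must be non-negative")
  }
  100 * copies_target / copies_reference
}
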