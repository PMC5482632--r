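# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops and explicit sorting, so they share no code
# path with the package implementation they check.

# percentile rank scores for one sample, by explicit enumeration
oracle_rank_scores <- function(x) {
  ok <- which(is.finite(x))
  n <- length(ok)
  bins <- ceiling(100 * seq_len(n) / n)
  out <- rep(NA_real_, length(x))
  for (i in ok) {
    below <- sum(x[ok] < x[i])
    ties <- which(x[ok] == x[i])
    out[i] <- mean(bins[below + seq_along(ties)])
  }
  out
}

# ARS/delta for a small matrix by exhaustive per-sample sorting
oracle_score_table <- function(values, condition) {
  scores <- matrix(apply(values, 2, oracle_rank_scores),
                   nrow = nrow(values))
  ars <- function(g, cond) mean(scores[g, condition == cond, drop = TRUE])
  data.frame(
    row = seq_len(nrow(values)),
    ars_case = vapply(seq_len(nrow(values)), ars, numeric(1),
                      cond = "case"),
    ars_control = vapply(seq_len(nrow(values)), ars, numeric(1),
                         cond = "control")
  ) |>
    transform(delta = ars_case - ars_control)
}

# AUC by exhaustive case-control pair counting, ties worth one half
oracle_auc <- function(case_values, control_values) {
  s <- 0
  for (a in case_values) {
    for (b in control_values) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(case_values) * length(control_values))
}

# Youden maximizer by brute force over observed cutoffs, smallest wins ties
oracle_youden <- function(case_values, control_values) {
  cuts <- sort(unique(c(case_values, control_values)))
  j <- vapply(cuts, function(cc) {
    mean(case_values >= cc) + mean(control_values < cc) - 1
  }, numeric(1))
  best <- max(j)
  list(cutoff = min(cuts[j >= best - 1e-12]), j = best)
}

# two-group log-rank by an explicit risk-table walk
oracle_logrank <- function(time, status, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2L)
  evt <- sort(unique(time[status == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in evt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Cox log partial likelihood (no ties assumed), written out directly
oracle_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# step-function lookup (right-continuous), value before first step supplied
step_at <- function(t, times, values, before = 1) {
  i <- findInterval(t, times)
  ifelse(i == 0L, before, values[pmax(i, 1L)])
}

# small expression fixture: probes x samples with known values
make_rank_tibble <- function(values, probe_id = NULL, gene_id = NULL) {
  df <- tibble::as_tibble(as.data.frame(values))
  names(df) <- paste0("s", seq_len(ncol(df)))
  if (!is.null(gene_id)) df <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), df)
  if (!is.null(probe_id)) df <- dplyr::bind_cols(tibble::tibble(probe_id = probe_id), df)
  df
}

make_conditions <- function(n_case, n_control) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n_case + n_control)),
    condition = rep(c("case", "control"), c(n_case, n_control))
  )
}
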