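#' Percentile rank-score transformation
#'
#' Converts each sample's intensities to percentile rank scores on the
#' integer-anchored scale 1..100, the normalization that makes expression
#' values comparable across microarray platforms: any strictly increasing
#' per-sample distortion of the intensities leaves the scores unchanged.
#'
#' Within a sample the `N` non-missing intensities are ranked ascending;
#' the value at rank `k` maps to the score `ceiling(100 * k / N)`, so the
#' largest value in a sample always scores exactly 100. Tied intensities
#' receive the mean of the scores their ranks would map to, mirroring
#' average-rank tie handling. Missing entries stay missing and do not
#' count toward `N`.
#'
#' @param expression A data frame with a `probe_id` column (plus any other
#'   non-numeric id columns, which pass through) and one numeric column
#'   per sample.
#' @return A tibble of the same shape with intensities replaced by rank
#'   scores in `[1, 100]`.
#' @examples
#' rank_transform(tibble::tibble(
#'   probe_id = c("p1", "p2", "p3"), s1 = c(5, 1, 9)))
#' @export
rank_transform <- function(expression) {
  parts <- split_sample_cols(expression, id_cols = c("probe_id", "gene_id"))
  scored <- purrr::imap(parts$values, function(x, nm) {
    ok <- is.finite(x)
    n <- sum(ok)
    if (n == 0L) {
      data_error(sprintf("sample `%s` has no finite values", nm))
    }
    bin <- ceiling(100 * seq_len(n) / n)  # score image of ranks 1..n
    # average the mapped scores over tied ranks
    r_min <- rank(x[ok], ties.method = "min")
    r_max <- rank(x[ok], ties.method = "max")
    cum <- cumsum(bin)
    score <- (cum[r_max] - c(0, cum)[r_min]) / (r_max - r_min + 1)
    out <- rep(NA_real_, length(x))
    out[ok] <- score
    out
  })
  dplyr::bind_cols(as_tibble(parts$ids), as_tibble(scored))
}

#' Average rank score (ARS) per gene and condition
#'
#' The ARS of a gene in a condition is the arithmetic mean of its rank
#' scores over that condition's samples — a platform-robust summary of
#' expression intensity, always in `[1, 100]`.
#'
#' @param rank_scores A rank-score tibble from [rank_transform()] (or
#'   [collapse_probes()]), with a `probe_id` or `gene_id` id column.
#' @param conditions A data frame with columns `sample_id`, `condition`.
#' @param min_samples Minimum non-missing samples per condition for a row
#'   to be scored (rows below it get `NA`); at least 1.
#' @return A tibble with the id column(s), `condition`, `ars`, and
#'   `n_samples` (non-missing count).
#' @export
average_rank_score <- function(rank_scores, conditions, min_samples = 1L) {
  parts <- split_sample_cols(rank_scores, id_cols = c("probe_id", "gene_id"))
  conditions <- check_conditions(conditions, parts$sample_cols)
  min_samples <- check_count(min_samples, "min_samples")
  id_cols <- names(parts$ids)
  long <- dplyr::bind_cols(as_tibble(parts$ids), as_tibble(parts$values)) |>
    tidyr::pivot_longer(dplyr::all_of(parts$sample_cols),
                        names_to = "sample_id", values_to = "score") |>
    dplyr::inner_join(conditions, by = "sample_id")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, "condition")))) |>
    dplyr::summarise(
      n_samples = sum(is.finite(.data$score)),
      ars = ifelse(.data$n_samples >= min_samples,
                   mean(.data$score, na.rm = TRUE), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::relocate("ars", .before = "n_samples")
}

check_conditions <- function(conditions, sample_cols) {
  if (!is.data.frame(conditions) ||
      !all(c("sample_id", "condition") %in% names(conditions))) {
    data_error("`conditions` needs columns `sample_id` and `condition`")
  }
  conditions <- as_tibble(conditions)[c("sample_id", "condition")]
  missing <- setdiff(sample_cols, conditions$sample_id)
  if (length(missing) > 0L) {
    data_error(paste0("samples without a condition label: ",
                      paste(head(missing, 5L), collapse = ", ")))
  }
  conditions
}

#' Collapse probes to genes by maximum pooled ARS
#'
#' When several probes measure one gene, the single probe with the highest
#' ARS pooled over *all* samples (both conditions) represents the gene, so
#' the same probe speaks for the gene in every condition. Probes without a
#' gene mapping are dropped with a warning reporting the count.
#'
#' @param rank_scores A rank-score tibble with a `probe_id` column.
#' @param probe_map A data frame with columns `probe_id`, `gene_id`;
#'   each probe must map to at most one gene.
#' @return A gene-level tibble: `gene_id`, `probe_id` (the representative
#'   probe), and the sample columns of the retained probe rows.
#' @export
collapse_probes <- function(rank_scores, probe_map) {
  if (!"probe_id" %in% names(rank_scores)) {
    data_error("`rank_scores` needs a `probe_id` column")
  }
  if (!is.data.frame(probe_map) ||
      !all(c("probe_id", "gene_id") %in% names(probe_map))) {
    data_error("`probe_map` needs columns `probe_id` and `gene_id`")
  }
  if (anyDuplicated(probe_map$probe_id) > 0L) {
    data_error("`probe_map` maps some probe to more than one gene")
  }
  parts <- split_sample_cols(rank_scores, id_cols = c("probe_id", "gene_id"))
  mapped <- rank_scores |>
    dplyr::select(-dplyr::any_of("gene_id")) |>
    dplyr::left_join(probe_map[c("probe_id", "gene_id")], by = "probe_id")
  n_unmapped <- sum(is.na(mapped$gene_id))
  if (n_unmapped > 0L) {
    warn(sprintf("dropping %d probe(s) with no gene mapping", n_unmapped))
    mapped <- dplyr::filter(mapped, !is.na(.data$gene_id))
  }
  pooled <- rowMeans(as.matrix(mapped[parts$sample_cols]), na.rm = TRUE)
  mapped |>
    dplyr::mutate(.pooled_ars = pooled) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$.pooled_ars, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id) |>
    dplyr::select("gene_id", "probe_id",
                  dplyr::all_of(parts$sample_cols))
}

#' Delta statistic: difference in average rank scores
#'
#' The screen's differential-expression statistic: ARS in the case
#' condition minus ARS in the control condition. Both arguments must lie
#' in `[1, 100]`, so the delta lies in `[-99, 99]`.
#'
#' @param ars_case,ars_control Numeric vectors of average rank scores.
#' @return `ars_case - ars_control`, vectorized.
#' @examples
#' delta_score(97.3, 45.25)  # 52.05
#' @export
delta_score <- function(ars_case, ars_control) {
  bad <- function(x) any(is.finite(x) & (x < 1 | x > 100))
  if (bad(ars_case) || bad(ars_control)) {
    data_error("average rank scores must lie in [1, 100]")
  }
  ars_case - ars_control
}

#' Per-gene score table: ARS by condition, delta, screen flag
#'
#' Computes, for every gene, the ARS in the case and control conditions,
#' the delta statistic, the screen pass flag
#' (`delta > delta_min & ars_case > ars_min`) and — when the control
#' condition has enough samples — the gene-plasticity score of the control
#' distribution (see [gpl_score()]).
#'
#' A gene needs at least `min_samples` non-missing samples in each
#' condition to be scored; otherwise its ARS values are `NA` and it cannot
#' pass the screen.
#'
#' @param rank_scores A gene-level rank-score tibble (see
#'   [collapse_probes()]; a `probe_id`-only tibble is treated as one gene
#'   per probe).
#' @param conditions A data frame with columns `sample_id`, `condition`.
#' @param case,control Condition labels to contrast.
#' @param delta_min,ars_min Screen thresholds (defaults 45 and 80).
#' @param min_samples Minimum non-missing samples per condition (default 2).
#' @param gpl Whether to attach the plasticity score of the control
#'   condition (needs >= 10 samples; `NA` otherwise).
#' @return A tibble `gene_id`, `ars_case`, `ars_control`, `delta`, `pass`
#'   (and `gpl`), one row per gene.
#' @export
gene_score_table <- function(rank_scores, conditions,
                             case = "case", control = "control",
                             delta_min = 45, ars_min = 80,
                             min_samples = 2L, gpl = FALSE) {
  if (!"gene_id" %in% names(rank_scores)) {
    rank_scores <- dplyr::rename(rank_scores, gene_id = "probe_id")
  }
  ars <- average_rank_score(
    dplyr::select(rank_scores, -dplyr::any_of("probe_id")),
    conditions, min_samples = min_samples)
  both <- c(case, control)
  missing_cond <- setdiff(both, unique(ars$condition))
  if (length(missing_cond) > 0L) {
    data_error(paste0("condition(s) not present: ",
                      paste(missing_cond, collapse = ", ")))
  }
  wide <- ars |>
    dplyr::filter(.data$condition %in% both) |>
    dplyr::mutate(condition = ifelse(.data$condition == case,
                                     "ars_case", "ars_control")) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "condition",
                       values_from = "ars") |>
    dplyr::mutate(
      delta = .data$ars_case - .data$ars_control,
      pass = !is.na(.data$delta) & .data$delta > delta_min &
        .data$ars_case > ars_min
    )
  if (gpl) {
    parts <- split_sample_cols(rank_scores,
                               id_cols = c("probe_id", "gene_id"))
    ctrl_samples <- conditions$sample_id[conditions$condition == control]
    ctrl <- as.matrix(rank_scores[intersect(parts$sample_cols,
                                            ctrl_samples)])
    gpl_vals <- apply(ctrl, 1L, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 10L) NA_real_ else
        unname(diff(quantile(x, c(0.1, 0.9))))
    })
    wide <- dplyr::left_join(
      wide, tibble(gene_id = rank_scores$gene_id, gpl = gpl_vals),
      by = "gene_id")
  }
  dplyr::arrange(wide, .data$gene_id)
}

#' Screen genes on delta and case ARS thresholds
#'
#' Retains genes with `delta > delta_min` and `ars_case > ars_min`
#' (strict inequalities), sorted by case ARS descending with delta as the
#' tie-break — the ordering in which screen tables are reported.
#'
#' @param score_table A tibble from [gene_score_table()] (needs columns
#'   `gene_id`, `ars_case`, `delta`).
#' @param delta_min,ars_min Thresholds; defaults 45 and 80.
#' @return The retained rows, ranked.
#' @export
screen_genes <- function(score_table, delta_min = 45, ars_min = 80) {
  if (!is.data.frame(score_table) || nrow(score_table) == 0L) {
    data_error("`score_table` must be a non-empty data frame")
  }
  check_number(delta_min, "delta_min", min = -99, max = 100)
  check_number(ars_min, "ars_min", min = 0, max = 100)
  score_table |>
    dplyr::filter(!is.na(.data$delta), !is.na(.data$ars_case),
                  .data$delta > delta_min, .data$ars_case > ars_min) |>
    dplyr::arrange(dplyr::desc(.data$ars_case), dplyr::desc(.data$delta))
}

#' Rank-based expression (RBE) curve of a gene
#'
#' The RBE curve shows, per condition, the proportion of samples whose
#' rank score falls at each score 1..100 — a rank-scale picture of the
#' expression distribution in which a right-shifted peak means high
#' expression. Raw proportions sum to one per condition; an optional
#' Gaussian kernel (default bandwidth 3 rank units) smooths the curve for
#' display.
#'
#' @param rank_scores A rank-score tibble with `probe_id` or `gene_id`.
#' @param conditions A data frame with columns `sample_id`, `condition`.
#' @param gene The `gene_id` (or `probe_id`) of the row to plot.
#' @param bandwidth Gaussian kernel bandwidth in rank units (0 disables
#'   smoothing).
#' @return A tibble of class `rbe_curve`: `condition`, `score` (1..100),
#'   `proportion` (raw) and `smoothed`.
#' @export
rbe_curve <- function(rank_scores, conditions, gene, bandwidth = 3) {
  id_col <- if ("gene_id" %in% names(rank_scores)) "gene_id" else "probe_id"
  row <- rank_scores[rank_scores[[id_col]] == gene, , drop = FALSE]
  if (nrow(row) == 0L) data_error(sprintf("gene `%s` not found", gene))
  if (nrow(row) > 1L) row <- row[1L, , drop = FALSE]
  check_number(bandwidth, "bandwidth", min = 0)
  parts <- split_sample_cols(row, id_cols = c("probe_id", "gene_id"))
  conditions <- check_conditions(conditions, parts$sample_cols)
  scores <- unlist(parts$values, use.names = TRUE)
  cond_of <- conditions$condition[match(names(scores),
                                        conditions$sample_id)]
  grid <- 1:100
  out <- purrr::map(unique(cond_of), function(cc) {
    x <- scores[cond_of == cc]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      warn(sprintf(
        "condition `%s` has fewer than 2 samples; raw counts only", cc))
    }
    counts <- tabulate(pmin(pmax(round(x), 1L), 100L), nbins = 100L)
    prop <- counts / sum(counts)
    smoothed <- if (bandwidth > 0 && length(x) >= 2L) {
      w <- outer(grid, grid, function(s, t) dnorm(s - t, sd = bandwidth))
      w <- w / rowSums(w)  # renormalize at the 1/100 boundaries
      as.numeric(w %*% prop)
    } else prop
    tibble(condition = cc, score = grid, proportion = prop,
           smoothed = smoothed)
  }) |>
    dplyr::bind_rows()
  class(out) <- c("rbe_curve", class(out))
  attr(out, "gene") <- gene
  out
}

#' Gene-plasticity (spread) score of a rank-score distribution
#'
#' Summarizes how variable ("plastic") a gene's expression rank is across
#' a condition's samples. The default formula is a documented stand-in —
#' the width of the central 80% of the rank-score distribution, i.e.
#' `quantile(0.9) - quantile(0.1)` — and is configurable through `probs`;
#' it has **not** been validated against any published plasticity value
#' and should be read as a relative spread measure only.
#'
#' @param rank_scores A rank-score tibble with `probe_id` or `gene_id`.
#' @param conditions A data frame with columns `sample_id`, `condition`.
#' @param gene The gene to score.
#' @param condition The condition whose distribution is summarized.
#' @param probs Lower/upper quantiles delimiting the central mass
#'   (default `c(0.1, 0.9)`).
#' @return A single non-negative number (0 for a constant gene).
#' @export
gpl_score <- function(rank_scores, conditions, gene,
                      condition = "control", probs = c(0.1, 0.9)) {
  if (length(probs) != 2L || any(!is.finite(probs)) ||
      probs[1] >= probs[2] || any(probs < 0) || any(probs > 1)) {
    config_error("`probs` must be two increasing values in [0, 1]")
  }
  id_col <- if ("gene_id" %in% names(rank_scores)) "gene_id" else "probe_id"
  row <- rank_scores[rank_scores[[id_col]] == gene, , drop = FALSE]
  if (nrow(row) == 0L) data_error(sprintf("gene `%s` not found", gene))
  parts <- split_sample_cols(row[1L, ], id_cols = c("probe_id", "gene_id"))
  conditions <- check_conditions(conditions, parts$sample_cols)
  keep <- conditions$sample_id[conditions$condition == condition]
  x <- unlist(parts$values[intersect(parts$sample_cols, keep)])
  x <- x[is.finite(x)]
  if (length(x) < 10L) {
    data_error(sprintf(
      "condition `%s` has %d samples; >= 10 required for a plasticity score",
      condition, length(x)))
  }
  unname(diff(quantile(x, probs)))
}
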