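#' Describe a per-sample monotone platform distortion
#'
#' Microarray platforms measure the same transcript abundances on different,
#' platform-specific intensity scales. As long as a platform's response is
#' strictly increasing in abundance, within-sample ranks — and hence every
#' rank-based statistic in this package — are unchanged. The simulator
#' emulates platform effects with the strictly increasing family
#' \deqn{g(x) = a + b x + c\,\mathrm{sign}(x)|x|^p,\qquad b > 0,\ c \ge 0,\ p \ge 1,}
#' an affine map plus an optional signed power term. Parameters may be
#' scalars (one distortion for all samples) or vectors recycled per sample.
#'
#' @param a Intercept(s); any real value.
#' @param b Linear slope(s); must be strictly positive.
#' @param c Power-term weight(s); must be non-negative.
#' @param p Power exponent(s); must be >= 1 so the map stays strictly
#'   increasing on all of the real line.
#' @return An object of class `distortion_spec`.
#' @examples
#' d <- distortion_spec(a = 10, b = 2, c = 0.5, p = 1.5)
#' @export
distortion_spec <- function(a = 0, b = 1, c = 0, p = 1) {
  if (!all(is.finite(a), is.finite(b), is.finite(c), is.finite(p))) {
    config_error("distortion parameters must be finite")
  }
  if (any(b <= 0) || any(c < 0) || any(p < 1)) {
    config_error(paste0(
      "distortion must be strictly increasing: require b > 0, c >= 0, p >= 1"))
  }
  structure(list(family = "affine_power", a = a, b = b, c = c, p = p),
            class = "distortion_spec")
}

apply_distortion <- function(values, spec, n_samples) {
  par <- lapply(spec[c("a", "b", "c", "p")], rep_len, n_samples)
  for (j in seq_len(n_samples)) {
    x <- values[[j]]
    values[[j]] <- par$a[j] + par$b[j] * x +
      par$c[j] * sign(x) * abs(x)^par$p[j]
  }
  values
}

# draw one random affine-power distortion per sample (used by
# distortion = "random"); scales/offsets span a generous platform-like range
random_distortion <- function(n_samples) {
  distortion_spec(
    a = rnorm(n_samples, 0, 50),
    b = runif(n_samples, 0.5, 3),
    c = runif(n_samples, 0, 0.5),
    p = runif(n_samples, 1, 2)
  )
}

#' Specify a two-condition synthetic expression cohort
#'
#' Defines the simulation used throughout the package's tests: two compared
#' populations (diseased cases vs. normal controls), gene-wise log-normal
#' intensity baselines, a configurable number of probes per gene, spiked
#' "effect" genes whose log-intensity is shifted upward in cases, and an
#' optional strictly increasing per-sample distortion standing in for
#' platform differences.
#'
#' @param n_case,n_control Samples per condition; each must be >= 2.
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes measuring each gene (>= 1).
#' @param effect_genes Data frame with columns `gene` (index in
#'   `1:n_genes` or a gene id like `"g0007"`) and `shift` (upward case
#'   shift in units of `noise_sd` on the log-intensity scale), or `NULL`
#'   for a global null.
#' @param noise_sd Standard deviation of the log-intensity noise.
#' @param distortion `NULL` (no distortion), a [distortion_spec()], or
#'   `"random"` to draw one distortion per sample from the seed.
#' @param seed Integer seed; identical specs give byte-identical cohorts.
#' @return An object of class `expression_sim_spec`.
#' @seealso [gen_expression()]
#' @export
expression_sim_spec <- function(n_case = 50, n_control = 50,
                                n_genes = 1000, probes_per_gene = 1,
                                effect_genes = NULL, noise_sd = 1,
                                distortion = NULL, seed = 1L) {
  spec <- list(
    n_case = check_count(n_case, "n_case", min = 2L),
    n_control = check_count(n_control, "n_control", min = 2L),
    n_genes = check_count(n_genes, "n_genes"),
    probes_per_gene = check_count(probes_per_gene, "probes_per_gene"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (!is.null(effect_genes)) {
    if (!is.data.frame(effect_genes) ||
        !all(c("gene", "shift") %in% names(effect_genes))) {
      config_error("`effect_genes` needs columns `gene` and `shift`")
    }
    if (any(!is.finite(effect_genes$shift))) {
      config_error("effect-gene shifts must be finite")
    }
  }
  spec$effect_genes <- effect_genes
  if (is.character(distortion) && identical(distortion, "random")) {
    spec$distortion <- "random"
  } else if (!is.null(distortion) && !inherits(distortion, "distortion_spec")) {
    config_error(
      "`distortion` must be NULL, \"random\", or a distortion_spec()")
  } else {
    spec$distortion <- distortion
  }
  structure(spec, class = "expression_sim_spec")
}

gene_label <- function(i, n) sprintf("g%0*d", max(4L, nchar(n)), i)

#' Generate a synthetic two-condition expression cohort
#'
#' Intensities are drawn gene-wise from a log-normal baseline (meanlog drawn
#' once per gene, probe-specific offsets layered on top), effect genes are
#' shifted upward in cases on the log scale by `shift * noise_sd`, and each
#' sample's intensities are finally passed through its (strictly increasing)
#' distortion. Because every downstream statistic is rank-based, the
#' distortion changes intensities but never the analysis result.
#'
#' @param spec An [expression_sim_spec()].
#' @return A list of class `expression_cohort` with elements
#'   \describe{
#'     \item{expression}{tibble: `probe_id` plus one numeric column per
#'       sample (intensities).}
#'     \item{probe_map}{tibble: `probe_id`, `gene_id`.}
#'     \item{conditions}{tibble: `sample_id`, `condition`
#'       (`"case"`/`"control"`).}
#'     \item{truth}{tibble of spiked genes: `gene_id`, `shift`.}
#'   }
#' @examples
#' cohort <- gen_expression(expression_sim_spec(
#'   n_case = 5, n_control = 5, n_genes = 20, seed = 7))
#' dim(cohort$expression)
#' @export
gen_expression <- function(spec) {
  if (!inherits(spec, "expression_sim_spec")) {
    config_error("`spec` must come from expression_sim_spec()")
  }
  set.seed(spec$seed)
  n_s <- spec$n_case + spec$n_control
  gene_ids <- gene_label(seq_len(spec$n_genes), spec$n_genes)
  probe_map <- tidyr::expand_grid(
    gene_id = gene_ids,
    probe = seq_len(spec$probes_per_gene)
  ) |>
    dplyr::mutate(probe_id = paste0(.data$gene_id, "_p", .data$probe)) |>
    dplyr::select("probe_id", "gene_id")
  n_p <- nrow(probe_map)

  sample_ids <- c(sprintf("case_%03d", seq_len(spec$n_case)),
                  sprintf("control_%03d", seq_len(spec$n_control)))
  condition <- rep(c("case", "control"), c(spec$n_case, spec$n_control))

  meanlog <- rnorm(spec$n_genes, mean = 4, sd = 1)
  probe_offset <- rnorm(n_p, mean = 0, sd = 0.25)

  shift <- numeric(spec$n_genes)
  truth <- tibble(gene_id = character(), shift = numeric())
  if (!is.null(spec$effect_genes) && nrow(spec$effect_genes) > 0L) {
    idx <- spec$effect_genes$gene
    if (is.character(idx)) idx <- match(idx, gene_ids)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > spec$n_genes)) {
      config_error("effect genes outside 1..n_genes")
    }
    shift[idx] <- spec$effect_genes$shift
    truth <- tibble(gene_id = gene_ids[idx], shift = spec$effect_genes$shift)
  }

  gene_of_probe <- match(probe_map$gene_id, gene_ids)
  log_base <- meanlog[gene_of_probe] + probe_offset
  is_case <- condition == "case"

  log_int <- matrix(rnorm(n_p * n_s, sd = spec$noise_sd), n_p, n_s)
  log_int <- log_int + log_base
  log_int[, is_case] <- log_int[, is_case] +
    shift[gene_of_probe] * spec$noise_sd

  values <- as.data.frame(exp(log_int))
  names(values) <- sample_ids

  dist <- spec$distortion
  if (identical(dist, "random")) dist <- random_distortion(n_s)
  if (!is.null(dist)) values <- apply_distortion(values, dist, n_s)

  structure(list(
    expression = dplyr::bind_cols(tibble(probe_id = probe_map$probe_id),
                                  as_tibble(values)),
    probe_map = probe_map,
    conditions = tibble(sample_id = sample_ids, condition = condition),
    truth = truth
  ), class = "expression_cohort")
}
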