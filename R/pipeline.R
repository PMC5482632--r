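#' Run the full screening and outcome pipeline
#'
#' Orchestrates the stages in analysis order: read inputs, rank-transform,
#' collapse probes, score and screen genes, draw the top gene's RBE curve,
#' then — when a clinical table is supplied — ROC/cutoff evaluation of the
#' transcript level, dichotomization, per-group Kaplan-Meier and
#' cumulative-incidence estimates with log-rank and Gray tests, and a Cox
#' model with backward elimination. All tabular outputs are written under
#' `out_dir` (TSV/CSV/JSON) together with a run log recording package
#' version and parameters; a given config and seed always produce
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()] (or the list/YAML equivalent).
#' @return Invisibly, a list with the in-memory results: `score_table`,
#'   `screened`, `rbe`, and when clinical data is present `roc`, `groups`,
#'   `km`, `cif`, `logrank`, `gray`, `cox`, `elimination`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  set.seed(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("rankscreen %s", as.character(packageVersion("rankscreen"))),
    sprintf("seed: %d", config$seed),
    sprintf("thresholds: delta_min=%g ars_min=%g", config$delta_min,
            config$ars_min),
    sprintf("rbe_bandwidth: %g", config$rbe_bandwidth),
    sprintf("dichotomize: %s", paste(config$dichotomize, collapse = "")),
    sprintf("t_star: %g months; ties: %s; keep_alpha: %g", config$t_star,
            config$ties, config$keep_alpha),
    sprintf("rfs_events: %s", paste(config$rfs_events, collapse = "+")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "rankscreen_pipeline_error")
    })
  }
  results <- list()

  # --- screen ---------------------------------------------------------
  expr <- stage("read_expression", read_expression(config$expression_path))
  probe_map <- stage("read_probe_map", read_probe_map(config$probe_map_path))
  conditions <- stage("read_conditions",
                      read_conditions(config$conditions_path))
  ranked <- stage("rank_transform", rank_transform(expr))
  collapsed <- stage("collapse_probes", collapse_probes(ranked, probe_map))
  score_table <- stage("gene_score_table", gene_score_table(
    collapsed, conditions, case = config$case, control = config$control,
    delta_min = config$delta_min, ars_min = config$ars_min, gpl = TRUE))
  screened <- stage("screen_genes", screen_genes(
    score_table, delta_min = config$delta_min, ars_min = config$ars_min))
  readr::write_tsv(score_table, file.path(out_dir, "score_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(screened, file.path(out_dir, "screened_genes.tsv"),
                   progress = FALSE)
  log_lines <- c(log_lines, sprintf("genes scored: %d; genes retained: %d",
                                    nrow(score_table), nrow(screened)))
  results$score_table <- score_table
  results$screened <- screened

  if (nrow(screened) > 0L) {
    top_gene <- screened$gene_id[1L]
    rbe <- stage("rbe_curve", rbe_curve(
      collapsed, conditions, top_gene, bandwidth = config$rbe_bandwidth))
    readr::write_tsv(rbe, file.path(out_dir, "rbe_top_gene.tsv"),
                     progress = FALSE)
    log_lines <- c(log_lines, sprintf("top gene: %s", top_gene))
    results$rbe <- rbe
  }

  # --- clinical evaluation -------------------------------------------
  if (!is.null(config$clinical_path)) {
    clinical <- stage("read_clinical", read_clinical(config$clinical_path))
    if (!"transcript_level" %in% names(clinical)) {
      abort("pipeline stage `clinical` failed: no `transcript_level` column",
            class = "rankscreen_pipeline_error")
    }
    lv <- clinical$transcript_level

    cutoff <- NULL
    if (is.numeric(config$dichotomize)) {
      cutoff <- config$dichotomize
      grp <- factor(ifelse(lv > cutoff, "high", "low"),
                    levels = c("low", "high"))
    } else if (config$dichotomize == "youden") {
      normals <- stage("read_normals", readr::read_csv(
        config$normal_levels_path, show_col_types = FALSE,
        progress = FALSE))
      roc <- stage("roc_auc", roc_auc(lv, normals[[1L]]))
      cutoff <- youden_cutoff(roc)
      grp <- factor(ifelse(lv >= cutoff, "high", "low"),
                    levels = c("low", "high"))
      readr::write_tsv(tidy(roc), file.path(out_dir, "roc_points.tsv"),
                       progress = FALSE)
      jsonlite::write_json(as.list(glance(roc)),
                           file.path(out_dir, "roc_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      results$roc <- roc
    } else {
      grp <- stage("dichotomize_median", dichotomize_median(lv))
    }
    clinical$group <- grp
    results$groups <- grp
    log_lines <- c(log_lines, sprintf(
      "groups: low=%d high=%d%s", sum(grp == "low"), sum(grp == "high"),
      if (!is.null(cutoff)) sprintf(" (cutoff %g)", cutoff) else ""))

    km_steps <- purrr::map(levels(grp), function(gl) {
      f <- km_fit(clinical[clinical$group == gl, , drop = FALSE],
                  rfs_events = config$rfs_events)
      dplyr::mutate(tidy(f), group = gl, .before = 1L)
    })
    readr::write_tsv(dplyr::bind_rows(km_steps),
                     file.path(out_dir, "km_by_group.tsv"),
                     progress = FALSE)
    results$km <- km_steps

    cif <- stage("cif_fit", cif_fit(clinical))
    readr::write_tsv(tidy(cif), file.path(out_dir, "cif_overall.tsv"),
                     progress = FALSE)
    results$cif <- cif

    lr <- stage("logrank", logrank(clinical, "group",
                                   rfs_events = config$rfs_events))
    gr <- stage("gray_test", gray_test(clinical, "group"))
    results$logrank <- lr
    results$gray <- gr

    covs <- union("group", config$covariates)
    cox <- stage("cox_fit", cox_fit(clinical, covs, outcome = "relapse",
                                    ties = config$ties))
    elim <- stage("backward_eliminate", backward_eliminate(
      clinical, covs, keep_alpha = config$keep_alpha,
      outcome = "relapse", ties = config$ties))
    report <- list(
      logrank = as.list(lr),
      gray = purrr::transpose(gr),
      cox_full = purrr::transpose(tidy(cox)),
      elimination_trace = purrr::transpose(elim$trace),
      cox_final = if (is.null(elim$fit)) list() else
        purrr::transpose(tidy(elim$fit)),
      cir_at_t_star = as.list(point_estimate_at(cif, config$t_star)),
      t_star = config$t_star
    )
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
                         auto_unbox = TRUE, digits = NA)
    results$cox <- cox
    results$elimination <- elim
    log_lines <- c(log_lines, sprintf(
      "cox: %d covariates in, %d retained", length(covs),
      length(elim$covariates)))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
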