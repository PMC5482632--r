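#' Read a tab-delimited expression matrix
#'
#' Expects probes as rows and samples as columns: a header row of sample
#' ids, first column the probe id. Duplicate probe ids or sample headers,
#' ragged rows and non-numeric cells are rejected with informative errors.
#'
#' @param path Path to the TSV file.
#' @return A tibble: `probe_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  raw <- suppressWarnings(suppressMessages(
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)))
  if (ncol(raw) < 2L) data_error("expected a probe id column plus samples")
  header <- names(raw)
  dup_s <- unique(header[duplicated(header)])
  # readr de-duplicates repeated headers as name...k; catch those too
  mangled <- grepl("\\.\\.\\.[0-9]+$", header)
  if (length(dup_s) > 0L || any(mangled)) {
    data_error(paste0("duplicated sample header(s): ",
                      paste(unique(c(dup_s, sub("\\.\\.\\.[0-9]+$", "",
                                                header[mangled]))),
                            collapse = ", ")))
  }
  names(raw)[1L] <- "probe_id"
  dup_p <- unique(raw$probe_id[duplicated(raw$probe_id)])
  if (length(dup_p) > 0L) {
    data_error(paste0("duplicated probe id(s): ",
                      paste(head(dup_p, 5L), collapse = ", ")))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    data_error(paste0("malformed rows at line(s): ",
                      paste(head(unique(prob$row), 5L), collapse = ", ")))
  }
  for (j in setdiff(names(raw), "probe_id")) {
    x <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.na(raw[[j]]) & raw[[j]] != "" & is.na(x))
    if (length(bad) > 0L) {
      data_error(sprintf(
        "non-numeric cell(s) in column `%s` at data line(s) %s",
        j, paste(head(bad, 5L), collapse = ", ")))
    }
    raw[[j]] <- x
  }
  raw
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expression A tibble with `probe_id` plus numeric sample columns
#'   (a `gene_id` column, if present, is dropped: gene annotation lives in
#'   the probe map).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  split_sample_cols(expression, id_cols = c("probe_id", "gene_id"))
  out <- expression |>
    dplyr::select(-dplyr::any_of("gene_id")) |>
    dplyr::relocate("probe_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a two-column probe-to-gene annotation table
#'
#' @param path TSV path with columns `probe_id`, `gene_id`.
#' @return A tibble.
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(pm))) {
    names(pm)[1:2] <- c("probe_id", "gene_id")
  }
  pm[c("probe_id", "gene_id")]
}

#' @rdname read_probe_map
#' @param probe_map The annotation tibble.
#' @export
write_probe_map <- function(probe_map, path) {
  readr::write_tsv(probe_map[c("probe_id", "gene_id")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read / write sample condition labels
#'
#' @param path CSV path with columns `sample_id`, `condition`.
#' @return A tibble.
#' @export
read_conditions <- function(path) {
  readr::read_csv(path, col_types = "cc", progress = FALSE)
}

#' @rdname read_conditions
#' @param conditions The condition tibble.
#' @export
write_conditions <- function(conditions, path) {
  readr::write_csv(conditions[c("sample_id", "condition")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a clinical cohort CSV
#'
#' Requires columns `time` (positive months) and `event` (one of
#' `relapse` / `death` / `censored`); any other columns (subject ids,
#' transcript levels, covariates) pass through. Unknown event codes and
#' non-positive times are rejected.
#'
#' @param path CSV path.
#' @return A typed tibble with `event` as a factor.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_records(raw)
}

#' @rdname read_clinical
#' @param cohort The cohort tibble.
#' @export
write_clinical <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration for [run_pipeline()]. Recognized keys
#' (with defaults): input paths `expression_path`, `probe_map_path`,
#' `conditions_path`, optional `clinical_path` and `normal_levels_path`;
#' `case` / `control` condition labels; screen thresholds `delta_min`
#' (45) and `ars_min` (80); `rbe_bandwidth` (3); `dichotomize`
#' (`"median"`, `"youden"` or a fixed numeric cutoff); survival settings
#' `t_star` (60 months), `ties` (`"efron"`), `keep_alpha` (0.1),
#' `rfs_events`; `covariates`; `seed`; `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A named list of settings (see above).
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    expression_path = NULL, probe_map_path = NULL, conditions_path = NULL,
    clinical_path = NULL, normal_levels_path = NULL,
    case = "case", control = "control",
    delta_min = 45, ars_min = 80, rbe_bandwidth = 3,
    dichotomize = "median",
    t_star = 60, ties = "efron", keep_alpha = 0.1,
    rfs_events = c("relapse", "death"),
    covariates = character(), seed = 1L, out_dir = "."
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    config_error(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  check_number(cfg$delta_min, "delta_min", min = -100, max = 100)
  check_number(cfg$ars_min, "ars_min", min = 0, max = 100)
  check_number(cfg$keep_alpha, "keep_alpha", min = 1e-12, max = 1 - 1e-12)
  check_number(cfg$t_star, "t_star", min = 0)
  check_number(cfg$rbe_bandwidth, "rbe_bandwidth", min = 0)
  if (!(is.numeric(cfg$dichotomize) ||
        cfg$dichotomize %in% c("median", "youden"))) {
    config_error(
      "`dichotomize` must be \"median\", \"youden\" or a fixed number")
  }
  structure(cfg, class = "pipeline_config")
}
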