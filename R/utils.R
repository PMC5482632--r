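# internal helpers: argument checking and error classes

config_error <- function(msg) {
  abort(msg, class = "rankscreen_config_error")
}

data_error <- function(msg) {
  abort(msg, class = "rankscreen_data_error")
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    config_error(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < min || x > max) {
    config_error(sprintf("`%s` must be a single number in [%s, %s]",
                         name, format(min), format(max)))
  }
  as.numeric(x)
}

# split an expression tibble into its id columns and its numeric sample block
split_sample_cols <- function(x, id_cols = "probe_id") {
  if (!is.data.frame(x)) data_error("expected a data frame of intensities")
  id_cols <- intersect(id_cols, names(x))
  sample_cols <- setdiff(names(x), id_cols)
  if (length(sample_cols) == 0L) data_error("no sample columns found")
  bad <- sample_cols[!vapply(x[sample_cols], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    data_error(paste0("non-numeric sample columns: ",
                      paste(bad, collapse = ", ")))
  }
  list(ids = x[id_cols], values = x[sample_cols], sample_cols = sample_cols)
}

event_levels <- function() c("relapse", "death", "censored")

check_records <- function(records, require_cols = c("time", "event")) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    data_error("`records` must be a data frame with at least one row")
  }
  missing_cols <- setdiff(require_cols, names(records))
  if (length(missing_cols) > 0L) {
    data_error(paste0("`records` is missing columns: ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    data_error("all `time` values must be finite and positive")
  }
  ev <- as.character(records$event)
  unknown <- setdiff(unique(ev), event_levels())
  if (length(unknown) > 0L) {
    data_error(paste0("unknown event code(s): ",
                      paste(unknown, collapse = ", "),
                      " (expected relapse/death/censored)"))
  }
  records$event <- factor(ev, levels = event_levels())
  records
}
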