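#' Published top-20 differential screen table
#'
#' The bundled screen table of the 20 genes most over-expressed in adult
#' B-cell ALL relative to normal B cells, as selected by the
#' `delta > 45 & ARS > 80` screen on rank-normalized microarray cohorts.
#' Columns give the average rank score in the disease (`ars_case`) and
#' normal (`ars_control`) conditions, their difference (`delta`), the
#' same three quantities after a cohort update (`*_updated`), and the ARS
#' in chronic lymphocytic leukemia B cells (`ars_cll`) as an
#' out-of-disease comparator.
#'
#' @return A 20-row tibble.
#' @examples
#' screen_genes(published_screen_table())
#' @export
published_screen_table <- function() {
  readr::read_tsv(
    system.file("extdata", "top20_ars_table.tsv", package = "rankscreen"),
    col_types = "ciddddddd", progress = FALSE) |>
    dplyr::rename(gene_id = "gene")
}
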