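#' Published chromosome-level linkage-map summary for Atlantic salmon
#'
#' The chromosome-level sex-specific linkage-map summary reported for a
#' Norwegian Atlantic salmon breeding population (29 autosomes, physical
#' lengths from Ssal_v3.1): marker counts, physical length (Mb), male and
#' female map length (cM), female/male ratio and cM/Mb rates.  Bundled as
#' reference input for aggregation checks.
#'
#' @return data frame with 29 rows.
#' @export
salmon_map_table <- function() {
  utils::read.delim(system.file("extdata", "salmon_map_table.tsv",
                                package = "meiomap", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published per-sex recombination trait summary for Atlantic salmon
#'
#' Reported descriptive and variance-component summary for crossover
#' count (CC) and intra-chromosomal shuffling (rbar) by sex: numbers of
#' FIDs and meioses, trait mean and SD, heritability with its standard
#' error, phenotypic and residual variances.
#'
#' @return data frame with 4 rows (trait x sex).
#' @export
salmon_trait_table <- function() {
  utils::read.delim(system.file("extdata", "salmon_trait_summary.tsv",
                                package = "meiomap", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
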