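#' Published reference tables for the worked study system
#'
#' Returns the packaged transcriptions of the published summary tables for
#' the *Parthenium hysterophorus* MaxEnt study system that this pipeline
#' reproduces in miniature: the selected bioclimatic variables and their
#' averaged model contributions, the model evaluation scores before and
#' after spatial rarefaction, the per-continent habitat-change percentages,
#' and the per-administrative-division suitable-area projections for South
#' Korea under SSP2-4.5 and SSP5-8.5. These are *reference data*, not
#' outputs of this package; they back arithmetic consistency checks and the
#' worked examples.
#'
#' @return A list of tibbles: `table1` (variable contributions), `table2`
#'   (evaluation scores), `table3` (continent percent changes), `table5`
#'   (South-Korea AD areas in km^2).
#' @export
reference_tables <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "maxentsdm",
                        mustWork = TRUE)
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
  }
  list(
    table1 = rd("table1_variable_contributions.csv"),
    table2 = rd("table2_evaluation_scores.csv"),
    table3 = rd("table3_continent_change.csv"),
    table5 = rd("table5_korea_ad_areas.csv")
  )
}
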