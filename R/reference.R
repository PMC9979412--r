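#' Published reference estimates for the worked-example arithmetic
#'
#' `reference_estimates()` returns the published sex-specific CVD-free
#' life expectancies at age 40 (years, restricted at age 81) by sleep
#' category and clinical sleep disorder from the UK Biobank cohort
#' analysis this package re-implements; `reference_counts()` returns the
#' published baseline participant counts per sleep category and sex.
#' These are inputs for worked examples and acceptance checks (e.g.
#' recomputing years of life lost from the published expectancies with
#' [years_of_life_lost()]); the package's estimators never read them.
#'
#' @return data.frames read from the CSV files under
#'   `inst/extdata/`: estimates with columns `sex`, `exposure`, `label`,
#'   `reference`, `e_free`; counts with columns `sex`, `category`, `n`.
#' @export
reference_estimates <- function() {
  read.csv(system.file("extdata", "reference_estimates.csv",
                       package = "sleeple"),
           stringsAsFactors = FALSE, na.strings = "")
}

#' @rdname reference_estimates
#' @export
reference_counts <- function() {
  read.csv(system.file("extdata", "reference_counts.csv",
                       package = "sleeple"),
           stringsAsFactors = FALSE)
}
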