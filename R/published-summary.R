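#' Published genetic-variability summary of the bluegrass drought trial
#'
#' The printed per-environment summary statistics of the 100-ecotype
#' Kentucky bluegrass irrigation trial this package is modelled on: trait
#' mean (with its standard error), GCV, PCV, broad-sense heritability,
#' genetic advance and GAM for each of seven traits in each year (2018,
#' 2019) and irrigation regime (non-stress control, 50% deficit drought).
#' These published values calibrate [paper_trial_spec()] and let the
#' internal arithmetic of the summary statistics (e.g.
#' `h2 = 100 * (GCV/PCV)^2`, `GAM = 100 * GA / mean`) be re-derived without
#' the raw plot data, which were never released in machine-readable form.
#'
#' Traits: FY/DY fresh and dry forage yield (g/plot), A net photosynthesis
#' rate (umol m-2 s-1), gs stomatal conductance (mol m-2 s-1), Tr
#' transpiration rate (mmol m-2 s-1), Chl chlorophyll content (mg g-1),
#' FvFm photochemical efficiency (ratio).
#'
#' @return A tibble with columns `trait`, `year`, `regime`, `mean`, `se`,
#'   `gcv`, `pcv`, `h2`, `ga`, `gam` (28 rows).
#' @export
bluegrass_summary <- function() {
  path <- system.file("extdata", "bluegrass_summary.tsv", package = "forageQG",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    trait = "c", year = "c", regime = "c",
                    .default = readr::col_double()
                  ))
}
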