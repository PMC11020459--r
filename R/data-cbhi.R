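#' Published CV summary for zone-level CBHI coverage
#'
#' The published zone-level analysis of community-based health insurance
#' coverage in Ethiopia (2019 EMDHS survey with 2007 census auxiliaries)
#' reports a six-row summary of the percent CVs of the direct and
#' hierarchical-Bayes estimates over the 77 sampled zones.  The table is
#' shipped here so the efficiency-gain convention implemented in
#' [cv_comparison_table()] can be checked against those printed cells;
#' the underlying microdata are access-restricted and not included.
#'
#' @return Data frame with columns `quantity` (Minimum, 1st quartile,
#'   Median, Mean, 3rd quartile, Maximum), `direct_cv`, `hb_cv`.
#' @export
cbhi_cv_summary <- function() {
  path <- system.file("extdata", "cbhi_cv_summary.csv", package = "zonesae",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
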