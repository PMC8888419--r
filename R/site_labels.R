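#' Per-site risk labels of the confirmed phylloxera sites
#'
#' The published validation of the statewide risk map reported, for 23
#' vineyard sites with confirmed phylloxera infestations, how many fell in
#' each single-factor risk class: 22 sites high and 1 moderate by sand
#' content, 10 high and 13 low by soil temperature. Because the one
#' moderate-sand site was also temperature-low, those marginal counts
#' determine the full per-site label table, which this function returns
#' (site ids are arbitrary — the real site locations are confidential).
#' Feeding the table through [combine_risk()] and [tally()] reproduces the
#' published combined-risk validation.
#'
#' @return data frame with columns `site_id`, `sand_risk`, `temp_risk`
#'   (23 rows).
#' @export
confirmed_site_labels <- function() {
  utils::read.csv(system.file("extdata", "confirmed_site_labels.csv",
                              package = "phylrisk"),
                  stringsAsFactors = FALSE)
}
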