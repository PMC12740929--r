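#' Published roflumilast report counts shipped with the package
#'
#' Small reference tables of report counts from a published roflumilast
#' pharmacovigilance analysis of FAERS (2004-2025Q1): sex and outcome
#' counts, time-to-onset bin counts, cumulative adverse-event counts per
#' System Organ Class, positive-signal PT-category counts per SOC, and the
#' most frequent signal's printed ROR confidence interval. They serve as
#' worked-example inputs: the package's summary functions recompute the
#' published percentages from these counts.
#'
#' @param name one of `"sex_counts"`, `"outcome_counts"`,
#'   `"tto_bin_counts"`, `"soc_event_counts"`, `"soc_signal_pt_counts"`,
#'   `"reference_signal"`.
#' @return data.frame.
#' @examples
#' published_counts("sex_counts")
#' @export
published_counts <- function(name = c("sex_counts", "outcome_counts",
                                      "tto_bin_counts", "soc_event_counts",
                                      "soc_signal_pt_counts",
                                      "reference_signal")) {
  name <- match.arg(name)
  path <- system.file("extdata", "published_counts",
                      paste0(name, ".csv"), package = "faersignal")
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
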