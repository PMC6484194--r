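#' Published per-subject MSE reference table
#'
#' Loads the per-subject MSE values reported by a published 21-subject
#' test-retest resting-state analysis of the precentral gyrus (two sessions
#' of 74 time points each, Fisher-Z scale), shipped with the package as a
#' plain-text table. Columns: `subject`, `mse_raw`, `mse_mean`,
#' `mse_shrinkage`. Useful for checking the evaluation-summary arithmetic
#' (percent reductions, extremes, boxplot outliers) against reported
#' results.
#'
#' @param include_average Keep the reported `Average` row (the source's own
#'   across-subject averages, computed before rounding, so they differ in
#'   the fourth decimal from the column means of the rounded per-subject
#'   values). Default `FALSE` returns per-subject rows only.
#' @return A data.frame with 21 rows (22 with `include_average = TRUE`).
#' @examples
#' ref <- reference_mse_table()
#' summarize_evaluation(ref)$summary
#' @export
reference_mse_table <- function(include_average = FALSE) {
  path <- system.file("extdata", "retest_mse_reference.tsv",
                      package = "fcshrink", mustWork = TRUE)
  tab <- utils::read.delim(path)
  if (!include_average) tab <- tab[tab$subject != "Average", ]
  tab$subject <- utils::type.convert(tab$subject, as.is = TRUE)
  tab
}
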