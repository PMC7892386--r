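#' Transcribed example observations bundled with the package
#'
#' A small transcription of published example tables of gene perturbations
#' in OA animal models (genes with discrepant results and genes with both
#' genetic and exogenous evidence), used in tests and the documentation.
#' The `inferred_printed` column carries the effect label as printed at the
#' source; `anomalous` flags rows (the TTR entries) whose printed label is
#' inverted relative to the inference rule that every other row follows —
#' consistent with a transposition at the source — and which are therefore
#' excluded from rule-reproduction checks.
#'
#' @param path Path to the fixture (defaults to the installed copy).
#' @return List with `observations` (parsed via [read_observations()]) and
#'   `printed` (the raw transcription including `inferred_printed` and
#'   `anomalous`).
#' @export
printed_examples <- function(path = system.file("extdata",
                                                "printed_examples.tsv",
                                                package = "oagenes")) {
  printed <- utils::read.delim(path, stringsAsFactors = FALSE)
  obs <- read_observations(
    path,
    schema = c(activity_change = "effect_on_protein")
  )
  printed$inferred_printed <- tolower(gsub(" ", "_", printed$inferred_printed))
  list(observations = obs, printed = printed)
}
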