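#' Reference narrative-shift frequencies
#'
#' Published hand-coded relative frequencies (percent) of the seven
#' narrative-shift types in a census of 24 popular Hollywood films released
#' 1940--2010: overall, between scenes excluding sequences, and between
#' subscenes within sequences. These vectors serve as generator defaults and
#' as fixed inputs for worked-example checks.
#'
#' @return Tibble with `label` and percent columns `overall`,
#'   `excluding_sequences`, `within_sequences`.
#' @export
reference_shift_frequencies <- function() {
  tibble::tibble(
    label = shift_levels()[1:7],
    overall = c(30.3, 40.3, 6.9, 7.6, 0.5, 13.3, 1.1),
    excluding_sequences = c(37.4, 35.2, 0.9, 10.0, 0.1, 16.1, 0.5),
    within_sequences = c(20.6, 47.1, 15.5, 4.4, 1.2, 9.6, 2.0)
  )
}
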