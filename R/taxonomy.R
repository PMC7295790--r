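#' Classify 16S rRNA percent identity into taxon-novelty calls
#'
#' The culturomics novelty rule for an isolate's 16S identity to its
#' nearest named species: below 95% identity the isolate is a candidate
#' new genus; from 95% up to (but excluding) 98.65% a candidate new
#' species; at 98.65% or above a known species. Both thresholds are
#' strict: equality falls in the higher class (95 is a new species,
#' 98.65 a known species). Percent identity is an input here — computing
#' it (alignment, BLAST) is outside this package.
#'
#' @param percent_identity numeric vector of identities in \[0, 100\].
#' @return factor with levels `known_species`, `new_species`, `new_genus`,
#'   same length as the input.
#' @examples
#' classify_identity(c(99.2, 98.64, 94.9))
#' @export
classify_identity <- function(percent_identity) {
  if (!is.numeric(percent_identity) || anyNA(percent_identity)) {
    stop("percent_identity must be numeric without NAs", call. = FALSE)
  }
  if (any(percent_identity < 0 | percent_identity > 100)) {
    stop("percent_identity must lie in [0, 100]", call. = FALSE)
  }
  call <- ifelse(percent_identity < 95, "new_genus",
                 ifelse(percent_identity < 98.65, "new_species",
                        "known_species"))
  factor(call, levels = c("known_species", "new_species", "new_genus"))
}

#' Tally novelty calls
#'
#' @param calls a factor from [classify_identity()], or a numeric vector
#'   of percent identities (classified first).
#' @return named integer vector of counts over the three call classes;
#'   counts sum to the input length.
#' @export
tally_novelty <- function(calls) {
  if (is.numeric(calls)) calls <- classify_identity(calls)
  calls <- factor(calls, levels = c("known_species", "new_species",
                                    "new_genus"))
  if (anyNA(calls)) stop("unrecognized novelty call", call. = FALSE)
  stats::setNames(as.integer(table(calls)), levels(calls))
}
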