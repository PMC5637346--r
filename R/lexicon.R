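#' Gradable-qualifier lexicon
#'
#' The lexicon drives statement extraction: four ordinal classes of
#' qualifier phrase (`high_decrease < decrease < increase < high_increase`),
#' a set of excluded (undefined-direction) phrases, and the trigger
#' substrings that signal expression language
#' (`express, production, produce, transcription, transcribe`).
#'
#' @param increase_phrases,high_increase_phrases,decrease_phrases,
#'   high_decrease_phrases character vectors of qualifier phrases, matched
#'   case-insensitively, longest match wins.
#' @param excluded_phrases phrases that describe an undefined expression
#'   change (e.g. "aberrant"); a sentence whose only qualifier is excluded
#'   yields no statement.
#' @param trigger_substrings substrings any one of which, contained in a
#'   sentence token, marks the sentence as expression-related.
#'
#' @return An object of class `"qualifier_lexicon"` (a list of the six
#'   phrase sets).
#' @seealso [read_lexicon()], [default_lexicon()]
#' @export
qualifier_lexicon <- function(increase_phrases,
                              high_increase_phrases,
                              decrease_phrases,
                              high_decrease_phrases,
                              excluded_phrases = character(),
                              trigger_substrings = c("express", "production",
                                                     "produce", "transcription",
                                                     "transcribe")) {
  lex <- list(
    increase_phrases      = tolower(as.character(increase_phrases)),
    high_increase_phrases = tolower(as.character(high_increase_phrases)),
    decrease_phrases      = tolower(as.character(decrease_phrases)),
    high_decrease_phrases = tolower(as.character(high_decrease_phrases)),
    excluded_phrases      = tolower(as.character(excluded_phrases)),
    trigger_substrings    = tolower(as.character(trigger_substrings))
  )
  classes <- lex[c("increase_phrases", "high_increase_phrases",
                   "decrease_phrases", "high_decrease_phrases",
                   "excluded_phrases")]
  all_phr <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_phr)) {
    dup <- unique(all_phr[duplicated(all_phr)])
    stop("qualifier classes must be pairwise disjoint; duplicated phrase(s): ",
         paste(dup, collapse = ", "))
  }
  if (length(lex$trigger_substrings) == 0L)
    stop("trigger_substrings must be non-empty")
  structure(lex, class = "qualifier_lexicon")
}

#' Read a qualifier lexicon from a YAML file
#'
#' @param path path to a YAML file with keys `increase_phrases`,
#'   `high_increase_phrases`, `decrease_phrases`, `high_decrease_phrases`,
#'   `excluded_phrases`, `trigger_substrings`.
#' @return A `"qualifier_lexicon"` object.
#' @export
read_lexicon <- function(path) {
  y <- yaml::read_yaml(path)
  needed <- c("increase_phrases", "high_increase_phrases",
              "decrease_phrases", "high_decrease_phrases")
  miss <- setdiff(needed, names(y))
  if (length(miss))
    stop("lexicon file is missing field(s): ", paste(miss, collapse = ", "))
  qualifier_lexicon(
    increase_phrases      = y$increase_phrases,
    high_increase_phrases = y$high_increase_phrases,
    decrease_phrases      = y$decrease_phrases,
    high_decrease_phrases = y$high_decrease_phrases,
    excluded_phrases      = if (is.null(y$excluded_phrases)) character() else y$excluded_phrases,
    trigger_substrings    = if (is.null(y$trigger_substrings))
      c("express", "production", "produce", "transcription", "transcribe")
    else y$trigger_substrings
  )
}

#' The lexicon shipped with the package
#'
#' @return The `"qualifier_lexicon"` read from the packaged
#'   `extdata/lexicon.yaml`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "degbias",
                           mustWork = TRUE))
}

#' @export
print.qualifier_lexicon <- function(x, ...) {
  cat("qualifier_lexicon:",
      length(x$increase_phrases), "increase,",
      length(x$high_increase_phrases), "high-increase,",
      length(x$decrease_phrases), "decrease,",
      length(x$high_decrease_phrases), "high-decrease,",
      length(x$excluded_phrases), "excluded phrases;",
      length(x$trigger_substrings), "trigger substrings\n")
  invisible(x)
}

#' Ordinal delta levels
#'
#' The four gradable directions a statement can take, in increasing order.
#' @return character vector `c("high_decrease","decrease","increase","high_increase")`.
#' @export
delta_levels <- function() {
  c("high_decrease", "decrease", "increase", "high_increase")
}

#' Sign of a delta value
#'
#' @param delta character vector of delta levels.
#' @return `+1` for `increase`/`high_increase`, `-1` for
#'   `decrease`/`high_decrease`.
#' @export
delta_sign <- function(delta) {
  if (!all(delta %in% delta_levels()))
    stop("unknown delta value(s): ",
         paste(setdiff(delta, delta_levels()), collapse = ", "))
  ifelse(delta %in% c("increase", "high_increase"), 1L, -1L)
}
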