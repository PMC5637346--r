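## Rule-based sentence segmentation. Not a full statistical boundary
## detector: terminal punctuation + abbreviation/initial guards + a hard
## constraint that no boundary falls inside an entity mention span.

# tokens that, followed by ".", do not end a sentence
.abbrev_guard <- c("e.g", "i.e", "et al", "al", "fig", "figs", "vs", "cf",
                   "ca", "dr", "mr", "mrs", "ms", "no", "approx", "resp",
                   "spp", "sp", "subsp", "var", "st")

#' Split a document into sentence spans
#'
#' Splits on terminal punctuation (`.`, `!`, `?`) followed by whitespace,
#' with three guards: a known-abbreviation list (`e.g.`, `et al.`,
#' `Fig.`, ...), single-letter initials (so `E. coli` is never split), and
#' a requirement that the next sentence starts with an uppercase letter,
#' digit or opening bracket/quote. No boundary may fall strictly inside an
#' entity mention span. The returned spans partition the text (trailing
#' whitespace belongs to the preceding span); text without terminal
#' punctuation yields a single span.
#'
#' @param document an [annotated_document()], or a character scalar.
#' @return data frame with 0-based, end-exclusive columns `start`, `end`
#'   and the covered `text`.
#' @export
split_sentences <- function(document) {
  if (is.character(document))
    document <- annotated_document("NA", document)
  text <- document$text
  if (!nzchar(text)) stop("document text is empty")
  n <- nchar(text)

  # candidate boundaries: 0-based index of the first char of the next
  # sentence, i.e. position right after "[.!?]+\\s+"
  m <- gregexpr("[.!?]+[\"')\\]]*[[:space:]]+", text, perl = TRUE)[[1]]
  starts0 <- 0L
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      punct_at <- as.integer(m[k])                       # 1-based
      after <- punct_at + attr(m, "match.length")[k]     # 1-based next char
      if (after > n) next
      # guard 1: next sentence must open with uppercase/digit/bracket
      nxt <- substr(text, after, after)
      if (!grepl("[A-Z0-9(\"'\\[]", nxt)) next
      # guard 2: abbreviation or initial before the period
      before <- substr(text, max(1L, punct_at - 12L), punct_at - 1L)
      tok <- regmatches(before, regexpr("[A-Za-z.]+$", before))
      if (length(tok)) {
        tk <- tolower(sub("\\.$", "", tok))
        if (tk %in% .abbrev_guard || grepl("^[a-z]$", tk)) next
        two <- regmatches(before, regexpr("[A-Za-z]+ [A-Za-z]+$", before))
        if (length(two) && tolower(two) %in% .abbrev_guard) next
      }
      # guard 3: never split inside a mention span
      b0 <- after - 1L                                   # 0-based boundary
      mm <- document$mentions
      if (nrow(mm) && any(b0 > mm$start & b0 < mm$end)) next
      starts0 <- c(starts0, b0)
    }
  }
  starts0 <- sort(unique(starts0))
  ends0 <- c(starts0[-1], n)
  data.frame(start = starts0, end = ends0,
             text = substring(text, starts0 + 1L, ends0),
             stringsAsFactors = FALSE)
}

#' Detect in-document abbreviation definitions
#'
#' Finds `long form (SHORT)` patterns and returns the mapping from the
#' short form to the 0-based span of the long form, used to let a disease
#' abbreviation stand in for the disease mention in later sentences.
#'
#' @param text document text.
#' @return data frame with columns `short`, `long_start`, `long_end`.
#' @export
detect_abbreviations <- function(text) {
  out <- data.frame(short = character(), long_start = integer(),
                    long_end = integer(), stringsAsFactors = FALSE)
  m <- gregexpr("\\(([A-Z][A-Za-z0-9-]{1,9})\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  for (k in seq_along(m)) {
    op <- as.integer(m[k])
    len <- attr(m, "match.length")[k]
    short <- substr(text, op + 1L, op + len - 2L)
    # long form: up to length(short-token-count)+... take preceding words,
    # heuristically as many words as letters in the short form, max 6
    nw <- min(max(nchar(short), 2L), 6L)
    pre <- substr(text, 1L, op - 2L)
    words <- regmatches(pre, regexpr(paste0("(\\S+\\s+){0,", nw - 1L, "}\\S+$"),
                                     pre, perl = TRUE))
    if (!length(words)) next
    long_start <- op - 2L - nchar(words)   # 0-based
    out <- rbind(out, data.frame(short = short, long_start = long_start,
                                 long_end = op - 2L, stringsAsFactors = FALSE))
  }
  out
}
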