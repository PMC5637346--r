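#' Detect expression trigger language in a sentence
#'
#' A sentence is expression-related when any token contains one of the
#' lexicon's trigger substrings (case-insensitive); the default set is
#' `express, production, produce, transcription, transcribe`, so
#' "overexpression", "produced" and "transcriptional" all trigger.
#'
#' @param sentence character scalar.
#' @param lexicon a [qualifier_lexicon()].
#' @return logical scalar.
#' @export
detect_trigger <- function(sentence, lexicon = default_lexicon()) {
  s <- tolower(sentence)
  any(vapply(lexicon$trigger_substrings,
             function(tr) grepl(tr, s, fixed = TRUE), logical(1)))
}

# all qualifier-phrase matches in a lowercased sentence:
# data.frame(phrase, class, sign, start [1-based], length)
.delta_matches <- function(s, lexicon) {
  classes <- c(increase_phrases = "increase",
               high_increase_phrases = "high_increase",
               decrease_phrases = "decrease",
               high_decrease_phrases = "high_decrease")
  out <- list()
  for (field in names(classes)) {
    for (ph in lexicon[[field]]) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ph), "\\b")
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        phrase = ph, class = classes[[field]],
        sign = if (classes[[field]] %in% c("increase", "high_increase")) 1L else -1L,
        start = as.integer(m), length = attr(m, "match.length"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(phrase = character(), class = character(),
                      sign = integer(), start = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify the gradable qualifier of a sentence
#'
#' Returns the delta of the longest matching qualifier phrase (so
#' "greatly elevated" wins over "elevated" and maps to `high_increase`,
#' while "significantly overexpressed" maps to `increase`). A sentence
#' whose only match is an excluded phrase ("aberrant", "dysregulated", ...)
#' is classified as excluded; one with no qualifier at all as
#' `no_qualifier`.
#'
#' @inheritParams detect_trigger
#' @return list with `delta` (a [delta_levels()] value, or `NA`) and
#'   `reason` (`"ok"`, `"excluded"` or `"no_qualifier"`).
#' @export
classify_delta <- function(sentence, lexicon = default_lexicon()) {
  s <- tolower(sentence)
  dm <- .delta_matches(s, lexicon)
  if (nrow(dm)) {
    best <- dm[order(-dm$length, dm$start), , drop = FALSE][1L, ]
    return(list(delta = best$class, reason = "ok"))
  }
  excl <- any(vapply(lexicon$excluded_phrases, function(ph)
    grepl(paste0("\\b", ph, "\\b"), s, perl = TRUE), logical(1)))
  list(delta = NA_character_,
       reason = if (excl) "excluded" else "no_qualifier")
}

# word tokens of a string with 1-based start offsets
.tokenize <- function(s) {
  m <- gregexpr("\\S+", s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# token index containing 1-based char position p (0 if none)
.token_index <- function(tokens, p) {
  i <- which(tokens$start <= p & tokens$end >= p)
  if (length(i)) i[1] else 0L
}

empty_statements <- function() {
  data.frame(pmid = character(), gene = character(), disease = character(),
             delta = character(), sentence_start = integer(),
             sentence_end = integer(), sentence = character(),
             stringsAsFactors = FALSE)
}

#' Extract DEG statements from an annotated corpus
#'
#' Applies the tri-occurrence rule sentence by sentence: a statement
#' `(pmid, gene, disease, delta)` is emitted for every sentence containing
#' at least one gene mention, at least one target-disease mention (or an
#' in-document abbreviation of one), and a trigger substring, provided a
#' gradable qualifier classifies the direction. Gene mentions whose
#' identifier resolves to more than `max_gene_ambiguity` symbols are
#' dropped. When qualifiers of opposite sign co-occur in a sentence, each
#' gene takes its nearest qualifier by token distance, which must lie
#' within `token_window` tokens of the gene mention or of a trigger token;
#' if opposite signs tie at that distance the gene is skipped as
#' ambiguous. Redundant `(pmid, gene, disease, delta)` tuples
#' are discarded, keeping the first in document order.
#'
#' @param corpus list of [annotated_document()] objects (e.g. from
#'   [read_pubtator()]).
#' @param lexicon a [qualifier_lexicon()].
#' @param target_diseases character vector of disease identifiers to
#'   extract for; `NULL` means all disease mentions qualify.
#' @param token_window token distance used to resolve sentences containing
#'   qualifiers of opposite sign.
#' @param max_gene_ambiguity maximum number of gene symbols a mention may
#'   resolve to before it is discarded.
#' @return data frame of statements with columns `pmid`, `gene`, `disease`,
#'   `delta`, `sentence_start`, `sentence_end`, `sentence`.
#' @export
extract_statements <- function(corpus, lexicon = default_lexicon(),
                               target_diseases = NULL, token_window = 8L,
                               max_gene_ambiguity = 3L) {
  rows <- list()
  for (doc in corpus) {
    mm <- doc$mentions
    if (!nrow(mm)) next
    sent <- split_sentences(doc)
    # abbreviation pass: short forms whose long form overlaps a disease mention
    dis_rows <- mm[mm$type == "Disease", , drop = FALSE]
    abbr <- detect_abbreviations(doc$text)
    abbr_map <- list()
    if (nrow(abbr) && nrow(dis_rows)) {
      for (a in seq_len(nrow(abbr))) {
        hit <- which(dis_rows$start < abbr$long_end[a] &
                     dis_rows$end > abbr$long_start[a])
        if (length(hit))
          abbr_map[[abbr$short[a]]] <- dis_rows$id[hit[1]]
      }
    }
    for (si in seq_len(nrow(sent))) {
      s0 <- sent$start[si]; s1 <- sent$end[si]
      stext <- sent$text[si]
      in_sent <- mm$start >= s0 & mm$end <= s1
      genes <- mm[in_sent & mm$type == "Gene", , drop = FALSE]
      dis <- mm[in_sent & mm$type == "Disease", , drop = FALSE]
      dis_ids <- dis$id
      # abbreviation occurrences count as disease mentions
      for (short in names(abbr_map)) {
        if (grepl(paste0("\\b", short, "\\b"), stext))
          dis_ids <- c(dis_ids, abbr_map[[short]])
      }
      if (!is.null(target_diseases))
        dis_ids <- dis_ids[dis_ids %in% target_diseases]
      dis_ids <- unique(dis_ids)
      if (!nrow(genes) || !length(dis_ids)) next
      if (!detect_trigger(stext, lexicon)) next
      slow <- tolower(stext)
      dm <- .delta_matches(slow, lexicon)
      if (!nrow(dm)) next
      mixed <- length(unique(dm$sign)) > 1L
      tokens <- .tokenize(slow)
      trig_tok <- which(vapply(seq_len(nrow(tokens)), function(i) {
        tk <- substr(slow, tokens$start[i], tokens$end[i])
        any(vapply(lexicon$trigger_substrings, grepl, logical(1), x = tk,
                   fixed = TRUE))
      }, logical(1)))
      for (gi in seq_len(nrow(genes))) {
        symbols <- strsplit(genes$id[gi], "[;,]")[[1]]
        symbols <- symbols[nzchar(symbols)]
        if (length(symbols) > max_gene_ambiguity) next
        gene_tok <- .token_index(tokens, genes$start[gi] - s0 + 1L)
        use <- dm
        if (mixed) {
          # opposite signs in one sentence: each gene takes its nearest
          # qualifier, which must be within the token window of the gene
          # or of a trigger token; sign ties at that distance skip the
          # gene as ambiguous
          qt <- vapply(dm$start, function(p) .token_index(tokens, p),
                       integer(1))
          d_gene <- if (gene_tok > 0L) abs(qt - gene_tok) else
            rep(Inf, nrow(dm))
          d_trig <- vapply(qt, function(q)
            if (length(trig_tok)) min(abs(q - trig_tok)) else Inf,
            numeric(1))
          in_window <- pmin(d_gene, d_trig) <= token_window
          if (!any(in_window)) next
          nearest <- which(in_window & d_gene == min(d_gene[in_window]))
          use <- dm[nearest, , drop = FALSE]
          if (length(unique(use$sign)) > 1L) next
        }
        best <- use[order(-use$length, use$start), , drop = FALSE][1L, ]
        for (sym in symbols) for (d_id in dis_ids) {
          rows[[length(rows) + 1L]] <- data.frame(
            pmid = doc$pmid, gene = sym, disease = d_id,
            delta = best$class, sentence_start = s0, sentence_end = s1,
            sentence = stext, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_statements())
  out <- do.call(rbind, rows)
  key <- paste(out$pmid, out$gene, out$disease, out$delta, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 of extracted statements
#'
#' Set-based comparison over `(pmid, gene, disease, delta)` tuples. By
#' convention an empty predicted set has precision 1 (nothing asserted,
#' nothing wrong) and, against a non-empty gold set, recall 0.
#'
#' @param predicted,gold statement data frames with columns `pmid`, `gene`,
#'   `disease`, `delta`.
#' @return list with `precision`, `recall`, `f1`, `n_predicted`, `n_gold`,
#'   `n_correct`.
#' @export
evaluate_extraction <- function(predicted, gold) {
  keyify <- function(x) {
    if (!nrow(x)) return(character())
    unique(paste(x$pmid, x$gene, x$disease, x$delta, sep = "\r"))
  }
  kp <- keyify(predicted); kg <- keyify(gold)
  n_correct <- length(intersect(kp, kg))
  precision <- if (length(kp) == 0L) 1 else n_correct / length(kp)
  recall <- if (length(kg) == 0L) 1 else n_correct / length(kg)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_predicted = length(kp), n_gold = length(kg), n_correct = n_correct)
}
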