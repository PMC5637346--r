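#' Annotated document
#'
#' A single abstract with entity mentions, the unit consumed by the
#' extractor. Offsets follow the PubTator convention: 0-based,
#' end-exclusive, over the concatenation `title + " " + abstract`.
#'
#' @param pmid document identifier (coerced to character).
#' @param title,abstract document text; the working text is their
#'   space-separated concatenation.
#' @param mentions data frame with columns `start`, `end` (integer offsets),
#'   `text` (surface form), `type` (`"Gene"` or `"Disease"`), `id`
#'   (identifier; multiple candidate gene symbols separated by `";"`).
#' @return An object of class `"annotated_document"`.
#' @export
annotated_document <- function(pmid, title, abstract = "",
                               mentions = empty_mentions()) {
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  if (nrow(mentions)) {
    needed <- c("start", "end", "text", "type", "id")
    miss <- setdiff(needed, names(mentions))
    if (length(miss))
      stop("mentions lack column(s): ", paste(miss, collapse = ", "))
    mentions$start <- as.integer(mentions$start)
    mentions$end <- as.integer(mentions$end)
    bad <- mentions$start < 0L | mentions$end > nchar(text) |
      mentions$start >= mentions$end
    if (any(bad))
      stop("mention span(s) outside document text for pmid ", pmid,
           " at row(s) ", paste(which(bad), collapse = ", "))
  }
  structure(list(pmid = as.character(pmid), title = title,
                 abstract = abstract, text = text, mentions = mentions),
            class = "annotated_document")
}

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), text = character(),
             type = character(), id = character(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat("annotated_document", x$pmid, "-", nchar(x$text), "chars,",
      nrow(x$mentions), "mentions\n")
  invisible(x)
}

#' Read a PubTator-format corpus
#'
#' Parses the classic PubTator export: per document a `PMID|t|...` line, a
#' `PMID|a|...` line, then tab-delimited mention lines
#' `PMID<TAB>start<TAB>end<TAB>text<TAB>type<TAB>id`, documents separated by
#' blank lines.
#'
#' @param path file path.
#' @return A list of [annotated_document()] objects, in file order.
#' @export
read_pubtator <- function(path) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  cur <- NULL
  flush_doc <- function(cur) {
    if (is.null(cur)) return(NULL)
    m <- if (length(cur$mentions)) {
      do.call(rbind, cur$mentions)
    } else empty_mentions()
    annotated_document(cur$pmid, cur$title, cur$abstract, m)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) {
      d <- flush_doc(cur)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    tpos <- regexpr("\\|t\\|", ln)
    apos <- regexpr("\\|a\\|", ln)
    if (tpos > 0 && (apos < 0 || tpos < apos)) {
      cur <- list(pmid = substr(ln, 1L, tpos - 1L),
                  title = substr(ln, tpos + 3L, nchar(ln)),
                  abstract = "", mentions = list())
    } else if (apos > 0) {
      if (is.null(cur)) stop("abstract line before title at line ", i)
      cur$abstract <- substr(ln, apos + 3L, nchar(ln))
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 6L)
        stop("malformed annotation line ", i, ": ", ln)
      if (is.null(cur)) stop("annotation line before title at line ", i)
      cur$mentions[[length(cur$mentions) + 1L]] <-
        data.frame(start = as.integer(f[2]), end = as.integer(f[3]),
                   text = f[4], type = f[5], id = f[6],
                   stringsAsFactors = FALSE)
    }
  }
  d <- flush_doc(cur)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  docs
}

#' Write a corpus in PubTator format
#'
#' @param corpus list of [annotated_document()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(corpus, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (doc in corpus) {
    writeLines(paste0(doc$pmid, "|t|", doc$title), con)
    writeLines(paste0(doc$pmid, "|a|", doc$abstract), con)
    m <- doc$mentions
    if (nrow(m)) {
      writeLines(paste(doc$pmid, m$start, m$end, m$text, m$type, m$id,
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
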