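## Tab-delimited readers and writers for every artifact the pipeline
## exchanges: expression matrices with a sample-group sidecar, statement
## tables, popularity counts and gene-term annotations.

#' Read an expression matrix with its sample-group sidecar
#'
#' @param matrix_path TSV, first column feature ids, remaining columns
#'   samples, values on the log2 scale.
#' @param groups_path two-column TSV `sample<TAB>group` with groups
#'   `disease` or `normal`; every matrix column must be labelled.
#' @return list with `matrix` (numeric, rownames = features) and `groups`
#'   (named character vector aligned to the matrix columns).
#' @export
read_expression <- function(matrix_path, groups_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (ncol(g) < 2L) stop("groups sidecar needs two columns: sample, group")
  groups <- g[[2]]
  names(groups) <- g[[1]]
  miss <- setdiff(colnames(mat), names(groups))
  if (length(miss))
    stop("samples missing a group label: ", paste(miss, collapse = ", "))
  list(matrix = mat, groups = groups[colnames(mat)])
}

#' Write an expression matrix and its group sidecar
#'
#' @param expression list with `matrix` and `groups` as returned by
#'   [generate_expression()] or [read_expression()].
#' @param matrix_path,groups_path output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expression, matrix_path, groups_path) {
  tab <- data.frame(feature = rownames(expression$matrix),
                    expression$matrix, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(expression$groups),
                                group = unname(expression$groups)),
                     groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read / write a statement table
#'
#' Statements are exchanged as TSV with columns `pmid`, `gene`, `disease`,
#' `delta` and optionally `sentence`.
#'
#' @param path TSV path.
#' @return data frame of statements.
#' @export
read_statements <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("pmid", "gene", "disease", "delta")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("statement file missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' @rdname read_statements
#' @param statements statement data frame.
#' @export
write_statements <- function(statements, path) {
  utils::write.table(statements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-popularity table
#'
#' Two-column TSV `gene<TAB>count`.
#'
#' @param path TSV path.
#' @return named integer vector gene -> count.
#' @export
read_popularity <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  counts <- as.integer(x[[2]])
  names(counts) <- x[[1]]
  counts
}

#' @rdname read_popularity
#' @param popularity named integer vector.
#' @export
write_popularity <- function(popularity, path) {
  utils::write.table(data.frame(gene = names(popularity),
                                count = unname(popularity)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-term annotations
#'
#' Accepts a two-column TSV (`gene<TAB>term`) or a GAF 2.x subset, from
#' which only the gene-symbol (column 3) and GO-id (column 5) fields are
#' used; GAF comment lines (`!`) are skipped.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return data frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    out <- data.frame(gene = x[[1]], term = x[[2]], stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 5L)
    if (length(bad)) stop("malformed GAF line ", bad[1])
    out <- data.frame(gene = vapply(f, `[[`, "", 3L),
                      term = vapply(f, `[[`, "", 5L),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

#' @rdname read_annotations
#' @param annotations data frame with columns `gene`, `term`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations[, c("gene", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-level DE table
#'
#' @param de_table data frame from [fit_moderated_t()] /
#'   [collapse_probes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de_table, path) {
  utils::write.table(de_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
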