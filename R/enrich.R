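#' Term overrepresentation by one-sided Fisher test
#'
#' For every term annotated to at least one universe gene, tests whether
#' the study set contains more term members than expected under
#' hypergeometric sampling: `p = P(X >= k)` with `k` study-set members of
#' the term, `K` universe members, study size `n`, universe size `N`;
#' Bonferroni correction over the tested terms. Genes of the study set or
#' annotation map absent from the universe are dropped (with a warning for
#' annotation genes). Universe genes with no annotation are assigned the
#' pseudo-term `"unclassified"`, which is tested like any other term.
#'
#' @param study_set character vector of gene identifiers (subset of the
#'   universe).
#' @param universe character vector of gene identifiers.
#' @param annotations data frame with columns `gene`, `term`.
#' @return data frame with one row per term: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `p_bonf`, sorted by `p` then term id.
#' @export
fisher_overrep <- function(study_set, universe, annotations) {
  universe <- unique(universe)
  study_set <- unique(study_set)
  if (!length(study_set)) stop("study set is empty")
  extra <- setdiff(study_set, universe)
  if (length(extra))
    stop("study set contains gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  drop <- !(annotations$gene %in% universe)
  if (any(drop)) {
    warning(sum(drop), " annotation row(s) for genes outside the universe dropped")
    annotations <- annotations[!drop, , drop = FALSE]
  }
  unclassified <- setdiff(universe, unique(annotations$gene))
  if (length(unclassified))
    annotations <- rbind(annotations[, c("gene", "term")],
                         data.frame(gene = unclassified,
                                    term = "unclassified",
                                    stringsAsFactors = FALSE))
  annotations <- unique(annotations[, c("gene", "term")])
  N <- length(universe)
  n <- length(study_set)
  terms <- sort(unique(annotations$term))
  K <- as.integer(table(factor(annotations$term, levels = terms)))
  in_study <- annotations$gene %in% study_set
  k <- as.integer(table(factor(annotations$term[in_study], levels = terms)))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  m <- length(terms)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    p_bonf = pmin(1, p * m), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two enrichment result lists
#'
#' Counts the terms Bonferroni-significant in each list
#' (`p_bonf < alpha`) and their intersection, plus the intersection of the
#' two top-k-by-p displays.
#'
#' @param rows_a,rows_b data frames from [fisher_overrep()].
#' @param k display depth for the top-k comparison (default 20).
#' @param alpha significance bound on `p_bonf` (default 0.05).
#' @return list with `shared_significant`, `n_sig_a`, `n_sig_b`,
#'   `shared_terms` (character), `shared_top_k`, `top_k_terms`.
#' @export
top_k_overlap <- function(rows_a, rows_b, k = 20L, alpha = 0.05) {
  if (k < 1L) stop("k must be >= 1")
  sig_a <- rows_a$term[rows_a$p_bonf < alpha]
  sig_b <- rows_b$term[rows_b$p_bonf < alpha]
  shared <- intersect(sig_a, sig_b)
  top_a <- utils::head(rows_a$term[order(rows_a$p, rows_a$term)], k)
  top_b <- utils::head(rows_b$term[order(rows_b$p, rows_b$term)], k)
  top_shared <- intersect(top_a, top_b)
  list(shared_significant = length(shared),
       n_sig_a = length(sig_a), n_sig_b = length(sig_b),
       shared_terms = sort(shared),
       shared_top_k = length(top_shared),
       top_k_terms = sort(top_shared))
}
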