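#' Over- versus under-expression reporting ratio
#'
#' Counts unique genes by reported direction: a gene counts once per
#' direction it is reported in (so a gene reported both over- and
#' under-expressed contributes to both tallies). The input is either a
#' statement data frame (`gene`, `delta`) or a list with `up`/`down`
#' character vectors of gene identifiers.
#'
#' @param x statements data frame or `list(up =, down =)` gene sets.
#' @return list with `n_over`, `n_under`, `pct_over`, `pct_under`
#'   (percentages summing to 100) and `ratio` (`n_over / n_under`,
#'   `Inf` when nothing is under-expressed).
#' @export
over_under_ratio <- function(x) {
  if (is.data.frame(x)) {
    if (!nrow(x)) stop("no statements to summarise")
    sgn <- delta_sign(x$delta)
    n_over <- length(unique(x$gene[sgn > 0]))
    n_under <- length(unique(x$gene[sgn < 0]))
  } else {
    n_over <- length(unique(x$up))
    n_under <- length(unique(x$down))
  }
  tot <- n_over + n_under
  if (tot == 0L) stop("no directed genes to summarise")
  list(n_over = n_over, n_under = n_under,
       pct_over = 100 * n_over / tot, pct_under = 100 * n_under / tot,
       ratio = if (n_under == 0L) Inf else n_over / n_under)
}

#' 2x2 membership counts for two gene sets in a universe
#'
#' @param n_universe universe size `N`.
#' @param n_a,n_b,n_ab set sizes |A|, |B| and |A intersect B|.
#' @return validated list of class `"overlap_counts"`.
#' @export
overlap_counts <- function(n_universe, n_a, n_b, n_ab) {
  stopifnot(n_universe >= 1, n_a >= 0, n_b >= 0, n_ab >= 0)
  if (n_ab > min(n_a, n_b))
    stop("n_ab cannot exceed min(n_a, n_b)")
  if (n_a > n_universe || n_b > n_universe)
    stop("set sizes cannot exceed the universe")
  if (n_a - n_ab > n_universe - n_b)
    stop("counts imply |A \\ B| larger than the complement of B")
  structure(list(n_universe = n_universe, n_a = n_a, n_b = n_b, n_ab = n_ab),
            class = "overlap_counts")
}

#' Overlap counts from explicit gene sets
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe either a character vector of identifiers (sets are
#'   intersected with it) or a single integer universe size.
#' @return An [overlap_counts()] object.
#' @export
overlap_counts_from_sets <- function(set_a, set_b, universe) {
  if (is.character(universe)) {
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
    n_universe <- length(unique(universe))
  } else {
    n_universe <- as.integer(universe)
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  overlap_counts(n_universe, length(set_a), length(set_b),
                 length(intersect(set_a, set_b)))
}

#' Positive likelihood ratio of set membership
#'
#' `LR+ = P(A | B) / P(A | not B)` computed from the 2x2 counts as
#' `(n_ab / n_b) / ((n_a - n_ab) / (N - n_b))`. Returns `Inf` when A
#' contains every member of B it could (`n_a = n_ab > 0`) and `0` when the
#' sets are disjoint while A is non-empty. Undefined (error) when B is
#' empty or B is the whole universe.
#'
#' @param counts an [overlap_counts()] object.
#' @return non-negative number, possibly `Inf` (or `NaN` when `n_a = 0`).
#' @export
lr_plus <- function(counts) {
  stopifnot(inherits(counts, "overlap_counts"))
  N <- counts$n_universe; n_a <- counts$n_a; n_b <- counts$n_b
  n_ab <- counts$n_ab
  if (n_b == 0L) stop("LR+ undefined: conditioning set B is empty")
  if (n_b == N) stop("LR+ undefined: conditioning set B is the whole universe")
  if (n_a == 0L) return(NaN)
  if (n_ab == 0L) return(0)
  if (n_a == n_ab) return(Inf)
  (n_ab / n_b) / ((n_a - n_ab) / (N - n_b))
}

#' Pairwise LR+ matrix across diseases
#'
#' Entry `[i, j]` is the LR+ of a gene being in disease i's set given it
#' is in disease j's set; the matrix is not symmetric in general. The
#' diagonal is infinity by definition and should be excluded from
#' summaries.
#'
#' @param sets named list of gene-identifier character vectors.
#' @param universe_size universe size N (or identifier vector).
#' @return numeric matrix, rows = outcome disease, columns = conditioning
#'   disease.
#' @export
pairwise_disease_lr <- function(sets, universe_size) {
  k <- length(sets)
  out <- matrix(Inf, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    out[i, j] <- lr_plus(overlap_counts_from_sets(sets[[i]], sets[[j]],
                                                  universe_size))
  }
  out
}

#' Multi-disease overlap counts and k-wise LR+ summaries
#'
#' Counts genes that belong to exactly / at least k of the disease sets,
#' and for each k >= 2 computes the LR+ of membership in one disease given
#' joint membership in each (k-1)-subset of the others, summarised by
#' min/mean/max over all arrangements (arrangements whose conditioning
#' intersection is empty are skipped).
#'
#' @param sets named list (length >= 2) of gene-identifier vectors.
#' @param universe_size universe size N (or identifier vector).
#' @return list with `membership_counts` (data frame `k`, `n_exact`,
#'   `n_at_least`) and `lr_summary` (data frame `k`, `n_arrangements`,
#'   `lr_min`, `lr_mean`, `lr_max`).
#' @export
multi_disease_overlap <- function(sets, universe_size) {
  if (length(sets) < 2L) stop("need at least two disease sets")
  nd <- length(sets)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  k_of <- rowSums(member)
  counts <- data.frame(
    k = seq_len(nd),
    n_exact = vapply(seq_len(nd), function(k) sum(k_of == k), integer(1)),
    n_at_least = vapply(seq_len(nd), function(k) sum(k_of >= k), integer(1)))
  rows <- list()
  for (k in 2:nd) {
    lrs <- numeric(0)
    for (target in seq_len(nd)) {
      others <- setdiff(seq_len(nd), target)
      subs <- utils::combn(others, k - 1L, simplify = FALSE)
      for (S in subs) {
        B <- Reduce(intersect, sets[S])
        if (!length(B)) next
        lrs <- c(lrs, lr_plus(overlap_counts_from_sets(sets[[target]], B,
                                                       universe_size)))
      }
    }
    finite <- lrs[is.finite(lrs)]
    rows[[k - 1L]] <- data.frame(
      k = k, n_arrangements = length(lrs),
      lr_min = if (length(lrs)) min(lrs) else NA_real_,
      lr_mean = if (length(finite)) mean(finite) else NA_real_,
      lr_max = if (length(lrs)) max(lrs) else NA_real_)
  }
  list(membership_counts = counts, lr_summary = do.call(rbind, rows))
}

#' Cumulative probability of being reported given fold change above x
#'
#' For each threshold `x`, the fraction of genes with `fc > x` that belong
#' to the literature-reported set:
#' `p(reported | fc > x) = |{reported and fc > x}| / |{fc > x}|`.
#' Thresholds whose denominator falls below `min_denominator` are flagged
#' unstable.
#'
#' @param lit_set character vector of reported gene identifiers.
#' @param de_table gene-level data frame with columns `gene` (or
#'   `feature_id`) and `fc`.
#' @param thresholds numeric grid of linear fold-change thresholds.
#' @param min_denominator stability flag cutoff (default 10).
#' @return data frame with `threshold`, `n_above`, `n_reported`, `prob`,
#'   `stable`.
#' @export
cumulative_reporting_prob <- function(lit_set, de_table, thresholds,
                                      min_denominator = 10L) {
  ids <- if ("gene" %in% names(de_table)) de_table$gene else de_table$feature_id
  reported <- ids %in% lit_set
  out <- data.frame(threshold = thresholds)
  out$n_above <- vapply(thresholds, function(x) sum(de_table$fc > x), integer(1))
  out$n_reported <- vapply(thresholds, function(x)
    sum(reported & de_table$fc > x), integer(1))
  if (all(out$n_above == 0L))
    stop("no gene exceeds any threshold: empty denominators throughout")
  out$prob <- ifelse(out$n_above > 0L, out$n_reported / out$n_above, NA_real_)
  out$stable <- out$n_above >= min_denominator
  out
}

#' Point-biserial correlation between reporting and popularity
#'
#' Pearson correlation between a binary reported/overexpressed indicator
#' and the gene popularity counts, with a two-sided t-based p-value and a
#' significance flag at `alpha`.
#'
#' @param indicator numeric/logical 0-1 vector, one entry per gene.
#' @param popularity numeric vector of mention counts, same length.
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `r`, `p`, `significant`, `n`.
#' @export
popularity_correlation <- function(indicator, popularity, alpha = 0.05) {
  indicator <- as.numeric(indicator)
  if (length(indicator) != length(popularity))
    stop("indicator and popularity lengths differ")
  if (length(indicator) < 3L) stop("need at least 3 genes")
  if (stats::var(indicator) == 0)
    stop("indicator is constant: correlation undefined")
  ct <- stats::cor.test(popularity, indicator, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha, n = length(indicator))
}

#' Per-gene mention counts joined with fold change and popularity
#'
#' Aggregates a statement table into the per-gene counts used by the
#' mention models: the number of plain increase mentions, the number of
#' high-increase mentions, the popularity count, and the gene-level
#' log2 fold change / signed fold change from a DE table. Genes absent
#' from the statements get zero counts; the table covers every gene of the
#' DE table.
#'
#' @param statements statement data frame (`gene`, `disease`, `delta`).
#' @param de_table gene-level data frame (`gene` or `feature_id`, `log2fc`,
#'   `fc`).
#' @param popularity named numeric vector, gene -> mention count.
#' @param disease optional disease id to restrict the statements to.
#' @return data frame `gene`, `increase_mentions`, `high_increase_mentions`,
#'   `popularity`, `log2fc`, `fc`.
#' @export
mention_count_table <- function(statements, de_table, popularity,
                                disease = NULL) {
  if (!is.null(disease))
    statements <- statements[statements$disease %in% disease, , drop = FALSE]
  ids <- if ("gene" %in% names(de_table)) de_table$gene else de_table$feature_id
  inc <- table(factor(statements$gene[statements$delta == "increase"],
                      levels = ids))
  hinc <- table(factor(statements$gene[statements$delta == "high_increase"],
                       levels = ids))
  pop <- popularity[ids]
  pop[is.na(pop)] <- 0
  data.frame(gene = ids,
             increase_mentions = as.integer(inc),
             high_increase_mentions = as.integer(hinc),
             popularity = as.numeric(pop),
             log2fc = de_table$log2fc, fc = de_table$fc,
             stringsAsFactors = FALSE)
}

# shared OLS backbone for the two mention models
.linear_fit <- function(y, x1, x2, names12) {
  X <- cbind(x1, x2)
  if (qr(cbind(1, X))$rank < 3L)
    stop("collinear regressors: ", names12[1], " and ", names12[2],
         " (with intercept) are not of full rank")
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)
  co <- sm$coefficients
  sd_safe <- function(v) { s <- stats::sd(v); if (s == 0) NA_real_ else s }
  list(alpha = unname(co["x1", "Estimate"]),
       beta = unname(co["x2", "Estimate"]),
       gamma = unname(co["(Intercept)", "Estimate"]),
       p_alpha = unname(co["x1", "Pr(>|t|)"]),
       p_beta = unname(co["x2", "Pr(>|t|)"]),
       r_squared = sm$r.squared,
       alpha_std = unname(co["x1", "Estimate"]) * sd_safe(x1) / sd_safe(y),
       beta_std = unname(co["x2", "Estimate"]) * sd_safe(x2) / sd_safe(y),
       n = length(y))
}

#' High-increase mentions as a function of fold change and mentions
#'
#' Ordinary least squares of the per-gene count of high-increase mentions
#' on the linear fold change and the plain increase-mention count:
#' `high_increase_mentions ~ alpha*fc + beta*increase_mentions + gamma`.
#' Disentangles whether "highly overexpressed" phrasing tracks the
#' measured fold change once overall mention frequency is accounted for.
#'
#' @param table a [mention_count_table()].
#' @param fc_scale `"linear"` (default) regresses on `fc`, `"log2"` on
#'   `log2fc`.
#' @return list with `alpha`, `beta`, `gamma`, `p_alpha`, `p_beta`,
#'   `r_squared`, standardized coefficients `alpha_std`/`beta_std`, `n`.
#' @export
fit_high_increase_model <- function(table, fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (nrow(table) < 3L) stop("need at least 3 genes")
  x1 <- if (fc_scale == "linear") table$fc else table$log2fc
  .linear_fit(table$high_increase_mentions, x1, table$increase_mentions,
              c(fc_scale, "increase_mentions"))
}

#' Increase mentions as a function of log2 fold change and popularity
#'
#' Ordinary least squares
#' `increase_mentions ~ alpha*log2fc + beta*popularity + gamma`, testing
#' whether a gene's chance of being mentioned as overexpressed tracks its
#' measured fold change, its popularity in the literature at large, or
#' both. Standardized coefficients allow the two influences to be ranked.
#'
#' @param table a [mention_count_table()].
#' @param log_popularity if `TRUE` regress on `log10(popularity + 1)`
#'   instead of the raw count (off by default).
#' @return as [fit_high_increase_model()].
#' @export
fit_mention_model <- function(table, log_popularity = FALSE) {
  if (nrow(table) < 3L) stop("need at least 3 genes")
  x2 <- if (log_popularity) log10(table$popularity + 1) else table$popularity
  .linear_fit(table$increase_mentions, table$log2fc, x2,
              c("log2fc", "popularity"))
}

#' Zero-intercept trend of high-increase mentions versus mentions
#'
#' Least-squares line through the origin, `slope = sum(x*y) / sum(x^2)`,
#' with the uncentered coefficient of determination
#' `r2 = 1 - sum((y - slope*x)^2) / sum(y^2)` (the centred r2 is
#' ill-defined without an intercept and can be negative; the uncentered
#' definition is used and reported as such).
#'
#' @param x strictly positive regressor (mention-count bin values).
#' @param y response (mean high-increase mentions per bin).
#' @return list with `slope` and `r_squared`.
#' @export
zero_intercept_trend <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (all(x == 0)) stop("all-zero x: slope undefined")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, r_squared = r2)
}

#' Mean high-increase mentions per increase-mention bin
#'
#' Groups genes by their plain increase-mention count (bins 1..`max_bin`)
#' and averages the high-increase mention count within each bin; the
#' binned means feed [zero_intercept_trend()].
#'
#' @param table a [mention_count_table()].
#' @param max_bin largest mention count retained (default 9).
#' @return data frame `mentions` (bin value), `mean_high`, `n_genes`
#'   (empty bins are dropped).
#' @export
bin_mention_counts <- function(table, max_bin = 9L) {
  keep <- table$increase_mentions >= 1L & table$increase_mentions <= max_bin
  t2 <- table[keep, , drop = FALSE]
  if (!nrow(t2))
    return(data.frame(mentions = integer(), mean_high = numeric(),
                      n_genes = integer()))
  agg <- stats::aggregate(high_increase_mentions ~ increase_mentions,
                          data = t2, FUN = mean)
  cnt <- as.data.frame(table(t2$increase_mentions), stringsAsFactors = FALSE)
  data.frame(mentions = agg$increase_mentions,
             mean_high = agg$high_increase_mentions,
             n_genes = as.integer(cnt$Freq[match(agg$increase_mentions,
                                                 as.integer(cnt$Var1))]))
}

#' LR+ between literature and microarray sets across fold-change cutoffs
#'
#' At each log2 fold-change threshold `t`, the microarray up-set is the
#' significant genes with `log2fc > t`; both conditional directions are
#' computed: LR+ of microarray membership given literature membership and
#' vice versa, with a two-sided Fisher exact p-value on the underlying
#' 2x2 table. Thresholds where a conditioning set is empty are flagged
#' undefined (`NA`) rather than erroring.
#'
#' @param lit_set character vector of literature-reported genes.
#' @param de_table gene-level DE data frame (`gene`/`feature_id`, `log2fc`,
#'   `p_adj`).
#' @param thresholds numeric grid of log2 fold-change cutoffs.
#' @param universe_size universe size N (or identifier vector; sets are
#'   clipped to it).
#' @param alpha adjusted-p significance for the microarray set.
#' @return data frame `threshold`, `n_micro`, `n_lit`, `n_overlap`,
#'   `lr_micro_given_lit`, `lr_lit_given_micro`, `fisher_p`.
#' @export
source_lr_vs_threshold <- function(lit_set, de_table, thresholds,
                                   universe_size, alpha = 0.05) {
  ids <- if ("gene" %in% names(de_table)) de_table$gene else de_table$feature_id
  N <- if (is.character(universe_size)) length(unique(universe_size)) else
    as.integer(universe_size)
  lit <- unique(if (is.character(universe_size))
    intersect(lit_set, universe_size) else lit_set)
  rows <- lapply(thresholds, function(tt) {
    micro <- unique(ids[de_table$p_adj < alpha & de_table$log2fc > tt])
    if (is.character(universe_size)) micro <- intersect(micro, universe_size)
    n_ab <- length(intersect(micro, lit))
    lr_ml <- if (length(lit) == 0L || length(lit) == N) NA_real_ else
      lr_plus(overlap_counts(N, length(micro), length(lit), n_ab))
    lr_lm <- if (length(micro) == 0L || length(micro) == N) NA_real_ else
      lr_plus(overlap_counts(N, length(lit), length(micro), n_ab))
    fp <- if (length(micro) && length(lit)) {
      tab <- matrix(c(n_ab, length(micro) - n_ab,
                      length(lit) - n_ab,
                      N - length(micro) - length(lit) + n_ab), 2L, 2L)
      stats::fisher.test(tab)$p.value
    } else NA_real_
    data.frame(threshold = tt, n_micro = length(micro), n_lit = length(lit),
               n_overlap = n_ab, lr_micro_given_lit = lr_ml,
               lr_lit_given_micro = lr_lm, fisher_p = fp)
  })
  do.call(rbind, rows)
}
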