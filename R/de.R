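## Two-group differential expression with empirical-Bayes variance
## moderation, written from first principles (method-of-moments on log
## residual variances, trigamma inversion by Newton's method).

# solve trigamma(x) = y for x > 0; Newton iteration on 1/trigamma scale
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# (d0, s0_sq) by moment matching of log s^2 against a scaled-F marginal
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    # (near-)noiseless data: no spread to estimate a prior from
    return(list(d0 = Inf, s0_sq = if (any(ok)) mean(s2[ok]) else 0,
                inversion_failed = FALSE))
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  failed <- FALSE
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (is.finite(d0)) {
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      failed <- TRUE
      s0_sq <- exp(emean)
    }
  } else {
    # no excess spread in the log variances: common-variance prior
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq, inversion_failed = failed)
}

#' Moderated two-group t-statistics
#'
#' For each feature of a log2-scale matrix, computes the disease-minus-
#' normal mean difference, the pooled residual variance, and a moderated
#' t-statistic in which the residual variance is shrunk toward an
#' empirical-Bayes prior: the prior degrees of freedom `d0` and prior
#' variance `s0_sq` are estimated by matching the moments of the log
#' residual variances to their scaled-F marginal (digamma/trigamma
#' method), the posterior variance is
#' `(d0*s0_sq + df*s2) / (d0 + df)`, and p-values use `d0 + df` degrees of
#' freedom. With `moderate = FALSE` the ordinary pooled-variance t-test is
#' computed instead.
#'
#' Features with zero variance in both groups and zero mean difference are
#' assigned `p = 1`; an all-constant matrix is an error (the prior moment
#' matching is undefined). When the trigamma inversion finds no finite
#' solution the prior degrees of freedom fall back to infinity with a
#' warning.
#'
#' @param values numeric feature-by-sample matrix, log2 scale, finite.
#' @param groups character/factor of length `ncol(values)` with levels
#'   `"disease"` and `"normal"` (at least 2 samples each).
#' @param moderate logical; shrink variances (default) or use the
#'   classical pooled t.
#' @return list with `table` — data frame `feature_id`, `log2fc`, `fc`
#'   (signed linear fold change `sign(log2fc) * 2^|log2fc|`), `t_mod`,
#'   `df_total`, `p`, `p_adj` (Benjamini-Hochberg) — and `params`
#'   (`d0`, `s0_sq`).
#' @export
fit_moderated_t <- function(values, groups, moderate = TRUE) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("groups must label every sample column")
  bad <- setdiff(unique(groups), c("disease", "normal"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  i1 <- which(groups == "disease"); i2 <- which(groups == "normal")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))

  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  log2fc <- m1 - m2
  ss1 <- rowSums((values[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  if (all(s2 == 0) && all(log2fc == 0))
    stop("all-constant matrix: nothing to test and no prior to estimate")

  cfac <- sqrt(1 / n1 + 1 / n2)
  if (moderate) {
    prior <- estimate_prior(s2, df)
    if (prior$inversion_failed)
      warning("trigamma inversion failed; falling back to infinite prior ",
              "degrees of freedom (common variance for all features)")
    s2_post <- if (is.finite(prior$d0)) {
      (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
    } else rep(prior$s0_sq, length(s2))
    df_total <- df + prior$d0
  } else {
    prior <- list(d0 = 0, s0_sq = NA_real_)
    s2_post <- s2
    df_total <- rep(df, length(s2))
  }
  t_mod <- log2fc / (sqrt(s2_post) * cfac)
  p <- 2 * stats::pt(abs(t_mod), df = pmin(df_total, .Machine$double.xmax),
                     lower.tail = FALSE)
  # zero variance, zero difference: nothing observed, p = 1 by convention
  degenerate <- s2_post == 0 & log2fc == 0
  t_mod[degenerate] <- 0
  p[degenerate] <- 1
  # zero posterior variance with nonzero difference: infinitely significant
  p[s2_post == 0 & log2fc != 0] <- 0
  t_mod[s2_post == 0 & log2fc != 0] <- sign(log2fc[s2_post == 0 & log2fc != 0]) * Inf

  table <- data.frame(
    feature_id = rownames(values),
    log2fc = unname(log2fc),
    fc = unname(sign(log2fc) * 2^abs(log2fc)),
    t_mod = unname(t_mod),
    df_total = unname(if (length(df_total) == 1L)
      rep(df_total, nrow(values)) else df_total),
    p = unname(p),
    stringsAsFactors = FALSE)
  # exact-zero p (zero variance, nonzero difference) clamped for the
  # step-up, which is defined on (0, 1]
  table$p_adj <- bh_adjust(pmax(table$p, .Machine$double.xmin))
  table$p_adj[table$p == 0] <- 0
  list(table = table, params = list(d0 = prior$d0, s0_sq = prior$s0_sq))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_i = min_{j >= rank(i)} ( p_(j) * m / j )`, capped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(pvals[o] * m / seq(m, 1L)))
  adj[order(o)]
}

#' Collapse probe-level results to gene level
#'
#' One record per gene: the probe with the smallest adjusted p-value
#' (ties broken by larger |log2fc|, then lexicographically smallest probe
#' id). Probes without a mapping are dropped.
#'
#' @param results probe-level data frame from [fit_moderated_t()]
#'   (`$table`).
#' @param probe2gene data frame with columns `probe`, `gene`; each probe
#'   maps to at most one gene.
#' @param rule collapse rule: `"min_padj"` (default), `"max_fc"` (largest
#'   |log2fc| wins, ties by smaller p_adj), or `"mean"` (mean log2fc,
#'   Fisher-combined representative probe = smallest p_adj for the other
#'   columns).
#' @return gene-level data frame with a `gene` column.
#' @export
collapse_probes <- function(results, probe2gene,
                            rule = c("min_padj", "max_fc", "mean")) {
  rule <- match.arg(rule)
  if (anyDuplicated(probe2gene$probe))
    stop("each probe must map to at most one gene")
  idx <- match(results$feature_id, probe2gene$probe)
  keep <- !is.na(idx)
  res <- results[keep, , drop = FALSE]
  res$gene <- probe2gene$gene[idx[keep]]
  if (!nrow(res)) return(cbind(results[0, , drop = FALSE],
                               gene = character(0)))
  ord <- switch(rule,
    min_padj = order(res$gene, res$p_adj, -abs(res$log2fc), res$feature_id),
    max_fc = order(res$gene, -abs(res$log2fc), res$p_adj, res$feature_id),
    mean = order(res$gene, res$p_adj, -abs(res$log2fc), res$feature_id))
  res <- res[ord, , drop = FALSE]
  first <- !duplicated(res$gene)
  out <- res[first, , drop = FALSE]
  if (rule == "mean") {
    mfc <- tapply(res$log2fc, res$gene, mean)
    out$log2fc <- unname(mfc[out$gene])
    out$fc <- sign(out$log2fc) * 2^abs(out$log2fc)
  }
  rownames(out) <- NULL
  out[, c("gene", setdiff(names(out), "gene"))]
}

#' Significant up- and down-regulated gene sets
#'
#' Thresholds operate on the signed linear fold change
#' `fc = sign(log2fc) * 2^|log2fc|`: the up-set is
#' `{p_adj < alpha and fc > fc_cutoff}`, the down-set
#' `{p_adj < alpha and fc < -fc_cutoff}`. `fc_cutoff = 0` admits every
#' significant gene by sign (the "any significant overexpression" cutoff),
#' `fc_cutoff = 2` corresponds to a twofold change, i.e. |log2fc| > 1.
#'
#' @param results gene-level data frame with columns `gene` (or
#'   `feature_id`), `fc`, `p_adj`.
#' @param fc_cutoff non-negative linear fold-change cutoff.
#' @param alpha adjusted-p significance level.
#' @return list with character vectors `up` and `down`.
#' @export
filter_degs <- function(results, fc_cutoff = 0, alpha = 0.05) {
  if (fc_cutoff < 0) stop("fc_cutoff must be non-negative")
  ids <- if ("gene" %in% names(results)) results$gene else results$feature_id
  sig <- results$p_adj < alpha
  list(up = ids[sig & results$fc > fc_cutoff],
       down = ids[sig & results$fc < -fc_cutoff])
}
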