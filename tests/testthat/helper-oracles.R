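# Independent oracles used across the suite. Each one computes the target
# quantity from its definition, by brute force, without touching the
# package's own code paths.

# Benjamini-Hochberg step-up straight from the definition:
# adj_i = min_{j >= rank(i)} p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- p[o]
  adj <- vapply(seq_len(m), function(k) min(s[k:m] * m / (k:m)), numeric(1))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# LR+ by exhaustive membership enumeration over explicit indicator vectors
lr_oracle <- function(in_a, in_b) {
  p_given_b <- mean(in_a[in_b])
  p_given_notb <- mean(in_a[!in_b])
  p_given_b / p_given_notb
}

# upper hypergeometric tail P(X >= k) as an explicit sum of binomials
hyper_tail_oracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  i <- max(k, 0L):min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ordinary least squares through the normal equations
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# classical pooled-variance two-sample t for one feature
pooled_t_oracle <- function(x_disease, x_normal) {
  n1 <- length(x_disease); n2 <- length(x_normal)
  s2 <- (sum((x_disease - mean(x_disease))^2) +
           sum((x_normal - mean(x_normal))^2)) / (n1 + n2 - 2)
  tt <- (mean(x_disease) - mean(x_normal)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2,
       p = 2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE))
}

# a tiny hand-built annotated document
make_doc <- function(pmid, title, abstract, genes = list(),
                     diseases = list()) {
  text <- paste(title, abstract)
  rows <- list()
  for (g in genes) {
    p <- regexpr(g, text, fixed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      start = p - 1L, end = p - 1L + nchar(g), text = g, type = "Gene",
      id = g, stringsAsFactors = FALSE)
  }
  for (d in diseases) {
    p <- regexpr(d, text, fixed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      start = p - 1L, end = p - 1L + nchar(d), text = d, type = "Disease",
      id = d, stringsAsFactors = FALSE)
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), text = character(),
               type = character(), id = character())
  annotated_document(pmid, title, abstract, m)
}
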