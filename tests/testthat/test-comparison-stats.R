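test_that("over/under ratios follow the unique-gene counting rule", {
  st <- data.frame(
    pmid = as.character(1:6),
    gene = c("A", "B", "C", "C", "D", "D"),
    disease = "X",
    delta = c("increase", "increase", "high_increase", "increase",
              "decrease", "increase"))
  ou <- over_under_ratio(st)
  # over: A, B, C, D; under: D (counted once per direction)
  expect_equal(ou$n_over, 4L)
  expect_equal(ou$n_under, 1L)
  expect_equal(ou$pct_over + ou$pct_under, 100)
  expect_equal(ou$ratio, 4)
  ou2 <- over_under_ratio(list(up = c("A", "B", "B"), down = c("C", "D")))
  expect_equal(ou2$ratio, 1)
  expect_equal(ou2$pct_over, 50)
  expect_equal(over_under_ratio(list(up = "A", down = character()))$ratio, Inf)
  expect_error(over_under_ratio(st[0, ]), "no statements")
})

test_that("LR+ matches its definition on hand-checked tables", {
  expect_equal(lr_plus(overlap_counts(100, 10, 10, 1)), 1)   # independence
  expect_equal(lr_plus(overlap_counts(1000, 50, 40, 20)), 16)
  expect_equal(lr_plus(overlap_counts(100, 10, 10, 0)), 0)
  expect_equal(lr_plus(overlap_counts(100, 5, 10, 5)), Inf)
  expect_error(lr_plus(overlap_counts(100, 10, 0, 0)), "empty")
  expect_error(lr_plus(overlap_counts(100, 10, 100, 10)), "whole universe")
  expect_error(overlap_counts(100, 5, 10, 6), "n_ab")
})

test_that("LR+ equals the exhaustive-enumeration oracle on small universes", {
  set.seed(202)
  for (N in 2:50) {
    for (rep in 1:8) {
      in_a <- runif(N) < runif(1, 0.1, 0.9)
      in_b <- runif(N) < runif(1, 0.1, 0.9)
      n_b <- sum(in_b)
      if (n_b == 0L || n_b == N || sum(in_a) == 0L) next
      ours <- lr_plus(overlap_counts(N, sum(in_a), n_b, sum(in_a & in_b)))
      expect_equal(ours, lr_oracle(in_a, in_b), tolerance = 1e-12)
    }
  }
})

test_that("LR+ is strictly increasing in the overlap at fixed margins", {
  vals <- vapply(0:9, function(k) lr_plus(overlap_counts(100, 10, 12, k)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("log LR+ is centred on zero under independent sampling", {
  set.seed(203)
  logs <- replicate(500, {
    in_a <- runif(2000) < 0.15
    in_b <- runif(2000) < 0.15
    v <- lr_plus(overlap_counts(2000, sum(in_a), sum(in_b),
                                sum(in_a & in_b)))
    if (is.finite(v) && v > 0) log(v) else NA_real_
  })
  logs <- logs[is.finite(logs)]
  expect_lt(abs(mean(logs)), 3 * sd(logs) / sqrt(length(logs)))
})

test_that("pairwise disease LR+ matrices match hand-computed overlaps", {
  sets <- list(A = c("g1", "g2", "g3"),
               B = c("g2", "g3", "g4", "g5"),
               C = c("g6"))
  M <- pairwise_disease_lr(sets, 100)
  expect_true(all(is.infinite(diag(M))))
  expect_equal(M["A", "B"], (2 / 4) / (1 / 96))       # 48
  expect_equal(M["B", "A"], (2 / 3) / (2 / 97))
  expect_equal(M["C", "A"], 0)
  # identical sets: both directions infinite
  M2 <- pairwise_disease_lr(list(X = c("a", "b"), Y = c("a", "b")), 50)
  expect_true(is.infinite(M2["X", "Y"]) && is.infinite(M2["Y", "X"]))
})

test_that("independent random sets give near-unity mean LR+", {
  set.seed(204)
  vals <- replicate(100, {
    in_a <- runif(17126) < 0.05
    in_b <- runif(17126) < 0.05
    lr_plus(overlap_counts(17126, sum(in_a), sum(in_b), sum(in_a & in_b)))
  })
  expect_gt(mean(vals), 0.8)
  expect_lt(mean(vals), 1.25)
})

test_that("multi-disease membership counts match brute-force enumeration", {
  universe <- paste0("g", 1:30)
  sets <- list(W = universe[1:10], X = universe[5:14],
               Y = universe[8:20], Z = universe[c(1, 9, 10, 25)])
  res <- multi_disease_overlap(sets, 30)
  # brute force over the universe
  k_of <- vapply(universe, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), numeric(1))
  for (k in 1:4) {
    expect_equal(res$membership_counts$n_exact[k], sum(k_of == k))
    expect_equal(res$membership_counts$n_at_least[k], sum(k_of >= k))
  }
  # disjoint sets: every k >= 2 count is zero
  res2 <- multi_disease_overlap(list(A = "g1", B = "g2", C = "g3"), 30)
  expect_true(all(res2$membership_counts$n_exact[2:3] == 0))
  # nested sets: count at the deepest level equals the innermost set
  res3 <- multi_disease_overlap(list(A = universe[1:3], B = universe[1:6],
                                     C = universe[1:12]), 30)
  expect_equal(res3$membership_counts$n_exact[3], 3L)
})

test_that("cumulative reporting probability follows the definition", {
  de <- data.frame(gene = paste0("g", 1:6),
                   fc = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5))
  lit <- c("g3", "g5", "g6")
  cur <- cumulative_reporting_prob(lit, de, thresholds = c(0, 2, 4),
                                   min_denominator = 2)
  # fc > 0: 3 of 6 reported; fc > 2: g3,g5,g6 of {g3..g6}; fc > 4: g5,g6 of {g5,g6}
  expect_equal(cur$prob, c(3 / 6, 3 / 4, 1))
  # threshold below the minimum fc: the overall reported fraction
  expect_equal(cumulative_reporting_prob(lit, de, -1)$prob, 0.5)
  # empty literature set: identically zero
  expect_true(all(cumulative_reporting_prob(character(), de, c(0, 2))$prob == 0))
  expect_error(cumulative_reporting_prob(lit, de, 10), "empty denominator|no gene")
})

test_that("reporting curves rise with fold change on planted data", {
  cfg <- synthetic_config(n_genes = 3000, n_diseases = 1, frac_de = 0.3,
                          report_alpha = 1.5, report_beta = 0.3,
                          distractor_frac = 0, seed = 41)
  st <- simulate_study(cfg)
  stm <- extract_statements(st$corpus, target_diseases = "DIS01")
  lit_up <- unique(stm$gene[delta_sign(stm$delta) > 0])
  de <- fit_moderated_t(st$expression$DIS01$matrix,
                        st$expression$DIS01$groups)$table
  de$gene <- de$feature_id
  cur <- cumulative_reporting_prob(lit_up, de, thresholds = seq(0, 4, 1))
  cur <- cur[cur$stable, ]
  # non-decreasing up to a 3-SD binomial envelope
  for (i in seq_len(nrow(cur) - 1)) {
    envelope <- 3 * sqrt(cur$prob[i] * (1 - cur$prob[i]) / cur$n_above[i + 1])
    expect_gte(cur$prob[i + 1], cur$prob[i] - envelope)
  }
  expect_gt(cur$prob[nrow(cur)], cur$prob[1])
})

test_that("point-biserial correlation matches the textbook formula", {
  ind <- c(1, 0, 1, 0, 1, 0)
  pop <- c(10, 2, 8, 1, 12, 3)
  out <- popularity_correlation(ind, pop)
  r_hand <- sum((ind - mean(ind)) * (pop - mean(pop))) /
    sqrt(sum((ind - mean(ind))^2) * sum((pop - mean(pop))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(out$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(popularity_correlation(rep(1, 6), pop), "constant")
  # monotone construction gives positive correlation
  pop2 <- 1:100
  ind2 <- as.integer(pop2 > 50)
  expect_gt(popularity_correlation(ind2, pop2)$r, 0)
  # independence null: r near zero at large n
  set.seed(50)
  n <- 17126
  r0 <- popularity_correlation(rbinom(n, 1, 0.1), rpois(n, 5))$r
  expect_lt(abs(r0), 3 / sqrt(n))
})

test_that("mention models recover exact linear data to machine precision", {
  set.seed(60)
  tab <- data.frame(gene = paste0("g", 1:40),
                    increase_mentions = rpois(40, 3),
                    popularity = rpois(40, 20),
                    log2fc = rnorm(40), fc = NA)
  tab$fc <- sign(tab$log2fc) * 2^abs(tab$log2fc)
  tab$high_increase_mentions <- 0.005 * tab$fc +
    0.2 * tab$increase_mentions + 0.1
  f1 <- suppressWarnings(fit_high_increase_model(tab))
  expect_equal(f1$alpha, 0.005, tolerance = 1e-10)
  expect_equal(f1$beta, 0.2, tolerance = 1e-10)
  expect_equal(f1$gamma, 0.1, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-10)
  tab$increase_mentions <- 2 * tab$log2fc + 0.5 * tab$popularity + 3
  f2 <- suppressWarnings(fit_mention_model(tab))
  expect_equal(f2$alpha, 2, tolerance = 1e-10)
  expect_equal(f2$beta, 0.5, tolerance = 1e-10)
  # collinear regressors are refused by name
  tab$popularity <- tab$log2fc * 2
  expect_error(fit_mention_model(tab), "collinear")
})

test_that("OLS fits reproduce the normal equations on random designs", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    tab <- data.frame(gene = paste0("g", 1:n),
                      increase_mentions = rnorm(n),
                      popularity = rnorm(n),
                      log2fc = rnorm(n), fc = rnorm(n),
                      high_increase_mentions = rnorm(n))
    f <- fit_mention_model(tab)
    o <- ols_oracle(tab$increase_mentions,
                    cbind(tab$log2fc, tab$popularity))
    expect_equal(c(f$gamma, f$alpha, f$beta), o, tolerance = 1e-10)
  }
})

test_that("permuted responses give uniform coefficient p-values", {
  set.seed(62)
  n <- 60
  tab0 <- data.frame(gene = paste0("g", 1:n),
                     increase_mentions = rpois(n, 2),
                     popularity = rpois(n, 10),
                     log2fc = rnorm(n), fc = rnorm(n),
                     high_increase_mentions = rpois(n, 1))
  pa <- replicate(200, {
    tab <- tab0
    tab$high_increase_mentions <- sample(tab$high_increase_mentions)
    fit_high_increase_model(tab)$p_alpha
  })
  expect_gt(stats::ks.test(pa, "punif")$p.value, 0.01)
  # shuffled popularity is rarely significant
  pb <- replicate(200, {
    tab <- tab0
    tab$popularity <- sample(tab$popularity)
    fit_mention_model(tab)$p_beta
  })
  expect_gte(mean(pb >= 0.05), 0.9)
})

test_that("zero-intercept trend uses the uncentered definitions", {
  out <- zero_intercept_trend(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$slope, 2)
  expect_equal(out$r_squared, 1)
  out2 <- zero_intercept_trend(c(1, 2), c(1, 1))
  expect_equal(out2$slope, 0.6)
  expect_equal(out2$r_squared, 0.9)
  expect_error(zero_intercept_trend(c(0, 0), c(1, 2)), "all-zero")
  # agrees with lm through the origin
  set.seed(63)
  x <- runif(20, 1, 9); y <- 0.3 * x + rnorm(20, 0, 0.2)
  fit <- lm(y ~ 0 + x)
  out3 <- zero_intercept_trend(x, y)
  expect_equal(out3$slope, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(out3$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
})

test_that("mention-count binning averages high-increase counts per bin", {
  tab <- data.frame(gene = paste0("g", 1:6),
                    increase_mentions = c(1, 1, 2, 2, 10, 0),
                    high_increase_mentions = c(0, 1, 2, 4, 9, 5),
                    popularity = 1, log2fc = 0, fc = 0)
  bins <- bin_mention_counts(tab, max_bin = 9)
  expect_equal(bins$mentions, c(1, 2))
  expect_equal(bins$mean_high, c(0.5, 3))
  expect_equal(bins$n_genes, c(2L, 2L))
})

test_that("source LR+ curves behave at the engineered extremes", {
  de <- data.frame(gene = paste0("g", 1:100),
                   log2fc = seq(-2, 3, length.out = 100),
                   p_adj = 0.01)
  de$fc <- sign(de$log2fc) * 2^abs(de$log2fc)
  # literature set equal to the microarray up-set at cutoff 1
  lit <- de$gene[de$log2fc > 1]
  cur <- source_lr_vs_threshold(lit, de, thresholds = 1, universe_size = 100)
  expect_true(is.infinite(cur$lr_micro_given_lit))
  expect_true(is.infinite(cur$lr_lit_given_micro))
  # empty conditioning set flags NA, no error
  cur2 <- source_lr_vs_threshold(character(), de, thresholds = 1,
                                 universe_size = 100)
  expect_true(is.na(cur2$lr_micro_given_lit))
})

test_that("random literature sets give LR+ curves near one", {
  set.seed(70)
  cfg <- synthetic_config(n_genes = 4000, n_diseases = 1, frac_de = 0.25,
                          seed = 71)
  ex <- generate_expression(cfg, "DIS01")
  de <- fit_moderated_t(ex$matrix, ex$groups)$table
  de$gene <- de$feature_id
  means <- colMeans(do.call(rbind, lapply(1:20, function(i) {
    lit <- sample(de$gene, 400)
    cur <- source_lr_vs_threshold(lit, de, thresholds = c(0, 0.5, 1),
                                  universe_size = 4000)
    c(cur$lr_micro_given_lit[1], cur$lr_lit_given_micro[1])
  })))
  expect_true(all(means > 0.8 & means < 1.25))
})

test_that("LR+ curves rise with the threshold on reporting-biased data", {
  # reporting probability increases with |log2FC|, so the two sources
  # agree more as the cutoff rises; asserted on the seed-averaged
  # microarray-given-literature curve (the reverse direction is infinite
  # at low cutoffs here because the generator never reports false DEGs,
  # making the literature a subset of the significant set)
  curves <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_genes = 3000, n_diseases = 1, frac_de = 0.3,
                            report_alpha = 0.8, report_beta = 0.3,
                            report_intercept = -4, distractor_frac = 0,
                            seed = 600 + s)
    st <- simulate_study(cfg)
    stm <- extract_statements(st$corpus, target_diseases = "DIS01")
    lit_up <- unique(stm$gene[delta_sign(stm$delta) > 0])
    de <- fit_moderated_t(st$expression$DIS01$matrix,
                          st$expression$DIS01$groups)$table
    de$gene <- de$feature_id
    source_lr_vs_threshold(lit_up, de, thresholds = c(0, 1, 1.5),
                           universe_size = 3000)$lr_micro_given_lit
  }, numeric(3))
  avg <- rowMeans(curves)
  expect_gt(avg[3], avg[1])
})

test_that("mention count tables aggregate statements consistently", {
  st <- data.frame(pmid = as.character(1:5),
                   gene = c("g1", "g1", "g2", "g1", "g3"),
                   disease = c("D", "D", "D", "E", "D"),
                   delta = c("increase", "high_increase", "increase",
                             "increase", "decrease"))
  de <- data.frame(gene = c("g1", "g2", "g3"), log2fc = c(1, -1, 0),
                   fc = c(2, -2, 1), p_adj = 0.01)
  pop <- c(g1 = 10, g2 = 5, g3 = 1)
  tab <- mention_count_table(st, de, pop, disease = "D")
  expect_equal(tab$increase_mentions, c(1L, 1L, 0L))
  expect_equal(tab$high_increase_mentions, c(1L, 0L, 0L))
  expect_equal(tab$popularity, c(10, 5, 1))
})
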