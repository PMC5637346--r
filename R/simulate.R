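#' Configuration of the synthetic study
#'
#' Bundles every parameter of the generator: the two-group expression
#' design, the planted differential-expression signal, the power-law
#' popularity of genes in the wider literature, and the reporting model
#' that turns planted fold changes into literature statements.
#'
#' The reporting model is logistic per (gene, disease) pair: a truly
#' differentially expressed gene is reported with probability
#' `plogis(report_intercept + report_alpha*|log2FC| +
#' report_beta*log10(popularity))`; for underexpressed genes that
#' probability is divided by `over_report_ratio`, so the expected
#' over:under ratio of reported genes equals `over_report_ratio` exactly
#' when planted effect sizes are direction-balanced. Reported pairs receive
#' `1 + Poisson(mention_rate * log10(popularity + 1))` mentions, each
#' phrased as a high-grade qualifier with probability
#' `high_qualifier_rate`.
#'
#' @param n_genes,n_diseases,n_samples_per_group design sizes.
#' @param frac_de fraction in (0,1) of genes truly DE per disease.
#' @param lfc_scale positive scale of planted log2 fold changes; magnitudes
#'   are drawn uniformly from `[lfc_scale, 3*lfc_scale]`.
#' @param noise_sd per-sample Gaussian noise SD on the log2 scale.
#' @param popularity_exponent power-law tail index of gene popularity.
#' @param report_alpha,report_beta,report_intercept logistic coefficients
#'   coupling reporting probability to |log2FC| and log10(popularity).
#' @param over_report_ratio multiplicative reporting preference for
#'   overexpressed versus underexpressed genes.
#' @param high_qualifier_rate probability in (0,1) that a mention is
#'   phrased with a high-grade qualifier.
#' @param mention_rate rate scale for extra mentions of a reported gene.
#' @param distractor_frac fraction in \[0,1\] of corpus sentences that are
#'   distractors (no trigger, no qualifier, or an excluded qualifier);
#'   `1` yields a corpus with no extractable statement.
#' @param statements_per_abstract number of statement sentences bundled
#'   into one synthetic abstract.
#' @param n_go_terms,n_enriched_terms,go_base_rate,go_odds_factor GO
#'   annotation model: number of terms, number planted as enriched,
#'   baseline per-gene membership probability, and the odds multiplier
#'   applied to DE genes for enriched terms.
#' @param seed integer root seed; all generator streams derive from it.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 2000L, n_diseases = 4L,
                             n_samples_per_group = 10L, frac_de = 0.1,
                             lfc_scale = 1, noise_sd = 0.4,
                             popularity_exponent = 1.7,
                             report_alpha = 0.8, report_beta = 1.2,
                             report_intercept = -3,
                             over_report_ratio = 3.5,
                             high_qualifier_rate = 0.25,
                             mention_rate = 1,
                             distractor_frac = 0.3,
                             statements_per_abstract = 1L,
                             n_go_terms = 40L, n_enriched_terms = 5L,
                             go_base_rate = 0.05, go_odds_factor = 5,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_diseases = as.integer(n_diseases),
              n_samples_per_group = as.integer(n_samples_per_group),
              frac_de = frac_de, lfc_scale = lfc_scale, noise_sd = noise_sd,
              popularity_exponent = popularity_exponent,
              report_alpha = report_alpha, report_beta = report_beta,
              report_intercept = report_intercept,
              over_report_ratio = over_report_ratio,
              high_qualifier_rate = high_qualifier_rate,
              mention_rate = mention_rate,
              distractor_frac = distractor_frac,
              statements_per_abstract = as.integer(statements_per_abstract),
              n_go_terms = as.integer(n_go_terms),
              n_enriched_terms = as.integer(n_enriched_terms),
              go_base_rate = go_base_rate, go_odds_factor = go_odds_factor,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, cfg$n_diseases >= 1L,
            cfg$n_samples_per_group >= 1L,
            cfg$frac_de > 0, cfg$frac_de < 1,
            cfg$lfc_scale > 0, cfg$noise_sd >= 0,
            cfg$popularity_exponent > 0,
            cfg$over_report_ratio > 0,
            cfg$high_qualifier_rate > 0, cfg$high_qualifier_rate < 1,
            cfg$mention_rate >= 0,
            cfg$distractor_frac >= 0, cfg$distractor_frac <= 1,
            cfg$statements_per_abstract >= 1L,
            cfg$go_base_rate > 0, cfg$go_base_rate < 1,
            cfg$go_odds_factor > 0)
  structure(cfg, class = "synthetic_config")
}

# deterministic child seed per generator stream (< 2^31)
child_seed <- function(root, stream) {
  as.integer(((as.double(root) %% 2147483647) * 48271 + stream) %% 2147483629 + 1)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))
disease_ids <- function(n) sprintf("DIS%02d", seq_len(n))

#' Planted ground truth for a synthetic study
#'
#' Draws, per disease, which genes are differentially expressed and their
#' planted log2 fold changes (direction-balanced, magnitudes uniform on
#' `[lfc_scale, 3*lfc_scale]`; non-DE genes have exactly 0), and the
#' power-law popularity counts. Gold statements and enriched terms are
#' filled in later by [generate_corpus()] and [generate_go_annotations()].
#'
#' @param config a [synthetic_config()].
#' @return list of class `"synthetic_truth"` with `genes`, `diseases`,
#'   `de_table` (gene x disease matrix of planted log2FC), `popularity`
#'   (named integer vector), `gold_statements` (`NULL` until the corpus is
#'   generated), `enriched_terms` (`NULL` until annotations are generated).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- gene_ids(config$n_genes)
  diseases <- disease_ids(config$n_diseases)
  de_table <- matrix(0, config$n_genes, config$n_diseases,
                     dimnames = list(genes, diseases))
  n_de <- round(config$frac_de * config$n_genes)
  set.seed(child_seed(config$seed, 1L))
  for (j in seq_len(config$n_diseases)) {
    idx <- sample.int(config$n_genes, n_de)
    sgn <- rep(c(1, -1), length.out = n_de)[sample.int(n_de)]
    mag <- stats::runif(n_de, config$lfc_scale, 3 * config$lfc_scale)
    de_table[idx, j] <- sgn * mag
  }
  popularity <- generate_popularity(config)
  structure(list(genes = genes, diseases = diseases, de_table = de_table,
                 popularity = popularity, gold_statements = NULL,
                 enriched_terms = NULL),
            class = "synthetic_truth")
}

#' Power-law gene popularity counts
#'
#' Literature mention counts per gene, drawn from a discretised Pareto
#' distribution with tail index `popularity_exponent` (all counts >= 1;
#' larger exponents give lighter tails and smaller maxima).
#'
#' @param config a [synthetic_config()].
#' @return named integer vector, gene -> mention count.
#' @export
generate_popularity <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(child_seed(config$seed, 2L))
  u <- stats::runif(config$n_genes)
  counts <- pmax(1L, as.integer(floor((1 - u)^(-1 / config$popularity_exponent))))
  names(counts) <- gene_ids(config$n_genes)
  counts
}

#' Two-group expression matrix with planted fold changes
#'
#' Simulates a log2-scale gene-by-sample matrix for one disease:
#' `n_samples_per_group` normal and `n_samples_per_group` diseased samples,
#' per-gene baselines uniform on \[4, 12\], the planted log2FC added to the
#' diseased group, and i.i.d. Gaussian noise of SD `noise_sd`.
#'
#' @param config a [synthetic_config()].
#' @param disease disease identifier (a column of `truth$de_table`).
#' @param truth a [simulate_truth()] result under the same config;
#'   generated on the fly when omitted.
#' @return list with `matrix` (genes x samples, log2 scale), `groups`
#'   (named character vector, `"disease"`/`"normal"`), and `truth_slice`
#'   (data frame gene, planted `log2fc`).
#' @export
generate_expression <- function(config, disease, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_samples_per_group < 2L)
    stop("n_samples_per_group must be >= 2 (within-group variance undefined)")
  if (!disease %in% colnames(truth$de_table))
    stop("unknown disease: ", disease)
  j <- match(disease, colnames(truth$de_table))
  lfc <- truth$de_table[, j]
  n <- config$n_samples_per_group
  g <- config$n_genes
  set.seed(child_seed(config$seed, 10L + j))
  baseline <- stats::runif(g, 4, 12)
  noise <- matrix(stats::rnorm(g * 2L * n, 0, config$noise_sd), g, 2L * n)
  mat <- baseline + noise
  mat[, seq_len(n) + n] <- mat[, seq_len(n) + n] + lfc
  groups <- c(rep("normal", n), rep("disease", n))
  colnames(mat) <- paste0(disease, "_", groups, "_", c(seq_len(n), seq_len(n)))
  names(groups) <- colnames(mat)
  rownames(mat) <- truth$genes
  list(matrix = mat, groups = groups,
       truth_slice = data.frame(gene = truth$genes, log2fc = unname(lfc),
                                stringsAsFactors = FALSE))
}

# predicate-friendly qualifier phrases used by the sentence templates
.gen_phrases <- list(
  increase = c("elevated", "increased", "significantly overexpressed",
               "upregulated"),
  high_increase = c("greatly elevated", "markedly increased",
                    "strongly overexpressed"),
  decrease = c("decreased", "reduced", "downregulated",
               "significantly reduced"),
  high_decrease = c("greatly decreased", "markedly reduced",
                    "strongly downregulated")
)

# one statement sentence; returns text plus relative 0-based mention offsets
.render_statement <- function(gene, disease, phrase, template) {
  switch(template,
    paste0("Expression of ", gene, " was ", phrase,
           " in patients with ", disease, "."),
    paste0(gene, " transcription was ", phrase, " in ", disease,
           " tissue compared with controls."),
    paste0("We found that ", gene, " production was ", phrase,
           " in ", disease, ".")
  )
}

.render_distractor <- function(gene, disease, kind) {
  switch(kind,
    paste0(gene, " levels correlate with ", disease, " severity."),
    paste0("Expression of ", gene, " was aberrant in patients with ",
           disease, "."),
    paste0(gene, " is expressed in tissues affected by ", disease, ".")
  )
}

# locate the (first) occurrence of each entity in the abstract and return
# PubTator mention rows relative to the full text (title + " " + abstract)
.mention_rows <- function(title, abstract, entities, types) {
  off <- nchar(title) + 1L   # 0-based offset of abstract start in full text
  out <- list()
  used <- integer(0)
  for (k in seq_along(entities)) {
    pos <- gregexpr(entities[k], abstract, fixed = TRUE)[[1]]
    pos <- setdiff(as.integer(pos), used)
    if (!length(pos) || pos[1] < 0) next
    p <- pos[1]
    used <- c(used, p)
    out[[length(out) + 1L]] <- data.frame(
      start = off + p - 1L, end = off + p - 1L + nchar(entities[k]),
      text = entities[k], type = types[k], id = entities[k],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_mentions())
  unique(do.call(rbind, out))
}

#' Synthetic annotated corpus encoding the planted reporting model
#'
#' Realises literature statements from the planted truth: each truly DE
#' (gene, disease) pair is reported with the logistic probability described
#' in [synthetic_config()]; reported pairs receive one or more mention
#' sentences, each carrying the gene mention, the disease mention, a
#' trigger word and a qualifier phrase consistent with the planted
#' direction (high-grade with probability `high_qualifier_rate`).
#' Distractor sentences (no trigger, excluded qualifier, or no qualifier)
#' are interleaved so that they make up `distractor_frac` of all
#' sentences; at `distractor_frac = 1` the corpus contains distractors
#' only and the gold statement set is empty.
#'
#' @param config a [synthetic_config()].
#' @param truth a [simulate_truth()] result under the same config.
#' @return list with `corpus` (list of [annotated_document()]) and `truth`
#'   (the input truth with `gold_statements` filled in: a data frame
#'   `pmid, gene, disease, delta, log2fc`, deduplicated on the tuple).
#' @export
generate_corpus <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  set.seed(child_seed(config$seed, 20L))
  pop <- truth$popularity
  mentions <- list()   # one row per realised mention
  for (j in seq_along(truth$diseases)) {
    dis <- truth$diseases[j]
    lfc <- truth$de_table[, j]
    de_idx <- which(lfc != 0)
    if (!length(de_idx)) next
    lp <- config$report_intercept + config$report_alpha * abs(lfc[de_idx]) +
      config$report_beta * log10(pop[de_idx])
    p <- stats::plogis(lp)
    p[lfc[de_idx] < 0] <- p[lfc[de_idx] < 0] / config$over_report_ratio
    reported <- stats::rbinom(length(de_idx), 1L, p) == 1L
    for (i in de_idx[reported]) {
      n_m <- 1L + stats::rpois(1L, config$mention_rate * log10(pop[i] + 1))
      high <- stats::rbinom(n_m, 1L, config$high_qualifier_rate) == 1L
      base <- if (lfc[i] > 0) "increase" else "decrease"
      delta <- ifelse(high, paste0("high_", base), base)
      for (d in delta)
        mentions[[length(mentions) + 1L]] <- data.frame(
          gene = truth$genes[i], disease = dis, delta = d,
          log2fc = unname(lfc[i]), stringsAsFactors = FALSE)
    }
  }
  gold_mentions <- if (length(mentions)) do.call(rbind, mentions) else
    data.frame(gene = character(), disease = character(),
               delta = character(), log2fc = numeric(),
               stringsAsFactors = FALSE)
  if (config$distractor_frac >= 1)
    gold_mentions <- gold_mentions[0, , drop = FALSE]
  n_gold <- nrow(gold_mentions)
  n_distract <- if (config$distractor_frac >= 1) {
    max(10L, length(mentions))
  } else {
    round(config$distractor_frac / (1 - config$distractor_frac) * n_gold)
  }

  # sentences: gold mentions followed by distractors, then shuffled into
  # abstracts of `statements_per_abstract` sentences
  sent <- character(n_gold + n_distract)
  sent_gene <- character(length(sent))
  sent_dis <- character(length(sent))
  is_gold <- logical(length(sent))
  if (n_gold) {
    for (k in seq_len(n_gold)) {
      ph_set <- .gen_phrases[[gold_mentions$delta[k]]]
      ph <- ph_set[sample.int(length(ph_set), 1L)]
      sent[k] <- .render_statement(gold_mentions$gene[k],
                                   gold_mentions$disease[k], ph,
                                   sample.int(3L, 1L))
      sent_gene[k] <- gold_mentions$gene[k]
      sent_dis[k] <- gold_mentions$disease[k]
      is_gold[k] <- TRUE
    }
  }
  if (n_distract) {
    dg <- sample(truth$genes, n_distract, replace = TRUE)
    dd <- sample(truth$diseases, n_distract, replace = TRUE)
    for (k in seq_len(n_distract)) {
      sent[n_gold + k] <- .render_distractor(dg[k], dd[k],
                                             1L + (k - 1L) %% 3L)
      sent_gene[n_gold + k] <- dg[k]
      sent_dis[n_gold + k] <- dd[k]
    }
  }
  ord <- sample.int(length(sent))
  docs <- list()
  gold_rows <- list()
  spa <- config$statements_per_abstract
  n_docs <- ceiling(length(sent) / max(spa, 1L))
  for (d in seq_len(n_docs)) {
    take <- ord[seq((d - 1L) * spa + 1L, min(d * spa, length(sent)))]
    pmid <- sprintf("9%06d", d)
    title <- paste0("Report on ", sent_dis[take[1]], " biology.")
    abstract <- paste(sent[take], collapse = " ")
    ment <- .mention_rows(title, abstract,
                          entities = c(sent_gene[take], sent_dis[take]),
                          types = c(rep("Gene", length(take)),
                                    rep("Disease", length(take))))
    # the title's disease word is not annotated: only abstract mentions are
    docs[[d]] <- annotated_document(pmid, title, abstract, ment)
    for (k in take[is_gold[take]]) {
      gold_rows[[length(gold_rows) + 1L]] <- data.frame(
        pmid = pmid, gene = gold_mentions$gene[k],
        disease = gold_mentions$disease[k], delta = gold_mentions$delta[k],
        log2fc = gold_mentions$log2fc[k], stringsAsFactors = FALSE)
    }
  }
  gold <- if (length(gold_rows)) do.call(rbind, gold_rows) else
    data.frame(pmid = character(), gene = character(), disease = character(),
               delta = character(), log2fc = numeric(),
               stringsAsFactors = FALSE)
  key <- paste(gold$pmid, gold$gene, gold$disease, gold$delta, sep = "\r")
  gold <- gold[!duplicated(key), , drop = FALSE]
  rownames(gold) <- NULL
  truth$gold_statements <- gold
  list(corpus = docs, truth = truth)
}

#' Synthetic gene-to-GO-term annotations with planted enrichment
#'
#' Every term has baseline membership probability `go_base_rate` per gene;
#' for the `n_enriched_terms` planted terms the membership odds of truly DE
#' genes (nonzero planted log2FC in any disease) are multiplied by
#' `go_odds_factor`. Every gene is guaranteed at least one term.
#'
#' @param config a [synthetic_config()].
#' @param truth a [simulate_truth()] result under the same config.
#' @return list with `annotations` (data frame `gene`, `term`) and `truth`
#'   with `enriched_terms` filled in.
#' @export
generate_go_annotations <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  set.seed(child_seed(config$seed, 30L))
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  enriched <- sample(terms, min(config$n_enriched_terms, length(terms)))
  de_gene <- rowSums(truth$de_table != 0) > 0
  p0 <- config$go_base_rate
  odds_de <- p0 / (1 - p0) * config$go_odds_factor
  p_de <- odds_de / (1 + odds_de)
  rows <- list()
  for (t in terms) {
    p_vec <- rep(p0, config$n_genes)
    if (t %in% enriched) p_vec[de_gene] <- p_de
    member <- stats::rbinom(config$n_genes, 1L, p_vec) == 1L
    if (any(member))
      rows[[length(rows) + 1L]] <- data.frame(gene = truth$genes[member],
                                              term = t,
                                              stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  orphan <- setdiff(truth$genes, unique(ann$gene))
  if (length(orphan)) {
    ann <- rbind(ann, data.frame(
      gene = orphan, term = sample(terms, length(orphan), replace = TRUE),
      stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$gene, ann$term), , drop = FALSE]
  rownames(ann) <- NULL
  truth$enriched_terms <- sort(enriched)
  list(annotations = ann, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs every generator under one root seed: planted truth, one expression
#' matrix per disease, the annotated corpus and the GO annotations.
#'
#' @param config a [synthetic_config()].
#' @return list of class `"synthetic_study"` with `config`, `truth`
#'   (gold statements and enriched terms filled), `expression` (per-disease
#'   list of `matrix`/`groups`), `corpus`, `annotations`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  truth <- simulate_truth(config)
  expression <- lapply(truth$diseases, function(d)
    generate_expression(config, d, truth))
  names(expression) <- truth$diseases
  corp <- generate_corpus(config, truth)
  ann <- generate_go_annotations(config, corp$truth)
  structure(list(config = config, truth = ann$truth,
                 expression = expression, corpus = corp$corpus,
                 annotations = ann$annotations),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", x$config$n_genes, "genes,",
      x$config$n_diseases, "diseases,",
      length(x$corpus), "abstracts,",
      nrow(x$truth$gold_statements), "gold statements\n")
  invisible(x)
}
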