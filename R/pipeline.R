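#' Assemble and validate a pipeline run configuration
#'
#' A run is configured either with a `synthetic` block (arguments for
#' [synthetic_config()]) or with `paths` to user-supplied inputs
#' (`corpus`, per-disease `expression` matrix/groups TSV pairs,
#' `popularity`, `annotations`, optional `probe_map`), never neither.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised top-level fields: `synthetic`, `paths`, `diseases`,
#'   `fc_grid` (linear fold-change cutoffs, default `c(0, 2)`), `alpha`
#'   (default 0.05), `outdir`, `seed`.
#' @return validated config list of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$synthetic) && is.null(config$paths))
    stop("config must contain either a 'synthetic' block or a 'paths' block")
  if (!is.null(config$paths)) {
    needed <- c("corpus", "expression", "popularity", "annotations")
    miss <- setdiff(needed, names(config$paths))
    if (length(miss))
      stop("paths block is missing stage input(s): ",
           paste(miss, collapse = ", "))
    flat <- c(config$paths$corpus, config$paths$popularity,
              config$paths$annotations,
              unlist(config$paths$expression, use.names = FALSE))
    gone <- flat[!file.exists(flat)]
    if (length(gone))
      stop("configured input file(s) do not exist: ",
           paste(gone, collapse = ", "))
  }
  if (is.null(config$fc_grid)) config$fc_grid <- c(0, 2)
  if (is.null(config$alpha)) config$alpha <- 0.05
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) config$outdir <- tempfile("degbias_run_")
  structure(config, class = "run_config")
}

.log_stage <- function(quiet, ...) if (!quiet) message("[degbias] ", ...)

#' Run the full literature-versus-expression comparison
#'
#' Orchestrates the pipeline end to end: simulate (or load) the inputs,
#' extract statements from the corpus, run moderated-t differential
#' expression per disease, compute every comparison statistic
#' (over/under ratios, zero-intercept trend, cumulative reporting curves,
#' popularity correlations, the two mention models, pairwise and
#' multi-disease LR+ and the LR+-versus-threshold curves) and the
#' enrichment overlap. All tabular outputs are written as TSV under
#' `config$outdir` together with a JSON manifest recording the
#' configuration, seed, package version and an MD5 checksum of every
#' output file; reruns with the same config and seed reproduce the
#' checksums exactly.
#'
#' @param config a [run_config()] (or a list / YAML path coercible to
#'   one).
#' @param lexicon a [qualifier_lexicon()]; the packaged default when
#'   omitted.
#' @param quiet suppress per-stage log messages.
#' @return list of class `"degbias_report"` with sections `statements`,
#'   `de`, `over_under`, `trend`, `cumulative`, `popularity_correlation`,
#'   `mention_models`, `lr`, `lr_vs_threshold`, `enrichment`, plus
#'   `manifest` and (for synthetic runs) `truth`.
#' @export
run_pipeline <- function(config, lexicon = default_lexicon(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL

  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    syn_args$seed <- config$seed
    scfg <- do.call(synthetic_config, syn_args)
    .log_stage(quiet, "simulate: ", scfg$n_genes, " genes, ",
               scfg$n_diseases, " diseases, seed ", scfg$seed)
    study <- simulate_study(scfg)
    corpus <- study$corpus
    expression <- study$expression
    popularity <- study$truth$popularity
    annotations <- study$annotations
    diseases <- study$truth$diseases
    universe <- study$truth$genes
    truth <- study$truth
    write_pubtator(corpus, file.path(outdir, "corpus.pubtator"))
  } else {
    corpus <- read_pubtator(config$paths$corpus)
    expression <- lapply(config$paths$expression, function(pp)
      read_expression(pp$matrix, pp$groups))
    popularity <- read_popularity(config$paths$popularity)
    annotations <- read_annotations(config$paths$annotations)
    diseases <- if (!is.null(config$diseases)) config$diseases else
      names(expression)
    universe <- NULL  # set after DE below
  }

  .log_stage(quiet, "extract: ", length(corpus), " abstracts")
  statements <- extract_statements(corpus, lexicon,
                                   target_diseases = diseases)
  .log_stage(quiet, "extract: ", nrow(statements), " unique statements")
  write_statements(statements, file.path(outdir, "statements.tsv"))

  de <- list()
  for (d in diseases) {
    fit <- fit_moderated_t(expression[[d]]$matrix, expression[[d]]$groups)
    tab <- fit$table
    if (!is.null(config$paths$probe_map)) {
      pm <- utils::read.delim(config$paths$probe_map,
                              stringsAsFactors = FALSE)
      names(pm)[1:2] <- c("probe", "gene")
      tab <- collapse_probes(tab, pm)
    } else {
      tab$gene <- tab$feature_id
      tab <- tab[, c("gene", setdiff(names(tab), "gene"))]
    }
    de[[d]] <- tab
    write_de_table(tab, file.path(outdir, paste0("de_", d, ".tsv")))
    .log_stage(quiet, "de ", d, ": ",
               sum(tab$p_adj < config$alpha), " significant genes (d0 = ",
               signif(fit$params$d0, 3), ")")
  }
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(de, `[[`, "gene"))))
  N <- length(universe)

  lit_sets <- lapply(diseases, function(d) {
    st <- statements[statements$disease == d, , drop = FALSE]
    sgn <- if (nrow(st)) delta_sign(st$delta) else integer(0)
    list(up = intersect(unique(st$gene[sgn > 0]), universe),
         down = intersect(unique(st$gene[sgn < 0]), universe))
  })
  names(lit_sets) <- diseases
  micro_sets <- lapply(config$fc_grid, function(cut)
    lapply(de, filter_degs, fc_cutoff = cut, alpha = config$alpha))
  names(micro_sets) <- paste0("fc_gt_", config$fc_grid)

  # --- reporting-direction ratios -------------------------------------
  over_under <- list(
    literature = lapply(lit_sets, function(s)
      tryCatch(over_under_ratio(s), error = function(e) NULL)),
    microarray = lapply(micro_sets, function(sets_at_cut)
      lapply(sets_at_cut, function(s)
        tryCatch(over_under_ratio(s), error = function(e) NULL))))

  # --- mention-count tables, trend fit, mention models ----------------
  trend <- list(); mention_models <- list()
  cumulative <- list(); pop_cor <- list()
  thresholds <- seq(0, 3, by = 0.5)
  for (d in diseases) {
    mct <- mention_count_table(statements, de[[d]], popularity, disease = d)
    bins <- bin_mention_counts(mct)
    trend[[d]] <- list(
      bins = bins,
      fit = if (nrow(bins)) zero_intercept_trend(bins$mentions,
                                                 bins$mean_high) else NULL)
    mention_models[[d]] <- list(
      high_increase = tryCatch(fit_high_increase_model(mct),
                               error = function(e) NULL),
      mentions = tryCatch(fit_mention_model(mct), error = function(e) NULL))
    cumulative[[d]] <- tryCatch(
      cumulative_reporting_prob(lit_sets[[d]]$up, de[[d]],
                                thresholds = thresholds),
      error = function(e) NULL)
    ind <- as.integer(de[[d]]$gene %in% lit_sets[[d]]$up)
    pop_cor[[d]] <- list(
      literature = tryCatch(
        popularity_correlation(ind, mct$popularity),
        error = function(e) NULL),
      microarray = lapply(micro_sets, function(s) tryCatch(
        popularity_correlation(as.integer(de[[d]]$gene %in% s[[d]]$up),
                               mct$popularity),
        error = function(e) NULL)))
  }

  # --- LR+ structure ---------------------------------------------------
  lit_up <- lapply(lit_sets, `[[`, "up")
  lr <- list(literature = list(
    pairwise = if (length(diseases) >= 2L)
      pairwise_disease_lr(lit_up, N) else NULL,
    multi = if (length(diseases) >= 2L && any(lengths(lit_up) > 0))
      multi_disease_overlap(lit_up, N) else NULL))
  for (cut_name in names(micro_sets)) {
    mu <- lapply(micro_sets[[cut_name]], `[[`, "up")
    lr[[cut_name]] <- list(
      pairwise = if (length(diseases) >= 2L)
        pairwise_disease_lr(mu, N) else NULL,
      multi = if (length(diseases) >= 2L && any(lengths(mu) > 0))
        multi_disease_overlap(mu, N) else NULL)
  }
  lr_curves <- lapply(diseases, function(d)
    source_lr_vs_threshold(lit_sets[[d]]$up, de[[d]],
                           thresholds = seq(0, 2, by = 0.5),
                           universe_size = N, alpha = config$alpha))
  names(lr_curves) <- diseases

  # --- enrichment overlap ---------------------------------------------
  enrichment <- list()
  for (d in diseases) {
    per_cut <- list()
    for (cut_name in names(micro_sets)) {
      mic_up <- micro_sets[[cut_name]][[d]]$up
      if (!length(lit_sets[[d]]$up) || !length(mic_up)) next
      rows_lit <- fisher_overrep(lit_sets[[d]]$up, universe, annotations)
      rows_mic <- fisher_overrep(mic_up, universe, annotations)
      per_cut[[cut_name]] <- list(
        literature = rows_lit, microarray = rows_mic,
        overlap = top_k_overlap(rows_lit, rows_mic, k = 20L,
                                alpha = config$alpha))
    }
    enrichment[[d]] <- per_cut
  }
  .log_stage(quiet, "compare + enrich done (universe N = ", N, ")")

  # --- manifest --------------------------------------------------------
  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(files)
  manifest <- list(
    seed = config$seed,
    fc_grid = config$fc_grid,
    alpha = config$alpha,
    diseases = diseases,
    universe_size = N,
    package_version = as.character(utils::packageVersion("degbias")),
    config = config[setdiff(names(config), "outdir")],
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(statements = statements, de = de,
                 lit_sets = lit_sets, micro_sets = micro_sets,
                 over_under = over_under, trend = trend,
                 cumulative = cumulative,
                 popularity_correlation = pop_cor,
                 mention_models = mention_models,
                 lr = lr, lr_vs_threshold = lr_curves,
                 enrichment = enrichment,
                 universe = universe, manifest = manifest, truth = truth),
            class = "degbias_report")
}

#' @export
print.degbias_report <- function(x, ...) {
  cat("degbias_report:", nrow(x$statements), "statements,",
      length(x$de), "disease DE tables, universe N =",
      x$manifest$universe_size, "\n")
  lit <- x$over_under$literature
  for (d in names(lit)) {
    if (is.null(lit[[d]])) next
    cat(sprintf("  %s literature: %.1f%% over / %.1f%% under (ratio %.2f)\n",
                d, lit[[d]]$pct_over, lit[[d]]$pct_under, lit[[d]]$ratio))
  }
  invisible(x)
}
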