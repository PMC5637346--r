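Package: degbias
Title: Reporting Bias in Literature-Derived Differential Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares differential gene expression (DEG) evidence mined from
    the biomedical literature with evidence from two-group expression
    experiments. Provides rule-based extraction of gradable DEG statements
    from entity-annotated abstracts (tri-occurrence of gene, disease and
    trigger word, with a gradable-qualifier lexicon), empirical-Bayes
    moderated t-statistic differential expression with Benjamini-Hochberg
    adjustment and fold-change filtering, and the bias statistics that
    relate the two sources: over- versus under-expression reporting ratios,
    positive likelihood ratios of gene-set overlap across fold-change
    cutoffs, cumulative reporting-probability curves, popularity models and
    Gene Ontology overrepresentation overlap. A synthetic-data generator
    with known ground truth makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
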