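# degbias

Quantifying reporting bias in literature-derived differential gene
expression.

## What problem this addresses

Evidence that a gene is differentially expressed (a DEG) in a disease
comes from two sources that are rarely reconciled: two-group expression
experiments, and free-text statements in abstracts ("S100A7 was greatly
elevated in psoriatic skin"). The literature is not a neutral mirror of
the measurements — it prefers overexpression over underexpression,
prefers genes that are already popular, and tracks measured fold changes
only weakly. `degbias` is for computational biologists and text-mining
practitioners who want to measure those biases on their own corpora and
expression data, or to study them under controlled synthetic conditions.

The package implements:

* **Statement extraction** — rule-based mining of
  `(PMID, gene, disease, delta)` tuples from PubTator-style annotated
  abstracts via tri-occurrence (gene mention + disease mention + an
  expression trigger word in one sentence), with a gradable-qualifier
  lexicon (`delta` in `{high_decrease, decrease, increase,
  high_increase}`), exclusion phrases, in-document disease abbreviations
  and ambiguity filters.
* **Differential expression** — empirical-Bayes moderated t-statistics
  (moment-matched prior `d0`, `s0²`; posterior variance
  `(d0·s0² + d·s²)/(d0 + d)`), Benjamini–Hochberg adjustment, probe→gene
  collapsing, and signed fold-change filtering
  (`fc = sign(log2FC)·2^|log2FC|`).
* **Bias statistics** — over/under reporting ratios; the positive
  likelihood ratio of gene-set overlap,
  `LR+ = P(A|B) / P(A|¬B) = (n_AB/n_B) / ((n_A−n_AB)/(N−n_B))`,
  pairwise across diseases, for multi-disease memberships, and as curves
  over fold-change cutoffs; cumulative reporting probability
  `p(reported | FC > x)`; point-biserial popularity correlations; two
  OLS mention models (high-increase mentions ~ FC + increase mentions;
  increase mentions ~ log2FC + popularity) and a zero-intercept trend
  with uncentered r².
* **Enrichment** — one-sided hypergeometric overrepresentation with
  Bonferroni correction and top-k / significant-set overlap between two
  term rankings.
* **A synthetic-data generator** — annotated corpora, expression
  matrices, power-law popularity and GO annotations with planted ground
  truth (fold changes, reporting couplings, over-report preference,
  enriched terms), so every stage is testable end to end offline.

## Worked example

```r
library(degbias)
rep <- run_pipeline(list(synthetic = list(n_genes = 6000, n_diseases = 2,
                                          frac_de = 0.3,
                                          over_report_ratio = 3.5),
                         seed = 42, outdir = "demo_run"))
print(rep)
```

```
[degbias] simulate: 6000 genes, 2 diseases, seed 42
[degbias] extract: 1094 abstracts
[degbias] extract: 766 unique statements
[degbias] de DIS01: 1874 significant genes (d0 = 1670)
[degbias] de DIS02: 1872 significant genes (d0 = 913)
[degbias] compare + enrich done (universe N = 6000)
degbias_report: 766 statements, 2 disease DE tables, universe N = 6000
  DIS01 literature: 78.4% over / 21.6% under (ratio 3.63)
  DIS02 literature: 80.5% over / 19.5% under (ratio 4.12)
```

The generator was told to prefer reporting overexpressed genes 3.5:1;
the extracted literature shows ratios of 3.63 and 4.12 — the planted
bias, recovered through the full extract-and-count path (the spread is
binomial noise at ~250 reported genes per disease). Two more sections of
the same report object:

```r
cur <- rep$cumulative$DIS01
cur[cur$threshold %in% c(0, 2), ]
#>   threshold n_above n_reported       prob stable
#> 1         0    3018        207 0.06858847   TRUE
#> 5         2     865        205 0.23699422   TRUE
```

A gene with fold change above 2 is ~3.5 times more likely to have been
reported as overexpressed than an arbitrary positively-changed gene —
the generator couples reporting probability to effect size, and the
cumulative curve exposes it.

```r
rep$mention_models$DIS01$mentions[c("alpha", "p_alpha", "beta", "p_beta")]
#> alpha = 0.0632 (p = 2.4e-124), beta = 0.00394 (p = 7.4e-08)
```

Both the measured log2 fold change (`alpha`) and the gene's popularity
in the wider literature (`beta`) independently predict how often a gene
is mentioned as overexpressed; standardized versions of the two
coefficients (`alpha_std`, `beta_std`) put them on a common scale.

Every tabular output is also written under `outdir` as TSV, with a
`manifest.json` recording the seed, configuration and an MD5 checksum of
every file; rerunning the same configuration reproduces the checksums
bit for bit.

The same pipeline runs on real inputs by replacing the `synthetic` block
with a `paths` block (PubTator corpus, per-disease expression TSV +
group sidecar, popularity TSV, annotation TSV/GAF); see
`?run_config`.

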