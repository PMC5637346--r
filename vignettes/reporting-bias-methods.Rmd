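---
title: "Methods: comparing literature-reported and measured differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing literature-reported and measured differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degbias)
```

## The problem

Claims that a gene is differentially expressed in a disease come from two
very different places: structured two-group expression experiments, and
free-text assertions scattered across abstracts ("FLG expression was
markedly reduced in atopic dermatitis lesions"). The two sources disagree
in characteristic ways — the literature prefers overexpression over
underexpression, prefers genes that are already popular, and tracks
measured fold changes only loosely. `degbias` implements both arms of the
comparison and the statistics that quantify the disagreement, together
with a synthetic-data generator so the whole pipeline is testable with
known ground truth and no external downloads.

## Statement extraction

The unit of literature evidence is the tuple (PMID, gene, disease, delta),
where delta is one of the four ordinal values `high_decrease < decrease <
increase < high_increase`. Extraction is deliberately rule-based and
inclusive:

1. **Sentence segmentation.** Terminal punctuation followed by whitespace
   and an uppercase/digit opener, guarded by an abbreviation list
   (`e.g.`, `et al.`, `Fig.`, ...), single-letter initials (so *E. coli*
   never splits), and a hard rule that no boundary may fall inside an
   annotated entity span. This is a pragmatic stand-in for a trained
   boundary detector: the downstream comparison statistics, not
   segmentation fidelity, are the subject of the package.
2. **Tri-occurrence.** A sentence is a candidate only if it contains a
   gene mention, a target-disease mention (or an in-document abbreviation
   of one, recovered from `long form (SHORT)` patterns), and a token
   containing one of the trigger substrings
   `express, production, produce, transcription, transcribe`.
3. **Qualifier classification.** The gradable qualifier lexicon maps
   phrases to delta values; matching is case-insensitive and
   longest-match-wins, so "greatly elevated" beats "elevated". Phrases
   describing an undefined change (`aberrant`, `dysregulated`,
   `differentially expressed`, ...) block a sentence instead of
   classifying it. The lexicon ships as an editable YAML file
   (`system.file("extdata", "lexicon.yaml", package = "degbias")`); the
   five phrase classes must stay pairwise disjoint, which the loader
   enforces.
4. **Disambiguation and hygiene.** Gene mentions resolving to more than
   three symbols are dropped. When qualifiers of opposite sign share a
   sentence, each gene takes its *nearest* qualifier by token distance,
   which must lie within `token_window` (default 8) tokens of the gene or
   a trigger; ties between signs skip the gene as ambiguous — a
   conservative, automatic stand-in for what would otherwise require
   manual review. Redundant tuples are deduplicated, keeping the first in
   document order.

A negation guard ("not increased") is supported by the lexicon design but
off by default; in the corpora this package targets such phrasings are
rare, and silently flipping signs on mis-scoped negation would be worse
than occasionally missing one.

## Differential expression

The expression arm is a two-group comparison with empirical-Bayes
variance moderation, written from first principles. For feature $g$ with
pooled residual variance $s_g^2$ on $d_g$ degrees of freedom, the log
variances are matched in moments against their scaled-F marginal to give
prior degrees of freedom $d_0$ and prior variance $s_0^2$ (digamma /
trigamma method; the trigamma equation is inverted by Newton iteration).
The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

yields the moderated statistic
$t_g = \widehat{\Delta}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ with
$d_0 + d_g$ degrees of freedom. Two limits are asserted numerically in
the tests: with moderation disabled the classical pooled t is recovered
exactly, and when the log variances show no excess spread the estimate
is $d_0 = \infty$ and the statistic collapses to a common-variance
z-form. The test suite also cross-checks $d_0$, $s_0^2$, $t$ and $p$
against the reference empirical-Bayes implementation in *limma* to
1e-10 on heteroscedastic data; *limma* is used only as an independent
oracle there, never as the implementation.

Conventions worth stating:

* **Fold change.** Thresholds operate on the signed linear fold change
  $\mathrm{fc} = \mathrm{sign}(\mathrm{log_2FC}) \cdot 2^{|\mathrm{log_2FC}|}$,
  so "|FC| > 2" means $|\mathrm{log_2FC}| > 1$ and "FC > 0" admits every
  significant overexpressed gene.
* **Degenerate features.** Zero variance with zero difference gives
  $p = 1$ (nothing observed); zero variance with a nonzero difference
  gives $p = 0$ and an infinite statistic; an all-constant matrix is an
  error. Exact-zero p-values are clamped to the smallest positive double
  before the Benjamini–Hochberg step-up, whose domain is (0, 1].
* **Probe collapse.** The probe with the smallest adjusted p represents
  its gene (ties: larger |log2FC|, then lexicographic probe id). The rule
  is unobservable from published gene-level counts, so it is
  configurable (`max_fc`, `mean`).
* **Multiple testing.** The step-up adjustment is implemented directly
  from its definition and verified against a brute-force oracle and
  `p.adjust` on random vectors.

Input matrices are assumed normalized, log2-scale data; background
correction, normalization and batch assessment are out of scope.

## The comparison statistics

* **Over/under ratio.** Unique genes per reported direction; a gene
  reported both ways counts once per direction (configurable only by
  pre-filtering the statements, and documented because it affects
  percentage tables).
* **Positive likelihood ratio.** For gene sets $A, B$ in a universe of
  size $N$,
  $LR^+ = \frac{P(A \mid B)}{P(A \mid \lnot B)} =
  \frac{n_{AB}/n_B}{(n_A - n_{AB})/(N - n_B)}$.
  Zero cells are reported exactly as 0 or $\infty$ — no continuity
  correction — so perfect containment and disjointness are visible
  rather than smoothed away. The conditioning set being empty or the
  whole universe is an error for the scalar form and an `NA` flag in the
  threshold curves. One universe is used for every LR+ in a run: the
  generator's gene set for synthetic data, the DE table's genes
  otherwise, configurable for reproducing published universes.
* **Threshold curves.** `source_lr_vs_threshold()` recomputes both
  conditional directions at each log2FC cutoff with a Fisher exact
  p-value per threshold; `cumulative_reporting_prob()` gives
  $p(\text{reported} \mid \mathrm{fc} > x)$ with denominators below 10
  flagged unstable.
* **Mention models.** Two ordinary-least-squares fits:
  high-increase mentions on (linear fc, increase mentions), and increase
  mentions on (log2FC, raw popularity). Raw popularity is the default
  regressor because that is how popularity enters published correlation
  tables; a log10 option exists. Standardized coefficients are reported
  so the two influences can be ranked on a common scale.
* **Zero-intercept trend.** Genes are binned by increase-mention count
  (bins 1–9), the response is the mean high-increase count per bin, the
  slope is $\sum xy / \sum x^2$ and the $r^2$ is *uncentered*
  ($1 - \sum(y-\hat y)^2/\sum y^2$): the centred definition is
  ill-posed without an intercept and can be negative. The binned-mean
  reading of the display is an interpretation choice and is flagged as
  such.
* **Enrichment.** One-sided hypergeometric tail with Bonferroni
  correction over tested terms; genes with no annotation form an
  `unclassified` pseudo-term that is tested like any other. Overlap
  between two rankings is reported both as shared Bonferroni-significant
  terms and as shared top-20 terms, because published "shared classes"
  counts are ambiguous between the two readings.

## The synthetic study conditions

The generator's defaults are the package's study conditions, chosen once
to be realistic for disease-versus-normal tissue comparisons on
expression arrays, and not revisited:

| parameter | default | rationale |
|---|---|---|
| `n_genes`, `n_diseases` | 2000, 4 | desk-scale universe; four diseases mirror a two-pairs design |
| `n_samples_per_group` | 10 | typical small clinical series |
| `frac_de` | 0.1 | 10% truly DE genes per disease |
| planted \|log2FC\| | uniform on `[lfc_scale, 3*lfc_scale]`, `lfc_scale = 1` | twofold to eightfold changes, direction-balanced |
| `noise_sd` | 0.4 | per-sample log2 SD in the range reported for arrays |
| `popularity_exponent` | 1.7 | literature gene-mention counts are famously heavy-tailed with a tail index near 2 |
| `report_alpha`, `report_beta`, `report_intercept` | 0.8, 1.2, −3 | reporting odds rise with effect size and popularity; base probability well below saturation |
| `over_report_ratio` | 3.5 | the several-fold preference for overexpression reports |
| `high_qualifier_rate` | 0.25 | a quarter of mentions use emphatic phrasing |
| `distractor_frac` | 0.3 | corpus noise: no-trigger, no-qualifier and excluded-qualifier sentences |

The reporting model is logistic per (gene, disease) pair:
$\mathrm{logit}\, p = \gamma_0 + \alpha |\mathrm{log_2FC}| +
\beta \log_{10}(\mathrm{popularity})$, with the probability for
underexpressed genes divided by `over_report_ratio`. Dividing the
probability (rather than multiplying odds) makes the expected over:under
ratio of reported genes equal the configured preference exactly under
direction-balanced truth, which is what the recovery tests exploit.
Published mention-count regressions are linear in counts; the generator
is deliberately probabilistic per pair — counts arise by aggregation
(one Bernoulli report decision, then $1 + \mathrm{Poisson}$ extra
mentions scaled by $\log_{10}$ popularity) — because that keeps
probabilities in [0, 1] while preserving every monotone dependency the
fitting stage estimates. Popularity enters the *generator* as log10 so
the heavy tail cannot saturate the logit; the *fitting* stage still uses
raw popularity.

Randomness is disciplined: one root seed, deterministic child seeds per
generator stream (truth, popularity, per-disease expression, corpus, GO),
so identical configurations are byte-identical and components can be
regenerated independently.

Sentences are template-generated from a small grammar over the qualifier
lexicon; no attempt is made at naturalistic language. The number of
statement sentences per abstract is a config knob
(`statements_per_abstract`, default 1) since the empirical distribution
is not observable from published summaries.

### What the generator does not emulate

No false literature reports: every generated statement reflects a truly
DE gene, so synthetic literature sets are subsets of the true DE genes
and extraction precision is structurally 1 when distractors cannot
classify. Consequently literature-given-microarray LR+ curves can be
infinite on synthetic data at permissive cutoffs (perfect containment) —
real literature, with its claims from other assays, tissues and eras,
will not behave this way. Probe-level artifacts, batch effects,
normalization residue, coreference, and full-text structure are likewise
out of scope. Passing the recovery tests therefore demonstrates that the
statistics measure what they claim on data obeying the stated model, not
that real corpora obey it.

## Problem sizes and numerical tolerances

The test suite runs entirely on generated data: oracle sweeps use
universes up to 50 (LR+ enumeration), tables up to N = 25 (closed-form
hypergeometric tails), 1,000 random vectors (step-up adjustment) and
random small designs at 1e-10 (normal equations). Recovery tests use
2,000–10,000 genes with 100-seed batteries for the enrichment ranking
and 10–25 seeds for curve-shape properties; these sizes were chosen so
the full suite documents the behaviour at comfortable statistical power
while remaining desk-scale. `scripts/acceptance.R` regenerates a
6,000-gene, two-disease study from a command-line seed and recomputes
every headline quantity from scratch.

## Interfaces

All exchange formats are plain text: PubTator-style annotated abstracts,
TSV expression matrices with a sample-group sidecar, two-column TSV
popularity and annotation tables (plus a GAF 2.x subset reader), TSV
statement and DE tables, and a JSON manifest with per-file checksums.
The package's functions, the `run_pipeline()` orchestrator and
`scripts/acceptance.R` are the intended entry points; an optional GEO
series-matrix converter is not provided — matrices are expected in the
canonical TSV form.

## Known limitations

* The qualifier lexicon is seeded with characteristic phrases, not an
  exhaustive inventory; recall on real abstracts depends on extending it
  (the YAML file is the extension point).
* The sentence splitter is rule-based; unusual abbreviation patterns can
  over- or under-split, though entity spans are always protected.
* The anatomical-location disambiguation that manual curation would
  perform is reduced to a per-disease target filter.
* Enrichment results depend entirely on the supplied flat gene→term map;
  no ontology graph propagation is performed, and term-name
  reproducibility across annotation database versions is explicitly not
  a goal.
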