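---
title: "Predicting splice-altering scSNVs: models, evaluation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting splice-altering scSNVs: models, evaluation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single nucleotide variants that fall in the splicing consensus regions at
exon/intron boundaries — positions −3..+8 around the 5′ (donor) splice site
and −12..+2 around the 3′ (acceptor) site, excluding the nearly invariant
GT/AG dinucleotides — can disrupt spliceosomal recognition and cause exon
skipping, intron retention or cryptic splice-site use. We call these
variants scSNVs. Individual splice-site scoring tools emit a score for a
*site*, not for a *substitution*, which makes their output hard to act on:
the question a geneticist asks is "does swapping this allele change
splicing?", a per-substitution question. This package turns per-site scores
into per-substitution features, combines them with ensemble classifiers
into a single interpretable probability, and provides the surrounding
machinery: evaluation, enrichment statistics, genome-wide enumeration of
candidate scSNVs, and seeded synthetic data for testing every step.

# Splice-site scoring models

Two self-contained scoring engines are provided, trainable from example
site sequences.

**Position weight matrix (PWM).** `train_pwm()` estimates per-position base
frequencies with an additive pseudocount (default 0.5 per cell, so small
training sets never produce zero frequencies). `score_pwm()` sums log
frequencies over positions and min–max normalizes to 0–100, the classical
convention for consensus-strength scores: the per-position argmax sequence
scores exactly 100 and the argmin sequence 0. The finite 0–100 range is
what makes an *absolute* score variation well defined downstream. The score
is monotone: substituting a base by one with a higher frequency at that
position can never lower the score.

**Maximum-entropy model.** `train_maxent()` fits the maximum-entropy
distribution over L-mers subject to empirical marginal constraints on all
single positions (order 1) plus adjacent pairs (order 2, default) or
adjacent triples (order 3). Constraints are restricted to adjacent position
subsets deliberately: the constraint graph is then chain-decomposable, and
the entropy maximizer has an exact closed form — a Markov chain of order
(constraint order − 1) whose gram tables are the smoothed empirical
marginals. Fitting is therefore direct and exact rather than iterative; for
L ≤ 8 the implementation still verifies every constraint marginal by full
enumeration against the requested tolerance and fails loudly if violated.
Pseudocounts are applied only to the highest-order gram tables, which keeps
the implied lower-order marginals mutually consistent (both the pair table
at positions (i−1, i) and the one at (i, i+1) imply the same singleton
marginal at i). `score_maxent()` returns `log2(P_model / P_background)`,
unbounded in both directions; the background is uniform by default
(configurable to the empirical positional composition). Because the range
is infinite, this score family contributes only a relative variation
downstream.

The test suite cross-checks the closed-form fit against an independent
iterative-proportional-fitting oracle over all 256 outcomes at L = 4
(agreement within 1e-4 total variation; observed agreement is ~1e-14).

# From score pairs to features

For one variant and one tool, `score_variation()` reduces the wild-type and
mutant scores to the signed difference `d = wt − mut`, so loss of signal is
positive. Two normalizations are produced: *relative* (`d / wt`) and, when
the tool has a finite declared range, *absolute* (`d / (hi − lo)`). A
wild-type score of zero means the tool failed to detect the true splice
site; the variation is then *missing*, as data rather than as an error. The
sign convention (signed, not absolute value) is a design choice: splice-site
loss is the dominant mechanism inside consensus regions, and signal *gains*
come out negative and are left for the classifiers to use.

`screen_tools()` applies the pre-screening rule: tools whose wild-type
scores are missing for more than 5% of variants are excluded from
evaluation. With the canonical eight-tool input this retains four tools
(PWM, the maximum-entropy log-odds score, a neural-network splice-site
score and a splicing-signal composite score), giving seven score
variations: relative+absolute for the three range-bounded tools, relative
only for the log-odds tool. `build_feature_row()` assembles them in a
frozen, documented order (`scsnv_features()`), optionally extended by four
annotation scores (two phyloP conservation values and two CADD values) to
eleven features. The order is frozen so serialized models remain portable.

# Ensemble classifiers

Two classifier families produce the splice-altering probability scores
(`ada_score`, `rf_score`).

**Boosting** (`train_adaboost()`) is authored in this package. Base
learners are depth-2 regression or class-probability trees (fit with
rpart, converted into an explicit node table used for prediction and JSON
serialization). The `gentle` variant fits each tree by weighted least
squares to the ±1 labels; the `real` variant adds half log-odds from
weighted class-probability trees. Both run under logistic loss by default
(exponential optionally); the margin F is mapped to a probability with the
logistic link `1/(1 + exp(−2F))`. Defaults: 50 iterations, depth 2, unit
shrinkage. Two numerical safeguards: leaf log-odds are clipped at
probability 1e-5, and each step is halved until the training loss does not
increase (iteration stops early if no improving step exists), which makes
the loss path provably non-increasing. Missing feature cells are first-class:
at every internal node the rows with a missing split variable are routed to
the child minimizing the weighted training loss (falling back to the
heavier child), and the stored route is reused at prediction, so boosting
scores exist for incomplete rows.

**Random forests** (`train_random_forest()`) wrap the `randomForest`
package at its standard defaults (500 trees, `mtry = floor(sqrt(p))`),
reflecting that a forest is a commodity component here. Forests cannot use
incomplete rows: they are dropped (counted and messaged) at training and
scored `NA` at prediction — which is exactly why the boosting score has a
lower missing rate than the forest score when both are precomputed
genome-wide.

`relative_importance()` reports boosting selection frequencies (summing to
1) or the forest's out-of-bag permutation mean decrease in accuracy.
`call_splice_altering()` applies the downstream decision rule: strict
`score > 0.6`, either-score (screening) or both-scores (conservative).

The 7-feature models default to gentle boosting; the 11-feature model uses
real boosting, mirroring the configuration that performed best in the
original evaluation of this pipeline.

# Evaluation

`roc_auc()` sweeps thresholds over unique score values with ties grouped,
integrates by trapezoid (equal to the Mann–Whitney statistic with ties
counted ½ — property-tested against exhaustive pair counting), and
`optimum_cutoff()` picks the accuracy-maximizing candidate among midpoints
of adjacent unique scores plus ±∞, breaking ties by sensitivity +
specificity and then by the smaller cutoff. `cross_validate()` runs
stratified k-fold (default 10) cross-validation: fit on k−1 folds, select
the cutoff on those folds, evaluate AUC and confusion metrics on the
held-out fold; fold curves are vertically averaged on a fixed 101-point
FPR grid and all scalars are averaged arithmetically. Stratification is the
default because the intended class balance (1164 positives vs 1795
negatives) makes unstratified small folds risk losing a class; an
unstratified run that loses a class in a training fold errors with that
advice, and a single-class *test* fold (as in leave-one-out) simply
contributes no AUC. `cv_paired_ttest()` compares two models sharing a fold
assignment via the paired t statistic on per-fold AUC differences
(df = k − 1); degenerate zero-variance differences return the limiting
p-value (1 at zero mean, 0 otherwise) rather than NaN.

`confusion_from_counts()` flags undefined ratios (for example PPV with no
positive calls) by name instead of propagating NaN.

# Enrichment statistics

`chisq_trend()` (Cochran–Armitage-style trend in proportions, no continuity
correction, default scores 1..k, delegated to `stats::prop.trend.test`) and
`pearson_chisq()` (uncorrected by default, Yates optional — the reference
environment's 2×2 default differs, hence the explicit flag) serve the
downstream application: testing whether predicted splice-altering calls are
enriched among recurrent somatic variants and within known cancer genes.
Degenerate trend tables (all or no events) return chi² = 0, p = 1 with a
warning. P-values below representable precision are displayed as
"< 2.2e-16" alongside the raw float. `recurrence_table()` bins calls by
observation count (default once/twice, three/four, five+; empty bins
omitted).

# Genome-wide enumeration and the score database

`gene_model()` / `read_gene_models()` capture transcript structures
(1-based inclusive coordinates throughout the user-facing surface, matching
VCF and the database dialect). `enumerate_scsnvs()` emits, per intron, the
21 modeled consensus positions (9 donor + 12 acceptor after GT-AG
exclusion) × 3 alternative alleles = 63 records, always reported on the +
strand (minus-strand gene geometry is mapped through the coordinate
arithmetic; the reference base is read from the + strand, so alleles are
automatically in + strand space). Records shared by several transcripts are
merged into one row keyed by (chrom, pos, ref, alt) with the transcript
list joined — a variant is one row however many transcripts it touches.
When one position falls into two consensus windows (possible with exons
shorter than 6 bp), `classify_variant()` reports every context; the
database row stores a single site annotation, a documented simplification
of an ambiguous corner case. `write_db()`/`read_db()`/`query_db()` provide
the tab-delimited dialect (header `#chr pos ref alt refseq_tx ensembl_tx
site offset ada_score rf_score`, `.` for missing, sorted input enforced,
malformed lines reported by number, exact-variant and half-open region
queries), and `annotate_vcf()` adds `SCSNV_ADA`/`SCSNV_RF`/`SCSNV_SITE`
INFO fields to matching VCF records without touching anything else.

# Synthetic data: what it emulates and what it does not

The curated table of labeled scSNVs with per-tool scores that the original
pipeline was trained on is an external download, so the package generates a
statistically calibrated stand-in. `gen_feature_table()` draws
class-conditional Gaussian features sharing a within-class latent factor
(default correlation ρ = 0.5): the seven variations of one variant measure
the same underlying event and are correlated by construction, and
ensemble-versus-single comparisons are only meaningful with correlated
features. Each feature's positive-class shift is solved in closed form from
its target AUC (`AUC = Φ(δ/(sd·√2))`, so `δ = qnorm(AUC)·sd·√2`) rather
than by search. Defaults are fixed to the study conditions: 1164 positives
vs 1795 negatives; single-feature AUC targets 0.95, 0.95, 0.94, 0.90,
0.91, 0.93, 0.93 (and 0.80 for the four annotation scores); per-tool
missing rates 2.6% / 2.8% / 2.3% / 2.2% applied jointly to both variations
of a tool (a missing wild-type score wipes out both). A manifest attribute
records realized class sizes, AUCs and missing rates.

What passing tests on this generator demonstrate: the pipeline's ranking
behavior (ensembles above single features; 11 features at least as good as
7), calibration of the evaluation machinery, and end-to-end mechanics. What
they do not demonstrate: performance on real variants — real score
variations are non-Gaussian (bounded, spiky at 0 and 1), their correlation
structure is richer than one latent factor, and missingness is not
independent of the signal. Numeric equality with published AUCs is
therefore only checked when a user supplies the real scored-variant table
(`evaluate_published_table()`, `scsnv.training_table` option).

`gen_splice_sites()` mixes a canonical donor/acceptor consensus with
uniform noise (invariant GT/AG always planted). `gen_toy_genome()` plants
multi-exon genes on alternating strands with consensus dinucleotides at
intron ends and emits FASTA/GTF text in the dialects the readers consume.
`gen_recurrence()` draws recurrence/call tables at configured per-bin
proportions (defaults 0.707 / 0.742 / 0.845). All generators are pure
functions of (spec, seed).

# Numerical choices and problem sizes

- PWM log frequencies are floored at the smallest double before
  normalization so pseudocount-0 models stay finite; scores are clamped to
  [0, 100].
- The maximum-entropy verification tolerance (default 1e-6) is checked by
  enumeration for L ≤ 8 and guaranteed analytically beyond.
- Boosting weights and margins are computed overflow-safe (clipped
  exponents); leaf probabilities are clipped at 1e-5.
- All stochastic fits take an explicit integer seed; boosting is
  deterministic given the data.
- The test suite and the acceptance script run cross-validation at the
  study size (2959 rows, 10 folds, 5 seeds for the sweep), which completes
  in a few minutes on one CPU; unit tests use a few hundred rows.

# Known limitations

- Branch-point and exonic/intronic splicing enhancer/silencer signals are
  out of scope; only donor/acceptor consensus regions are modeled.
- Only single nucleotide substitutions are handled (no indels).
- The database row keeps one site annotation per variant even when two
  consensus windows overlap it.
- Published parameter files of the original site-scoring tools are not
  reproduced; the models here are the same families trained on
  user-supplied (or synthetic) site sequences.
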