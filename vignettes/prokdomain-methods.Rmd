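---
title: "Methods: genomic-feature encoding and domain classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-feature encoding and domain classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`prokdomain`: what exactly is computed, which decisions were genuinely open,
how they were resolved, and what the synthetic benchmark does and does not
demonstrate about real genomes.

## The 77-feature encoding

A genome is analysed as five *components*: the whole genome (the
concatenation of its replicon sequences — chromosome plus any plasmids) and
the four annotated gene classes CDS, rRNA, tRNA and ncRNA. Each gene
component is represented by the concatenation, in genomic order, of the
sense-strand sequences of its genes; minus-strand genes are
reverse-complemented before concatenation, because the composition of an RNA
gene is only biologically meaningful on the transcribed strand. Multi-part
(`join(...)`) locations are concatenated across parts in annotation order
and reverse-complemented as a whole when on the minus strand.

Two conventions here were open choices:

* **Concatenation, not per-gene averaging.** All four scores are computed
  once on the component concatenation rather than averaged over genes. For
  composition-driven scores (Shannon, both Chargaff scores) the two agree in
  expectation; for topological entropy the concatenation sees a longer
  sequence and therefore a larger word length `n`. Concatenation treats the
  component as a single element, matches how the per-component base counts
  are defined, and makes score values comparable across genomes with
  different gene counts.
* **Sense strand, not reference strand.** An alternative is to count
  composition on the plus strand for all features. The two differ exactly by
  the A↔T, C↔G swap on minus-strand genes, which would dilute any real
  strand-parity signal; the sense-strand convention is used throughout.

Ambiguity codes (N and the other IUPAC letters) are excluded from the
canonical counts: frequencies are over A+C+G+T only, and any n-mer window
containing a non-ACGT character is skipped by the subword census. This keeps
every score inside its documented range; complete genomes contain few such
characters, so the effect is negligible in practice.

### Score definitions and degenerate cases

* **Shannon entropy** `H = -Σ pᵢ log₂ pᵢ` over the four nucleotide
  proportions, in bits (0–2); zero-probability terms contribute zero. A
  sequence with no canonical bases has no defined entropy and raises an
  error (such genomes never pass the filters).
* **Topological entropy** uses the finite-sequence approximation based on
  subword complexity: choose the largest `n` with `4ⁿ + n − 1 ≤ L`, census
  the distinct `n`-mers among the `4ⁿ` windows of the length-`(4ⁿ + n − 1)`
  *prefix*, and return `log₄(count)/n`. The prefix form is the primary
  definition of the finite approximation; an alternative averages the census
  over all admissible starting positions, which is smoother but no longer a
  single well-defined census. The prefix form is implemented and is verified
  in the test suite against a brute-force window-enumeration oracle on
  random sequences of length 4–2000. The implementation encodes windows as
  rolling base-4 integers; the oracle hashes window strings — two
  independent routes to the same census.
* **Chargaff PF** `= |A−T|/(A+T) + |C−G|/(C+G)` (0 = perfect parity,
  range 0–2). The skew of an empty base pool (A+T = 0 or C+G = 0) is taken
  as 0, the parity limit.
* **Chargaff CT** `= ½(min(A,T)/max(A,T) + min(C,G)/max(C,G))` (1 = perfect
  parity, range 0–1). The ratio of an all-zero pair is taken as 1. Both
  conventions are unreachable for filtered genomes and exist so the scores
  are total functions.

For strictly positive counts the two scores agree on perfection:
PF = 0 ⇔ CT = 1 (property-tested).

## Genome filters

Inclusion rules are class-specific: bacterial genomes smaller than 580,076
bp *and* with fewer than 491 CDS are removed, archaeal genomes smaller than
490,885 bp *and* with fewer than 493 CDS likewise (the thresholds are the
smallest accepted representative of each domain). The conjunction is read
literally — removal requires both criteria below threshold — with
`size_cds_combination = "either"` available since the intended reading is
ambiguous. Genomes lacking any of rRNA, tRNA or ncRNA annotation are
excluded. When several records share a species, the longest genome is kept;
the species key is the first two whitespace tokens of the organism name,
lowercased (a deliberately simple, auditable key), and exact-length ties
break to the lexicographically smallest accession. Rejection reasons are
assigned in a fixed order (size rule, then missing components in
rRNA/tRNA/ncRNA order, then duplication), so reports are deterministic and
filtering is idempotent.

## The synthetic-genome generator

The generator exists so that every downstream stage — parsing, encoding,
filtering, modelling, evaluation — is testable without network access. Per
class it draws, for each genome: per-component base probabilities from a
Dirichlet distribution (the concentration vector is the class's
entropy dial — a symmetric concentrated vector gives near-maximal Shannon
entropy, an asymmetric one lowers it); a genome length and per-component
gene counts and lengths from uniform integer ranges; a strand per gene from
Bernoulli(`minus_strand_prob`); and gene sense-strand sequences i.i.d. from
the component composition *reweighted for parity skew*: within the A/T pool
the A share becomes `½ + skew/4` (and symmetrically C within C/G), so each
pool's skew is `skew/2` and the expected PF score of a long gene
concatenation equals `skew` exactly — a closed form the tests exploit. Genes
are placed without overlap at multinomially distributed gaps; intergenic
sequence is drawn from the genome-level composition. One replicon per
record; multi-replicon handling is exercised by hand-built fixtures instead.

Default study conditions: the default class specs contrast a "bacterial"
class (near-uniform tRNA/rRNA/CDS composition, parity skew 0.02) with an
"archaeal" class (A-enriched composition, skew 0.12), in the direction of
the reported real-data contrasts (higher bacterial tRNA entropy, more
extreme bacterial CDS parity). Effect sizes are the package's own choice of
a clearly separable parameterization — they are *not* calibrated to real
data, which only reports medians and distributions graphically. Default
genome length is 140–180 kb with 80–110 CDS, 2–6 rRNA, 20–40 tRNA and 5–15
ncRNA genes: large enough that the genome-level subword census uses `n = 8`
(a regime comparable to real replicons) while keeping a 100–200-genome
dataset cheap to generate. Real genomes are megabase-scale; nothing in the
encoding depends on absolute length except the census word length, which
grows only logarithmically, so this is a benign compression. The generated
genomes deliberately lack codon structure, operons, GC-skew replication
arcs, repeats and taxonomy metadata: a high synthetic classification
accuracy therefore demonstrates that the pipeline recovers *planted*
composition/parity signal, not that real domains are separable — the
published full-scale figures speak to that.

Class imbalance is exact: `round(n_total × minority_fraction)` minority
records (the study-scale fraction 0.041 gives 109 of 2655). All randomness
derives from one integer seed; each record gets its own derived sub-stream,
so datasets regenerate bit-identically.

## Modelling pipeline

* **Split.** Stratified by domain; per class, `floor(n_class ×
  test_fraction)` rows are held out, so 109 + 2546 at 20% gives a 21 + 509
  test set and an 88 + 2037 training set.
* **Cross-validation.** Stratified k-fold (default 10) with repeats (study
  scale: 25 for feature elimination, 100 for tuning). Within each fold the
  minority class is upsampled with replacement to exact balance, then
  centring/scaling statistics are computed on the (upsampled) fold-training
  rows only and applied to the held-out fold. The diagnostics mode records
  fold assignments, per-fold class counts and per-fold scaling statistics so
  the no-leakage property is directly auditable, and is asserted in the test
  suite. Upsampling is also applied inside the feature-elimination
  resamples, for consistency with model training (configurable).
* **Feature elimination.** Random-forest RFE: per resample, the forest is
  fitted on all current features, features are ranked by impurity
  importance, and for each candidate subset size (descending) the top-ranked
  subset is refitted, scored on the held-out fold, and *re-ranked* before
  the next elimination step. The best size is the argmax of mean held-out
  accuracy, ties to the smaller size (parsimony); the returned subset is the
  head of the consensus ranking (mean full-model rank across resamples),
  which is more stable than any single resample's ranking.
* **Classifiers and grids.** Exact tuning grids were an open gap; the
  package follows the 3-values-per-parameter convention: RLR α ∈ {0, 0.5, 1}
  × λ log-spaced on [10⁻⁴, 10]; RF mtry ∈ {√p/2, √p, 2√p} (500 trees at
  study scale); SVM cost ∈ {0.25, 0.5, 1} with the RBF width from the
  median pairwise-distance heuristic computed per fit (only cost is tuned);
  NN hidden units ∈ {1, 3, 5} × weight decay ∈ {0, 10⁻⁴, 0.1}, trained by
  full-batch quasi-Newton (deterministic given the seed, appropriate at this
  data size). The best grid point by mean CV accuracy is refitted on the
  full training set (upsampled, then scaled; the scaling statistics are
  stored in the model and reapplied at prediction). A grid point whose fit
  fails is scored with accuracy 0 and logged, never silently dropped.
* **Prediction.** Class = positive (Bacteria) iff P(positive|x) ≥ 0.5,
  matching how misclassification probabilities are reported; probabilities
  are clamped to [0, 1].

## Evaluation

Bacteria is the positive class. Metrics follow the standard confusion-matrix
formulas; a metric whose denominator is zero is returned as `NA` rather than
a conventional value, so degenerate test sets are visible. MCC uses exact
integer arithmetic in the numerator and a single square root. ROC AUC is the
midrank-normalized Mann–Whitney statistic; it is reported as a diagnostic
only and never used for model selection, because under strong imbalance a
large change in minority-class errors moves AUC very little. Variable
importance is method-appropriate — absolute standardized coefficients (the
model is fitted on scaled features) for RLR, impurity decrease for RF, and
seeded permutation importance for SVM/NN, for which no model-intrinsic
measure is standard — linearly rescaled to 0–100. Per-feature class
contrasts use two-sided Wilcoxon rank-sum tests, reported raw by default
(with `p.adjust` methods available); constant features return p = 1 with a
warning. Exploratory summaries standardize features, drop zero-variance
columns with a warning, and return PCA variance fractions, the Pearson
correlation matrix and a 2-D classical MDS of Euclidean distances.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at reduced
resampling scale as the package's own configuration choice: typically 3–5
folds with 1–2 repeats, 50–200 trees, candidate subset sizes
{2, 5, 8, 12, 18, 25} on the 25-feature benchmark, 60–200 genomes per
synthetic dataset, and 250–1000 fuzz cases for the score kernels. The
study-scale settings (10 × 25, 10 × 100, 500 trees, sizes up to 77) remain
the documented defaults of `cv_config()`, `rfe_random_forest()` and
`run_config()` and are what a full-scale reproduction on the real feature
table would use. Reduced repeats widen the variance of CV estimates but do
not change any estimator.

## Known limitations

* The per-organism printed score values of specific accessions depend on the
  upstream tool's exact conventions (prefix vs averaged census, sense vs
  reference strand, concatenation vs per-gene means); without network access
  these cannot be resolved empirically, so the package documents its
  conventions and verifies them against internal oracles instead.
* The GenBank parser handles the location forms that occur in prokaryotic
  annotation (`a..b`, `complement(...)`, `join(...)`, `order(...)`, partial
  markers `<`/`>`); nested compound locations are skipped with a warning.
* Exact reproduction of the published cross-validated accuracies is not
  attempted: they depend on unseeded randomness in the original analysis.
  The published test-set metrics, by contrast, are deterministic functions
  of the printed confusion matrices and are reproduced exactly (with one
  internally inconsistent cell, asserted at its matrix-derived value).
* The neural network uses one hidden layer with sigmoid activations and an
  entropy loss; it is not a drop-in for any particular framework's defaults.
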