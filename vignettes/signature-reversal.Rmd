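---
title: "Signature-reversal drug repurposing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repurposing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The problem

Diffuse intrinsic pontine glioma (DIPG) is a pediatric brainstem tumor for
which matched normal tissue is essentially never biopsied, so the standard
tumor-vs-adjacent-normal differential comparison is not available. The
repurposing strategy implemented here works around that in four steps:

1. **Surrogate controls.** Embed a large healthy-tissue RNA-seq compendium
   together with the disease cohort using an autoencoder, and select the
   normal samples whose embeddings correlate best with the disease samples.
2. **Disease signature.** After adjusting for unwanted technical variation,
   test each gene for differential expression between tumor and the selected
   controls, and keep genes with |log2 fold change| > 1 at an adjusted
   p-value below 0.05, split into up- and down-regulated sets.
3. **Reversal scoring.** For every drug perturbation profile in a
   landmark-gene library, ask whether the drug pushes the disease-up genes
   down and the disease-down genes up, using a bidirectional
   Kolmogorov–Smirnov (KS) enrichment statistic. The per-profile score is
   the reversal gene expression score (RGES); per-compound scores are
   summarized across cell lines, doses, and durations into sRGES.
4. **Evaluation and hits.** Correlate sRGES with independent drug-sensitivity
   data (AC50), test whether known target classes concentrate among the top
   predictions, and filter to a final hit table.

Every stage is exercised end-to-end on synthetic data with known ground
truth, which is what the test suite and the acceptance script certify.

## The scoring model

For a ranked drug profile over a gene universe of size $n$ (rank 1 = most
up-regulated by the drug) and a gene set with sorted ranks
$V_1 < \dots < V_t$, the enrichment score is

$$a = \max_j\left(\frac{j}{t} - \frac{V_j}{n}\right), \qquad
  b = \max_j\left(\frac{V_j}{n} - \frac{j-1}{t}\right), \qquad
  \mathrm{ES} = \begin{cases} a & a > b \\ -b & \text{otherwise.}\end{cases}$$

Positive ES means the set concentrates at the top of the ranking, negative
at the bottom. The implementation is verified exactly against an exhaustive
running-sum oracle for every gene set over universes up to size 12. One
boundary note: ES lies in $[-1, 1]$; the value $-1$ is attained only by a
singleton set at the very last rank position.

RGES for a profile is $\mathrm{ES}_{up} - \mathrm{ES}_{down}$ when the two
scores disagree in sign, and 0 when they agree (a profile that pushes both
sets the same way neither reverses nor mimics coherently; this follows the
connectivity-map convention and can be disabled with
`same_sign_zero = FALSE`). Negative RGES indicates reversal. When a
signature direction exceeds `top_n = 100` genes it is truncated to the 100
largest |log2FC| before scoring; ranking ties are broken by gene id so
scoring is deterministic.

### sRGES summarization

Compounds are profiled repeatedly across cell lines, concentrations, and
durations. The summarization (a) adjusts each RGES to the 10 µM / 24 h
reference condition by subtracting dose and duration offsets fitted by one
ordinary least squares of RGES on $\log_{10}(\text{dose}/10)$ and
$(\text{duration} - 24)$ pooled over all compounds — offsets are zero when
the metadata are absent — then (b) averages adjusted scores within cell
line, and (c) averages the cell-line means. The exact weighting scheme of
the original "summarized RGES" statistic is not recoverable from its
one-sentence description, so this pooled linear correction is the package's
own choice, with `adjust = FALSE` giving the plain mean-of-means. Compounds
with sRGES < −0.1 (strict) are called effective reversers.

## Reference-control selection

The autoencoder takes $\log_2(\mathrm{TPM}+1)$, standardized per gene on
the training set, through encoder widths 512 → 128 to a 64-unit bottleneck
with a mirrored decoder. Hidden layers use batch normalization, rectified
linear activations, and dropout (rate 0.1); training uses Adam at learning
rate 0.0002, batch size 128, for 100 epochs — the published embedding
recipe. The layer widths, dropout rate, and normalization type are not
published; the defaults here are the smallest design consistent with that
recipe, and all are configurable. The disease samples are included in
training, as in the original recipe.

Controls are selected by Pearson correlation (Spearman by flag) between
each normal sample's embedding and each disease sample's embedding,
aggregated across disease samples by the **median** — robust to an outlier
disease sample — then the top k = 100 are taken, ties broken by sample id.
Whether correlation should be computed per disease sample and aggregated,
or against a disease centroid, is genuinely open; per-sample aggregation by
median is the package's choice.

A randomly initialized encoder is already a random projection that
preserves tissue geometry, so tissue recovery is robust to under-training;
the test suite trains at reduced epochs (8) and widths and still requires
≥ 90 of the top-100 controls to come from the disease source tissue.

## Disease signatures

**Empirical negative controls.** The empirical gene set feeding the
unwanted-variation step is taken to be the *least*-DE genes — the
negative-control recipe of the remove-unwanted-variation (RUVg) method,
which requires genes assumed *unaffected* by the contrast.
(The alternative most-DE reading would put the disease signal directly into
the nuisance factors.) Weakly expressed genes are filtered before the
first-pass test: they are too noisy to carry useful control information.
The default count is 5000, capped by the gene universe.

**Factor estimation.** Counts are brought to a common (geometric-mean)
library size, log2-transformed, and row-centered; the top k right singular
vectors of the control-gene rows form W. Two numerical details matter.
First, without depth normalization the leading singular vector simply
recovers sequencing depth. Second, when the case/control grouping is
supplied, the control-gene matrix is centered within groups before the SVD
so the factors cannot absorb the biological contrast — with small groups
the random batch covariate can correlate with the contrast by chance, and
the first-pass DE then excludes exactly the batch-carrying genes from the
control set. The pipeline always passes the grouping. k is never stated in
the source description; the default is k = 1, exposed in the configuration.

**Differential expression** uses the edgeR negative-binomial framework —
TMM scale factors, trend-shrunk tagwise dispersion, gene-wise GLM with a
likelihood-ratio test, the W columns as covariates — with
Benjamini–Hochberg adjustment. The weak-expression filter keeps genes with
≥ 1 count-per-million in at least the smaller group's number of samples.
The calibration contract is property-level: on null simulations the raw
p < 0.05 fraction stays near 5%, and with planted two-fold-change genes
sensitivity is ≥ 0.8 at observed FDR ≤ 0.1.

**Single-cell signature.** Values are $\log(\mathrm{RSEM} + 0.1)$; genes
with variance across all cells below 0.1 are removed; each gene gets an
equal-variance two-sample t-test (malignant vs oligodendrocyte). The mean
difference is on the natural-log scale and is divided by $\log 2$ to report
log2 fold changes — the base is not stated in the source description.

**Meta-signature.** The combination rule is not described either; the
default is the direction-consistent intersection with averaged log2FC
(genes with conflicting directions are excluded and reported), with
`"union"` and `"average-rethreshold"` available.

## Evaluation

Sensitivity records keep only strong dose-response curves
(CCLASS < 4 and CCLASS2 < 4, both strict). Per compound, AC50 is
summarized as the **median across cell lines** then log10-transformed
(aggregation is unstated in the source; the median is robust and
monotone-preserving), and the Pearson correlation with sRGES is computed
over compounds passing the −0.1 cutoff (`srges_cutoff = NULL` correlates
over all overlapping compounds). Target-class enrichment reuses the KS
statistic on the sRGES-ascending compound ranking with a one-sided
permutation p-value; the +1 correction on numerator and denominator keeps
p strictly positive. Hit filtering drops compounds above the cutoff, in the
excluded mechanism classes (topoisomerase, CDK, HDAC, and DNA inhibitors by
default, matched case-insensitively), with fewer than 3 profiles, and
optionally preclinical ones.

The treatment reversal check ranks genes by drug-vs-vehicle log2FC and
computes the signature's $\mathrm{ES}_{up} - \mathrm{ES}_{down}$ in that
ranking **without** the same-sign zeroing: the zeroing convention creates a
point mass at 0 that would wreck the uniformity of the permutation p-value
under the null, and here the statistic feeds a permutation test rather than
a ranking.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis relies on:
negative-binomial counts (variance $\mu + \phi\mu^2$, $\phi = 0.1$, typical
bulk overdispersion) with tissue-specific expression profiles and sample
library sizes; an optional batch covariate loaded onto a random 20% of
genes; a disease cohort from one source tissue with planted |log2FC| ≥ 1
up/down gene sets and untouched negative-control genes; a landmark-gene
profile library where each compound carries a reversal strength θ ∈ [0, 1]
(profile values are $-\theta \cdot \text{effect}$ on signature genes plus
Gaussian noise, modulated by dose and duration around the 10 µM / 24 h
reference, clamped to [0.25, 1.5]); AC50s lognormal and decreasing in θ
($\log_{10} AC_{50} = a - b\theta + \varepsilon$, defaults $a = -4$,
$b = 2$, $\varepsilon \sim N(0, 0.5)$, so θ = 1 gives 1 µM-scale potency);
and lognormal single-cell values with dropout and four disjoint program
modules (cell cycle, OPC-like, AC-like, OC-like).

Default study conditions: 2000 genes with the first 978 as the landmark
scoring universe; brain/liver/muscle tissues (200/150/150 samples); a
22-sample disease cohort from brain; 100 compounds — 10 strong reversers
with θ ~ U(0.75, 1) and 90 with θ ~ U(0, 0.7) — each with 3–8 profiles over
four cell lines; profile noise SD 0.5; single-cell defaults of 2259
malignant and 232 oligodendrocyte cells (scaled down in tests). Gene
lengths are fixed at 1 kb so TPM is proportional to count over library
size, keeping the count↔TPM relation trivial and testable.

What it does **not** emulate: read-level sequencing artifacts, GC and
length biases, correlated gene–gene modules beyond tissue/batch/program
structure, heavy-tailed outlier samples, or the annotation noise of real
compound libraries. Passing tests therefore certify the *machinery* —
calibration, recovery of planted structure, determinism — not performance
on any real cohort.

## Worked example

```{r demo, eval = FALSE}
res <- sigreverse_demo(seed = 42)
res$evaluation          # Pearson r of sRGES vs log10 AC50
head(res$hits)          # final hit table, most-reversing first
autoplot(res$evaluation)
autoplot(res$srges)
```

The demo generates the default synthetic study, trains a reduced
autoencoder (32 encoded features, 15 epochs — enough for tissue recovery at
a fraction of the cost), builds the signature with one unwanted-variation
factor, scores the library, and filters hits. Under a fixed seed the run is
byte-deterministic, and every output table carries a header comment with
the configuration hash and seed.

## Numerical choices and degenerate inputs

- Profile-ranking and signature-ordering ties break by gene id; control
  selection ties break by sample id. All outputs are deterministic given
  inputs and seed.
- `ks_enrichment()` distinguishes an empty gene set from a set with no
  overlap with the ranking universe (different error classes).
- An empty thresholded signature is permitted (message, not error);
  downstream scoring requires a nonempty overlap with the landmark set.
- Correlation with fewer than 3 compounds errors rather than returning NaN.
- Constant genes: removed by the single-cell variance filter; constant
  control genes contribute zero factors in the unwanted-variation step.
- The autoencoder skips mini-batches of size 1 (batch statistics need at
  least 2 samples); `epochs = 0` returns the initialized model, and
  encoding still works.
- Test and acceptance problem sizes (hundreds of genes and samples, reduced
  epochs, 99–199 permutations, 200 replicate seeds) were chosen so the full
  suite completes in a few minutes while keeping every statistical check
  well-powered.

## Known limitations

- The dose/duration correction is a single pooled linear model; with few
  compounds or strongly unbalanced designs the dose slope partially
  absorbs compound strength.
- Factor adjustment assumes the nuisance factor is not fully confounded
  with the case/control contrast; under full confounding no control-gene
  method can separate them.
- The autoencoder is a plain dense network trained on CPU; it is not meant
  to scale to compendia with tens of thousands of samples, though the
  selection logic is independent of the embedding's origin.
- Published-signature ingestion expects the 3-column TSV format (gene,
  direction, log2fc); gene-id harmonization across platforms is the user's
  responsibility.
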