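---
title: "Cross-species tumor signatures and single-sample enrichment classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species tumor signatures and single-sample enrichment classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsig)
```

## Overview

`zfsig` implements a comparative-transcriptomics pipeline built around
transgenic zebrafish liver tumor models. Three oncogene-driven models
(*xmrk*, *kras*, *Myc*) each yield a SAGE (serial analysis of gene
expression) tag-count profile of tumor versus control liver; the genes
significantly up-regulated in each model form that model's *tumor
signature*. After mapping the signatures to human gene identifiers, each
individual human hepatocellular carcinoma (HCC) sample in a cohort is
classified against each signature by one-vs-rest gene-set enrichment:
the sample is treated as a singleton phenotype class, all remaining
cohort samples form the contrast, and a signature is called *represented*
in the sample when its enrichment is positive and significant at
permutation FDR < 0.25. Summaries over a cohort then give the percentage
of samples captured by each signature, by at least one signature, and by
signature pairs or all three (co-correlation).

The pipeline has two arms, mirrored by the scripts under `analysis/`:

1. **Signature derivation** (`run_signature_workflow()`): TPM
   normalization, differential-expression (DE) testing, selection by
   fold-change/p-value/expression criteria, and the three-model
   intersection (common core of deregulated genes).
2. **Cohort classification** (`run_classification_workflow()`):
   per-sample one-vs-rest enrichment, representation summaries,
   stage-wise profiles across a disease progression, and a signed
   log10-FDR pathway matrix over signature-correlated subgroups with
   hierarchical clustering.

Everything runs on synthetic data with known ground truth
(`simulate_sage_counts()`, `simulate_human_cohort()`), so every stage is
testable without downloads.

## Differential expression on SAGE counts

Tag counts are normalized to TPM (tags per million):
$\mathrm{TPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$. Every sample column
of a TPM matrix sums to $10^6$ exactly (checked to relative tolerance
$10^{-9}$).

Two DE tests are provided, matching the two study designs:

* **Unreplicated** (one tumor sample, $\ge 2$ controls; used for the
  *xmrk*- and *Myc*-style designs with 3 controls): per gene, the log2
  ratio $r_c = \log_2\!\frac{t + 1}{x_c + 1}$ is computed against each
  control $c$ (1 TPM pseudocount on both sides), and the set
  $\{r_c\}$ is tested against zero with a two-sided one-sample t-test
  ($n$ = number of controls).
* **Replicated** (two groups of $\ge 2$; the *kras*-style 2 vs 2
  design): two-sided pooled-variance Student's t on
  $\log_2(\mathrm{TPM} + 1)$. A Welch option exists but is not the
  default, since the heteroscedastic variant was used in this workflow
  only for qPCR validation.

The reported fold change is the ratio of pseudocount-adjusted mean TPMs,
expressed as a magnitude $\ge 1$ with a separate direction flag (listed
fold changes for down-regulated genes are magnitudes, e.g. 100 rather
than 0.01; the pseudocount bounds ratios for genes absent from one
group). Selection requires fold change > 1.5, p < 0.05 and mean TPM > 10
in at least one group; `select_deregulated()` is monotone in all three
thresholds.

**Variance floor.** A gene whose per-gene variance is exactly zero (a
tumor at an identical multiple of every control) would give an undefined
or infinite t. Instead of silently dropping the strongest candidates,
both tests floor the per-gene variance at the smallest nonzero per-gene
variance in the dataset (configurable via `var_floor`).

**A calibration caveat worth knowing.** The unreplicated one-sample
ratio test treats the per-control ratios as independent, but the single
tumor's sampling noise is common to all of them and acts as a true mean
shift. Its type-I error at p < 0.05 is therefore inflated (around 13%
in our null simulations, essentially independently of the noise level).
This is a structural property of the unreplicated design, not of the
implementation; the replicated test is calibrated (its null p < 0.05
fraction sits within binomial bounds of 5% in the test suite). Users
deriving signatures from unreplicated designs should read the selected
lists as enriched for true positives rather than error-controlled.

## Homolog mapping and collapsing

Transcript- or probe-level values collapse to gene clusters by the
per-sample **maximum** (`collapse_transcripts()`, `collapse_probes()`):
the rule is applied per expression value, so it is defined for cohort
data and commutes with sample subsetting. Zebrafish-to-human mapping
(`map_to_human()`) takes the **first** human cluster of each homolog
entry — the mapping resource's own ordering is treated as authoritative —
then deduplicates (two zebrafish genes may share one human homolog) and
reports unmapped members. The accounting is exact:
`|human| + |dropped| + |merged| = |input|`.

## The enrichment engine

Genes are ranked best-to-worst by a target-vs-rest statistic
(`rank_by_ttest()`): a pooled-variance two-sample t for classes with
$\ge 2$ samples, and for a singleton target the standardized shift
$(x - \bar{x}_\text{rest}) / s_\text{rest}$ — a two-sample t is undefined
at $n = 1$, and this statistic preserves the "compared to the rest"
semantics and is permutation-consistent. Signal-to-noise is available as
an alternative metric. Pre-ranked input uses the signed log10 p-value:
$-\log_{10} p$ for up-regulated genes, $+\log_{10} p$ (negative score)
for down-regulated ones (`rank_preranked()`). Ranking ties break
lexicographically by gene id, for bit-reproducibility across platforms.

The enrichment score (`enrichment_score()`) walks the ranked list of
$N$ genes: at each of the $k$ set hits the running sum increases by
$|s_i|^\alpha / \sum_{\text{hits}} |s_j|^\alpha$, at each miss it
decreases by $1/(N - k)$. The ES is the signed maximum deviation from
zero and lies in $[-1, 1]$; the walk ends at zero exactly. The weight
exponent $\alpha$ defaults to 1 (the established default of the
weighted statistic); $\alpha = 0$ gives the classic Kolmogorov–Smirnov
form used by the analytic test cases. When a |deviation| tie occurs
(e.g. exact $\pm x$), the first-attained extremum wins; a $10^{-12}$
guard keeps that rule stable under floating-point noise. Internally the
running sum is evaluated only at hits and immediately before hits (the
only candidate extrema), which makes permutation nulls cheap; the test
suite proves equality with the full brute-force walk on every subset of
small lists and against an independent reference implementation
(`fgsea::calcGseaStat`).

**Nulls, NES, p, FDR.** Two permutation modes exist. *Phenotype* mode
permutes the sample labels and re-runs the entire ranking + scoring
pipeline; when the number of distinct label arrangements does not exceed
the requested permutations (default 1000), all arrangements are
enumerated. *Gene-set* mode scores random same-size gene sets on the
fixed ranked list. NES is the ES divided by the mean magnitude of
same-sign null ES values; nominal p is the add-one-smoothed same-sign
permutation rank, $p = (1 + \#\{|\text{null}| \ge |es|\}) / (1 + n)$, so
finite permutations never report $p = 0$. FDR q uses the sign-separated
pooled-null ratio estimator (fraction of pooled normalized null scores
at least as extreme over the corresponding fraction of observed NES),
clipped to $[0, 1]$ and made monotone within each sign by a cumulative
minimum. On label-independent data the suite checks that nominal p is
super-uniform and the fraction of sets with q < 0.25 stays below 0.25
plus three Monte-Carlo standard errors.

## One-vs-rest cohort classification

`classify_cohort()` runs the singleton ranking for every sample and
scores every signature; a (sample, signature) pair is *correlated* when
q < 0.25 and NES > 0 (positivity required by default: the signatures are
up-regulated gene lists, so only concordant up-regulation counts).
Signatures whose overlap with the platform's genes falls below
`min_set_overlap` (default 5) yield a no-result marker; those samples
stay in every denominator, so representation percentages are over all
samples.

**Which null for a singleton class?** Both modes are available, and the
default is gene-set permutation, for two reasons. First, with an
exhaustive singleton phenotype null the null sample for a signature is
exactly the set of ES values of the other cohort samples — observed and
null distributions coincide across a whole-cohort run, which degenerates
the pooled FDR estimator. Second, the reference desktop implementation
itself recommends gene-set permutation for phenotype classes below seven
samples. FDR is computed within one (sample, signature) run; no pooling
across signatures, since each signature is classified separately.
Per-run RNG seeds are derived from the configured seed and the sample
id (not its column position), so results are invariant to sample and
gene ordering.

Representation summaries (`summarize_representation()`) report, per
dataset and overall, the percentage of samples correlated with each
signature, with at least one, with each unordered pair, and with all
signatures. The overall row is sample-weighted (total flagged over total
samples) by default; dataset-averaging is available by flag. The suite
enforces the inclusion–exclusion sanity constraints
(`pct_any >= max(per-signature)`, `pct_all <= min(pairs)`).

`stage_enrichment()` applies the same machinery stage-vs-rest across an
ordered progression (e.g. cirrhotic liver → dysplastic nodules → very
early/early/advanced/very advanced HCC), using the two-class ranking for
stages with $\ge 2$ samples and the singleton statistic otherwise.

## Pathway matrix and clustering

For each signature, the cohort splits into the correlated subgroup and
the rest; a two-group t-test per gene gives the signed log10-p ranking,
and pre-ranked enrichment of a user-supplied pathway collection yields
per-condition statistics. `build_signed_matrix()` encodes each cell as
$\mathrm{sign}(\mathrm{NES}) \cdot \min(-\log_{10} q,\; \text{cap})$
with the cap (default 4) standing in for $q = 0$ from finite
permutations; absent pathways stay missing. `filter_pathways()` drops a
pathway when the count of missing-or-$q{=}1$ cells exceeds 5 of the
conditions — the two degenerate states are one exclusion clause, which is
the only reading that makes a single "more than five" tally well-defined.
Clustering uses Euclidean distance and average linkage by default (the
defaults of the desktop tool conventionally used for such heatmaps),
missing cells entering distances as 0 (neutral); rows are pre-sorted by
pathway name so merge-height ties resolve deterministically. Only
pathway (row) clustering is performed; column clustering was left out as
it does not affect the row tree.

## Synthetic data: what it emulates, and what it does not

`simulate_sage_counts()` emulates the zebrafish arm: heavy-tailed
log-normal baseline abundances (sdlog 2, giving the strong
expression-skew typical of tag libraries), per-model planted up/down
gene sets arranged by an explicit 7-region Venn design with a common
core of 21 up and 16 down genes, multiplicative fold changes (default
8) on tumor proportions with renormalization, and negative-binomial
counts (dispersion 0.2 — tag counts are overdispersed Poisson; no noise
model is canonical, so one is fixed and documented). The desk-scale
library size default is $10^5$ tags so the whole suite runs in seconds;
passing a range such as `c(1e7, 2.3e7)` draws full-scale libraries
matching real SAGE depth. Planted genes draw their baselines from the
tag-detectable range (roughly 100–3000 TPM): real signatures are by
construction detectable, and planting truth below the TPM floor would
make recovery ill-posed. Default per-model planted totals (120/60/40 up,
30/60/50 down) are a desk-scale compromise: they preserve the real
common-core sizes (21/16), which caps how small the per-model lists can
be, rather than scaling the real totals (2,892/797/494 up) directly.

`simulate_human_cohort()` emulates the human arm: log2-scale intensities
with per-gene baselines around 7, Gaussian noise (sd 1), independent
Bernoulli signature memberships per sample (default probability 0.2,
overlaps allowed — this creates the co-correlation structure), and an
additive shift of `effect_size` noise-sd units (default 3) on active
signature genes.

Neither generator models batch effects, platform-specific artifacts,
probe saturation, or realistic liver gene identity; passing the
recovery tests shows the pipeline's statistics behave as designed under
a clean, known-truth noise model, not that any particular real cohort
would reproduce specific percentages.

## Numerical and design choices, in brief

* Pseudocount 1 TPM on both sides of every expression ratio; bounds
  fold changes for absent genes.
* Variance floors: smallest nonzero per-gene variance (DE tests,
  ranking statistics).
* Ranking ties: lexicographic by gene id; ES ties: first-attained
  extremum; clustering ties: rows pre-sorted by name.
* p-values from permutations are add-one smoothed; q clipped to
  $[0,1]$, monotone within sign.
* Problem sizes in the shipped tests and scripts (2,000-gene universes,
  100-sample cohorts, 200 permutations, 5–10 seeds) were chosen so a
  full run completes in minutes on one core while leaving Monte-Carlo
  margins well inside the asserted bounds; all are arguments, not
  constants.
* DE recovery is demonstrated at dispersion 0.05 (the low-dispersion
  regime) with 3 controls: with df = 2, the variance estimate's
  $\chi^2_2$ noise caps unreplicated sensitivity near 0.8 at dispersion
  0.2 — an honest property of the design, shown as such in the suite.
* The interface is the package's functions plus the numbered scripts
  under `analysis/`; no shell CLI wrapper is shipped.

## Known limitations

* The unreplicated DE test's type-I inflation (above) is inherited from
  the study design it reimplements.
* FDR q from a single-set run reduces to the same-sign pooled-null tail
  fraction; with the 0.25 threshold this is an exploratory, not
  confirmatory, significance level.
* The homolog mapping's first-entry rule depends entirely on the
  ordering of the user-supplied mapping table; no sequence-based
  inference is attempted.
* Missing values are rejected outright; imputation is out of scope.
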