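---
title: "Methods: PR stratification, TF activity scores and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PR stratification, TF activity scores and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtf)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical conventions that were pinned
where more than one choice was defensible, and what the synthetic-cohort
validation does and does not demonstrate.

## Single-sample signature scoring

The per-sample enrichment of a gene set is the classic running-sum
statistic: rank the sample's genes by decreasing expression, walk down the
ranking adding `1/m` at each of the `m` set members and subtracting
`1/(n - m)` elsewhere. The walk ends at zero by construction, so its
minimum `E-` is in `[-1, 0]` and its maximum `E+` in `[0, 1]`; they
quantify enrichment in the low- and high-expression tails. The statistic is
*unweighted*: expression magnitudes matter only through ranks, which is
what makes the permutation strategy below exact and cheap.

Significance is the add-one smoothed empirical p-value
`p = (1 + #exceedances) / (1 + n_P)` — for the low tail the exceedances are
null scores at or below the observed `E-`, for the high tail at or above
the observed `E+`. The reported score is the extremum of the more
significant tail (high tail on ties). The floor of the p-value is
`1/(n_P + 1)`; with the conventional `n_P = 100,000` that floor is
`1e-05`, which is why strong associations are reported *at* that value
rather than below it. Tests and the bundled pipeline default to
`n_P = 1000`, which changes only the resolution of the p-values, not the
scores.

Because the score depends only on where the `m` members land among `n`
ranks, permuting a sample's expression values is distributionally identical
to placing `m` memberships uniformly at random. `build_null()` therefore
samples membership placements once per `(n, m)` and the same null serves
every sample — numerically identical to per-sample expression permutation
at a tiny fraction of the cost. For universes with `choose(n, m)` small it
can enumerate all placements exactly, which is how the suite checks it
against brute force.

Numerical conventions: expression ties are broken by the stable input
order of the gene identifiers (ties are essentially absent in continuous
data; the convention only pins degenerate cases). Set members missing from
the expression universe are dropped with a warning and `m` adjusted —
signatures and platforms rarely coincide exactly. `m = 0` after
intersection and `m = n` are errors. A sample is called P+ (or R+) only
for significant *up*-regulation at `alpha` (default 0.05); significant
down-regulation is a negative call. Raw p-values drive the calls;
BH-adjusted values are available in every output table for readers who
prefer them — per-sample calling thresholds are a judgement call we expose
rather than hide.

## TF activity inference

Activity scores solve, per sample, the least-squares problem
`G[i, k] = sum_j T[i, j] A[j, k]` over the network's target-gene universe,
where `T` is the ternary (+1 activation / -1 repression / 0 none) target
matrix built from a curated regulatory table. Unknown-mode edges are
discarded at parse time; duplicate edges collapse; a pair annotated with
*both* modes is excluded with a warning (the table gives no way to choose).
TFs whose annotated targets are all absent from the expression matrix are
dropped and logged, as are TFs whose fitted activities have zero standard
deviation across samples — a constant score carries no ranking
information.

An intercept is fitted by default. The historical solver for this class of
model fits one unless told otherwise, and on mean-centered input it is
nearly zero anyway; the flag `intercept = FALSE` is provided because the
choice is not empirically identifiable from published descriptions and
costs nothing to expose. All samples share one pivoted QR decomposition of
the design; collinear columns yield `NA` activities that are flagged
("non-identifiable"), never silently zeroed, and propagate to missing
p-values and K− calls.

The null for activity scores permutes each sample's expression vector
across genes `n_perm` times, re-infers activities, and pools all
`n_perm * n_samples` scores per TF into one reference vector. Pooling
across samples conflates sample-specific scale; mean-centered input (the
pipeline always centers) keeps the pooled null honest. Degenerate permuted
fits are retained — they are legitimate draws from the null. The upper-tail
p-value uses the same add-one smoothing as above, and the K+ call for the
designated TF requires `p < alpha` *strictly*, so a p-value exactly at the
threshold is a negative call.

## Association analyses

Spearman correlations are Pearson correlations of midranks, with
permutation p-values (two-sided by default; sidedness is a flag since a
reported association floor is reachable either way). For whole tables
(genes x P/R scores; TFs x P/R scores; cell types x activity) one shared
set of permutations serves every row — a single matrix product yields all
null correlations — and BH adjustment is applied within each table
separately, mirroring per-analysis correction. Constant rows are flagged
missing rather than erroring.

Subtype overlap between two labelings uses the one-tailed Fisher exact
(hypergeometric upper-tail) probability per category pair, with pairs
ranked by overlap within each category so the best and second-best
mappings are immediate.

A TF "sustains" a programme when two independent criteria agree in sign
and significance (each BH-adjusted below `alpha`): its activity correlates
positively with the programme's enrichment score, and its annotated
targets are enriched (positive high-tail running score) among the genes
ranked by correlation with that same score. The label is correlational by
construction; no causal claim is implied.

## Survival and immune association

Kaplan–Meier, log-rank and Cox proportional-hazards computations delegate
to the `survival` package: Efron tie handling (the ecosystem default),
stage coded as a single ordinal covariate, age continuous, gender as a
binary indicator. The three standard multivariate models — both scores,
P-only, R-only, each with stage/age/gender — are fitted for overall and
relapse-free survival; per-covariate Wald tests and asymptotic 95%
confidence intervals are reported. Constant covariates are errors;
collinear ones warn loudly. No time-varying covariates, stratified
baselines, competing risks or treatment variables are supported.

Immune-cell fractions are consumed as a table (any deconvolution tool's
output; deconvolution itself is out of scope). Cell-type fractions
correlate with the designated TF's activity as above; K+/K− distributional
comparisons use the two-sided two-sample Kolmogorov–Smirnov test with
asymptotic p-values (exact optional for small groups), optionally within P
strata since both pooled and stratified readings of such comparisons are
defensible; the myeloid-vs-lymphoid validation uses a one-tailed Welch
(unequal-variance) t-test, with pooled variance available behind a flag.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` plants every structure the pipeline is supposed to
find: disjoint P and R signature sets whose genes are shifted by
`effect_size` (in noise-SD units) in positive samples; a random regulatory
network whose per-sample activities (standard normal) act on target genes
through the ternary design; a designated R-driving TF whose activity is
*set to* `effect_size` in R+ samples (these are the planted K+ samples) and
a symmetric P-driving TF; exponential survival with hazard multiplied by
`hazard_ratio_rpos` for R+ samples under independent exponential
censoring; and seven immune cell types on a common 0.12 scale, two myeloid
ones generated as logistic transforms of the designated TF's activity plus
noise, the rest independent.

Design choices worth spelling out:

- **Gaussian noise** idealises normalised log-scale intensities, the
  standard assumption for this data class.
- **K planting acts through the network**: the designated TF has no
  transcript of its own in the matrix; only its targets move. TF expression
  and TF activity are deliberately different things.
- **Label association**: P+ and R+ memberships are drawn from a 2x2 joint
  whose P+/R+ cell is shrunk from independence by `pr_anticorrelation`,
  preserving both marginal fractions (defaults 0.35). A naive
  "flip R to the opposite of P" rule would inflate the R+ fraction well
  above its nominal value, and per-gene mean-centering would then absorb
  most of the planted activity shift.
- **Coherent driver regulons**: the two planted programme-driving TFs are
  given all-activating target sets. With mixed modes the *activity* is
  still recoverable, but the target-set-enrichment arm of the sustaining
  call would be undetectable by construction for an unlucky
  majority-repressing draw.
- **`effect_size = 0` is the null cohort**: signature shifts, TF-to-target
  coupling and K planting are all switched off, making expression
  exchangeable across genes. This is what "null" must mean for the
  permutation machinery to be calibrated — leaving regulon coupling on
  would make expression non-exchangeable and the pooled TF null
  conservative in some directions and anti-conservative in others.
- **Fractions are not closed to 1**: closure would induce spurious
  negative coupling between independent cell types; the sub-unit scale
  reads as "remaining content is non-immune tissue".
- **Batches** (optional) add per-gene offsets that per-batch
  mean-centering removes exactly.

What passing the recovery tests shows: the statistics find exactly the
structure they are designed for at a realistic signal-to-noise ratio
(shifts of two noise SDs, 300 samples), and nothing on null data. What it
does not show: robustness to probe-level artefacts, platform mixtures,
non-Gaussian heavy tails, correlated gene-gene noise, or realistic
deconvolution error — none of which the generator attempts to emulate.

Validation problem sizes (chosen to exercise the asymptotics the methods
rely on while keeping the suite quick to run): calibration uses a 300-
sample, 1000-gene null cohort with 1000-permutation nulls; recovery uses
the default 300 x 2000 cohort with 50 TFs; TF-activity recovery uses 500
target genes, 20 TFs and 100 samples at noise SD 0.1; survival recovery
uses n = 500 with ten replicates and 50 null replicates. One calibration
subtlety: signature genes correlate with their own enrichment score even
in a null cohort — that is genuine structure, so the calibration rate is
measured over non-signature genes only.

## Reproducibility

Every stochastic step draws from a named stream derived from one master
seed (`derive_seed(seed, stream)`), so stages can be re-run in isolation
and the pipeline is bit-reproducible given its configuration. Outputs are
plain TSV plus a YAML manifest recording parameters, seed and package
version; a failing stage writes a `FAILED` marker naming the stage and
retains the partial outputs.

## Known limitations

- The activity model is unregularised least squares; heavily overlapping
  regulons produce correlated (or non-identifiable) activity estimates.
  Ridge or lasso variants are out of scope by design.
- The pooled TF null assumes samples are on a common scale after
  centering; strong per-sample variance differences would distort it.
- Per-sample P/R calls use raw p-values at `alpha = 0.05` by default; with
  hundreds of samples a few false positive calls per cohort are expected
  and visible in the null-cohort calibration numbers.
- Asymptotic KS p-values are anti-conservative below ~25 samples per
  group; switch `exact = TRUE` there.
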