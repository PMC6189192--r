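# prtf

Tumour expression cohorts can be stratified by two supervised gene
signatures: cell **p**roliferation (P) and tissue **r**emodelling (R). `prtf`
implements that stratification end to end for bulk transcriptomics cohorts
— single-sample signature scoring with permutation significance,
transcription-factor (TF) activity inference over a curated regulatory
network, discovery of TFs that *sustain* the P or R programme, survival
comparison of the resulting subtypes, and association of a designated TF's
activity with immune-cell infiltration. A synthetic-cohort generator with
planted ground truth makes every stage testable by recovery.

It is aimed at computational biologists who have a genes × samples
expression matrix (microarray or RNA-seq, normalised and log-scale), the P
and R signatures as gene sets, a TF→target table with activation/repression
annotations, and optionally clinical follow-up and immune deconvolution
fractions.

## The statistics at the core

**Signature score.** For a sample with *n* ranked genes and a signature of
*m* genes, the running enrichment score after the *i*-th ranked gene is

E_i = Σ_{j≤i} h(g_j),  h(g) = 1/m if g in the signature, −1/(n−m) otherwise,

so E_n = 0 exactly. The extrema E− = min_i E_i ∈ [−1, 0] and
E+ = max_i E_i ∈ [0, 1] measure enrichment in the low- and high-expression
tails. Significance is the add-one smoothed permutation p-value
p = (1 + #exceedances)/(1 + n_P), with floor 1/(n_P + 1); because the score
is rank-only the null depends only on (n, m) and is shared across samples.
A sample is P+ when the P signature is significantly up-regulated
(high-tail p < α), likewise R+.

**TF activity.** With a ternary target matrix T (T_ij = +1/−1/0 for
activation/repression/no annotation), each sample's expression over the
target-gene universe is modelled as G_·k = T · A_·k and solved by least
squares; A_jk is TF *j*'s activity score in sample *k*. Significance comes
from a pooled null: every sample's expression is shuffled across genes
n_perm times, activities re-inferred, and all n_perm × n_samples scores per
TF pooled; a sample is K+ for the designated TF when its upper-tail p-value
is below 0.05 (strict).

**Sustaining TFs.** A TF is called P→P when its activity correlates
positively and significantly (Spearman, permutation p, BH-adjusted) with the
P score *and* its annotated targets are significantly enriched at the top of
the gene ranking by correlation with the P score; R→R analogously.

Survival uses Kaplan–Meier/log-rank across subtype strata and multivariate
Cox proportional-hazards models (P and R scores plus stage, age, gender;
Wald tests). Immune association uses Spearman correlations of deconvolved
cell fractions with the designated TF's activity, two-sample
Kolmogorov–Smirnov tail comparisons between K+ and K− samples, and a
one-tailed Welch t-test of myeloid versus lymphoid activity scores.

## Worked example

```r
library(prtf)

cohort <- generate_cohort(synthetic_config(seed = 7))
result <- run_pr_pipeline(cohort)
result
#> <pr_pipeline_result>
#>   samples: 300  P+: 103  R+: 113
#>   designated TF TF01: 120 K+ call(s)
#>   sustaining TFs: 2
```

Of 300 synthetic samples, 103 are called P+ and 113 R+ (the generator
planted 35% of each, anti-correlated); 120 samples are K+ for the planted
R-driving TF. Both planted programme drivers are recovered with their
correct labels:

```r
result$sustaining_tfs
#> # A tibble: 2 × 6
#>   tf    programme activity_s activity_q enrichment_score enrichment_q
#> 1 TF02  P->P           0.606     0.0250            0.975       0.0250
#> 2 TF01  R->R           0.631     0.0250            0.975       0.0500
```

The R score carries the planted survival risk (hazard ratio 2 for R+
samples; the relapse-free Cox model containing only the R score among the
signature terms):

```r
tidy(result$cox$rfs$r_only)
#> # A tibble: 4 × 5
#>   term        hazard_ratio ci95_low ci95_high  wald_p
#> 1 r_score            1.70     1.23       2.34 0.00120
#> 2 stage              0.958    0.838      1.09 0.525
#> ...
```

and the two fraction-coupled myeloid cell types top the infiltration
correlations (`Neutrophils` S = 0.71, `Macrophages_M0` S = 0.72, both
q = 0.0035), while uncoupled cell types stay flat. `autoplot(result$correlations)`,
`plot_km()` and `plot_fraction_volcano()` draw the correlation plane, the
survival curves and the infiltration volcano.

Real data enter the same way via file paths:
`pipeline_config(expression = "expr.tsv", gene_sets = "pr.gmt", network =
"trrust.tsv", clinical = "clinical.tsv", fractions = "cibersort.tsv", ...)`
then `run_pr_pipeline(cfg)`.

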