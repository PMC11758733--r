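---
title: "Methods: two-sample Mendelian randomization in steromr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in steromr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steromr)
```

## The estimand and its assumptions

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. Each instrument must be (i) associated with the
exposure (*relevance*), (ii) independent of exposure–outcome confounders
(*exchangeability*), and (iii) affect the outcome only through the exposure
(*exclusion restriction*). With per-SNP exposure associations
$\hat\gamma_j \pm \sigma_{xj}$ and outcome associations
$\hat\Gamma_j \pm \sigma_{yj}$ (log-odds scale, aligned to the same effect
allele), the target is the causal log-odds effect $\theta$ in
$\Gamma_j = \theta\,\gamma_j + \alpha_j$, where $\alpha_j$ is the horizontal
pleiotropic effect of SNP $j$ (zero for a valid instrument).

The three estimators trade power for robustness:

* **IVW** (`mr_ivw`) assumes all $\alpha_j = 0$ and is the weighted
  least-squares slope through the origin with weights
  $w_j = \hat\gamma_j^2/\sigma_{yj}^2$. It is the most powerful of the three
  and the primary estimate.
* **Weighted median** (`mr_weighted_median`) is consistent when valid
  instruments carry more than 50% of the total weight.
* **MR-Egger** (`mr_egger`) allows directional pleiotropy under the InSIDE
  assumption (pleiotropy independent of instrument strength): the free
  intercept absorbs the mean pleiotropic effect and the slope remains a
  consistent (if low-powered) estimate of $\theta$.

Cochran's $Q$ quantifies heterogeneity of the per-SNP ratios (flagged at
$p < 0.05$); the Egger intercept tests directional pleiotropy; MR-PRESSO
detects and removes individual pleiotropic outliers; leave-one-out exposes
single-SNP leverage.

## Instrument selection parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pval_threshold` | 1e-5 | p-value | locus-wide threshold used when genome-wide (5e-8) yields too few instruments for a modest exposure GWAS; 5e-8 available by flag |
| `clump_r2` | 0.001 | r² | near-independence of index SNPs, so IVW weights are not double-counted |
| `clump_kb` | 10000 | kb | window within which LD is considered; closed interval on distance |
| `f_min` | 10 | F | conventional weak-instrument cutoff; applied per SNP with $F_j = (n_j-2)R_j^2/(1-R_j^2)$ |
| `sig` | 0.05 | p-value | heterogeneity / outlier flagging level |
| `n_boot` | 1000 | replicates | weighted-median bootstrap; SE Monte-Carlo error ≈ 2% of SE |
| `n_sim` | 1000 | replicates | MR-PRESSO simulations; empirical p resolution 1/1001 |

The per-SNP variance fraction uses the standardized-effect approximation
$R_j^2 = \frac{2e_j(1-e_j)b_j^2}{2e_j(1-e_j)b_j^2 + 2e_j(1-e_j)s_j^2 n_j}$,
which reduces to $2e(1-e)b^2$ for a unit-variance trait; the $n$-normalized
denominator keeps the quantity a valid fraction when inputs are
unstandardized. Users with a published $R^2$ can bypass this by constructing
the instrument set themselves.

The confounder screen is deliberately a user-supplied exclusion list
(`exclude_snps`, `read_exclusion_list`): phenome-wide lookups of index SNPs
are a manual, judgment-laden step, so the pipeline records removals rather
than automating the query.

Greedy clumping breaks p-value ties by (chrom, pos, snp_id) so the retained
set is independent of input row order.

## Harmonization conventions

The exposure's effect allele is the reference orientation; only the outcome
record is modified. Allele-order swaps negate the outcome beta; strand flips
are resolved by base complement before re-matching; SNPs whose allele sets
remain irreconcilable are dropped as mismatches. Palindromic SNPs (A/T, C/G)
are dropped by default because their strand is ambiguous from labels alone;
an optional `"infer"` policy keeps them when both allele frequencies are on
the same side of 0.5 and outside 0.42–0.58. Harmonization never alters a
standard error. `orient_positive` (required by MR-Egger, identity for the
other estimators' point values) negates both betas wherever
$\hat\gamma_j < 0$, which preserves every Wald ratio; `mr_egger` applies it
internally so callers cannot accidentally fit an unoriented regression.

## Numerical and inferential choices

* IVW uses closed-form sums; its SE under the default multiplicative
  random-effects model is the fixed-effects SE times
  $\max(1, \sqrt{Q/(J-1)})$ — floored at 1 so random effects never claim more
  precision than fixed effects. IVW p-values use the normal reference.
* MR-Egger is fit by QR-decomposed weighted least squares (numerically stable
  for near-collinear designs); coefficient SEs carry the same
  $\max(1,\cdot)$ overdispersion floor with scale $\sqrt{RSS_w/(J-2)}$, and
  p-values use $t_{J-2}$.
* The weighted median interpolates sorted ratios against cumulative midpoint
  percentiles $p_j = \sum_{i\le j} w_i' - w_j'/2$ at 0.5; its bootstrap
  resamples $\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{xj}^2)$ and
  $\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{yj}^2)$ under a caller-supplied
  seed, so the SE is bit-reproducible.
* Wald-ratio SEs use the first-order delta method (ignoring $\sigma_x$), the
  standard two-sample default; a second-order option adds
  $\hat\Gamma^2\sigma_x^2/\hat\gamma^4$ under the root.
* MR-PRESSO residuals are standardized by $\sigma_{yj}$ so the residual sum
  of squares is scale-free; empirical p-values use the add-one rule
  $(1+\#\{\cdot\})/(n_{sim}+1)$ and are therefore never exactly zero; per-SNP
  p-values are Bonferroni-multiplied by $J$ and capped at 1. The distortion
  test is reported but never gates anything: whenever outliers are flagged,
  the outlier-corrected IVW estimate is emitted alongside the full-set one.
* Degenerate inputs fail loudly: $\hat\gamma_j = 0$ raises a division error
  naming the SNP; estimators refuse sets below their instrument minima (1/2
  for fixed/random IVW, 3 for Egger and the median, 4 for PRESSO); a PRESSO
  run that flags every SNP is an error rather than a silent empty correction.
* Empirical-p determinism: every stochastic component takes an explicit seed;
  the pipeline derives component seeds from the single run seed recorded in
  the manifest.

## Significance over a grid

`run_grid` analyzes each exposure–outcome pair independently and labels each
cell's IVW p-value by `classify_significance`: *significant* below
0.05 divided by the number of exposures, *suggestive* between that and 0.05.
Dividing by exposures only (five exposures → 0.01) rather than by all pairs
is a deliberate, faithful reproduction of a common applied convention and is
flagged prominently here because it is less conservative than a full
Bonferroni over the grid. A replication outcome is just another grid column,
not a special case.

## What the synthetic generator does and does not emulate

`simulate_two_sample` draws, per SNP: allele frequency uniform on
`eaf_range`; true exposure effect $\gamma_j \sim N(0.1, 0.03^2)$ by default —
a few dozen strong, uniformly oriented instruments, so per-SNP F is far above
10 and positive orientation holds without flips (this matters: orienting on
$\hat\gamma$ sign would fold a directional pleiotropy distribution if true
effects straddled zero); SEs from the standardized-trait model
$\sigma = 1/\sqrt{2e(1-e)n}$, treating the outcome beta as a log-odds;
pleiotropy $\alpha_j$ of mode none / balanced / directional; optional
additive outlier shifts; and sampling noise around the truth (`noise = FALSE`
gives the infinite-sample limit, where all three estimators recover $\theta$
to machine precision). One run seed drives a hashed per-SNP substream, so
enlarging `j_snps` never perturbs earlier SNPs' draws. Default sample sizes
(50,000 exposure, 100,000 outcome), $\theta = 0.2$ and $J = 30$ mirror a
hormone-GWAMA-to-stroke-GWAMA setting at a size where recovery tests run in
seconds.

Not emulated: case-control ascertainment and winner's curse (instrument
effects are drawn, not selected from a scan, so selection bias on
$\hat\gamma$ is absent); between-sample allele-frequency differences and
population stratification; correlated pleiotropy violating InSIDE; and real
LD (the block generator produces idealized equi-correlated blocks with zero
between-block LD, sufficient to exercise the greedy clumping contract but not
a model of a real region). Passing recovery tests on these simulations
therefore validates the estimators and plumbing, not the untestable
identifying assumptions in any particular application.

## Validation problem sizes

The test suite checks estimator-vs-oracle agreement on 100 random instances
($J \in 3..20$, tolerance 1e-10 against explicit normal-equations and
sort-and-interpolate oracles); 95% CI coverage of $\theta = 0.2$ over 100
seeded replicates at $J = 30$; Egger-intercept recovery of a 0.05 directional
pleiotropy mean and its false-positive rate under balanced pleiotropy, 100
replicates each; MR-PRESSO detection of a single injected 10-SD outlier at
$J = 20$ with 500 simulations over 100 replicates plus 200 null replicates.
These sizes give Monte-Carlo error comfortably inside each acceptance band
while keeping the full suite under half a minute; `scripts/acceptance.R`
recomputes all of them from scratch for any seed.

## Known limitations

* No mode-based, multivariable, or contamination-mixture estimators; the
  scope is the IVW / Egger / weighted-median trio plus their standard
  diagnostics.
* No proxy-SNP search: instruments absent from the outcome GWAS are dropped.
* No LD computation from genotypes; an LD matrix must be supplied for
  clumping (or SNPs assumed independent).
* The weighted-median bootstrap ignores exposure-outcome sample overlap, as
  does everything else — the two-sample setting is assumed, not checked.
* PRESSO's simulation calibration is approximate for very small $J$; the
  $J \ge 4$ floor is a hard precondition, not a sufficiency guarantee.
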