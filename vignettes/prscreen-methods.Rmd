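---
title: "Models and methods behind prscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prscreen)
```

`prscreen` implements a polygenic-score screening analysis for
behavioural traits: construct a schizophrenia-style polygenic risk score
(PRS) in a target cohort, screen many traits for association with it in
the undiagnosed sub-population, and contrast the resulting
PRS-by-trait gradients with trait values in diagnosed, medicated and
non-medicated individuals. This vignette records the models, the
defaults and why they are what they are, the numerical choices, and
what the synthetic cohorts do and do not emulate.

## The polygenic score

The PRS of individual $i$ is $\sum_j \hat\beta_j d_{ij}$ over a set of
approximately independent SNPs: summary statistics are harmonised to
the target's allele orientation (effect alleles matching the target's
counted allele keep their log odds ratio; those matching the other
allele are sign-flipped exactly once; strand-ambiguous A/T and C/G
pairs and duplicated ids are excluded), then greedily clumped — the
most significant unclaimed SNP becomes an index and claims every SNP
within 250 kb either side on the same chromosome with squared dosage
correlation $r^2 \ge 0.1$ — and finally thresholded at $P < 0.05$ for
the *best-fit* profile or $P < 5\times10^{-8}$ (or an explicit sentinel
list) for the *GW-significant* profile. The lenient threshold is fixed
rather than tuned in the target: searching thresholds in-target
optimises on the outcome and changes the meaning of downstream
P-values, so a threshold grid exists but is off by default.

Numerical conventions worth stating:

* clumping ties are broken by P, then position, then id, making the
  output invariant to input row order;
* the ±250 kb window (500 kb total span) follows the PLINK/PRSice
  convention for windows quoted without sidedness;
* missing dosages are imputed at twice the effect-allele frequency, so
  an individual missing every selected SNP scores at the population
  mean;
* scores are standardised before regression; this makes them invariant
  to rescaling the weights and to recoding any SNP's counted allele
  (dosage $d \to 2-d$ with the weight's sign flipped).

## The screen

Each trait is regressed on the standardised PRS with covariate
adjustment — linear for quantitative traits, logistic for binary ones —
and the PRS term's Wald statistics are reported together with the
incremental variance explained: the difference in $R^2$ between the
covariates-only and covariates-plus-PRS fits, or the difference in
Nagelkerke pseudo-$R^2$ for logistic fits (both pseudo-$R^2$ values are
computed against the same intercept-only deviance, so the difference is
the PRS's share). Listwise deletion gives each trait its own sample
size, mirroring per-trait availability in questionnaire data.
Separation or non-convergence of a logistic fit flags the result rather
than erroring: in a screen of hundreds of traits a single degenerate
outcome must not abort the run.

Two significance tiers are applied: plain Bonferroni, $0.05/n$ for $n$
traits screened (no FDR layer — the tier structure is part of the
design being reproduced), and a stringent $P < 10^{-7}$ tier guarding
against the subtle confounding that biobank-scale sample sizes can
promote to nominal significance. Profile concordance (sign agreement
and nominal GW-profile significance for stringent best-fit hits) and a
PC-count sensitivity analysis (default 15 vs 40 PCs, reported as beta
ratios against the smallest count) are the two built-in triangulation
checks.

## The quantile contrast

The undiagnosed population is ranked by PRS into 20 equal-count bins
(sizes differ by at most one; ties keep stable sample order). The trait
is regressed on one-hot bin indicators plus covariates with bin 11 as
the omitted reference, so each coefficient estimates the trait
difference from the middle stratum, the reference coefficient is
identically zero, and — with no covariates and a linear family — each
coefficient equals the bin mean minus the reference bin mean exactly.
Switching the reference shifts all coefficients by a constant; pairwise
differences are invariant.

Diagnosed individuals are excluded from the bins and appended to the
same regression as extra factor levels (a non-medicated and a medicated
group when medication status exists, one case group otherwise),
reflecting their expected higher genetic burden. Confidence intervals
are 95% Wald throughout.

Concordance of a case group with the genetic trend is a judgement the
original analysis made by inspection; it is operationalised here as:
trend direction = sign of the least-squares slope of the 20 bin
coefficients on bin index; a case group is *concordant* if its
coefficient shares that sign while the slope is nominally significant
($P < 0.05$), *discordant* if the signs oppose, *flat* otherwise. The
rule (and its $\alpha$) is a package choice, exposed as an argument,
because no formula exists to copy.

## Quality control

Filters run in a fixed order — SNP missingness, MAF, HWE, sample
missingness, kinship, ancestry — with counts recorded per step.
Boundaries are strict as conventionally quoted: missingness strictly
greater than 0.02 (SNPs) or 0.01 (samples) removes; MAF strictly below
0.01 removes; HWE removes below $P = 10^{-8}$ by a 1-df chi-square on
observed vs expected genotype counts (no continuity correction — at a
$10^{-8}$ threshold the exact test changes nothing that matters).
The SNP missingness-and-MAF wording reads literally as a conjunction
but is conventionally a union of removal rules; the union is the
default and `conjunctive = TRUE` selects the literal reading.

Kinship uses the KING method-of-moments estimator from heterozygote and
opposite-homozygote sharing,
$\hat\phi = (N_{\text{het,het}} - 2N_{\text{AA,aa}})/(N^{(i)}_{\text{het}} + N^{(j)}_{\text{het}})$,
counted over SNPs non-missing in both members. The between-family
variant that divides by twice the smaller heterozygote count is robust
to strong ancestry differences but carries a small downward bias in
homogeneous cohorts (it exceeded ±0.01 on simulated unrelated pairs);
the symmetric denominator estimates duplicates at 0.5 and unrelated
pairs at 0 without bias, which is what the pruning threshold of 0.088
(third-degree cutoff) assumes. Pruning removes exactly one member per
flagged pair, greedily by flagged-pair count with ties broken by
sample-id order — deterministic and row-order invariant.

PCA standardises dosages by $\sqrt{2p(1-p)}$ (Patterson convention;
sample-SD scaling by flag), drops zero-variance columns, mean-imputes
missing calls, and computes components from the eigendecomposition of
the $n \times n$ cross-product (cheap when samples are fewer than
SNPs). Signs follow a fixed convention — each component's
largest-magnitude loading is positive — so repeated runs are identical.
Ancestry clustering is 4-means on PC1–PC2 with 10 restarts under a
fixed seed, returning the largest cluster as the analysis subset.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be validated with
known ground truth; its defaults are the study conditions, not tuning
knobs.

**Genotypes.** Two latent Gaussian haplotypes per individual, AR(1)
with correlation `ld_rho` (default 0.5) within blocks of
`ld_block_size` SNPs (default 10, each block spanning ~100 kb),
thresholded at each SNP's allele-frequency quantile and summed. This
gives Hardy–Weinberg marginals with tunable, measurable neighbour
$r^2$ — the target of the clumping step — at negligible cost.
Population structure is Balding–Nichols: subpopulation frequencies are
Beta draws around an ancestral frequency (uniform on `maf_range`,
default 0.05–0.5) with drift `fst`. Allele pairs are drawn from the
strand-unambiguous combinations so default harmonisation keeps every
simulated SNP.

**Disorder.** Standard liability threshold: liability = genetic score
over `n_causal` SNPs (default 30) scaled to variance `h2_liability`
(default 0.3), plus any scenario contribution, plus Gaussian residual,
standardised empirically to variance 1 (so LD among causal SNPs cannot
inflate it); cases exceed the $1-K$ quantile at prevalence $K = 0.01$,
the conventional schizophrenia figure. Misclassification flips a
configurable fraction of true cases to unaffected labels while true
status is retained — the rate is deliberately a free parameter, since
the hypothesised misclassification has no quantified value to copy.
Medication among labelled cases is Bernoulli with probability
$\operatorname{logit}^{-1}(s(\ell - t))$ centred at the diagnostic
threshold $t$, so slope $s = 2$ (default) gives realistic ~50–70%
treatment rates while making medicated cases genetically more burdened,
and the medication effect on the trait is a simple additive shift
(`medication_trait_shift`) — the simplest mechanism that reproduces a
case group opposing the population trend.

**Scenarios.** Exactly one causal arrow per scenario: `null` (noise),
`pleiotropy` (a heritable latent mediator with its own causal SNP set
drives both trait and liability), `structure` (per-subpopulation trait
offsets `env_gradient`, no individual-level genetic effect),
`disorder_to_trait` (trait shifts by `trait_effect` in true cases), and
`trait_to_disorder` (trait heritable at `h2_trait` on the disorder's
causal set, feeding `trait_effect` times its standardised value into
liability). `simulate_cohort()` fixes the causal ordering per scenario;
age, sex and the deprivation index are genotype-independent by default,
with opt-in deprivation→trait loading for confounding studies.

**Locations.** Birth coordinates uniform on a square map (default
500 km, 10 km raster cells with Gaussian urban density peaks over a
rural base); a log-normal displacement for a configurable mover
fraction, with log-magnitude optionally increasing in the
risk-taking-like trait and/or deprivation; years at residence decrease
with displacement. This emulates the coordinate→density→migration
derivation, not any real geography.

**What passing tests do not show.** The generator has no realistic LD
map, no allele-frequency/effect-size coupling, no assortative mating or
case ascertainment, planar instead of national-grid coordinates, and
noise-free phenotype measurement. Tests against it validate the
*machinery* — estimators, invariances, calibration, qualitative causal
signatures — not effect sizes transferable to real biobank data.

## Oracle summary statistics

The external discovery GWAS is emulated in two modes. `oracle` adds
Gaussian noise to the true per-allele liability effects with the
standard case-control standard error
$1/\sqrt{2p(1-p)\,n\,\phi(1-\phi)}$ at a nominal discovery size
(balanced $\phi = 0.5$); it is exact in the $n \to \infty$ limit and
gives uniform P-values at null SNPs. `cohort_gwas` runs per-SNP
logistic regressions of diagnosis on dosage in an independently
simulated cohort. Oracle mode is the default for validation because its
error structure is known in closed form.

## Simulation sizes

The test suite sizes its simulations to the smallest scales at which
each property is decisive: calibration screens use 1000 null traits at
$n = 2000$; effect-recovery coverage uses 100 replicates at
$n = 10\,000$; structure attenuation 50 replicates at
$n = m = 1000$; the clumping oracle 200 random instances of up to 60
SNPs; replicate counts for secondary properties are 10–50. The
acceptance script re-runs the same analyses at half scale. One caveat
is inherent in the structure-attenuation summary: the drift-induced
confound has random sign and magnitude per replicate, so attenuation is
summarised by the median ratio and pooled betas rather than a mean of
per-replicate ratios, which is unstable when a replicate happens to
carry no confounding.

## Known limitations

* LD is block-diagonal; there is no inter-block LD for clumping to
  disentangle, so clumping is validated against its definition (an
  exhaustive oracle), not against real LD complexity.
* Liability-scale $R^2$ for binary traits is offered only through the
  Nagelkerke difference; a full liability-scale transformation is out
  of scope.
* The KING estimator assumes autosomal biallelic SNPs; no X-chromosome
  handling.
* `cohort_gwas` mode fits one GLM per SNP and is intended for small
  simulated panels, not biobank-scale genotype files.
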