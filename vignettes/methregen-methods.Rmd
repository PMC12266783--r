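---
title: "Methods: models, parameters and design choices in methregen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methregen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methregen)
```

methregen analyses paired contralateral-limb methylation-array studies of
skeletal muscle regeneration: per-probe differential methylation,
conversion of significant CpGs to methylation peaks, TSS-distance
regulatory-potential integration with RNA-seq differential expression, and
linear epigenetic-clock age analysis. This vignette documents the models,
the parameters that matter, the numerical conventions, and the design
choices that were genuinely open, so that results can be interpreted and
the pipeline re-parameterised with eyes open.

## The differential-methylation model

Beta values $\beta_{gs} \in [0,1]$ (methylated fraction of probe $g$ in
sample $s$) are modelled directly by ordinary least squares, probe by
probe, for the BaCl2-vs-PBS limb contrast within one arm (YV, OV or OS).
Modelling beta values untransformed keeps effects interpretable as
methylation differences; because their variance shrinks near 0 and 1, a
logit ("M-value") option is available (`diff_methylation(on = "mvalue")`).
The default design blocks on animal, which absorbs the shared per-animal
intercept of the paired design (and any chip effect, since contralateral
limbs are processed on the same chip); `paired = FALSE` switches to the
covariate-only model with batch indicator columns, matching analyses that
enter group and chip as covariates without pairing. Probes with missing
values are fitted on their observed subset with recomputed residual
degrees of freedom.

Unknown structured confounding is absorbed by one latent factor estimated
from negative-control probes: the control submatrix has the fitted known
covariates removed, rows centred, and its first right singular vector
(unit norm, sign fixed so the largest-magnitude entry is positive) enters
the design as a numeric covariate. Controls are user-supplied when a
validated negative set exists; otherwise (`ruv = "auto"`) the 1% least
variable probes after covariate removal stand in. Estimating the factor
against a minimal covariate set preserves more of the factor's span;
projecting out a rich design (e.g. animal blocks) leaves only the
residual-space component, which is still exactly what the subsequent fit
needs.

Variance moderation follows the standard empirical-Bayes treatment:
residual variances $s_g^2$ on $d_g$ df are assumed to follow
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g$ with a scaled
inverse-chi-square prior $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$. The
prior is estimated by matching the first two moments of $\log s_g^2$ to
the scaled-F prior predictive, inverting the trigamma function by Newton
iteration (relative tolerance 1e-8, 50 iterations). When the observed
log-variances are no more dispersed than chi-square sampling alone
explains, $d_0 = \infty$ and $s_0^2$ is the pooled mean variance. The
moderated $t$ uses the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on $d_0 + d_g$ df,
capped at the total residual df the data carry — the finite-sample
convention of the established moderated-t implementations, against which
the test suite cross-checks this one. Multiplicity is controlled by
Benjamini–Hochberg; q < 0.05 (configurable) defines significance, and
direction is the sign of the BaCl2 − PBS effect (hypo = negative),
matching the convention that fold changes below 1 against the
contralateral control limb indicate hypomethylation. A significant record
with an exactly zero effect is left unclassified (`ns`) rather than
assigned a direction arbitrarily.

## Regulatory potential, rank products and the direction test

Each significant CpG becomes a single-bp peak (array CpGs have single-base
resolution, so intervals would add spurious width). A gene's regulatory
potential is

$$\mathrm{RP}(g) = \sum_{\text{peaks},\ d \le D} e^{-(\alpha + \beta d / D)},$$

where $d$ is the absolute distance from the strand-aware TSS. Defaults
$\alpha = 0.5$, $\beta = 4$, $D = 10^5$ bp follow the regulatory-potential
formulation the peak-based integration method is built on; all three are
exposed because published uses of the decay differ and sensitivity
analysis should be cheap. The decay is strand-agnostic in distance
(upstream and downstream contribute alike) but the TSS itself is
strand-aware, so plus/minus mirror constructions score identically — a
property the tests enforce on randomised configurations.

Integration with differential expression ranks genes within each DE
direction set (adjusted p < 0.05, split by fold-change sign) by RP
descending and DE p ascending. Ranking is competition-style with
lexicographic gene-id tie-breaks, making outputs deterministic and
permutation-invariant to input order. The rank product
$(r_{\mathrm{RP}} \cdot r_{\mathrm{DE}})/n^2$ lies in $(0, 1]$; genes
below the cutoff (default 0.25) with at least one peak are flagged as
predicted targets. The cutoff is deliberately configurable: the upstream
literature does not fix the value that defines a "predicted" list, so the
default is a round mid-scale choice, and downstream claims should rest on
the direction test rather than the flag.

The direction test asks whether the up- (or down-) regulated set carries
systematically more regulatory potential than the static background,
defined as genes with DE adjusted p ≥ 0.5 (configurable; the
non-differential remainder between the two thresholds is excluded from
both sides). The statistic is the one-sided two-sample Kolmogorov–Smirnov
$D^+ = \sup_x [S_{\mathrm{set}}(x) - S_{\mathrm{bg}}(x)]$ on survival
functions, so excess regulatory potential in the set increases $D^+$. For
$\min(m, n) \ge 50$ the asymptotic $p = e^{-2 D^{+2} mn/(m+n)}$ is used;
otherwise a label permutation with mandatory seed (default B = 9999) gives
$p = (1 + \#\{D^+_{\mathrm{perm}} \ge D^+_{\mathrm{obs}}\})/(B+1)$.
Because RP distributions contain many ties (zeros and lattice values of
$D^+$), permuted statistics within 1e-9 of the observed one count as
exceedances; excluding such ties makes the test anti-conservative and
floating-point-fragile. Both routes are validated against exhaustive
label enumeration on small sets and against each other at large, balanced
sizes.

## Clocks

A clock is a sparse linear map
$\widehat{\mathrm{age}}_s = c + \sum_j w_j \beta_{js}$ (weeks), applied
after gold-median imputation: any weighted probe absent from the matrix,
or missing in a sample, takes its reference median, and the per-sample
imputation count is reported. A probe absent from both the matrix and the
medians is an error, not a silent drop. The published muscle clocks'
coefficients are external resources; the package therefore carries the
application machinery plus a ridge-regression trainer
(`train_synthetic_clock`, closed-form normal equations on centred data,
intercept unpenalised, gold medians = training medians) so the
clock stage is testable end to end. An output-transform slot
(`log_linear`) exists because published mammalian clocks calibrate ages
through log-linear maps; the default is the identity (weeks in, weeks
out), and results are reported in the units the clock file declares.
Deceleration is summarised as
$100 (\bar a_{\mathrm{ctrl}} - \bar a_{\mathrm{trt}})/\bar a_{\mathrm{ctrl}}$
with the absolute difference in weeks alongside.

## What the synthetic generator emulates — and what it does not

`simulation_config()` defaults define the emulated study: arms YV (6
animals), OV (11), OS (9), each animal contributing both limbs (52
samples); 2,000 genes with 8 probes each (two promoter CpGs, the rest
distributed over gene features) at desk scale; beta baselines drawn from
feature-class-specific Beta distributions (promoters hypomethylated);
injury effects on 10% of promoter CpGs with a mean beta shift of −0.20
(senolytic arm −0.05 further), injected on the logit scale so values stay
in (0,1) without clipping; a per-animal random intercept (logit SD 0.20)
inducing the paired-limb correlation; a per-chip batch shift (SD 0.20,
both limbs of an animal share a chip); one latent factor with N(0, 0.30)
loadings and 200 designated control probes; residual logit noise SD 0.15.
Counts are negative binomial (variance $\mu + \alpha\mu^2$, $\alpha =
0.05$) with log2 means shifted by $-\gamma$ times the promoter-beta
deviation for coupled genes ($\gamma = 5$ per unit beta, so
hypomethylation upregulates), plus a 5% set of expression-only responders
so both DE directions are populated. Effect sizes and noise SDs are chosen
for testability at desk scale — the study itself reports DM fractions, not
effect-size distributions.

Clock CpGs carry an age trend that is linear on the *beta* scale
($\beta_j = m_j + s_j \cdot \mathrm{age}$, slopes about ±0.002/week), with
the age signal of old injured limbs pulled toward the young mean by the
rejuvenation factor $\rho$ (default 0.5). Linear-in-beta trends are the
natural generative counterpart of clocks that are linear in beta: the
emitted clock ($w_j = s_j/\sum_k s_k^2$, intercept $-\sum_j w_j m_j$) is
then the exact inverse of the noise-free generative map at every
intermediate effective age, which the tests verify to 1e-6 weeks. A
logit-linear trend would make exact inversion by any beta-linear clock
impossible once $\rho$ creates a third effective age.

The generator does **not** emulate: raw IDAT intensities or
normalisation artifacts, probe cross-reactivity, detection failures
(missingness must be introduced explicitly), cell-type composition shifts,
genomic correlation between neighbouring CpGs, or read-level RNA-seq.
Passing tests therefore demonstrate that the chain recovers the structure
it models — not that real arrays satisfy that structure.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based closed internally, the GenomicRanges convention;
  BED input/output is converted at the boundary (0-based half-open), GTF
  and manifests are ingested as 1-based. Dialect-equivalence tests pin the
  TSS conventions (start on +, end on −; strand `*` is an error because
  the TSS is undefined).
- Beta values outside [0, 1], duplicate probe or sample ids, unknown
  feature classes, and promoter probes without a gene or outside the
  promoter window (default ±1,000 bp) are validation errors naming the
  offender.
- Missing betas are carried as NA and never imputed outside the clock
  stage, where imputation is explicit and counted.
- All-zero count genes are excluded from the internal DE table with a
  message; fewer than 30 genes fall back to unmoderated t statistics.
- Two-way ANOVA on a numerically constant response returns F = 0, p = 1
  for every effect instead of 0/0; a zero-variance probe is flagged with
  $s_g^2 = 0$ and shrunk like any other.
- Geometric-mean paired fold changes skip animals with a zero control-limb
  beta (with a message) rather than producing infinities.
- The pipeline expands its global seed into per-stage seeds by fixed
  offsets, restores the caller's RNG state after permutation tests, and
  rewrites byte-identical outputs for identical configs.

## Problem sizes used by the test and acceptance suites

The suites run the chain at reduced scale chosen to exercise every code
path with comfortable statistical margins: differential-methylation
recovery and type-I control on 2,000-probe studies with 10 animals per
arm (5 replicate seeds for the null); integration recovery on a
2,000-gene study; direction-test calibration on 200 replicates of 30-vs-30
draws with B = 499; moderation recovery on 5,000 probes; clock detection
rates on 100 seeds of a 40-probe, 20-animal design. These sizes are the
package's own choices for a fast, reproducible desk-scale demonstration;
the same functions run unchanged at array scale.

## Known limitations

- The unwanted-variation adjustment estimates a single factor; studies
  with richer technical structure need the factor generalised (k > 1) or
  external tools.
- Limbs are treated as independent observations in the two-way ANOVA,
  mirroring the study-level convention; a mixed-model alternative is out
  of scope, so interaction p-values inherit that approximation.
- The direction test conditions on the DE direction sets; it does not
  propagate DE estimation uncertainty.
- Competition ranking with lexicographic tie-breaks makes rank products
  deterministic but means exactly tied genes are ordered by id, not
  jointly averaged.
- The static-background definition (adjusted p ≥ 0.5) is a convention;
  conclusions should be checked under alternative thresholds via the
  exposed configuration.
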