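---
title: "Methods: two-sample Mendelian randomization with mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The causal model and its assumptions

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure: per-variant summary effects on the exposure (`bx_j`, SE
`sx_j`) come from one GWAS, effects on the outcome (`by_j`, SE `sy_j`) from
another, non-overlapping GWAS. If a variant (i) is robustly associated with
the exposure, (ii) independent of confounders and (iii) affects the outcome
only through the exposure, then the Wald ratio `by_j / bx_j` estimates the
causal effect, and pooling ratios across independent instruments trades off
power against the risk of pleiotropy. For binary outcomes all outcome-side
effects are interpreted as log odds ratios, and results are reported as
`OR = exp(beta)` with normal-theory intervals.

The estimator suite spans the usual robustness ladder:

* **IVW** (`mrIVW`) is the efficient choice when all instruments are valid.
  The automatic mode inspects Cochran's Q and switches to the
  multiplicative random-effects SE when heterogeneity is detected
  (p < 0.05), recording the decision. The random-effects SE is floored at
  the fixed-effects SE — extra heterogeneity can only widen intervals.
* **MR-Egger** (`mrEgger`) relaxes assumption (iii) to InSIDE (pleiotropic
  effects independent of instrument strength): its intercept estimates the
  average directional pleiotropy and its slope remains a causal estimate.
  Rows are oriented so `bx_j >= 0` before fitting, the convention that makes
  the intercept interpretable; inference is Student-t on J − 2 df.
* **Weighted median** (`mrWeightedMedian`) is consistent while more than
  half the weight comes from valid instruments.
* **Weighted mode** (`mrWeightedMode`) is consistent when the largest
  cluster of agreeing ratios is valid (ZEMPA).

A result is treated as primary on the IVW p-value, Bonferroni-corrected
across the four methods (`0.05/4 = 0.0125`, suggestive up to 0.05); the
battery additionally records whether all computed estimates agree in sign
(`direction_consistent`), the convention under which a significant IVW with
direction-consistent but non-significant supplements is still reportable.
The pipeline reports the flag and leaves the judgement to the analyst.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `p_threshold_primary` | 5e-8 | p | genome-wide screen |
| `p_threshold_fallback` | 5e-6 | p | locus-wide screen, applied (and logged) when fewer than `min_instruments` survive; microbiome traits conventionally use 1e-5 |
| `min_instruments` | 3 | SNPs | MR-Egger's minimum |
| `r2_max`, `window_kb` | 0.001, 10000 | r², kb | clumping: retained instruments pairwise independent |
| `f_min` | 10 | F | conventional weak-instrument cutoff |
| `presso_n_sim` | 3000 | cycles | outlier-test Monte-Carlo resolution 1/3001 |
| `n_boot` | 1000 | replicates | bootstrap SE for median/mode |
| `eafWindow` | 0.08 | frequency | palindromic ambiguity window around 0.5 |
| `phi` | 1 | — | mode bandwidth multiplier on Silverman's rule |

Thresholding is strict (`p < threshold`). Minimum instrument counts are
enforced and documented: Q needs 2, Egger and leave-one-out 3, the outlier
test 4 (its leave-one-out machinery is undefined below that).

## Harmonization policy

The two GWAS are intersected on variant id and aligned to the exposure's
effect allele; swapped alleles flip the outcome beta and complement its
frequency. Non-palindromic single-base alleles that match only after strand
complementation are treated as opposite-strand reports; indel alleles are
compared literally and never strand-flipped. Palindromic variants (A/T,
C/G) cannot be resolved from alleles alone; the default policy infers the
strand from allele frequencies and drops variants whose frequency on either
side lies within 0.08 of 0.5 (or is missing). This default mirrors common
two-sample practice; it is a package decision, since published analyses
typically delegate it to their software without stating the rule. `drop`
and `keep` policies are available for sensitivity analysis.

## The outlier test

The global statistic is the weighted residual sum of squares
`RSS = sum_j (by_j - theta_(-j) bx_j)^2 / sy_j^2` with `theta_(-j)` the
leave-one-out IVW estimate. Parametric replicates resample **both** sides,
`bx* ~ N(bx, sx)` and `by* ~ N(theta_(-j) bx, sy)`: the observed residuals
carry variance `sy^2 + theta^2 sx^2`, so resampling only the outcome would
leave the replicates under-dispersed and the test would reject under the
null. All Monte-Carlo p-values use the add-one estimator — resolution
`1/(nSim + 1)`, never exactly zero — and are bit-reproducible given
`(nSim, seed)`. Per-SNP outlier p-values are Bonferroni-adjusted across the
J instruments (threshold 0.05 by default; with 30 instruments this needs at
least ~600 cycles to be attainable at all). The distortion p-value compares
the raw-minus-corrected estimate change against changes from removing
random same-size subsets. Flagged outliers are removed and the estimators
re-run exactly once by the orchestration layer, matching the single-removal
workflow of applied analyses.

## The synthetic-data generator

`simulatePair()` emulates the statistical structure of a
cytokine-or-taxon exposure against a rare binary endpoint: exposure GWAS of
8,293 individuals, outcome with 287 cases / 360,143 controls, allele
frequencies uniform on (0.1, 0.9), per-SNP effect magnitudes half-normal
with scale 0.15 (per-SNP F spanning roughly 10–800, the weak-to-strong
range seen in practice), and closed-form standardized-trait sampling SEs
`1/sqrt(2 n eaf (1-eaf))`. Effects are coded on the exposure-increasing
allele — the convention for MR instrument tables — which is also what makes
directional pleiotropy detectable after Egger's `bx >= 0` orientation; with
sign-symmetric coding a constant pleiotropic offset would be sign-mixed by
orientation and no intercept test could see it. Pleiotropy is layered on as
`alpha_j ~ N(mu, sd^2)` for a configurable fraction of variants,
independent of instrument strength (InSIDE holds by construction;
`insideViolation` correlates them to stress-test Egger). Planted outliers
add a fixed or median-relative offset to the observed outcome effect. A
configurable fraction of variants (default 0.17, the approximate
genome-wide share) receives palindromic allele pairs.

What the generator does **not** emulate: LD between instruments (LD enters
only through a user-supplied r² matrix), true liability-scale binary
sampling (log-OR noise reuses the standardized closed form — adequate for
method calibration, not for power planning of a real case/control design),
allele-frequency differences between studies, and winner's-curse selection
bias. Passing calibration on this generator therefore demonstrates that
the estimators and tests are implemented correctly and behave nominally
under their own assumptions, not that any particular real-data finding is
correct.

Calibration problem sizes (the package's own choices, stated here so the
suite is interpretable): recovery/coverage at `theta = 0.2` uses J = 30 and
500 replicates with per-study samples of 10^6, a deliberately asymptotic
regime in which weak-instrument regression dilution
(~`se_x^2 / scale^2` relative, about 10^-4 there) sits far below Monte-Carlo
resolution; type-I error uses 1000 replicates at the study-scale default
samples; Egger size/power 500 replicates; outlier-test calibration and
detection 200 runs at 1000 cycles; mediation recovery 200 replicates.
Calibration runs set the palindromic fraction to zero so the instrument
count is exactly J.

## Mediation and multivariable analyses

`twoStepMediation()` estimates each leg by IVW-auto (Wald ratio for a
single instrument) and decomposes once via `decomposeMediation()`; the
mediated effect is `beta1 * beta2` with delta-method variance
`beta2^2 se1^2 + beta1^2 se2^2` (a parametric-bootstrap interval is the
obvious alternative; the delta method is the default because applied
reports rarely state how such intervals were formed). Log-scale additivity
(direct + mediated = total) holds to machine precision by construction, so
direct- and mediated-effect odds ratios always multiply to the total-effect
odds ratio. Published mediation tables occasionally print triples that
violate this identity (transposed digits are a common cause); the package
never "repairs" such rows — its own tables are generated from the
decomposition, where the identity is structural. The proportion mediated is
flagged undefined when `|beta3| < 1e-8` or when the mediated and total
effects have opposite signs, where it is uninterpretable. Instruments
selected for the exposure are excluded from the mediator→outcome leg: a
variant instrumenting both traits reaches the outcome through the
exposure's direct path too, violating that leg's exclusion restriction and
inflating `beta2` (measurably so in the chain simulations).

`mvmrIVW()` fits the no-intercept weighted multiple regression; the
instrument set is the union of each exposure's selection, jointly
harmonized to the first exposure's alleles with complete-case rows — the
union rule is a documented default (applied papers rarely state theirs) and
the per-exposure selections make it auditable. Confounder adjustment is
pairwise by default (primary + one confounder per fit, one adjusted row per
confounder, the usual forest-plot layout) with a full-joint option. An
exposure column with no genetic signal at all is dropped with a warning
rather than poisoning the design matrix; genuinely collinear exposure pairs
abort with the pair named.

## Numerical choices and degenerate inputs

* Written tables use 17 significant digits, so write→read is the identity.
* Tie-breaks in clumping are deterministic: ascending p, then variant id.
* The weighted median interpolates between bracketing order statistics and
  snaps to an exact order statistic when a cumulative midpoint hits 0.5
  within 1e-12, so equal weights and odd J return the sample median exactly.
* The mode search evaluates the kernel sum on a 512-point grid and refines
  by golden-section in the bracketing interval; a degenerate zero bandwidth
  (all ratios identical) returns the heaviest ratio.
* Chi-square tail probabilities are floored at the smallest positive double
  so p-values stay in (0, 1] even for extreme Q.
* `bx = 0` instruments are a domain error for ratio methods (a null
  instrument has no Wald ratio).
* Egger refuses designs with no spread in `bx` (slope unidentifiable).

## Known limitations

* Sample overlap between the two GWAS biases estimates toward the
  observational association; the package only quantifies the maximum
  overlap rate (`sampleOverlapPercent`), it cannot correct for it.
* No Steiger filtering, radial MR, or model-selection frameworks; reverse
  causation is probed only by the role-swapped reverse run.
* Confounder screening is a user-supplied exclusion list; the package makes
  no external lookups.
* The group F statistic uses the standardized-trait variance-explained
  approximation; with unstandardized units it is only a relative guide.
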