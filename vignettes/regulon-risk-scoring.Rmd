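---
title: "Ranking transcription factors by the prognostic value of their lncRNA regulons"
author: "regulonSurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking transcription factors by the prognostic value of their lncRNA regulons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonSurv)
```

# The method

## Why score a TF through its targets

A transcription factor's own expression is often only weakly informative
about outcome, because its effect is mediated by the programme it drives.
`regulonSurv` therefore evaluates each TF through its *regulon*: the set
of lncRNAs it plausibly binds (a candidate resource, supplied as GMT)
*and* with which it is positively co-expressed in the cohort at hand.
The co-expression filter keeps a candidate pair when Pearson's r > 0 and
the Benjamini–Hochberg FDR < 0.05, with the FDR family taken over **all**
tested candidate pairs jointly. A per-TF family is available
(`family = "per_tf"` in `buildNetwork()`) because the choice of family is
a genuine modelling decision: the global family treats the resource as
one hypothesis set and is the default; the per-TF family conditions on
the TF and is slightly more permissive for small regulons. Both use
strict inequalities, so a pair sitting exactly at FDR = 0.05 is excluded.

## The risk score

For a TF with usable regulon members $lnc_1,\dots,lnc_n$ the per-patient
score is the linear predictor

$$\mathrm{RiskScore}(s) = \sum_{i=1}^{n} \beta_i\,\mathrm{Exp}(lnc_i, s),$$

where each $\beta_i$ is the coefficient of a **univariate** Cox
proportional-hazards fit of survival on that lncRNA alone. Univariate
weights (rather than a joint multivariate fit) keep the score defined for
regulons larger than the event count, make the weights comparable across
cohorts of different size, and make each weight interpretable as that
lncRNA's marginal risk direction. The cost is that correlated regulon
members are double-counted; we accept this deliberately, since the score
is used for ranking and splitting rather than for effect estimation.

Patients are dichotomized at the **median** score of the cohort being
evaluated; scores exactly at the median go to the low-risk group, so an
odd cohort splits n = 2k+1 into k+1 low / k high (399 → 200/199). The
split is compared by the log-rank test, and a Cox fit on the standardized
continuous score reports a hazard ratio **per SD of score** — the
headline effect size, chosen because the raw score scale depends on the
expression units and on $n$, so a per-unit HR would not be comparable
across cohorts. Both the group-based log-rank p and the continuous-score
Wald p are reported; ranking uses the log-rank p (ties broken by |log HR|
then TF id) because the median-split Kaplan–Meier comparison is the
primary read-out of the workflow.

## Evaluation modes and what they mean

`screenTFs()` evaluates in-sample by default: weights, cut-point and test
all come from the same cohort. This mirrors the discovery workflow but is
**anti-conservative** — the same events that set the weights are tested
with them. The held-out mode (`evalBundle =`) trains on one cohort and
evaluates on another via `validateTransfer()`; its p-values are
calibrated (the test suite checks a ~5% null rejection rate at
$\alpha = 0.05$, and that the in-sample rate exceeds it). Conclusions
about *significance* should come from held-out evaluation or from
independent-cohort validation; the in-sample screen is a ranking device.

Independent validation comes in two first-class flavours, because both
are natural readings of "apply the model to another cohort":

* `validateRefit()` repeats the whole construction inside the validation
  cohort (weights and median cut-point re-estimated there) — the primary
  validation, testing whether the *regulon* carries signal;
* `validateTransfer()` keeps the training weights, z-score-normalizes
  the validation scores within the cohort (sample sd, n−1) and applies
  the z-transformed training median as cut-point — testing whether the
  *fitted model* transfers. The z step absorbs cohort-specific location
  and scale of the score, so any uniform affine change of the validation
  expression leaves the groups unchanged (this is tested exactly), and
  applying the transfer to the training cohort itself reproduces the
  training split as a fixed point.

## Clinical stratification and adjustment

`stratifyCohort()` partitions on one variable at a time: age at the
cohort median (younger = at or below); grade G1/G2 vs G3/G4; stage I/II
vs III/IV; residual tumour diameter ≤ 10 mm vs > 10 mm. Samples missing
the variable are excluded (with a logged count) — no imputation.
`multivariateAdjust()` fits the score jointly with the clinical
covariates; ordinal variables enter as integer scores, one hazard ratio
per variable, which keeps one row per variable in the output at the cost
of assuming linearity across levels. Perfect collinearity is an error
naming the offending pair rather than a silent drop.

## Time-dependent ROC

`tdROC()` uses the cumulative/dynamic definition at horizon $t$ (default:
the cohort's Kaplan–Meier median survival time): cases experienced the
event by $t$, controls are still under observation after $t$. Two
estimators are provided. `exclude_censored` simply drops samples censored
before $t$; it is the default because it is the transparent, assumption-
light reading of the definition, but it is biased when early censoring is
informative about the marker. `ipcw` keeps all classifiable samples and
weights them by inverse Kaplan–Meier censoring survival
($1/\hat G(T_i^-)$ for cases, $1/\hat G(t)$ for controls), which is
consistent under independent censoring; the acceptance checks use it.
The two coincide exactly when no censoring occurs before $t$. AUC is the
trapezoidal area with tied scores contributing 1/2, so constant scores
give exactly 0.5 and an error-free ranking gives exactly 1.

## Risk-direction consistency

`riskDirectionConsistency()` compares the sign of each lncRNA's
univariate Cox coefficient across per-cohort models and retains a lncRNA
only when it was fitted in **every** cohort and all signs agree (and are
nonzero). The filter is monotone: adding a cohort can only shrink the
retained set. Under the null a lncRNA passes a 4-cohort filter with
probability $2 \cdot (1/2)^4 = 1/8$, so the retained set should always be
interpreted against that baseline, not as an error-controlled discovery
set.

# The simulator

`simulateStudy()` generates what the analysis assumes and nothing more:
per cohort, each TF has a latent standard-normal activity per sample; the
TF's measured expression is activity plus Gaussian noise (sd 0.5); each
target lncRNA is $w \cdot a + \sqrt{1-w^2}\,\varepsilon$ so that
TF–target correlation is $\approx w$ and two co-targets correlate at
$\approx w^2$; non-targets are independent noise. Survival is exponential
(Weibull behind a switch) with hazard
$h_0 \exp(\sum_j \gamma_j x_j)$ on the **standardized** expression of the
planted TF's targets — defining $\gamma$ per SD keeps the planted truth
invariant to the cohort-level affine shift/scale applied afterwards.
Censoring is independent exponential with rate calibrated by the closed
form $c/(h_0+c)$ to the target fraction.

Default parameters are the study design the pipeline targets: four
cohorts of 399/107/278/75 samples, 1234 lncRNAs, 145 TFs with ~30
candidate targets each, $w = 0.6$, one planted TF with $\gamma = 0.3$ per
target and SD, $h_0 = 0.015$ per month (null event-time median ≈ 46
months), censoring target 0.5 (mid-range of the 40–70% typical of ovarian
cancer follow-up). The planted effect is deliberately strong — with ~30
correlated targets the aggregate signature signal is far larger than a
real single-TF signature would carry — because its role is to provide an
unambiguous ground truth for recovery, ranking and sign tests, not to
mimic published effect magnitudes.

What the simulator does **not** emulate: count-level RNA-seq noise
(expression is Gaussian), batch structure beyond one affine map per
cohort, informative censoring, correlated clinical covariates (age,
stage, grade, residual and nodal status are independent of expression and
of survival), or missing clinical fields. Passing tests therefore show
that the machinery is correct under the proportional-hazards data model,
not that the pipeline is robust to the messiness of real cohorts.

A master seed drives a hierarchical seed tree (one derived seed per
cohort), so a study is bit-reproducible and each cohort individually so.

# Numerical choices

* Cox fits use Newton iterations with Efron tie handling (the common
  software default; Breslow available for cross-checks), convergence at
  eps 1e-9 within 50 iterations. Monotone likelihood is flagged when
  |β̂| > 15; degenerate (constant) covariates yield an NA coefficient
  flagged per row rather than an error, except in single-covariate fits
  inside `fitRiskModel()`, where the member is dropped with a log.
* Confidence intervals are 95% Wald on the log-HR scale.
* Kaplan–Meier medians are the first time the curve reaches 0.5 or
  below, NA (undefined) if never reached.
* The expression matrix is used as provided; `log2p1 = TRUE` on
  `CohortBundle()` applies log2(x+1) for raw RNA-seq quantifications.
  No transform is imposed by default because the scoring and splitting
  machinery is rank-stable under monotone maps at the evaluation stage,
  while the Cox weights legitimately depend on the analyst's chosen
  scale.
* Probe-level microarray matrices collapse to gene level by the
  arithmetic mean over uniquely mapped probes; a probe mapping to two
  genes is an error, not a silent drop, because it violates the unique-
  mapping contract of the upstream re-annotation.
* Constant expression rows are excluded from correlation testing and
  from regulons (correlation and a Cox weight are undefined for them),
  always with a logged count.

# Problem sizes used by the test suite

The statistical tests run at deliberately modest sizes chosen to keep the
whole suite in the minutes range while leaving comfortable margins on
every band checked: null calibration uses 20 simulated two-cohort studies
of 50 TFs each (1000 held-out TF-tests, n = 300); planted-signal recovery
uses 20 studies of 50 TFs at n = 400; the null time-dependent AUC
averages 50 cohorts of n = 500; the direction-consistency check uses 20
four-cohort studies with 6 planted among 40 null lncRNAs. The
`scripts/acceptance.R` run uses the simulator's full default study
(399/107/278/75 samples, 145 TFs).

# Known limitations

* In-sample screening p-values are optimistic by construction; the
  package surfaces but does not correct this (BH q-values across the TF
  family are reported alongside).
* Dropping model members absent from a validation matrix without
  re-normalizing the remaining weights means transferred scores on
  partially overlapping platforms measure a truncated signature; the
  dropped members are logged and recorded.
* The per-SD hazard ratio convention makes effects comparable across
  cohorts but is not the only convention in the literature; group-vs-
  group and raw-scale effects can be derived from the returned objects.
* No penalized estimation: very large regulons with few events rely on
  the univariate weighting for stability, not on shrinkage.
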