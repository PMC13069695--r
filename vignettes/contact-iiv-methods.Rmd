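---
title: "Quantifying intra-individual variability in contact counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-individual variability in contact counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal contact surveys are usually summarised by mean contact
rates: how many people someone meets on an average day, by age,
occupation, or pandemic phase. But two people with the same mean can
behave very differently — one meets four others every day, the other
alternates between none and a dozen. For airborne transmission that
difference matters: temporally clustered contacts change outbreak
dynamics even at a fixed mean. `contactiiv` implements a two-step
residual method for quantifying this *intra-individual variability*
(IIV) in non-household contact counts from panel surveys, together
with a synthetic data generator that makes the whole pipeline testable
without access to restricted survey microdata.

## The two-step method

**Step 1 — expected contact level.** Daily non-household contact
counts $y_{it}$ (participant $i$, observation $t$) are zero-heavy,
right-skewed and capped at 100. They are modelled as NB2:

$$y_{it} \sim \mathrm{NegBin}_2(\mu_{it}, \theta), \qquad
\operatorname{Var}(y_{it} \mid \mu_{it}) = \mu_{it} + \mu_{it}^2/\theta,$$

with a log-linear predictor containing sociodemographic covariates
(age group, sex, household size, occupation), pandemic covariates
(vaccination status, pre-existing health risk, quarantine, risk
perception, recent test result, waves joined), weekday, natural cubic
splines for day of year, district stringency index (SI), incidence
trend and mortality, and random intercepts for participant, reporting
date, reporting week and district. Complete cases only; missing
infection status in early waves is first recoded as "not tested",
reflecting limited test access early in the pandemic.

**Step 2 — residual dispersion.** Pearson residuals
$r_{it} = (y_{it} - \hat\mu_{it}) / \sqrt{\hat\mu_{it} +
\hat\mu_{it}^2/\hat\theta}$ are taken against the *conditional* mean,
i.e. including the empirical-Bayes modes of the random intercepts, so
that a person's own typical level is part of the expectation. For each
participant with at least two observations,

$$\mathrm{riSD}_i = \sqrt{\tfrac{1}{n_i - 1}
\sum_t (r_{it} - \bar r_i)^2},$$

the within-person standard deviation of the residuals. Subtracting
$\bar r_i$ makes riSD invariant to person-level mean shifts — in
particular to random-intercept shrinkage — so riSD isolates
wave-to-wave instability, not level.

**Step 3 — mean-ratio regressions.** riSD is positive and
right-skewed, so it is modelled as Gamma with a log link, each unit
weighted by $n_i$ (riSD from more waves is more precise).
Exponentiated coefficients are mean ratios (MR). Three designs are
built in: sociodemographic main effects; a paired pre/post
first-vaccination window contrast (day offsets $-100..0$ vs $1..100$,
at least two observations on each side); and a paired strong/weak
stringency contrast (SI $\ge 50$ vs $< 50$). Person-window rows enter
as independent units, exactly as the regression equations specify —
a documented simplification, since a person's two riSD values share
that person's behavioural traits.

An adjusted intraclass correlation summarises step 1:
$\mathrm{ICC} = \hat\sigma^2_{\mathrm{participant}} / (\sum_f
\hat\sigma^2_f + \sigma^2_{\mathrm{resid}})$ with the latent-scale
NB2 residual variance under the lognormal approximation
$\sigma^2_{\mathrm{resid}} = \log(1 + 1/\bar\mu + 1/\hat\theta)$
(a trigamma variant is available).

## Estimation

The NB2 mixed model is fitted by maximum marginal likelihood. The
default backend is glmmTMB (Laplace approximation; supports the full
crossed random-intercept structure). A second backend, `"agq"`, is the
package's own adaptive Gauss–Hermite fit for designs with exactly one
random-effect factor: each participant's likelihood integral is
centred at its posterior mode (damped Newton) and scaled by the local
curvature before quadrature. Its purpose is verifiability — at 25
nodes the marginal log-likelihood can be checked against dense
numerical integration to $10^{-4}$, which the test suite does — and it
provides an independent route for cross-checking the Laplace fit on
small designs.

Gamma regression coefficients come from the weighted score equations
(IRLS via `stats::glm`). The shape $\kappa$ is estimated by the
weighted Pearson moment estimator by default, with Wald intervals from
$\operatorname{cov}(\hat\beta) = (X^\top W X)^{-1}/\hat\kappa$. A
maximum-likelihood $\kappa$ is available, but it is *not* the default
for a concrete reason: riSD values are sample SDs of heavy-tailed NB
residuals and are more dispersed than a Gamma variable with the same
mean structure. The ML shape understates that dispersion and yields
clearly anti-conservative intervals at a few hundred participants,
while the Pearson estimator targets the realised coefficient of
variation and keeps null-calibration coverage near nominal (the
calibration test in the suite measures this directly). A side effect worth knowing: with the Pearson
shape, the overall scale of the weights cancels (only weight ratios
matter); with the ML shape, weights act as absolute replication counts
and doubling them shrinks standard errors by $\sqrt 2$.

Zero riSD values (constant residuals) have no Gamma likelihood. The
default policy excludes them with a recorded count; an alternative
shifts them to half the smallest positive riSD. Both are provided
because published descriptives show zero riSD values can occur while
the regression equations presume positivity.

## The synthetic generator

`simulate_population()` draws panels with the structure the analysis
assumes: waves of 8 days separated by 11-day gaps from 1 April 2020;
staggered recruitment (70% at wave 1, the rest later — keeping wave
sizes roughly stable, as panel replenishment does) with per-wave
dropout (0.12) and re-entry (0.45), giving a mean of about 9
observations per member at the 12-wave default; NB2 counts capped at
100 with mean near 2 and $\theta = 1.5$; participant (SD 0.8) and
district (SD 0.15) intercepts; weekday, seasonal and stringency
effects; a vaccination rollout from 26 December 2020; and a
district-level stringency trajectory
$50 + 14\cos(2\pi(t - \mathrm{phase}_d)/180) + \delta_d$ that
alternates lockdown-grade and relaxed phases on a half-year rhythm.
The district-specific phase is deliberate: with a single national
cycle, truncating the panel at the study end systematically
over-samples one regime, and the small-sample downward bias of the
sample SD (noticeable at 4–6 observations per window side) then
masquerades as a window effect. District-varying timing balances the
two sides in expectation while keeping the within-district temporal
coherence the paired design relies on.

The IIV signal is injectable: `iiv_signal = c(weak_SI = 0.6,
strong_SI = 0)` multiplies the conditional mean by a lognormal factor
$u$ with the stated log-SD and $E[u] = 1$ in the labelled window,
raising within-person dispersion without moving the mean.
`oracle_risd_ratio()` computes the implied between-window riSD ratio
by brute force — simulating from the generator and forming residuals
from the *true* mean and dispersion, with no model fitting — so
end-to-end signal recovery can be judged against a ground truth. Mean
inflation (not $\theta$ modulation) was chosen as the signal mechanism
precisely because this oracle can evaluate it without any estimation
step.

What the generator does **not** emulate: quota sampling and
population weighting, real German district geography and indicator
series (stringency, incidence trend and mortality are synthetic
stand-ins), household linkage for child proxy reporting, partner
turnover or contact duration, and second/third-dose effects beyond
dose-count bookkeeping. Passing tests therefore demonstrate that the
*method* behaves as claimed under a faithful generative structure, not
that any particular published estimate from restricted data is
reproduced.

## Numerical and design choices

- **Boundary conventions.** Day offset 0 (the dose date) belongs to
  the pre-vaccination window; SI exactly at the threshold counts as
  strong stringency. Both follow the printed interval definitions of
  the designs.
- **Eligibility.** Paired designs require at least two observations
  per side — forced by riSD needing an SD on each side, and applied to
  the stringency design as well, where published wording only says
  participants "contributed data in both periods".
- **Reporting-interval caps** (sensitivity analyses) drop a
  participant if *any* consecutive gap between their report dates
  exceeds the cap; a median-gap rule is switchable. The filter is
  applied to the observations entering riSD, keeping the two-step
  structure (no baseline refit).
- **Windows never refit.** Residuals come from one baseline fit on all
  data and are partitioned afterwards; only the infection-status
  recode variant refits, because it changes the complete-case set.
- **Splines** are natural cubic, unpenalised, knots at quantiles of
  retained data, df 5 by default (df 3 in the scaled test
  configurations); no basis or penalisation is prescribed by the
  design, so the simplest standard choice is used.
- **Convergence.** glmmTMB's defaults (gradient tolerance ~1e-6);
  the AGQ backend uses BFGS with inner Newton mode-finding to 1e-10.
  Non-convergence is flagged on the result, not raised. A diverging
  dispersion estimate (effectively Poisson counts) is capped at 1e6
  with a warning.
- **Default panel scales.** The generator default is 300 participants
  and 12 waves — large enough for stable fits at interactive speed.
  The 12-wave window ends before the (calendar-faithful) rollout day,
  so pipeline configurations default to 24 waves, which span the
  rollout and several stringency phases; the acceptance script and
  the end-to-end analyses use that scale. Calibration and recovery
  tests use 150–500 participants and 20–200 replicates.
- **Determinism.** Every stochastic step is seeded; `withr::with_seed`
  keeps the caller's RNG state untouched, and a rerun with the same
  configuration writes byte-identical numeric tables. The run manifest
  records a hash of the configuration.

## Known limitations

riSD inherits the small-sample bias of the sample SD: with few
observations its expectation sits noticeably below the residuals'
true scale, so mean riSD stays under 1 even for a perfectly specified
model — the package's calibration checks accept a band below 1
rather than 1 exactly — and window contrasts are only unbiased when
both sides have comparable observation counts. Precision weighting mitigates but does
not remove this. The independent-unit Gamma regression ignores shared
estimation noise in the residuals; its effect shrinks with panel size
but is visible at a few hundred participants. The vaccination design
measures behaviour around the *first* dose only, and the generator's
dose-date distribution concentrates doses late in the panel, so
narrow windows can have few eligible participants — the sensitivity
grid reports such cells as infeasible rather than estimating from
too-thin data.
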