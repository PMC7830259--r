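---
title: "Modelling colistimethate acidic hydrolysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colistimethate acidic hydrolysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmskinetics)
```

## The model

Colistimethate (CMS) hydrolyses under sulfuric acid to colistin (CS).
`cmskinetics` treats the reaction as reversible first-order in a closed
two-species system:

$$\frac{dA}{dt} = -k_f A + k_r (c_0 - A), \qquad A(0) = c_0,$$

where $A$ is percent CMS remaining, $c_0 = 100$, $k_f$ is the forward
hydrolysis constant and $k_r$ the reverse constant, both in
min$^{-1}$. CS formed is tracked implicitly as $c_0 - A$, because the
assay normalises everything to percent remaining CMS; mass is conserved
by construction. The analytic solution

$$A(t) = A_{eq} + (c_0 - A_{eq})\,e^{-(k_f+k_r)t}, \qquad
  A_{eq} = c_0\frac{k_r}{k_f+k_r},$$

is the reference implementation (`remaining_pct()`); a stiff-capable
numerical integrator (`integrate_scheme()`, via `deSolve::lsoda` at
`rtol = atol = 1e-12`) produces the same trajectory to better than
$10^{-8}$ relative and exists so the architecture generalises to
multi-step schemes later.

Assumptions inherited from the assay context: CS itself is not degraded
by the acid; all CMS congeners are pooled into a single species; only
one acid concentration (0.5 M H$_2$SO$_4$) is modelled, so rates carry
no acid-dependence.

Temperature dependence follows the Arrhenius law
$\ln k = \ln A - E_a/(RT)$ with $R = 8.314$ J mol$^{-1}$K$^{-1}$ fixed
and $T$ in kelvin ($T_K = T_C + 273.15$; the $.15$ is standard practice
and immaterial at the precision involved). `fit_arrhenius()` is
unweighted OLS of $\ln k$ on $1/T$ — with three temperatures any
weighting scheme is indistinguishable. Extrapolation outside the fitted
range is permitted (the study design itself extrapolates 40–60 °C down
to 20 °C) but flagged in `predict()` output and in `rate_table()`.

## Estimating the rate constants

Two estimators are provided, mirroring the two-stage analysis of an
accelerated-stability run:

**Early-window log-linear fit** (`fit_first_order()`): OLS of
$\ln A$ on $t$ over the first 10 min (configurable), giving
$k = -\text{slope}$ and intercept $\ln c_0 = \ln 100 = 4.605$. A
mathematical point worth stating: as the window shrinks to zero this
slope converges to $k_f$ alone, *not* $k_f + k_r$ — at $t = 0$ no CS
exists, so the reverse flux vanishes and
$\mathrm{d}\ln A/\mathrm{d}t|_0 = -k_f$. The property tests assert this
limit (1 % tolerance at a 2-min window).

**Full-course reversible fit** (`fit_reversible()`): nonlinear least
squares of the closed-form trajectory against all observations,
minimising $\sum_i (y_i - A(t_i))^2$ on the *percent* scale. The percent
scale (not log) was chosen because the estimator emulates
trajectory-matching kinetic simulation, which compares concentrations
directly; log-scale fitting is what the early-window method is for.
Implementation details:

* Bounds $k_f > 0$, $k_r \ge 0$ (L-BFGS-B). A negative reverse rate is
  unphysical; when the optimum sits at the $k_r = 0$ bound the
  covariance for $k_r$ is reported as `NA`, not a spurious number. This
  matters for runs truncated early (stopped near 50 % remaining), where
  $k_r$ is weakly identified.
* Initialisation (when `init = NULL`): $k_f + k_r$ from the
  early-window fit, the split between them from the last observed value
  read as the plateau ($k_r = k_{sum} A_{eq}/c_0$). The optimum is
  independent of initialisation to below $10^{-6}$ relative across an
  init grid; a tight polish pass after the main optimisation enforces
  this.
* Convergence: relative SSE change below `epsilon = 1e-8` (the accuracy
  setting of the kinetics-simulator workflow this re-implements).
  L-BFGS-B occasionally reports a line-search failure exactly at the
  $k_r = 0$ bound even when the optimum is reached, so convergence is
  judged by the SSE criterion, not the optimiser's return code alone.
* Unweighted residuals: no weighting scheme is defensible for
  percent-remaining data with roughly constant CV over most of the
  range, and none was used in the source analysis.
* Parameter covariance from the SSE Hessian,
  $\widehat{\mathrm{cov}} = 2\hat\sigma^2 H^{-1}$ with
  $\hat\sigma^2 = SSE/(n-2)$.

## Half-lives, completeness, verification

`half_life()` uses $t_{1/2} = 0.693/k$ with the *rounded* constant
0.693 by default, because that is the convention of the rate tables the
package reproduces; `use_ln2 = TRUE` switches to $\ln 2$. The two
conventions differ in the third decimal: e.g. $0.693/0.0709 = 9.774$
while $\ln 2/0.0709 = 9.776$, which round to 9.77 and 9.78 min
respectively — reported half-life tables can mix the two, and the
acceptance tests document exactly this.

`time_to_remaining()` inverts the trajectory,
$t = \ln\frac{c_0 - A_{eq}}{\text{target} - A_{eq}} / (k_f + k_r)$,
and raises an error for targets at or below the equilibrium floor
(unreachable). At the 60 °C constants ($k_f = 0.4485$,
$k_r = 2.11\times 10^{-3}$) the 10 % mark is passed at ≈ 5.2 min, which
is why a 10-min/60 °C protocol achieves effectively complete
hydrolysis, while the extrapolated 20 °C half-life of ≈ 38.5 h shows
room-temperature protocols cannot.

The verification error convention is
`percent_error(k_obs, k_pred)` $= (k_{obs}-k_{pred})/k_{pred}$,
reported as a fraction. This definition was adopted (over alternatives
such as symmetric or absolute error) because it is the one consistent
with the published 20 °C verification figure of 0.33 computed from the
rounded pair (0.0004, 0.0003).

A note on internal consistency of the source figures: the narrative
plateau values sometimes quoted for such runs (≈ 50 % remaining at
40 °C, 30 % at 50 °C) are inconsistent with the equilibrium fraction
implied by the fitted constants themselves
($100 k_r/(k_f+k_r) \approx 13\%$ at 40 °C). The package reproduces the
*model*; the only narrative bound it asserts is the one the model
satisfies (< 10 % at 60 °C by 130 min). Likewise two slightly different
activation energies circulate depending on whether first-order slopes
or full-course constants are regressed (≈ 148.7 vs ≈ 148.2 kJ/mol);
regression on the tabulated full-course constants gives
$E_a = 148.4$ kJ/mol and that is the path implemented and tested, with
the first-order figure documented rather than targeted.

## Quantitation statistics

* `fit_calibration()` fits order-1 (CSA, CSB) or order-2 (CMS)
  polynomials by least squares, with coefficient standard errors from
  the regression covariance. Simulation tests confirm the reported SEs
  track the Monte-Carlo spread within 20 %.
* `pool_curves_f_test()` implements the extra sum-of-squares F test
  comparing independent per-run fits against one global fit:
  $F = \frac{(SS_{pool}-SS_{sep})/(df_{pool}-df_{sep})}{SS_{sep}/df_{sep}}$.
  Nesting guarantees $SS_{pool}\ge SS_{sep}$; tiny negative round-off is
  clipped so identical replicate sets give exactly $F = 0$, $p = 1$
  without dividing by zero. $p > 0.05$ supports one shared curve.
* `lod_loq()` is the ICH-style $3.3\sigma/S$ and $10\sigma/S$ pair, so
  LOQ/LOD is always $10/3.3$. Two conventions for $\sigma$ are offered
  (`calibration_sigma()`): the SD of replicate responses at the lowest
  level (default) or the curve's residual SD. For the quadratic CMS
  curve the slope $S$ comes from an OLS line over the lowest three
  levels (`linear_range_slope()`), where the response is effectively
  linear; the level count is configurable.
* `partition_cs()` splits total colistin by the fixed reference-standard
  mass fractions (default CSA 0.301), conserving mass exactly;
  `indirect_cms()` is the assay difference with a negative-result guard
  and an optional completeness check that evaluates the kinetic model at
  the protocol's temperature and duration and warns when more than 10 %
  CMS would survive.
* `accuracy_precision()` reads a level-by-run replicate table;
  accuracy is $100|\bar y - \text{nominal}|/\text{nominal}$ per
  level-run (absolute value, since validation tables report bounds),
  repeatability is the within-run %RSD, intermediate precision the %RSD
  of run means. Single-replicate cells report precision as missing —
  never as zero.
* `invert_calibration()` solves the quadratic analytically and accepts
  the unique root inside the calibration range; zero or two in-range
  roots raise an ambiguity error (impossible for curves monotone on the
  fitted range, the normal case).

## The synthetic-data generator

`study_design()` fixes the study conditions: accelerated runs at 40, 50
and 60 °C sampled every 2 min to 10 min then every 10 min to 130 min
(18 points), plus a 20 °C verification run; multiplicative Gaussian
noise with CV 0.02 (LC-MS peak-area noise scales with signal, and 2 %
matches the repeatability magnitudes of a validated assay); the $t = 0$
point pinned at exactly 100 % because the data are normalised to
percent remaining.

Generating parameters: forward rates follow an Arrhenius truth — by
default the regression through the three tabulated accelerated
constants ($E_a = 148{,}366$ J/mol, $\ln A = 52.70$) — so generated
forward rates are Arrhenius-smooth and differ from the three printed
constants by the regression scatter (up to ≈ 15 % at 50 °C, where the
printed value sits below the line). Reverse rates are the tabulated
per-temperature constants ($2.2$, $3.54$, $2.11 \times 10^{-3}$
min$^{-1}$), which show no temperature trend and are therefore kept as
constants rather than given their own Arrhenius law.

The verification run needs two of its own choices. First, its schedule:
at 20 °C the half-life is ≈ 38.5 h, so a 130-min window would observe
only ~4 % decay and leave the rate constant unidentifiable at 2 % noise.
The design therefore samples it at 10-min intervals out to 2400 min,
spanning one half-life — matching how such a verification run is
actually conducted. Second, its reverse rate: none was ever fitted at
20 °C, and carrying over the accelerated-run values would be physically
wrong (with $k_r \approx 2.6\times10^{-3} \gg k_f \approx
2.8\times10^{-4}$ the plateau would sit at ~90 % remaining, flatly
contradicting the observed 50 % crossing). The verification run is
generated as pure first-order decay ($k_r = 0$), consistent with how it
is analysed.

Calibration sets use the published global curve coefficients as truth
(CSA $y = 130.1x - 195.3$; CSB $y = 125.2x - 372.8$; CMS
$y = 1.425x^2 + 20.97x + 131.6$), the printed level designs (CMS totals
2–22 µg/mL, seven levels; CS levels derived from the six totals
6–22 µg/mL through the 30.1 % split, giving CSA 1.806–6.622 µg/mL), three
runs, and additive response noise (SD 20 by default, comparable to the
published intercept uncertainties). Every generator call derives a
sub-seed deterministically from the design seed and the temperature (or
analyte), so series are reproducible and independent across conditions.

What the generator does *not* emulate: chromatographic peak shapes,
matrix effects, heteroscedastic response at the extremes, drift between
runs, or CMS congener heterogeneity. Passing the recovery tests
therefore demonstrates the estimators are correct and well-calibrated
under the stated noise model — not that the assay itself is valid on
real plasma, which is an experimental question.

## Problem sizes and numerical tolerances in the test-suite

The suite runs entirely on generated data: 18-point series for the
accelerated runs, 241 points for the verification run, 200-seed
Monte-Carlo batteries for the noisy-recovery and F-test calibration
bounds, 500 seeds for the coefficient-SE check, and 100 random parameter
draws for integrator-versus-closed-form agreement ($\le 10^{-6}$
relative). These sizes keep the whole suite under ~10 s while leaving
the Monte-Carlo bounds (95 % recovery rate, 90 % type-I behaviour) with
comfortable margin. Noiseless round-trips are asserted at $10^{-4}$
relative for rate parameters (optimiser-limited) and $10^{-9}$ for the
linear-algebra paths (exact in theory).

## Known limitations

* Single-species CMS: congeners with different sulfomethylation degrees
  hydrolyse at different rates in reality; the pooled model absorbs this
  into effective constants.
* $k_r$ is only weakly identified when a run is stopped before its
  plateau; the fit then reports it at or near the bound with undefined
  uncertainty, which downstream consumers must respect.
* No global multi-temperature fit with shared $E_a$; each temperature is
  fitted independently and the Arrhenius regression is a second stage.
* Acid concentration, ionic strength and matrix effects are outside the
  model.
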