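---
title: "Projecting chronic-disorder prevalence with an illness-death model under epidemic incidence shocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting chronic-disorder prevalence with an illness-death model under epidemic incidence shocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmproj)
library(dplyr)
```

## The model

`idmproj` projects the prevalence of a chronic but remitting disorder —
the motivating application is anxiety disorders — with a three-state
illness-death model in discrete time.  A population of single-year age
cohorts is split into susceptible ($S$) and diseased ($C$) compartments;
the dead are absorbing.  Four transitions connect the states: the
incidence rate $i$ (per person-year), the mortality rates among the
susceptible $m_0$ and the diseased $m_1$, and the per-step remission
probability $r$ by which diseased individuals return to the susceptible
state.  Over a step of length $\tau$ years the adopted first-order scheme
is

$$S_{k+1} = S_k\,(1 - (i_k + m_{0,k})\tau) + r_k C_k, \qquad
  C_{k+1} = C_k\,(1 - m_{1,k}\tau - r_k) + i_k \tau S_k .$$

Dividing the two updates gives a recursion for the prevalence odds
$\pi = p/(1-p) = C/S$ that is independent of population size:

$$\pi_{k+1} = \frac{\pi_k (1 - m_{1,k}\tau - r_k) + i_k\tau}
                   {1 - (i_k + m_{0,k})\tau + r_k \pi_k}.$$

Repeated application projects the prevalence forward; solved for $r_k$ it
turns observed prevalence series plus incidence and mortality into an
estimate of remission — the one transition for which no direct
population-level data exist:

$$r_k = \frac{\pi_k(1 - m_{1,k}\tau) + i_k\tau - \pi_{k+1}(1 - (i_k + m_{0,k})\tau)}
             {\pi_k\,(\pi_{k+1} + 1)}.$$

All flows in a step are computed from start-of-step stocks (no
within-step ordering of remission against same-step incident cases); the
equivalence of the compartment and odds forms, and the stability of the
discretisation under step halving, are enforced by property tests rather
than assumed.

### Stability and mass accounting

Per-step probabilities $i\tau$, $m_0\tau$, $m_1\tau$ must each stay below
0.5 (an explicit guard; violating it is an error instructing a smaller
$\tau$).  Extreme shocks at a coarse step can still drive a compartment
slightly negative; such values are clamped at zero and the clamped mass
accumulated, and a projection aborts if more than 0.01% of the starting
population mass is ever clamped — silent creation or destruction of mass
is never tolerated.

## Trend surfaces and the two-group mortality model

Historical incidence and prevalence by single year of age and calendar
year (one surface per sex) are smoothed with additive natural-cubic-spline
models on the log scale: `log val ~ ns(age) + ns(year)`.  Additivity is
deliberate — it is the most parsimonious smooth reading of "a function of
age and time", it keeps the calendar extrapolation stable, and a
tensor-product interaction remains available behind the `interaction`
switch of `fit_rate_surface()` for surfaces whose age profile genuinely
changes shape.  Default knots sit every 10 years of age and every 5
calendar years, matching the reporting resolution of burden-of-disease
extracts; both are overridable.  The natural-spline boundary property
makes the log-scale fit continue *linearly* beyond the last calendar
knot, which is exactly how projection years are extrapolated.  Age is
never extrapolated.  Zeros are lifted to a floor of `1e-8` before the log
transform — far below any plausible rate resolution.

Disease-specific mortality is rarely observed.  The package instead takes
an overall mortality surface $m_{all}$ — either supplied, or derived from
cohort shrinkage of a no-migration population projection via
`mortality_from_pyramid()` — and splits it with a mortality-risk ratio:

$$m_{all} = p\,m_1 + (1-p)\,m_0, \qquad m_1 = RR(t)\,m_0,
  \qquad RR(t) = \max\!\big(1,\; rr_0 - d\,(t - t_{ref})\big).$$

The default calibration is $rr_0 = 1.4$ at $t_{ref} = 2019$, the excess
all-cause mortality risk meta-analytically estimated for anxiety
disorders.  The linear decline $d$ (default 0.01/yr, floored at $RR = 1$)
encodes the expectation that disease-group mortality improves faster than
background mortality as management improves; the magnitude is a
configuration default, not an empirical claim.  The mixture identity and
the ratio identity hold to $10^{-12}$ at every evaluation point by
construction and by test.

### Remission

Remission is carried internally as an annual rate $\rho$ with per-step
probability $r = \rho\tau$, so a schedule estimated on the annual history
grid transfers consistently to the weekly projection grid.  Following the
conservative choice of holding remission stable into the future,
`prepare_projection()` freezes the last estimated age profile of $\rho$
across all projection years.  Inverted estimates outside $[0,1]$ (possible
when the input series was not generated by the model) are clamped with a
reported count; cells with zero prevalence have no diseased mass to remit
and come back `NA`.

## Epidemic waves and the incidence shock

The weekly epidemic incidence series (2020–2022) is decomposed into $K$
Gaussian waves,
$\mathrm{rate}(t) \approx \sum_w A_w e^{-(t-\mu_w)^2/(2\sigma_w^2)}$, by
Levenberg–Marquardt least squares with positivity bounds
(`minpack.lm::nls.lm`).  Initial values come from the $K$ most prominent
local maxima (prominence = height above the higher flanking minimum),
with each $\sigma$ seeded from the peak's half-height span; too few
prominent maxima is an error suggesting a smaller $K$.  No baseline
offset is fitted by default — epidemic incidence decays to
approximately zero between waves — but a constant offset is available via
`baseline = TRUE`.  Each wave's duration is its full width at half
maximum, $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, and its interval is
$[\mu - \mathrm{FWHM}/2,\ \mu + \mathrm{FWHM}/2]$.

The disorder-incidence shock is a piecewise-linear envelope over those
intervals.  For wave $w$ with interval $[s_w, e_w]$ of duration $D_w$ the
relative increase rises linearly from 0 at $s_w$ to
$h_w = h_0 e^{-\lambda(w-1)}$ over the wash-in $W_{in} D_w$, holds at
$h_w$ through $e_w + \Delta D_w$ (the delay by which the mental-health
elevation outlasts the infection wave), and falls to 0 over the wash-out
$W_{out} D_w$.  Two open choices were resolved as follows and isolated
behind switches: (1) between wash-in and decline the shock *plateaus*
(`shape = "trapezoid"`, the simplest shape consistent with a linear rise,
a sustained elevation during the delay, and a wash-out decline; a
`"triangle"` variant starts the decline immediately); (2) the delay is a
*fraction of wave duration*, dimensionally consistent with $W_{in}$ and
$W_{out}$.  Overlapping wave contributions are summed, preserving
continuity and monotonicity.  The shock multiplies baseline incidence
uniformly over age and sex: $i_{eff} = i_{base}(1 + A(t))$, so
$h_0 = 1, 5, 10$ mean +100%, +500%, +1000% at the first wave's plateau.

The scenario grid couples $W_{in} = W_{out} \in \{0.1, 0.2, 0.3\}$,
$\Delta \in \{0, 0.25, 0.5\}$, $h_0 \in \{1, 5, 10\}$ and
$\lambda \in \{0.1, 0.2, 0.3\}$ into 81 factorial scenarios plus the
shock-free baseline (scenario 0), indexed
$\mathrm{id} = 27a + 9c + 3b + d + 1$ with $a, c, b, d$ the ascending
level indices of $h_0, \lambda, \Delta, W$:

```{r grid}
scenario_grid()
```

## The projection

`prepare_projection()` fits both sexes' surfaces, builds the mortality
model, estimates remission, initialises compartments from the population
pyramid at the start year ($C = pN$, $S = (1-p)N$) and precomputes every
rate on the weekly grid.  `run_projection()` then steps the model at
$\tau = 1/52$ — weekly, because the shock varies within a year and annual
steps would alias it; 52 equal steps also make calendar years exact — and
at every year boundary ages all cohorts by one year, retires the age-95
cohort from the analysis, and admits the year's births at age 0 as
susceptible.  Births come from the population-projection input; deaths
come from the model's $m_0$/$m_1$, so small discrepancies against the
official projection's deaths are accepted in exchange for internal
consistency of the illness-death accounting.  Migration is set to zero
throughout, on the usual argument that equal prevalence among migrants
and residents leaves prevalence dynamics unaffected.  Year-start
aggregates (cases, population, prevalence) are recorded per scenario and
sex over the default horizon 2019–2030.

## What the synthetic generator emulates

Every stage above is testable without downloads because
`synth_config()` fixes a complete ground truth:

* **History** (`gen_consistent_history()`): log-quadratic incidence in
  age peaking at 25 with a log-linear calendar decline (peak level
  0.009/yr women, 0.005/yr men — the disorder is roughly twice as common
  in women); Gompertz mortality with calendar decline;
  $RR(t) = \max(1, 1.4 - 0.01(t - 2019))$; constant remission rate
  0.05/yr.  The prevalence surface is *exactly* the forward simulation of
  the odds recursion from the no-differential-mortality equilibrium
  $p_0 = i/(i+\rho)$, so inverting it recovers the remission ground truth
  to machine precision — the round-trip that anchors the whole pipeline.
* **Population** (`gen_population()`): a base pyramid aged forward with
  the ground-truth mortality and no migration, plus lognormally
  fluctuating births (sd 2%), giving cohort-consistent counts by
  construction.
* **Weekly epidemic series** (`gen_covid_series()`): seven Gaussian waves
  spanning 2020.2–2022.9 — small early waves, dominant waves in winter
  2021/22, a final autumn-2022 wave — with centres separated by more than
  one FWHM so the mixture stays identifiable, under multiplicative
  lognormal noise (default sd 0.05, positive and heteroscedastic as
  incidence data are).

What the generator does **not** emulate: real demographic detail
(migration, war- or reunification-era cohort scars), uncertainty
intervals around the rate estimates, reporting artefacts in surveillance
series (holiday dips, testing-regime changes), or any age/sex structure
in the shock.  Passing tests therefore demonstrate the *mechanics* —
consistency, invertibility, monotonicity, recovery of known parameters —
not fidelity to German surveillance data; applying the pipeline to real
extracts is a separate, documented reproduction mode via the CSV readers.

## Numerical choices

* Optimizer: Levenberg–Marquardt, iteration budget 500, box constraints
  $A > 0$, $\sigma \in [10^{-4}, \mathrm{span}]$; non-convergence reports
  the best residual rather than returning silently.
* Odds steps fail loudly when the denominator vanishes (prevalence
  approaching 1), rather than returning unbounded odds.
* Remission inversion at $p_k = 0$ is reported `NA`, never clamped —
  absence of diseased mass is information, not noise.
* Tie-breaks in peak initialisation: equal prominences resolve by order
  of `sort()`'s stable ranking; seeded widths are floored at two weekly
  spacings.
* Problem sizes: the test suite and examples run the full design — 96
  ages × 624 weekly steps × 2 sexes × 82 scenarios — in well under a
  minute on a single core, because all rates are precomputed on the
  age-by-week grid and each scenario reuses them.

## A worked run

```{r run, fig.width = 7, fig.height = 4}
cfg <- synth_config(seed = 1)
rates <- bind_rows(gen_consistent_history(cfg, "female")$rates,
                   gen_consistent_history(cfg, "male")$rates)
pop <- gen_population(cfg)
covid <- gen_covid_series(cfg)

waves <- fit_waves(covid$series, k = 7)
glance(waves)
autoplot(waves)

prep <- prepare_projection(rates, pop)
sel <- scenario_grid() |> filter(scenario_id %in% c(0, 19, 61))
res <- run_scenario_grid(prep, waves, sel)
summarise_projection(res, years = c(2020, 2021, 2023, 2030))
autoplot(res)
```

## Known limitations

The shock is homogeneous over age and sex, although the mental-health
impact of an epidemic is not; remission is frozen at its last estimated
profile; the mortality-risk-ratio decline is an assumption with a
configurable slope, not an estimate; projections are deterministic point
trajectories with no uncertainty propagation; and the additive spline
surface cannot express cohort effects (an age-profile *shape* drifting
over time) unless the interaction switch is enabled.
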