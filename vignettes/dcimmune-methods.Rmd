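---
title: "Methods: the dcimmune tumor–immune delay model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dcimmune tumor–immune delay model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcimmune)
```

## The biological system and the model

B16/F10 melanoma is induced in mice with a 6×10⁴-cell inoculum; one week
later, antigen-loaded dendritic cells (DCs) are infused weekly to prime a
cytotoxic T lymphocyte (CTL) response. The model reduces this system to
four integrated populations — tumor cells $T$, activated CTLs $C_a$,
naive CTLs $C_i$, TGF-β concentration $F_\beta$ — plus a closed-form DC
forcing $D(t)$:

* **Tumor.** Gompertz growth $rT\ln(K/T)$ (rate $r$, carrying capacity
  $K$), minus a mass-action kill term $a_T C_a T$ modulated by a
  Michaelis–Menten suppression factor
  $s + e_s(1-s)/(e_s+F_\beta) \in [s, 1]$: TGF-β at concentration
  $e_s$ halves the suppressible part of CTL efficiency, and at
  saturation the efficiency floor is $s$.
* **Dendritic cells.** Each dose of $n_i$ cells at time $t_i$ decays at
  rate $\mu_D$; only a fraction $ef$ reaches the lymph nodes. Because
  every pulse decays independently and linearly,
  $D(t) = ef\sum_{t_i\le t} n_i e^{-\mu_D(t-t_i)}$ is exact, so $D$ is
  implemented as this closed form rather than integrated numerically:
  dose discontinuities are exact and the delayed lookups $D(t-\tau)$
  cost nothing.
* **CTLs.** Activation moves cells from the naive to the activated pool
  at rate $r_a$, driven by DC contact saturating with constant
  $\theta_D$; both contact and the subsequent expansion (rate $r_e$,
  saturation $\theta_a$) act with a delay $\tau$ and survival discounts
  $e^{-\mu_i\tau}$, $e^{-\mu_a\tau}$. No naive-cell source exists: the
  mouse mounts no response before therapy, so $C_i$ starts at a baseline
  pool and only decreases — a structural invariant the tests check.
* **TGF-β.** Produced proportionally to tumor burden ($p_\beta$ per cell
  per hour) and degraded at $\mu_\beta$.

Two symbols that share a name in parts of the literature are kept as
distinct parameters because they have different units and roles: the
suppression floor `supp_floor` (dimensionless) and the TGF-β production
rate `p_beta` (concentration per cell per hour).

Units are cells and hours throughout; TGF-β is in arbitrary
concentration units, consistent between `e_supp` and `p_beta`, since no
absolute cytokine calibration is available.

### Events and thresholds

* **Host death**: integration halts at the first grid point with
  $T \ge T_{death}$ (reference 1.6×10¹⁰ cells — a ≈ 4.4 cm tumor under
  the spherical conversion below). For efficacy metrics a dead host's
  burden is held at $T_{death}$, so a fixed 1000-h metric window stays
  well defined without modelling censoring.
* **Eradication**: once $T$ falls to the single-cell threshold
  $T_{erad}$ it is clamped to 0 and integration continues for the
  immune states. The Gompertz term $\ln(K/T)$ diverges as $T\to 0$, so
  the growth and kill terms are gated off at and below $T_{erad}$: a
  sub-single-cell tumor is biologically extinct, and the guard makes
  that explicit rather than relying on floating-point behaviour.

## Numerical scheme

The integrator is fixed-step classic RK4 with step `dt` (default 1 h)
and a dense stored history. Delayed states at stage times are linearly
interpolated between grid points; the pre-history for $t<0$ is constant
at the initial condition (no immune response exists before
inoculation). $\tau \ge dt$ is required so that every delayed lookup
falls in already-computed history; the delay-free system is served by a
dedicated ODE-limit path (`simulate_ode_limit()`) with identical
stepping, which the tests validate against an independent adaptive
solver.

Dose times must lie on the integration grid. Within one RK4 step the
forcing is evaluated with doses restricted to those given at or before
the step's left endpoint: a dose landing exactly at the step's right
endpoint does not contaminate the stages of the step that precedes it,
so each step integrates a smooth piece of the dynamics and the solver
retains clean fourth-order behaviour across infusions (verified by a
step-halving Richardson check in the tests). The exported
`dendritic_forcing()` keeps the right-continuous convention (a dose at
$t$ is visible at $t$), which is what the stored trajectory reports.

States are clamped at zero if a step drives them slightly negative; the
clamp count is reported on the trajectory, and a large count signals
that the step is too coarse for the parameter regime. At the default
1 h step and murine-scale rates ($r \sim 10^{-3}\,h^{-1}$), the
trajectory agrees with the Gompertz closed form to ~10⁻⁸ relative; the
RK4 truncation error grows like $r^5 dt^4$, so hypothetical tumors
growing an order of magnitude faster would need a finer step to hold
the 10⁻⁶ tolerance the tests use.

### Quantization of the delay

One numerical property deserves emphasis: with a fixed grid, the time at
which a dose's delayed effect begins ($t_i + \tau$) is effectively
quantized to the step size. An infinitesimal change of $\tau$ across a
grid boundary can therefore lag the effector response by one full step,
changing the final burden by order $a_T C_a\,dt$ (sub-1 % at the
illustrative parameters) even though the smooth $\tau$-dependence is far
weaker — analytically, the activation flux
$r_a e^{-\mu_i\tau} C_i(t-\tau)$ is nearly $\tau$-invariant when $C_i$
decays exponentially, because the survival discount and the older,
larger $C_i$ cancel. Local sensitivity results for $\tau$ at very small
perturbations are thus bounded by this quantization amplitude rather
than shrinking to zero, and the sensitivity tests treat $\tau$
accordingly. At the ±1 % perturbations actually used for sensitivity
analysis the effect is dominated by genuine dynamics for delays of a
few days.

## Protocol experiments

Efficacy is the mean, over the study's measurement times, of the
percent reduction in tumor burden relative to an untreated control
started from the same initial state. The measurement grid is the animal
protocol's: day 7 after inoculation, then every two days from day 10,
truncated at the horizon (default 1000 h). Hypothetical protocols start
at 168 h — consistent with the validated weekly schedule — since no
other convention is available for schedules that were never run in
animals.

In interval sweeps the default dose count gives every dose that fits in
the three-week treatment window (first dose 168 h, last at or before
504 h): 8 doses at a 48-h interval down to 2 at 192–216 h. An explicit
`n_doses` overrides this.

The TGF-β knockout experiment disables the suppression pathway by
setting $p_\beta = 0$; with $F_\beta(0)=0$ the cytokine then stays at
zero and the suppression factor is identically 1. Knockout can only
reduce the tumor relative to baseline — suppression only ever protects
the tumor — and the tests assert exactly that comparison.

## Calibration

**Diameter conversion.** Tumor cell counts are derived from calliper
diameters assuming a spherical tumor of close-packed spherical cells of
diameter 17.4 µm: $N = (d/17.4\,\mu m)^3$. The conversion is exactly
cubic and round-trips with its inverse.

**Gompertz fit.** `fit_gompertz()` fits $(r, K)$ to an untreated time
course with the inoculum fixed, using the closed-form solution rather
than repeated integration (exact, fast, and free of solver error). The
default objective is least squares on **log** counts: murine tumor data
span five decades and carry multiplicative measurement error, so raw-
scale SSE is dominated entirely by the last one or two observations and
estimates $r$ erratically under realistic noise, while log-scale least
squares is the maximum-likelihood objective under the lognormal error
model the synthetic generator uses. A raw-scale option is retained for
comparison. On the log scale the model is linear in $\log K$ given $r$,
so $\log K$ is profiled out in closed form and $r$ is found by a
deterministic grid-plus-bracket 1-D search — no starting-value
sensitivity, bit-reproducible results.

**Therapy parameters.** `fit_therapy_params()` is an exhaustive grid
search over $(a_T, r_a, r_e, \tau)$, scoring each combination by NRMSE
of the simulated treated trajectory against the treated data. Ties are
broken by the first minimum in row-major grid order ($a_T$ varying
fastest), recorded in the result; the scored grid is returned whole so
the selection can be audited.

**NRMSE.** Root-mean-square error at the observation times divided by
the observed range (max − min), in percent. Range normalization is the
default; mean normalization is available as a switch, since published
NRMSE figures rarely state their convention and the two differ
materially on data spanning decades.

## Sensitivity analysis

`lpsa()` perturbs each parameter by ±1 % (one at a time), re-simulates
the protocol, and reports the percent change of the tumor burden at the
final common grid time across the baseline and the two perturbed runs —
the earliest death time wins, keeping the comparison at a single well-
defined time even when a perturbation shifts host death. Parameters at
zero stay zero under relative perturbation and are flagged degenerate;
a zero baseline burden makes the ratio undefined, in which case the
absolute burdens are still reported and the row flagged. The report is
ordered by the larger absolute change of the ± pair, which is the
natural bar-chart ranking. The stopping thresholds are excluded by
default (they are experiment-design constants, not biology), but the
perturbed set is user-selectable.

## Synthetic data

`synthesize_growth_data()` generates mouse cohorts on the study's
measurement design: simulate the model under the generating parameters,
sample the burden at the measurement times, apply per-observation
multiplicative lognormal noise with log-mean 0 (median-unbiased, so the
per-time median across mice converges to the truth — a property the
tests check at 200 mice). Measurements stop at simulated host death, as
the animal protocol's did; this matters for calibration, because
holding a dead mouse's burden at the death threshold would inject a
clipped observation and bias the fitted growth rate by roughly 10 %.
Defaults: σ = 0.1 (a ~10 % coefficient of variation, plausible for
calliper-derived volumes), 700-h horizon matching the control
observation window, seeds mandatory. What the generator does **not**
emulate: inter-mouse parameter heterogeneity, dropout other than death,
measurement rounding, or diameter-stage noise (noise is applied to
counts, not diameters) — so parameter-recovery results here bound what
idealised, homogeneous cohorts can show, not what any real colony will.

## Parameter values shipped with the package

`inst/extdata/example_params.yaml` is an **illustrative** set: the
growth parameters ($r = 0.00106\,h^{-1}$, $K = 6.754\times10^{15}$
cells, inoculum 6×10⁴), the arrival fraction ($ef = 0.5$) and the death
threshold (1.6×10¹⁰ cells) are study-reported values; the immune-
kinetic constants are order-of-magnitude choices from the murine
CTL/DC/TGF-β modelling literature (e.g. a ~3-day DC half-life, a
suppression floor of 0.69), chosen once so that the pipeline exhibits
the qualitative regime of interest — partial response at 10⁶ DCs
weekly, eradication at large doses or short intervals — and not fitted
to any dataset. Quantitative conclusions about the real therapy require
a user-supplied calibrated parameter file; the loader deliberately has
no defaults for rate constants.

## Problem sizes and determinism

Simulations in the tests and the acceptance script use the study-scale
problem: 700–1000 h windows at a 1-h step (≤ 1001 grid points), cohorts
of 10–200 mice, 16-point therapy grids, and 20-seed recovery
replications — each run completing in well under a second, the full
suite in tens of seconds. Identical inputs produce bit-identical
trajectories (no randomness exists outside the synthetic-data module,
whose seeds are explicit arguments), and every artifact written by the
pipeline embeds the settings needed to regenerate it.

## Known limitations

* No spatial structure, stochastic birth–death, additional cytokines
  (IL-2, IL-10), MHC expression, or DC pre-treatment modelling; the
  model is deliberately the five-interaction reduction.
* The delay enters through a single lumped $\tau$ for both activation
  and expansion.
* Fixed-step RK4 has no error control; the step must be chosen against
  the fastest rate in the parameter set (the tests' convergence checks
  show how to verify a choice).
* Eradication and death are grid-resolved events (accurate to `dt`).
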