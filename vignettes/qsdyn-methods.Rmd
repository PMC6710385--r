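---
title: "Methods: the qsdyn quorum-sensing model, its calibration and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the qsdyn quorum-sensing model, its calibration and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qsdyn)
```

## The model and its assumptions

`qsdyn` describes AI-2 quorum sensing in an *E. coli* batch culture
with three variables: cell density $X$ (OD600), extracellular AI-2
activity $A$ (arbitrary reporter units) and *lsr* operon expression $L$
(β-galactosidase units). The model makes four structural assumptions:

1. **Growth is autonomous.** $X(t)$ follows a Gompertz curve
   $X_0 + C e^{-e^{-B(t-M)}}$ and is unaffected by signalling. The
   package therefore never integrates $X$; every trajectory carries the
   closed-form evaluation exactly, and growth parameters are fitted
   separately (stage one) before the kinetics (stage two).
2. **Synthesis is growth-driven.** All AI-2 made by the LuxS pathway is
   exported, at a saturating (Hill) rate in $X$ — synthesis reflects
   metabolic activity, not signalling state.
3. **Uptake has two gears.** A basal PTS route, Hill in $X$ with a
   half-saturation density `km2` near the stationary density (so it
   switches on in late-exponential phase), and an LsrACDB route
   proportional to $A \cdot L \cdot X/X_\delta$, active only once the
   operon is expressed.
4. **Regulation is lumped.** Phosphorylation, LsrR binding and
   de-repression are collapsed into the feedback term `kAL` and the
   first-order repression `kR`; there are no intracellular species and
   $L$ has no saturation (implemented literally, so $L$ can grow until
   its driving signal $A$ is depleted).

The initial state defaults to $A(0) = L(0) = 0$: cultures are
inoculated at low density before any signal has accumulated. Both are
overridable.

## Parameters

| name | unit | default | role |
|------|------|---------|------|
| `X0` | OD600 | 0.064 | inoculum density |
| `C` | OD600 | 5.8828 | capacity above `X0` |
| `B` | 1/h | 0.6384 | growth rate |
| `M` | h | 3.2823 | inflection time |
| `kA` | activity/h | 1561.68 | AI-2 synthesis velocity |
| `km1`, `n1` | OD600, — | 1.5793, 2.9302 | synthesis half-saturation / steepness |
| `kXA` | 1/h | 343.98 | PTS uptake rate |
| `km2`, `n2` | OD600, — | 5.8205, 8.9542 | PTS switch-on density / steepness |
| `kLA` | 1/(β-gal·h) | 0.0044 | LsrACDB uptake rate |
| `Xdelta` | OD600 | 5.7953 | density scale of the LsrACDB terms |
| `kL` | β-gal/(activity·h) | 0.5825 | expression rate |
| `km3`, `n3` | OD600, — | 3.9128, 0.0017 | expression half-saturation / steepness |
| `kAL` | 1/(activity·h) | 0.0028 | feedback expression rate |
| `kR` | 1/h | 0.1037 | repression rate |

`default_truth()` returns this set; it doubles as the ground truth of
the synthetic-data generator. A note on units: the printed unit of
`kLA` in the source calibration is dimensionally inconsistent with its
rate equation; `qsdyn` documents `kLA` (and `kAL`) in the units that
make $\mu_{LA}$ an activity/h (respectively β-gal/h) rate.

`n3` and `Xdelta` are clamped by default during fitting
(`default_fixed()`, at 0.001722 and 5.7953) because they are
practically non-identifiable from single-culture data — see below.

## Numerical integration

Trajectories are integrated with `deSolve::lsoda` (adaptive-step,
stiff-capable) and a compiled right-hand side, at `rel_tol = 1e-8`,
`abs_tol = 1e-10`. Reported $A$, $L$ in $[-100\,\mathrm{abs\_tol}, 0)$
are clipped to 0 (solver roundoff); anything more negative raises an
error, since structurally every negative term in $dA/dt$ carries a
factor $A$ and every negative term in $dL/dt$ a factor $L$, so genuine
negativity signals misuse rather than roundoff. Halving the tolerances
moves reported values by less than $10^{-4}$ relative (tested).

## Calibration

The objective is the normalized sum of squares

$$SSWR(\theta) = \sum_j \sum_i w_{ij}
  \left(\frac{y_{ij} - \hat y_{ij}(\theta)}{\max_i y_{ij}}\right)^2,$$

with per-variable normalization by the **data** maximum, so OD, activity
and β-gal series contribute comparably; weights default to 1 and are
the hook for the weighted bootstrap. The optimizer is the classic
rand/1/bin differential evolution (mutant $a + F(b-c)$, binomial
crossover with one guaranteed gene, greedy selection, reflection at the
bounds) with Storn–Price settings: population $10\times$ dimension,
$F = 0.5$, $CR = 0.9$, stop on a population cost spread below
$10^{-8}$. Runs are bit-reproducible given a seed.

Fitting is two-stage: the growth series pins $(X_0, C, B, M)$ by
closed-form least squares, then the kinetic stage integrates the ODEs
on the union of the data grids and scores $A$ and $L$ only. Failed
integrations inside the optimizer score a finite penalty ($10^6$)
rather than aborting. Default kinetic bounds follow the reference
calibration's interval ranges where available; the `kXA` range is
widened to $[100, 500]$ because the printed interval ($[400, 500]$)
excludes the printed best fit (343.98) — an inconsistency in the
source table.

**Reconciling the sparse expression series.** The β-gal series has
fewer points than the others. Protocols whose cost requires equal
point counts linearly interpolate the sparse *data* onto the dense
grid; `qsdyn` exposes that as `l_align = "data"` but defaults to
`l_align = "model"`, which scores the $L$ residuals at their native
times against the densely simulated model. The two are *not*
equivalent: interpolating a coarse series through the expression peak
distorts its curvature, and with the default sampling design that
bias displaces the repression rate `kR` by about 25% even on noiseless
data. With the default alignment, two-stage recovery on noiseless
synthetic data is exact to optimizer precision (all parameters to
within 0.1% at a population of 80 and up to 1500 generations).

## Identifiability

`profile_likelihood()` clamps one parameter at 21 scan values —
log-spaced over $[\hat\theta/5,\, 5\hat\theta]$, or linear over
$[10^{-3}, 1]$ for Hill exponents sitting near zero, whose action is
only distinguishable on that scale — and re-optimizes the remaining
parameters at each value with a reduced, warm-started budget. The scan
walks outward from the optimum on each side, seeding every point's
population from its inner neighbour (continuation); the profiled
parameter's scan deliberately ignores the fitting box, because
clamping is a constraint, not a bound move. `classify_identifiability()`
calls a parameter identifiable when the re-optimized cost exceeds the
minimum by a threshold on **both** sides; the default threshold is the
pointwise 95% chi-square increase $3.84\,\hat\sigma^2$ with
$\hat\sigma^2$ the per-point residual variance on the normalized scale,
estimated from the best cost. The threshold is configurable because the
underlying judgment ("visibly concave") is qualitative.

On synthetic data at the default 5% noise the package finds:

* `n3` — flat: for any tiny exponent the expression Hill term is the
  constant $1/2$ (absorbable into `kL`), and even at $n_3 = 1$ the term
  can be made density-independent by sending `km3` to its lower bound.
* `Xdelta` — flat: it enters only as `kLA/Xdelta` and `kAL/Xdelta`, an
  exact ridge; only the ratios are estimable. Its flat directions
  include the rightward one a calibrator notices first when the rates
  sit well inside their bounds.
* `kA` — steeply rising to the left, but *compensable to the right*:
  raising `km1` pushes the synthesis half-saturation beyond the
  observed density range, so the asymptotic velocity `kA` escapes
  upward with little cost change; at 5% noise the rightward rise stays
  below the chi-square threshold. Under-converged re-optimization hides
  this ridge and makes `kA` look cleanly concave; the converged profile
  is the honest one, and it implies that a bounded `kA` interval
  partly reflects the chosen box, not data curvature. The data would
  pin `kA` only if synthesis saturation were observed — i.e. if `km1`
  stayed well below the stationary density.

## Uncertainty

`weighted_bootstrap()` re-fits the kinetic stage under i.i.d.
Exponential(1) weights (mean and variance one) attached to each
point's squared normalized residual; intervals are the 2.5%/97.5%
replicate quantiles with linear interpolation between order statistics
(quantile type 7 — stated because conventions differ). Weight draws
are seeded `seed + replicate`; the replicate optimizer and its
warm-start jitter reuse the master seed, so replicate scatter is
attributable to the weights alone (common random numbers) and the
degenerate all-weights-1 bootstrap is bit-identical across replicates
(zero-width intervals — a machinery check, not a statement about
uncertainty). Replicates are warm-started around the baseline estimate
at roughly half the baseline budget; failures are recorded and
excluded, and more than 20% of them is an error. Only the kinetic
stage is bootstrapped: the growth stage is closed-form,
orders-of-magnitude better determined, and the reference analysis
reports intervals only for kinetic constants.

A caveat that follows from the identifiability section: for a
ridge-riding parameter such as `kA`, the single-realization estimate
can sit far up the ridge, and the bootstrap then quantifies
reweighting variability *around that displaced estimate* — its interval
need not cover the generating value for every noise realization, even
when the machinery is correct.

## Interference model

Co-culture couples a producing wild strain and a LuxS⁻ knockout
(senses and consumes, never produces) through a shared medium: the
capacity splits as $C_w = f\,C$, $C_{ko} = (1-f)\,C$ with
$C_w + C_{ko} = C$ exactly. AI-2 synthesis uses $X_w$ only; PTS and
LsrACDB uptake sum over both strains; expression follows the wild
strain (the equation set uses a single shared $L$, implemented
literally rather than giving the knockout its own expression state).

**Horizon.** Interference simulations default to 24 h (single culture:
12 h). With the capacity halved, neither strain reaches the PTS
switch-on density `km2` ≈ 5.82, the signal is never strongly cleared,
and expression keeps rising well past 12 h; a 12 h window would report
a truncation artifact as the "peak". By 24 h the expression plateau is
realized, and the 50/50 co-culture peaks at 3.2× the monoculture peak.

**Pre-culture.** The knockout's head start is modelled as growth alone
in its own medium — the full-capacity Gompertz curve, the law the
growth stage actually fits for a strain growing alone — for $\tau$
hours; the pre-grown biomass (measured as the increment from $t = 0$,
so $\tau = 0$ reduces exactly to the plain co-culture) is then added
and the strain grows its co-culture share $C_{ko}$ on top. A pure time
shift inside a half-capacity Gompertz cannot reproduce any suppression:
the knockout would then never exceed $X_0 + C/2 \approx 3$, far below
`km2`, and the PTS scavenging that drives the effect would never
activate. With the adopted encoding the pre-grown knockout crosses the
PTS threshold and strips the signal: peak expression falls 14-fold
between $\tau = 2$ and $\tau = 3$ h.

**Suppression flag.** The sweep's treatment variable is $\tau$ with
$\tau = 0$ as its control, so a pre-culture time counts as suppressing
when peak $L$ falls below 10% of the $\tau = 0$ co-culture peak. The
verdict — minimal suppressing $\tau = 3$ h — is insensitive to that
threshold anywhere in $(0.06, 0.69)$.

## Synthetic data

`generate_dataset()` emulates the structure of bench time courses for
this system: X and AI-2 activity sampled every 0.5 h over $[0, 10]$ h,
β-gal every 1.5 h (sparser, as in the real assays), multiplicative
Gaussian noise $y(1 + \mathrm{CV}\,z)$ clipped at zero with CV 5% by
default — multiplicative because OD and luminescence errors scale with
signal across decades. The generating parameters are stored in the
dataset (and its file header), making recovery experiments
self-contained. What it does **not** emulate: reporter-strain
saturation and delay in the AI-2 assay, β-gal assay background,
day-to-day batch effects, or digitization error — so passing recovery
tests demonstrate correctness of the machinery under the stated noise
model, not robustness to real assay pathologies.

## Problem sizes used by the shipped tests

The test suite favours depth over bulk at desk scale: recovery runs use
the default design (21 + 21 + 7 points) with a DE population of 80 and
up to 1500 generations; profiles use 21 scan points at population 24 /
80 generations per point with continuation; the bootstrap spot-check
uses 50 replicates at population 20 / 100 generations. The full
500-replicate bootstrap of the reference analysis is available through
the same interface (`n_reps = 500`).

## Known limitations

* $L$ is unbounded by construction; with uptake disabled it grows
  without limit while $A$ persists.
* The co-culture shares one expression variable; a knockout-specific
  $L_{ko}$ (it does sense AI-2) would change the knockout's LsrACDB
  uptake timing. The shared-$L$ form is kept deliberately as the
  minimal literal model.
* Capacity sharing is phenomenological — there is no explicit
  substrate; "pre-culture" changes initial biomass, not medium
  composition.
* The DE optimizer is the only fitting route (no gradient-based
  polish); budgets, not tolerances, control practical convergence.
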