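# qsdyn

Kinetic modelling of autoinducer-2 (AI-2) mediated quorum sensing in
*Escherichia coli*: simulation, calibration, identifiability,
uncertainty, and co-culture interference.

## The problem

*E. coli* coordinates group behaviours (biofilm formation, virulence,
motility) through the interspecies signal AI-2. Cells synthesize AI-2
via the LuxS enzyme and export it; the extracellular pool is imported
back first through the phosphotransferase system (PTS) and then — once
the *lsr* operon is induced — much faster through the LsrACDB
transporters, whose expression is itself activated by imported AI-2 and
repressed by LsrR. The result is a pulse of extracellular AI-2 that
rises during exponential growth and is abruptly depleted in
late-exponential phase.

`qsdyn` implements a compact three-variable model of this loop for
modellers and experimentalists who want to fit it to growth /
AI-2-activity / β-galactosidase time courses, interrogate which
parameters the data actually constrain, and simulate *interference*
strategies in which a LuxS⁻ knockout strain (senses and consumes AI-2,
produces none) scavenges the signal away from a wild-type strain.

## The model

Cell density follows a Gompertz curve (never integrated numerically):

    X(t) = X0 + C exp(-exp(-B (t - M)))

Extracellular AI-2 activity `A(t)` and *lsr* expression `L(t)` obey

    dA/dt = mu_A - mu_XA - mu_LA
    dL/dt = mu_L + mu_AL - mu_R

with Hill/Monod-type rates

    mu_A  = kA  X^n1 / (X^n1 + km1^n1)          (synthesis, growth-driven)
    mu_XA = kXA X^n2 / (X^n2 + km2^n2) A        (basal PTS uptake)
    mu_LA = kLA (X / Xdelta) A L                (LsrACDB uptake)
    mu_L  = kL  X^n3 / (X^n3 + km3^n3) A        (PTS-driven expression)
    mu_AL = kAL (X / Xdelta) A L                (feedback expression)
    mu_R  = kR L                                (LsrR repression)

In co-culture the wild strain and the knockout share the carrying
capacity (`C_w + C_ko = C`); the knockout contributes uptake terms at
its own density but no synthesis.

Calibration minimizes the normalized sum of squares
`SSWR = sum_j sum_i w_ij ((y_ij - yhat_ij) / max_i y_ij)^2` with the
classic rand/1/bin differential-evolution optimizer, in two stages
(growth first, kinetics second). Identifiability is diagnosed by
profile likelihood; uncertainty by a weighted bootstrap with
Exponential(1) per-point weights.

## Worked example

```r
library(qsdyn)
truth <- default_truth()          # reference calibration

# single culture over 12 h
traj <- simulate_qs(truth$growth, truth$qs)
print(traj)
#> Quorum-sensing trajectory: 241 time points over [0, 12] h (X, A, L)
#> maxima: X = 5.924, A = 1035, L = 1080
```

Growth saturates near OD600 5.9; AI-2 activity peaks around 1035 units
in mid-exponential phase and is depleted afterwards; operon expression
peaks near 1080 β-gal units and then decays under LsrR repression.

```r
# 50/50 co-culture with a LuxS-knockout scavenger
co <- simulate_cocult(truth$growth, truth$qs, cocult_config(0.5, 0))
max(co$L) / max(simulate_qs(truth$growth, truth$qs, t_grid = co$time)$L)
#> [1] 3.249481
```

Counter-intuitively, an equal co-culture *triples* the wild strain's
peak operon expression: neither strain reaches the density that
switches on strong PTS uptake, so the signal lingers. Pre-growing the
knockout before mixing reverses this:

```r
sweep_preculture(truth$growth, truth$qs)
#>   tau_h     peak_L suppressed
#> 1     0 3510.44982      FALSE
#> 2     2 2437.83361      FALSE
#> 3     3  176.24998       TRUE
#> 4     4   18.73404       TRUE
#> 5     5   11.81847       TRUE
#> control (tau = 0) peak L: 3510; threshold 0.10
#> minimal suppressing pre-culture time: 3 h
```

A knockout pre-cultured to its mid-exponential phase (3 h) or later
depletes the AI-2 pool fast enough to keep the wild strain's operon
essentially silent.

Fitting, identifiability and uncertainty follow the same pattern:

```r
ds  <- generate_dataset(truth$growth, truth$qs, design_spec(seed = 1))
fit <- qs_fit(ds, qs_control = de_control(pop_size = 60, max_gen = 500, seed = 1))
coef(fit)
prof <- profile_likelihood(ds, fit, "kA")
classify_identifiability(prof)
boot <- weighted_bootstrap(ds, fit, n_reps = 500, seed = 1)
print(boot)
```

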