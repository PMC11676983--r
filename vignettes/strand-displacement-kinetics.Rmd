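---
title: "Models and methods: reversible strand-displacement kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reversible strand-displacement kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsdrkit)
```

## The reaction model

A reversible toehold-mediated strand displacement reaction exchanges an
invader strand X1 into a gate duplex X2, producing the post-exchange gate X3
and releasing the incumbent X4. Both gates expose a toehold — t1 on X2
nucleates the forward reaction, t2 on X3 the backward one — so the system is
modelled as one lumped reversible bimolecular step

$$X_1 + X_2 \underset{k_d}{\overset{k_a}{\rightleftharpoons}} X_3 + X_4,
\qquad v = k_a x_1 x_2 - k_d x_3 x_4,$$

with both rate constants in nM⁻¹ s⁻¹. The lumping assumes toehold binding
and branch migration are fast relative to the overall exchange, which is the
standard coarse-graining at the 6-nt toehold length this package targets;
multi-step toehold-binding/branch-migration models are deliberately out of
scope. Temperature dependence, leak reactions and sequence-level
thermodynamics are likewise not modelled.

Two formulations of the same kinetics coexist on purpose:

- `simulate_tmsdr()` integrates the four-species ODE with `deSolve::lsoda`
  (stiff-capable; relative tolerance 1e-8, absolute tolerance 1e-10 nM).
  Rate constants vary by more than two orders of magnitude across reporter
  configurations, so a stiff-capable integrator with tight tolerances is the
  safe default.
- `closed_form_extent()` integrates the scalar extent ODE exactly. With
  initial concentrations $(a, b, c, d)$ and extent $x$,
  $\dot x = k_a(a-x)(b-x) - k_d(c+x)(d+x)$ is quadratic in $x$,
  $\dot x = \alpha x^2 + \beta x + \gamma$, and separation of variables with
  partial fractions gives
  $$x(t) = r_1\,\frac{1 - e^{\lambda t}}{1 - (r_1/r_2)\,e^{\lambda t}},
  \qquad \lambda = \alpha (r_1 - r_2) < 0,$$
  where $r_1$ is the attracting root of the quadratic and $r_2$ the other.
  Degenerate cases are handled by their limits rather than by division by
  zero: $k_a = k_d$ collapses to a linear relaxation
  $x(t) = (-\gamma/\beta)(1 - e^{\beta t})$; coincident roots (e.g. the
  irreversible reaction with equal initials) give the algebraic decay
  $x = \alpha r^2 t/(1 + \alpha r t)$; $\gamma = 0$ means the system starts
  at equilibrium and the extent stays 0.

Having an exact curve buys two things: an independent oracle for the
integrator (the test suite requires agreement to a relative 1e-5 across a
$k_a, k_d \in \{10^{-6}, 10^{-4}, 10^{-2}\}$ grid with equal and unequal
initials), and a model function cheap enough to evaluate thousands of times
during multi-start fitting.

`equilibrium_extent()` returns the physically admissible root of
$k_a(a-x)(b-x) = k_d(c+x)(d+x)$: the one inside
$[-\min(c,d), \min(a,b)]$ reachable from $x = 0$ by continuity, which is the
attracting root the closed form relaxes to. For $k_d = 0$ (irreversible) the
limiting reactant is consumed, $x^* = \min(a,b)$.

## Substitution ratio

The quantity of scientific interest is the **substitution ratio**: the
fraction of invader converted,
$(x_{1,0} - x_1)/x_{1,0}$, equal to $x_4/x_{1,0}$ when products start at
zero. (A definition read literally as "X1 after / X1 before" would be its
complement; the displaced fraction is the convention that matches how the
field quotes these numbers, e.g. a backward-dominant construct is described
as "roughly 10%", not 90%.) For equal initial concentrations of both
reactants the equilibrium value has the concentration-invariant closed form

$$r^* = \frac{\sqrt{k_a/k_d}}{1 + \sqrt{k_a/k_d}},$$

which the tests verify for initial concentrations of 1, 10 and 100 nM. This
invariance is also why all steady-state results here are insensitive to the
choice of operating concentration; the package defaults to
$x_{1,0} = x_{2,0} = 10$ nM with no initial products.

For the four reference reporter configurations
(`reference_rate_constants()`), the model predicts:

```{r}
ref <- reference_rate_constants()
init <- reaction_state(10, 10)
data.frame(ref[1:2],
           eq_pct = sapply(seq_len(nrow(ref)), function(i)
             round(100 * substitution_ratio(
               equilibrium_extent(tmsdr_system(ka = ref$ka[i], kd = ref$kd[i]),
                                  init), 10))))
```

## Observation model and calibration

The FRET readout is affine in the reporter-species concentration:
$F(t) = f_0 + (f_{100} - f_0)\,[\mathrm{reporter}](t)/x_{1,0}$. Calibration
uses two dedicated samples: the fully labelled gate alone (fluorophore and
quencher both present, no reaction possible) defines the baseline $f_0$, and
the fluorophore-only species at the reference concentration defines the
100%-substitution level $f_{100}$. `normalize_to_substitution()` inverts the
affine map with **time-averaged** calibration levels — full calibration
traces are recorded, but using their means makes the normalization robust to
instrument jitter, and the affine-invariance property (any $aF + b$, $a>0$,
applied to all traces leaves the result unchanged) then holds exactly.

Two deliberate choices:

- Normalized values are **not clipped** to [0, 1] before fitting; noise
  legitimately puts points slightly outside, and clipping would bias the
  least-squares estimates. Clamping is for display only.
- Instruments need a stabilization window (≥ 120 s) before the reaction is
  triggered; `fit_rates(exclude_before =)` (or the `exclude_before` config
  key) drops that leading segment from the fit.

## The synthetic-data generator

`generate_dataset()` emulates the fluorometer protocol: a reading every 10 s
for 90 min (541 points), three replicates per role, reaction traces equal to
the noiseless model prediction plus i.i.d. Gaussian noise, and baseline /
positive-control traces fluctuating about $f_0$ and $f_{100}$. The noise SD
defaults to 2% of the dynamic range on the normalized scale — photon noise
at high count rates is approximately Gaussian, and published experiments of
this kind report only mean ± SD bands, so the level is a declared choice,
not an inference. Noise is independent across replicates and calibration
traces; an optional linear drift term exists purely to stress-test the
normalization and defaults to 0. Everything is reproducible bit for bit
from the protocol seed (`withr::with_seed`, so the caller's RNG stream is
untouched).

What the generator does **not** emulate: correlated instrument noise,
photobleaching, inner-filter effects, pipetting errors in the initial
concentrations, or gate preparation artifacts (truncated strands, leak).
Passing recovery tests on these synthetic data therefore demonstrates that
the estimation machinery is correct and well-conditioned under the stated
noise model — not that real traces are free of systematic effects the model
omits.

## Rate-constant estimation

`fit_rates()` minimizes the sum of squared residuals between the observed
substitution-ratio course and the closed-form model curve. Design choices:

- **Log₁₀ parameter space.** The rates span several decades and must stay
  positive; optimizing $(\log_{10} k_a, \log_{10} k_d)$ inside
  $[10^{-8}, 1]$ nM⁻¹ s⁻¹ handles both.
- **Multi-start.** When one direction dominates by a large factor the RSS
  surface is nearly flat along the dominated rate, and a single start can
  stall on the plateau. A 5×5 log-spaced grid of starts (25 for the
  one-parameter variant) with Levenberg–Marquardt (`minpack.lm::nls.lm`,
  step/gradient/function tolerances 1e-10, 200 iterations) is run and the
  best converged start wins. Per-start diagnostics are kept in the result.
- **Unweighted by default.** The replicate SD is available and
  `fit_options(weighted = TRUE)` switches to inverse-variance weighting, but
  the default loss is plain least squares on the replicate mean.
- **Failure is a result.** If no start converges the fit returns
  `converged = FALSE` with the per-start table rather than throwing; the
  pipeline command maps this to its own exit code.
- **Optional bootstrap.** `bootstrap_rates()` resamples replicates with
  replacement (default 200 draws, seed-controlled) for percentile intervals;
  it is off the default path since the headline analysis reports point
  estimates.

Identifiability, measured on synthetic data at the four reference operating
points (triplicates, 2% noise, 20 seeds per condition): the median absolute
log₁₀ error of both rates stays below 0.05, except the dominated rate when
the other direction is more than 50× faster, where the test suite asserts
the widened 0.15 band explicitly. Noiseless data pin both rates to better
than 0.1% relative error. A companion negative-result check reproduces a
characteristic failure mode: data generated at the 3′-asymmetric operating
point (backward rate ~17× **below** theory) and refit with the backward
rate clamped **to** theory inflate the RSS by well over an order of
magnitude — one free parameter cannot absorb both the transient and the
steady state, which is exactly the diagnostic signature that the label has
genuinely shifted the rate constant.

Estimates are reported as ratios to the theoretical rate constant for the
toehold length (5.0×10⁻⁴ nM⁻¹ s⁻¹ at 6 nt; `theoretical_rate_table()`
accepts user entries for other lengths), rounded to two significant figures
in reports while full precision is kept internally. Equilibrium percentages
in reports are rounded to the nearest percent.

## Problem sizes and numerical conventions

The test suite and examples run the protocol-default 541-point grids;
Monte-Carlo checks use 20 seeds per condition (recovery) and 40 replicates
(noise calibration), sizes at which the binomial/sampling error of the
checked statistics is comfortably below the asserted tolerances. Sampling
grids are truncated, never extended, at the protocol duration. Trajectory
conservation ($x_1 + x_3$, $x_2 + x_3$, $x_4 - x_3$) is asserted to drift
less than 1e-6 nM; detailed balance at the end of a long simulation to
1e-9 nM/s. Ties and degenerate inputs: zero-duration grids yield the
single-point trajectory at the initial state; a single replicate aggregates
with SD 0 and an explicit warning flag; exact-zero SDs under weighting are
replaced by the smallest positive SD to keep weights finite.

## Known limitations

- The lumped one-step model cannot represent toehold-occlusion or
  branch-migration intermediates; if a real trace deviates from the
  two-parameter family, the fit will show structured residuals rather than a
  diagnosis.
- Calibration assumes the affine FRET map with a common $f_0$, $f_{100}$
  across replicates; fluorophore-concentration mismatches between reaction
  and control samples translate directly into scale errors of the ratio.
- The mechanism by which reporter labels shift specific rate constants is
  not modelled — the package quantifies the shift, it does not explain it.
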