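# tmsdrkit

Kinetic analysis of **reversible toehold-mediated strand displacement
reactions (TMSDRs)** measured by FRET reporters.

In DNA computing, a TMSDR exchanges an invader strand X1 into a gate duplex
X2, releasing the product gate X3 and the incumbent strand X4. When both
gates carry a toehold, the exchange is reversible:

```
            ka
X1 + X2  <======>  X3 + X4        v = ka·[X1][X2] − kd·[X3][X4]
            kd
```

with lumped bimolecular rate constants `ka` (forward) and `kd` (backward) in
nM⁻¹ s⁻¹. Reaction progress is read out by fluorescence: the gate carries a
fluorophore (FAM) and quencher (BHQ1), so the signal is affine in the
concentration of the unquenched reporter species. The catch is that the
reporter labels themselves perturb the kinetics — by up to an order of
magnitude relative to the theoretical rate constant for a 6-nt toehold
(5.0×10⁻⁴ nM⁻¹ s⁻¹) — and in a reversible reaction that shifts not just the
transient but the steady-state substitution ratio
√(ka/kd) / (1 + √(ka/kd)) (equal initial concentrations).

`tmsdrkit` is for researchers quantifying such label effects from
fluorometer time series. It provides:

- **reaction model** — ODE simulation (`simulate_tmsdr`), an exact
  closed-form progress curve (`closed_form_extent`; the extent ODE is
  quadratic and integrates by partial fractions), and equilibrium analysis
  (`equilibrium_extent`, `substitution_ratio`);
- **observation model** — affine FRET prediction (`predict_fluorescence`)
  and normalization of measured traces to substitution-ratio courses against
  a quenched-gate baseline and fluorophore-only positive control
  (`normalize_to_substitution`, `aggregate_replicates`);
- **synthetic data** — `generate_dataset` emulates the measurement protocol
  (10 s sampling over 90 min, triplicates, additive Gaussian noise) with
  known ground truth and a fixed seed;
- **estimation** — multi-start nonlinear least squares for (ka, kd) in log
  parameter space (`fit_rates`), ratios to the theoretical rate constant
  (`ratio_to_theory`) and condition reports (`build_report`);
- **pipeline commands** — `cmd_simulate`, `cmd_generate`, `cmd_fit`, plus a
  thin shell wrapper in `inst/scripts/tmsdr-cli.R`.

## Worked example

Generate a noisy triplicate dataset for the 5′-toehold asymmetric construct
and recover its rate constants:

```r
library(tmsdrkit)

sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4,
                    toehold_orientation = "five_prime",
                    modification = "asymmetric")
init <- reaction_state(10, 10)                     # 10 nM each reactant
ds <- generate_dataset(sys, init, synthetic_protocol(seed = 42))

calib <- calibration_set(ds$baseline, ds$positive_control)
courses <- lapply(ds$reaction, normalize_to_substitution, calib = calib)
fit <- fit_rates(aggregate_replicates(courses), init)
fit
#> TMSDR rate-constant fit
#>   ka = 0.000174 nM^-1 s^-1, kd = 0.000856 nM^-1 s^-1
#>   RSS = 0.06486 over 541 points (25 starts, 25 converged)
#>   ratio to theory: ka 0.35, kd 1.7
```

Both rates come back within ~1% of the generating values despite 2% noise.
The ratios to theory (0.35 and 1.7) say the labels slowed the forward
reaction ~3× and sped the backward reaction ~2×. The condition report adds
the predicted steady state:

```r
build_report(list(list(toehold = sys$toehold_orientation,
                       modification = sys$modification,
                       fit = fit, initial = init)))
#>      toehold modification      ka_nM_s ka_ratio      kd_nM_s kd_ratio
#> 1 five_prime   asymmetric 0.0001743863     0.35 0.0008558692      1.7
#>   equilibrium_substitution_pct       rss converged
#> 1                           31 0.0648632      TRUE
```

i.e. only ~31% of the invader ends up displaced at equilibrium — a
steady-state consequence of the label-shifted rate constants.
`reference_rate_constants()` holds the fitted rates for all four
label configurations (5′/3′ toehold × symmetric/asymmetric modification).

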