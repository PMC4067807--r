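# breathpk

Pharmacokinetic modelling of exhaled drug concentrations.

Breath-by-breath monitors (for example an ion mobility spectrometer reporting
one exhaled-propofol value per minute) promise non-invasive, online insight
into a patient's drug exposure during anaesthesia. But the exhaled
concentration is not the plasma concentration: whenever the plasma level
changes, the breath signal follows with a lag, so plotting breath against
plasma over an induction–maintenance–washout course opens a *hysteresis
loop*, and a direct regression of one on the other is useless. `breathpk`
implements the two observation models that collapse that loop, on top of a
weight-scaled Marsh three-compartment plasma engine with a plasma-targeting
TCI (target-controlled infusion) controller, and everything needed to fit and
to stress-test them. It is aimed at PK/PD researchers working on exhaled-drug
monitoring and at anyone who needs a reproducible synthetic testbed for such
analyses.

## Models

**Plasma engine.** The Marsh propofol parameter set: central volume
`V1 = 0.228·weight` L with fixed rate constants `k10 = 0.1190`,
`k12 = 0.1140`, `k21 = 0.0550`, `k13 = 0.0419`, `k31 = 0.0033` min⁻¹. The
linear system is advanced with the exact constant-input update (matrix
exponential), and a discrete controller recomputes the infusion rate every
10 s so that the predicted plasma concentration `Cp = A1/V1` sits on the
target (e.g. the clinical 3 µg/ml) at every control-interval boundary.

**Lung-compartment model.** An added lung compartment exchanging with plasma
by the per-minute difference equation

    LCC(t+1) = LCC(t) + k1L·Cp(t) − kL1·LCC(t)

with steady state `Cp·k1L/kL1`.

**Delay (equilibration) model.** A first-order plasma↔breath equilibration
constant `ke0lung`, discretized as the standard effect-compartment update

    LCC(t+Δt) = Cp(t) + (LCC(t) − Cp(t))·exp(−ke0lung·Δt).

**Calibration.** A zero-intercept quadratic `y = a·x² + b·x` maps the breath
signal `x` (ppb or volt) to the modelled lung concentration `y` (µg/ml).

**Fitting.** All free parameters are estimated by maximizing the coefficient
of determination R² between the modelled lung series and the calibrated
breath signal (equivalently minimizing the normalized residual sum of
squares); when `(a, b)` are free they are profiled out by an inner
zero-intercept linear least squares at each outer iteration. The
lung-compartment model with *everything* free is scale-degenerate
(`(c·k1L, a/c, b/c)` fits identically); the fit detects and flags this.

## Worked example

Simulate the reference acquisition — 346 min sampled once per minute, TCI
from 0 to 330 min — then generate a noisy synthetic breath channel and fit
the delay model:

```r
library(breathpk)

params <- marsh_parameters(80)
tci <- run_tci(params, tci_protocol(target = 3, t_stop = 330), duration = 346)
series_values(tci$plasma)[60]
#> [1] 3

study <- generate_study(default_protocol(), "delay", delay_params(0.27),
                        quadratic_calibration(-4.2, 7.14, "ppb"),
                        noise = noise_model(cv = 0.05, seed = 1))
fit <- fit_model(study$plasma, study$breath_ppb,
                 fit_spec("delay", free = c("ke0lung", "a", "b")))
fit
#> <fit_result> model=delay, n=346
#>   parameters: ke0lung=0.289315, a=-9.47237, b=8.98645
#>   R2 = 0.940330, SSE = 0.922259, converged = TRUE

direct_correlation(study$plasma, study$breath_ppb)$r2
#> [1] 0.06995938
loop_area(hysteresis_data(study$plasma, study$breath_ppb))
#> [1] 0.2458338
```

Reading the output: the TCI controller holds the plasma target exactly at the
sampled minutes; with 5 % multiplicative signal noise the joint fit recovers
the generating `ke0lung = 0.27` min⁻¹ to about 7 % (the quadratic
coefficients are the softest direction of the fit), with R² = 0.94. The
direct plasma↔breath regression collapses to R² ≈ 0.07 and the (plasma,
breath) trajectory encloses a visibly nonzero loop area — the hysteresis the
dynamic models exist to remove. On noiseless data the same fit returns the
generating parameters to machine precision with R² = 1.

A command-line pipeline over the same functions lives in
`inst/cli/breathpk.R` (`simulate`, `synth`, `fit`, `report` subcommands).

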