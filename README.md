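# presspulse

Transient predator–prey dynamics in serially diluted microcosms under
press and pulse disturbance.

`presspulse` is for microbial ecologists and modellers studying how
disturbance strength and duration shape the *transient* recovery of
interacting populations — in particular the **prey release** that
follows when a predator is knocked down harder than its prey can
exploit. The reference system is a semi-continuous bacterial–ciliate
microcosm (a density-limited prey, a bacterivorous predator that also
grows osmotrophically on dissolved nutrients), maintained by daily
tenfold dilution and disturbed either by a sustained 40-fold daily
dilution (press) or a single 2500-fold dilution (pulse).

## The model

Between transfers, prey `P` and predator `C` (cells ml⁻¹) follow a
discrete-time Lotka–Volterra-type map at a 7.5-min step, 192 steps per
day:

    P[t+1] = P[t] + r_P P[t] (1 − P[t]/K_P) − c_P P[t] C[t]
    C[t+1] = C[t] + r_C C[t] + c_C P[t] C[t]

The daily transfer multiplies both stocks by the retention fraction
`1/fold` (per-day dilution rate `d = 1 − 1/fold`; tenfold ⇒ 0.9 d⁻¹).
`r_C` is the predator's coupling to the alternative resource: it lets
the predator persist — barely — without prey, and small changes in it
reshape recovery dramatically. Defaults: `r_P = 0.094`,
`r_C = 0.012` (per step), `K_P = 4.9e8`, `c_P = 3.5e-6`,
`c_C = 1.4e-11`.

On top of the simulator the package provides:

* **Disturbance regimes and schedules** (`controlRegime()`,
  `pressRegime()`, `pulseRegime()`, `buildSchedule()`, fold ↔ rate
  conversions);
* **Calibration**: staged Nelder–Mead fits to 24-h growth curves
  (`fitGrowthCurves()`), then Latin-hypercube refinement against the
  control series (`refineLatinHypercube()`), both minimising the
  fourth-power relative-distance objective
  (`relativePowerObjective()`);
* **Transient metrics**: Nash–Sutcliffe efficiency
  (`nashSutcliffe()`), equilibrium bands, response/recovery times,
  deviation time `D_T`, and the windowed prey–predator covariance that
  diagnoses prey release;
* **Simulation sweeps** over press duration (2–12 d), pulse fold
  (10–10⁶) and `r_C` (0.007–0.011) with per-run recovery curves
  (`runSweep()`);
* **Synthetic data**: seed-reproducible triplicate daily counts and
  hourly growth curves with mean-1 lognormal noise
  (`generateMicrocosmCounts()`, `generateGrowthCurves()`);
* **Pipeline commands** (`cmdSimulate()`, `cmdCalibrate()`,
  `cmdSweep()`, `cmdMetrics()`, `cmdFixtures()`) driven by YAML
  configs, with shipped presets under
  `system.file("extdata", "configs", package = "presspulse")` and a
  shell dispatcher at `inst/scripts/presspulse`.

## Worked example

Simulate the press experiment — 40-fold dilution on days 22–31 over a
10-fold baseline — and evaluate its transients:

```r
library(presspulse)

sc <- runScenario(modelParameters(), pressRegime(),
                  populationState(3.6e7, 4.2e4), nDays = 62)
sc$metrics
#> TransientMetrics
#>   prey     response 0 d, recovery 7 d
#>   predator response 0 d, recovery 6 d
#>   covariance before -2.763e-06, during/after -0.185
```

Both species leave their day-7-to-21 equilibrium bands on the first
disturbed day (response 0 d): the predator is diluted faster than it
can regrow and collapses, while the released prey climbs toward
carrying capacity. After the press ends on day 32 the predator re-enters
its band in 6 days and the prey in 7. The prey–predator covariance
(each series scaled by its maximum) drops from ≈ 0 before the press to
−0.185 during/after it — the signature of prey release.

How strongly the alternative resource buffers the predator:

```r
res <- runSweep(sweepSpec("r_C"))
subset(sweepTable(res), species == "predator")
#>  value  species recoveryDays censored extinct
#>  0.007 predator           NA     TRUE   FALSE
#>  0.008 predator           23    FALSE   FALSE
#>  0.009 predator           15    FALSE   FALSE
#>  0.010 predator           10    FALSE   FALSE
#>  0.011 predator            8    FALSE   FALSE
```

Weaker coupling ⇒ slower recovery from the 2500-fold pulse; at
`r_C = 0.007` the predator has not returned within the 30-day
post-disturbance horizon and is reported censored, not extrapolated.

See `vignettes/transient-dynamics.Rmd` for the model conventions,
calibration design and every tunable default.

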