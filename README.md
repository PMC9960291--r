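# jumpload

Skeletal loading during exercise is hard to measure outside the laboratory:
force plates — the gold standard for ground reaction force — are immobile and
expensive. `jumpload` implements an accelerometry-based alternative for
high-impact jumping exercise: it processes raw signals from body-worn
accelerometers (ankle, lower back, hip), extracts per-jump impact events, and
converts them into the two quantities that matter for bone-loading research:

- **pGRF** — peak ground reaction force (N), the maximum of the force signal
  around a landing;
- **pLR** — peak loading rate (N/s), the maximum time-derivative of force
  between foot-contact onset and the force peak.

It is aimed at researchers in biomechanics, sports science and bone health
who want to estimate mechanical loading from wearable sensors, validate such
estimates against force-plate recordings, or develop similar prediction
models.

## The model

Each of the twelve prediction equations is a fixed-coefficient linear model

```
outcome = b0 + b1 * predictor + b2 * mass + b3 * predictor * mass
```

where the predictor is the peak acceleration **pACC** (g, 1 g = 9.807 m/s²)
for pGRF equations and the peak acceleration rate **pAR** (g/s) for pLR
equations, and mass is body mass in kg. One equation exists per outcome
(pGRF, pLR) × signal vector (resultant, vertical) × accelerometer placement
(ankle, lower back, hip). For example, the hip/resultant pGRF equation is

```
pGRF (N) = -493.877 + 188.759 pACC + 18.008 mass + 1.279 (pACC × mass)
```

The package also implements the machinery used to develop and validate such
equations: the raw-signal processing chain (resampling to 100 Hz, zero-phase
4th-order 20 Hz Butterworth low-pass, resultant vector, clock plus
cross-correlation synchronization), impact-peak detection (trial mean + 3 SD
threshold, 0.2 s/4 s minimum separation by jump type), centered-derivative
loading rates, linear mixed models with subject and jump-condition random
intercepts, Nakagawa–Schielzeth conditional R², subject-wise leave-one-out
cross-validation, MAE/MAPE/RMSE, and Bland–Altman agreement analysis.
Because no laboratory data ship with the package, a synthetic paired
force-plate/accelerometer jump simulator with known ground truth
(`protocol_spec()`, `simulate_trial()`, `simulate_summary_table()`) makes
every step testable end to end.

## Worked example

Simulate one drop-jump trial (30 cm, eight landings), run the processing
chain, and predict pGRF from the hip accelerometer:

```r
library(jumpload)

spec  <- protocol_spec(subjects = 1, seed = 42)
trial <- simulate_trial(spec, subject = 1, jump_type = "drop", height_cm = 30)

res <- process_trial(trial$force, trial$accel$hip,
                     meta = list(subject_id = "S001",
                                 body_mass_kg = trial$truth$body_mass_kg,
                                 jump_type = "drop", height_cm = 30,
                                 placement = "hip"))
res$sync
#> <sync_result> lag = 32 samples (0.3200 s) [clock 0 + xcorr 32 + manual 0], peak xcorr = 0.9115
res$summary
#>   subject_id body_mass_kg jump_type height_cm placement    vector   pACC_g
#> 1       S001     102.1758      drop        30       hip resultant 6.636527
#>    pAR_gs   pGRF_N   pLR_Ns
#> 1 180.763 3629.019 99139.36

m <- get_model("pGRF", "resultant", "hip")
predict_loading(m, predictor_value = res$summary$pACC_g,
                body_mass_kg = res$summary$body_mass_kg)
#> [1] 3466.089
```

Reading the output: the simulator injected a 0.32 s clock offset between the
accelerometer and the force plate, and the cross-correlation synchronizer
recovered it exactly (32 samples at 100 Hz). The eight landings averaged a
measured peak force of 3629 N for this 102 kg subject; the published
hip/resultant equation, given only the accelerometer peak (6.64 g) and body
mass, predicts 3466 N — about 4.5 % low, well inside the accuracy reported
for this class of model.

A command-line wrapper with `simulate`, `process`, `predict` and `validate`
subcommands is installed at `inst/cli/jumpload.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "jumpload.R", package = "jumpload"))')" \
  simulate --out fixtures/ --seed 1
```

## Vignette

`vignettes/mechanical-loading.Rmd` describes the processing model and its
assumptions, the simulator design, the numerical choices (filter
initialization, tie-breaking, degenerate inputs) and known limitations.
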