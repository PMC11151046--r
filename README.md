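# celia

Kinetic simulation and endpoint quantification for coupled
exponential-to-linear isothermal DNA amplification circuits (PEN-toolbox /
EXPAR-style), in R.

## The problem

Exponential DNA amplification (PCR, EXPAR, LAMP, ...) is ultrasensitive,
but quantification requires *real-time* monitoring to extract an
amplification time `At` — the threshold-crossing time that is linear in
`-log10` of the target concentration. That ties up an optical instrument
for the entire incubation. Linear amplification, by contrast, can be read
once at the end, but has poor sensitivity. Coupling an exponential switch
to a downstream linear amplifier gets both: after the switch fires at
`At`, a linear stage with constant gain accumulates signal, so a single
endpoint reading at time `T`

```
endpoint ≈ gain · (T − At − δ),      At ≈ ln(α_thr/α0) / r_exp
```

is an analog record of `At`, hence of the log-concentration — a molecular
circuit that computes a logarithm. An inverter (NOT-gate) variant reverses
the correlation, and a microRNA converter template turns the assembly into
an endpoint microRNA assay with a femtomolar-range limit of detection and
a six-decade dynamic range. Endpoint readout also changes throughput
arithmetic: incubation happens offline and a reader only needs ~2 min per
plate, a ~60-fold capacity gain over real-time occupancy.

This package is for people who want to study, calibrate or teach such
circuits in silico: it provides the reaction-network builders, a
deterministic ODE simulator (with a Gillespie stochastic oracle), the
trace observables (`At`, gain, saturation, linear window, endpoint), the
endpoint calibration statistics (sigmoid fit
`f(x) = L + H/(1 + b·e^{−k(x−x0)})`, blank-based LoD = mean + 3 SD,
closed-form inversion, symmetric fold-difference panel accuracy), and a
synthetic plate-reader data generator with an explicit optical noise
model.

## Worked example

```r
library(celia)

# coupled circuit at two trigger levels: later At, lower endpoint
for (a0 in c(0.1, 1e-4)) {
  ts <- simulate_ode(celia_circuit("coupled", alpha0 = a0),
                     t_end = 1000, dt_out = 2)
  at <- amplification_time(get_trace(ts, "alpha"), list(absolute = 10))
  ep <- endpoint_signal(get_trace(ts, "omega"), 1000)
  cat(sprintf("alpha0 = %-6g  At = %5.1f min   endpoint = %5.1f a.u.\n",
              a0, at$at, ep))
}
#> alpha0 = 0.1     At = 193.1 min   endpoint =  77.6 a.u.
#> alpha0 = 0.0001  At = 599.6 min   endpoint =  37.4 a.u.
```

A 1000-fold (3-decade) smaller trigger delays `At` by ~406 min
(3 × ln10/r_exp ≈ 3 × 135 min) and lowers the endpoint by ~40 signal
units (the gain is 0.1 /min), which is the whole trick: the endpoint is a
linear function of `At`.

```r
# linear-amplifier characterization (template preloaded with its input)
ts <- simulate_ode(build_linear_module(5, 125, preactivated_frac = 1),
                   3000, 2)
linear_phase_fit(get_trace(ts, "omega"))
#> linear phase: gain = 0.2493 signal/min, saturation = 125,
#>               window = 501.8 min (r2 = 1.0000)
```

Gain = `k_lin·[template]` (0.05 × 5), saturation = reporter total, window
≈ saturation/gain — the three independently tunable knobs of the linear
stage.

```r
# endpoint microRNA assay: calibrate on a synthetic plate, then quantify
plate <- generate_plate(calibration_series(), seed = 11)
obs <- merge(plate$wells, analyze_wells(plate, t_end = 1000),
             by = "well_id")
std <- obs$true_molar > 0
m <- fit_sigmoid(log10(obs$true_molar[std]), obs$endpoint[std])
m$lod_molar <- lod(m, obs$endpoint[!std])$lod_molar
m
#> Endpoint calibration sigmoid f(x) = L + H/(1 + b exp(-k (x - x0)))
#>   L = 20.79, H = 70.99, b = 1, k = 0.8677 per log10 M, x0 = -11.47
#>   residual sd = 3.792; calibrated range 1e-15 .. 1e-9 M
#>   LoD = 4.84e-15 M

quantify_endpoints(m, c(35, 60, 80))
#>   well_id endpoint_used estimate_molar flag
#> 1    W001            35   8.543879e-14   ok
#> 2    W002            60   5.889810e-12   ok
#> 3    W003            80   2.447128e-10   ok
```

Endpoint signals of 35, 60 and 80 a.u. map back through the inverted
calibration to ~85 fM, ~5.9 pM and ~245 pM; signals outside the
invertible band or under the LoD come back flagged
(`below_range`/`above_range`/`below_lod`) instead of as numbers.

A thin command-line wrapper over the same functions lives in
`inst/cli/celia.R` (subcommands `simulate`, `analyze`, `calibrate`,
`panel` — the last runs the full synthetic 54-sample panel demo).

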