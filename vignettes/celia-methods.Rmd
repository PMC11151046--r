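---
title: "Modelling coupled exponential-to-linear DNA amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coupled exponential-to-linear DNA amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celia)
```

## The circuit family

`celia` models isothermal DNA/enzyme reaction circuits built from the
polymerase–exonuclease–nickase (PEN) toolbox, in which an EXPAR-like
exponential amplification switch is coupled to a downstream *linear*
amplifier so that a single endpoint fluorescence reading carries the
quantitative information normally obtained by real-time monitoring. The
building blocks are:

* **Exponential switch** — an amplification template autocatalytically
  replicates the trigger strand $\alpha$ through polymerization/nicking
  cycles; a pseudotemplate deactivates $\alpha$
  ($\alpha \to \alpha_i$), acting as a tunable threshold/delay; an
  exonuclease degrades free strands; a quenched hairpin reporter reads
  $\alpha$ in the green channel. The amplification time $A_t$ — the first
  threshold crossing of that channel — is linear in
  $-\log_{10}$ of the initial trigger (or target) amount.
* **Linear amplifier** — a template irreversibly activated by $\alpha$
  (type IIS nicking design) produces the secondary strand $\omega$ at a
  constant rate; $\omega$ reacts irreversibly with its reporter. The slope
  (gain) is $k_\mathrm{lin}\,[\alpha to\omega]$, the plateau is
  $s_F\,[rT\omega]$, and the linear window is their ratio. The endpoint at
  a fixed readout time $T$ is therefore
  $\mathrm{gain}\cdot(T - A_t - \delta)$ with a small constant onset delay
  $\delta$ — an analog record of $A_t$, hence of the log-concentration.
* **Inverter (NOT gate)** — a constitutively active variant driven by a
  $\beta$ strand that binds its template *reversibly* (type IIP nicking
  design, quasi-equilibrium occupancy $\beta/(K_\beta+\beta)$). When
  $\alpha$ amplifies, a killer template produces the degradable
  pseudotemplate $pT\beta$, which deactivates $\beta$ and stops $\omega$
  production: the endpoint becomes *positively* correlated with $A_t$.
  The killer template also leaks $pT\beta$ slowly without $\alpha$.
* **MicroRNA converter** — transduces a microRNA input (a recycled
  catalyst) into a constitutive $\alpha$ source with Michaelis-type
  saturation, $k_\mathrm{conv}[miRto\alpha]\, c/(K_\mathrm{conv}+c)$.

## Rate-law reduction

No rate equations accompany the original circuit descriptions, so each
template's enzymatic polymerization/nicking cycle is lumped into a single
phenomenological production term — first order in the template, saturating
(Michaelis) in the loading strand — the standard desk-scale reduction for
PEN circuits. Enzymes are not explicit species; their activities are
absorbed into the rate constants. Two reporter semantics are used: the
$\omega$ reporter is consumed irreversibly (extension along the probe), so
its channel is non-decreasing and saturates at $s_F\,[rT\omega]$; the
$\alpha$ reporter is modelled as fast quasi-equilibrium hybridization
(signal $= s_F\,[rT\alpha]\,\alpha/(K_r+\alpha)$), since only its threshold
crossing matters.

The autocatalytic production is
$(r_\mathrm{exp}+k_\mathrm{deg})\,K_\mathrm{exp}\,\alpha/(K_\mathrm{exp}+\alpha)$,
so that the **net** low-$\alpha$ growth rate is exactly $r_\mathrm{exp}$
(the degradation loss is compensated), giving the closed-form shift
$\Delta A_t = \ln 10 / r_\mathrm{exp}$ per decade of input that the
threshold-crossing tests verify. The amplification template acts
structurally: with none present the production reaction is absent;
$r_\mathrm{exp}$ is defined as the net growth rate at the shipped template
load. Trigger loading onto the linear template is catalytic (the template
hybridizes only a few bases of $\alpha$; no sequestration of the trigger is
modelled).

## Default parameters

All concentrations are nM, all times minutes. The defaults are calibration
targets chosen once to reproduce the circuit family's reported behaviors,
not measured physical constants; every one is overridable.

| parameter | default | why |
|---|---|---|
| `r_exp` | 0.017 /min | ~135 min of $A_t$ shift per decade, matching an $A_t$ span of 10–1000 min over ~6 decades of input |
| `K_exp` | 60 nM | with `k_deg`, puts the $\alpha$ plateau near 100 nM |
| `k_deact` | 0.005 /nM/min | a few nM of pseudotemplate defers or defeats amplification |
| `k_deg` | 0.01 /min | slow exonuclease turnover of unprotected strands |
| `k_act` | 0.0025 /nM/min | places the linear-template activation onset ($\alpha \approx r_\mathrm{exp}/k_\mathrm{act}$) at the detection threshold, so the linear stage stays below 1% of saturation until the switch fires and then kicks in with a constant onset delay $\delta \approx 30$ min |
| `k_lin` | 0.05 /min | gain $0.1$ signal/min at the reference 2 nM template; linear window $[rT\omega]/(k_\mathrm{lin}[\alpha to \omega]) \approx 2000$ min at the 2 nM / 200 nM setting |
| `k_rep` | 0.1 /nM/min | reporting fast relative to production (quasi-steady $\omega$) |
| `K_r` | 10 nM | $\alpha$-probe half-saturation |
| `K_beta` | 5 nM | with $\beta_0 = 50$ nM the occupancy is buffered near 0.9, keeping the inverter's constitutive rate nearly constant |
| `k_kill`, `leak_kill`, `k_degP` | 0.2, 0.001, 0.02 | $pT\beta$ rises within ~1 h of amplification; the leak alone produces a slow, visible droop of the $\omega$ rate |
| `k_conv`, `K_conv` | 0.001 /min, 1 nM | femtomolar-to-nanomolar targets map to $A_t \approx 80$–900 min at 10 nM converter |
| `s_F` | 1 signal/nM | arbitrary fluorescence scale; instrument scaling belongs to the noise model |

Default template loads: amplification 20 nM, $\alpha$ reporter 50 nM,
linear template 2 nM, $\omega$ reporter 200 nM, converter 10 nM, inverter
templates 2 nM with $\beta_0 = 50$ nM. The killer template defaults to
2 nM: a larger load shortens the post-$A_t$ inhibition delay (~2 h here) at
the price of a larger leak, and this value keeps the endpoint–$A_t$
relation linear over $A_t \approx 10$–800 min, the regime in which $\beta$
depletion completes before the 1000-min readout.

The default **assay** circuit also carries a background initiator
$\alpha_0 = 10^{-5}$ nM representing nonspecific priming. Blank wells
therefore amplify late (around 730 min) instead of never, which is what
makes a blank-based limit of detection meaningful and places it in the
femtomolar range; without it the LoD would be degenerate ("below the
lowest calibrated concentration").

## Simulation

`simulate_ode()` integrates the network with LSODA (automatic
stiff/non-stiff switching; relative tolerance $10^{-8}$, absolute
$10^{-12}$ nM) and samples the dense solution on a uniform grid (default
cadence 2 min, plate-reader-like). Output concentrations are clipped at
zero; the clip magnitude is recorded and stays at numerical-noise level
($<10^{-9}$ nM in the shipped tests). Halving the output cadence or
tightening the tolerance tenfold leaves the channels unchanged to well
below $10^{-4}$ relative. `simulate_ssa()` is a hand-written Gillespie
direct-method oracle for validating the deterministic integrator on small
volumes; saturating laws are evaluated on counts converted to
concentrations (a mean-field hybrid), so it is documented as an oracle,
not as a small-copy-number model.

## Trace observables

* **Amplification time** — first crossing of a threshold by the
  baseline-subtracted signal, linearly interpolated between samples. The
  baseline is the mean of the first $\min(3,\lceil n/10\rceil)$ samples
  (at least one), which leaves short, already-baselined traces untouched.
  Thresholds are either a fixed absolute level shared across wells or a
  fraction (default 0.2) of the trace's own plateau, robust to per-well
  optical rescaling.
* **Gain / saturation / window** — the plateau is accepted when the final
  5% of the trace has local slope below 1% of the peak slope (otherwise
  the trace is censored at its end); the window is the interpolated time
  to 99% of the plateau. The gain is the least-squares slope over the
  central 80% of the *rising phase*, defined as the contiguous run around
  the peak smoothed slope where the local slope keeps at least half of it.
  This slope-based definition tracks the developed linear regime and is
  invariant under time-translation of the amplification, so the fitted
  gain is condition-independent: noise-free, its CV across amplification
  conditions with at least ~250 min of developed linear phase is ~1–3%,
  and under the default optical noise it reproduces the designed ~5%.
* **Endpoint** — linear interpolation at the readout time.

## Calibration, LoD and quantification

Endpoint vs $\log_{10}$ molar concentration is fitted with the sigmoid
$f(x) = L + H/(1+b\,e^{-k(x-x_0)})$ by multi-start nonlinear least squares
(8 deterministic data-driven starts; best SSE wins, ties to the smallest
$k$). The shape parameter $b$ is not identifiable jointly with $x_0$
($b = e^{k\Delta}$ trades exactly against a midpoint shift), so the fit
holds $b = 1$ and absorbs it into $x_0$; the fitted curve is unaffected
and the caveat is reported by `summary()`. Blanks are excluded from the
fit (log of zero) and used only for the LoD, defined as the concentration
whose calibrated signal equals the blank mean plus three blank standard
deviations. Inversion is closed-form on the open band
$(L+\varepsilon,\,L+H-\varepsilon)$,
$\varepsilon = \max(\text{residual SD}, 10^{-6}H)$; outside it estimates
are censored (`below_range`/`above_range`), and in-band estimates under
the LoD are flagged `below_lod` and excluded from accuracy summaries.
Panel accuracy uses the symmetric fold difference
$\max(\hat c/c,\, c/\hat c) \ge 1$ (the only definition under which a
"mean fold difference of 2.3" is interpretable).

## Synthetic plates and the noise model

`generate_plate()` simulates the assay circuit per well at each sample's
spiked concentration and applies noise to the reporter channels only:
a per-(well, channel) lognormal optical scale (unit mean, CV 5% by
default), a per-well baseline offset (SD 0.02), and i.i.d. per-timepoint
additive noise (SD 0.01). RNG streams derive from (seed, well index,
channel), so plates are reproducible under well reordering. Kinetic
stochasticity is deliberately *not* part of the noise model — that is the
SSA oracle's job — because endpoint scatter is attributed to the scanner.

The random panel draws concentrations log-uniformly on 5 fM–100 pM
(the headline interval; the source also prints narrower variants of this
range, and the generator accepts any bounds). The calibration series is a
tenfold dilution from 1 fM to 1 nM in triplicate plus blank triplicates.

What the generator does **not** emulate: pipetting/volume errors,
carry-over contamination, cross-target interference, temperature drift,
enzyme batch effects, or instrument-specific export formats. Passing the
shipped tests therefore demonstrates the correctness and calibration of
the *pipeline* on data matching the stated noise model, not performance
on any particular instrument's raw exports.

## Problem sizes in the shipped tests

The test-suite simulations are desk-scale by design: 12-condition sweeps
for the endpoint–$A_t$ regressions (coupled and inverter), a 24-well
calibration plate and a 54-sample × 2-target panel for the end-to-end
recovery property, 200 seeded trajectories for each SSA comparison, a
fixed-step Euler cross-check at $dt = 10^{-3}$ min over 500 min, and a
$10^4$-draw check of the noise model's endpoint CV. The whole suite runs
in well under a minute of CPU.

## Known limitations

* Rate constants are phenomenological; absolute times/LoDs are
  calibration targets, and only the *relations* between observables
  (log-linearity of $A_t$, gain constancy, endpoint correlations,
  monotone six-decade calibration, femtomolar-range LoD) are asserted.
* $\alpha$ bound to the linear template is not sequestered from the
  exponential module; sensitivity to this choice has not been explored.
* The $\alpha$ reporter is modelled as recycled (quasi-equilibrium); if
  the probe were consumed, the plateau normalization of the fractional
  threshold would change, but not the interpolation logic.
* Enzymatic activity decay over long incubations is not modelled.
* Rolling-circle variants of the architecture are out of scope.
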