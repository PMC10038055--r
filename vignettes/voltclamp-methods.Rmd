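---
title: "voltclamp: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voltclamp: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the generative model behind the simulator, the estimators behind each
analyzer, the defaults and why they were chosen, and what a green test
suite does and does not establish.

## 1. The generative model

A cell is an ensemble of `N` identical, independent channels, each with
two independent gates.

**Activation gate.** Steady state
`p∞(V) = p_open_max / (1 + exp((V₀.₅,act − V)/k_act))` and
mono-exponential relaxation with time constant `τ_act` (constant, a
function of voltage, or 0 for an instantaneous gate). Scaling `p∞` by
`p_open_max` (rather than multiplying the current) makes the *stochastic*
open probability saturate below 1, which is what NSFA actually estimates
as `P₀`.

**Inactivation gate.** Steady-state availability
`h∞(V) = I_ss + (1 − I_ss)/(1 + exp((V − V₀.₅,inact)/|k_inact|))`, time
constant `τ_inact`. `I_ss` is the non-inactivating fraction; `I_ss = 1`
disables inactivation. `k_inact` is *stored and reported negative*: the
availability curve falls with depolarization, and inactivation slope
factors are conventionally printed with a negative sign even when the
fitting equation, taken literally, would require a positive one. The
fitter works with the magnitude and negates on output.

**Conduction.** Ohmic single-channel current
`i(V) = γ (V − V_rev)/1000` pA (pS·mV). No GHK rectification: every
analyzer in the chain assumes the linear-driving-force form, and the
simulator's job is to make the analyzers' assumptions true by
construction, so that any failure to recover parameters is the
analyzer's fault.

**Gating charge.** A per-cell charge pool
`Q∞(V) = N·q·e₀·Boltzmann(V; V₀.₅,g, k_g)` relaxing with `τ_gating`;
the gating current is `dQ/dt`. One relaxing pool, not a per-channel
stochastic process: ON-charge integration only constrains the total
displaced charge and its time scale.

**Measurement model.** Linear leak `g_leak·V`, capacitive transients
`A·ΔV·e^{−t/τ_cap}` at every step edge, and white Gaussian noise of
variance `b = noise_sd²`. Series-resistance voltage error is *not*
modeled (amplifier compensation is an acquisition-time operation).

**CDI.** Calcium-dependent inactivation is a phenomenological rate
multiplier `1 + cdi_rate·∫|I_ionic|dt` on the inactivation rate, active
only with the Ca carrier. Any monotone flux-dependent mechanism would do;
the package only needs the Ca/Ba *difference* (`cdi_index`) to be zero
without CDI and positive with it.

**BayK8644.** Modeled purely as raised `p_open_max` and slowed gate
kinetics (`apply_bayk()`), not as a ligand scheme — the agonist's only
role here is to put tail-current `P₀` in a range where the NSFA parabola
is well conditioned.

### Stochastic engine

Channels are simulated as aggregated state counts over the four gate
combinations; per time step the number of gate flips is drawn binomially,
vectorized across repeats. Transition probabilities use the **exact
two-state propagator** over one sample interval,
`P(C→O) = p∞(1 − e^{−Δt/τ})`, `P(O→C) = (1 − p∞)(1 − e^{−Δt/τ})`,
rather than the naive `1 − e^{−rate·Δt}` per-rate form. The naive form
biases the chain's equilibrium at order `(Δt/τ)²`, which is measurable
against the deterministic mode at 2000 repeats; the exact propagator
makes the stochastic mean equal the gate ODE at the sample times for any
step size, and the two modes agree within Monte-Carlo error by
construction. A stability guard still rejects `Δt/τ > 0.1`, where the
discrete chain under-resolves the gating-noise spectrum that NSFA
consumes. Deterministic mode propagates the gate expectations in closed
form per constant-voltage epoch (per-sample exponential updates when CDI
couples the rate to the current integral).

Simulations are seeded (`seed` in the model, overridable per call) and
bit-reproducible; sweeps always start from gate equilibrium at the
holding potential.

### Default parameter choices

| parameter | default | rationale |
| --- | --- | --- |
| `n_channels` | 1000 | ~1 channel/µm² on a 10-pF cell (1 µF/cm²), the order seen in surface-density estimates |
| `gamma_ps` | 4.6 | gives i ≈ −0.5 pA at a −49 mV tail with V_rev ≈ 60 mV, matching reported single-channel tail currents |
| `p_open_max` | 0.8 | agonist-bound (BayK) maximal open probability |
| `tau_act_ms` | 2 | activation time constants of a few ms at test potentials |
| `tau_inact_ms` | 500 | fast enough that a 5-s conditioning step reaches steady state (e^−10), slow enough to barely distort 50-ms test pulses |
| `tau_gating_ms` | 0.3 | ON-gating transients complete well inside the 2-ms integration window (1 − e^{−2/0.3} ≈ 99.9%) |
| `q_gating_e0` | 12 | ≈3 e₀ per voltage sensor × 4 domains |
| activation/inactivation Boltzmanns | WT Ca presets | population means of the wild-type characterization this package re-implements |
| sample rates | 50 kHz (short protocols), 20 kHz (5-s) | the acquisition rates of the original recordings |

The cell capacitance default (10 pF) is a typical HEK-293 value. Because
no published `G_max` or cell size accompanies the printed parameter sets,
absolute current densities are *free* choices here; only shape parameters
(`V₀.₅`, `k`, `V_rev`, `I_ss`, ratios) are recoverable targets.

Real inactivation is multi-component (fast + slow, VDI + CDI); the model
has a single VDI gate, so `τ_inact` is a *protocol-level* configuration:
500 ms for SSI work, seconds for 5-s-pulse work (a residual of 0.42 after
5 s corresponds to τ ≈ 5.8 s with `I_ss = 0`). One τ cannot reproduce
both at once, and the package does not pretend otherwise.

## 2. Analyzer conventions and numerics

**Windows and signs.** Inward current is negative pA everywhere. Time is
0-based in samples; epoch windows are half-open `[start, end)` so
segments partition sweeps exactly; ms→sample conversions round to
nearest with ties toward the earlier sample. The text exchange format
writes 9-significant-digit scientific notation, LF endings — a
`sweep_set` always serializes to identical bytes and write→read→write
round trips are byte-identical.

**Peak measurement.** The first 0.2 ms after step onset are blanked
(capacitive spike); the peak is the extremum of largest |I|, signed, so
sweeps beyond `V_rev` contribute positive currents to the I-V fit.

**I-V fit.** `nls` (port) with deterministic initialization — `V_rev`
from the highest-voltage sign change, `V₀.₅` from the half-amplitude
crossing, `k = 8`, `G_max` from the supra-peak slope — plus four
deterministically jittered restarts (fixed internal seed), best SSR wins.
`v_max` is reported at the measured grid level (ties toward the more
hyperpolarized level; printed `V_max` values in the field reflect the
sampled grid), with the continuous argmax reported separately. The
activation threshold is solved on the *fitted* curve's hyperpolarized
flank at 5% of the continuous peak amplitude, by bisection to 0.001 mV
(a dense-grid oracle in the tests agrees to 0.02 mV); a printed "voltage
at 5% of current density" could also be read off raw normalized data,
but the fitted-curve reading is smoother and is the default.

**Conductance transform.** Implemented as `G = I·1000/(V − V_rev)`. The
commonly printed form of this equation is typographically garbled
(sign and denominator); dimensional consistency with the I-V fit equation
forces the version used here, which gives `G ≥ 0` for a conducting
channel and `G(V₀.₅) = G_max/2`.

**Kinetics.** Mono-exponential fit of the blanked rising phase; a
bi-exponential candidate is accepted only at ΔAICc > 2 and flagged
(flagged traces are conventionally omitted from τ summaries). A
numerically perfect candidate fit maps to AICc −∞ deliberately.

**SSI.** Availability is the post/pre test-pulse peak ratio *within each
sweep* (cancels slow rundown). Two small, understood biases exist:
during the 50-ms test pulse the inactivation gate keeps relaxing, and at
strongly depolarized conditioning the post-pulse current partially
*recovers* toward `h∞(V_max)` — both are absorbed almost entirely by the
fitted `I_ss` and shift `V₀.₅,inact`/`k` by well under 0.01 mV at the
default τ; the raw availability floor can sit a few % above `I_ss`.

**r250 / residual_after.** `I(t)/I_peak` at the sample nearest `t` with
the global extremum of the step as the peak (the normalization when
currents peak late is not standardized; the global extremum is used and
documented). The textbook closed form `r250 = e^{−250/τ}` holds only
when `h∞ ≈ 0` at the step potential — the test fixture steps far above
the inactivation midpoint for exactly this reason.

**Q_ON.** Trapezoidal integral over the first 2 ms at the sweep closest
to the fitted `V_rev` (warning beyond 2 mV mismatch). Units pA·ms = fC;
`e₀ = 1.602·10⁻⁴ pA·ms`. Charge conservation (integral = `N·q·e₀` over a
saturating step) holds within 1% because `τ_gating ≪ window`.

**NSFA.** Mean and unbiased variance across sweeps at each tail sample;
analysis window from 0.1 ms after the mean-tail peak (the "shortly after
the peak" start is not standardized; the offset is configurable and
recorded) down to 5% of the tail peak; equal-count binning into 50 bins;
*unweighted* least squares of `σ² = iI − I²/N + b` by default, for
reproducibility. Options: successive-difference variance estimator (for
rundown-contaminated data) and iteratively reweighted fitting with
weights `1/σ̂⁴` (the sampling variance of a sample variance). A parabola
opening upward is a hard error ("variance not saturating"), not a
negative-N estimate. `P₀ = I_peak/(iN)`; density uses 1 pF = 100 µm².
Fitted `i` is signed (negative for inward tails) with the magnitude
reported alongside, since published single-channel currents are usually
magnitudes.

**Statistics.** Shapiro-Wilk on every group; *any* p < 0.05 routes the
whole comparison to the rank branch (the conservative reading of
"depending on whether data were normally distributed" — no published
rule states the aggregation). Two groups: pooled-variance t or exact
Mann-Whitney; more: ANOVA with Bonferroni pairwise t (pooled SD) or
Kruskal-Wallis with Dunn's rank-sum z and Bonferroni family correction.
The branch can be forced for oracle testing. Selection is a pure
function of the normality flags and is recorded in the output.

## 3. What the synthetic tests do and do not establish

The simulator makes every analyzer assumption true by construction:
Boltzmann steady states, mono-exponential gates, ohmic conduction,
binomial channel statistics, white Gaussian background. Green tests
therefore establish *estimator correctness* — each fitter recovers the
parameters of data generated under its own model, to stated tolerance,
and the error paths fire on degenerate inputs. They do **not** establish
robustness to what real recordings add: series-resistance error,
rundown, multi-component inactivation, flicker/block noise, filters with
phase distortion, imperfect space clamp. Where a robustness lever exists
(successive-difference variance, variance weighting, configurable
windows) it is exposed and unit-tested, but not exercised against real
pathology.

NSFA at 400 sweeps has inherent single-cell Monte-Carlo error of order
10–20% in `N` (adjacent tail samples share sweeps, so the effective
number of independent variance observations is far below the window
length). The recovery test pins the fixture seed — the package default
`seed = 1`, set when the model type was designed — and the consistency
test checks that error shrinks as sweeps grow; neither claims that every
seed lands inside 10/15%.

The I-V grid (−80 to +70 mV, Δ5 mV) is a configuration choice: published
tables state Δ10 mV only for the 300-ms r250 protocol, and the 50-ms I-V
increment is unstated. The acceptance round trips disable inactivation
(`I_ss = 1`) so the 50-ms peaks are exactly Boltzmann-shaped; with the
inactivating preset the same pipeline lands within ~0.06 mV (see the
README example), which is the honest size of the protocol-induced bias.

## 4. Known limitations

* No GHK flux, no ω-current pathway, no OFF-gating analysis, no
  recovery-from-inactivation protocol, no ABF binary I/O (the text
  dialect is the exchange format; an ABF adapter would sit behind the
  same `sweep_set` contract).
* Gating current is deterministic; gating-charge *fluctuation* analysis
  is out of scope.
* One inactivation gate: protocols probing fast and slow inactivation
  simultaneously need per-protocol τ configuration.
* `compare_groups` implements the two conventional decision trees only;
  it is not a general statistics front end.
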