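---
title: "A calibrated lumped-parameter model of the left heart and circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibrated lumped-parameter model of the left heart and circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiolpm)
```

## The model

`cardiolpm` simulates the left atrium (LA), left ventricle (LV), aortic and
mitral valves, and the systemic and pulmonary circulations as a
zero-dimensional electrical-analog network, and calibrates that network per
patient from quantities measurable without catheterization: Doppler
echocardiography and a brachial cuff. Its outputs are full pressure, flow
and volume waveforms over one steady heartbeat; PV-loop stroke work
("LV workload"); transvalvular gradients; and counterfactual
"correct one disease constituent at a time" workload breakdowns for
intervention planning.

### Chambers

Each chamber couples pressure to volume through a time-varying elastance,

$$P(t) = E(t)\,\bigl(V(t) - V_0\bigr),$$

with $V_0$ the unloaded volume. The normalized elastance waveform is a
double-Hill curve: an ascending Hill term for contraction (sigmoidal, the
shape of cooperative myocyte recruitment) multiplied by a descending Hill
term for relaxation,

$$E_N(t) = N\,
  \frac{(t/\tau_1)^{m_1}}{1 + (t/\tau_1)^{m_1}}\,
  \frac{1}{1 + (t/\tau_2)^{m_2}} + E_{min}, \qquad
  N = \tfrac{1}{2}(E_{max} - E_{min}).$$

The default parameters (LV: $E_{max}$ 2.1, $E_{min}$ 0.06 mmHg/mL,
$m_1$ 1.32, $m_2$ 27.4, $\tau_1$ 0.269 T, $\tau_2$ 0.452 T; LA: 0.17, 0.06,
1.32, 13.1, 0.110 T, 0.18 T) are standard adult values; $\tau_1, \tau_2$
scale with the cycle period T, so one parameter set serves any heart rate.
LA contraction is phase-shifted to begin at 0.85 T, i.e. 0.15 T before the
next ventricular systole, with the curve wrapping across the cycle
boundary.

**Elastance scaling.** The curve above does not have a unit peak, so
"normalized" admits three readings, all implemented behind a strategy flag
(`run_config(strategy = ...)`):

* `peak-rescaled` (default) — affinely rescale the raw Hill product so the
  chamber elastance attains exactly $E_{max}$ at its peak and $E_{min}$ at
  its trough. This honors the definition of a normalized curve
  ($E_N = E/E_{max}$ has unit peak) and gives physiological left-atrial
  volumes (roughly 30–160 mL in the cases below) and transvalvular
  gradients consistent with published severe-stenosis cohorts.
* `emax-scaled` — multiply the curve by $E_{max}$ literally. Because the LA
  curve's minimum is then $0.17 \times 0.06 \approx 0.01$ mmHg/mL, the LA
  behaves as an implausibly compliant bag (several hundred mL); we keep
  the strategy for comparison.
* `literal-eq3` — read the curve directly as mmHg/mL.

The strategy in force is recorded in every result's metadata.

### Valves

Each valve branch is an inertance in series with a flow-dependent
Bernoulli resistance, the net transvalvular pressure gradient (after
pressure recovery) being

$$\Delta P = L\,\frac{dQ}{dt} + k\,Q\,|Q|,$$

computed in dyn/cm^2 and converted to mmHg (1 mmHg = 1333.22 dyn/cm^2).
For aortic branches $L = 2\pi\rho/\sqrt{E_LCo}$ and
$k = \rho/(2\,E_LCo^2)$ with the energy-loss coefficient
$E_LCo = \mathrm{EOA}\cdot A/(A - \mathrm{EOA})$ correcting the effective
orifice area for pressure recovery in the receiving vessel (ascending
aorta for forward flow, LVOT for the regurgitant jet). For mitral branches
pressure recovery is negligible (large receiving chambers), so
$L = M_{MV}/\mathrm{EOA}$ with the inertance constant
$M_{MV} = 0.53$ g/cm^2 and $k = \rho/(2\,\mathrm{EOA}^2)$. The signed
$Q|Q|$ form keeps the gradient direction-consistent for transient reverse
flow. Branches behave as diodes: a closed branch opens when its driving
pressure turns positive and carries no flow otherwise; flow is clamped at
zero from below after every integration step rather than located by event
detection — at the 0.1 ms step this is accurate and keeps the integrator
simple.

Regurgitation severity is graded qualitatively from colour Doppler and
mapped to representative regurgitant orifice areas on the clinical cm^2
scale: mild 0.05, mild-moderate 0.10, moderate-severe 0.25, severe
0.35 cm^2 (`grade_to_regurgitant_eoa()`). A competent valve contributes no
branch at all. A paravalvular leak after valve replacement is modelled as
aortic regurgitation through the same branch.

### Network topology

The right heart is not modelled; a prescribed pulmonary-valve flow source
replaces it — a rectified sine of amplitude $Q_{MPV}$ and duration equal
to the ejection time, zero for the rest of the cycle. From there:
source → pulmonary arterial capacitor $C_{PA}$ →
($R_{PA} + R_{PC}$ in series with inductor $L_{PC}$) → pulmonary venous
capacitor $C_{PVC}$ → ($R_{PVC} + R_{PV}$ with $L_{PV}$) → LA →
mitral branches → LV → aortic branches → aortic capacitor $C_{ao}$ →
$R_{ao}$ → junction, from which the upper-body resistance $R_{ub}$ drains
directly to the central venous pressure $P_{CV0} = 4$ mmHg, and
$R_{pda} + R_{SA}$ lead through the systemic capacitor $C_{SAC}$ and
$R_{SV}$ to $P_{CV0}$. The junction carries no capacitor; its pressure is
solved algebraically from Kirchhoff continuity at every derivative
evaluation. Every element appears exactly once; the wiring reproduces the
described flow paths (aorta, upper body, descending aorta, systemic
arteries and veins). Blood volume is not globally conserved across the
source/sink pair — per-cycle steady-state consistency is enforced instead
through the $Q_{MPV}$ calibration.

The 12-component state comprises the two chamber volumes, four valve
branch flows, four capacitor pressures and two pulmonary inductor flows.
`assemble_odes()` exposes the right-hand side for inspection; the
integrator runs in compiled code.

## Numerical scheme

The network is integrated cycle by cycle with the classical fourth-order
Runge-Kutta scheme at a fixed 0.1 ms step (`run_config(dt = 1e-4)`). The
system is non-stiff at this resolution — the fastest time constant, a
severe mitral-regurgitation branch under load, is ≈0.4 ms — and the fixed
step makes valve clamping and elastance tabulation exact and cheap
(elastance and source waveforms are precomputed once per run on the RK4
node grid).

**Periodic steady state.** A run is declared steady when the forward
stroke volume and the aortic pressure extrema each change by less than
`steady_tol` (relative, default 1e-5) between consecutive cycles. The
dominant transient — filling of the venous and atrial compliances — decays
with time constants of tens of seconds, so plain cycling would need
hundreds of beats. An Aitken-type extrapolation of the cycle-to-cycle
state map (per state component, applied every third cycle, extrapolation
gain capped at 300) jumps along this slow mode; it disengages by itself
once the deltas fall to integration-noise scale. With it, cold starts
reach steady state in 20–120 cycles and warm starts in well under 50; the
cap means a noisy ratio estimate can at worst slow convergence, not
destabilize it. The default `steady_tol = 1e-5` is deliberately tight:
at 1e-4 the residual beat-to-beat drift (a few tenths of a mmHg,
path-dependent through warm starts) is on the same scale as the pressure
calibration tolerance and destabilizes the least-squares step.

Degenerate configurations (e.g. a near-zero compliance) make the explicit
step unstable; the integrator detects the resulting non-finite state and
raises an error rather than returning NaNs. A run that fails to become
periodic within `max_cycles` (default 500) errors with the last cycle's
metrics attached, or returns flagged `steady = FALSE` when
`allow_unsteady = TRUE`.

The final steady cycle is resampled to 1000 uniform points for waveform
output and metrics; scalar cycle metrics (stroke volumes, pressure
extrema) come from the dense solver grid.

## Patient-specific calibration

Inputs per patient (`patient_inputs()`): forward LVOT stroke volume, cycle
period, ejection time, aortic and mitral effective orifice areas, aorta
and LVOT cross-sections, regurgitant orifice areas (or absent), and cuff
systolic/diastolic pressures. All can be derived from raw Doppler
measurements (`build_patient_inputs()`): stroke volume as
$A_{LVOT} \times VTI_{LVOT}$, aortic EOA by the continuity equation,
mitral area as the ellipse $\pi d_1 d_2 / 4$, volumes by the biplane
formula $V = A_1 A_2 / \mathrm{mean}(L_1, L_2)$ — implemented exactly in
this form, with the conventional $8/(3\pi)$ biplane-ellipsoid factor
available behind a flag for comparison, defaulting to the form above for
fidelity to the source formulation.

Calibration alternates two response-optimization steps until all targets
hold simultaneously (`calibrate_full()`):

1. **Flow step** (`calibrate_qmpv()`): the source amplitude $Q_{MPV}$ is
   solved (secant iteration with a bisection fallback on the bracket
   50–800 mL/s) so the simulated forward LVOT stroke volume matches the
   measured one within 0.1 mL.
2. **Pressure step** (`calibrate_systemic()`): $R_{SA}$, $C_{ao}$ and
   $C_{SAC}$ are fitted by bounded Levenberg-Marquardt least squares so the
   simulated aortic pressure extrema match the cuff systolic and diastolic
   pressures within 0.5 mmHg. Two pressure targets cannot pin down three
   parameters — the two compliances trade off along a flat manifold — so
   the residual vector carries two weak log-scale pulls (weight 0.05)
   toward the starting compliances. These select one point on the manifold
   and satisfy the least-squares routine's requirement of at least as many
   residuals as parameters; at the 0.5 mmHg scale they are inert. The
   observable match, not parameter uniqueness, is the contract. The
   optimizer restarts (fresh trust region) up to three times if it stalls
   above tolerance.

$R_{SA}$ is initialized from the measured mean arterial pressure (cuff
estimate $DBP + PP/3$) divided by cardiac output, minus the fixed
$R_{ao} + R_{SV} + R_{pda}$. When a measured end-diastolic volume is
supplied, the LV unloaded volume $V_0$ is additionally adjusted by secant
iteration (0.5 mL tolerance) so the simulated EDV matches; otherwise
$V_0 = 0$ for both chambers (its value is not separately identifiable from
the calibration targets). Pulmonary constants are excluded from
optimization: their influence on the outputs is negligible, and they stay
at their table values. All simulations inside calibration warm-start from
the previous solution's state.

The two steps alternate to joint convergence (outer loop capped at 20;
single-pass behaviour is available via `max_outer = 1`). In the cases
below, 1–4 outer iterations suffice.

**Upper-body resistance.** $R_{ub}$ is not patient-fitted; it is set once
(`calibrate_upper_body()`) so the upper-body branch carries 15% of
cycle-mean systemic flow in a fixed healthy baseline: aortic EOA 3.0 cm^2,
mitral EOA 4.0 cm^2, no regurgitation, 120/80 mmHg, 70 mL forward stroke
volume, 70 bpm, aorta 3.0 cm and LVOT 2.0 cm diameters, ejection time
0.3 T. The scalar solve interleaves with full recalibration until the 15%
split holds within 0.1 percentage points in the recalibrated model.

## Metrics and the counterfactual breakdown

LV workload is the area of the pressure-volume loop over one steady cycle
(shoelace rule; 1 mmHg mL = 1.33322e-4 J). Transvalvular gradients are
computed on $P_{LV} - P_{ao}$ during forward ejection (mean over the
conducting interval, and peak). `rms_error()` with `resample_waveform()`
compares a simulated pressure waveform against an external reference
tracing on a common uniform grid.

`workload_breakdown()` replaces each disease constituent by its normal
condition one at a time — stenotic aortic or mitral valve to the
configured normal areas (defaults 3.0 / 4.0 cm^2), regurgitant branch
removed — recalibrates the counterfactual model *to the same measured
targets* (predicted-intervention semantics), simulates, and compares
workloads. The default convention reports the percent *decrease*
$100\,(W_{dis} - W_{cf})/W_{dis}$ achieved by correcting that constituent,
i.e. the predicted percent reduction in LV workload following that
intervention; the percent-excess convention
$100\,(W_{dis} - W_{cf})/W_{cf}$ is available via
`convention = "increase"`. We chose the decrease convention because it is
the quantity an interventionalist ranks, and because it is the convention
under which the two published reference contributions for the mixed
aortic-stenosis/mitral-regurgitation case study are mutually consistent
with our computed loop areas. A per-constituent calibration failure is
reported in the result table without aborting the other constituents.

## The synthetic-patient generator

`synthesize_patient()` emulates a TAVR-referral cohort, not a general
population. Sampling ranges follow the cohort statistics of that setting:
pre-intervention aortic EOA ~ N(0.58, 0.16) truncated to [0.3, 0.95] cm^2,
heart rate N(70.7, 9.5), cuff pressures N(139, 22.5)/N(79, 11.7), forward
stroke volume N(48.3, 11.7); post-TAVR prosthetic EOA N(1.75, 0.4),
pressures N(135, 16.8)/N(68, 10.3); regurgitation grades drawn with
probabilities matching the reported grade-2-or-worse prevalences (~48% AR,
~19% MR pre-intervention). Profiles: `healthy`, `severe-as`,
`severe-as-mr`, `post-tavr`, `hypertensive`. Generation is deterministic
per (profile, seed) and restores the caller's RNG state.

What the generator does *not* emulate: measurement error and
intra-observer variability of Doppler readings, atrial fibrillation or any
beat-to-beat variability, ventricular dysfunction (elastance parameters
are never sampled), and correlations between inputs beyond the range
truncations. Passing calibration round-trips on synthetic patients
therefore demonstrates that the estimation machinery recovers consistent
targets across the cohort's input ranges — not that the model reproduces
any individual real patient's hemodynamics.

## Worked example

```{r example, eval = FALSE}
# severe aortic stenosis with mild AR and moderate-to-severe MR
T <- 60 / 70.7
patient <- patient_inputs(
  forward_lvot_sv = 54, T = T, t_ej = 0.3 * T,
  eoa_av = 0.5, eoa_mv = 4.0,
  a_ao = circular_area(3.0), a_lvot = circular_area(2.0),
  eoa_ar = grade_to_regurgitant_eoa("mild"),
  eoa_mr = grade_to_regurgitant_eoa("moderate-severe"),
  sbp = 115, dbp = 40
)
report <- calibrate_full(patient)
hemodynamic_metrics(report$result)
workload_breakdown(report)
```

Calibrated to this patient's 54 mL stroke volume and 115/40 mmHg cuff
pressures, the model reports a 12,767 mmHg mL (1.70 J) LV workload, peak
LV pressure 153 mmHg against 115 in the aorta, and mean/maximum aortic
gradients of 42/77 mmHg. The breakdown attributes the workload mostly to
the mitral regurgitation (48% predicted decrease if corrected) and the
aortic stenosis (46%), with mild AR nearly neutral — so mitral repair
ranks first for this disease mix.

## Problem sizes and runtime

One cardiac cycle is ~8,500 RK4 steps (~1 ms of CPU); a cold-start
simulation runs in well under 0.2 s and a full patient calibration in
1–10 s depending on disease mix. The test suite calibrates ten synthetic
patients end-to-end plus the case studies in a few minutes; these sizes
were chosen so that every property is exercised at full fidelity (no
reduced-step or reduced-tolerance shortcuts) while the whole suite stays
interactive.

## Known limitations

* No right heart, baroreflex, respiratory coupling or wave propagation;
  the prescribed pulmonary inflow fixes the timing and shape of venous
  return.
* The two-residual/three-parameter pressure step returns one point on a
  solution manifold; reported compliances are representative, not
  identified.
* Counterfactual breakdowns keep the measured cuff pressures as targets.
  After a real intervention the arterial state changes (both case-study
  patients were hypertensive post-TAVR), so predicted workload decreases
  for stenosis correction exceed observed pre-to-post decreases.
* Regurgitant-grade mapping uses fixed representative orifice areas; the
  clinical grade bins span ranges.
* The elastance parameter set is population-typical; patient ventricular
  function enters only through $V_0$ when a measured EDV is supplied.
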