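---
title: "Modelling and calibrating circle of Willis hemodynamics with cowflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and calibrating circle of Willis hemodynamics with cowflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

## The model

cowflow simulates cerebral blood flow with a lumped-parameter (0D,
electrical-analog) arterial network. Each artery segment is a uniform,
thin-walled, homogeneous deformable tube characterized by three lumped
elements:

* viscous resistance from laminar Hagen–Poiseuille flow,
  $R = 128 \mu l / (\pi d^4)$;
* blood inertance, $L = 4 \rho l / (\pi d^2)$;
* wall compliance from the thin-wall elastic tube law,
  $C = \pi d^3 l / (4 E h)$, with wall thickness $h = 0.1\,d$.

The tube diameter $d$ is the *volume-equivalent diameter* of the segment:
the uniform-tube diameter preserving the lumen volume of the vessel measured
at several points along its course
($d_{eq} = \sqrt{\sum_i d_i^2 l_i / \sum_i l_i}$; equal sub-lengths are
assumed unless measured positions are supplied — thirds for the
three-point ICA/MCA/ACA/PCA measurements, halves for the two-point basilar
measurement).

The common network has 33 segments: 18 cerebral segments resolving the
circle of Willis (bilateral distal ICA, M1, A1, A2, P1, P2, posterior
communicating and intracranial vertebral arteries, plus the anterior
communicating and basilar arteries) and 15 systemic segments (aorta, iliac,
subclavian, common carotid, extracranial ICA and vertebral arteries) that
provide the background circulation. A patient-specific network is obtained
by replacing the reference diameters with the measured ones; a segment
whose diameters are all 0 is absent and is pruned, after which every
Windkessel territory must remain reachable from the aortic root (otherwise
the build fails with a named "non-perfusable territory" error). Segment
lengths are not patient measurements; the shipped values are a declared
convention from standard adult anatomy, overridable per patient, and frozen
in the versioned topology file `inst/extdata/cow33_topology.json`.

A prescribed flow waveform drives the root of the ascending aorta — by
default a half-sine systolic ejection over 35% of the cycle integrating to
a 70 ml stroke volume, with the period taken from the patient's heart rate.
The stroke volume is a convention shared by the simulator and the
calibration, because neither TCD nor cuff pressure constrains cardiac
output in this model class. Each of the 11 outlets carries a three-element
Windkessel (WK3): proximal resistance $R_p$ (10% of the total by default, a
characteristic-impedance convention) in series with distal resistance $R_d$
parallel to a compliance $C$, referenced to a venous pressure of 5 mmHg.
Outlet compliances are seeded from a peripheral time constant,
$C = \tau / R_d$, with $\tau = 1.3$ s for the systemic territories (total
peripheral compliance ≈ 1.3 ml/mmHg, a physiological total arterial
compliance) and $\tau = 0.06$ s for the cerebral territories. The split
matters: intracranial arterial beds are far stiffer than systemic ones,
and a uniform time constant nearly shorts the pulsatile cerebral load,
producing flow pulsatility several times the mean with pan-cerebral
diastolic reversal — which real TCD never shows. With the cerebral value
chosen so the simulated middle-cerebral pulsatility index sits in the
physiological 1–1.5 range, diastolic cerebral flow stays positive across
the virtual cohort. All of these are configuration keys, not constants.

### Wall viscoelasticity

A purely elastic RLC ladder rings at ~50 Hz (aortic inertance against wall
compliance) with a decay time of several seconds, which no real artery
exhibits: arterial walls are viscoelastic. Each junction node therefore
lumps half of every incident segment's compliance behind a Voigt-type
series resistance $R_v = \tau_w / C_{node}$ with wall relaxation time
$\tau_w = 5$ ms (configurable; 0 recovers the purely elastic wall). This
damps the non-physiological high-frequency modes, changes the input
impedance by only a few percent at the heart rate, and leaves mean (DC)
flows exactly unchanged.

## Numerics

The assembled system is linear and time-invariant: states are the segment
flows (through the inertances), the node capacitor pressures and the WK3
compartment pressures, with the inflow the only forcing. The default
integrator is therefore an *exact* matrix-exponential stepper: one matrix
exponential of the augmented system per run, then one matrix-vector product
per output step, with the inflow interpolated piecewise-linearly (and
renormalized so the sampled waveform delivers the stroke volume exactly —
the sampling bias $(\pi \Delta t / T_s)^2/12 \approx 2\times10^{-4}$
otherwise leaks into every calibrated parameter). This stepper is A-stable
and exact for the LTI network, so the wide spread of RC time constants
across terminals costs nothing. A conventional stiff adaptive integrator
(`deSolve::lsoda`) is retained as an independent cross-check route and the
two agree to ~1e-4 in the test suite.

Two auxiliary states accumulate inflow and venous-outflow volume, so volume
conservation (inflow − outflow = compliant storage change over a cycle) can
be audited to ~1e-12.

Simulations run cardiac cycles until the relative L2 difference between
consecutive cycles (pressures and flows separately) falls below the
periodicity tolerance (default 1%), plus one confirming cycle, capped at 10
cycles; from the DC starting state the default patient is periodic at 1%
within 5–6 cycles. For the calibration loops, where unbiased cycle means
matter more than the transient, the one-cycle return map is solved directly
for the exact periodic state (`init = "periodic"`), which makes cycle
averages coincide with the DC solution to discretization accuracy. Cycle
averages use composite Simpson quadrature on the 200-samples-per-cycle
output grid.

The mean-flow (DC) solve used by calibration step 1 is an independent nodal
conductance assembly (inertances shorted, compliances open, WK3 as a series
conductance to venous pressure) — it is not derived from the ODE matrices,
and the two routes are cross-checked against each other and against a
branch-variable oracle in the tests.

## Personalized calibration

Calibration personalizes the WK3 outlets and wall stiffness from three
clinical inputs: cuff systolic/diastolic pressure (mean pressure defaults
to $DBP + PP/3$ when not monitored), TCD mean velocities at up to nine
insonation sites, and the heart rate. TCD velocities convert to mean-flow
targets through the insonated segment's lumen, $Q = v \cdot \pi
d_{eq}^2/4$. The procedure runs three steps in order:

1. **Peripheral resistance** — a fixed point of the linear circuit model.
   The MCA, ACA and PCA sites each constrain one cerebral terminal: the
   terminal's target flow is the insonated segment's target corrected by
   the collateral flow the current DC solution routes around that segment
   (so communicating-artery exchange is honoured); uninstrumented
   territories share the remaining inflow in proportion to their feeding
   cross-sections, and the ICA and basilar sites remain as consistency
   checks. Because the inflow is a prescribed flow source, flow targets
   determine only resistance *ratios*; the mean blood pressure input
   anchors the overall level (the aortic-root mean pressure is driven to
   MAP inside the fixed point). Targets whose collateral correction implies
   a negative flow are floored at 5% of the area-proportional allocation,
   which keeps the implied resistances positive when noisy observations are
   mutually inconsistent.
2. **Systemic stiffness and peripheral compliance** — two shared
   multipliers (systemic Young's modulus; systemic WK3 compliances) are fit
   by a 2D quasi-Newton iteration so the simulated aortic-root systolic and
   diastolic pressures match the cuff values. In this network the pulse
   pressure responds monotonically to the *wall* stiffness, while the WK3
   compliance is partially masked by the proximal resistance at heart-rate
   frequency; the 2D solve needs no monotonicity assumption.
3. **Cerebral stiffness** — a shared multiplier on the cerebral Young's
   modulus is fit so the simulated systolic/diastolic flow ratio at the
   instrumented sites matches the TCD envelope ratio. With fixed WK3
   outlets, a *softer* cerebral wall shunts more pulsatile flow through the
   insonated segment, so the ratio decreases monotonically with stiffness;
   sites with near-reversing diastolic flow (ratio > 50) are excluded as
   uninformative. If no envelope velocities are supplied the step is
   skipped with a warning and the result flags the degradation.

The staged estimates are then polished jointly: a damped Gauss–Newton
(Levenberg–Marquardt) pass over all three multipliers against the full
residual vector (log SBP, log DBP, per-site log flow ratios). This matters
because the systemic compliance and cerebral stiffness couple weakly
through the pulse waveform — sequentially alternating steps 2 and 3 has a
loop gain near one, and collapsing the site ratios to their mean admits
spurious exact roots. With the full residual vector, a noise-free synthetic
patient is recovered to ~1e-6 (terminal resistances), ~1e-5 (systemic
multipliers) and ~5e-4 (cerebral multiplier).

Defaults: terminal resistance bounds $[10^6, 10^{12}]$ Pa s/m³, multiplier
bounds $[0.1, 10]$, step-1 tolerance $10^{-9}$ on the relative resistance
change (the DC solves are cheap, so there is no reason to stop at the
spec-level $10^{-3}$), pressure residual tolerance $2\times10^{-4}$ on the
log scale, ratio tolerance $10^{-5}$, at most 100/40/30 iterations per
step. All are arguments of `calib_config()`.

## The TCD observation model

`simulate_tcd_report()` maps the converged simulation onto the nine
standard insonation sites (bilateral distal ICA, proximal MCA, ACA,
basilar, bilateral PCA) and reports cross-section-average velocities
$v = Q/A$ in cm/s (mean, systolic, diastolic over the final cycle). The
ACA site maps to the pre-communicating A1 segment by default — the TCD
report does not distinguish A1 from A2, a known ambiguity — and the
mapping is overridable (`site_segment_map()`), e.g. to study the A2
alternative. No Doppler physics (insonation angle, spectral envelope, bone
window) is modelled.

## Agreement statistics

Measured-vs-simulated agreement uses the intraclass correlation coefficient
in its two-way random, consistency, single-rater form:
$ICC(C,1) = (MS_S - MS_E) / (MS_S + MS_E)$ from the two-way ANOVA with
subjects = paired artery observations and raters = {TCD, simulation}, so a
fixed systematic offset between the methods does not lower it. The 95%
confidence interval uses the exact F-distribution method. Limits of
agreement are computed on the base-10 logarithmic scale and reported as
multiplicative factors $10^{\bar d \pm 1.96 s_d}$ — "the simulation may
differ from TCD by $(1-\text{lower})$ below to $(\text{upper}-1)$ above".
Paired differences are tested with the Wilcoxon signed-rank test (exact for
n ≤ 25 without ties). Subgroup analysis computes the ICC per level of a
dichotomous label and flags whether the two 95% CIs intersect — overlap
meaning the difference is compatible with chance. Tests are two-sided at
α = 0.05 with no multiplicity correction.

## The virtual aSAH cohort

Because the clinical cohort behind this model class is not public, the
package generates virtual aneurysmal subarachnoid hemorrhage patients so
the whole chain can be validated end to end:

* **Anatomy** — reference diameters jittered log-normally (σ = 0.05)
  per patient; circle of Willis variants drawn by zeroing segments (ACoA
  10%, each PComA 25%, each A1 10%, each P1 15% — literature-typical
  incompleteness rates, configurable); a draw that disconnects a territory
  is rejected and redrawn. Vasospasm narrows 1–3 cerebral segments by
  20–50% in half of the patients, emulating the subacute post-hemorrhage
  window.
* **Hemodynamic truth** — instrumented cerebral territories receive 13% of
  cardiac output distributed by feeding area and perturbed log-normally
  (σ = 0.25, the scatter of "optimal" peripheral resistance); WK3
  terminals are fitted to those flows at a drawn MAP (SBP ~ N(145, 15),
  DBP ~ N(80, 10) mmHg, matching a hypertensive aSAH population). The
  drawn pulse pressure is projected onto the 30–55 mmHg range the lumped
  network can represent within the wall-multiplier bounds — the analogue
  of redrawing a non-perfusable anatomy — with DBP absorbing the
  projection so the SBP distribution (the stratification covariate) is
  preserved. The wall multipliers are then fitted so the simulated
  waveform reproduces the drawn cuff pressures and perturbed log-normally
  (σ = 0.15), so the cohort inherits the specified blood-pressure
  distribution while the true multipliers stay random.
* **Observations** — the truth simulation's site velocities with
  multiplicative log-normal noise (TCD error scales with magnitude,
  consistent with log-scale Bland–Altman analysis) and point diameters
  with additive Gaussian noise truncated at 0.2 mm. Vitals record the
  simulated SBP/DBP/MAP and the heart rate. Two feasibility rules mirror
  what real insonation can encode: a perturbation draw that reverses the
  net flow of a fitted insonated segment (a collateral steal the
  positive-antegrade observation model cannot represent) is redrawn, and
  sites whose mean velocity falls below a 1 cm/s detectability floor are
  omitted from the report — e.g. the basilar becomes a zero-flow stub
  when both P1 segments are absent, since its cerebellar side branches
  are not modelled and real TCD would find no signal there.
* **Labels** — a DCI-like flag marks patients whose peripheral-resistance
  perturbation deviates most from the area-proportional
  (Hagen–Poiseuille-consistent) allocation — a modelling convention
  mirroring the observation that such patients agree worst with the model,
  not a clinical claim. Fisher-like grades and aneurysm-location labels are
  drawn with frequencies typical of an aSAH cohort purely to exercise the
  subgroup analysis.

All randomness derives from a single spec seed via per-patient substreams,
so any patient is reproducible in isolation.

What the synthetic cohort does *not* emulate: operator- and bone-window-
dependent TCD error structure, beaded (non-uniform) vasospastic geometry —
the uniform-tube assumption cannot represent it — cerebral autoregulation,
within-cycle lumen variation, and any true anatomical covariance between
segment sizes. A perfect score on synthetic data therefore demonstrates
the internal consistency and identifiability of the pipeline, not clinical
accuracy on real patients.

## Validation summary

The test suite checks, among others: DC solves against an independent
branch-variable oracle on five analytic networks (1e-10); dynamic
integration against `lsoda`, the DC limit and the closed-form WK3
frequency response; volume conservation (1e-6); noise-free calibration
recovery on 20 virtual patients (terminal resistances within 2%, site mean
velocities within 1%, systemic multipliers within 5%, cerebral within
10%); agreement statistics against explicit sums-of-squares and exact
enumeration oracles; end-to-end noise-free cohort agreement (ICC > 0.99,
LoA factors within [0.98, 1.02]) with agreement degrading monotonically
(median over three seeds) across a 0–20% velocity-noise sweep; and
simulability with conservation for every single-segment circle of Willis
variant. Problem sizes — 20 recovery patients, a 50-patient noise-free
cohort, 8-patient sweep cohorts — were chosen as the smallest that make
the recovery and monotonicity properties unambiguous.

## Known limitations

* The basilar artery is a single lumped tube: its paired side branches
  (e.g. the cerebellar arteries) are neglected, which is the main reason
  basilar velocities are the least constrained quantity in this model
  class.
* Stroke volume is a convention, not a measurement; absolute flows are
  identified only up to the accuracy of that convention, though velocities
  at instrumented sites are fitted regardless.
* The cerebral stiffness multiplier is weakly identified (its effect on
  flow pulsatility is ~20× smaller than the systemic compliance's); it is
  recoverable on noise-free data thanks to the joint polish, but on noisy
  data it should be interpreted with caution.
* Lumped (0D) means no wave propagation: pulse-wave velocity and
  within-segment pressure gradients are outside the model.
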