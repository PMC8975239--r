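---
title: "The cardiopulmonary model behind cpsim: structure, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cardiopulmonary model behind cpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpsim)
```

`cpsim` simulates the closed-loop interaction of heart, circulation,
lungs and short-term autonomic control under mechanical ventilation.
This vignette documents the model itself: the equations, the parameters
that matter, the numerical machinery, and the places where a design
choice had to be made and why.

## The heart

Each ventricular free wall (and the septal wall) is a variable-elastance
element. Its transmural pressure blends an end-systolic line and an
end-diastolic exponential,

$$P = \varphi(t)\,E_{max}(V - V_u) + (1-\varphi(t))\,P_0(e^{k_E V}-1),$$

with a half-sine-squared activation $\varphi(t)=\sin^2(\pi t/T_{sys})$
over the systolic interval and $\varphi=0$ in diastole. At $\varphi=0$
and $\varphi=1$ the relation reduces exactly to the end-diastolic and
end-systolic curves. The systolic duration shortens with heart rate,
$T_{sys} = T_{sys0} - k_{sys}/T$; the activation period itself is the
heart period, held constant within a beat and refreshed from the
autonomic effectors at each cardiac-cycle rollover, avoiding mid-beat
period changes.

The two ventricles share the interventricular septum. An imaginary
plane splits the ventricular blood volume into free-wall-bounded parts
and a signed septal volume, $V_{lv} = V_{lvf} + V_{spt}$ and
$V_{rv} = V_{rvf} - V_{spt}$, positive $V_{spt}$ bulging into the right
ventricle. The septal wall carries the same biphasic relation with its
own (much stiffer) parameters and zero unstressed volume, and its
position is determined algebraically at every instant by the pressure
balance

$$P_{spt}(V_{spt}) = P_{lvf}(V_{lvf}) - P_{rvf}(V_{rvf}).$$

All three wall relations are increasing in $V_{spt}$, so the root is
unique; a warm-started, bisection-safeguarded Newton iteration resolves
it to $10^{-9}$ mmHg inside every derivative evaluation (typically 1–2
iterations). The explicit septal equation is not published in the
lineage this model condenses, so the biphasic form with the tabulated
septal parameters is a reconstruction; its consequences are visible in
the absolute septal volume (a few ml larger than the source model
reports) though not in the directional septal behaviour.

The pericardium wraps the four chambers plus 40 ml of pericardial
fluid: $P_{pcd} = P_{0,pcd}(e^{k_{E,pcd}(V_{tot}-V_{u,pcd})}-1)$, and
$P_{peri} = P_{pl} + P_{pcd}$ is the reference pressure of every heart
chamber. Because the relation is exponential, pericardial constraint is
negligible at rest and grows steeply when total heart volume rises —
which is why a stiffened pericardium (2x its elastance coefficient)
*increases* stroke-volume variation in the sensitivity sweep.

The atria are variable-elastance chambers referenced to $P_{peri}$,
with a small activation that leads ventricular systole by a tenth of a
cycle; there is no inter-atrial mechanical interaction (the atria are
taken as connected through a rigid wall). Valves are ideal diodes with
a flow-proportional viscous resistance in the ejection pathways
($R = k_R P_{max}$, the constant-resistance approximation of the
lineage model); the pulmonary valve ejects into the pulmonary arterial
node, and the arterial inertance sits downstream of that node.

## Pulmonary circulation

Four pressure nodes — arteries (pa), arterioles (pal), capillaries
(pc), veins (pv) — plus a shunt branch. The wiring follows the
parallel-series identity that defines the lumped peripheral resistance:
seen from the arteriolar node, the shunt resistance $R_{ps}$ lies in
parallel with the series pair $R_{pal} + R_{pc}$,

$$R_{pp,tot} = \frac{R_{ps}(R_{pc}+R_{pal})}{R_{ps}+R_{pc}+R_{pal}},$$

and the partition implemented in
`partition_peripheral_resistances()` is the unique one that also routes
the fraction `sh` of steady flow through the shunt. The capillary node
is referenced to alveolar pressure; everything else intrathoracic is
referenced to pleural pressure. Two mechanisms let lung inflation
compress the capillary bed:

1. the arteriolar resistance grows quadratically with lung volume,
   $R_{pal} = \frac{R_{pp,tot}}{2(1-sh)} (V_A/FRC_{nom})^2$;
2. once the capillary volume is squeezed below a critical value
   $V_{crit} = V_{u,pc} + c\,C_{pc}$ (transmural reserve $c$, default
   8 mmHg), the post-capillary resistance rises as
   $R_{pc} \propto 1/V_{pc}^2$ — the Poiseuille scaling for a collapsing
   vessel. At and above the resting operating point $R_{pc}$ equals its
   partitioned value, so the steady-state identities above are
   untouched.

The second mechanism is a design choice. The source description only
prints the arteriolar law, but marks all three peripheral resistances
as variable; with a constant $R_{pc}$ the alveolar-referenced capillary
bed empties completely on every insufflation and the within-breath
stroke-volume variation comes out several-fold too large. The collapse
law restores realistic damping while acting only in compression.

`FRC_nom` is a fixed normalisation constant, 2.25 l, the static
equilibrium of the *nominal* respiratory mechanics — not the FRC of
whatever patient is configured. We evaluated the alternative
(re-deriving it per configuration): the quadratic volume term then
dominates every intra-breath quantity and the sensitivity ratios of the
elastance/resistance sweeps leave their published range, so the fixed
constant is used.

## Systemic circulation and autonomic control

The systemic side is the classic six-compartment arrangement: arteries,
splanchnic and extrasplanchnic peripheral beds, their venous
compartments, and thoracic venae cavae exposed to pleural pressure,
draining into the right atrium. Abdominal pressure is identically zero,
a stated simplification that biases the model toward over-predicting
the ventilation-induced reduction in venous return. Volume expansion is
a constant-rate infusion into the extrasplanchnic venous compartment
(mimicking a peripheral line).

The baroreflex follows the familiar sigmoidal-afferent /
exponential-efferent structure: arterial pressure is low-pass filtered,
mapped to an afferent firing rate, and sympathetic and vagal efferents
drive seven effectors (heart period via both branches; the three wall
elastances; the two peripheral resistances; venous unstressed volume)
each through a pure delay, a log-compressed static gain and a
first-order lag. Effective values are basal parameter *plus* tonic
contribution — at the pressure setpoint the model sits at its basal
tone, and the printed basal elastances are pre-tone values (the resting
effective LV elastance is about 2.9 mmHg/ml for a basal parameter of
2.392). Freezing the reflex pins every effector input at its setpoint
value; a frozen run shows no heart-rate response to a PEEP step while
an active run shows clear sympathetic tachycardia.

Chemoreflex sensitivities exist in the configuration for completeness
but must be zero: gas exchange is not modelled (the validation
scenarios are sedated patients with those sensitivities zeroed), and a
nonzero value raises an error rather than silently doing nothing.

## Respiratory mechanics and the ventilator

A single-compartment reduction: $P_{pl} = (V_A - V_{u,cw})/C_{cw} -
P_{mus}$, $P_A = P_{pl} + (V_A - V_{u,L})/C_L$, $\dot V_A = (P_{ao} -
P_A)/R_{aw}$, with all the printed mechanics values (airway resistance
1.7459 cmH2O·s/l, compliances, unstressed volumes) parameterising
exactly this reduction. Pressure-control and pressure-support modes
share a square-wave pressure program (rise to PEEP + support, optional
end-inspiratory pause, passive release to PEEP) smoothed by a 50 ms
cosine ramp to avoid step stiffness; volume control delivers the
flow-programmed equivalent linear rise. Spontaneous effort is a
half-sine inspiratory muscle-pressure wave occupying the first third of
the breath; its amplitude is the "basal breathing amplitude" and zero
means a fully sedated patient. Airway and pleural pressures are carried
in cmH2O, blood pressures in mmHg, converted in exactly one place
(1 mmHg = 1.35951 cmH2O).

## Numerics

The coupled system (23 states: 14 blood volumes, inertance flow,
alveolar volume, cardiac clock, and six control states) is integrated
with the classic fixed-step fourth-order Runge-Kutta scheme at
0.0005 s. The septal root solve runs inside every stage evaluation.
Reflex delays are serviced by a ring buffer sampled at the fixed step.
Per-beat summaries (end-diastolic volumes at activation onset, minimum
volumes, arterial pressure extrema) are accumulated at the full 2 kHz
rate regardless of the recording decimation (100 Hz by default), so
pulse pressures never suffer sampling bias. Identical inputs produce
bit-identical output; halving the step changes the end-expiratory
hemodynamic surface of a 2000 s run by less than 0.1%. Total blood
volume is conserved to rounding over thousands of simulated seconds.

Degenerate inputs are rejected at configuration time (shunt fraction
outside [0,1), negative PEEP, unknown keys) and the integrator aborts
with a time-stamped error if any state goes non-finite.

## Parameters: printed, inherited, calibrated

Parameters fall in three tiers, all visible in
`default_parameters()`:

- *printed*: the heart-wall, septal, pericardial and pulmonary-vessel
  constants and the nominal respiratory mechanics, taken at face value;
- *inherited*: the baroreflex maps, gains, delays and time constants,
  valve and viscous coefficients, and the systemic-circulation
  structure, which this model's lineage defines but the condensed
  description does not reprint;
- *calibrated*: the handful of inherited scalars that the lineage also
  does not pin numerically (total blood volume, venous outflow
  resistances and vena-cava compliance, atrial elastances, the reflex
  setpoint, the capillary-collapse reserve). These were fixed once
  against the resting end-expiratory hemodynamic surface and the
  baseline stroke-volume-variation pair, and are never tuned per run.

Residual discrepancies are known and deliberate: end-diastolic
ventricular pressures and mean right-atrial pressure sit above the
source model's printed column (while inside clinical normal ranges) —
they hinge on diastolic and atrial parameters the lineage does not
print; and under the elastance-partitioning protocol the
pulmonary-ARDS arm reproduces the pleural-pressure partitioning and the
extrapulmonary directions but not the published rise of right
end-systolic volume with PEEP, which in the source model rides on the
per-patient strength of the capillary-compression term discussed above.

## Scenarios and problem sizes

The built-in protocols (`run_scenario()`) reproduce the shape of the
ventilation studies the model was built around: a PEEP ladder with
terminal volume expansion, a constant-support intra-breath analysis, an
elastance-partitioning comparison of pulmonary vs extrapulmonary ARDS
mechanics, and a hypovolemic-vs-septic pulse-pressure-variation
protocol. Default phase durations are 180 s with a 60 s trailing
analysis window: the slowest autonomic effector has a 20 s time
constant and a 5 s delay, so each phase settles well within two
minutes and summaries match the full-length clinical durations (20–30
minutes, available via `full_duration = TRUE`) to within about one
percent. The hypovolemic and septic virtual patients are defined by a
reduced total blood volume (4700 ml) and reduced peripheral resistances
(R_sp0 = 0.95, R_ep0 = 0.35 mmHg·s/ml) respectively, chosen once so
both present the same low mean arterial pressure with baseline
pulse-pressure variation near 15% and 9%.

What the simulator emulates is an average sedated (or quietly
breathing) adult on a ventilator; what it does not emulate — nonlinear
lung compliance and recruitment, gas exchange and chemoreflex-driven
breathing, abdominal pressure, atrial interdependence, regional (West
zone) lung perfusion — bounds what agreement with its outputs can say
about real patients. Within-breath indices (SVV, ΔPP) are faithful to
their clinical definitions but inherit the model's linear-compliance
assumptions; across-PEEP behaviour is linear in pleural pressure where
real lungs recruit and stiffen.
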