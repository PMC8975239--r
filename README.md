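# cpsim — heart-lung interactions under mechanical ventilation

`cpsim` is a closed-loop, lumped-parameter (0D) simulator of the human
cardiopulmonary system built to study how positive-pressure ventilation
perturbs cardiac function. It is aimed at physiologists, intensive-care
researchers and modellers who want a fast, deterministic sandbox for
ventilator settings (PEEP, pressure support, rate, I:E, end-inspiratory
pause) and their hemodynamic consequences: stroke-volume variation
(SVV), pulse-pressure variation (ΔPP), Frank-Starling behaviour,
ventricular interdependence and pulmonary capillary compression.

## The model

The cardiovascular side is a four-chamber variable-elastance heart
embedded in systemic and pulmonary circulations:

- **Free walls.** Each ventricular free wall follows a biphasic
  pressure-volume relation blended by a half-sine activation φ(t) whose
  period equals the heart period T:

  P(V, t) = φ(t) · E_max (V − V_u) + (1 − φ(t)) · P_0 (e^{k_E V} − 1),

  the first term the end-systolic line, the second the end-diastolic
  exponential. Systole lasts T_sys = T_sys0 − k_sys / T.
- **Interventricular septum.** The total ventricular space splits into
  free-wall volumes and a signed septal volume V_spt with
  V_lv = V_lvf + V_spt and V_rv = V_rvf − V_spt. At every instant V_spt
  solves P_spt(V_spt) = P_lvf − P_rvf (a monotone scalar root, found by
  safeguarded Newton iteration inside each derivative evaluation), so
  left and right ventricles are mechanically coupled.
- **Pericardium.** An exponential membrane around the four chambers:
  P_pcd = P_0,pcd (e^{k_E,pcd (V_tot − V_u,pcd)} − 1), with
  P_peri = P_pl + P_pcd acting as the external pressure of every
  chamber.
- **Pulmonary circulation.** Four nodes (arteries, arterioles,
  capillaries, veins) plus a shunt branch. The capillary node is
  referenced to *alveolar* pressure, the others to pleural pressure.
  The pre-capillary resistance grows with lung inflation,
  R_pal = R_pp,tot / (2(1 − sh)) · (V_A / FRC_nom)², and the
  post-capillary resistance rises as 1/V² once the capillary bed is
  squeezed below a critical volume — the two routes by which lung
  expansion raises right-ventricular afterload.
- **Baroreflex.** A sigmoidal afferent of filtered arterial pressure
  drives sympathetic/vagal efferents which modulate (with delays and
  first-order lags) the heart period, the three wall elastances, the
  peripheral resistances and the venous unstressed volume. The reflex
  can be frozen.
- **Respiratory mechanics.** A single linear lung + chest-wall
  compartment produces V_A, P_A and P_pl from the ventilator waveform
  and/or a spontaneous-effort drive.

Everything is integrated with a fixed-step classic Runge-Kutta scheme
at 0.0005 s (2 kHz); runs are bit-reproducible. Derived indices follow
the clinical definitions, e.g.

SVV = (SV_max − SV_min) / ((SV_max + SV_min)/2) · 100

per breathing cycle, and likewise ΔPP for arterial pulse pressure.

## Worked example

```r
library(cpsim)

## resting physiology: 300 s of quiet spontaneous breathing
sim <- simulate_cp(default_parameters(), 300)
round(summary(sim)[c("HR", "P_sa_mean", "EDV_lv", "ESV_lv", "P_pa_mean", "CO")], 2)
#>      HR P_sa_mean EDV_lv ESV_lv P_pa_mean  CO
#> 1 64.46     90.46 136.16  55.47     15.18 5.2

## a ventilated, sedated patient (pressure control, PEEP 5 cmH2O,
## 15 breaths/min, 0.5 s end-inspiratory pause)
cfg <- system.file("extdata", "study3_overrides.yaml", package = "cpsim")
p <- load_parameters(cfg)
vent <- simulate_cp(p, 240)
beats <- segment_beats(vent)
breaths <- breath_summaries(beats, vent$breath_starts)
colMeans(tail(breaths, 14)[c("SVV_lv", "SVV_rv", "dPP")])
#>    SVV_lv    SVV_rv       dPP
#> 11.627427 19.991919  9.470675
```

The first block reports trailing-window averages of the resting
hemodynamics (heart rate in bpm, pressures in mmHg, volumes in ml, cardiac output in
l/min). The second runs the ventilated configuration to a periodic
state and summarises the within-breath variation of left and right
ventricular stroke volume and of arterial pulse pressure — the right
ventricle, facing the swings in venous return and pulmonary impedance
directly, always varies more than the left.

Ready-made protocols live behind `run_scenario()`:

```r
run_scenario("study2_peep_ve")     # PEEP ladder 0..20 + volume expansion
run_scenario("ards_partitioning")  # lung vs chest-wall elastance split
sweep_svv("k_E_pcd")               # pericardial stiffness sensitivity
```

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/cpsim", package="cpsim"))') \
    run study2_peep_ve --param PEEP=10 --out out/
```

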