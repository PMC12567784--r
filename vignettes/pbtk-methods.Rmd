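---
title: "A permeability-limited PBTK model for inhaled TiO2 nanoparticles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBTK model methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanopbtk)
```

## The model and its assumptions

`nanopbtk` simulates the absorption, distribution and excretion of inhaled
20 nm TiO₂ nanoparticles in a 0.263 kg rat as a system of 23 mass-balance
ODEs. The structural assumptions are:

- **Permeability-limited organs.** Nanoparticles do not equilibrate freely
  with tissue; transfer between an organ's capillary blood and its tissue is
  limited by the membrane term `X_o · Q_o · (C_cab − C_tis / P_o)`. The
  partition ratio `P_o` sets the equilibrium tissue/blood concentration
  ratio; the dimensionless permeability `X_o` sets how fast it is
  approached. Organs are treated as homogeneous (no sub-organ anatomy).
- **Saturable, delayed phagocytosis.** Each tissue hosts a phagocytic-cell
  (PC) pool that engulfs particles at the Hill rate
  `K_up(t) = K_max · tⁿ⁰/(K_50ⁿ⁰ + tⁿ⁰)` and releases them at `K_out`. The
  Hill clock `t` is absolute time since exposure onset, shared across all
  compartments and never reset — a modelled maturation of the macrophage
  response, not a per-compartment memory. A direct consequence is that the
  whole system remains **linear in the state**: rate coefficients depend on
  time, not on mass, so doubling a bolus dose exactly doubles every
  trajectory. The test suite asserts this to 1e-8.
- **Four-region respiratory tract.** Inhaled mass deposits into the upper
  airway, tracheobronchial and alveolar regions in fixed fractions.
  Deposition fractions are inputs (normally produced by external
  particle-dosimetry software), not computed here. The alveolar surface
  exchanges with the lung interstitium; the interstitium exchanges with the
  lung capillary across the air–blood barrier; alveolar PC material rides
  the mucociliary escalator back to the tracheobronchial region and is
  swallowed. The escalator term is a *gain* to the tracheobronchial
  balance: writing it as a loss on both sides, as one could naively do, the
  system would destroy mass, and conservation fixes the sign.
- **Circulation closure.** The systemic organs are perfused in parallel
  (their flows sum exactly to the cardiac output in the reference tables);
  venous blood collects all organ capillary outflows; the lung capillary
  sits in series between venous and arterial blood and carries the full
  cardiac output. No hepatic portal routing of splenic outflow is modelled,
  because no portal flow is parameterized.
- **Three excretion routes.** Upper-airway and tracheobronchial clearance to
  feces, biliary excretion of liver PC content to feces, and urinary
  excretion of kidney tissue content. Excretion attaches to the PC pool in
  the liver and the tissue pool in the kidney, following the naming of the
  rate constants. The sinks are state variables, so the conservation audit
  can compare total system mass against the integrated source exactly.

## Parameters

All constants live in a single nested registry addressable by dotted keys
(`chemical.liver.K_50`, `respiratory.P_lu`, ...), with YAML/JSON overrides
and a validator that checks positivity, sub-volume consistency, and the
flow-sum identity. Three parameter decisions deserve a note:

- **Hill coefficients.** The reference tables list Hill `K_max` and `K_50`
  values but no Hill exponents. We default `n0 = 1` everywhere — the least
  informative choice, exposed as ordinary configuration — and flag that the
  behaviour of the spleen block (`K_50 = 1000 h` with `K_max = 240/h`) is
  quite sensitive to this: with `n0 = 1` the splenic uptake rate is already
  ~20/h at 100 h, whereas a large exponent would keep it negligible over
  the whole study window.
- **No allometry.** Values are stored at the reference body weight
  (0.263 kg); no rescaling to other weights is attempted, since no scaling
  rule is part of the model.
- **Units.** Volumes L, flows L/h, rates 1/h, times h. Breathing rate is
  accepted in L/min (the unit used for rodent minute volume) and converted
  once, centrally, to L/h; aerosol concentrations convert as
  1 mg/m³ = 10³ ng/L.

## Exposure scenarios

Two dosing modes cover the use cases. A **bolus** places deposited masses in
the three entry regions at t = 0; a **continuous** scenario feeds
`EC · BR · 60 · FR_region` ng/h while `t < duration`. The calibration-study
preset represents its 2 h intratracheal exposure as a bolus of 40 ng
(tracheobronchial) + 892 ng (alveolar) at t = 0, because the published
simulated curves start from exactly these values at 0 h; the upper-airway
burden is unreported and is set to 0, which is inconsequential for systemic
kinetics because the upper airway feeds only the weakly permeable
rest-of-body compartment (X = 1e-4). The validation-study preset is a
continuous 6 h exposure at 20 mg/m³ = 2 × 10⁴ ng/L; its breathing rate and
deposition fractions were not published, so the preset requires them as
arguments rather than inventing values. Its observation times (24, 48 and
672 h) and 720 h window follow that study's 1/2/28-day sampling design.

## Numerical choices

- **Integrator.** `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12` ng.
  The system is genuinely stiff: capillary equilibration rates reach
  `X_li · Q_li / V_li,cab ≈ 2 × 10⁶` per hour. For continuous exposures the
  integration is split at the cut-off so the source discontinuity falls on
  a segment boundary. The mass-balance audit (max residual against the
  integrated source) is the solver-quality gate; at the defaults it sits
  around 1e-11 ng on a 932 ng dose, far below the 1e-4 ng acceptance gate.
- **Solver cross-check.** An explicit fixed-step RK4 integration cannot be
  run at the reference parameters (the stability limit at the stiffest rate
  would demand steps below a microsecond-hour); the cross-check in the test
  suite therefore compares lsoda to fixed-step RK4 on a mildly-rated
  parameter variant (all membrane rates of order 10/h) where both are
  accurate, agreeing to well within 0.5 %.
- **Output grid.** 0.25 h spacing by default (6001 points over the 1500 h
  reference window), so peaks are located to better than the 0.5 h
  requirement; requested observation times are inserted into the grid
  exactly rather than interpolated. Tests that only need trends run at
  0.5–2 h spacing to keep the suite fast.
- **Peak descriptors.** The peak is refined by a parabola through the three
  grid points around the maximum; the half-peak time is the first crossing
  *after* the peak, located by linear interpolation between the bracketing
  grid points, and reported as "not reached" when the curve never falls
  that far within the window.
- **Log-linear regressions.** Decay rates and half-lives are least-squares
  slopes of `ln(mass)` vs time. Slopes at roundoff scale (|k| ≤ 1e-12/h)
  are reported as "no elimination" instead of a quintillion-hour
  half-life. The default half-life window of 1–672 h follows the
  elimination-phase convention of the reference analysis even though it
  straddles the peak for slowly-filling organs (the kidney peaks near the
  middle of it); the window is an argument, not a constant.
- **Sensitivity.** `S(t) = ∂ln y/∂ln θ` by central differences in log space
  with `h = 0.01`; halving `h` moves the coefficients by under 1 %, and on
  a closed-form one-compartment model the finite difference matches the
  analytic value within its O(h²) truncation error. The aggregate score is
  `max |S(t)|` over the observation times by default; because the published
  single-number coefficients do not state their aggregation rule, the rule
  is recorded in every result and alternatives (`mean_abs`, `final`) are
  selectable.
- **Calibration.** The optional automated fit minimizes
  `Σ(ln sim − ln meas)²` in log-parameter space (Brent for one parameter,
  L-BFGS-B otherwise), replacing interactive slider calibration with a
  reproducible procedure. On noise-free synthetic data each of the three
  most influential parameters is recovered to well under 1 % from a 2×
  displaced start.

## The synthetic-data generator

Real observed datasets for this model exist only as published figures, so
the package generates its own: it simulates a preset, samples the
observables at the preset's observation times, and applies independent
multiplicative lognormal noise per simulated animal, with
`sigma² = ln(1 + cv²)` and a mean-one multiplier so `cv = 0` reproduces the
simulation exactly. Lognormal noise is the natural choice for strictly
positive contents spanning four orders of magnitude; a 20 % coefficient of
variation is typical of the inter-animal spread visible in rodent
biodistribution studies. What these fixtures do **not** emulate: digitized
values of the real measurements, inter-organ noise correlation within an
animal, or measurement-specific background subtraction — so passing
evaluation tests demonstrates that the metrics and calibration machinery
are correct, not that the model reproduces any particular laboratory's
data.

## What the reference parameter set does and does not reproduce

Simulating the calibration bolus with the printed parameter tables and
`n0 = 1` reproduces part of the published curve description well: the lung
observable peaks at 624 ng (published: 625 ng), the alveolar content at
28 h is 142 ng (published: 158 ng), the alveolar slow/fast decay-rate ratio
is 15.8 % (published: 17 %), and the kidney peak is 5.1 ng (published:
5.86 ng).

Other published descriptors are not reproducible from the printed
equations and constants, and the discrepancies are structural rather than
numerical. With `n0 = 1`, the liver PC pool equilibrates at
`K_max/K_out ≈ 13.5` times the liver tissue mass, so the simulated liver
observable peaks near 69 ng — an order of magnitude above the published
7.2 ng — and the resulting biliary excretion flux (`0.0884/h` of a large PC
pool) drains the whole body on a ~100 h timescale, placing the lung
half-peak crossing at ~102 h against the published 721 h and shortening
every late-time descriptor (liver/kidney half-peak times, spleen residual,
the 1–672 h liver half-life). Algebraically, the published secondary-organ
peaks (7.2 / 5.86 / 0.89 ng) are mutually consistent with near-empty PC
pools and tissue–blood partition equilibrium against the arterial
concentration implied by the lung content — a regime the printed Hill
constants with any monotone-increasing uptake and `n0 = 1` cannot produce.
The published tracheobronchial value at 21 h (0.12 ng) likewise implies
~18.7 h of first-order clearance at the printed rate, i.e. a ~2 h clock
offset consistent with the exposure duration, whereas the bolus-at-zero
representation yields 0.06 ng at t = 21 h. We implement the equations as
printed and report the computed values as they are; the acceptance checks
for the affected descriptors fail visibly rather than being tuned toward
the published numbers, and the passing subset (lung peak, alveolar
kinetics, kidney peak) delineates exactly which part of the published
behaviour the printed model specification supports.

## Known limitations

- Organs are homogeneous; no sub-organ anatomy, no protein-corona,
  agglomeration or dissolution kinetics.
- Deposition fractions must be supplied; the package does not compute
  aerosol dosimetry.
- No allometric scaling: predictions apply to the reference rat.
- The Hill exponents are unconstrained by the reference tables; all
  defaults use `n0 = 1`.
- The sensitivity aggregation behind published single-number coefficients
  is unstated; rankings can depend on the rule and the time set chosen.
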