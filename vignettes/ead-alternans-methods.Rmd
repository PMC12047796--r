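---
title: "Modeling EAD alternans: the stochastic spark cell, its deterministic limit, and the restitution map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling EAD alternans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eadsim)
```

# The scientific problem

Early afterdepolarizations (EADs) are secondary depolarizations during the
action-potential (AP) plateau.  In isolated myocytes they appear irregularly
from beat to beat, because repolarization near the plateau is exquisitely
sensitive to subcellular noise; in electrically coupled tissue, gap-junction
averaging suppresses that noise, and the question becomes what governs EAD
formation there.  `eadsim` implements a multiscale answer: a ventricular cell
model whose only noise source is the stochastic recruitment of Ca sparks at
junctional ryanodine-receptor (RyR) clusters, its deterministic (mean-field)
limit, a 2D monodomain tissue solver, and a nonlinear restitution-map toolkit
that characterizes the transition to EAD alternans and conduction block.

# Model structure

## Ca sparks

The `Nb` junctional (J) RyR clusters are exchangeable: the state is the
number `nb` of clusters currently firing a spark.  Over a step `dt` the
count evolves by binomial recruitment and extinction,

$$\Delta n_b^+ \sim B(\alpha_b\,dt,\; N_b - n_b), \qquad
  \Delta n_b^- \sim B(\beta_b\,dt,\; n_b),$$

which keeps `nb` in `[0, Nb]` by construction.  Binomial draws are used at
every `Nb` (no Gaussian approximation); a step with `alpha*dt > 1` is an
error, never a clamp.  In the mean-field limit the fraction `pb = nb/Nb`
obeys `dpb/dt = alphaB (1 - pb) - betaB pb`.  The recruitment rate is
driven by L-type channel openings and gated by junctional SR load,

$$\alpha_b = g_\alpha \, [\mathrm{O}] \,
  \frac{(c_{srb}/K_{sr})^{n_{sr}}}{1 + (c_{srb}/K_{sr})^{n_{sr}}},$$

while extinction is a constant `betaB` (default 0.05/ms, a 20 ms spark
lifetime).  These functional forms are this package's own construction,
calibrated against the printed single-cell statistics (see *Calibration*).

## Compartmental Ca cycling

Four well-mixed pools: cytosol and SR near J clusters (`cb`, `csrb`) and
near non-junctional clusters (`ci`, `csri`).  Release is
`Jrb = gb * csrb * pb`; uptake is a Hill-2 SERCA flux split between the
two cytosolic pools; `Jdc` and `Jdsr` are diffusive exchanges proportional
to the concentration differences; `JCa` (L-type entry) and `JNaCa`
(exchanger) act on the junctional cytosol.  Fluxes into the junctional
cytosol are positive; every flux is stored in whole-cell uM/ms and divided
by the destination volume fraction.  Cytosolic buffering is instantaneous
(one buffer, `Bcyt`, `Kbuf`); the update advances the buffered *total* and
inverts the isotherm, so a closed cell conserves total Ca exactly under
Euler stepping (verified to 1e-8 relative over 2e4 steps).  SR buffering is
a constant factor `betaSR`.  Non-junctional release `Jri` ships disabled
(`gri = 0`): without Ca waves it is secondary, and the J/NJ distinction
enters only through which clusters LCC openings can recruit.

## The L-type Ca channel

Two five-state populations (C1, C2, O, I1, I2), "spark off" channels
sensing the bulk junctional `cb` and "spark on" channels sensing the high
local Ca of an active spark (100 uM), coupled only through open channels:
O -> OS at the spark recruitment rate `alphaB`, OS -> O at `betaB`.
Ca-induced inactivation enters through

$$a_{24} = a_{24}^o + A_{Ca} F_{Ca}(c_b), \qquad
  F_{Ca}(c_b) = \frac{1}{1 + (c_{th}/c_b)^2},$$

and likewise for `a34`; for spark-on channels `FCa` is evaluated at the
spark-local Ca and is effectively 1.  `ACa = 0.15`/ms is the normal
preset; reducing it to 0.09 (the `"ead"` preset) weakens Ca-induced
inactivation, raises plateau Ca entry, and is the control parameter for
EADs.  Voltage acts on the C1/C2 activation step (Boltzmann, `vAct`,
`sAct`), on recovery from I1 (active below about -15 mV), and on the slow
recovery from the deep state I2 (active near the resting potential, time
constant a few hundred ms — this recovery sets the diastolic-interval
dependence of EAD susceptibility).  The population update is a
deterministic explicit-Euler step on the 10-state generator; occupancy is
checked to stay within 1e-9 of 1 rather than renormalized, so rate errors
cannot hide.

The EAD mechanism: during the dome, availability settles into a
quasi-steady balance between Ca-driven inactivation and voltage-dependent
recovery.  With `ACa` reduced, the balance sits higher, the window current
near the activation foot can regenerate as the dome decays, and a
secondary depolarization results.  Because recovery from I2 is slow, the
propensity for this regeneration grows with the preceding diastolic
interval — the origin of the abrupt rise in the restitution curve.

## Membrane currents and the cell

The remaining ionic currents use published rabbit ventricular
formulations (fast Na, rapid and slow delayed-rectifier K, inward
rectifier, transient outward fast/slow, Na/K pump) with fixed
intracellular Na and K; the Na/Ca exchanger senses the junctional `cb`
and carries the Ca-noise signal to the voltage.  `dV/dt = -(Iion -
Istim)/Cm`.  Subsystems advance in a fixed order per step — gates (Rush–
Larsen), LCC, sparks, Ca, currents, voltage — all reading beginning-of-
step values; consistency under step halving is tested.  The time step
alternates between 0.01 ms (upstrokes: within 7 ms of a stimulus or when
`|dV/dt| > 1` mV/ms) and 0.1 ms otherwise.

## Tissue

The monodomain cable equation with `DV = 1e-4` cm^2/ms on a uniform grid
(`dx = 0.015` cm), solved by operator splitting: the reaction substep is
the single-cell step per node, the diffusion substep an explicit 5-point
Laplacian with no-flux boundaries by ghost-node mirroring.  The adaptive
step is global.  Each cell owns an independent counter-seeded RNG stream
keyed by (run seed, cell index), so stochastic tissue runs are
reproducible and independent of update order and grid size.  Stability of
the explicit scheme requires `dtSlow <= dx^2/(4 DV)` (0.1 <= 0.5625 at the
defaults) and is enforced before a run starts.

## APD measurement

All APDs use the crossing conventions of the study: `APD-40mV` is the
time from the upstroke (first upward -40 mV crossing after a stimulus) to
the next downward -40 mV crossing; `APD90` uses the per-beat level
`rest + 0.1 (peak - rest)`, with rest read immediately before the
stimulus.  Crossings are located by linear interpolation.  Beats that
never recross before the next stimulus are capped at the cycle length and
flagged.  An EAD is flagged operationally as a local minimum followed by
a rise of at least 2 mV, both above -40 mV, later than 80 ms after the
upstroke (the delay excludes the phase-1 notch/dome sequence).  The
simulators measure beats online with the same conventions as
`detectApds()`, and the two are cross-checked in the test suite.

## The restitution map

`fitRestitution()` fits a natural cubic spline `F(DI)` to (DI, APD)
samples and refuses to extrapolate outside the sampled range.  The map
`A_{n+1} = F(DI_n)`, `DI_{n+1} = T - A_{n+1}` preserves `DI + APD = T`
exactly.  Fixed points of `G(DI) = T - F(DI)` and of its second iterate
are located by dense bracketing plus bisection, with stability read from
the spline's analytic derivative.  `findAlternansOnset()` reports the
smallest `T` at which `|F'| >= 1` at the period-1 point and classifies
the transition subcritical when off-diagonal unstable `G^2` fixed points
exist just below onset (the colliding separatrix of a subcritical
pitchfork), supercritical otherwise, and degenerate for linear maps.
Orbit classification uses a 0.5 ms tolerance on APD values; the
conduction-block rule `DI < 25` ms (tissue maps) is evaluated before the
domain check at each iterate, and `DI = 25` exactly counts as block.

# Calibration and the synthetic conditions

The supplement-level constants of the original compartment model (spark
rates, flux coefficients, LCC rate constants) are not reproduced in the
main text of the source study, so this package's values were fixed once,
by calibrating the model's emergent behavior to the study's printed
quantities, and are shipped as the registry defaults:

* `Nb = 4000`, CL = 500 ms, normal preset: mean APD90 about 235 ms with a
  coefficient of variation near 2.5%, inside the experimental band
  2.3 +/- 0.9% and uniquely so among `Nb` in {1000, 2000, 4000, 8000};
* `ead` preset (`ACa = 0.09`): deterministic EAD alternans appears
  abruptly near CL 526 ms, stochastic EADs from about CL 490-500 ms;
* plane-wave conduction velocity about 10.6 cm/s at the reference grid;
* S1 = 500 ms restitution with a gradual rise and an abrupt EAD step near
  DI 300 ms.

These defaults *are* the study conditions; the acceptance script runs
them unchanged.

# Numerical and design choices

* **Stimulus**: 2 ms pulse at 40 uA/uF, about 1.5x the diastolic
  threshold at CL 500 ms, fixed once in the registry.
* **Order of operator splitting** and the guarded (not forced)
  renormalizations are described above; errors are raised, never silently
  repaired (rate overflow, negative concentration, occupancy drift,
  diffusion instability).
* **Spark-off Ca sensing**: the Ca-dependent rates of spark-off channels
  follow the dynamic junctional concentration `cb` (the equations'
  reading), not a fixed diastolic constant.
* **Problem sizes**: the shipped tests and the acceptance script use
  2050 paced beats for the single-cell statistics, 200 beats per cycle
  length for sweeps, a 100-cell cable for conduction velocity and a
  60 x 3 strip for block scans; these sizes give seed-stable estimates
  (the cv of APD90 is estimated to about +/-0.1 percentage points).

# What the generator does and does not emulate

The synthetic data here are the model's own trajectories: spark-count
noise is the *only* stochastic source, so the APD distribution reflects
Ca-release noise filtered through the exchanger and the EAD
nonlinearity.  Real myocytes add ion-channel gating noise, beat-to-beat
variations in Na and K loading, and subcellular Ca waves (explicitly out
of scope here, as in the source model).  Passing tests therefore show
that spark-recruitment noise of the calibrated magnitude suffices to
reproduce the printed APD variability — not that it is the only noise
source in real cells.

# Known limitations

Three measured quantities deviate from the reference study's printed
values, and the package reports them as measured:

* **Restitution-map instability near 510 ms, not 650 ms.**  In this
  calibration the S1S2 spline map's knee (and hence the `T` at which the
  period-1 fixed point loses stability) sits close to the dynamic-pacing
  alternans onset.  The source model separates the two by over 100 ms —
  its single-probe S1S2 curve is substantially more stable than its
  steady-pacing behavior, implying strong protocol memory.  Attempts to
  reproduce that separation (slower deep-inactivation recovery, SR-load
  memory, slow IKs accumulation) either moved both numbers together or
  destabilized the calibrated single-cell statistics, and were not
  adopted.  The map's transition *is* classified subcritical, with the
  discontinuous jump the study emphasizes.
* **A degenerate bistability window.**  The deterministic transition to
  EAD alternans is discontinuous (the alternation amplitude jumps by
  about 200 ms within a 1 ms change of cycle length) but up- and
  down-sweeps switch at the same cycle length to within the sweep
  increment: long-run pacing shows no coexistence band at this
  calibration.  `alternansWindow()` therefore reports the common
  transition cycle length as the (zero-width) window's upper end.  The
  slow IKs gate and SR-load feedback both act against coexistence here;
  removing them wholesale broke other calibrated quantities.
* **Conduction block near DI 75 ms, not 25 ms.**  The AP's final
  repolarization below -40 mV is slow in this cell (the window-current
  tail), so tissue remains refractory well after the -40 mV crossing
  that defines DI.  Raising IK1 to speed the tail moves the block
  threshold toward the reference value but shortens APD90 out of its
  calibrated band; the shipped defaults keep the single-cell calibration
  and report the block threshold as measured.

Also note the reference grid spacing (0.015 cm) only marginally resolves
the upstroke front at this slow conduction velocity; conduction velocity
is calibrated *at* that spacing, and grid-convergence of the scheme is
demonstrated from finer spacings in the test suite.
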