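# eadsim

Multiscale simulation of arrhythmogenesis driven by early
afterdepolarizations (EADs) in cardiac cells and tissue.

EADs are secondary depolarizations of the action-potential (AP) plateau.
At the single-cell level they fluctuate strongly from beat to beat; in
gap-junction-coupled tissue those fluctuations are averaged away, and EADs
instead emerge as an abrupt, discontinuous transition to *alternans* — an
EAD on every other beat — which steepens repolarization gradients and
promotes conduction block and reentry.  `eadsim` is built for
electrophysiologists and modelers who want to study that chain of
mechanisms quantitatively.

The package implements, end to end:

* a **stochastic ventricular cell model** whose single noise source is
  binomial recruitment/extinction of Ca sparks at `Nb` junctional RyR
  clusters: over a step `dt`,
  `dnb = B(alphaB*dt, Nb - nb) - B(betaB*dt, nb)`,
  with release flux `Jrb = gb * csrb * pb`, `pb = nb/Nb`;
* a **two-population 10-state Markov L-type Ca channel** (spark-off
  channels sense the junctional Ca `cb`; spark-on channels face an active
  spark) with Ca-induced inactivation
  `a24 = a24o + ACa * FCa(cb)`, `FCa(cb) = 1/(1 + (cth/cb)^2)`;
  lowering `ACa` from 0.15 (preset `"normal"`) to 0.09 (preset `"ead"`)
  is the EAD control parameter;
* **compartmental Ca cycling** (junctional / non-junctional cytosol and
  SR), rabbit ventricular membrane currents, and the mean-field
  (deterministic) limit `dpb/dt = alphaB (1-pb) - betaB pb`;
* a **2D monodomain tissue solver**
  (`dV/dt = -Iion/Cm + DV (Vxx + Vyy)`, operator splitting, adaptive time
  step, per-cell RNG streams);
* **APD analysis** (APD90 and APD-40mV crossing detectors, EAD flags,
  statistics, bifurcation diagrams) and a **restitution-map toolkit**:
  natural-spline fit of `A_{n+1} = F(DI_n)`, iteration at fixed period
  `T = DI_n + A_n`, fixed points and stability of `G` and `G^2`,
  subcritical-pitchfork classification, and period-1 / period-2 /
  conduction-block phase diagrams.

## Worked example

Pace the stochastic cell at a 500 ms cycle length and measure the APD
statistics that calibrate the cluster count:

```r
library(eadsim)
p   <- defaultParams("normal")          # ACa = 0.15, Nb = 4000
run <- runPaced(p, pacingProtocol(500, 700), mode = "stochastic",
                seed = 101)
st  <- apdStatistics(run$beats$apd90, discard = 50)
round(c(mean = st$mean, sd = st$sd, cv_pct = 100 * st$cv), 2)
#>   mean     sd cv_pct
#> 235.83   5.40   2.29
```

A mean APD90 of about 235 ms with a beat-to-beat coefficient of variation
of about 2.3% — inside the experimental band (2.3 +/- 0.9%) that fixes
`Nb ~ 4000` recruitable clusters.  Switching to the EAD preset and
sweeping the cycle length brings out the abrupt alternans transition:

```r
win <- alternansWindow(defaultParams("ead"), cls = seq(519, 533, 2),
                       beatsPerCl = 200)
c(upper = win$upper, jump = round(win$jump))
#> upper  jump
#>   527   230
```

At CL 527 ms the deterministic model jumps discontinuously from a
period-1 APD of ~236 ms to large-amplitude alternans with an EAD on
alternate beats.  The same transition seen through the restitution map:

```r
tab <- s1s2Restitution(defaultParams("ead"), s1 = 500,
                       s2List = seq(240, 900, 20))
map <- fitRestitution(tab$di, tab$apd)
findAlternansOnset(map, c(420, 800), dT = 2)[c("Tc", "type")]
#> $Tc
#> [1] 510
#> $type
#> [1] "subcritical"
```

Tissue-level operations follow the same pattern: `tissueGrid()` +
`runUniform()` / `runPlanar()` for paced sheets,
`conductionVelocity()` for cable wave speed, `blockThreshold()` /
`s1s2Strip()` for S1S2 conduction-block scans, and `phaseDiagram()` for
the period-1/period-2/block map.  `exec/eadsim` exposes the same
operations as a command line (`params`, `simulate-cell`,
`simulate-tissue`, `restitution`, `map`, `phase`, `run`), and
`figureRecipe()`/`runRecipe()` encode the study protocols as data with
reproducible manifests.

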