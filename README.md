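# hippomech

Growth control in the *Drosophila* wing disc sits at the intersection of
biochemistry and mechanics: the Hippo kinase cascade sets the activity of
the growth effector Yorkie (Yki), while junctional tension — sensed by
alpha-catenin at adherens junctions — recruits the Wts inhibitor Ajuba
(Jub) and thereby feeds mechanical state into the same cascade.
`hippomech` implements a coupled model of this system for a seven-cell
hexagonal patch of wing-disc epithelium, for modellers who want to explore
cell-autonomous and non-cell-autonomous growth responses to force,
alpha-catenin level, and Jub expression.

The package couples three sub-models:

* **Upstream Hippo network** (ODEs, nM/min): Fat–Dachsous trans-dimers
  modulated by Four-jointed; Fat-inhibited membrane localization of Dachs
  (decreasing Hill) and Ds-promoted localization of Riquiqui (increasing
  Hill); reversible Warts binding to membrane Dachs (degradation route),
  Riq (Mnb-dependent inactivation route) and Expanded (activation route);
  Yki phosphorylation by active Wts plus direct Ex-dependent inhibition.
* **Three-state alpha-catenin gate**: C1 (folded) ⇌ C2 (M1 exposed) ⇌ C3
  (fully unfolded) with Bell-model rates
  `ku(f) = ku0 exp(f·xu/kBT)`, `kf(f) = kf0 exp(−f·xf/kBT)`,
  Vinculin-inhibited refolding of C2, and state-dependent Jub binding
  (affinity C3 > C1 > C2, so M1 exposure suppresses Jub recruitment).
* **Kelvin–Voigt cell network**: 24 junctional nodes, 30 actin-belt edges
  and per-cell transverse spokes, each a spring + dashpot in parallel with
  a constant contractile force; imposed radial boundary forces; rest-length
  growth `dl/dt = l·min(g0·max(0, Yki−Y0), rate_max)`.

The coupling loop per time step: relax mechanics → node tensions → force
per alpha-catenin molecule → state occupancies → bound Jub → mass-action
Warts sequestration → Hippo ODEs → Yki → rest-length growth.

## Worked example: the single-junction mechanosensor

```r
library(hippomech)
params <- bell_params()          # shipped calibrated defaults

crossover_force("C1C2", params)  # force where C1 and C2 occupancies cross
#> [1] 4.501343
crossover_force("C2C3", params)
#> [1] 10.00061

rel <- relax_catenin(4.5, params, initial = c(1, 0, 0))
rel$settling_time                # seconds to reach equilibrium within 1%
#> [1] 2.81

f <- seq(0, 15, by = 0.05)
b <- sapply(f, function(x) bound_jub(x, params, jub_pool = 30)["bound"])
f[which.min(b)]                  # bound Jub is lowest where M1 is exposed
#> [1] 7
```

The M1-exposed middle state binds Jub weakly, so bound Jub is high at zero
force (folded, moderate affinity), dips between 5 and 9 pN where C2
dominates, and is maximal at high force (fully unfolded, high affinity).
Through Warts sequestration this profile becomes a Yki activity profile:

```r
cfg <- bsm_config()
bsm_cell_steady(cfg, tension = 600, n_cat = 30)[["yki"]]  # nM active Yki
#> [1] 4.690308
```

Experiment drivers reproduce the canonical scans: `fat_production_scan()`
(membrane Dachs falls, Riq rises with Fat production),
`tension_catenin_heatmap()` (monotone Yki–tension response at low
alpha-catenin, triphasic at high), `center_perturbation()`,
`differential_response_scan()` and `jub_production_scan()` (centre vs
boundary-ring responses with growth feedback). `run_preset("fig16")` etc.
run them with the published settings pre-filled; results are written as
tidy CSV plus a JSON run manifest by `write_results()`. A command-line
driver lives at `inst/cli/hippomech.R`.

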