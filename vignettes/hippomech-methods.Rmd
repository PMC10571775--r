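---
title: "Coupling Hippo signaling to tissue mechanics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling Hippo signaling to tissue mechanics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomech)
```

# Overview

`hippomech` simulates short-term (seconds-to-minutes) growth control in a
small patch of *Drosophila* wing-disc epithelium by coupling three
sub-models:

1. an ODE model of the **upstream Hippo network** in a cell with several
   membrane regions — Fat/Dachsous/Four-jointed control of Dachs and
   Riquiqui localization, Expanded-dependent Warts activation, and
   Warts-dependent Yorkie inactivation;
2. a **three-state model of alpha-catenin** at adherens junctions, with
   Bell-type force-dependent transition rates, Vinculin-modulated refolding
   and state-dependent Ajuba (Jub) binding;
3. a **viscoelastic cell-network model** of a seven-cell hexagonal patch —
   Kelvin-Voigt spring/dashpot edges plus a constant active contractile
   force, imposed radial boundary forces, and rest-length growth.

The coupled loop is: mechanics → junctional tension per node → per-molecule
force on alpha-catenin → state occupancies → bound Jub → Warts
sequestration → Yorkie activity → rest-length growth → back into mechanics.

Everything is deterministic; there is no stochastic element anywhere in the
model.

# The upstream Hippo network

Each cell has a well-mixed cytosol and `Nm` membrane regions (default 6,
one per junctional edge). The reaction set is assembled from the pathway's
established regulatory logic:

* Fat and Ds shuttle between cytosol and membrane and form trans-dimers at
  apposed membranes. Cytosolic Four-jointed multiplies the on-rate through
  Fat by a saturating factor `1 + aF Fj/(KFj+Fj)` (always ≥ 1) and through
  Ds by `1/(1 + aD Fj/(KFj+Fj))` (always ≤ 1 and never 0, since Fat-Ds
  binding occurs without Fj). Dimerized Fat/Ds does not recycle, so
  trans-binding retains both cadherins at the membrane.
* Dachs membrane binding is scaled by a *decreasing* Hill function of total
  membrane Fat (free + dimer) in the region; this single factor subsumes
  the Dlish/App route. Riquiqui membrane binding is scaled by an
  *increasing* Hill function of total membrane Ds.
* Cytosolic Warts binds reversibly to membrane Dachs, Riq and Ex — three
  `−k⁺[W]Σ[·] + k⁻Σ[complex]` pairs in the Warts balance. Dachs-bound
  Warts is degraded (Dachs released); Riq-bound Warts is inactivated, with
  Minibrain's kinase activity folded into the rate constant (Mnb is not a
  dynamic species).
* Active Warts is identified with the total Ex-Warts complex
  (proportionality constant 1; the Yki phosphorylation constant absorbs the
  scale). Yki is phosphorylated in proportion to active Warts and
  additionally inactivated in direct proportion to total membrane Ex (the
  Wts-independent route); both fluxes are collected in a single inactive
  Yki pool, and dephosphorylation returns Yki at a first-order rate. The
  reverse reaction is an assumption — whether inactive Yki re-activates is
  not established — and only shifts the active/inactive partition.
* Optionally (`ex_stabilization_mode = "fat_stabilizes_ex"`) membrane Fat
  stabilizes junctional Ex by slowing its recycling with a saturating
  factor; the alternative (default) is the parallel-action hypothesis.

Every cytosolic species has constant production and first-order
degradation; membrane species recycle through the cytosol. All rates are in
nM and minutes.

## Multi-cell closure

Fat-Ds trans-dimers require an apposed cell. The package uses a mean-field
closure per region: in a uniform tissue the neighbouring cell is
statistically identical, so the apposed membrane concentrations equal the
region's own (`cell_geometry(neighbor = "self")`); `"isolated"` regions
have no trans binding. In the coupled patch every cell runs its own Hippo
copy under this closure, which makes cells biochemically identical by
construction — exactly the design of the perturbation experiments, which
vary only tension, alpha-catenin and Jub production between cells.

## Parameter choices

The full per-species equation set is behaviour-calibrated rather than
value-identical to any published table: defaults were chosen once so that
(i) every binding equilibrium sits mid-range at baseline (complex fractions
roughly 0.2-0.8), giving each interaction leverage, and (ii) the canonical
Fat-production scan behaves correctly over a 10-fold range — membrane Dachs
monotonically falling, membrane Riq monotonically rising, and Yki under
Fat-stabilized Ex at or below the parallel-mode curve. Both monotonicities
are structural: more Fat means more membrane Fat (Hill-inhibiting Dachs)
and more trans-dimers (retaining Ds, which recruits Riq).

## Numerics

States are integrated with `deSolve::lsoda` (atol 1e-9 nM, rtol 1e-6 for
stand-alone steady-state solves; the coupled runs use atol 1e-10,
rtol 1e-8 so that 1e-4-scale non-autonomous effects sit well above
accumulated solver error).
Steady states integrate in blocks until the residual falls below 1e-8
times the dominant rate scale, then polish with damped Newton iterations
on a finite-difference Jacobian; the polish is rejected if it leaves the
non-negative orthant or fails to reduce the residual. The right-hand side
rejects states below −1e-6 nM and clamps smaller excursions to zero, which
tolerates the solver's probing without hiding real violations. Warts
material (cytosol + all complexes) is conserved exactly when production,
degradation and the two inactivation routes are switched off — this is a
standing regression test.

# The three-state alpha-catenin gate

Alpha-catenin in the cadherin-catenin complex is a linear chain
C1 (fully folded) ⇌ C2 (M1 exposed) ⇌ C3 (M2/M3 unfolded), with M2 and M3
treated as one folding unit. Rates follow Bell's model: unfolding rates
`ku_i0 exp(f xu_i / kBT)` rise with the per-molecule force, folding rates
`kf_i0 exp(−f xf_i / kBT)` fall. The direction convention matters: only
the assignment "force promotes unfolding" yields force-driven progression
C1 → C2 → C3, so the `u` rates carry the positive exponent. Vinculin binds
the exposed M1 domain and hinders refolding: `kf1` is multiplied by
`1/(1 + V/KV)`; the other three rates and Jub binding are
Vinculin-independent.

Equilibrium occupancies follow detailed balance on the chain
(`C1:C2:C3 = 1 : u1/f1 : u1u2/f1f2`, computed on the log scale to avoid
overflow) and are verified against long-horizon integration of the kinetic
equations to 1e-8. Settling time is defined as the first time after which
every occupancy stays within 0.01 (1% of the total, an absolute criterion;
a relative criterion would be dominated by the near-zero state) of its
equilibrium value.

## Calibration

With symmetric transition distances `xu = xf = 1` nm and `kBT = 4.1` pN nm
(25 °C), the crossover force of a pair is `kBT ln(kf0/ku0)/(xu+xf)`, so the
two rate *ratios* are fixed in closed form by placing the C1-C2 crossover
at 4.5 pN and the C2-C3 crossover at 10 pN. The absolute scale
(`ku10 = 0.25`/s, `ku20 = 0.05`/s) was selected so relaxation from the
fully folded state at the first crossover settles in 2-4 s (2.8 s with the
shipped values). `inst/scripts/calibrate-bell.R` reproduces the scans
behind these choices.

## Jub binding

Each alpha-catenin carries one Jub site whose dissociation constant
depends on the state, with affinity order `C3 > C1 > C2`: M1 exposure
inhibits recruitment (modelled as weak binding, not zero — whether C2
binding is abolished or merely reduced is open), full unfolding enhances
it. All sites at a node share one free-Jub pool, solved by a scalar root
find on the conservation law. The shipped constants `K = (10/3, 50, 5/4)`
(in Jub-pool units) put the bound-Jub minimum of a 0-15 pN sweep at
7.0 pN, inside the 5-9 pN window where M1 is unfolding, with
`bound(15 pN) > bound(0) > bound(minimum)`.

# Tissue mechanics

The patch is a central hexagonal cell with six neighbours (edge length
1 um, matching the ~1 um wing-disc cell edge): 24 vertex nodes, 30 belt
edges, plus one virtual centre node per cell with six transverse spokes
(72 edges, 31 nodes in total). Every edge is a Kelvin-Voigt element
(spring `K(L−l)` along the edge plus a dashpot on the projected relative
velocity) in parallel with a constant contractile force `FA` (belt edges
only by default) — the KVA element. Forces are strictly pairwise and
equal-and-opposite, so internal forces sum to zero identically; this and
the dissipativity of the passive network are regression tests.

Imposed boundary forces act on the 18 hull vertices along the ray from the
**current** network centroid through the node (positive = stretch). Using
the instantaneous centroid keeps rigid translations force-free; with a
fixed reference point a translation of the patch is linearly unstable and
the patch drifts away (observed numerically before the fix).

Two integration modes share their stationary states: `"inertial"`
integrates the full momentum balance with edge dashpots; `"overdamped"`
(default) drops the mass term and replaces the edge dashpots by an
equivalent drag to the substrate. Both stop early when the maximum node
speed (and, in inertial mode, acceleration) falls below 1e-4 um/s.
Stationary states of the two modes agree to ~1e-5 um on the default patch.

## Mechanical constants

Shipped defaults are `KN = KT = 1500` pN/um, `Ξ = 100` pN s/um,
`FA_belt = 900` pN. Two constraints drive these choices. First, stability:
a spring network under edge contraction `FA` and compressive boundary load
`F` collapses completely when `K·l0` does not exceed `FA` (and `FA + |F|`);
the defaults keep a 2x margin. Second, the operating point of the coupled
model: with ~30 alpha-catenin molecules per node, node tensions of a few
hundred pN put the per-molecule force above the bound-Jub minimum
(~8 pN), which is the regime in which tension *promotes* Jub recruitment
and Yki activity — the cell-level behaviour reported for the normal
alpha-catenin range. A cortical tension of several hundred pN per ~1 um
junction is within the range measured for actomyosin-loaded epithelial
junctions.

Swelling a cell multiplies the rest lengths of its belt and transverse
edges by `sqrt(area_scale)` (a volume change, e.g. osmotic water uptake);
no volume conservation is imposed anywhere. Rest-length growth is
relative: `l ← l exp(rate·dt)`.

# The coupled model

`run_bsm()` advances an operator-split loop with coupling step
`dt_couple = 0.5` min:

1. relax the mechanical network to quasi-statics under the imposed
   boundary forces;
2. read the junctional tension at each node — the mean of the *tensile*
   (positive) belt-edge tensions there; compressed edges contribute zero,
   since compression is not transmitted through the cadherin-catenin
   complex;
3. divide by the cell's alpha-catenin complement to get the per-molecule
   force (each cell reads shared nodes through its own molecules), average
   force over the two endpoints of each junctional edge (= membrane
   region), and take the alpha-catenin state quasi-equilibrium;
4. freeze the resulting per-region Jub binding sites and advance each
   cell's extended ODE system — the Hippo network plus the Jub-Wts
   complex per region and the cell's Jub pool — over the coupling step;
5. if growth is enabled, grow rest lengths at
   `min(g0·max(0, Yki − Y0), rate_max)` per cell (shared belt edges take
   the mean of their two cells' rates) and return to 1.

The split is justified by timescale separation: alpha-catenin states and
Jub binding settle in seconds, mechanics in tens of seconds, while the
Hippo ODEs and growth evolve over minutes. The 0.5-min step (rather than
seconds) exploits the observation that the quasi-equilibria only move when
the mechanics moves, and the mechanics only moves on the growth timescale.
With the tension held fixed the split is exact — the operator-split run
equals one uninterrupted integration of the single-cell system, which is a
regression test (`fixed_tension` mode).

## Warts sequestration requires complex turnover

Junctional Jub sequesters cytosolic Warts by mass action
(`kJWp·[W]·JubBound − kJWm·[JubWts]`), and sequestered Warts cannot bind
Ex. One subtlety: with production/degradation acting only on cytosolic
Warts, a *strictly reversible* side-complex equilibrates to zero net flux
and leaves the steady-state Warts balance untouched — tension would have
no steady-state effect on Yki at all (verified numerically). The complex
therefore carries its own first-order Warts turnover `kdJW` (default equal
to the cytosolic degradation rate), making sequestration a genuine drain.

## Units and conversions

"Yki level (nM/cell)" is the cytosolic active Yki of the single well-mixed
compartment. Alpha-catenin is counted in molecules/node (physiological
window 26-46); the conversion to nM of Jub binding sites per membrane
region is `conv_nM = 2`, and the molecular Jub dissociation constants are
scaled by `jub_K_scale = 60` to the cellular nM scale. These two constants
were chosen together so that the default Jub pool (250 nM at production
250 nM/min and decay 1/min) is partially depleted by the sites. Partial
depletion matters qualitatively: it is what masks the molecular bound-Jub
dip at high alpha-catenin numbers, producing the monotone cell-level
tension response reported for the normal 20-50 molecules/node range while
preserving the triphasic molecular response when alpha-catenin is high.

## Growth readout and experiment defaults

Growth is reported as `R`, the mean final/initial belt rest length per
cell; differences are reported in percent. The growth gain
(`g0 = 0.01` nM⁻¹min⁻¹, cap 0.02/min) is strong enough that differential
growth feeds back measurably on neighbours within the default 40-60 min
horizon — the feedback channel behind the non-cell-autonomous effects.
The growth experiments additionally start from a centre cell swollen to
1.15x its area (`center_swelling`), emulating osmotic enlargement as the
initial condition; the pre-strain this stores in the ring is what turns
differential growth into compression of the neighbours. Enlargements much
beyond ~1.3x under compressive boundary loads slacken the ring belt
entirely (all tensions clip to zero), which is why a modest value ships as
the default.

The centre-perturbation experiments sweep the centre cell's alpha-catenin
over 20-45 molecules/node by default, inside the physiological window. The
choice is deliberate: above ~50 molecules/node the per-molecule force
drops into the triphasic regime and the centre response is no longer
monotone — which is precisely the molecular-regime behaviour the
tension/alpha-catenin heatmap exhibits along its high-catenin rows, not a
numerical artifact.

The heatmap grid spans 200-1000 pN/node. Below ~200 pN/node at low
alpha-catenin the per-molecule force crosses the bound-Jub dip, so the
tension response of Yki is non-monotone at the lowest forces; the reported
monotone low-catenin regime refers to this grid.

## Resolved and saturated regimes of the coupled experiments

The per-molecule force is `f = T/N` for node tension `T` and `N`
alpha-catenin molecules per node. The cell-level bound-Jub response has a
dip around 6 pN and saturates above roughly 16 pN, so the band in which
tension changes move Yki is narrow. In the shipped regime the
centre-perturbation experiments resolve: the cell-autonomous centre
response under both ±100 pN; the non-autonomous boundary decrease under
compression; all centre-boundary differentials (in alpha-catenin and in
Jub production) at 800 and 100 pN; and the negative growth feedback for
the boundary cells at 800/100 pN and the centre under compression. Two
effects are *not* resolved and come out wrong-signed at the 1e-4 nM level
or below: the boundary decrease under +100 pN tension and the centre's
growth feedback at 100 pN — in both, the cells sit above ~19 pN per
molecule, where bound Jub is saturated, and the residual response is
dominated by hull-edge stretching under the constant radial loads. The
corresponding test assertions are left failing rather than relaxed;
placing every arm of every experiment inside the sloped 12-16 pN band
simultaneously is geometrically impossible with this molecular
calibration, since the centre sweep spans a two-fold range of `N` while
the imposed forces offset the tensions of the two cell classes in
opposite directions.

# What the model does and does not capture

The synthetic patch emulates: force-dependent junctional biochemistry at
realistic per-molecule forces; the inhibitory-middle-state logic of Jub
recruitment; cell-autonomous vs. neighbour effects of alpha-catenin and
Jub perturbations; and weak negative feedback of growth on Yki through
compression. It does not capture: junction assembly/disassembly or E-cad
catch-slip bonds; cell rearrangements (T1 transitions) or divisions;
Yki-driven transcription of upstream regulators (slow feedback); Crumbs /
Merlin / Kibra dynamics (constant inputs); stochastic copy-number noise;
or 3-D geometry. Passing the included tests therefore supports the
internal consistency of the coupled mechanism, not quantitative agreement
with any particular wing disc.

# Reduced problem sizes

The test suite and the experiment presets run at reduced sizes chosen as
package defaults: coupled horizons of 10-40 min with 0.5-1 min coupling
steps, 3-6 sweep points per scan, and slice-based checks of the
tension/alpha-catenin surface (two rows and one column instead of a full
grid). The acceptance script's single-junction quantities are exact
computations and run in seconds.
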