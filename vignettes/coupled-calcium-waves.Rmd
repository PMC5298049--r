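---
title: "Coupled EC/SMC calcium dynamics on arterial surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled EC/SMC calcium dynamics on arterial surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vasowave)
```

## The biological problem

Arterial walls carry a single layer of endothelial cells (ECs) facing the
blood and layers of smooth muscle cells (SMCs) behind them. Luminal ATP,
whose near-wall concentration is set by wall shear stress, binds endothelial
P2Y receptors and drives production of inositol trisphosphate (IP3) at a
rate conventionally written $J_{PLC}$. IP3 opens store channels on the
ER/SR, released Ca$^{2+}$ sensitises further release (calcium-induced
calcium release, CICR), and the interplay of store release, SERCA re-uptake,
membrane extrusion, voltage-operated Ca$^{2+}$ entry (VOCC) and
Ca$^{2+}$-activated K$^+$ currents produces, for a window of $J_{PLC}$,
sustained SMC Ca$^{2+}$ oscillations. Gap junctions couple neighbouring
cells — within a layer (homocellular) and between layers (heterocellular) —
by exchange of Ca$^{2+}$, IP3 and membrane potential, and these couplings
organise single-cell oscillations into macroscopic Ca$^{2+}$ waves that
travel along the vessel. `vasowave` simulates this system on physiologically
tiled straight tubes and Y-bifurcations and provides the analysis tools
(bifurcation diagrams, space–time maps, wave metrics) used to characterise
the waves.

## The cell models

One SMC carries five state variables $(c_i, s_i, v_i, w_i, I_i)$: cytosolic
and SR Ca$^{2+}$ (µM), membrane potential (mV), the open fraction of
Ca$^{2+}$-activated K$^+$ channels and IP3 (µM). One EC carries four,
$(c_j, s_j, v_j, I_j)$. The right-hand sides are sums of named pathway
fluxes (Hill-type store release and CICR, linear leaks, saturating pumps,
Boltzmann-gated VOCC, a Na$^+$/Ca$^{2+}$ exchanger, BK$_{Ca}$/SK$_{Ca}$
currents in the EC); the complete symbol-keyed parameter set, with units and
one-line descriptions, ships as a flat text table
(`system.file("extdata", "model_parameters.tsv", package = "vasowave")`) and
is the single source for both the R reference implementation
(`smc_rhs()`, `ec_rhs()`) and the compiled tissue core. Units are µM, mV and
seconds throughout; $J_{PLC}$ (µM/s) enters only the EC IP3 equation, as a
constant production flux. The SMC has no intrinsic IP3 production; its IP3
arrives solely through gap junctions, which is why the heterocellular IP3
permeability controls where tissue starts to oscillate.

Two transcription safeguards are built in. First, the test-suite carries a
second, independently written transcription of all nine equations and
requires agreement to $10^{-12}$ relative. Second, trajectories are never
clamped: a concentration that goes negative is reported as a diagnostic
(`check_state_bounds()`), not silently repaired, because clamping would mask
sign errors exactly where they matter. During development this caught a sign
error in the Na/Ca exchanger's contribution to the membrane-potential
equation: with the wrong sign the voltage equation is linearly unstable and
runs away beyond $-180$ mV.

Initial conditions are a convention of this package (none are stated for
the original system): every cell starts at its isolated rest state at zero
agonist, found by 500 s of relaxation integration followed by a damped
Newton polish (`rest_state()`), with an optional seeded Ca$^{2+}$
perturbation (`tissue_initial_state(perturb = )`) to break the exact
symmetry of idealised meshes.

## Coupling and its calibration

Gap-junction fluxes are purely diffusive: flux into a cell is
$g\sum_k (x_k - x_{self})$ per species; the electro-diffusive drift term for
membrane potential is omitted as negligible for this model class. Four
canonical coupling cases span healthy to pathological connexin expression
(`coupling_case(1:4)`); see its help page for the flag table.

Rates (units 1/s): homocellular electrical coupling 1000 for both layers and
homocellular Ca$^{2+}$/IP3 coupling 0.05 are literature-anchored defaults.
Heterocellular electrical coupling defaults to 50 (the Cx43 conductance
slope of 50 nS/mV) and heterocellular Ca$^{2+}$ coupling to 0.05. The
heterocellular IP3 rate has no published value in rate units; it is the one
calibrated coefficient. We calibrate it once against a single anchor: the
lower onset of the Case-1 single-unit oscillatory window at
$J_{PLC} \approx 3.7$ µM/s. The default `g_ip3_hetero = 0.0026` places that
onset at 3.67. The Case-4 onset is then a genuine prediction of the model —
the sweep locates it at 2.98, against approximately 3.0 for the reference
system — and the ratio of the two onsets (1.23) matches without any second
knob. The smallness of the calibrated value is consistent with IP3's
relatively low connexin permeability.

Heterocellular pairing follows the fundamental tiling unit: 5 ECs and 13
SMCs of equal total footprint area, every EC–SMC pair overlapping in an
equal 10 × 5 µm rectangle, hence uniform weights. The weights are
normalised **per SMC** (1/5 each). The design alternative — normalising per
EC — was measured and rejected: it hands each SMC only 5/13 of the
unit-calibrated influx, which shifts the tissue's oscillation onset far
above the single-unit window and abolishes wave formation inside it,
whereas per-SMC normalisation makes tissue oscillations switch on at the
single-unit thresholds, which is the correspondence the space–time analyses
rely on (oscillations extinguishing at the single-unit lower-threshold
line). Heterocellular fluxes remain exactly conservative pair by pair.

## Surface geometry and tiling

Tubes and symmetric Y-bifurcations are generated patchwise by solving the
anisotropic biharmonic equation
$(\partial_u^2 + a^2 \partial_v^2)^2 \boldsymbol{\phi} = 0$ per Cartesian
coordinate on the unit parameter square, with Dirichlet positions and
Neumann derivatives on all four edges (a 13-point stencil; Neumann imposed
through one ghost layer; one sparse factorisation for the three
coordinates). A bifurcation is three tubular segments of two semi-tubular
patches each; the three seam curves meet at the top and bottom poles of the
junction and pass through the two outer-wall points and the carina apex,
and adjacent patches share seam discretisations exactly, so the stitched
mesh is watertight (Euler characteristic $-1$, every interior edge shared
by exactly two quads — both are tested).

The anisotropy constant defaults to $a = 0.1$. This is a deliberate choice:
circumferential surface modes decay along the axis like $e^{-2\pi a u}$
under this operator, so $a \sim 1$ visibly pinches a long tube's interior
radius, while $a = 0.1$ recovers an analytic cylinder to well under 1% of
the diameter (the interior sag scales like $(2\pi a)^4/384$). The value is
exposed in `geometry_spec()`.

Each quadrilateral is tiled with a 4 × 4 grid of fundamental units: 80 ECs
(4 × 20, footprint 65 × 10 µm, long axis axial) and 208 SMCs (52 × 4,
50 × 5 µm, long axis circumferential), 288 cells per quad. With the default
quad footprint (0.26 × 0.20 mm) the canonical bifurcation
(branch length 8.84 mm, diameter 2.55 mm, 30°) resolves to m = 34, n = 40
per segment, i.e. Q = 4080 quads and 1,175,040 cells; the census scales
exactly as Q·{80, 208, 288}. Quads near the junction are geometrically
distorted while their cell counts stay fixed — a known artefact of the
tessellation, accepted here as in the reference methodology.

## Time integration

The tissue is decomposed one quad per computational domain (configurable).
Within a communication interval (default 0.01 s) each domain advances
independently with an adaptive Dormand–Prince 5(4) scheme (error per step
controlled by `rtol`/`atol`, defaults $10^{-6}$/$10^{-9}$), reading
cross-domain neighbours from values frozen at the interval start; at
interval boundaries edge states are exchanged. This zeroth-order ghost hold
is the natural reading of a fixed exchange cadence; its cost is a splitting
error that the suite verifies shrinks as the interval shrinks, converging
to the monolithic solve. The serial backend is the reference; the parallel
backend (`backend = "parallel"`) distributes whole domains over worker
processes under the identical frozen-ghost contract and is verified
bitwise-identical on a 4-domain fixture. The physics core draws no random
numbers, so identical configurations reproduce identical archives.

Step sizes are stability-limited by the homocellular electrical coupling
(eigenvalues down to roughly $-8 g_v$), giving steps near $4\times10^{-4}$ s
and a practical cost of about 1.5 ms per cell per simulated second on one
core. That cost is what makes the full-scale meshes cluster work; the
package's own test problems are chosen accordingly (below).

Archives store snapshots each `output_interval` (default 1 s) and persist
as RDS with plain-CSV export; snapshots map onto the surface as ASCII VTU
(one quad cell per biological cell with Ca$^{2+}$, IP3, membrane potential
and a layer tag) readable by standard VTK tools.

## Agonist maps

The synthetic map is a sigmoid in the axial coordinate only (circumferential
uniformity is a property test): plateaus `j_min`/`j_max`, inflection at the
junction by default. The plateau defaults (2 and 5.5 µM/s) bracket the
Case-1 oscillatory window so a mapped vessel contains a steady band, an
oscillatory band and the lower threshold in between; the numeric sigmoid
parameters of the original figures are not published, so these are package
choices. ATP converts to $J_{PLC}$ linearly (`atp_to_jplc()`), the
relationship being monotone and approximately affine over the physiological
range; a saturating user-supplied function can be substituted where the
linear form is too crude.

The reduced transport module generates physiologically shaped maps without
a 3D CFD stage: steady advection–diffusion of ATP over an analytic
Poiseuille profile in a 2D channel, with a reactive Robin wall condition
$D\,\partial_y\phi|_{wall} = K\phi_{wall} - S(x)$,
$S = s_{max}\,\tau_w/\tau_m$, solved by finite volumes (first-order upwind
advection, central diffusion) with the wall condition applied iteratively
to a relative change below $10^{-8}$, as in the source methodology. $K$,
$\tau_m$ and $s_{max}$ are user-calibrated configuration values (the
literature values are deferred to a reference we do not reproduce);
defaults are physiologically plausible (ATP diffusivity
$2.36\times10^{-4}$ mm²/s, hydrolysis velocity $1.67\times10^{-3}$ mm/s,
$\tau_m = 1$ Pa). The discrete species balance closes to 0.1% and wall
profiles converge under grid refinement; the high-Péclet regime is why the
upwind/under-relaxed iteration was chosen. Full-geometry CFD maps enter via
`load_map()`.

## Analysis

`bifurcation_sweep()` integrates a single coupled unit (heterocellular
coupling only — the configuration under which the reference diagrams were
generated) across a $J_{PLC}$ grid, classifies each value as oscillatory
when the post-settle peak-to-peak SMC Ca$^{2+}$ exceeds 1% of its mean, and
bisects the onsets to 0.01 µM/s after refining to a 0.05 µM/s grid near the
crossing. Settle and measurement windows default to 200 s and 300 s — long
enough to resolve the slow dynamics near the Hopf points, and verified
stable against halved tolerances. `extract_line()` samples SMC Ca$^{2+}$
along an outer-wall inlet-to-outlet path into a space–time map;
`wave_metrics()` reports per-position amplitude and period (peak spacing),
the front trajectory (most upstream position whose sliding-window amplitude
exceeds a tolerance, default 0.05 µM over 30 s) and the inferred
propagation direction. Amplitude exceedance is used instead of phase
tracking because wave-packet phenomena make phase ill-posed.

## What the test problems do and do not show

The full-scale simulations behind the reference figures (Q = 4080, 1.17
million cells, 1000 s) are cluster-scale by design; at roughly 1.5 ms per
cell-second they are far outside a single-core test budget. The suite
therefore exercises every mechanism at reduced size, chosen once:

* single-unit sweeps at the full protocol (the two quantitative anchors);
* tissue oracles (decoupled limit, naive-loop equality, conservation,
  rotational equivariance, backend bitwise equality, splitting convergence)
  on 8–16-quad tubes (2,304–4,608 cells) over seconds;
* wave propagation on a 16-quad tube (4,608 cells, 1.04 mm) under a steep
  sigmoid spanning the oscillatory window, run for 60 s: long enough to
  show oscillation onset confined to the supra-threshold band and the
  amplitude front moving toward decreasing agonist and crossing the
  lower-threshold position, which is the desk-scale analogue of the
  full-scale upstream crossing (~200 s at full scale);
* census-only construction of the full Q = 4080 mesh (geometry and tiling
  are cheap; only the ODE integration is not).

What these runs cannot show: spiral wave ends and wave-packet communities
need hundreds of circumferential cells and hundreds of seconds; junction
artefact effects on wave speed need the full bifurcation run. The machinery
that produces them is the same code path that is tested.

## Known limitations

Single SMC layer; lumped (well-mixed) cells with no intracellular
gradients; no NO/eNOS chemistry; no pulsatile flow (the transport module is
steady and 2D, full CFD maps must be imported); connexin isoform selectivity
is represented only through the coupling-case flags; no checkpoint/restart.
The printed per-mesh ODE totals of the reference text (cells × 9) disagree
with the 4-per-EC + 5-per-SMC count the model defines; this package counts
4 and 5 and treats the discrepancy as a typographical artefact.
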