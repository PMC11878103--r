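---
title: "Modelling cardiac activation on labeled anatomies: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiac activation on labeled anatomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Segmented micro-CT volumes of human hearts resolve the cardiac conduction
system (CCS) — sinus node (SN), atrioventricular node (AVN), His bundle,
bundle branches and Purkinje network — as labeled voxel regions. Given such
a label volume, the activation sequence of a heartbeat can be computed by
reaction–diffusion simulation directly on the voxel grid, provided the
solver respects the wiring of the CCS: the SN speaks to the atria only
through discrete exit pathways, the AVN is the sole conducting bridge from
atria to ventricles and is otherwise insulated, and the His–Purkinje system
(HPS) delivers excitation to the ventricles only at discrete insertion
points. `ccsim` implements that pipeline — anatomy, electrophysiology, and
morphometry — with a synthetic phantom standing in for real segmentations,
which are not publicly deposited.

## Tissue model

Tissue dynamics follow the isotropic monodomain equation

$$\frac{\partial V_m}{\partial t} = D \nabla^2 V_m - \frac{I_{ion}}{C_m},$$

discretised with centred finite differences on the voxel grid (6-neighbour
stencil, no diagonal coupling) and explicit time stepping at
$\Delta t = 0.01$ ms. Only voxels with excitable codes become solver nodes.
An edge exists between two face-adjacent nodes only if the coupling policy
allows their code pair; its conductance is the harmonic mean of the two
regions' diffusion coefficients divided by $\Delta x^2$ (continuity of flux
across material interfaces). Every other interface is no-flux, which makes
the edge list symmetric and conserves total $\sum V_m$ under pure diffusion
(asserted to 1e-6 per step in the tests; a single step is also checked
against a dense Laplacian multiply to 1e-12 on small grids).

The default coupling policy encodes the CCS contract: SN core ↔ exits
only; exits ↔ atrial muscle; atrial codes (working atrium, crista
terminalis, pectinate muscles, Bachmann's bundle) mutually coupled; AVN ↔
atrium and His only; HPS ↔ AVN, itself, and its insertion points; insertion
points ↔ ventricular myocardium. Valve, fat, scar, cavities and background
are non-excitable and block everything. The phantom additionally realises
the atrioventricular insulation geometrically (a fibrous valve sheet with a
single His-sized channel), so insulation holds by both policy and anatomy.

Regional parameters (defaults of `default_region_table()`):

| region | D (mm²/ms) | upstroke scale | APD scale |
|---|---|---|---|
| working atrium | 0.3 | 1.0 | 0.9 |
| working ventricle | 0.3 | 1.0 | 1.0 |
| crista terminalis / pectinate / Bachmann's | 0.9 | 1.0 | 0.9 |
| SN core, SN exits, AVN | 0.1 | 0.25 | 1.2 |
| His–Purkinje, insertions | 0.9 | 2.0 | 1.3 |

The three diffusion coefficients are the study conditions; the upstroke and
APD scales are stand-ins chosen once (the original per-region parameter
table is not public) to produce slow nodal conduction, fast His–Purkinje
conduction, and shorter atrial repolarisation. Upstroke scales multiply a
baseline fixed by conduction-velocity calibration (below).

## Cell model

The reaction term is a minimal six-current formulation,
$I_{ion} = I_{Na} + I_{to} + I_{CaL} + I_{Kr} + I_{Kur} + I_{K1}$, each
current of the form (conductance) × (gate product) × ($V_m$ − reversal).
There is no concentration homeostasis and no pacemaker current: every
region, including the SN, is quiescent until driven (rest stability over
10 s is a test). Gates are first-order with sigmoid steady states and
constant time constants, so the Rush–Larsen update uses scalar decay
factors; the voltage advances by forward Euler. In tissue the nine
voltage-dependent sigmoids are tabulated on a 0.025 mV grid and linearly
interpolated, which removes all exponentials from the inner loop without
measurable error at that resolution.

Because the published equations behind the original model are not
available, the concrete shape parameters here are this package's own. Two
choices deserve explanation:

* **Gate shapes are deliberately forgiving.** Activation midpoint −45 mV,
  activation time constant 0.4 ms, inactivation midpoint −68 mV with slope
  −5 mV and time constant 10 ms. Sharper, more classical sodium kinetics
  propagate fine at the 0.292 mm calibration resolution but block in the
  weakly-coupled regime of the 1 mm phantom grid with nodal parameters
  (D = 0.1 mm²/ms, quarter upstroke): the depolarising front becomes
  narrower than a voxel. The chosen shapes keep the slow-region safety
  factor above ~1.5 at 1 mm while leaving the calibrated working-myocardium
  velocity and the $\sqrt D$ scaling intact. The price is a broad action
  potential peak near +60 mV and a moderate maximum upstroke
  (~130 mV/ms) — acceptable in a model whose purpose is the activation
  *sequence*, not waveform fidelity.
* **APD scaling acts on $I_{to}$, $I_{Kr}$, $I_{Kur}$ only.** The inward
  rectifier sets the resting potential and is left untouched so that APD
  heterogeneity does not perturb rest or excitability.

Membrane capacitance is normalised to 1, so currents carry mV/ms and the
monodomain reaction term is simply $-I_{ion}$.

## Conduction-velocity calibration

`calibrate_excitability()` bisects the sodium-conductance scale (log-scale
bisection in [0.01, 100]) until a planar wave in a 30 × 3 × 3 mm slab at
$\Delta x = 0.292$ mm, $\Delta t = 0.01$ ms, D = 0.3 mm²/ms travels at
0.713 m/s within 1%. Velocity is read from the activation map as plane
separation over the difference of median activation times between probe
planes at 25% and 75% of the slab length (both outside 10% boundary
margins). The stimulus covers the first 1.5 mm of one end face — a
one-voxel-deep layer cannot charge against the diffusive load of the
adjacent tissue at any physiological amplitude, so a face with physical
depth is the honest realisation of a "one-face stimulus". A scale whose
explicit upstroke diverges is treated as "faster than target" by the
bisection, and targets above $\Delta x / \Delta t$ are rejected outright.
The calibrated scale (≈ 1.78 under the defaults) is cached and becomes the
baseline multiplier of every region's upstroke scale.

## Stimuli and activation maps

Named protocols stimulate a sphere of radius 5 voxels clipped to the target
region's own code — clipping matters, because a sphere around the SN centre
would otherwise touch atrial muscle and short-circuit the exit-pathway
anatomy. Amplitude defaults to twice the single-cell diastolic threshold of
the target region's parameters (2 ms square pulse), with the scales used
for the threshold estimate clamped to the range where a single cell has a
well-defined rest. The sinus protocol targets the SN-core centroid; the
ectopic protocol targets the HPS voxel farthest from the AVN (a distal
branch), configurable to any explicit voxel.

Activation time is the first upward crossing of −20 mV — low enough to be
robust for reduced-upstroke nodal tissue whose peak stays well below
working-myocardium peaks. Maps carry `NA` at non-tissue voxels and `Inf`
for tissue that never activated; `region_scaled_map()` rescales each
region's times to [0, 1] for per-region displays, and
`latest_activation_report()` ranks the slowest tissue. Runs stop early once
no new node has activated for 30 ms (configurable); with a single beat and
no re-entry this cannot truncate the map, because a wavefront that will
ever activate more tissue does so on a much shorter horizon.

A conservative stability warning fires when
$\Delta t \cdot \max(D) \cdot 6 / \Delta x^2 > 0.5$; the fast-pathway
D = 0.9 at 0.292 mm sits at 0.63, inside the true explicit-diffusion limit
of 1 but flagged, mirroring the operating point of the whole-heart
conditions this reproduces.

## The phantom

`make_heart_phantom()` builds an idealised closed heart in a 96 mm cube at
1 mm voxels (≈ 56,000 excitable nodes): two half-ellipsoid ventricular
shells whose overlap forms the septum (LV wall 10 mm, RV 4 mm), a 2 mm
fibrous valve sheet over the whole ventricular footprint, spherical atrial
shells (3 mm walls) bridged by an interatrial septal block, and the full
CCS: an SN ellipsoid placed in a locally thickened right-atrial wall and
wrapped in fat except for superior and inferior exit caps; crista
terminalis and a pectinate comb as mid-wall ridges; Bachmann's bundle as an
interatrial strand; an AVN block in the septal base; and a His–Purkinje
tree traced as 6-connected digital paths — trunk through the valve channel,
bundle branches to each septal endocardium, and free-running branches
across the cavities ending in insertion voxels re-coded only where they
touch ventricular myocardium. Branch placement carries small seeded angular
jitter; identical spec + seed gives bit-identical phantoms.

Shapes are parametric idealisations: what the phantom shares with a real
segmentation is the **topology and adjacency** of the CCS, which is what
the activation sequence depends on. It does not emulate trabeculation,
papillary muscles, fibre orientation (the simulated physics is isotropic by
design), wall-thickness gradients, or realistic atrial geometry; passing
tests therefore demonstrate that the solver honours CCS wiring on a
CCS-complete anatomy, not that it reproduces any particular heart. Two
phantom-specific choices worth noting: the His channel through the valve
sheet has the same cross-section as the AVN face, because a narrower
channel produces a retrograde source–sink block at the His→AVN junction and
suppresses retrograde atrial activation; and a tidy pass merges the rare
single-voxel fragments left where thin structures carve the walls, so each
structure is one 6-connected component (fat legitimately occurs as multiple
deposits; insertion points are discrete by definition and are instead
required to touch both bundle and ventricle).

Infarction options shrink the SN (volume scale), thin the bundle paint
radius, and add a spherical transmural scar that replaces working
ventricular myocardium only — conduction-system voxels inside the sphere
survive, as traced structures do in segmentations.

## Morphometry conventions

Short-axis planes are z-slices: the base plane is one slice inferior to the
lowest valve voxel, the apex plane the last slice toward the apex showing
both ventricular cavities (4-connected in-plane components), mid their
floor midpoint; coronal planes use the same rule along y. Wall thickness is
a ray measurement: the distance along the ray between entering and leaving
the target code, sampled at an eighth of a voxel, so oblique rays measure
obliquely — exactly as manual rays do. The three-ray session places
parallel rays at 25/50/75% of the ventricles' in-plane extent; parameter
recovery is asserted on the central ray, which crosses the free walls
perpendicularly (the outer rays overestimate on curved walls by
construction). Chamber diameter is the longest in-plane run of the cavity
code along the axis orthogonal to the septum, measured in-plane only.
Structure volume is voxel count × voxel volume; conservation (per-label
volumes summing to the labeled total) is exact by construction.

Down-sampling by an integer factor takes a per-block majority vote with
ties broken by a fixed priority (conduction system first, then fast atrial
pathways, valve, fat, myocardium, cavities, background), protecting the
thin structures whose connectivity controls the activation sequence. How
the original factor-4 pooling was done is not stated anywhere; majority
with protective ties is this package's documented choice, and the
volume-agreement test (≤ 10% at factor 4 on the phantom) bounds its
distortion.

## Problem sizes and runtimes

All defaults are desk-scale by intent: the calibration slab holds ~12,500
tissue nodes and calibrates in a few seconds; a phantom beat (56,000 nodes,
$\Delta t = 0.01$ ms, early-stopped around 160–190 ms of simulated time)
runs in well under a minute. The whole-heart resolution this emulates
(tens of millions of grid nodes) is explicitly not a desk target; nothing
in the method changes with scale except wall-clock time, and the
property-based suite covers the physics at the small scale.

## Known limitations

* Isotropic scalar D; no fibre architecture, no bidomain, no ECG.
* Single-beat protocols only; no restitution, alternans or re-entry.
* The cell model is a sequence-oriented caricature: no concentration
  dynamics, broad peak, and APD/upstroke targets realised by scaling rather
  than by fitting published waveforms.
* Chamber diameters are measured in-plane; whether the original manual
  measurements were 3D is unknowable from the text, and the in-plane choice
  is flagged here.
* The phantom's atria sit on a flat valve sheet; regions of the atrial
  floor outside the ventricular footprint are separated by background
  rather than by valve tissue — electrically equivalent (both are no-flux),
  anatomically simplified.
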