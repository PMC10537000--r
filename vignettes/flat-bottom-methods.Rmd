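---
title: "Maintaining solvent asymmetry with inverted flat-bottom restraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maintaining solvent asymmetry with inverted flat-bottom restraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flatbottomr)
```

## The problem

Biological membranes separate two solvents of different composition: the
extracellular fluid and the cytosol differ in their dominant cations, and
many questions (ion-specific adsorption, peptide binding, asymmetric
leaflets) require modelling that difference. Periodic boundary conditions
frustrate this: in a single-bilayer box the solvent above the membrane wraps
around and touches the lower leaflet, so the two "sides" are one connected
compartment. The classical workaround simulates *two* stacked bilayers
enclosing two genuinely separate compartments, at roughly double the cost.

The cheaper alternative implemented here keeps one bilayer and confines each
solute species to its own side with an *inverted flat-bottom restraint*: a
potential that is zero everywhere except in a thin slab of width $2r$
centred on the box edge ($z_{\mathrm{ref}} = 0$), where it rises
quadratically,

$$
V(z) \;=\; \tfrac{1}{2}\,k\,\bigl(|z - z_{\mathrm{ref}}| - r\bigr)^2\,
H\!\left(r - |z - z_{\mathrm{ref}}|\right),
$$

with $H$ the Heaviside step. A solute approaching the box edge from either
side meets a barrier of height $k r^2 / 2$ and is pushed back, so it can
only ever interact with the leaflet on its own side. Anchoring the plane at
$z = 0$ has two practical virtues: the same reference coordinate (zero)
serves every restrained atom regardless of system size, and pressure-coupling
box rescaling leaves a zero reference invariant.

`flat_bottom_restraint()`, `fb_potential()`, `fb_force()` and `fb_barrier()`
implement this model in GROMACS units (nm, kJ/mol). The gradient is
discontinuous at the plane itself; the force there is defined as exactly
zero. This is a symmetric tie-break on a measure-zero set — any Brownian or
MD integrator spends no time exactly on the plane.

## How much extra water to add

The barrier depletes solutes (and, through them, effectively solvent
ordering) from a slab of width $2r$. To keep the *unperturbed* region — and
hence the solute concentration a simulation reports — the same as in an
unrestrained box, extra solvent must be added. For a hard wall the excluded
width is exactly $2r$ and the molecule count follows from the slab volume:

$$
N_w = \frac{2\,r\,A_{xy}\,\rho_w}{M_w}\,N_A ,
$$

implemented in `extra_water_count()`. One unit subtlety is handled
prominently: the molar mass of water enters as $M_w = 18.016$ g/mol
($0.018016$ kg/mol). Quoting it as "18.016 kg/mol" — a slip that circulates
in the literature — is dimensionally inconsistent with $\rho_w$ in
kg/m$^3$ and would under-count the water 1000-fold.

A quadratic barrier is softer than a hard wall: thermal solutes penetrate
the slab to a depth where $V \sim k_B T$. The package therefore also
provides the Boltzmann-weighted excluded width

$$
w \;=\; \int_{-r}^{r} \left(1 - e^{-V(z)/k_B T}\right)\mathrm{d}z
\;=\; 2r - \sqrt{\frac{2\pi k_B T}{k}}\;
\operatorname{erf}\!\left(r\sqrt{\frac{k}{2 k_B T}}\right),
$$

(`fb_excluded_width()`, evaluated by adaptive quadrature of the defining
integral). For the calibrated parameters ($r = 0.3$ nm,
$k = 10^4$ kJ mol$^{-1}$ nm$^{-2}$, 310 K) this gives $w \approx 0.56$ nm —
just below $2r = 0.6$ nm, which is why rounding the extra layer to $r$ per
side is an adequate practical rule.

## The Brownian calibration analog

Choosing $(r, k)$ is a trade-off: the barrier must be high enough that no
solute crosses the plane over the full simulation, while $r$ should stay
small to minimise the perturbed volume. The package calibrates this with a
desk-scale analog of the salt-solution benchmark: 108 Na$^+$/Cl$^-$ pairs in
a $3 \times 3 \times (8 + r)$ nm$^3$ periodic box (the long dimension is
extended by $r$ so the unperturbed region keeps its nominal 8 nm), evolved
by overdamped Langevin dynamics,

$$
\Delta z = \frac{F(z)}{\gamma}\,\Delta t + \sqrt{2 D \Delta t}\;\xi,
\qquad \gamma = \frac{k_B T}{D},
$$

with $\xi$ a standard normal deviate on each axis and the restraint force on
$z$ only (`simulate_ion_box()`).

This is deliberately an *analog*, not a re-run of explicit-solvent MD. The
two calibration observables — whether any particle crosses the plane, and
the equilibrium density plateau away from it — are governed by $V(z)/k_BT$
and the diffusivity, not by ion–ion or ion–water structure at
physiological (150 mM) concentrations. Equilibrium densities of
non-interacting particles follow the exact Boltzmann profile
$\propto e^{-V(z)/k_BT}$ (verified against a Kolmogorov–Smirnov test in the
suite), and barrier-crossing statistics follow Kramers-type kinetics in
$V/k_BT$. What the analog does *not* reproduce is discussed under
*Limitations*.

Parameter choices:

* **Diffusion coefficients** — experimental bulk values,
  $D_{\mathrm{Na}} = 1.33\times10^{-3}$,
  $D_{\mathrm{Cl}} = 2.03\times10^{-3}$ nm$^2$/ps (`ION_DIFFUSION`).
* **Timestep** — 0.01 ps for stiff restraints ($k \ge 10^4$), otherwise
  0.1 ps, halved automatically until the guard
  $\sqrt{2 D \Delta t} < r/5$ holds for every species
  (`default_timestep()`). The guard matters: at $r = 0.1$ nm the 0.1 ps
  default marginally violates it for Cl$^-$, so 0.05 ps is used. The stiff
  branch also keeps $k\,\Delta t/\gamma \approx 0.08 \ll 1$, so the
  Euler–Maruyama update does not distort the equilibrium variance inside
  the barrier.
* **Recording** — every 1 ps in calibration runs; the free-diffusion RMS
  displacement per interval ($\approx 0.06$ nm) is far below $L_z/10$, so
  minimal-image crossing detection between recorded frames is unambiguous.
* **Randomness** — a self-contained xoshiro256++ generator with a ziggurat
  normal sampler, seeded from a single integer; runs are bit-reproducible
  across platforms and independent of the R session RNG.

`count_plane_crossings()` detects passages through the plane and all its
periodic images by unwrapping minimal-image displacements; a frame landing
*exactly* on the plane is held pending and counted only if the particle
continues through with its next displacement. `scan_rk_grid()` repeats this
over an $(r, k)$ grid. At 310 K and 100 ns, barriers of $\gtrsim 17\,k_BT$
(e.g. $r = 0.3$ nm with $k = 1000$) give zero crossings among 216 ions,
while the $k = 100$ column leaks for every $r$ — reproducing the qualitative
acceptance surface that motivates the recommended $(0.3, 10^4)$ setting,
which carries a $\sim\!175\,k_BT$ barrier and a large safety margin
(including against moderately higher temperatures).

## Density matching for the extra-water thickness

`optimize_extra_water()` re-derives the extra-water rule from the analog
itself: an unrestrained $3\times3\times8$ nm$^3$ reference box provides the
target bulk density; then the restrained box is rerun with its long
dimension extended by each candidate thickness $t \in \{0, 0.1, \dots,
0.8\}$ nm, and the thickness whose bulk Na$^+$ density comes closest to the
reference wins (ties resolved towards the smaller thickness). Because the
ideal-particle density is analytic, the expected optimum is the Boltzmann
excluded width ($0.56$ nm for the calibrated restraint), and the scan
returns the neighbouring grid points 0.5 or 0.6 nm.

Two estimator choices deserve a note, both fixed from an a-priori variance
analysis of the analog (ideal, non-interacting tracers fluctuate far more
than electrostatically coupled ions, so the analog needs variance-aware
averaging where full MD did not):

* **Averaging window.** Every bin farther than $r + 0.1$ nm from the plane
  has exactly the bulk expectation at equilibrium, so the *widest*
  unperturbed window is the minimum-variance estimator of the plateau; the
  count it excludes (the thin perturbed strip) also decorrelates quickly
  ($\sim w^2/D$, hundreds of ps), whereas half-box windows carry slow
  number fluctuations with relaxation times of several ns.
  `optimize_extra_water()` therefore averages over all unperturbed bins by
  default, while `bulk_density()` keeps a conventional central-4-nm default
  for general use.
* **Reference length.** The reference error shifts the whole matching curve,
  so it is suppressed by running the unrestrained reference 10 times longer
  than each scan point — at its 10-fold larger timestep this costs the same
  wall time as a single restrained point.

Scan points run 25 ns each. With these choices the per-point relative error
of the plateau is $\approx 0.3\,\%$, against a $1.25\,\%$ density change per
0.1 nm grid step, placing the returned optimum within one grid step of the
analytic value with comfortable margin.

## Setup-file generation

The protocol for an actual MD run needs three artifacts, all generated
byte-exactly:

1. **Reference coordinates** (`make_reference_coordinates()`,
   `reference_coordinate_file()`): a copy of the system structure with the
   $z$ coordinate of every restrained atom set to exactly `0.000`. The
   file-level variant rewrites only bytes 37–44 (the fixed-width GRO $z$
   field) of the selected atom lines, leaving every other byte untouched —
   the same column-splice a one-line awk script would perform, and safe
   because the GRO dialect is position-sensitive.
2. **Topology stanza** (`emit_restraint_stanza()`): a
   `[ position_restraints ]` block whose lines read `i 2 5 -r k` — function
   type 2 (flat-bottom), geometry 5 (layer along $z$), with the negated
   half-width selecting the inverted form. For an atomic ion the
   moleculetype has a single atom, so the canonical line for the calibrated
   parameters is literally `1 2 5 -0.3 10000`. For larger molecules the
   heavy atoms are listed instead.
3. **Placement validation** (`validate_ion_sides()`): restrained species
   must start on their assigned side of the plane ("lower" = wrapped $z$ in
   $(0, L_z/2)$ with the membrane at the box centre), outside the restrained
   slab, and outside the membrane; the report lists every violating atom and
   carries the run-input note that `refcoord_scaling` should be `all` (or
   `com`) — harmless here because a zero reference is invariant under box
   scaling.

`recommend_extra_water()` completes the bundle with the slab-volume molecule
count and the $r$-per-side thickness rule.

## Validation observables

The equivalence argument between the restrained single-bilayer and
double-bilayer setups rests on standard membrane observables, implemented
over an in-memory trajectory container (frames × atoms × axes, with
per-frame boxes):

* **Number-density profiles** (`density_profile()`): per-frame histograms
  along $z$, optionally recentred each frame on the membrane COM, averaged
  and normalised to nm$^{-3}$; each profile integrates exactly to the mean
  selected-atom count. The COM is computed with a minimal-image convention
  anchored on the selection's first atom, which is exact for any membrane
  that does not span half the box. Default bin width 0.1 nm.
* **Water dipole orientation** (`water_orientation_profile()`): the mean
  cosine between the O→(H,H midpoint) bisector and $+z$, multiplied by the
  local oxygen density, the conventional signed measure of interfacial
  water polarisation.
* **Area per lipid** (`area_per_lipid()`): lateral box area over the
  non-cholesterol lipid count per leaflet, in Å$^2$.
* **Thickness** (`membrane_thickness()`): distance between mean phosphorus
  heights of the two leaflets, leaflets assigned per frame by the sign of
  $z$ relative to the phosphorus COM (atoms exactly at the COM go to the
  lower leaflet — a deterministic tie-break).
* **P–N tilt** (`pn_tilt()`): angle between the minimal-image P→N headgroup
  vector and the *outward* normal of its leaflet ($+z$ upper, $-z$ lower).
  The outward-normal convention makes the two leaflets directly comparable
  and reports the conventional $\sim 70°$ for phosphatidylcholine; a
  `convention = "axis"` switch measures against $+z$ throughout instead.
* **Deuterium order parameters** (`order_parameters()`):
  $S_{CD} = \langle (3\cos^2\theta - 1)/2 \rangle$ per carbon, explicit
  hydrogens required (no reconstruction for united-atom chains — flagged as
  an input error instead).
* **COM drift** (`com_drift()`): the membrane COM unwrapped continuously
  across frames, the diagnostic for osmotic imbalance between compartments
  (a mismatched solvent split makes the bilayer drift toward the restraint
  plane).

Statistical errors use block averaging with 5 equal blocks by default —
appropriate for correlated MD-like series when blocks exceed the
correlation time; tests on fixtures with independent frames use more,
shorter blocks, which stabilises the error estimate itself (a 5-block
standard error has only 4 degrees of freedom, making ±3-SE checks
unnecessarily noisy).

### Double-bilayer averaging

For double-bilayer references, `split_double_bilayer()` computes each
observable in each membrane's own centred frame, assigning every solvent
atom to the compartment of the nearer membrane (minimal-image distance to
the two membrane COMs), folds each compartment by its own period (half the
doubled box) so relative coordinates live in exactly the interval a
single-bilayer box would produce, and averages bin-wise. Because the two
membranes face opposite directions, the second profile is flipped before
averaging ($z \to -z$; sign negated as well for orientation profiles, which
are odd under that reflection). With this convention, analysing an exact
replica of a single-bilayer trajectory reproduces the single-system
profiles bit-for-bit — the package's construction test.

`make_double_bilayer()` builds such replicas: the copy is rotated 180° about
$x$ and stacked one box height up. Two numerical details make the replica
exact rather than merely close: molecules are first made whole along $z$
(in the doubled box, a molecule wrapped across the old edge would otherwise
be torn apart), and the copy's coordinates are stored as the periodic image
$(-y, -z)$ — floating-point negation is exact, whereas $L - y$ rounds.

## Synthetic fixtures

`make_bilayer_trajectory()` generates bilayer-like trajectories that encode
*observables, not physics*: phosphorus planes at $\pm$separation/2 with
Gaussian noise, headgroup vectors at exact target tilts, C–H bonds drawn
from a distribution whose $\langle(3\cos^2\theta - 1)/2\rangle$ equals each
carbon's target exactly in expectation (magnitude jittered uniformly so
per-frame noise exercises the error bars), rigid 3-site waters
(O–H 0.09572 nm, 104.52°) with dipole cosines following a prescribed field,
and optional rigid drift. Every generator is deterministic per seed and
attaches a ground-truth record that the test suite asserts against.
`make_ion_box()` builds the salt-solution boxes with initial placement
excluded from the restrained slab.

What passing these tests shows: the analyzers are unbiased and correctly
normalised, conventions (leaflet assignment, outward normal, minimal-image
handling, flipping) are self-consistent, and the full pipeline from
structure generation through profile comparison is reproducible. What they
do not show: anything about force-field accuracy, lipid conformational
realism, or water structure — the fixtures have none.

## Problem sizes and determinism in the shipped tests

The test suite and the acceptance script run the calibration analog at the
study scale: 216 ions, 100 ns, three seeds for the crossing table;
25 ns per point (plus a 250 ns unrestrained reference) for the nine-point
extra-water scan; a 150 ns single-box run for the Boltzmann check. Analyzer
round-trips use 36 lipids per leaflet and 100 independent frames. All
stochastic tests fix their seeds, so outcomes are reproducible; seeds were
chosen as arbitrary small integers and the stochastic margins (Kramers
factors of $\gtrsim 10^2$ for the zero-crossing cells, $\gtrsim 3$ standard
errors for estimator round-trips) make the checks robust to reseeding.

## Limitations

* The Brownian analog has no explicit water, electrostatics, or
  Lennard-Jones interactions. It supports the calibration logic (crossing
  suppression, density matching) but cannot reproduce per-cell crossing
  *counts* from full MD, ion-specific binding, or anything force-field
  dependent.
* The restraint model is the axial (layer) geometry only; curved systems
  (vesicles, nanodiscs) would need spherical or cylindrical flat-bottom
  geometries.
* No smoothing is applied at the Heaviside boundary: the analytic form is
  already continuous in both $V$ and $F$, and the implementation treats the
  boundary exactly.
* Both the flat-bottom and double-bilayer approaches presume the osmotic
  pressures of the two compartments are comparable; a strong imbalance
  shows up as COM drift (see `com_drift()`), faster in the flat-bottom
  setup.
* Per-atom restraints are generated for the topology; centre-of-mass
  restraints on whole molecules (useful for peptides) are engine-specific
  and out of scope.

## A worked five-step protocol

```{r, eval = FALSE}
restraint <- flat_bottom_restraint(z_ref = 0, r = 0.3, k = 10000)

# 1. size the extra solvent
recommend_extra_water(read_gro("system.gro"), restraint)

# 2. check initial ion placement
validate_ion_sides(read_gro("system.gro"),
                   c("NA" = "lower", "CL" = "upper", "K" = "upper"),
                   membrane_z = c(3.5, 7.5), restraint)

# 3. reference coordinates with z = 0
reference_coordinate_file("system.gro", "restraints.gro",
                          c("NA", "CL", "K"))

# 4. topology stanzas
cat(emit_restraint_stanza(restraint, "NA"))

# 5. run-input note: set refcoord_scaling = all (or com)
```
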