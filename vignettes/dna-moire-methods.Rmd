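---
title: "Modelling seeded DNA moiré superlattices: geometry, nucleation and Fourier recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seeded DNA moiré superlattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamoire)
```

# The system

Twisted DNA origami nanoseeds template the stacked growth of micrometre-scale
two-dimensional single-stranded-tile (SST) lattices. The seed is a hollow
helix bundle whose segments alternate between *growth* regions, on which an
SST sublattice nucleates and grows in plane, and short *spacer/twister*
regions, which set the interlayer spacing and impose a right-handed twist
between consecutive layers. Two stacked sublattices of constant
$a_\mathrm{sub}$ twisted by $\theta$ form a moiré superlattice of periodicity

$$p_M = \frac{a_\mathrm{sub}}{2\sin(\theta/2)},$$

the exact relation used everywhere in this package (the familiar small-angle
form $p_M \approx a_\mathrm{sub}/\theta$ is available as
`moire_period_small_angle()` for comparison only). With nanometre-scale
sublattice constants and twists of a few degrees, $p_M$ spans tens of
nanometres — between the ångström-scale moirés of twisted bilayer graphene
and the micrometre-scale moirés of twisted photonic lattices.

The package implements the computational side of this system as five layers
that mirror the physical pipeline: seed geometry (`compile_stack()` and
friends), sublattice generation (`generate_lattice()`,
`reciprocal_basis()`), moiré mathematics (`moire_period()`,
`moire_reciprocal()`, gradient fields), nucleation thermodynamics and
kinetics (`nucleation_rates()`, `simulate_growth()`), and image analysis on
synthetic micrographs (`render_layers()`, `analyze_micrograph()`,
`orientation_map()`).

# Seed geometry

A seed design is an ordered list of segments, each a base-pair count with a
role and a twist. Heights follow the canonical B-DNA axial rise of
0.34 nm/bp (configurable); this single constant reproduces all four design
heights printed for the two seed families (128 bp → 43.5 nm, 32 bp →
10.9 nm, 36 bp → 12.2 nm, 126 bp → 42.8 nm) to 0.1 nm. `segment_height()`
returns the exact product; rounding is left to reporting so that height is
exactly additive over concatenated segments and `compile_stack()` conserves
total height.

Twist rates are *calibration constants per array type* — 3.8° per 32-bp
spacer for the square-array seed and 1.2° per 36-bp spacer for the
honeycomb-array seed — taken from coarse-grained simulation results quoted
with the designs. Predicting them from first principles (helix mechanics of
the bundle) is explicitly out of scope; segments therefore store their twist
directly, and `segment_twist()` is the bp-to-angle helper.

```{r stack}
compile_stack(seed_preset("S"))
```

Growth segments relax to the untwisted sublattice (2D SST lattices have an
enormous torsional persistence length), so a layer's orientation is the
cumulative sum of the *spacer* twists below it — the design's registry rule.

The gradient seed preset (`seed_preset("SG")`) has a trapezoidal second
growth segment: its parallel face b carries only the spacer twist
$\theta \approx 2.8^\circ$, while the tilted face a adds
$\Delta\theta \approx 10.9^\circ$ for a total of $13.7^\circ$. Both angles
are stored design inputs: the bp-level trapezoid construction and the
geometric origin of $\Delta\theta$ are not modelled, and the 24-bp length
recorded for its spacer is the length consistent with the square-array twist
calibration, chosen here because the design tables do not pin it down.

# Sublattices and reciprocal space

Three sublattice symmetries are supported, each with a hydrated (cryo-EM)
and a dried (TEM-grid) lattice-constant preset: square 2.8/2.2 nm, kagome
5.4/4.4 nm, honeycomb 4.4/3.5 nm. `shrinkage()` swaps a spec between the
presets. $a_\mathrm{sub}$ is always the Bravais cell constant; for the
hexagonal symmetries the first-order diffraction spacing is
$d = \tfrac{\sqrt3}{2}a_\mathrm{sub}$, and all image-analysis routines apply
this factor so that reported constants stay on the conventional scale.

The kagome net deserves a note, because it admits two equivalent
descriptions and the package implements both:

* the **canonical** kagome (trihexagonal) lattice — hexagonal Bravais cell
  of constant $a_k$ with a three-site basis — is what
  `lattice_spec("kagome")` generates. Its first-order reciprocal families
  sit at mutual 60°/120°, matching observed FFT patterns;
* the **constructive** view of a loosely packed square lattice with one site
  of every 2×2 block removed (void fraction 1/4, cell constant doubled to
  $a_k = 2a_s$) is returned by `kagome_from_square()`. This is the view
  that explains how a square-array seed can template kagome growth. The
  specific periodic void pattern is this package's choice; the tile-level
  void arrangement is not printed in the design material, so the voided net
  is a stand-in with the right density and cell constant.

`generate_lattice()` enumerates lattice-plus-basis points of the rotated,
translated net inside a closed rectangular region (boundary points
included), and `reciprocal_basis()` returns the first-order $g$-vector
families with $|g| = 1/d$ (crystallographic convention, no $2\pi$).

# Moiré mathematics

`moire_period()` and `twist_from_period()` are exact inverses on
$\theta \in (0^\circ, 180^\circ]$; zero twist maps to an infinite-period
sentinel. `moire_reciprocal()` forms all pairwise differences
$g_1 - R(\theta)\,g_2$ between first-order families (including sign
partners): for identical layers the smallest non-zero difference has
magnitude $2|g|\sin(\theta/2)$, the reciprocal dual of $p_M$ — exactly
$1/p_M$ for square layers, and $\tfrac{\sqrt3}{2}\cdot$ that for hexagonal
layers, where the moiré superlattice itself is hexagonal and carries the
same $d/a$ factor. For hybrid stacks (e.g. square 2.2 nm over kagome
4.4 nm) the brute-force difference set is the prediction; no closed form is
assumed.

A gradient bilayer is described by an `orientation_field_spec()`: the local
second-layer twist runs from $\theta_a$ (tilted face) at the boundary
azimuth to $\theta_b$ (parallel face) after a full turn along the gradual
direction, with the single sharp discontinuity at the boundary. The
interpolation is linear in azimuth — the observations show only that the
change is "gradual", so the simplest monotone form was chosen and is
configurable. `local_period_map()` turns a twist field into a local-$p_M$
heat map; with the default faces the endpoints are 45.0 and 9.2 nm.

# Nucleation: capture patterns, wetting, and rates

Seeded nucleation is controlled by capture strands on the seed's lateral
surface. A site is a *capture pair* (enabling cooperative, double-domain
tile binding) only when both its capture-0 and capture-1 strands are
present. `classify_capture_pattern()` reduces a pattern to its mode — fully
cooperative (all pairs), non-cooperative (no pairs), or partial — plus the
longest vertical run of pairs, because z-continuity is what separates
effective partial seeds from ineffective ones.

The thermodynamic model is deliberately minimal classical nucleation
theory in two dimensions, chosen because SST lattice growth is planar: a
disc nucleus with line tension $\Gamma$ gives a homogeneous barrier

$$\Delta G^* = \frac{\pi \Gamma^2}{\Delta g(T)},\qquad
\Delta g(T) = \Delta h\,\frac{T_m - T}{T_m}$$

(absolute temperatures; reduced units with $k = 1$), and a seed surface with
contact angle $\psi$ scales it by the 2D wetting factor

$$f(\psi) = \frac{\psi - \sin\psi\cos\psi}{\pi} \in (0, 1].$$

These forms are documented stand-ins constrained to reproduce the reported
qualitative behaviour — the detailed derivation behind the published rate
curves is in supplementary material not available to this implementation.
What the model provably reproduces, and what the tests assert, is the
phenomenology: $R = N_\mathrm{hetero}/N_\mathrm{homo} \equiv 1$ when
$f = 1$ with matched prefactors; $R$ strictly increasing in $T$ for
$f < 1$ (on grids above $T_m/2$ in absolute terms, always true at
experimental temperatures), so selectivity peaks toward the melting
temperature where absolute rates collapse; and a high-wetting curve that
dominates a low-wetting curve pointwise, keeping seeded growth selective
over a broad temperature range. The default mapping from capture mode to
contact angle (fully → 30°, partial-with-z-run → 90°, otherwise → 180°) is
an arbitrary but documented calibration, configurable per call; only its
ordering matters for every conclusion drawn here.

# The growth simulator

`simulate_growth()` runs an exact Gillespie simulation (tau-leaping
switchable) of a well-mixed pool: homogeneous nucleation at a rate
proportional to $N_\mathrm{homo}(T)$ times the free-tile fraction, per-seed
heterogeneous nucleation at the wetting-reduced barrier (each seed
nucleates at most once), and perimeter-limited growth of each structure at
a rate proportional to $\sqrt{\mathrm{size}}$ times the free-tile fraction
(area-independent growth is selectable). All rates are in reduced units: no
kinetic constants are published, so the simulator is a trend instrument,
not a calibrated one, and the experimental percentages are direction
anchors only. The default kinetic prefactors make a single seed contribute
about $10^{-5}$ of the bulk's nucleation attempt frequency, reflecting how
few nucleation sites a nanoseed offers compared with the whole solution;
with the default barrier scale ($\Gamma = 8$, $T_m = 45\,^\circ$C) the
fully-wetting regime then suppresses homogeneous nucleation at 40 °C and
loses that suppression by 34 °C, mirroring the reported temperature window.

Simulated trends reproduced (and asserted over ≥ 20 paired replicates
sharing RNG seeds): mass conservation on every trajectory; more seeds →
smaller and tighter lattice-size distributions; lower temperature → lower
seeded fraction; no barrier reduction ($f = 1$) → seeded fraction
indistinguishable from the unseeded baseline.

# Synthetic micrographs

`render_layers()` turns point sets into micrograph-like images: each
lattice point becomes an isotropic Gaussian spot (default
$\sigma = 0.6$ nm) of unit integrated weight, stamped exactly (truncated at
$5\sigma$) on a calibrated pixel grid — exact stamping matters, because
interpolation-based splatting leaves aliasing ghosts in the spectrum that
masquerade as forbidden reflections. Defaults: 0.5 nm/px, 1024² px,
additive Gaussian read noise at 2 % of the dynamic range, optional Poisson
shot noise, optional central seed disc; rendering refuses pixel sizes above
$a_\mathrm{sub}/4$. The noise-free rendering is strictly linear in the
point sets, and all noise is driven by a mandatory RNG seed.

What the generator emulates: superposed rotated point lattices, gradient
(azimuthally varying) second layers, finite spot size, read and shot noise,
a seed disc. What it does not emulate: TEM contrast physics (defocus, CTF,
stain granularity), 3D projection, lattice defects, twin boundaries, or
edge faceting — so passing recovery tests demonstrate correctness of the
analysis chain on clean lattices, not robustness to every artefact of real
micrographs.

For the gradient scene the second layer is built by rotating each point
about the seed centre by the field value *at its final azimuth* (solved by
fixed-point iteration, the field slope being a strong contraction): naively
rotating by the field at the starting azimuth sweeps strongly rotated
points across the discontinuity and double-covers the sector behind it.

# Fourier recovery

`power_spectrum()` computes the Hann-windowed (default) magnitude spectrum
with axes in nm⁻¹. `detect_peaks()` finds local maxima above
`min_snr` × the annulus median, refines them by a 3×3 centre of mass
(ties: larger magnitude, then smaller $|g|$), and merges conjugate
partners. `estimate_lattice()` folds peak azimuths into the symmetry's
fundamental zone (90° square, 60° hexagonal — acute twists only), clusters
them by cutting the largest circular gaps, discards peaks below 5 % of the
strongest (layer families have comparable strength; residual noise maxima
do not), and reports per-family lattice constants, orientations (circular
means, magnitude-weighted) and their twist. Families separated by less than
0.5° collapse to a monolayer flag. The sublattice annulus defaults to the
expected $a_\mathrm{sub} \pm 30\%$ when a constant is supplied.

Moiré periods need one extra step: a linear spectrum of a *sum* of two
lattice images contains no difference frequencies, so
`estimate_moire_period()` squares the mean-subtracted image first. The
quadratic term carries peaks at all pairwise $g_1 - g_2$ differences — the
analysis-side analogue of the contrast nonlinearity that makes moiré
fringes visible in real micrographs — and the dominant peak below the
sublattice band gives $p_M$.

`orientation_map()` repeats the estimate in sliding windows (regular grid —
a deliberate difference from by-eye selected areas) and converts local
twist to local $p_M$ through the exact relation. Windows that straddle the
gradient discontinuity mix both branches; the azimuthal ring profile
therefore resolves the endpoint periods only when the window's azimuthal
subtense is small, which is why the gradient analysis uses a 1024-nm field
with 128-nm windows on a ring 330–480 nm from the seed.

# Numerical choices and problem sizes

* Angles are degrees in every interface, right-handed about $+z$; circular
  statistics are used throughout for azimuths.
* Region clipping and annulus bounds are closed; boundary points included.
* Zero twist, empty structures and unresolvable windows return documented
  sentinels (`Inf`, `NA`) rather than errors.
* Recovery validation uses a 3 symmetries × {2°, 5°, 10°} × 3 noise-seed
  sweep at 1024² px and 0.5 nm/px, the size at which first-order and moiré
  peaks are both comfortably resolved; the gradient analysis uses a single
  2048² scene. The stochastic-growth checks use pools of 3000–5000 tiles
  and 20 paired replicates. These sizes were chosen so every documented
  claim is exercised by direct computation at comfortable statistical
  margins.

# Known limitations

* The CNT expressions are stand-in forms: quantitatively fitting measured
  bilayer fractions or rate curves is out of scope by design.
* The kagome void pattern and the gradient interpolation form are package
  choices where the source material is silent; both are configurable.
* Printed measured pairs that are mutually inconsistent with the exact
  moiré relation (the kagome 26 nm/8.9° and honeycomb 42 nm/4.5° pairs read
  off independent measurements) are treated as observations, not as
  constraints on the mathematics.
* The simulator is well-mixed: no spatial diffusion, no tile-level lattice
  geometry during growth, one nucleation per seed.
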