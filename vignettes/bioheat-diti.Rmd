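---
title: "Modelling dynamic infrared thermography of thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dynamic infrared thermography of thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrotherm)
```

## The question the package addresses

Dynamic infrared thermography (DITI) of the neck records skin temperatures
while the patient recovers from a mild cold stress: the neck is cooled with a
fan for up to five minutes, then an infrared camera captures one thermogram
every 15 s for five minutes of natural reheating. Whether a thyroid nodule --
and which of its properties -- leaves a usable signature in those skin
temperatures is a bioheat-transfer question. `thyrotherm` answers it in
silico: it solves Pennes' bioheat equation on a two-dimensional cross-section
of the neck, drives the solution through the examination protocol, and
extracts exactly the quantities a thermography study would read off the
camera: skin temperature profiles, probe time series, and
region-of-interest series from (synthetic) thermogram frames.

## Model

Temperatures are in degrees Celsius throughout; the model is linear in $T$,
so no offset to Kelvin is needed. In each tissue region,

$$\rho c \,\partial_t T \;=\; \nabla\!\cdot(k \nabla T)
  \;+\; w_b \rho_b c_b\,(T_b - T) \;+\; Q_m ,$$

with $k$ the thermal conductivity, $\rho c$ the volumetric heat capacity,
$w_b$ the blood perfusion rate (volume of blood per volume of tissue per
second), $\rho_b c_b$ the blood's volumetric heat capacity (taken equal to
the host tissue's own, as is conventional when no separate blood data are
used), $T_b = 37$ the arterial temperature, and $Q_m$ the metabolic heat
(W/m^3^). The steady problem drops the time derivative. Perfusion acts as a
relaxation toward $T_b$ with volumetric conductance $W = w_b \rho_b c_b$; an
unbounded tissue sits at the fixed point $T_b + Q_m/W$.

Boundary conditions mirror the examination room: Newton cooling
$-\mathbf{n}\cdot k\nabla T = h\,(T - T_\mathrm{air})$ on the anterior skin
arc $\Gamma_1$ ($h = 10$ W/(m^2^K) in still air, $h = 50$ under the fan,
$T_\mathrm{air} = 25$), an insulated tracheal wall $\Gamma_2$, and a
prescribed core temperature of 37 on the posterior arc $\Gamma_3$. The
protocol chains three stages -- steady state, 300 s of forced cooling,
300 s of natural reheating -- each stage starting from the final field of
the previous one.

### The perfusion-units ambiguity

The tabulated gland perfusions (thyroid 0.098, nodule 0.465 (mL/s)/mL) are
two orders of magnitude above the other tissues. Taken literally, they give
$W \approx 3.7\times10^5$ and $1.8\times10^6$ W/(m^3^K): both gland tissues
are clamped to within 0.01--0.02 degC of arterial temperature and no
metabolic contrast can survive, whatever $Q_m$. Read as per-minute rates
(divide by 60), the malignant-like nodule ($Q_m = 42{,}000$, $w_b = 0.465$)
runs about 1.4 degC hot at its core, which is what the reference
temperatures for the nodule interior reflect. Neither reading can explain
every reported number at once, so both are kept as explicit presets
(`as_printed`, `per_minute_gland`) on `tissue_registry()`, every result
records which preset produced it, and the two reference quantities that are
only consistent with the *other* preset are reported as computed and
documented as irreconcilable (see *Known disagreements*).

## Geometry

The cross-section is a circle of perimeter 36 cm with concentric skin
(1 mm), fat (0, 3, 6 or 12 mm) and muscle (10 mm) layers; inside sit two
mirrored elliptic thyroid lobes, an elliptic nodule in the left lobe, and a
circular tracheal hole (radius 1.2 cm) on the sagittal axis. The nodule size
presets are stored as semi-axes -- small (1.2, 0.7) cm, medium (2.2, 1.26) cm,
large (3.14, 1.80) cm -- so their areas are $\pi a b$ = 2.64, 8.71 and
17.76 cm^2^, matching the documented nodule areas exactly.

Several placement choices are genuinely open and materially affect skin
contrast; the package fixes them once, as follows, and records every
primitive in the run metadata (`geometry_to_json()`):

* **Nodule direction.** The nodule centre lies on the radial ray 30 degrees
  to the patient's left of the anterior midline, putting the skin point in
  front of the nodule at arc coordinate $-3$ cm, where the reference skin
  profiles place their warm spot.
* **Depth anchoring.** The lobe is positioned so the large nodule's outer
  edge sits directly beneath the tissue stack, at depth skin + fat + muscle.
  A thicker fat layer therefore pushes the gland deeper, which is the
  anatomical reading of "adding subcutaneous fat" at fixed neck perimeter.
* **Concentric sizes.** All nodule presets share the lobe centre, so smaller
  nodules sit deeper in the gland. This is what makes nodule size matter:
  anchoring all sizes at equal depth instead would nearly erase the size
  effect at the skin.
* **Orientation.** The major axes are tangential (perpendicular to the
  radial), the only orientation under which the large nodule fits between
  the tracheal hole and the fat layer for every fat thickness: the ellipse's
  minimal width is 3.6 cm, wider than any radial corridor left by an
  anteriorly-placed trachea.
* **Trachea.** For the same reason the tracheal circle cannot sit anterior
  to the gland; it is placed on the sagittal axis at (0, -2.1) cm, posterior
  to the gland, where it keeps at least 3.5 mm clearance from the lobes in
  every case. Since its wall is insulated and deeply embedded in
  near-arterial tissue, its exact position has little influence on skin
  temperatures.

One consequence is worth stating plainly: with semi-axes of (3.14, 1.80) cm
the large nodule is so large that it crosses the sagittal midline, and the
mirror image of the nodule centre -- the natural "healthy lobe" probe --
falls *inside* the nodule. Its reading is therefore nodule-core-like
(~38.2) rather than healthy-gland-like (~37.2). No placement compatible
with the $-3$ cm arc position avoids this; see *Known disagreements*.

## Numerics

**Meshing.** All interface curves (layer circles, trachea, lobe and nodule
ellipses) are sampled at or below the target edge length `h_target`; thin
layers cap the sampling (2.2x the layer thickness) so elements spanning
them keep healthy angles, thick fat layers receive free intermediate rings,
and a hexagonal lattice fills the remainder, culled near the curves. The
Delaunay triangulation of this cloud (incremental Bowyer--Watson, compiled
code) then conforms to every interface; elements are tagged by centroid
classification, those outside the neck or inside the trachea are dropped,
and interior nodes get a few Laplacian smoothing sweeps with inverted-element
rollback. A deterministic jitter of $10^{-6}\,h$ breaks the exact
cocircularity of points sampled on circles before the floating-point
incircle test sees them; it is orders of magnitude below every geometric
tolerance. `generate_mesh(symmetric = TRUE)` instead meshes the left
half-plane (nodule interface omitted, i.e. nodule treated as thyroid, the
only configuration in which the continuous geometry is mirror-symmetric)
and reflects it exactly, for symmetry validation at the $10^{-6}$ degC
level. Mesh contracts checked by the test suite: minimum interior angle
>= 20 degrees, element areas summing to the disc minus the tracheal hole
within 0.1%, every region-separating edge joining interface nodes, every
boundary edge tagged exactly once and sitting on its circle within
$10^{-6}$ m.

**Discretization.** Linear (P1) triangles; exact edge-length quadrature for
the Robin terms; consistent mass matrices for both the perfusion and the
transient term. The prescribed-temperature arc is imposed strongly by
elimination, keeping the reduced system symmetric positive definite: one
sparse Cholesky factorization (Matrix package) serves an entire transient
phase. Time integration is an implicit theta-scheme, backward Euler
(`theta = 1`) with `dt = 1` s by default -- unconditionally stable, and
within 0.01 degC of a 20x-denser integration on the cooling phase, the
fastest transient in the protocol. Steady solves are accepted only if the
relative residual is below $10^{-10}$.

**Evaluation.** Fields are evaluated by barycentric interpolation in the
containing triangle, located through a cached grid-bucket index. Points on
the curved outer boundary, which the mesh represents by chords, are accepted
within a small barycentric slack (5% of an element) and clamped onto the
nearest element; genuinely exterior points raise an error. Skin profiles
are sampled on an arc grid that is symmetric about the midline, so
left/right comparisons subtract values at exactly mirrored points.

**Resolutions used.** Study-resolution runs (the acceptance script, the
reproduction driver) use `h_target = 1` mm, about 11,000 nodes; the test
suite mostly uses 2 mm meshes, whose steady probe readings sit within a few
thousandths of a degree of the 1 mm values (the suite checks refinement
sensitivity explicitly), and 4 mm meshes for purely structural checks.

## Series analysis and summary metrics

`extract_point_series()` concatenates the cooling and reheating samples at a
fixed probe (the junction field appears once). `rebase_series()` shifts a
series to a zero origin -- the common-origin representation used when
reheating curves of different cases or patients are overlaid -- and
`consecutive_differences()` forms the per-frame deltas, proportional to the
heating rate. Two scalar metrics summarize a case: `delta_TCL`, the steady
skin temperature in front of the nodule minus its contralateral mirror
point, and `delta_TF`, the temperature drop across the fat segment of the
line profile through the nodule centre, interpolated at the exact layer
interfaces (the nodule-side line is used; the mirror-side line gives nearly
the same drop). Rebasing subtracts the first value rather than aligning to
a nonzero constant: only a common origin is needed for comparison.

## Synthetic thermograms

`synthesize_thermogram_sequence()` stands in for the camera: for each
reheating sample it renders the skin-surface profile onto the columns of a
horizontal band of a 480 x 640 frame (one column per arc position, the
marked column aligned exactly with the front-of-nodule arc), fills the
background with room-temperature air, and adds i.i.d. Gaussian sensor noise
with a 0.04 degC standard deviation -- the camera's noise-equivalent
temperature difference bound -- under an explicit integer seed that never
touches the global RNG state. `patient_series()` then applies the clinical
reduction: the mean of an 11 x 11 pixel window centred on the marked pixel,
per frame. Windows that would cross the frame border are an error, never
silently truncated, because truncation would bias the series.

What the generator deliberately does **not** emulate: two-dimensional
radiometric rendering of a curved neck, emissivity and reflection effects,
spatially correlated sensor noise, patient motion, and the clinician's
manual choice of the marked point. Tests passing on synthetic sequences
therefore validate the *series pipeline* (embedding, windowing, noise
attenuation by the 11^2^-pixel average, rebasing, differencing) -- not the
radiometry of real examinations.

## Known disagreements with the reference temperatures

The reproduction report (`reproduce_all()`) recomputes fourteen headline
quantities; eleven land within their tolerances. Three cannot, for reasons
that are structural rather than numerical:

1. **Healthy-lobe mirror point.** As explained under *Geometry*, the mirror
   of the large nodule's centre lies inside the nodule itself, so the probe
   reads ~38.2 rather than ~37.2. Any geometry that frees the mirror point
   moves the nodule's skin projection far from the $-3$ cm arc position.
2. **Common contralateral contrast of the perfusion/metabolism combos.**
   Under `as_printed` perfusion the four (Q~m~, w~b~) combinations are
   indeed indistinguishable (pairwise spread < 0.01 degC, consistent with
   the indistinguishability claim), but they are indistinguishable *because*
   perfusion clamps the gland to arterial temperature -- which also clamps
   the contralateral contrast to ~0.0 degC, not ~0.5. A 0.5 degC contrast
   requires the hot-nodule (`per_minute_gland`) regime, where the combos
   differ strongly (the report records both presets). The two claims are
   mutually exclusive in this model family.
3. **Zero-fat transient limits.** The computed end-of-cooling for the
   zero-fat case is ~31.9 versus 32.3 reported (the end-of-reheating
   inherits the same offset); the start of cooling matches (35.56 vs 35.5),
   as do all three limits of the 1.2 cm-fat case. The zero-fat transient is
   exactly the configuration whose reference curve is itself documented as
   a possible numerical inconsistency, and it is an idealisation (no
   subcutaneous fat at all) rather than an anatomical case.

## Limitations

Two-dimensional cross-section (no axial conduction or cooling of the jaw
and clavicle regions); constant tissue properties (no temperature-dependent
perfusion or vasomotor response); no radiative or evaporative surface
exchange beyond the lumped convection coefficient; idealized concentric
layers and elliptic organs; the fan modelled purely as a raised convection
coefficient at room air temperature. These match the scope of the
examination protocol being simulated, but they mean absolute skin
temperatures carry an uncertainty of a few tenths of a degree -- comparable
to the tolerances used throughout the package.
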