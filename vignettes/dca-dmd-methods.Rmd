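---
title: "Deformable margin delineation for conformal arc lung SBRT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable margin delineation for conformal arc lung SBRT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dynamic conformal arc (DCA) delivery for lung stereotactic body radiotherapy
shapes the multileaf collimator (MLC) to the planning target volume's (PTV)
beam's-eye-view silhouette at every gantry angle of a coplanar arc. It is fast
to plan, fast to deliver, and robust to the interplay effect, but — lacking any
intensity modulation — it cannot be pushed toward better conformity by an
optimizer. The typical failure modes are a hot shell of prescription-level
dose hugging the PTV laterally and cold tips at the superior/inferior ends of
elongated targets, because the arc cross-fires in the axial plane while the
leaf stack quantizes the target along the body axis.

Deformable margin delineation (DMD) is a contour-space remedy: plan a
conventional conformal arc, find where the normalized dose is hot *outside*
the PTV and cold *inside* it, then deform the aperture-fitting target — shrink
it under hot regions, grow it under cold ones — re-plan on the deformed
target, and renormalize so the prescription still covers 95% of the *original*
PTV. The deformed contour is purely an aperture-shaping device; coverage is
always prescribed on the clinical target. Clinically this deformation is done
slice by slice by hand, by trial and error. This package's central
re-interpretation is to automate it as a morphological update on the target
mask, iterated to a tolerance, which makes the whole procedure reproducible
and testable.

## The automated DMD update

Given the hot mask $H$ (dose $\ge$ prescription, outside the original PTV,
inside the body) and cold mask $C$ (dose $<$ prescription, inside the PTV),
one iteration with step $s$ (default: one voxel) replaces the current target
$T$ by

$$
T' \;=\; \mathrm{close}_{r}\Big( \big(T \cup \delta_s(C)\big) \setminus
  \big(\delta_s(H) \cap B_s(T)\big) \Big)
$$

where $\delta_s$ is Euclidean dilation by $s$ mm, $B_s(T)$ is the inner
surface band of $T$ of depth $s$, and $\mathrm{close}_r$ is a morphological
closing with radius $r$ (default 2 mm) that smooths single-voxel roughness.
Restricting removal to the surface band means a distant hot island cannot
punch a hole through the target interior; such islands are instead handled
indirectly by renormalization. The result is clipped to the body and, by
default, forced to contain the ITV (the clinical procedure never fits
apertures tighter than the moving tumor envelope; this is configurable
because the practice is not universal).

The loop runs at most `max_iters` times (default 10) or until both hot and
cold volumes fall below `stop_tol_cc` (default 0.2 cc, roughly one cluster of
coarse voxels). Because the dose is renormalized to 95% coverage each round,
about 5% of the PTV is *always* below prescription, so the cold volume has a
floor set by the PTV size and the loop typically terminates on the iteration
cap. The returned plan is the iteration with the best (lowest) conformity
index, ties resolved toward fewer iterations — the automated analogue of a
manual planner keeping their best attempt. By construction the returned plan
is never worse than the conventional baseline, and every iteration satisfies
the defining constraint of the method: at least 95% of the original PTV at
prescription dose.

All morphology uses an exact anisotropic 3-D Euclidean distance transform
(separable lower-envelope algorithm, implemented in C++), so steps and radii
are in millimetres regardless of voxel shape.

## The dose engine, and what it is not

The engine is a declared, minimal arc model — *not* a clinical
convolution/superposition algorithm. Per control point each voxel receives

$$
D(v) \;=\; T_\sigma(v)\; f(r)\; e^{-\mu\, d_\mathrm{eff}(v)}
  \left(\frac{\mathrm{SAD}}{\lVert v - \mathrm{src}\rVert}\right)^{2}
$$

* $T_\sigma$: MLC aperture transmission at the voxel's beam's-eye-view
  position, after a 2-D Gaussian penumbra blur of width $\sigma$ (default
  3 mm at the isocenter plane). The blur is applied in the aperture plane
  before ray lookup — far cheaper than 3-D scatter and adequate at 2–3 mm
  grids.
* $f(r) = \max(0, 1 - k r)$: an unflattened (FFF-like) cone profile in
  off-axis distance $r$, $k = 0.0015$/mm.
* $\mu = 0.0046$/mm: effective attenuation per mm of water-equivalent depth
  (nominal 6 MV); $d_\mathrm{eff}$ is the radiological path length obtained
  by ray marching from the body surface with a step of half the smallest
  voxel spacing and trilinear density sampling. Air outside the body has
  density zero, so the line integral starts at the skin automatically.
* Inverse square in the actual source–voxel distance; source–axis distance
  1000 mm.

Control points are equally weighted (constant dose rate, as delivered in
conformal arc mode). There are no scatter kernels, no electron transport, no
build-up region, and no absolute output calibration: only relative dose and
index behavior are meaningful, which is exactly what the plan-quality suite
consumes. The model does reproduce the qualitative conformal-arc failure
modes (lateral hot shell, superior/inferior cold tips) through the
combination of attenuation asymmetry, penumbra, and the union geometry of the
arc apertures; the test suite pins the quantitative pieces to closed forms
(central-axis attenuation x inverse square within 1%, exact rotational
symmetry of a full arc on a cylindrically symmetric phantom, monotonicity in
aperture margin and in phantom density). A control-point spacing study run
once on the coarse benchmark case fixed the convergence statement used in the
tests: halving 10-degree spacing to 5 degrees moves no voxel by more than 3%
of the maximum dose.

## Planning conventions

* Apertures are fitted at every control point to the target silhouette with a
  0 mm MLC margin (the conformal arc convention), leaf width 5 mm at the
  isocenter, 60 pairs, collimator fixed so the leaves travel in the axial
  plane.
* The arc spans 340 degrees with the unused 20-degree sector oriented toward
  the contralateral lung; a full 360-degree arc is available for symmetry
  tests.
* Beam's-eye-view projection is divergent (point source, SAD-scaled) and
  projects voxel *centers*; the MLC fit then takes per-leaf-band extrema, so
  sub-pixel holes in a coarse silhouette cannot close leaves spuriously. The
  dose engine rasterizes the *fitted aperture*, never the raw silhouette.
* Normalization is analytic: dose scales linearly, so the scale that puts the
  k-th largest in-target voxel dose (k = ceiling(0.95 n)) at the prescription
  level is exact, and the covered fraction lands in [0.95, 0.95 + 1/n]. The
  prescription isodose as a fraction of the maximum dose is reported for
  information only; the 95%-coverage rule is operative.
* DVH statistics (D2%, D50%, D98%) are computed directly on the sorted
  in-mask voxel doses with linear interpolation; histogram bins
  (width max(0.1, Dmax/2000)) exist only for export and plotting. Coverage
  ties break toward the lower dose, i.e. conservatively.

## Plan-quality indices

For a normalized dose (prescription = 100), with $V_{Rx}$ the
prescription-isodose volume inside the body, TV the PTV volume, and
$TV_{PIV}$ their intersection:

* conformity index $CI = V_{Rx}/TV$ (ideal 1, usually above),
* Paddick conformity number $CN = TV_{PIV}^2/(TV \cdot V_{Rx})$ (coverage
  times selectivity, ideal 1),
* gradient index $R_{50\%}$ = half-prescription isodose volume / TV,
* $D_{2cm}$ = maximum dose, in % of prescription, at least 20 mm from the
  PTV surface (Euclidean distance transform, anisotropic spacing honored),
* homogeneity index $HI = (D_{2\%}-D_{98\%})/D_{50\%}$,
* external index $C_\Delta = (V_{Rx}-TV_{PIV})/TV$, the healthy tissue at
  prescription dose relative to the PTV,
* lung V20Gy, V2.5Gy (% of combined lungs) and mean lung dose in Gy, on the
  lungs minus the ITV by default (the "lung minus GTV/ITV" convention; the
  inclusive variant is a flag, since practice varies).

Isodose volumes are voxel-center counts with an inclusive threshold
(consistent with the hot-region convention "at or above prescription is
hot"); there is no sub-voxel surface extraction, so each index carries a
declared one-voxel-layer accuracy limit. Every index is pinned in the tests
to an exhaustive per-voxel oracle at 1e-12 relative tolerance.

## The synthetic cohort

No patient data ships with the package; the phantom generator emulates the
statistical structure of a twenty-case early-stage NSCLC SBRT cohort:

* ITV volumes log-uniform on 0.56–69.39 cc. The log-uniform choice follows
  from the cohort's right skew (median well below mean); its distribution
  mean (~14 cc) sits near the emulated cohort mean.
* PTV = ITV + 5 mm isotropic Euclidean expansion.
* Shapes: sphere, 3:1 prolate ellipsoid, bilobed (two overlapping spheres —
  concave, the hard case for conformal arcs), capped cylinder; at least one
  bilobed target per five cases.
* Placement central or peripheral (roughly 35/65), left or right lung
  (roughly 60/40), fractionation 3x18 / 5x11 / 8x7.5 Gy in 7:8:5 proportion.
* Densities: body 1.0, lung 0.26, tumor 1.0 (relative electron density;
  typical CT-derived values, declared rather than fitted); air outside the
  body is zero.
* Voxelization by center inclusion (a voxel belongs to a mask iff its center
  is inside the analytic shape), binary masks, no partial volume. Grids are
  2 mm / 128 voxels per axis by default; the tests and the acceptance script
  use a coarse 3 mm / 64 preset with 10-degree control points so a ten-case,
  two-arm run completes in a few minutes on one CPU.
* Sampled volumes are redrawn from the same law when a shape would be
  resolved by fewer than 3 voxels across at the requested spacing, so every
  generated case passes the generator's resolution guard.

What the phantoms do *not* contain: respiratory motion (the ITV is taken as
given), realistic CT texture and heterogeneity beyond the three-density
model, mediastinal anatomy and the organs at risk other than lung, and any
beam-quality difference between FFF energies. Passing tests therefore
demonstrate the *mechanism* of the method — that dose-driven margin
deformation improves conformity indices under a physically plausible arc dose
model while preserving coverage — not clinical dose accuracy on real
anatomy.

## Numerical and degenerate-input choices

* The coverage rescale multiplies by (1 + 1e-12) so the critical voxel lands
  at or above prescription despite floating-point rounding of the quotient.
* Normalization refuses targets with more than 5% zero-dose voxels
  ("coverage unattainable"); the DMD loop catches this, and a collapsed
  deformed target, by returning the best previous iteration with a warning
  flag.
* An empty mask is an error for projection, DVH and every index; a hot or
  cold mask that is empty is a valid no-op for deformation.
* The Wilcoxon signed-rank test drops zero differences, uses average ranks,
  and computes the exact tie-aware null distribution by convolution up to
  n = 25 (all-zero differences return p = 1 with a warning); beyond that a
  tie-corrected normal approximation without continuity correction is used.
  Spearman correlation is Pearson on average ranks and errors on constant
  input.
* Cohort statistics use two-sided tests at the conventional 0.05 level, with
  no multiple-testing correction (none is standard for this kind of paired
  dosimetric comparison), and always the rank test rather than gating on a
  normality check.

## Known limitations

* The dose engine's absolute accuracy is undefined by design; only relative
  and index-level behavior is tested.
* Best-iteration selection optimizes CI alone; a plan could in principle
  trade a slightly better CI for a slightly worse gradient index. The full
  per-iteration history is returned so users can apply their own selection.
* Leaf deliverability (speed limits, interdigitation, tongue-and-groove) is
  not modeled, and monitor units are out of scope, so delivery-time claims
  cannot be reproduced here.
* The hot/cold floor created by 95% normalization means the stopping
  tolerance is rarely reached; the iteration cap and best-iteration selection
  are what actually terminate the loop.
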