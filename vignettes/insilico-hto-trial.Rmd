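---
title: "Methods: an in silico trial of HTO plate fixation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an in silico trial of HTO plate fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteotrial)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic data does
and does not emulate, and the numerical choices made where the design
was genuinely open.

## The trial design

Medial opening-wedge high tibial osteotomy (HTO) realigns a varus knee
by opening a wedge in the proximal tibia, fixed with a plate until the
gap consolidates. The package runs a paired two-arm virtual trial:
every virtual patient receives the *same* osteotomy twice, once fixed
with a generic fixed-geometry plate and once with a personalised
surface-conforming plate, so each patient acts as their own control.
Per arm, construct mechanics are evaluated over 15 physiological load
steps (3 activities x 5 instances), three screw configurations (SC1
all screws, SC2 nearest-to-osteotomy removed, SC3 most distal removed)
at the early healing stage, and three healing stages for SC3. The
default matrix therefore schedules 5 (stage, configuration)
combinations x 15 steps x 2 arms per patient: 4200 load steps for a
28-patient cohort. The primary outcome is the number of load steps in
which the maximum plate von Mises stress exceeds the fatigue limit of
the plate material (FLIM = 180 MPa, the lower bound of the measured
200 +/- 20 MPa), compared between arms as an odds ratio.

## The synthetic cohort

No imaging enters the pipeline; the generator emulates the *statistical
structure* of the study population, not any individual anatomy.

* **Demographics.** Age, mass and height are truncated-normal draws
  inside the printed cohort ranges. Two conventions interact here: the
  SD is set so the admissible range spans roughly the mean +/- 2.5 SD,
  and the location parameter is then solved (`uniroot`) so that the
  *truncated* distribution's mean equals the printed mean (68 yr,
  90.1 kg, 169 cm). Without the second step an asymmetric range
  (e.g. mass 68.8--121.4 around 90.1) would bias the realised mean by
  ~0.5 kg. Sex is Bernoulli(0.54 female).
* **Geometry.** The proximal tibia is an extruded, tapered elliptical
  column (squircle-mapped structured grid, every hexahedron split into
  six tetrahedra sharing a consistent diagonal, which makes the mesh
  conforming and watertight by construction). Plateau ML width defaults
  to 4.5% of height (76 mm at 169 cm) with 2% multiplicative noise; AP
  depth is 0.72 of ML width; the shaft narrows to 0.45 of the plateau
  with a cubic metaphyseal flare; the meshed segment is 8.5% of height
  (~144 mm), long enough to carry a 115 mm plate. Hip and ankle centers
  are synthesized on the limb axis (femur 24.5%, tibia 22% of height);
  no femur or foot is meshed.
* **Varus deformity.** The ankle center is displaced medially by a
  truncated-normal offset (mean 29 mm, SD 6, minimum 5). Through the
  frontal-plane geometry this puts the pre-operative mechanical-axis
  plateau crossing around 20--35% and yields correction angles of
  roughly 5--11 degrees, the typical HTO range.
* **HU field.** Elements whose normalised elliptical radius exceeds
  0.70 form the cortical shell, HU ~ N(1400, 100^2); the core is
  trabecular, HU ~ N(300, 80^2). This is a two-compartment caricature:
  it exercises the HU-to-modulus mapping and produces physiological
  modulus ranges, but contains no subchondral densification, no
  anisotropy and no real CT texture.
* **Reproducibility.** Every patient draws from an RNG stream derived
  from (master seed, patient index), so enlarging a cohort never
  changes existing patients, and identical (spec, seed) gives
  byte-identical cohorts.

Passing tests on this generator therefore demonstrate that the
*pipeline* behaves correctly on anatomically plausible inputs; they do
not validate stress magnitudes against any real limb, and the absolute
stresses are far below those of image-based models with contact
mechanics (see Limitations).

## Osteotomy planning

Alignment is quantified in the frontal (x--z) projection: the fraction
at which the hip-to-ankle line crosses the medial-to-lateral plateau
chord (0 = medial edge). The target is 0.625. The correction angle is
found by bisection on the rotation of the distal fragment (and with it
the ankle center) about the anterior--posterior hinge axis, bracket
[-30, 30] degrees, terminating at 0.001 deg -- an order below the
0.01 deg planning tolerance. Bisection was chosen over a closed-form
Miniaci-style construction because it gives the identical answer with
fewer geometric special cases; a fixed-point test (re-planning the
planned limb returns 0 deg) and an exhaustive 0.001-deg scan oracle
guard it. Whether the 62.5% rule should be read on the frontal-plane
projection or along a 3-D plateau chord is ambiguous; the 2-D
convention is adopted as this package's definition. Negative
(valgus-correcting) angles are planned by the same machinery but
flagged.

The cut plane passes through the lateral hinge (default 10 mm below
the joint line -- the clinical minimum) dipping medially at 15 deg to
the plateau. Nodes below the plane rotate rigidly about the hinge;
tetrahedra straddling the plane become the **gap layer**, which simply
deforms to fill the opened wedge -- the mesh stays conforming and no
remeshing is needed. Gap elements within 10 mm of the hinge keep bone
material (the intact cortical hinge). Rigidity, hinge preservation and
the wedge dihedral (measured by total-least-squares plane fits to the
distal gap-face nodes before/after rotation) are asserted per run. A
numerically zero angle returns the geometry unchanged with an empty
gap set.

## Implants

The generic arm stands in for a standard commercial HTO plate whose
exact geometry is proprietary: a flat T-style plate of fixed
115 x 16 x 3 mm with a patient-invariant screw layout (4 proximal, 4
distal, perpendicular axes, fixed lengths 60/34 mm), anchored just
below the joint line. Because it is flat, its standoff from the curved
medial cortex is *computed*, not imposed, and exceeds 0.5 mm on every
realistic tibia. The personalised arm projects its inner surface onto
the post-osteotomy bone (clearance 0.1 mm, so standoff <= 0.5 mm
everywhere), scales width and thickness with `(mass/90.1)^(1/3)`
(adaptive sizing with patient size/weight; the cube root keeps section
changes moderate across the 69--121 kg range), sets screw lengths by a
bicortical-purchase rule, and adapts screw axes: tilting away from the
cut in 5-deg increments up to 45 deg, then shifting the entry along
the plate in 5 mm steps, until the screw clears both the cut plane (by
>= 2 mm) and the meshed gap layer itself. The element-layer check
matters because at coarse densities the gap layer is thicker than any
plane-distance clearance.

SC2 removes the screw with minimum distance to the gap, SC3 the most
distal screw; ties break by label order, masks are single-shot
(re-masking errors), and a configuration that would leave fewer than
two screws on either side is rejected.

## Materials

Bone follows the composed calibration `rho_CT = -0.00393573 +
0.000791701 HU`, `rho_Ash = 0.079 + 0.877 rho_CT` (g/cm^3), `E =
14664 rho_Ash^1.49` (MPa). Negative ash densities (air/fat HU) are
clamped to zero before the fractional power and the modulus floored at
1 MPa so stiffness matrices stay positive definite; the floor is a
numerical guard, not a biological claim. E is binned per fragment by
quantiles (default 240 proximal / 450 distal bins, bin value = bin
mean); with coarse meshes there are fewer elements than bins and
binning is a no-op, which is the intended degenerate behaviour.
Poisson's ratio is 0.3 throughout (bone, gap, implant) -- the single-nu
assumption also lets the solver cache unit-modulus element matrices
and rescale them per healing stage. Gap tissue takes 1, 28 and
528 MPa at stages HS2/HS3/HS4 (2/6/12 weeks); HS1 exists as a label
only and is never simulated. Titanium alloy implants use E = 110 GPa,
nu = 0.3 (handbook Ti-6Al-4V values).

## Loads

The default 15-step template is synthetic: total knee contact forces
of 2.2--3.0 body weights (BW) for fast walking and 3.0--3.8 BW for
chair rise and squat (the seated/squatting activities deliberately
exceed gait, matching their relative ordering in musculoskeletal
datasets), split 62/38% medial/lateral, plus a patellar-tendon force
at the tibial tuberosity. It makes no claim of matching any specific
subject's joint reactions and is fully replaceable via CSV. Forces are
stored per unit BW and scaled by `mass * 9.81`; application points are
registered from the template frame to each patient by the similarity
transform (Umeyama closed form) fitted to the five landmarks, and
force *directions* rotate with the transform while magnitudes never
scale with it -- only body weight scales loads. Each force is
distributed over surface nodes within a 6 mm patch (inverse-distance
weights) to avoid point-load singularities. The distal end of the
meshed segment is fully constrained, the standard construct-testing
convention.

## The finite-element core

Linear (constant-strain) tetrahedra with per-element isotropic
properties; screws are chains of 2-node Euler--Bernoulli beams (circular
section, segment length 6 mm) on their own 6-DOF nodes, coupled to
plate and bone translations by penalty multipoint ties (stiffness
1e7 N/mm, ~2 orders above nodal bone stiffness). Because the ties
couple only translations, each screw retains a free axial-spin mode;
a weak grounded rotational spring (10 N mm/rad, ~4 orders below the
beam torsional stiffness) removes the singularity without affecting
bending -- physically this spin is restrained by thread purchase. The
reduced system is factored once per (patient, arm, stage,
configuration) by sparse Cholesky and back-substituted for all 15
steps; a step whose relative residual exceeds 1e-8, or a factorization
failure, is reported unsolved and dropped (never zero-filled), and the
trial continues.

Two deliberate simplifications relative to image-based practice: the
analysis is geometrically **linear** (displacements here are small
fractions of element size, and linearity buys exact load
superposition, which the tests exploit), and all interfaces are
**bonded** -- no frictional plate--screw--bone contact. Contact is known
to concentrate compressive point stresses; bonded ties smooth them, so
absolute plate stresses here sit well below published peak values and
the fatigue-exceedance counts of a desk-scale run are not comparable
to image-based ones. The trial *contrasts* (arm deltas, healing-stage
ordering, configuration effects) are the meaningful outputs.

Verification (`validate_solver()`): patch test (interior stress
constant to 1e-8 -- exact for linear tets), uniaxial bar at nu = 0
(stress P/A and tip displacement PL/AE to <1%, machine-exact in
practice since the constant state is representable), end-loaded
cantilever against PL^3/3EI, zero stress under rigid translation, and
exact load linearity. Constant-strain tets are stiff in bending, so
the cantilever needs the converged density: at 12 cells across the
section (52k tets) the tip deflection error is 4.7%, inside the 5%
gate that also defines mesh convergence (strictly less than 5% change
in peak stress on element doubling). The cantilever oracle uses
nu = 0 so the Euler--Bernoulli closed form (which ignores Poisson
effects) is the right reference.

Outcome extraction: maximum von Mises stress over plate elements
(principal stresses from the closed-form symmetric 3x3 eigenvalues);
maximum equivalent deviatoric strain (sqrt(2/3)||dev eps||) over bone
elements within 2 mm of an active screw axis -- when the mesh is
coarser than 2 mm the probe widens to the nearest bone element, so the
probe never silently returns an empty set; and IFM as the maximum
relative displacement between paired proximal/distal gap-face nodes
(nearest-neighbour pairing in the reference configuration).

## Statistics

Exceedance uses `stress >= FLIM` -- equality counts as failure, the
conservative reading of a boundary the published tables leave
unassigned. The odds ratio (Personalised vs Generic) is the
cross-product ratio with the Woolf log-interval; with any zero cell
the Haldane--Anscombe +0.5 correction is applied to all four cells
(auto-selected), which for a single binary covariate coincides with
Firth penalisation. A multi-level logistic model with robust errors is
*not* re-implemented: the patient-level clustering structure needed to
fit one is exactly what a published 2x2 table lacks, so the package
offers crude/penalised ORs plus a patient-cluster bootstrap (2000
percentile resamples, mandatory seed) when per-patient counts exist.
Paired deltas (Generic - Personalised) are computed on step keys
solved in both arms, with cluster-bootstrap CIs. The per-step screw
configuration ANOVA is one-way with Bonferroni alpha = 0.05/15; a
fully degenerate step (zero variance, equal means) reports F = 0.
The power calculator is the standard two-sample normal approximation
`n = ceil(2 (z_{1-a/2} + z_power)^2 / d^2)`; for the published
stiffness inputs (mean 1950, SD 577 N/mm, 20% difference, 80% power)
it returns 35 per arm, which does not match the nomogram-derived 25
sometimes quoted for those inputs -- the calculator reports its own
figure and asserts nothing about the other, and in the paired design
the total equals the per-arm figure.

Full precision is kept internally; percentages and ORs round to 1--2
decimals only at the presentation layer.

## Problem sizes

Defaults were chosen so a full 28-patient trial runs on one CPU in
under an hour: tibia meshes of 8 x 8 x 16 cells (6144 tets), plate
meshes of 20 x 3 x 2 cells, ~8 s per patient for the five-combination
matrix. The test suite uses 6 x 6 x 12 tibias and 2--3 patient cohorts;
the acceptance checks run the cantilever at its converged 52k-tet
density and a 3-patient healing-monotonicity sweep. Mesh density is a
configuration knob gated by the 5% convergence rule, not a fixed
property of the method.

## Known limitations

* Stress magnitudes are not comparable to image-based, contact-bearing
  models; only within-trial contrasts are interpretable.
* The two-compartment HU field and analytic geometry cannot represent
  subject-specific cortical thinning, subchondral sclerosis or
  torsional deformity.
* Healing is three discrete gap moduli, identical for all patients; no
  mechanoregulated tissue differentiation.
* The load template is synthetic and shared (scaled by body weight)
  across the cohort, mirroring the single-donor convention of the
  study design it emulates.
* Beam screws with penalty ties cannot capture thread-level stress
  concentrations or screw loosening mechanics.
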