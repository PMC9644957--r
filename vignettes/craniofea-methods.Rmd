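---
title: "Methods: comparative cranial FE feeding biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative cranial FE feeding biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`craniofea` reconstructs, as a tested pipeline, a comparative
feeding-biomechanics analysis of two Early Jurassic longirostrine
ichthyosaur skulls: a robust morphotype (specimen analogue M1409, a
*Stenopterygius*-like skull, estimated 401 mm long with only the posterior
185 mm preserved) and a gracile morphotype (M1399, a
*Hauffiopteryx*-like skull, 335 mm, complete, with a slenderer snout and a
larger orbit). The pipeline estimates jaw-muscle forces from reconstructed
muscle dimensions, applies them to finite-element models of the crania
under bilateral biting at several tooth-row positions, summarizes von
Mises stress by anatomical region, and compares the two morphotypes; a
two-dimensional lever model supplies bite-force estimates along the tooth
row. All computations use a consistent mm-N-MPa unit system;
anteroposterior is +x (anterior positive), the bilateral symmetry plane is
y = 0, dorsal is +z.

## Dry-skull muscle forces

Seven jaw muscles are modelled per side: the three external adductors
(mAMEpr, mAMEsu, mAMEme), two internal adductors (mAMIps on the temporal
rim, mAMIpt on the pterygoid flange), the posterior adductor (mAMP, at the
quadrate) and the depressor mandibulae (mDM, behind the joint). For each,
the maximum force is the dry-skull estimate

F_max = (V / (L/3)) * P,

where V is reconstructed muscle volume (mm^3), L the origin-to-insertion
length (mm), L/3 the muscle-fibre length, V/(L/3) the average
physiological cross-section (mm^2), and P the specific muscle stress,
default 0.3 MPa (300 kPa, the standard measured value for living
vertebrate muscle). Muscle dimensions are consumed from a packaged fixture
table (`muscle_dimensions()`), not recomputed from 3D muscle solids: the
volumetric reconstruction requires the fossil geometry and is outside this
package's scope, so the published dimension table is the interface.

All arithmetic is kept at full precision; presentation tables round half
away from zero (`round_half_out()`), which is how the published per-muscle
integers reconcile with their printed totals (per-muscle forces that sum
to 292 print as a total of 291). Specimen totals sum the unrounded forces
of all seven muscles, *including* the depressor — biomechanically odd for
a bite-force numerator, but it is the convention of the reference tables;
`total_muscle_force(include_depressor = FALSE)` gives the adductor-only
total.

```{r}
library(craniofea)
muscle_force_table("M1399")
total_muscle_force(specimen_muscles("M1399"))  # 291.1 N unrounded
```

## Parametric skull geometry

The synthetic-geometry module replaces the CT-derived reconstructions. A
skull is a structured hexahedral grid, split into six conforming linear
tetrahedra per cell: a box-like posterior cranium (with lateral orbital
voids) blending into an elongated rostrum whose blended
square-to-elliptical cross-section shrinks anteriorly as
(distance-to-tip)^q for taper exponent q, down to a blunt tip
(`tip_fraction`, default 0.25, of the base section — real snouts carry
teeth to the tip and are not needle-pointed). The ventral margin is held
near z = 0, giving a straight tooth-row line.

The two shipped presets encode the printed proportional contrasts rather
than unpublished absolute anatomy: the robust skull is longer (401 mm)
with a proportionally longer, deeper rostrum (base 30 x 40 mm on a 75 mm
cranium) and smaller orbit (38 mm); the gracile skull is shorter (335 mm)
with a slenderer rostrum (22 x 28 mm on a 72 mm cranium) and larger orbit
(46 mm). Orbit geometry of the actual specimens is not tabulated
anywhere, so the presets only preserve the stated contrasts
(gracile orbit > robust orbit; gracile rostrum-height/cranium-height
0.39 < robust 0.53). The robust preset carries
`preserved_fraction = 0.4613` (185/401): the pipeline truncates its mesh
before analysis, mirroring the broken anterior rostrum of the fossil, and
its foremost preserved bite position then stands in for the mid-tooth-row
case, keeping the two models analogous.

Node sets are derived deterministically from the geometry: seven muscle
origin patches and four insertion areas per side (nearest-surface-node
patches around anatomically placed anchors — external adductors on the
temporal rim, pseudotemporalis antero-dorsally, pterygoideus on the
palatal flange, posterior adductor at the quadrate, depressor behind the
joint, with mandible-proxy insertion patches ventro-laterally), two
10-node basicranium (condylar) constraint patches, and three 20-node bite
sets (5 nodes x 2 adjacent teeth x 2 sides) at the posterior, middle and
anterior tooth-row positions. Right-side sets are selected first and
mirrored to the left, so bilateral pairing is exact by construction; the
lateral node grid is made bitwise antisymmetric for the same reason.

Mesh granularity: the original fossil-scale models meshed real crania at 0.5 mm element size
(~1.1-1.2 M elements). The scientific claims are about relative and
regional stresses, not absolute element-level values, so the presets
default to 4 mm edges (about 20,000-47,000 tetrahedra per skull), and
`convergence_study()` / `refine_params()` demonstrate that the regional
summaries and all comparative verdicts are stable one refinement level up
(edge / 1.25, roughly double the element count). Element quality is
audited, not assumed: aspect ratios above the configured bound (default 8)
are reported with a warning and recorded on the mesh object. Mesh volume
is checked in the test suite against an independent quadrature of the
parametric solid (within 2% at coarse granularity, converging under
refinement).

## Load cases

Muscle loading follows the two-nodes convention: the configured number of
nodes per attachment (50 at the mAMIps origin, 30 at mAMEpr, 35 at the
shared mAMEsu+mAMEme origin, a combined 115-node coronoid insertion, 50
for mAMIpt, 25 for mAMP, 40 for mDM) each carry F_max/n directed from the
node towards its nearest partner on the opposing attachment, so forces act
along the muscle's line of pull. Loaded subsets are chosen by
deterministic farthest-point sampling of the patch. Only the origin side
is loaded by default: the model is a cranium without a mandible, so the
insertion patches supply direction only (this also makes the total applied
magnitude per side equal the summed F_max); `apply = "both"` adds the
equal-and-opposite insertion forces for users modelling both elements.
Each side carries the full per-muscle F_max — paired muscles each generate
their force, and the published totals are per-side sums as in the 2D lever
convention. Constrained nodes are excluded from the loaded subsets: a node
cannot be both loaded and fixed.

Constraints fix all three translational freedoms at the chosen 20-node
bite set plus both 10-node basicranium patches (bilateral biting with a
supported braincase). The condylar patches are deliberately compact
anteroposteriorly (x-distance triple-weighted in the selection metric):
at fossil-scale granularity ten constrained nodes span ~1 mm of condyle,
and letting the patch grow into a long strip on a coarse mesh would
misrepresent that constraint and spuriously absorb the pitching moment.

## Finite-element solver

Linear elasticity on 4-node constant-strain tetrahedra — deliberately the
simplest formulation consistent with a tetrahedral mesh; higher-order
elements are out of scope, with the refinement/convergence utility
standing guard against discretization artefacts instead. The direct
sparse factorization covers every mesh size the package targets, so no
iterative fallback is provided. Models use homogeneous
isotropic bone everywhere (E = 15,000 MPa, Poisson 0.29 — crocodilian
cranial bone values; no sutures, matching an akinetic skull; no
cartilage). Assembly is sparse (`Matrix`), constraints are applied by
freedom elimination so reactions are recovered exactly, and the reduced
system is solved by direct sparse Cholesky factorization; an error naming
the offending element is raised for non-positive Jacobians, and singular
constrained systems fail with a hint about missing constraints. Stress is
evaluated once per element from the constitutive law; the von Mises
scalar uses the deviatoric second invariant. Verification is
property-based: translation invariance and exactly six rigid-body modes;
the patch test (exact reproduction of linear displacement fields, which
tet4 must pass identically); sigma = F/A on a prismatic bar; pure shear
giving sqrt(3)-tau; cantilever extreme-fibre stress converging to M c / I
(within 10% at moderate refinement, error decreasing); and agreement with
a dense direct solve to 1e-8 relative on small meshes. Global equilibrium
(applied + reactions = 0 per axis) is checked to 1e-6 relative on full
skull cases, and bilateral load cases reproduce mirror-symmetric stress
fields to well under 1%.

Regional summaries are volume-weighted (mean, median, p95, max of von
Mises per region). Elements touching loaded or fixed nodes are excluded
and counted separately — constant-strain elements adjacent to point
constraints carry singular artefacts — and a region with no valid
elements reports NA, never zero. Regions are geometric proxies for the
osteological areas of the original models: the synthetic skull has no bones, so
"nasal" is the dorsal posterior half of the (remaining) rostrum, "palate"
the ventral plate of the cranium, "orbital" the rim of the orbital void,
with the rest split into "rostrum" and "posterior_cranium".

## Lever mechanics

Mechanical advantage is in-lever over out-lever; bite force is
F = F_total * A, unrounded until presentation. The specimen fixtures carry
the published tip mechanical advantages (0.089 robust, 0.191 gracile)
directly, because the in-lever measurements behind them are not published;
in-lever lengths are recovered as A * out-lever when a profile along the
tooth row is requested, and the out-levers implied by the published
back-of-row forces are derived (`implied_out_lever()`) and reported as
consistency quantities, not anatomy.

## Comparative layer

Dentition: per-tooth crown aspect ratio (width at the widest point over
length) and per-specimen means, computed from the packaged ten-tooth
measurement tables. Two cells of the published table are internally
inconsistent with its own raw measurements (one gracile per-tooth ratio
prints 0.5 where its measurements give 2.8/7.2 = 0.39, and the gracile
mean diameter prints 2.7 where the ten diameters average 2.61); the
package computes from the raw measurements and the tests assert the
arithmetically consistent values, documenting the two exceptions.

Stress contrasts are region-statistic inequalities, never pixel
comparisons: the nasal shift index (mean_mid − mean_posterior) /
mean_posterior per morphotype, cross-morphotype rostrum+nasal mean ratios
at matched bite positions, and three boolean verdicts — gracile rostral
stress higher than robust, gracile shift index higher, gracile nasal mean
maximal at its mid bite. The first verdict is evaluated at the analogous
mid-bite pair (the pair of directly comparable simulations); at the posterior
pair the robust skull's short preserved rostrum lies entirely beside its
bite constraint, which confounds the regional comparison, so that ratio is
reported but not used as the verdict. The controlled experiment
(`morphotype_stress_experiment()`) applies one shared muscle set to both
skulls so geometry is the only difference; the pipeline proper loads each
specimen with its own muscles, as the original per-specimen analyses were loaded. No significance claims
are made anywhere: no published numeric threshold exists separating
"slightly affected" from "greater shifts", so directions plus magnitudes
are reported.

```{r}
ex <- morphotype_stress_experiment()
ex$contrast
```

## Pipeline and reproducibility

`run_pipeline()` executes tables -> geometry/FEA -> comparison from a
YAML-or-list configuration (schema-validated with explicit errors),
writes meshes and stress fields (legacy ASCII VTK, with the 0-3 MPa
contour-clamp convention recorded in the header), CSV tables and a
markdown report, and logs every stage. Runs are deterministic: identical
configuration and seed give byte-identical numeric tables, and a config
hash plus the seed are embedded in the report. A thin Rscript wrapper
(`inst/scripts/craniofea.R`) exposes subcommands, but the exported
functions are the primary interface. The truncation-sensitivity mode
re-runs the complete gracile skull with its rostrum truncated to the
robust skull's preserved fraction under the posterior bite: the
posterior-cranium regional mean changes by well under 1% at default
granularity, supporting comparisons between a broken and a complete
rostrum.

## Known limitations

- Absolute stress magnitudes are not comparable with the original fossil-scale results: the
  commercial solver's element order and stress recovery are unreported,
  the fossil geometry is replaced by a parametric solid, and granularity
  differs by an order of magnitude. Only patterns, ratios and directions
  are interpreted — the restriction appropriate to comparative FE work.
- The FE-vs-lever bite-force cross-check is scale-limited at desk
  granularity. The rigid-lever share of the applied muscle pitching moment
  at the gracile tooth-row tip is about 30 N here (same order as the 56 N
  lever estimate), but with 4 mm elements the 20-node condylar constraint
  patch spans ~8 mm and its rotational stiffness (growing as E d^3)
  elastically diverts roughly two thirds of that moment away from the tip
  constraint, leaving a summed vertical tip reaction near 10 N. At
  fossil-scale 0.5 mm elements the same 20-node patch spans ~1 mm, is
  rotationally soft, and the split approaches the rigid-lever limit — the
  regime of the published 59 N vs 56 N cross-check. The packaged
  order-of-magnitude check therefore fails at desk scale, and is left
  failing rather than compensated by re-dimensioning the skull or
  shrinking the constraint policy.
- The mandible is not modelled; bite constraints act on cranial
  tooth-margin nodes, and insertion patches on the cranium act as
  mandible proxies for muscle pull directions. How the mandible
  participated mechanically in the original cranial models is not
  documented, so only the cranial side is constrained here.
- Passing tests on synthetic geometry show the pipeline reproduces the
  published arithmetic exactly and the published stress *contrasts*
  directionally; they cannot show that the parametric solids capture any
  particular fossil's stress field.
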