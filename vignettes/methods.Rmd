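---
title: "Template-guided plan scaffolding: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided plan scaffolding: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtplankit)
```

## What this package models

rtplankit is a vendor-independent re-implementation of the scaffold around
template-guided automated radiotherapy planning: everything a planning
automation layer does *except* inverse optimization and physical dose
calculation. Given a planning CT, a structure set, a clinical-protocol
template and an automation configuration, it derives optimization structures
by declarative rules, validates the case, lays out a VMAT plan skeleton
(isocenter, arcs, jaws), and evaluates dose-volume goals once a dose
distribution exists. The packaged use case is hippocampal-avoidance
whole-brain radiotherapy (HA-WBRT): 30 Gy in 10 fractions to the whole-brain
target while limiting hippocampal dose, with the goal set used by modern
HA-WBRT trials (target D2% <= 37.5 Gy, D98% >= 25 Gy, V30Gy >= 95%,
hippocampi D100% <= 9 Gy and D0.03cc <= 16 Gy, optic nerve and chiasm
D0.03cc <= 30 Gy).

Because patient data and a commercial optimizer are out of scope, the package
ships a seeded synthetic head phantom and a dose-shape emulator so that the
entire pipeline is exercisable end to end and every numerical claim in the
test suite is recomputable from code.

## Geometric substrate

All geometry lives on axis-aligned grids in DICOM patient coordinates (LPS,
millimetres); a voxel is represented by its center and indices are 0-based.
Oblique acquisitions are rejected rather than resampled — HA-WBRT planning
CTs are axial, and silent resampling would make every downstream volume
ambiguous.

**Rasterization.** A voxel belongs to a contoured structure iff its center
lies inside an odd number of that slice's polygons (even-odd rule), which
supports holes and is deterministic and testable. Contour extraction traces
the 0.5 iso-level of the occupancy on each zero-padded slice, so
rasterize-extract-rasterize is idempotent after one cycle; the round-trip
tolerance is half a voxel around the contour.

**Margins.** Template margins (PRVs, rings) use center-to-center Euclidean
distance on the anisotropic grid: a dilation by d mm occupies every voxel
whose center lies within d mm of an occupied voxel center; erosion is the
dual (a voxel survives iff no background center lies within d mm). The
engine is an exact squared Euclidean distance transform computed by per-axis
min-convolution with the squared-offset penalty, capped at the requested
radius so cost stays linear in grid size for clinical margins (<= 50 mm).
Whether the original clinical system expands margins Euclidean-wise or
per-axis is not published; Euclidean was chosen because it is the standard
PRV semantics and is isotropy-correct on anisotropic grids. Tests enforce
equality with a brute-force all-pairs oracle on grids up to 24^3.

**Rings.** `ring(S, inner, outer)` is the band between the inner and outer
expansions and therefore *excludes* S itself when `inner = 0`. The clinical
template only names its ring ("NS_Ring_05"); the exclusive convention is
stated explicitly here because a falloff-control ring that overlapped its
target would be useless in optimization.

## Templates and structure matching

The clinical protocol is the package's own XML schema carrying what a TPS
planning template exposes: prescription (total dose = fractions x
dose/fraction, validated to 1e-6 Gy), default machine, per-field geometry,
and clinical goals. The automation configuration (YAML) carries the
derivation rules, the model-structure matching map with target dose levels
in absolute Gy, optional bilateral evaluation groups, and algorithm
overrides. A vendor structure dictionary is modelled as canonical-id ->
synonyms XML.

Name matching is tiered and deterministic: case-insensitive exact match
first, then dictionary synonyms (the requested name may itself be a
synonym), then a normalized comparison with spaces, underscores and hyphens
stripped. The first tier with exactly one hit wins; two or more hits within
a tier is an ambiguity *error* rather than an arbitrary pick, because a
wrong silent match in a clinical pipeline is worse than a loud stop. No
template entry is ever dropped: unresolved names surface as flagged rows.
The one-to-many model-to-contour aggregation some vendors support is
deliberately not implemented; the map here is one-to-one with flags.

## Derived structures

Rules execute in order and may consume earlier outputs, so the packaged
HA-WBRT set is expressible declaratively:

* `Hippocampi_05` — 5 mm PRV margin on the hippocampi;
* `NS_Ring_05` — 5 mm ring immediately outside the PTV;
* `PTV_WBopt` — PTV minus the hippocampal PRV, the optimization target;
* `NS_FaceAvoid` — anterior-inferior part of Body at least 10 mm from the
  PTV.

A rule with an unresolvable operand is flagged and skipped while the rest
run (pass-or-flag semantics); inputs are never mutated. `PTV_WBopt` and
`NS_FaceAvoid` have no published construction — the PTV-minus-PRV definition
is the simplest one consistent with how the optimization target is used, and
the face/orbit avoidance is a parametric stand-in (anterior half and
inferior 40% of the PTV bounding box, configurable). Both live in the
configuration file, not in code.

## Plan skeleton

The isocenter is the center of the target's bounding box rounded to 0.1 mm —
robust to asymmetric inferior extent, unlike the centroid (which `centroid()`
still reports for comparison). Fields are instantiated one-per-template:
for HA-WBRT, three full arcs travelling between gantry 180.1 and 179.9
in alternating directions with collimators 345, 15 and 90 degrees. Arcs are
encoded as start/stop plus travel direction, so field 1 travels 180.1 ->
179.9 the short way across anterior; the convention is documented here
because start/stop angles alone are ambiguous. Jaw fitting projects every
occupied target voxel orthographically into the beam's eye view at gantry
angles sampled every 10 degrees (configurable) along the arc, applies the
collimator rotation, and adds a 7 mm margin on all sides; exceeding the
200 mm half-field is an error. The skeleton carries arcs and jaws only — no
MLC sequence or monitor units, since optimization is out of scope.

## Validation semantics

Checks have four states ordered pass < tracked < warning < flag, and the
report's overall state is the maximum. "More than 14 days old" is a strict
inequality on whole calendar days: exactly 14 days passes. Every check takes
its clock as an argument — nothing reads the wall clock — so reruns are
bit-identical. User overrides (machine, fractions, structure matches) are
never silently applied: each becomes a change record, recorded once per
distinct value pair. The pipeline always proceeds past warnings and flags
and reports them; only hard errors (missing or unreadable inputs) abort, and
they abort before any artifact is written.

## Dose-volume metrics

The DVH is sample-based: the empirical distribution of per-voxel dose over
the structure, with no pre-binning (binning applies only to exported
curves, default 0.05 Gy). DxGy-style metrics are defined as the exact
supremum on that distribution: Dx% is the greatest dose d such that at least
x% of the volume receives >= d, which is the ceil(n*x/100)-th largest
sample. This makes D100% the minimum dose, makes Dx% and VxGy near-inverse
(`volume_at_dose(dose_at_volume(x%)) >= x`), and makes the
normalize-then-cover property exact: after rescaling so that D95% of the
target equals the prescription, V_rx >= 95% holds by construction, not
approximately. An interpolating quantile definition was rejected because it
breaks that guarantee. `volume_at_dose` allows a 1e-9 relative tolerance at
the threshold so the covering voxel survives floating-point rescaling.

Absolute-volume metrics (D0.03cc) convert volume to a voxel count through
the voxel volume. Bilateral organs are evaluated on the union of their
left/right masks when the configuration declares a group (clinical goal
sheets report "optic nerve" as one row). The homogeneity index is reported
in percent, 100 x (D5% - D95%) / rx, the convention under which published
HA-WBRT values of ~4 are intelligible.

The paired-cohort comparison uses the Wilcoxon signed-rank test at alpha =
0.05. Zero differences are dropped (Wilcoxon's original procedure; the Pratt
variant is available by flag). For effective n <= 25 the two-sided p is
exact, computed by dynamic programming over the null distribution of the
rank sum with ranks doubled so tied average ranks stay integral; above that
a normal approximation with tie correction and continuity correction takes
over. Tests pin the exact path to a full 2^n enumeration oracle up to
n = 12 and to the reference implementation in `stats` where its exact path
applies.

## The synthetic phantom and what it does (not) show

The phantom emulates the topology of an HA-WBRT case, not anatomy: a head
ellipsoid (Body), a brain ellipsoid (PTV_3000, ~1.6 l), bilateral
hippocampal arc tubes (~4 cc per side, strictly inside the PTV), optic
nerve cylinders and a chiasm below the brain. The default grid is 96^3 at
2.5 mm isotropic — the resolution class of a planning dose grid, small
enough that the full pipeline runs in seconds. All geometry is analytic and
deterministic; voxelization inflates the thin hippocampal tubes somewhat
relative to the analytic volume, which is why the declared nominal is the
design target (4 cc) rather than the analytic integral.

The dose emulator is a *shape* model: prescription-level plateau inside the
PTV with a smooth 1.5% ripple, Gaussian cold wells (depth 0.74 x rx, sigma
2.5 mm) centered on the hippocampi, exponential falloff (25 mm length
constant) outside the PTV, and seeded Gaussian noise (0.15 Gy). The
parameters were calibrated once so that the default phantom satisfies the
packaged goal set with margin, then frozen in
`inst/extdata/phantoms/default_dose_model.yaml`; the cold-well width is the
binding parameter, since widening it drags target D98% down while deepening
it spares the hippocampi. Passing tests on this phantom demonstrate that the
*evaluation machinery* is correct and that the goal set is attainable by a
distribution of the intended shape — they say nothing about what an
optimizer achieves on real anatomy, where hippocampal proximity to the
target boundary, setup margins and deliverability all bite.

## Numerical choices and degenerate inputs

* Grid equality within 1e-6 mm; no implicit resampling anywhere — dose is
  resampled to a structure grid only through the explicit trilinear (or
  nearest-neighbor) `resample_dose()`.
* Margin magnitude capped at 50 mm (sanity bound); distance-transform
  comparisons carry a 1e-9 mm^2 epsilon against floating-point ties.
* Empty structures: empty contour sets rasterize to empty masks with a
  warning; DVHs, centroids and isocenters of empty masks are errors naming
  the structure.
* Timing endpoints (time-to-execute: application start to plan trigger;
  technical planning time: planning start to end) are derived from injected
  event timestamps and are non-negative and additive by construction.
* Problem sizes in the test suite: oracle equivalence runs on 100 random
  20^3 dose/mask pairs and on masks up to 24^3; these sizes make brute-force
  oracles exact and fast while exercising anisotropy.

## Known limitations

* No DICOM I/O: cases are read and written in the package's plain-text
  interchange format (JSON contours + CSV grids). Converting DICOM-RT to
  this format is a few lines with any DICOM toolkit.
* Axis-aligned grids only; no partial-volume fractions (a voxel is in or
  out by its center).
* No optimization, fluence, MU or physical dose engine — the dose emulator
  is explicitly synthetic and labelled as such.
* The KBP model interface stops at structure matching; predicted-DVH bands
  are not modelled.
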