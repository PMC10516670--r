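---
title: "Quantifying recombination foci in germline image stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying recombination foci in germline image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadfoci)
```

## The measurement problem

In *C. elegans*, meiotic nuclei are arranged along the gonad in a spatial
gradient that doubles as a time axis: a nucleus's distance from the distal
tip approximates how far it has progressed through meiotic prophase.
Recombination is followed cytologically by immunostaining for proteins that
mark successive repair intermediates — RAD-51 on resected double-strand
break ends, MSH-5/HIM-6/COSA-1 on later and crossover-designated
intermediates, HTP-3 on the chromosome axes. Each marker appears as
diffraction-limited puncta ("foci") in 3D image stacks, and the biology is
read out as counts, colocalization fractions, axis-association fractions,
and spatial zones of those foci.

`gonadfoci` implements that readout as a tested pipeline: 3D focus
detection, assignment of foci to nucleus ROIs, object-based colocalization,
axis-association scoring, cell-row zone rules, and crossover-position
statistics on traced chromosomes — plus a synthetic-scene generator that
provides ground truth for every stage.

## Focus detection

Foci are intensity maxima. A voxel of intensity $h$ is called a focus iff:

1. $h \ge$ `min_peak_height`;
2. no voxel within the anisotropic ellipsoidal neighborhood
   $(dz/r_z)^2 + (dy/r_{xy})^2 + (dx/r_{xy})^2 \le 1$ is brighter;
3. it is topographically prominent: no strictly brighter voxel can be
   reached from it along a 26-connected path through voxels brighter than
   $h -$ `noise`;
4. among surviving candidates within each other's neighborhood, only the
   brightest is reported (ties go to the smallest $(z, y, x)$, so a flat
   plateau is reported once).

Defaults are $r_{xy} = r_z = 1.5$ voxels and `noise` $= 100$ intensity
units, the standard plugin defaults for this kind of data;
`min_peak_height` has no universal default and is calibrated per image
(below). Radii are in voxels, not nm, matching the convention of the
plugins this mirrors.

**Why topographic prominence.** The "noise" criterion had two plausible
formalizations: peak height minus the minimum on the neighborhood shell, or
noise-tolerance merging against the surrounding terrain. We implemented
both and kept the topographic form as the definition, for a concrete
reason: with 1.5-voxel radii, shot noise on top of a bright focus routinely
creates a secondary maximum 2–3 voxels from the main peak — outside the
suppression neighborhood, but connected to the main peak by terrain far
above `noise`. Shell prominence keeps such twins (they are locally
prominent), inflating counts by 5–10% on realistic scenes; terrain merging
absorbs them into the main peak while leaving genuinely separate foci —
whose connecting paths descend to background — untouched. The criterion is
also monotone (raising `noise` can only remove foci) and invariant to
intensity translation, two properties the test suite checks.

**Threshold calibration.** `calibrate_min_peak_height()` returns the
maximum intensity over user-supplied background regions — the starting
value of the empirical procedure in which the detector is re-run at
increasing thresholds until false positives and false negatives are
jointly minimized. Two practical notes: background regions must be
focus-free (a region covering a focus raises the start value to at least
that focus's peak — the function's documentation warns about this), and
with integer photon-count data the returned maximum itself ties at many
background voxels, so iteration should start strictly above it.

**Masking.** When ROIs (or a mask) are supplied, the volume outside is
cleared of all signal before detection, reproducing the workflow in which
the area outside manually drawn nucleus outlines is deleted before running
the maxima finder.

## Nucleus assignment and gonad position

A focus belongs to a nucleus ROI iff its maximum's $(x, y)$ lies inside the
ROI polygon, boundary inclusive (max projection preserves xy, so the 3D
maximum's xy is the projected position). Foci inside multiple overlapping
ROIs are resolved to the ROI with the nearest centroid (ties to the smaller
id), and every resolution is listed in a report — a deterministic,
auditable stand-in for the manual overlap curation this step replaces.
Counts conserve: per-nucleus counts plus unassigned foci always equal the
table total.

A nucleus's position along the gonad is its ROI centroid x, expressed as a
percentage of the quantified region (0% = distal start, 100% = region
end). The gonad's curved geometry is approximated by linear x position;
that approximation is inherited from the upstream convention of using the
xy position of each ROI.

## Colocalization

Two foci of different species colocalize when their 3D distance is under
the resolution limit $0.61\lambda/\mathrm{NA}$ — 242 nm for 555 nm
emission, 282 nm for 647 nm emission at NA 1.4. Classification is
directional nearest-neighbor: for each query focus, the distance to the
nearest focus of the reference species, colocalized iff strictly under the
threshold ("under" is taken literally; a distance exactly at the threshold
does not colocalize). Distances are 3D Euclidean in nm using voxel-center
physical coordinates; z is never collapsed.

Choices the source convention left open, and what we chose:

* For a pair imaged at two wavelengths, the threshold defaults to the
  longer wavelength's limit (resolvability is set by the redder channel);
  configurable per pair.
* Thresholds are used exactly (241.82… nm), not rounded; the rounded
  integer value is available for reporting. Both behaviors are supported.
* The 95% confidence interval on a colocalized fraction is the Wilson
  score interval (well-behaved at extreme fractions and zero counts);
  Clopper–Pearson is available via `ci_method`.

Three-species classification labels each focus solo / +X / +Y / +X+Y by
independent pairwise tests; per-species category counts always partition
the species' total.

## Axis association

Axis association is scored through a binary mask of the axis channel:
threshold the axis signal (fixed value or Otsu's method — the upstream
recipe this stands in for is not fully specified, so the mask step is
parameterized and its provenance recorded), then dilate the mask by one
voxel in z only, so that foci adjacent to or tethered to the axis one z
step away are captured; xy is never dilated. A focus is axis-associated iff
the dilated mask is true at its maximum's voxel, and the reported degree of
association is (axis-associated foci)/(total foci) with a binomial CI.
Genotype comparisons on these counts use Fisher's exact test.

## Zones along the gonad

The "cell row" — a column of nuclei perpendicular to the gonad axis, read
by eye in practice — is operationalized as equal-width bins of ROI centroid
x. The default pitch is the median nearest-neighbor spacing among distinct
centroid-x values; nuclei in the same row have nearly identical x, so
within-row spacings (numerical noise) are excluded by a 1e-6-voxel
tolerance. This binning is a documented stand-in for the by-eye row
assignment.

Three zone rules, all using "majority" = strictly more than 50% of a row's
nuclei:

* **Majority-staining zone** (e.g. the CHK-2-active zone scored by SUN-1
  pS24): the longest contiguous run of positive rows, earliest run on
  ties.
* **Count-rule boundaries** (e.g. the early pachytene zone): starts at the
  first row where most nuclei satisfy a start predicate (at least one
  RAD-51 focus) and ends at the first subsequent row where most satisfy an
  end predicate (exactly six MSH-5 foci); an unmet rule is an explicit
  error, never a silent default.
* **Peak window**: the fixed-width window (default 10 rows) maximizing the
  median per-nucleus count, earliest window on ties — the zone in which
  focus counts are compared across genotypes.

All three are verified against exhaustive-enumeration oracles.

Group statistics delegate to the standard two-sided tests: Mann–Whitney
for count distributions, Welch's t for zone lengths, Fisher's exact for
association tables. Brood-viability arithmetic takes the total eggs laid
as the largest of the two egg counts and the adult count (guarding against
undercounted young larvae), then computes % hatching, % reaching adulthood
and % males from that total.

## Chromosome traces

Traced chromosomes are 3D polylines in µm. Length is the polyline arc
length. A crossover site is snapped to the nearest point on the polyline
(default tolerance 0.5 µm — a CO focus sits on its chromosome, so larger
distances indicate a mis-assigned site) and its position is reported as arc
distance to the nearer end divided by total length, which lies in
$[0, 0.5]$ and is invariant under reversing the trace. Fusion chromosomes
are classified by length strictly greater than 15 µm. The CO-position
histogram (default 10 bins over $[0, 0.5]$; the bin count is configurable
since no canonical value exists) is normalized within each class.

## The synthetic-scene generator

`generate_scene()` emulates the statistical structure of spread/whole-mount
gonad fields so that every stage can be validated against known truth:

* **Geometry.** Nuclei on a row grid along x (`rows` per cell row),
  circular 24-gon ROIs. Default nucleus radius 25 voxels = 2 µm at the
  default 80 nm xy pixels — the scale of a pachytene nucleus. Voxel
  spacing defaults to (200, 80, 80) nm (z, y, x): 200 nm z steps are the
  widefield convention (125 nm for structured illumination); the paper
  does not state the xy pixel size, so 80 nm was chosen once as typical of
  a 100×/1.4 NA widefield system.
* **Foci.** Per-nucleus counts are Poisson (or exact); positions are
  uniform in the nuclear volume subject to a resolvability constraint
  (same-species spots keep 4 voxels clearance in xy or 3 in z, beyond the
  Sparrow limit of $2\sigma$ for the rendered PSF) so that ground-truth
  counts are meaningful for a maxima-based detector. Spots are separable
  Gaussians truncated at $4\sigma$, $\sigma = (1.1, 1.3, 1.3)$ voxels
  (FWHM ≈ 3 voxels in xy, the diffraction-limited widefield scale); peak
  heights are Normal (default 1000 ± 100).
* **Colocalization.** A species pair with nominal fraction $p$: each
  partner focus is, with probability $p$, placed 100 nm (below both
  thresholds) from a free anchor focus of the other species — anchors are
  one-to-one, so pairs stay resolvable — and all unpaired partners are
  rejection-sampled at least 564 nm (twice the larger threshold) from
  every anchor, making ground truth unambiguous. The pair/axis character
  of each focus is drawn once, before position sampling, so rejection
  cannot bias the realized fractions; realized fractions are recorded next
  to nominal ones.
* **Axis.** Smoothed random-walk tracks rendered brightly in the axis
  channel at the central z plane; axis-associated foci sit on track
  points, non-associated foci keep 3 voxels xy clearance.
* **Background.** Additive Gaussian noise, added last, clipped at zero and
  rounded to integer counts (16-bit range).
* **Determinism.** The seed fixes the scene bit-for-bit; per-nucleus
  sub-seeds keep realizations stable under spec edits. `render = FALSE`
  skips image rendering for point-pattern studies.

What the generator does **not** emulate: optics (no PSF tails beyond the
truncated Gaussian, no depth-dependent aberration, no deconvolution
artifacts), chromatin texture, clustered or axis-anisotropic focus
placement beyond the axis flag, nucleus shape variation, or gonad
curvature. Passing tests therefore demonstrate that the pipeline's
algorithms are correct and well-calibrated under controlled conditions,
not that any particular biological dataset would be recovered perfectly.

## Validation design and problem sizes

Every operation with a non-trivial contract is checked against an
independent oracle: maxima finding against a nested-loop evaluation of its
post-conditions (with a label-relaxation flood for the prominence rule),
point-in-polygon against a hand-written ray caster, nearest-neighbor
classification against an all-pairs scan, zone rules against exhaustive
enumeration. Parameter-recovery studies run at fixed seeds: detection
recall/precision on scenes of 12 nuclei (~50 foci) at signal-to-noise
ratios 10 and 20 with an empirically iterated threshold; colocalization
fractions at nominal 0.1/0.5/0.9 with ~400 query foci; axis association at
nominal 0.6 with ~300 foci; trace analytics on 60 traces. These sizes give
binomial tolerances ($3\sqrt{p(1-p)/n}$) tight enough to catch systematic
bias while keeping the full suite around two minutes on one CPU.

## Known limitations

* Sub-voxel localization is out of scope: positions are voxel centers, so
  distances carry up to half-a-spacing quantization per axis. At 200 nm z
  spacing this matters for colocalization near the threshold; the
  synthetic validation accounts for it.
* The Otsu mask is a stand-in for the full upstream axis-masking recipe;
  provenance fields record exactly what was applied so the step can be
  replaced.
* Overlap resolution is deterministic nearest-centroid, not the manual
  curation it replaces; the resolution report exists so a human can audit
  it.
* SWC trace input carries no CO sites (the format has no such field); use
  the JSON dialect when CO positions are needed.
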