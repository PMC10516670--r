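# gonadfoci

Quantification of recombination-protein foci in 3D immunofluorescence
image stacks of the *C. elegans* germline.

During meiotic prophase, germline nuclei progress through recombination as
they move along the gonad, and the state of each nucleus can be read from
diffraction-limited immunofluorescence puncta: RAD-51 foci mark early
double-strand-break repair intermediates, MSH-5/HIM-6/COSA-1 foci mark
later and crossover-designated sites, and HTP-3 marks the chromosome axes.
`gonadfoci` turns multi-channel z-stacks of such gonads into the standard
quantitative readouts:

* **3D focus detection** — anisotropic local-maxima calling with a minimum
  peak height, ellipsoidal neighborhood radii (default 1.5/1.5 voxels) and
  a topographic-prominence "noise" tolerance (default 100), plus
  background-based threshold calibration;
* **nucleus assignment** — boundary-inclusive point-in-polygon assignment
  of foci to manually drawn nucleus ROIs (ImageJ `.roi`/`.zip` or a JSON
  dialect), deterministic overlap resolution, per-nucleus counts, and
  relative gonad positions (0% distal tip to 100% end of region);
* **object-based colocalization** — directional nearest-neighbor
  classification under the Rayleigh resolution limit
  `0.61 λ / NA` (242 nm at λ = 555 nm, 282 nm at λ = 647 nm for a 1.4 NA
  objective), two- and three-species category reports with Wilson 95%
  confidence intervals;
* **axis association** — thresholded axis-channel masks dilated one voxel
  in z, association fractions with CIs, Fisher-exact genotype comparisons;
* **gonad zones** — cell-row binning, majority-staining zones (e.g. the
  CHK-2-active zone), count-rule stage boundaries (early/late pachytene),
  and fixed-width peak-accumulation windows;
* **chromosome traces** — arc lengths of traced chromosomes, crossover
  positions as relative distance from the nearest chromosome end
  (in [0, 0.5]), fusion-chromosome classification by the 15 µm length
  cutoff, and per-class position histograms;
* **synthetic scenes** — a seeded generator producing image stacks, ROIs
  and full ground truth (positions, pairings, association flags, rows) so
  every stage is testable without microscope data.

A pipeline driver (`run_pipeline()`) executes all configured stages from a
single JSON config with full provenance, and a thin command-line front end
(`exec/gonadfoci`) exposes each stage as a subcommand
(`simulate`, `detect`, `assign`, `coloc`, `axis-assoc`, `zones`, `traces`,
`stats`, `run`).

## Worked example

Simulate a small gonad field with a known colocalization structure, detect
foci in both channels, count them per nucleus, and classify
colocalization:

```r
library(gonadfoci)

spec <- scene_spec(
  n_nuclei = 12, rows = 3, nucleus_radius_vox = 12, nz = 10, seed = 42,
  species_params = list(
    "RAD-51" = species_param(emission_nm = 647, n_mean = 5),
    "MSH-5"  = species_param(emission_nm = 555, n_mean = 3)),
  coloc_spec = list(pair = c("RAD-51", "MSH-5"), fraction = 0.5),
  background = c(mean = 100, sd = 10))
scene <- generate_scene(spec)

rad51 <- find_maxima_3d(scene$stack, "RAD-51",
                        detection_params(min_peak_height = 500),
                        mask = scene$rois)
msh5  <- find_maxima_3d(scene$stack, "MSH-5",
                        detection_params(min_peak_height = 500),
                        mask = scene$rois)

tab    <- resolve_overlaps(assign_foci(rad51, scene$rois), scene$rois)
counts <- count_foci_per_nucleus(tab)
head(counts, 3)
#>   nucleus_id species n
#> 1       n001  RAD-51 5
#> 2       n002  RAD-51 6
#> 3       n003  RAD-51 2

thr <- resolution_threshold(647, 1.4)   # 281.9 nm, reported as 282
rec <- nearest_neighbor_classify(msh5, rad51, thr)
coloc_report(rec)[, c("n_total", "n_coloc", "percent",
                      "ci_lower", "ci_upper")]
#>   n_total n_coloc percent  ci_lower  ci_upper
#> 1      28      14      50 0.3263313 0.6736687

nrow(scene$truth$pairs)
#> [1] 14
```

Fourteen of the 28 detected MSH-5 foci fall within 282 nm of a RAD-51
focus — exactly the 14 pairs the generator planted at 100 nm offsets — so
the recovered colocalized percentage (50%, Wilson 95% CI 33–67%) matches
the nominal pairing fraction of the scene.

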