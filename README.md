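# cellmon

Label-free monitoring and quality control of adherent cell cultures from
relief-contrast (oblique epi-illumination) microscopy.

Routine cell culture fails quietly: primary cells senesce or transform
over serial passaging, and by the time a downstream assay misbehaves the
culture that caused it is long gone. Continuous label-free imaging inside
the incubator makes culture state measurable day by day — if the images
can be turned into numbers. `cellmon` is the analysis side of such a
monitoring workflow, aimed at cell biologists and culture facilities who
want automated, reproducible readouts of proliferation, morphology and
downstream functional assays:

* **Plate/schedule data model** — wells, imaged regions, and periodic
  acquisition windows (e.g. hourly from 24 h to 72 h of culture), with
  physical pixel calibration carried on every image.
* **Segmentation** — relief-contrast frames have bipolar (bright/dark)
  edge shading that defeats plain intensity thresholding; `cellmon`
  flattens illumination, builds a unipolar gradient-energy map, thresholds
  it against a robust noise floor, splits touching cells by a
  distance-transform watershed, and refines each cell boundary at fine
  scale. Outputs: cell count, centroids, confluency, binary mask.
* **Morphometrics** — projected area and circularity
  `4πA/P²` per cell, with a multi-directional (Cauchy–Crofton) perimeter
  estimator (naive boundary counting biases circularity low by ~20% for
  discs), plus round/non-round × small/large profile classification.
* **Growth analysis** — per-well counts from region averages, doubling
  time `T_d = Δt·ln2 / ln(N₂/N₁)` from endpoints or a log-linear fit, and
  through-origin regression for comparing automated with manual
  (haemocytometer) counts.
* **Capillary networks** — distance-ordered homotopic thinning (2-D and
  3-D, anisotropic voxels) to a medial skeleton, graph extraction with
  junction clustering and spur pruning, total/mean segment length and
  branch-point counts for tube-formation assays.
* **Spheroid formation** — microwell-grid detection (φ500 µm wells at
  600 µm pitch) and per-well aggregate tracking, classifying compacting vs
  dissociating vs non-aggregating dynamics.
* **QC rules** — rule-based flags (`SENESCENCE_SUSPECT`: slowing growth
  with enlarging cells; `TRANSFORMATION_SUSPECT`: accelerating growth with
  small spindle-shaped cells) over per-passage profiles, with JSON/CSV
  reports and trend plots.
* **Synthetic-data generator** — every module is validated against
  simulated relief-contrast fields, growth series, tube networks and
  spheroid series with exact analytic ground truth, so the whole toolkit
  is testable without any real microscope data.

## Worked example

```r
library(cellmon)

# simulate a field of 20 cells with known geometry, then measure it back
field <- synth_field(cell_population_spec(n_cells = 20, seed = 42))
det   <- detect_cells(field$image)
det
#> <cell_labels> 20 cells in 512 x 512 px frame

confluency(det$mask)
#> [1] 0.07592773

cells <- measure_cells(det, field$image)
summarize_morphology(cells)
#> # A tibble: 1 x 9
#>       n area_mean area_sd circularity_mean circularity_sd n_round_small ...
#> 1    20      213.    62.0            0.756         0.0837             3 ...

mean(field$truth$area_um2)          # analytic ground truth
#> [1] 213.1388

# growth: simulate a monitored well, count every frame, fit the doubling time
g  <- growth_sim_spec(doubling_time_h = 20, seed = 1,
                      n0_cells_per_well = 2.28e5,
                      schedule = acquisition_schedule(24, 72, 480, regions = 1))
tl <- synth_timelapse(g, pop = population_preset("P4", min_gap_um = 6),
                      frame_size_px = c(768, 768))
fit <- doubling_time_loglinear(count_frames(tl))
fit
#> <growth_fit> Td = 20.5 h (log-linear over 24-64 h, R2 = 0.922)

# capillary network metrology on a synthetic tube tree
nw <- synth_network(n_segments = 10, seed = 1)
analyze_network(tube_mask(nw$mask, nw$voxel_size_um))$metrics
#> # A tibble: 1 x 7
#>   total_length_um mean_segment_length_um n_branch_points n_edges ...
#> 1            476.                   95.2               2       5 ...
nw$truth$total_length_um
#> [1] 490.8741
```

The counts are exact here because the planted cells respect the hard-core
spacing the segmenter is validated under; the measured mean area (213 µm²)
and circularity (0.756) sit within a percent of the analytic truth
(213 µm², 0.750); the fitted doubling time recovers the planted 20 h
within the Poisson counting noise of ~30–120 cells per frame; and the
skeleton length lands within 3% of the generating polylines (note the
network graph fuses collinear segments that meet at degree-2 bends, so 10
generated segments appear as 5 capillary edges between the 2 true branch
points and 4 endpoints).

A thin command-line wrapper over the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "cellmon.R", package = "cellmon"))') \
    segment --in field.tif --out results/ --pixel-size 0.463
```

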