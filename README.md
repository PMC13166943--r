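# metquant

Quantitative multiplex immunofluorescence (IFA) analysis of MET receptor
activation in tumor specimens.

## The problem

The receptor tyrosine kinase MET drives a subset of solid tumors, and
activated MET — marked by phosphorylation of tyrosine 1235 in the kinase
activation loop — is both a candidate predictive biomarker and the
pharmacodynamic readout for MET-directed therapy. Measuring it reliably in
tissue requires a *quantitative* microscopy assay: a four-plex stain
(DAPI nuclear counterstain, Na⁺/K⁺-ATPase plasma-membrane marker, total
MET, pY1235-MET), compartment segmentation, isotype-control-calibrated
positivity thresholds, and binary-area endpoint metrics. `metquant`
implements that pipeline end to end for people building or validating
such assays: image I/O, segmentation, thresholding, endpoint
quantitation, the pharmacodynamic statistics layer, and a synthetic
scene generator with exact ground truth so every stage is testable
without proprietary slide images.

## Endpoints

For each image field (or rectangular ROI) with nuclear mask *N*, membrane
mask *M*, tissue mask *T*, marker-positivity mask *P* and nucleus count
*n*:

- **Marker area positive per cell** = |P ∩ T| · s² / n  (µm²/cell, with
  pixel size s in µm/px)
- **%MAP** (percent membrane area positive) = 100 · |P ∩ M| / |M|
- **dual %MAP** (MET⁺ & pY1235-MET⁺ colocalization)
  = 100 · |P₁ ∩ P₂ ∩ M| / |M|
- **%NAP** (percent nuclear area positive) = 100 · |P ∩ N| / |N|
- **phospho/total ratio** = (phospho area per cell) / (total area per
  cell)

Positivity is strict (`intensity > cutoff`) with cutoffs derived from
isotype controls (default mean + 3·SD of control pixels). Undefined
denominators yield missing values, never zeros. Group comparisons use
exact unpaired Mann-Whitney tests (full enumeration for pooled n ≤ 16,
tie-corrected normal approximation otherwise), concordance between
assays uses Spearman midrank correlation, and treatment effects are
normalized as `100·(sample − vehicle mean)/vehicle mean`. Specimens with
fewer than 3,000 pooled tumor cells are flagged non-evaluable.

## Worked example

A simulated TKI dose-response study — 3 dose groups (vehicle, 1× and
10× the IC50) × 4 replicate animals — generated, quantified, and tested
in a few lines:

```r
library(metquant)
dir <- tempfile()
cfg <- makeFixtures("dose-response", dir, seed = 7)
res <- runQuantification(cfg)
subset(res$summaries, metric == "area_per_cell_um2_phospho_met")
#>                          metric   group n     mean        sd
#> 5 area_per_cell_um2_phospho_met vehicle 4 51.26250 1.1875219
#> 6 area_per_cell_um2_phospho_met  dose_1 4 25.74375 0.8673175
#> 7 area_per_cell_um2_phospho_met dose_10 4  4.98750 0.1831438
subset(res$comparisons, metric == "area_per_cell_um2_phospho_met")
#>                          metric group_a group_b n_a n_b u          p method
#> 3 area_per_cell_um2_phospho_met  dose_1 vehicle   4   4 0 0.02857143  exact
#> 4 area_per_cell_um2_phospho_met dose_10 vehicle   4   4 0 0.02857143  exact
```

The phospho-MET area per cell falls from ~51 to ~5 µm²/cell across the
dose range (the generator suppresses the phospho channel by
1/(1 + dose/IC50) while leaving total MET untouched), and both dose
groups differ from vehicle at the smallest exact two-sided p attainable
with n = 4 vs 4 (2/70 ≈ 0.029). Total-MET group means stay within a few
percent of each other — the signature of target inhibition without
target loss.

The endpoint table (`quant_records.csv`) has one row per field/ROI with
columns: `field_id`, `roi_id`, `specimen_id`, `group`, `nucleus_count`,
`tissue_area_um2`, `membrane_area_um2`, `nuclear_area_um2`,
`positive_area_um2_{total_met,phospho_met}`,
`area_per_cell_um2_{total_met,phospho_met}`,
`pct_map_{total_met,phospho_met}`, `pct_map_dual`,
`pct_nap_{total_met,phospho_met}`, `phospho_total_ratio`, `evaluable`,
`qc_notes`. Missing values are written as the token `NA`.

A thin command-line wrapper (`inst/scripts/metquant.R`) exposes
`quantify`, `thresholds`, `fixtures` and `stats` subcommands over the
same functions.

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic dose-response study
from scratch under the given seed, runs the complete pipeline on it
(fixture generation → TIFF I/O → segmentation → control-derived
thresholds → endpoint metrics → group statistics), prints the group
means, and writes its results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
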