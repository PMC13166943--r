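---
title: "Quantifying MET activation by multiplex immunofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MET activation by multiplex immunofluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metquant)
```

## The assay model

`metquant` implements the image-analysis half of a quantitative
immunofluorescence assay for MET receptor activation. The staining design
is a four-plex: a DAPI nuclear counterstain, a Na⁺/K⁺-ATPase α1 membrane
marker that outlines the plasma membrane, an antibody against total MET,
and an antibody specific to MET phosphorylated at Y1235 — the
activation-loop phosphosite required for MET signal transduction.
Because activated MET acts both at the plasma membrane (canonical
HGF-driven signaling) and, after proteolytic cleavage and nuclear
translocation, in the nucleus, the assay quantifies each marker in three
compartments: whole tumor cell, plasma membrane, and nucleus.

All endpoints are *binary-area fractions*: a pixel is marker-positive or
it is not, and metrics are ratios of pixel counts (or physical areas)
within compartment masks. There is no intensity weighting — no H-score
analogue — which keeps every metric checkable against a naive per-pixel
counting oracle and makes the measurement robust to overall gain changes
that preserve the positive/negative calling.

The pipeline per field is:

1. **Read** the registered multichannel TIFF; channels are addressed by
   *role* (nuclear stain, membrane marker, total MET, phospho MET), never
   by file page order.
2. **Segment** nuclei from the nuclear channel (threshold → hole fill →
   minimum-area filter → optional watershed declumping) and the membrane
   from the membrane-marker channel (threshold only).
3. **Build** the tissue mask: nuclei dilated by a configurable radius,
   unioned with the membrane mask — the denominator region standing in
   for "tumor cell area".
4. **Threshold** the two MET channels with cutoffs calibrated on isotype
   controls.
5. **Quantify** per ROI: area per cell, %MAP (single and dual), %NAP,
   phospho/total ratio, with QC flags.
6. **Test**: group means ± SD, exact Mann-Whitney contrasts against the
   vehicle group, percent-change-from-vehicle normalization, Spearman
   concordance against an orthogonal assay when one is supplied.

### Assumptions

- Channels are registered (true of a multiplexed stain on one section;
  no registration is attempted).
- The membrane marker is expressed broadly enough that its mask is a
  usable denominator; %MAP is undefined (missing) on fields where it is
  empty.
- Pixel size is supplied by the user: image files are not trusted to
  carry a calibration, and every physical quantity (µm², µm²/cell)
  scales from `pixel_size_um` alone.

## Endpoint definitions and conventions

For masks N (nuclear), M (membrane), T (tissue), P (marker-positive) and
nucleus count n:

| endpoint | definition | undefined when |
|---|---|---|
| area per cell | \|P ∩ T\|·s²/n µm²/cell | n = 0 |
| %MAP | 100·\|P ∩ M\|/\|M\| | \|M\| = 0 |
| dual %MAP | 100·\|P₁ ∩ P₂ ∩ M\|/\|M\| | \|M\| = 0 |
| %NAP | 100·\|P ∩ N\|/\|N\| | \|N\| = 0 |
| phospho/total ratio | apc(phospho)/apc(total) | apc(total) = 0 |

Undefined values are carried as missing (`NA`) with a QC note and are
excluded from group statistics; zero-filling them would bias
treated-group means downward, exactly where the assay is most sensitive.
The ratio is defined on the area-per-cell endpoints (the nucleus count
cancels, so raw areas would give the same number; the contract simply
names one definition). Denominators are per-field only — group summaries
average per-ROI values rather than pooling pixels across fields,
matching how replicate fields/cores are plotted and tested as points.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pixel_size_um` | none (required) | µm/px | scanner-dependent; no safe default |
| nuclear threshold | Otsu | intensity | parameter-free and reproducible; fixed override available |
| `min_nucleus_area_um2` | 10 | µm² | debris rejection; below any credible tumor-nucleus cross-section |
| `split_touching_nuclei` | off | — | counting is unbiased for non-touching cells; watershed declumping available when needed |
| `connectivity` | 8 | — | standard for blob labeling; 4 available (and used by the oracle tests) |
| membrane threshold | Otsu | intensity | same reproducibility argument; `fixed` and `control_derived` available |
| `tissue_dilation_um` | 5 | µm | approximate cytoplasmic rim beyond the nucleus in tumor cells of ~10–14 µm diameter |
| threshold method | mean + 3·SD of isotype control | intensity | conventional 3σ background exclusion; percentile and fixed rules available |
| `min_cells` | 3000 | cells/specimen | fitness-for-purpose evaluability floor for this assay class |
| Mann-Whitney `exactCutoff` | 16 | pooled n | exact enumeration is instant up to here; beyond it the tie-corrected normal approximation is standard |

No morphological post-processing is applied to the membrane mask: %MAP
is a ratio *within* that mask, so thinning or closing cancels to first
order; the choice is documented rather than hidden.

## Numerical choices

- **Positivity is strict** (`intensity > cutoff`). With a zero-variance
  control this makes the control itself exactly 0% positive — the
  boundary convention the threshold-derivation oracle tests pin down.
- **Population (1/N) SD** in the mean + k·SD rule: an explicit, testable
  estimator; at pixel-sample sizes the 1/N vs 1/(N−1) difference is
  negligible.
- **Nearest-rank percentiles**: `sorted[ceiling(p/100·n)]`,
  integer-friendly and verifiable by sorting.
- **Otsu ties**: the first histogram bin maximizing the between-class
  variance wins, so on a bimodal image the cutoff sits at the low end of
  the empty gap — deterministic, and conservative for bright-object
  segmentation.
- **Connected components** by iterative minimum-label propagation;
  **hole filling** uses the dual background connectivity (4 against
  8-connected foreground). Both are verified against a stack-based
  flood-fill oracle.
- **Distances** (tissue dilation, watershed) use the two-pass chamfer
  transform with weights 1/√2 — within ~8% of Euclidean, which a 5 µm
  dilation absorbs; the dilation is tested directly against the
  generator's cell masks (≥ 99% coverage).
- **Mann-Whitney**: U from midranks; exact p by a counting recursion
  over all C(n₁+n₂, n₁) group assignments when tie-free and pooled
  n ≤ 16; two-sided p is the doubled smaller tail, capped at 1. With
  ties (or larger n) the tie-corrected normal approximation with
  continuity correction is used and the method is recorded in the
  result. The exact and approximate paths agree within 0.02 at
  n = 8 vs 8 (tested).
- **Spearman**: Pearson correlation of midranks; p from the t
  approximation on n − 2 df. No exact enumeration path is implemented —
  the recorded method says so.
- **No multiple-testing correction by default** (pairwise contrasts are
  reported unadjusted, as is conventional for these pharmacodynamic
  designs); Holm adjustment is available as an opt-in column.

## The synthetic-scene generator

Real validation data for this assay are proprietary tumor images, so the
package ships a generator whose scenes make every stage testable with
exact ground truth. A scene is a field of non-overlapping disk cells
(default: 128×128 px at 0.5 µm/px, 10 cells of radius 5–7 µm), each with
a 1 µm annular membrane at its rim and a concentric nucleus at 0.6 of
the cell radius. Intensities are 16-bit with background mean 100,
specific stain 3000, and additive zero-mean Gaussian noise of SD 50 —
a bright, well-separated stain over dim background, as a well-optimized
fluorescence panel is tuned to be, quantized to the bit depth (clipped
at 0) the way a camera would.

Marker positivity is painted as an **exact pixel subset**: for each
(marker, compartment) fraction f, exactly ⌊f·|compartment|⌋ pixels are
chosen (seeded) and set to the signal level. Ground truth therefore
records exact rational fractions, and recovery tests can demand
within-2-point agreement at default noise and *exact* agreement at zero
noise with fixed thresholds. Replicate seeds derive deterministically
(`seed + counter`), so every fixture file is bit-reproducible.

Presets span the biological scenarios the assay distinguishes:
negligible expression (an SNU-1-like null), weak, moderate, and high
constitutively-active expression (GTL-16/SNU-5-like); a nuclear-shift
pair (nuclear phospho fraction 0.3 vs 0.6) emulating ligand-driven
nuclear accumulation; an isotype control (marker channels background
only, geometry identical); and a dose-response series in which the
phospho fractions are scaled by 1/(1 + (dose/IC50)^h) while total MET is
untouched — the signature pharmacodynamic pattern of a MET kinase
inhibitor.

What the generator deliberately does **not** emulate: point-spread
optics, spectral bleed-through, autofluorescence, stromal/necrotic
regions, 3-D sectioning effects, staining gradients, or irregular cell
shapes. A green recovery test therefore establishes that the *pipeline
arithmetic and calling logic* are correct on images whose truth is
known — it does not establish robustness to the full messiness of FFPE
tissue, which only real stained sections can probe. Fixture configs set
the evaluability floor to 0 because desk-scale scenes carry tens of
cells, not the thousands of a real biopsy section.

## Design decisions on genuinely open points

- **Tissue mask** ("tumor cell area" denominator): defined as dilated
  nuclei ∪ membrane, marker-agnostic. Production deployments of such
  assays sometimes add a tumor-vs-stroma classifier; that divergence is
  documented rather than imitated, and the tissue definition is
  contained in one function.
- **Unit of analysis**: the ROI/core is the default statistical unit
  (matching per-point plotting of replicate cores); per-animal
  aggregation first is available via `aggregateBy = "specimen_id"`,
  since both conventions are defensible for nested designs.
- **Threshold granularity**: the config freezes thresholds per marker
  and can reuse them across batches or re-derive them per batch; the
  package does not assert which granularity a given laboratory should
  use.
- **Nuclear-threshold default**: Otsu rather than a fixed value, because
  no published nuclear cutoff exists to inherit; every oracle test that
  needs exactness overrides it with a fixed threshold.
- **ROIs are rectangles** (whole field by default): keeps geometry
  trivial, testable, and sufficient for core/field-based designs.
- **TIFF subset**: the built-in codec covers uncompressed unsigned
  8/16-bit grayscale, single- or multi-page, both byte orders on read.
  Proprietary scanner formats are out of scope; export to TIFF first.

## Known limitations

- No single-cell resolution: the membrane is quantified in aggregate per
  field, so per-cell membrane heterogeneity is invisible.
- No machine-learned segmentation; heavily overlapping or irregular
  nuclei will be under-split (watershed helps only for modest touching).
- The %MAP/%NAP endpoints inherit the threshold calibration: a
  miscalibrated isotype control shifts all positivity calls. The
  threshold provenance (method, parameter, control id, cutoff) is
  recorded in every run log and serialized with the results for audit.
- Chamfer distances slightly underestimate Euclidean disks; dilation
  radii are approximate at the ~8% level (absorbed by the default 5 µm
  rim, and irrelevant to all percentage endpoints).
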