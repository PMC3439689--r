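---
title: "Quantifying myogenic CFC assays: the model behind cfcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myogenic CFC assays: the model behind cfcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcquant)
```

## The measurement problem

In a muscle colony-forming-cell (CFC) assay, single satellite cells are
sorted into wells and grown into clonal colonies that mix undifferentiated
cells, differentiated myocytes and fused myotubes. Each colony is imaged as
a merged RGB micrograph: DAPI-stained nuclei in the blue channel, sarcomeric
myosin heavy chain (MHC) immunostain in the red channel. Three per-colony
quantities summarize proliferation and differentiation:

* **total nuclei** — proliferative output of the founding cell;
* **coefficient of differentiation** $D_f = 1 - \dfrac{\#\text{stain-negative}}{\text{total nuclei}}$,
  the fraction of nuclei lying inside MHC+ cytoplasm;
* **fusion index** $U_i = \dfrac{\sum \text{nuclei in cells with} > 2 \text{ nuclei}}{\text{total nuclei}}$,
  the fraction of nuclei in definitive fusion products (a binucleated cell
  may merely be dividing, so only cells with more than two nuclei count).

Both indices run from 0 to 1 and $U_i \le D_f$ by construction. Counting by
eye is slow and inter-observer variability is substantial, mostly because
dense colonies contain clumps of overlapping nuclei and myotubes adjacent
to many single cells. `cfcquant` automates the count.

## The pipeline

Each channel is processed identically, with its own two tunable
parameters:

1. **Background removal** — grayscale morphological opening with a flat
   disk of radius $R$ (erosion then dilation). Bright features narrower
   than the disk — debris specks, noise — are suppressed; the interior
   intensity of larger structures is preserved. Opening is anti-extensive
   and idempotent, and $R = 0$ is the identity.
2. **Thresholding** — a pixel is foreground iff its intensity is *strictly*
   greater than $T \in [0, 1]$. Plain value thresholding is used
   deliberately; adaptive methods (e.g. Otsu) are not offered because they
   proved less predictable on stained colony images than a per-dataset
   hand-chosen $T$.
3. **Labeling** — 8-connected components of the binary mask, each with its
   pixel area, centroid (unweighted mean of member pixel coordinates) and
   traced outer boundary. Regions touching the border are kept; interior
   holes do not count toward area.

Defaults used throughout the package's validation: DAPI $R = 2$,
$T = 0.3$; MHC $R = 3$, $T = 0.3$. Intensities are always normalized to
$[0, 1]$ from the source bit depth, so thresholds are bit-depth
independent. All coordinates are 1-based `(row, col)` with row 1 at the top
— the native convention of R matrices; adopting it everywhere (centroids,
truth tables, CSV output) avoids a perpetual off-by-one translation layer
at the package boundary.

## Resolving clumped nuclei: dataset-wide size calibration

A connected DAPI+ region may be one nucleus or several overlapping ones.
Rather than attempting shape-based splitting, the pipeline calibrates on
size. Region areas from *every* image in the batch are pooled into one
histogram (default bin width 10 px²). In a typical dataset this histogram
shows a narrow first peak (single nuclei), a broader second peak (doublets
and triplets) and a long tail (larger clumps).

The *first peak* defines the single-nucleus reference area:

* **USER_BOUNDS** (the faithful workflow): the user inspects the histogram
  (`autoplot()`, or the `histogram.csv`/`histogram.png` written by
  `run_calibrate()`) and selects the lower and upper area of the first
  peak — ideally the smallest and largest single nucleus — iterating on
  $R$ and $T$ until satisfied.
* **AUTO** (for unattended runs): counts are smoothed with a 3-bin moving
  average; the first local maximum scanning from small areas upward is the
  peak; the bounds extend to the nearest enclosing local minima (ties are
  treated as still descending, so a noisy shoulder does not truncate the
  walk) or to the histogram ends.

Every region inside the bounds is assigned a nuclear quantity of exactly 1.
Every region outside — larger clumps *and* sub-peak debris — is assigned
the fractional quantity $\text{area} / \text{mean single area}$, never
rounded at this stage. An optional `min_area` filter (default 0 = off) can
discard debris below a stated area for datasets where specks survive the
opening. Totals are therefore conserved: an image's total nuclear quantity
is the in-peak count plus the out-of-peak area sum over the mean single
area.

## Mapping nuclei into MHC+ cytoplasm

The red channel yields MHC+ regions via the same open–threshold–label
pipeline. Membership is decided by the centroid rule: the centroid of a
DAPI+ region is snapped to the nearest pixel (halves toward the larger
index) and looked up in the MHC label image; if it lands on a labeled
pixel, the *entire* DAPI+ quantity belongs to that region, otherwise the
nucleus is stain-negative. A region's nuclei total is the sum of assigned
unrounded quantities.

Fiber classification bridges fractional estimates to the integer
mono/bi/multinucleated vocabulary: $n = \text{round-half-up}(\text{total})$,
with $n = 0$ anucleate, $n = 1$ mono, $n = 2$ bi, $n \ge 3$ multi. The
$U_i$ numerator sums the *unrounded* totals of MULTI-classified regions, so
classification and conservation stay consistent. Rounding versus truncating
this bridge is a genuinely open choice; half-up rounding was chosen once
and used everywhere, including centroid snapping.

## Batch processing

`run_batch()` makes the dataset-wide calibration explicit as two passes:
pass 1 segments every blue channel and fits one calibration model for the
whole directory; pass 2 assigns quantities, detects MHC+ regions, computes
metrics and appends one row per colony to `results.csv` (exact column
order: `image_id`, `total_nuclei`, `stain_negative_nuclei`,
`mhc_positive_nuclei`, `df`, `ui`, `mono_count`, `bi_count`,
`multi_count`), then writes the group summary, the histogram artifacts and
optional per-image overlays (MHC+ pixels red; DAPI+ regions blue, cyan or
magenta for single, doublet-scale and larger size classes). Files are
processed in byte-order lexicographic filename order; a corrupt file is
logged and skipped, never fatal. Each run rewrites its outputs from
scratch — appending across sessions would break the guarantee that
identical inputs and configuration reproduce byte-identical CSVs.

Group statistics are means with two-sided 95% Student-t confidence
intervals per metric, and Welch's unequal-variance t test for unpaired
two-group comparisons — a robust default for group sizes and variances
that have no reason to match.

## The synthetic-colony generator

`generate_colony()` renders the structures the algorithm must cope with,
with exported ground truth, so every stage is testable without microscope
data:

* nuclei as flat-intensity disks (0.9) with a 1-px soft edge, radius
  $\mathcal{N}(4.5, 0.3^2)$ px truncated at 3 sd, centres on the integer
  pixel grid; overlap is the *union* of disks, so merged clumps are smaller
  than the sum of their parts, as in real images;
* singles separated by more than twice the maximum radius; doublets and
  multiplets as chains with centre spacing 1.7 × radius, guaranteeing each
  cluster merges into a single DAPI+ region while staying resolvable by
  area;
* MHC+ cytoplasm as elongated axis-aligned rectangles (intensity 0.8);
  nuclei assigned to a region are kept a margin inside it, all others a
  margin outside, making ground-truth membership unambiguous;
* additive Gaussian noise (sd 0.02) on all channels and 1–5 px debris
  specks in the blue plane to exercise the opening and `min_area`
  decisions.

Default study conditions: 384 × 384 px images, 30 singles, 6 doublets, 3
multiplets of 3–5 nuclei, 4 MHC+ regions, half the nuclei inside MHC+
cytoplasm. Integer centres make the idealized case well-posed: with zero
radius spread and zero noise, every single rasterizes to the identical
area, the histogram collapses to one bin, and the pipeline count is exact.

What the generator does **not** emulate — and hence what passing tests do
not show about real micrographs: optics (point-spread blur, chromatic
shift), uneven illumination, intensity gradients within nuclei, bleed
between channels, myotube shapes beyond convex rectangles, and densely
packed fields where single nuclei touch. Its hard-separation placement
model also caps how crowded a region can get: colonies with nearly all
nuclei packed into one small MHC+ region are not representable, which is
why validation draws the in-MHC fraction below 0.9 across at least two
regions.

## Numerical choices and degenerate inputs

* **Exact Euclidean disk**: the structuring element contains every offset
  with $\sqrt{dr^2 + dc^2} \le R$. MATLAB-style decomposed disk
  approximations differ slightly; the exact disk is reproducible from its
  definition.
* **8-connectivity** for foreground components (the default convention of
  MATLAB-lineage image toolboxes); validated exhaustively against a
  flood-fill oracle on all $2^{16}$ binary 4 × 4 masks plus random
  64 × 64 masks.
* **Strict threshold** (`>`): $T = 0$ then cleanly means "any signal" and
  $T = 1$ selects nothing.
* **Degenerate cases**: an all-identical-area histogram spans a single bin
  (model fitted with a warning); a zero-nucleus image reports
  $D_f = U_i = 0$ with a warning so batch CSVs stay rectangular; a
  single-colony group summary has a degenerate CI at the mean.
* **Validation problem sizes**: exhaustive 4 × 4 labeling plus 100 random
  64 × 64 masks; 500-region calibration ensembles; 10-image batches at
  320 × 320 px for counting and end-to-end recovery; 200 randomized
  224 × 224 px colonies for the metric identities; 1,000 null replicates
  for the statistical layer. These sizes give stable estimates while
  keeping a full validation run in minutes on one core.

## Known limitations

* Counting accuracy rests on the first peak being identifiable: heavily
  overlapping size distributions (very variable nuclei, or doublets no
  larger than big singles) bias clump quantities; the bias is graceful
  (fractional, not catastrophic) but real. Shape-based features
  (eccentricity, solidity) could disambiguate and are a natural extension,
  deliberately out of scope here.
* One MHC+ label is one fiber: touching myotubes merge into a single
  region and their nuclei pool.
* The centroid rule misassigns a nucleus whose region barely overlaps a
  myotube edge if its centre lies outside — symmetric with the human
  convention it replaces.
* Cloning efficiency (fraction of seeded wells forming a colony) needs
  plate-layout metadata that image files do not carry; it is not computed.
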