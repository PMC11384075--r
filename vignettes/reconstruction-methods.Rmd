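---
title: "Reconstructing spatial transcriptomics arrays from barcoded flow cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing spatial transcriptomics arrays from barcoded flow cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novaST)
```

## The problem

Patterned sequencing flow cells carry hexagonally packed nano-wells
(~300 nm openings at a ~625 nm pitch on the current large-format surface).
When each well is seeded with a single randomly barcoded oligonucleotide and
clonally amplified, a first sequencing pass reveals which 32-base barcode
sits at which position — turning the flow cell into a spatial capture array
with sub-micrometre feature spacing. A tissue section placed on a diced
piece of that surface releases mRNA onto the barcoded lawn; a second
(standard) library sequencing run then yields reads that pair a spatial
barcode with a transcript and a UMI.

The computational task this package implements is the reconstruction in
between: turning per-tile FASTQ from the array-definition run plus the
spatial library into a spatially resolved gene expression matrix. The
stages are:

1. **Barcode indexing** — parse per-tile FASTQ, validate each read against
   the barcode design, store compact binary indexes and a 10,000-read
   subset per tile for later tile identification.
2. **Fiducial detection** — rasterise barcode occupancy per tile, detect
   the concentric-circle fiducial voids with a circle transform, and
   compute a per-tile anchor centroid.
3. **Stitching** — place all tiles into one physical frame (nanometres)
   using the fiducial centroids, a least-squares scale calibration, and the
   staggered swath layout (even swaths offset by one tile).
4. **Tile selection, whitelist, quantification** — identify
   tissue-covered tiles from the first million spatial reads, build a 31-nt
   whitelist, match reads with at most one mismatch, deduplicate UMIs by
   single-mismatch merging, and emit a GEM table (gene, x, y, molecule
   count).
5. **Binning and QC** — square-bin the GEM at 728/1456/2912 native units
   (25/50/100 µm), drop bins with fewer than 75/250/500 detected genes,
   normalise bins to 10,000 counts and log-transform.
6. **Registration** — fit a six-parameter affine transform from manually
   selected landmark pairs to align stained images with the spatial frame.

Everything is exercised end to end against a bundled synthetic flow-cell
simulator that provides ground truth for every read.

## Desk geometry

The only quantities reproducible without sequencing data are closed-form:
a hexagonal lattice assigns each well a unit cell of
$\frac{\sqrt{3}}{2}\,p^2$ for pitch $p$, so the S4-type surface
(p = 625 nm) has ~296 wells per 100 µm² and per-site dead space
$\frac{\sqrt{3}}{2}p^2 - \pi (d/2)^2$. Comparing the S4 surface
(625/300 nm) with the denser X-25B surface (399/280 nm) gives a dead-space
ratio of 3.51 — the "~3.5×" reduction. A 56-section diced flow cell with
two functional surfaces per section yields 112 chips.

Two notes on interpretation, both deliberate design choices:

* *Dead space is defined per lattice site* (unit-cell area minus well
  area). The alternative area-fraction reading gives ~1.4× between the two
  surfaces and is rejected because it does not reproduce the published
  ratio from the published pitches and diameters.
* *The ~350 spots per 100 µm² sometimes quoted for the 625 nm surface is
  inconsistent with hexagonal close packing at that pitch*, which gives
  295.6. `packing_density()` reports the closed-form value; the
  discrepancy is documented rather than matched.

## What the simulator emulates

`sim_config()` fixes the study conditions; its defaults are chosen once and
used everywhere (tests, acceptance script):

* **Scale.** One raw read-name unit is 25000/728 ≈ 34.34 nm, so that a
  728-unit bin edge is exactly 25 µm. The well pitch is 18.2 raw units
  (625 nm).
* **Chip layout.** 6 swaths × 6 tile rows; even swaths are offset by one
  full tile along the tile-row axis. Tiles are 5000 × 5000 raw units
  (~172 µm) — a deliberately desk-sized tile, chosen so a full chip holds
  ~1.7 million wells; all geometric relationships (pitch : bin : fiducial
  radii in pixels) match the full-scale system.
* **Occupancy.** Each lattice site independently receives a unique
  pattern-conformant barcode with probability 0.80. The ~20% non-unique
  wells are simulated as empty: mixed-cluster reads are not modelled, since
  their sequence outcome is not characterised. Barcode uniqueness is
  enforced at the trimmed 31-mer level so that ground-truth identity is
  preserved by the whitelist trim (the real pipeline's symmetric
  trim-collision dropping is still implemented and tested on constructed
  fixtures; at realistic whitelist sizes it affects ~10⁻⁵ of entries).
* **Fiducials.** Four marks per tile at the quarter positions, each a
  filled inner disc (radius 550 raw units = 22 binned pixels) plus an outer
  ring (radius 1100 = 44 px, width 150): wells under the marks emit
  nothing, producing the circular voids the detector looks for. Both radii
  sit centrally in the published detection ranges (15–30 and 40–80 px).
* **Read-frame jitter.** Each tile's coordinate origin is displaced by a
  uniform integer in ±10 raw units, modelling the per-tile registration
  error that stitching must correct. The fiducial marks themselves sit on
  the manufactured grid.
* **Spatial library.** Wells inside a rectangular tissue mask emit
  Poisson(1) molecules; each molecule gets a uniformly chosen gene (600
  genes with unique random 40-nt transcript tags), a 9-nt UMI, and a
  geometric number of duplicate reads with mean 3 (support ≥ 1 — a
  molecule with zero reads is unobservable and therefore not part of the
  ground truth). R1 is the 34-nt barcode read, R2 is 91 nt: UMI, tag,
  poly-A filler. UMIs within one (barcode, gene) group are kept at Hamming
  distance ≥ 2 on their first 8 bases so that single-mismatch merging
  cannot conflate distinct ground-truth molecules; real data has no such
  guarantee, which is one reason measured counts on real tissue are
  approximations.
* **Errors.** `error_rate` applies independent substitutions to the
  spatial library reads (R1 and R2). The array-definition reads have their
  own knob, `hdmi_error_rate`, defaulting to 0: the array pass is treated
  as the chip's ground truth. This separation matters — corrupting the
  array reads removes wells from the whitelist entirely (constant-block
  errors invalidate the read), a failure mode that no downstream matching
  can repair.

What the simulator does *not* emulate: optical cluster chemistry, polony
size, index reads, mixed clusters, transcript abundance skew, alignment
ambiguity, or tissue morphology. Passing tests therefore demonstrate the
correctness of the reconstruction machinery under its stated error model,
not sensitivity on real tissue.

## Numerical and algorithmic choices

**Barcode validation** is position-local over IUPAC symbols (V = A/C/G,
B = C/G/T, N = any). The stored orientation of the 32-mer (12 constant
bases, then the 20-base degenerate block) follows from the capture oligo
and reverse-complement demultiplexing; it is configurable because the
post-demultiplexing layout is an inference, not a printed fact.

**Density images** bin valid-barcode coordinates into 25×25-unit pixels.
Normalisation is robust rather than max-based: counts are scaled by the
median nonzero pixel count and clipped to 255. With ~2 wells per pixel the
occupancy histogram is Poisson-sparse, and under strict max-normalisation
the typical occupied pixel lands *below* half of the observed maximum, so a
fixed binarisation threshold of 128 after inversion would classify tissue
as void. Median-referenced clipping makes typically occupied pixels
saturate, preserving the intended semantics of the fixed 128 threshold.
Denoising is a 3×3 median rank filter — the natural denoiser for a
near-binary image whose only defect is isolated salt pixels (empty pixels
inside tissue, P ≈ 0.2 per single-site pixel).

**Circle detection** is a gradient-voting circle transform: edge pixels of
the binary void image vote along their local gradient direction (both
senses) at every radius in the configured range; one run per radius range
(outer 40–80 px, inner 15–30 px). Two stabilisations matter on stochastic
boundaries: gradient directions are estimated on a Gaussian-smoothed
(σ = 2 px) copy of the image, and the accumulator is summed over 5×5
boxes before peak extraction. The vote threshold is fixed at 3 × 2π·r_min
box votes: on simulated tiles true circles score 6–7× the minimum
circumference while background clutter stays below 1.5×, so the threshold
sits in a wide gap rather than on a knife edge. Accepted peaks must be
separated by at least 2 × r_min (the fiducial spacing on the simulated
tile, 100 px, is smaller than 2 × r_max for the outer range, which would
otherwise suppress genuine neighbours). Each candidate is refined by an
algebraic (Kåsa) least-squares circle fit to edge pixels within the radius
window; for the two concentric edge circles of the outer ring the fitted
centre is shared by symmetry. Typical centroid accuracy on simulated tiles
is ~0.1–0.3 px, an order of magnitude inside the 2-px acceptance band.

**Centroids** use all 8 circle centres jointly (the per-class means are
reported for QC); a tile is complete only with 4 outer + 4 inner circles.
Missing centroids are interpolated as the mean of grid-distance-1
neighbours under the constant-placement assumption.

**Stitching** is translation-only per tile, matching the printed
correction procedure; rotation and shear residuals are out of scope. The
grid is anchored at the top-left tile's observed centroid, so all global
coordinates are relative to that tile's frame. The nm-per-unit scale is the
analytic least-squares ratio over measured (nm, raw) spacing pairs.

**Matching semantics.** Whitelist entries are barcodes trimmed to 31 nt.
A read barcode matches exactly, or is assigned to the unique entry at
Hamming distance 1; two or more candidates leave it unassigned —
deterministic and conservative, never probabilistic. UMI deduplication
merges UMIs (first 8 of the 9 extracted bases; the 9th is retained but
unused, following the printed quantifier parameters) into connected
components of the Hamming-1 graph; the molecule count is the component
count. This is the simplest reading of "1MM_All"-style merging and is
cross-checked against an explicit component oracle in the tests. Gene
assignment in the internal quantifier looks the R2 payload up against the
synthetic transcript tags with the same unique-single-mismatch tolerance
as barcode matching; at zero error rate this is identical to exact lookup.
Real-read alignment is delegated to the external matrix-import path
(`import_counts()`), which ingests a Matrix Market triplet file with
barcode and feature lists.

**GEM and binning.** GEM coordinates are global nanometres divided by the
calibrated scale and rounded to native grid units; records sharing
(gene, x, y) are summed. Bins are anchored at the chip origin (not the
data bounding box) so that bin indices are reproducible across runs and
subsets, and so that 2912-unit bins are exact 4×4 aggregations of
728-unit bins. The QC rule "too few genes are removed" is implemented as
*keep iff detected genes ≥ threshold* — the boundary bin is kept, since
the printed rule states the cutoff but not its inclusivity.
Mitochondrial percentages are reported per bin but never filtered on.
Downstream steps (HVG selection, regression, scaling, PCA, clustering) are
standard toolkit calls and are deliberately not reimplemented here.

**Registration** fits the full six-parameter affine map by least squares;
at least three non-collinear landmark pairs are required, and degenerate
configurations are an error rather than a silent pseudo-inverse.

## Problem sizes used in tests

The bundled checks run a full 6 × 6-tile chip (~1.7 M wells) for fiducial
recovery, 10 seeds of 2 × 2-tile chips for scale/offset recovery, two
2 × 2-tile end-to-end runs (error rates 0 and 0.005; ~260,000 read pairs
each) for conservation and recovery, a 10⁴-query × 10⁴-entry
matcher-versus-brute-force comparison, and 10³ random UMI multisets
against the component oracle. These sizes were chosen as the smallest
chips that exercise every geometric feature (staggered swaths, four
fiducials per tile at the published pixel radii, partial tissue coverage).

## Known limitations

* Per-tile correction is translation-only; real chips may show small
  rotations that would appear as residual centroid error.
* The internal quantifier's gene assignment requires the simulator's
  unique transcript tags; it is not an aligner.
* Whole-flow-cell usable area is not modelled (flow-channel dimensions are
  not part of the geometry module's scope).
* The density-image normalisation assumes the void/tissue contrast of a
  reasonably covered tile; a nearly empty tile would need the debug images
  inspected before trusting detection.
* Cross-surface (top/bottom glass) co-registration is out of scope; each
  chip is one surface.
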