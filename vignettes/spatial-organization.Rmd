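---
title: "Quantifying the spatial organization of multiplexed smFISH puncta"
author: "punctacoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the spatial organization of multiplexed smFISH puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctacoloc)
```

## The problem

Single-molecule FISH (smFISH) renders individual RNA transcripts as
diffraction-limited fluorescent spots ("puncta"). With multiplexed
protocols a dozen RNA species can be imaged in the same tissue section,
which raises a quantitative question: are different mRNA species packaged
together into common ribonucleoprotein granules, or do they localize
independently, overlapping only as often as chance and their abundances
dictate? Answering it requires (i) turning spot images into segmented
punctum objects, (ii) measuring object-based colocalization between
channels, (iii) estimating how much colocalization is expected at random,
and (iv) relating the excess over random to per-channel abundance.
`punctacoloc` implements this pipeline end to end, together with a
synthetic-scene generator that provides ground truth for validating every
stage.

## Data model

All geometry lives in a rectangular ROI of physical extent
$W \times H\ \mu m$ discretised at $s$ pixels per micrometre
(default $s = 9.6679$, the scale of the 63x acquisitions the defaults were
chosen for). Pixel $(row, col)$ is 0-based and covers the half-open square
$[col/s, (col+1)/s) \times [row/s, (row+1)/s)$; continuous coordinates are
micrometres from the ROI top-left corner, x rightward and y downward. This
convention makes image masks and coordinate tables round-trip exactly
(to within half a pixel pitch).

A punctum carries a centroid, an area ($\mu m^2$), a Feret (maximum
caliper) diameter, a total intensity (sum of member-pixel values) and a
mean intensity. When puncta come from segmentation they also carry their
pixel footprint; puncta loaded from coordinate tables do not, and are
materialised as discs of their recorded Feret diameter whenever a
pixel-overlap operation needs a footprint. Centroid-distance operations
use the table values directly.

## Segmentation

Channel images are thresholded and 8-connected components become puncta
(single-pixel components retained by default; an optional minimum-area
filter is recorded in provenance). The threshold is calibrated against
the channel's negative-control image: `calibrateThreshold()` returns the
lowest threshold at which the puncta count on the control is at most a
stated fraction (default 3%, with 1% available) of the experimental
count. Candidate thresholds are scanned over quantiles of the pooled
positive pixel values with a densified upper tail, plus a value just
above the control's maximum, so the scan always terminates and loosening
the bound can never raise the returned threshold. Nuclear exclusion
removes any punctum sharing a pixel with the DAPI mask after each nucleus
is expanded by +10% area — an isotropic dilation by
$r = R(\sqrt{1.1} - 1)$ for equivalent-circle radius $R$ (for a 4 µm
nucleus, $r \approx 0.195\ \mu m$). Whether "+10%" should mean area
growth, radius growth or a fixed ring is genuinely open; area growth is
the most literal reading and the fraction is exposed as a parameter.

Feret's diameter is computed as the maximum pairwise distance between
member-pixel corner points, over the convex hull — the standard
particle-analysis caliper, so a single pixel has Feret equal to its
diagonal.

## Colocalization and its null

Two overlap definitions are supported, with all operations counting each
*reference* punctum at most once however many partners it touches:

* **pixel mode** — the reference punctum shares at least 1 pixel
  (configurable) with the union mask of the target channel. This mirrors
  the segmented-object intersection ("having") semantics of commercial
  analysis software.
* **centroid mode** — some target punctum lies at centroid distance
  strictly less than $f \cdot (F_A + F_B)/2$ with $F$ the Feret
  diameters; $f = 0.99$ is the lenient ">1% overlap" definition and
  $f = 0.50$ the stringent ">50% overlap" one. The inequality is strict
  ("less than"), so borderline ties do not colocalize.

Two normalizations convert counts to percentages:
$100\,|A_{coloc}|/|A|$ (percent of the reference channel) and the
symmetric $100\,(|A_{coloc}| + |B_{coloc}|)/(|A| + |B|)$ (percent of the
pair). The pair form counts colocalized ids on both sides rather than
twice the number of pairs, so hub puncta are not double-counted. Empty
denominators yield missing values, never zero. Puncta straddling the ROI
edge are kept; no edge correction is applied.

Chance colocalization is estimated by rotating the reference channel 90°
(clockwise, square ROIs only) or 180° about the ROI centre and
re-measuring. Rotation acts on coordinates and pixel footprints, not on
rendered images, so the null is available for coordinate-table input;
abundance, area and intensity distributions are preserved exactly. The
random percentage is subtracted cell-wise from the experimental matrix;
negative cells are reported unclipped (clipping would bias replicate
averages) with a warning. On a uniform point process the expected
subtracted value is zero; on real tissue the rotation cannot reproduce
cytoarchitectural exclusions, so subtracted values there retain a
positive bias that the package does not attempt to correct.

For a uniform scene the probability that a reference punctum with radius
$r_A$ colocalizes (centroid rule) with at least one of $n_B$ uniform
target puncta of radius $r_B$ in an ROI of area $S$ has the closed form

$$p = 1 - \left(1 - \frac{\pi\,(f\,(r_A + r_B))^2}{S}\right)^{n_B},$$

which the test-suite uses as an independent oracle across a density
ladder.

## Composition, distributions, correlation

`classifyComposition()` places every focal punctum in exactly one
category — singleton, dimer with a named partner channel, multimer
including the special partner, or multimer without it — where "dimer"
and "multimer" count distinct partner *channels*, not partner puncta
(union-of-intersections layer algebra cannot distinguish multiplicity
within a channel). Fractions sum to 100%. The same classification run on
the rotated focal channel gives the chance composition; on uniform
scenes the null singleton fraction factorises as
$\prod_c (1 - p_c)$ over partner channels, another closed-form oracle.
`gateByMarker()` restricts all channels to puncta overlapping a protein
marker (an immunostain mask or segmented channel), using pixel overlap by
default.

Area and normalized-intensity distributions are summarised as
relative-percent histograms (area bin width 0.1 µm² with an open tail
from 1.0 µm²; both configurable). Normalized total intensity is
`total/mean` per punctum, which on pixel-backed puncta equals the pixel
count exactly — an area surrogate that is comparable across channels
acquired with different exposure settings; a per-channel-mean variant is
available behind a flag, but the per-punctum reading is the default
because it is the one that correlates with area. Replicate histograms
are averaged on the relative-percent scale (not pooled counts) with SEM.
Profiles are clustered agglomeratively with Ward-D2 linkage: manhattan
distance for area/intensity distributions (robust on skewed data),
euclidean for colocalization profiles. Ward's criterion formally assumes
squared-euclidean geometry; the manhattan/Ward pairing is kept
deliberately because it is the analysis convention this package
reproduces. `hclust` is deterministic given the input order, and
identical profiles merge at height zero. `abundanceCorrelation()` fits
ordinary least squares of a reference channel's colocalization
percentages against partner abundances and reports the slope and $R^2$.

## The synthetic-scene generator

`generateScene()` emulates the statistical structure of multiplexed
puncta fields: per-channel counts are Poisson around the specified
expected count; centroids are uniform outside a nuclear mask (discs of
~8 µm placed uniformly — the DAPI-exclusion geometry without nuclear
biology); areas are log-normal draws from one of four size classes; the
Feret diameter is the equivalent-circle diameter times a shape factor
uniform on [1, 1.3]; transcript copy numbers come from a per-channel
distribution. Granule plans co-place a stated fraction of one channel's
puncta within a jitter radius (default 0.1 µm, small enough that planted
pairs satisfy both the 1-pixel and the >50% criteria) of distinct
partner puncta, recording granule ids as ground truth.

The size classes are parameterised from empirical per-cluster
summaries: the median area fixes the log-mean (small 0.23, small-broad
0.27, large-broad 0.285, large 0.346 µm², the across-RNA averages), and
the log-sd is fitted by least squares to the cluster's relative mass in
the 0.6–1.0 µm² bin and above 1.0 µm². A two-parameter log-normal
cannot additionally pin the histogram peak bin; with tail-mass fitting
the small-class peak falls in the 0.1–0.2 µm² bin, consistent with the
reported peak-bin labels read as upper bin edges.

`renderImages()` draws each punctum as a disc of its area carrying its
total intensity, blurs with a Gaussian PSF, and adds constant background
plus Gaussian noise; the matched negative control is background plus
noise only. The generator does **not** emulate dendrite morphology,
transport dynamics, 3D PSFs, autofluorescence structure, or the
cytoarchitectural exclusions of real neuropil — so passing tests
demonstrate estimator correctness under known conditions, not image
realism. No reference signal-to-noise ratio is available for typical source imagery;
the validation suite uses SNR 10 (median per-pixel punctum amplitude
over the noise sd) as its rendering condition.

`simulateDilution()` models serial probe dilution: each punctum's
labeled copies are Binomial(copy number, labeled fraction) and detection
requires labeled fluorescence to reach a threshold. Single-copy
populations lose *count* linearly in the labeled fraction while the
detected-intensity distribution is invariant; high-copy populations keep
their count while mean intensity falls linearly — the two diagnostic
branches that distinguish low- from high-copy-number puncta. The
apparent-diameter readout uses a cube-root map of detected intensity
(volume-proportional loading); any increasing map gives the same
qualitative behaviour.

## Abundance-matching simulation

`augmentChannel()` adds synthetic puncta to a channel until it reaches a
target count: attributes are bootstrap-resampled with replacement from
the observed puncta (hence bounded by the observed min–max; a
uniform-over-range alternative sits behind a flag since the protocol
description admits both readings), centroids are uniform over the ROI
with exact-duplicate coordinates rejected, and the observed puncta and
the partner channel are never modified. Nuclear masks are ignored at
this stage, matching the segmented-without-DAPI-removal inputs the
procedure was designed for. `simulatedColocalization()` repeats the
augmentation over (by default) 10 bootstrap iterations and averages the
per-iteration colocalization percentage, reproducing the observation
that raising one channel's abundance to another region's level raises
pairwise colocalization to that region's level.

## Numerical choices and determinism

* All stochastic operations take an integer seed and restore the
  caller's RNG state; identical configuration and seed give identical
  outputs (the pipeline stamps results with a config hash, seed and
  package version).
* Threshold calibration scans ~60 candidates; component counting uses
  4-connected labeling with a union-find merge of diagonally adjacent
  labels to obtain 8-connectivity.
* Centroid-mode neighbour search bins target puncta into square cells of
  the maximal interaction distance and scans the 3x3 neighbourhood, so
  pairwise matrices on ~10^4-puncta channels stay subsecond.
* Histogram bins are half-open on the left edge and the final bin is
  open-ended; bin edges are rounded at the 12th decimal to keep
  floating-point sequence noise out of bin labels.
* Degenerate inputs: empty reference channels yield missing percentages
  (not zeros); empty images segment to empty sets; a punctum without the
  attribute an operation needs (pixels, Feret) is reported by id.

## Validation problem sizes

The shipped test-suite and acceptance script validate on: density
ladders of 200 reference vs up to 13,000 target puncta in a 180 µm ROI
(50 seeds per rung against the closed form); planted fractions
q in {0.05, 0.2, 0.5} at 300+300 puncta (20 seeds); rendered 52 µm
scenes of 100 puncta at SNR 10 for segmentation recovery; 12 profile
items over four planted families (50 seeds) for clustering; and 4,000
puncta per dilution condition. These sizes were chosen so each
Monte-Carlo comparison has at least 3-sigma resolution at the tolerance
being asserted.

## Known limitations

* 2D only: the analysis targets maximum projections; no 3D objects or
  sub-pixel spot fitting.
* The rotation null underestimates chance colocalization in structured
  tissue (excluded volumes are not modelled); subtracted values on real
  images retain that bias.
* Touching spots are not split (no watershed); a bright pair closer than
  the PSF merges into one punctum.
* Pixel-intensity correlation coefficients (Pearson/Manders) are out of
  scope by design — the object-based approach is the point.

## A minimal session

```{r example, eval = FALSE}
roi <- roiSpec(52, 52)
scene <- generateScene(
    list(channelSpec("A", 200, "small_broad"),
         channelSpec("B", 400, "small")),
    roi, plans = list(granulePlan("A", "B", 0.2)), seed = 1)
crit <- overlapCriterion("centroid", fraction = 0.99)
percentOfReference(scene@channels$A, scene@channels$B, crit)
nullRes <- randomSubtractedMatrix(scene@channels, crit, angle = 90)
nullRes@subtracted
```
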