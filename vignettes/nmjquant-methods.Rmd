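---
title: "Quantifying synaptic-vesicle distribution at the Drosophila NMJ: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic-vesicle distribution at the Drosophila NMJ: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

At the *Drosophila* larval neuromuscular junction, synaptic vesicles (SVs)
redistribute within presynaptic boutons upon stimulation: vesicle-marker
staining (CSP) densifies near the bouton edge, where active zones sit, and
dye-loading assays (FM1-43) read out how much of the labelled pool is
released. `nmjquant` implements the image-quantification chain these
questions require:

1. **Bouton masks** from a membrane (HRP) channel; type-Ib boutons are kept
   by the size filter 2.5–12 µm² (inclusive bounds), and the size
   distribution itself is modelled by Gaussian mixtures scored with BIC.
2. **Particle detection** (vesicle marker): local intensity maxima inside the
   bouton mask, with a peripheral zone defined as the band within 200 nm of
   the bouton's outer edge and a central zone comprising the rest. Zone
   densities are particles/µm².
3. **Radial profiles**: the bouton is peeled into shells by successive
   8-connected morphological erosions; shells are grouped into equal-area
   bands (10% deciles, or quartiles) and a density is measured per band. The
   stimulated/unstimulated density ratio is the vesicle-mobilization readout.
4. **Intensity and FM1-43 metrics**: background-corrected ROI means over the
   bouton's maximum-area slice ± 2 flanking slices; the FM unload fraction is
   $1 - \mathrm{unload}/\mathrm{load}$ per bouton, averaged per preparation.
5. **Colocalization**: thresholded Manders coefficients M1/M2 between the
   vesicle channel and an endosome-marker channel, computed in 3D inside the
   bouton footprint replicated along Z.

Real acquisitions of this kind are not distributable at desk scale, so the
package pairs every measurement stage with a synthetic-scene generator that
plants known geometry, puncta, destaining fractions and channel overlap, and
validates the stages by parameter recovery.

# Conventions

* Indices are 1-based `(y, x, z)`; voxel arrays are dimensioned (Y, X, Z).
* A pixel's physical footprint is `pixel_size_xy`² (nm²); the area of a mask
  is its pixel count × `(pixel_size_xy/1000)²` µm². No sub-pixel bookkeeping
  anywhere: every partition in the package is pixel-exact by construction.
* Distances (e.g. the 200 nm peripheral cut) are measured from pixel center
  to the nearest exterior pixel center and scaled by the pixel size; at the
  STED calibration (27.5 nm/px) the band is ≈ 7.27 px deep.
* Calibration presets: `"sted"` = 27.5 nm XY / 0.1145 µm Z,
  `"confocal"` = 60 nm XY / 0.5 µm Z.
* Scene files are one grayscale TIFF per channel plus a YAML manifest; 8- and
  16-bit integer data round-trip bit-exactly. Rendered scenes default to
  16-bit quantization, which is also what integer-valued cameras deliver.

# Particle detection (local maxima)

A pixel is a particle candidate iff it is ≥ all 8 neighbours, ≥ the
detection threshold, and inside the mask. Runs of equal-valued candidates
(plateaus, common in quantized data) yield exactly one particle at the
plateau centroid, rounded with ties toward the top-left; a plateau counts
only if some neighbour outside it is strictly smaller, so constant images
contain no particles. Two further choices matter in practice:

* **Automatic threshold.** `min_intensity = "auto"` uses background mean +
  `auto_k` × background s.d., estimated outside all masks. With quantized
  noise, ties make the neighbourhood condition vacuous for isolated
  above-threshold pixels, so the expected number of pure-noise particles is
  ≈ `n_mask_pixels × P(Z > auto_k)` — not the `n/9` a continuous-noise
  argument suggests. For boutons of 10⁴–10⁵ pixels, `auto_k = 5` keeps that
  expectation below ~0.01 per bouton while detecting peaks at 10× the noise
  s.d. with essentially unit probability; `auto_k = 2` would admit on the
  order of one noise particle per 10⁴ mask pixels.
* **Non-maximum suppression.** Additive noise raises secondary maxima on the
  flank of a bright blurred spot (~2 px from the peak at the STED PSF, where
  the spot still carries ~40% of its peak). Among maxima closer than
  `min_separation_px` (default 3 px ≈ 82 nm at STED — at the optical
  resolution limit, so no resolvable pair is merged) only the strongest is
  kept. Setting `min_separation_px = 1` disables suppression.

Raising the threshold can only remove particles (suppressors never
disappear before the suppressed), so detection counts are monotone
non-increasing in `min_intensity`; this is tested as a property.

# Zones, shells and bands

`partition_zones()` uses the Euclidean distance transform of the footprint:
peripheral = pixels within `band_nm` of the exterior, central = rest. The two
zones partition the footprint pixel-exactly, and on rasterized disks the
peripheral area fraction matches the analytic annulus value
$1 - ((R - 200\,\mathrm{nm})/R)^2$ within the discretization error of two
pixel rows.

`erosion_shells()` erodes with the 3×3 full square (8-connectivity; fixed so
that an independent oracle can reproduce it — a 5×5 square yields shells of
16, 8 and 1 pixels). Shells are grouped **whole** into bands: each shell goes
to the band whose nominal cumulative-area interval contains the midpoint of
the shell's cumulative-area span. Splitting shells would invent sub-pixel
bookkeeping the erosion procedure does not define; the midpoint rule is the
declared tie-break for shells straddling a 10% boundary. Quartiles are
rebuilt from the shells at `n_bands = 4`, not by averaging deciles, so the
exact-partition invariant survives re-binning. Both particle-count and
intensity densities are offered; particle mode is the default.

## The mobilization estimator

Per bouton, `mobilization_ratio()` is the elementwise S/US ratio with
zero-denominator entries flagged undefined. At study level the package
estimates the ratio as (mean S density)/(mean US density) across pairs with
a delta-method standard error: at realistic planted densities a single
bouton carries only a handful of peripheral particles, and the mean of
per-pair ratios is biased upward by $E[1/Y]$ at such counts, whereas the
ratio of means is consistent. Per-pair ratios remain available.

# Intensity and FM1-43

The representative bouton intensity is the equal-weight mean of the ROI
means of the center (maximum-area) slice and its 2 flanking slices on each
side. The alternative reading of "adding" the flanking-slice intensities as
a 5-slice *sum* would scale with slice count and break comparability across
stacks of different depth; the mean convention is the package default with
`slice_agg = "sum"` as an escape hatch. Background is subtracted once per
measurement (`corrected = max(raw − bk, 0)`, the raw value retained), so
adding a constant to both image and background leaves results unchanged —
an exact invariant. Backgrounds come in three strategies: *remote* (5%
dimmest tiles outside all masks — a deterministic stand-in for a hand-chosen
empty region, overridable by an explicit ROI), *local* (ring 3–10 px outside
each bouton), and their *combined* mean, the FM default, which mirrors
averaging an image-remote background with the non-synaptic region lateral to
each bouton. Control normalization divides by the control group's mean
within each experiment, making the control mean exactly 1 per experiment and
idempotent under re-normalization.

The FM unload fraction is $1 - \mathrm{unload}/\mathrm{load}$ of the
background-corrected means on the maximum-area slice, clipped to [0, 1] with
the raw value kept, undefined when the corrected load is not positive; the
per-preparation (per-larva) summary is the unweighted mean over its boutons.

# Colocalization

Channels are segmented inside the footprint replicated along the whole Z
axis; Otsu thresholds are computed from within-mask intensities only (the
in-package Otsu exists precisely because frame-wise implementations cannot
restrict to a mask). M1/M2 follow the standard thresholded-Manders
convention: M1 = Σ vesicle intensity over doubly-positive voxels ÷ Σ vesicle
intensity over vesicle-positive voxels, M2 symmetric. This makes
identical channels give exactly (1, 1), disjoint signals (0, 0), and
`manders(A, B)$m1 == manders(B, A)$m2` exactly; each coefficient is invariant
to rescaling a channel together with its fixed threshold.

For *recovery* studies on sparse spots over near-zero background, Otsu is
ill-posed: with a tiny bright class it lands near half the spot peak, and a
2-D Gaussian spot holds only ~50% of its mass inside its half-max radius, so
M2 would be biased low at every overlap. The recovery analyses therefore use
fixed thresholds a few noise s.d. above zero (capturing >99% of each spot's
mass); Otsu remains the default for bimodal within-mask histograms, where it
is well posed.

# The synthetic generator: what it emulates, and what not

Footprints are star-shaped rasterized outlines (low-order Fourier radius
perturbations) placed without overlap; areas are drawn from the type-Ib
range 2.5–12 µm² by default and realized within 5% of target. The membrane
channel is a 2-px rim of the footprint — the minimal faithful structure for
an edge-labelling antibody; rims of neighbouring boutons stay ≥ 8 px apart
by default so the segmentation's 3-px closing cannot bridge them (a 2-px
minimum gap is always enforced). Puncta counts are Poisson with mean
density × zone area, positions uniform within the zone, a 2-px minimum
spacing enforced by thinning — and the *realized* counts are recorded as
truth, because recovery must be judged against what was actually planted.
Spots are normalized 2-D Gaussians (integral = amplitude; default PSF σ
40 nm), so the noiseless, background-free vesicle channel integrates exactly
to the summed amplitudes. Noise is additive Gaussian read noise (default
s.d. 5 at background 10) with optional Poisson shot noise; default scenes are
single-slice because the analyses run on maximum-intensity projections, with
a multi-slice mode (per-slice rim shrinkage) for center-slice logic.

Deliberately **not** emulated: drift, bleaching beyond the planted unload
fraction, spectral bleed-through, depth-dependent PSFs, structured muscle
background, and deconvolution artifacts. Passing recovery tests therefore
demonstrates correctness of the measurement chain under controlled imaging
statistics, not robustness to every pathology of real acquisitions; the
optional hand-drawn-ROI path exists for data where automatic segmentation is
not trustworthy.

Spot amplitudes and noise levels are configuration for testability, not
claims about real staining; defaults put default-amplitude spot peaks ~13
noise s.d. above background, and the detection study plants peaks at exactly
10 noise s.d.

# Study sizes and numerical choices

The recovery suites use sizes chosen to estimate each quantity to a few
percent: 100 random masks for partition exactness, 20 scenes × 50 planted
puncta for detection, 200 seeds for zone-density recovery (planted 2.0/0.5
puncta/µm², single boutons of 6–10 µm² at STED calibration), 200
unstimulated/stimulated pairs of 4 boutons each (confocal calibration) for
the mobilization ratio 1.8, 50 seeds per level of the FM unload ladder
{0, 0.3, 0.6, 0.9}, 20 seeds per level of the overlap ladder
{0, 0.25, 0.5, 0.75, 1}, and 50 samples of n = 500 for BIC selection.
Stochastic recoveries are held to 3 standard errors of the estimator (0.02
absolute for FM, 0.05 for Manders); algebraic identities (partitions, the
worked 5-slice example, Manders limit cases, byte-level pipeline
determinism) are held exactly. `scripts/acceptance.R` re-runs the same
measurements at reduced replicate counts and reports the recovered values.

Other numerical choices: mixture fits use EM (mclust's deterministic
hierarchical initialization; the `seed` argument is kept for interface
stability) with BIC $= -2\log L + (3k - 1)\log n$ and ties broken toward
smaller k; the derived type-Ib interval is the dominant component's mean ±
2 s.d. clipped to positive — a declared convention, since only the resulting
range is ever used. Degenerate inputs are flagged, not silently zeroed:
zero-area central zones report `NA` densities, zero denominators in ratios
are undefined, constant images segment to nothing with a warning, and
empty masks are validation errors.

# Known limitations

* Segmentation fills the thresholded rim, so segmented footprints run ~1 px
  outside the true membrane mid-line (a few percent of area for type-Ib
  boutons); Jaccard against truth is ≥ 0.9 at default noise, and the
  ROI-import path bypasses the issue entirely.
* Particle detection is pixel-resolution (no sub-pixel Gaussian fitting, by
  scope); positional accuracy is 1 px.
* The per-slice particle mode aggregates maxima by unique (y, x) and does
  not link detections across Z into 3-D objects.
* The BIC machinery assumes Gaussian components; heavy-tailed size
  distributions will inflate the selected k.
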