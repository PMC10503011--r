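# nmjquant

Quantification of synaptic-vesicle distribution in *Drosophila* larval
neuromuscular-junction (NMJ) boutons from multi-channel fluorescence
Z-stacks — for synapse biologists measuring activity-dependent vesicle
mobilization, dye-release, and endosomal colocalization phenotypes, and for
methodologists who need every stage of such a pipeline testable against
ground truth.

## What it measures

Given a membrane (HRP) channel and marker channels with physical calibration
(XY pixel size in nm, Z step in µm), the package computes, per bouton *b*
with footprint mask *M<sub>b</sub>*:

* **Segmentation and size.** Boutons are filled regions enclosed by the
  thresholded membrane rim; area = |M<sub>b</sub>| · (pixel size)². Type-Ib
  boutons are selected by the inclusive size filter 2.5 ≤ A ≤ 12 µm², and
  the size distribution is fitted with Gaussian mixtures, k chosen by
  BIC = −2 log L + (3k−1) log n.
* **CSP particles and zone densities** ("Program A"). Particles are local
  intensity maxima (8-neighborhood, deterministic plateau rule,
  non-maximum suppression at the resolution scale). The *peripheral zone* is
  the band within 200 nm of the bouton's outer edge (Euclidean distance
  transform); the *central zone* is the remainder. Densities are
  particles/µm² per zone.
* **Radial profiles and mobilization** ("Program B"). Successive 8-connected
  morphological erosions peel the bouton into shells; whole shells are
  grouped into 10 equal-area bands (or quartiles) from periphery (0–10%) to
  center, giving a density per band. Vesicle mobilization is the ratio of
  stimulated to unstimulated densities, per zone or band:
  ratio = ρ<sub>S</sub>/ρ<sub>US</sub>.
* **Intensity and FM1-43.** Background-corrected mean intensity over the
  maximum-area slice ± 2 flanks (equal-weight mean), normalized to a control
  group per experiment; FM unload fraction = 1 − unload/load of the
  corrected bouton means, averaged per preparation.
* **Colocalization.** Thresholded Manders coefficients inside the
  Z-replicated bouton mask:
  M1 = Σ<sub>both+</sub> I<sub>CSP</sub> / Σ<sub>CSP+</sub> I<sub>CSP</sub>,
  M2 symmetric for the endosome (Rab) channel.

A synthetic-scene generator (`make_bouton_geometry()`, `make_puncta_scene()`,
`make_paired_scenes()`, `make_fm_pair()`, `make_coloc_scene()`) plants known
footprints, puncta, destaining fractions and channel overlap, so every stage
is validated by parameter recovery; scenes round-trip losslessly through
single-channel TIFFs plus a YAML manifest.

## Worked example

```r
library(nmjquant)

# a synthetic STED scene: 2 boutons, planted densities 2.0 (peripheral)
# and 0.5 (central) puncta/um^2
sc <- make_puncta_scene(n_boutons = 2, peripheral_density = 2,
                        central_density = 0.5, seed = 8)

masks <- filter_by_area(segment_boutons(sc$scene))$kept
for (m in masks) {
  ps <- detect_local_maxima(sc$scene, m, background_exclude = masks)
  zd <- zone_density(ps, partition_zones(m))
  cat(sprintf(
    "bouton %d: area %.2f um^2, %d particles, peripheral %.2f /um^2, central %.2f /um^2\n",
    m$label, m$area_um2, ps$n_total, zd$peripheral_density,
    zd$central_density))
}
#> bouton 1: area 9.00 um^2, 8 particles, peripheral 1.49 /um^2, central 0.72 /um^2
#> bouton 2: area 7.26 um^2, 7 particles, peripheral 2.22 /um^2, central 0.55 /um^2
```

Each bouton's area passes the type-Ib filter; the detected particle counts
split into the 200 nm peripheral band and the center, giving per-zone
densities. Single boutons carry only a handful of particles, so individual
densities scatter around the planted 2.0/0.5 — the recovery analyses average
hundreds of scenes.

```r
pair <- make_fm_pair(0.6, load_mean = 1000, noise = list(gaussian_sd = 0), seed = 1)
masks <- lapply(seq_along(pair$truth$boutons), function(i)
  structure(list(footprint = pair$truth$boutons[[i]]$footprint, label = i),
            class = "bouton_mask"))
res <- fm_metrics(pair$load, pair$unload, masks)
res$summary$mean_unload_fraction
#> [1] 0.6
```

A noiseless load of 1000 and unload of 400 (after combined background
subtraction) give an unload fraction of exactly 0.600.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated scenes
written to `results/`:

```sh
Rscript analysis/01_simulate_scenes.R    # scenes + ground truth to results/scenes/
Rscript analysis/02_segment_and_size.R   # segmentation vs truth; BIC size model
Rscript analysis/03_zone_densities.R     # Program A zone densities
Rscript analysis/04_radial_profiles.R    # Program B profiles + mobilization ratio
Rscript analysis/05_fm_dye.R             # FM1-43 load/unload metrics
Rscript analysis/06_colocalization.R     # Manders M1/M2 overlap ladder
```

`run_pipeline(run_config(...))` runs the scene→segment→measure chain in one
call with a strict config and byte-deterministic CSV outputs.

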