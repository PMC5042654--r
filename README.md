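# hsmad

Adaptive detection and quantification of plasmonic nanoparticles in
hyperspectral dark-field microscopy images of histological tissue sections.

## The problem

Metallic nanoparticles (gold nanorods, nanoshells, silica-coated
nanospheres) are widely used as imaging probes and therapeutic carriers, and
their organ- and cell-level biodistribution must be characterised after
administration. Hyperspectral dark-field microscopy records a full scattering
spectrum at every pixel of a tissue section, so plasmonic particles — which
scatter strongly at a characteristic resonance wavelength (e.g. a narrow
~900 nm peak for large gold nanorods in mounting medium) — can in principle
be detected down to single particles without any label. In practice the
particle spectrum mixes with spatially diverse tissue and stain scattering,
illumination varies across the field, and chromatic aberrations at tissue
edges mimic red-shifted particle spectra. `hsmad` implements an adaptive
workflow that handles all of these effects and turns a hyperspectral cube
into per-pixel particle calls and per-organ uptake statistics.

## The method

For each field of view (H x W pixels, B = 361 bands over 400–1000 nm):

1. **Vignetting correction** — every intensity is divided by
   cos⁴(tan⁻¹(R/d)), R the physical distance from the image centre computed
   from the pixel pitch (410 x 408 nm at 40x) and d = 2 mm.
2. **Adaptive segmentation** — the histogram of per-pixel mean intensities
   (510 bins, re-interpolated every 5 intensity units) is scanned for its
   first minimum after the background peak (times α, default 1.05) and the
   dominant tissue mode (times β, default 1.5), yielding thresholds that
   split pixels into *background*, *tissue* and *candidate* classes.
3. **Spectral preprocessing** — candidate spectra are truncated below
   566 nm, Savitzky–Golay smoothed (window 11, order 3) and max-normalized.
4. **Library training** — k-means (default k = 4) on candidate pixels of
   training images learns a spectral cluster library; the nanoparticle
   cluster is auto-selected as the centroid peaking inside the plasmon band
   (833–988 nm). A fifth, chromatic-aberration cluster is added by averaging
   falsely detected pixels from particle-free control images.
5. **Classification** — each candidate pixel is assigned to the nearest
   library centroid (Euclidean distance); NP+ iff it lands on the
   nanoparticle centroid. A Spectral Angle Mapper baseline
   (`classify_sam()`) is included for comparison.
6. **Quantification** — the relative NP signal of a field of view is
   `sum(s over NP+ pixels) / N_tissue / median(s over NP+ pixels)` with
   `s` the 833–988 nm band mean; per-ROI uptake uses the simpler pixel
   coverage (NP+ / non-background counts). Diagnostics report sensitivity
   and specificity with log-method confidence intervals, and a
   point-spread-function check (σ = 0.21 λ / NA ≈ 0.25 µm at 910 nm,
   NA 0.75) tests whether an isolated NP+ pixel is consistent with a single
   particle.

A fully synthetic phantom generator (`generate_phantom()`) emulates stained
tissue, sub-pixel particles convolved with the instrument PSF, hybridized
aggregate spectra, edge artifacts, vignetting and sensor noise, with ground
truth masks — so the whole pipeline is testable without microscope data.

## Worked example

```r
library(hsmad)

bm <- phantom_benchmark(train_seeds = 1:3, test_seed = 4, control_seeds = 5,
                        size = 256L, k = 4L)
round(c(sensitivity = bm$sensitivity, specificity = bm$specificity,
        edge_fp_disabled = bm$edge_fp_disabled,
        edge_fp_enabled = bm$edge_fp_enabled), 4)
#>      sensitivity      specificity edge_fp_disabled  edge_fp_enabled
#>           1.0000           0.9971           1.0000           0.0000
round(100 * bm$relative_signal, 2)  # relative NP signal, % of tissue pixels
#> [1] 1.49
```

Here the library was trained on three synthetic tissue scenes, the
chromatic-aberration cluster was learned from a particle-free control, and a
held-out scene was classified: every planted single particle was recovered
(sensitivity 1.0), 99.7% of true tissue/edge pixels were called negative,
and enabling the aberration cluster removed all edge-artifact false
positives that the plain library produced. The relative NP signal (~1.5%)
is the scale-invariant uptake statistic reported per organ section.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/hsmad.R simulate --preset lgnr --seed 3 --size 128 --out sim/
Rscript inst/cli/hsmad.R pipeline --config config.json --out run/
```

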