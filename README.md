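# angioqa

Quantitative quality assessment of time-of-flight MR angiography (TOF-MRA)
and cross-modality comparison against reference angiograms such as digital
subtraction angiography (DSA).

Ultra-high-field (7-T) TOF-MRA can resolve intracranial vessels — down to
lenticulostriate and thalamic perforating arteries — that clinical 3-T
protocols barely depict. Deciding whether a higher-resolution protocol is
actually *better* requires numbers, not impressions: signal-to-noise and
contrast-to-noise ratios measured the same way on every acquisition,
reader-score aggregation, an objective count of detected vessel borders, and
a similarity index against the angiographic reference standard. `angioqa`
implements that analysis pipeline for neuroimaging physicists and
image-analysis researchers, together with a digital vascular phantom so
every stage is testable without clinical data.

## The quantities at the core

* **Difference-method SNR.** From two back-to-back acquisitions A and B of
  the same protocol (identical except for noise), for each vessel ROI:

  `SNR = (1/sqrt(2)) * mean_ROI((A + B)/2) / sd_ROI(A - B)`

  For a homogeneous ROI of signal S and per-acquisition noise sigma this
  converges to `S / (2 sigma)`; the conventional NEMA prefactor
  (`sqrt(2)` instead of `1/sqrt(2)`, converging to `S / sigma`) is available
  via `convention = "nema"`.

* **Paired-ROI CNR.** Each vessel ROI is paired with an adjacent parenchymal
  ROI of identical voxel count:

  `CNR = (mean_vessel - mean_parenchyma) / sqrt(sd_vessel^2 + sd_parenchyma^2)`

* **Rigid registration.** Repeat acquisitions and lower-resolution datasets
  are aligned by a multiscale 6-degrees-of-freedom rigid registration
  maximizing mutual information (32-bin joint histogram, partial-volume
  weighting); ROI labels propagate by nearest-neighbour resampling so no
  interpolated label values are invented.

* **Canny edge-pixel counts.** Angiogram quality quantified as the number of
  vessel-border pixels a full Canny detector (Gaussian smoothing, Sobel
  gradients, non-maximum suppression, double-threshold hysteresis) finds on
  maximum intensity projections.

* **CW-SSI.** The complex-wavelet structural similarity index between an MRA
  MIP and a DSA(-like) image, both Otsu-segmented first:

  `CW-SSI = (2 |sum(c_x * conj(c_y))| + K) / (sum|c_x|^2 + sum|c_y|^2 + K)`

  per wavelet sub-band, pooled over scales and orientations. Because a small
  rigid shift only rotates coefficient phases coherently, the index
  tolerates the residual misalignments that pixelwise comparison cannot.
  The complex wavelet transform is an exactly invertible FFT-domain complex
  steerable pyramid implemented in the package.

* **Score tables and detection rates.** Aggregation of 0-4 vessel-visibility
  reader scores (per vessel category, volunteer and field strength), exact
  paired Wilcoxon signed-rank tests, and detection-rate percentages.

## Worked example

```r
library(angioqa)

# a vascular phantom: curved branching tubes, calibers 4 mm down to 0.25 mm
tree <- build_vessel_tree(seed = 1, extent = c(14, 14, 14))
spec <- phantom_spec(grid_shape = c(96, 96, 64),
                     voxel_size = c(0.2, 0.2, 0.3))   # finest 7-T regime
clean <- rasterize(tree, spec)

# a repeat-acquisition pair and the difference-method SNR in one ROI
pair <- make_pair(clean, sigma = 10, seed_a = 1, seed_b = 2)
rois <- default_roi_set(tree, clean)
snr_difference(pair, roi_voxels(rois, 1), roi_label = "roi_01")
#> <snr_result> acq/roi_01: SNR = 15.41 (mean 300.1, sigma_diff 13.77, paper convention)

cnr(pair$volume_a, roi_voxels(rois, 1), roi_voxels(rois, 101))
#> <cnr_result> acq/roi: CNR = 16.63 (vessel 300.2±10.1, parenchyma 60.42±10.2)

# cross-modality similarity against a DSA-like rendering of the same anatomy
mra <- mip(pair$volume_a, "axial")
dsa <- project_dsa_like(pair$volume_a, "axial", rotation_deg = 2,
                        blur_sigma_px = 1, intensity_gamma = 1.5,
                        noise_sigma = 0.01, seed = 3)
compare_modality(mra, dsa)
#> <similarity_result> CW-SSI = 0.9687 over 18 sub-bands (windowed_mean)
```

The trunk ROI's SNR of 15.4 is the printed-formula value `S/(2*sigma)` for
its mean signal of 300 at noise 10, with the extra `sigma_diff` telling you
how much independent noise the A-B difference actually carried; the CNR of
16.6 reflects the phantom's clean vessel/parenchyma contrast at this noise
level (240 contrast over `sqrt(2)*10` pooled noise); and a CW-SSI near 0.97
despite the rotation, blur and gamma mismatch is precisely the
small-misalignment tolerance the complex-wavelet index is chosen for
(mismatched anatomy scores below ~0.3).

The end-to-end study is one call: `run_protocol_comparison()` simulates the
three 7-T resolution regimes plus a clinical 3-T reference, computes SNR/CNR
for 17 paired ROIs per regime, runs paired Wilcoxon tests between all regime
couples, counts MIP edge pixels, and writes CSV/JSON reports with full
provenance. `run_similarity_comparison()` does the same for the
MIP-versus-DSA similarity sweep. A thin command-line front-end is installed
at `inst/cli/angioqa`.

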