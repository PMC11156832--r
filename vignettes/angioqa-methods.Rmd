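---
title: "Methods behind angioqa: phantom, estimators, registration and the similarity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind angioqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(angioqa)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the synthetic phantom does and does not emulate, and where the numerically
delicate points are.

## The digital vascular phantom

Every quantitative claim the package makes is exercised on a synthetic
phantom, because clinical 7-T TOF-MRA / DSA image pairs are not freely
available. The phantom emulates the *statistical structure* the analyses
assume:

* **Geometry.** `build_vessel_tree()` grows a connected tree of tubes with
  hemispherical caps. Radii halve per branching generation, from a 2 mm
  trunk radius down to sub-0.15 mm perforator-like twigs, spanning the four
  caliber classes (large ≥ 1.4 mm radius, medium 0.7–1.4, small 0.3–0.7,
  perforator < 0.3). Branches are polylines with gentle kinks rather than
  straight rods: a straight trunk makes rotation about its axis nearly
  unidentifiable, which would turn registration validation into a lottery.
  All geometry is generated in world millimetres, independent of any voxel
  grid.
* **Rasterization.** `rasterize()` is exact up to partial volume: voxels
  whose centres are deeper than half a voxel diagonal inside a tube receive
  `vessel_intensity`, far voxels receive `background_intensity`, and
  boundary voxels get the in-tube volume fraction estimated from an
  8×8×8 subdivision of the voxel. The default intensities (300 vessel, 60
  background) and noise (sigma 10) put CNR values in the single digits,
  the range reported for in vivo TOF-MRA; they are configuration, not
  claims about any scanner.
* **Noise.** Additive, i.i.d., zero-mean Gaussian. Real magnitude MR noise
  is Rician; Gaussian is chosen deliberately because the difference-method
  SNR algebra (below) then has a closed form that tests can verify to
  within Monte-Carlo error. At the SNR levels in play (≥ 5) the
  Gaussian/Rician distinction is small, but it is a stated limitation:
  passing tests show estimator correctness, not Rician-bias behaviour at
  very low SNR.
* **Repeat acquisitions.** `make_pair()` produces the (A, B) couple the
  difference method requires: same object, independent noise seeds, and
  optionally a small rigid misalignment of B. Inter-acquisition motion can
  be emulated two ways: resampling the clean volume (spec-faithful, but
  linear interpolation visibly smooths 1–2-voxel vessels), or rasterizing a
  rigidly transformed tree via `transform_tree()`, which emulates re-scanning
  a moved subject exactly. Registration validation uses the second form; see
  below for why.
* **DSA stand-in.** `project_dsa_like()` renders a maximum intensity
  projection, then rotates, blurs, renormalizes, adds mild noise and
  gamma-remaps it — a "same vessels, different modality rendering" partner.
  It does not model projective X-ray geometry, contrast dynamics or
  subtraction artifacts; the similarity analysis therefore tests geometric
  and tonal robustness, not radiographic physics.

What the phantom does *not* emulate: flow-related signal, slab-boundary
artifacts, field-dependent background suppression (the 3-T regime in the
default protocol comparison simply gets a brighter background, a one-knob
stand-in for weaker suppression at lower field), coil sensitivity profiles,
and anatomy beyond branching tubes.

## SNR and CNR estimators

For each ROI j the difference-method SNR is implemented exactly as the
printed estimator:

$$\mathrm{SNR}_j = \frac{1}{\sqrt 2}\,
  \frac{\mathrm{mean}_j\!\big((A+B)/2\big)}{\mathrm{sd}_j(A-B)},$$

which for a homogeneous ROI converges to \(S/(2\sigma)\). Note this is half
the conventional difference-method value \(\sqrt2\,\mathrm{mean}/\mathrm{sd}\);
the `convention = "nema"` flag switches to the conventional form. The
ambiguous "mean of (A, B)" numerator is read as the ROI mean of the
voxelwise average — the standard difference-method numerator.

CNR uses the A acquisition only, with a parenchymal partner ROI of
*identical voxel count* adjacent to each vessel ROI:

$$\mathrm{CNR}_j = \frac{\bar v_j - \bar p_j}
  {\sqrt{s_{v,j}^2 + s_{p,j}^2}}.$$

All standard deviations are sample (n−1) throughout, so the closed-form
recovery tests are exact in expectation. Degenerate inputs (zero sd) raise
errors, never infinities. ROI geometry defaults to spheres of diameter
0.8× the local vessel diameter, floored at about one voxel so ROI standard
deviations stay defined on coarse grids; partners are integer-voxel
translated copies, which guarantees the equal-size invariant exactly.

Summary statistics follow box-plot conventions (median, quartiles, 5th/95th
percentiles) with linear interpolation between closest ranks (type-7
quantiles), and paired comparisons use an exact Wilcoxon signed-rank test:
zero differences dropped, ties mid-ranked, the null distribution computed by
dynamic programming over doubled midranks for n ≤ 25 (the 17-ROI design
falls well inside), and a tie-corrected normal approximation with continuity
correction above.

## Rigid registration

The registration contract is *recovery*: a rigid misalignment of up to 5 mm
and 5° must be estimated to within 0.25 voxel and 0.5°. The final stage
maximizes mutual information on the raw volumes — 32-bin joint histogram
with linear partial-volume weighting of the interpolated moving samples —
so the reported metric is MI, as is conventional for multi-protocol MR
alignment. Getting reliably *into* that optimum's basin on a sparse
thin-vessel image is the hard part, and three implementation choices carry
it:

1. **Scale-space capture on correlation.** Plain MI pyramids (block-mean
   ×4/×2 levels) are multimodal for a sparse tree: decimation aliasing and
   branch self-similarity create false optima several degrees away. The
   capture and refine stages therefore run on Gaussian-blurred (1.5 and
   0.7 voxel), block-averaged copies and maximize intensity correlation,
   whose basin is wide and smooth for same-modality inputs; translation is
   initialized from intensity centroids and rotation from a deterministic
   ±6° grid scan.
2. **Foreground-prioritized metric sampling.** The metric is evaluated on
   all vessel/boundary voxels plus a sparse uniform background sample
   (≤ 40 000 samples). Uniform stride subsampling makes the metric ripple
   as the sampled subset shifts with pose — enough to stall any local
   optimizer 1–2.5° from the truth.
3. **Line searches plus simplex.** Each stage combines cyclic Brent line
   searches with shrinking brackets (robust on long monotone slopes, where
   a simplex collapses prematurely) and a Nelder–Mead polish for parameter
   coupling; the final narrow-bracket pass doubles as the convergence check,
   and a pose that still moves flags the result as non-converged rather
   than failing silently.

Validation geometry matters as much as the optimizer. The moved acquisition
is *rasterized from the transformed tree*, not interpolated from the fixed
volume: linear resampling smooths 1–2-voxel vessels so strongly that the
metric optimum genuinely moves off the nominal ground truth (the
back-resampled volume correlates only ~0.66 with the original), a bias no
optimizer can undo. And the tree sits well inside the field of view, as a
head does in practice — with a FOV-filling object, ±5 mm motions clip
content differently in the two images and displace the optimum by degrees.

Image values are only ever interpolated linearly *inside* the registration;
final label and value resampling (`resample_nn()`, `propagate_rois()`) is
nearest-neighbour, so label volumes never acquire interpolated values. ROI
propagation onto a much coarser grid can legitimately extinguish a sub-voxel
ROI; that raises an error naming the label rather than silently dropping it.

## Edge-pixel quantification

`canny()` implements the full detector: Gaussian smoothing (default 1.4 px),
Sobel gradients, non-maximum suppression, and 8-connected double-threshold
hysteresis with thresholds expressed as fractions of the maximum gradient
magnitude (defaults 0.1/0.2), making edge maps invariant to positive
intensity rescaling. Suppression compares each pixel against bilinearly
interpolated magnitudes one unit step along the exact gradient direction;
the nearest-of-8 quantized variant is available behind the `nms` flag but
leaves double ridges where a curved border crosses a direction-sector
boundary, violating the 1-px-ridge property. On a 200×200 disk of radius
50 px the edge count lands within 15% of the brute-force digital perimeter
(disk pixels with any 8-neighbour outside — the discrete border a ridge
traces). The parameters used are recorded in every edge map for provenance.

## The complex-wavelet similarity index

Both printed forms of the per-band index are implemented and
cross-validated; since \(|c_x \bar c_y| = |c_x||c_y|\) pointwise, the
factored form (magnitude-agreement term × phase-consistency term) is
algebraically identical to the direct quotient, and the tests verify the
two agree to 1e-12.

The transform is an FFT-domain complex steerable pyramid: raised-cosine
radial filters split octave bands, \(\cos^{K-1}\) angular filters split
orientations over half-planes (hence complex, analytic coefficients), and
each band is decimated by cropping its spectrum — which is exact here
because each band is strictly bandlimited to the cropped region. The filters
tile the frequency plane as a tight frame, so reconstruction is exact to
machine precision and coefficient energy equals image energy; both are
tested. Defaults: 4 levels × 6 orientations.

Pooling and the stabilizer K required two decisions the index's definition
leaves open:

* **K is a numerical guard, not a tuning knob.** `K = "auto"` uses
  1e-8 × (coefficients summed). A larger K (e.g. proportional to band size
  on [0,1] images) dominates the small energies of coarse bands and pulls
  their scores toward K/K = 1, inflating the similarity of *unrelated*
  images — independent-noise pairs scored 0.72 under such a K, versus
  0.04–0.06 with the guard value. K only matters where band energy vanishes,
  where 1 (two empty bands agree) is the right limit.
* **Energy-weighted windowed pooling over scales ≥ 2.** Finest-scale
  coefficient envelopes decorrelate after a 1–2 px shift, and a rotation's
  spatially varying displacement breaks a global phase sum, so a global
  all-scales mean is *not* shift/rotation tolerant (0.82 at 2 px, 0.48 at
  3°). The default instead scores sliding 7×7 windows per band — unwrapping
  the phase locally — and pools windows weighted by their energy, so the
  mostly-empty background of an angiogram neither dilutes nor inflates the
  score; scale 1 is excluded. Global pooling and `min_scale = 1` remain
  available in the configuration.

Measured contracts with the default configuration on 256×256 phantom MIPs
(fixed at release): similarity ≥ 0.9 for shifts of 1–3 px (0.95–0.96 at
2 px), ≥ 0.85 for a 3° rotation (≈ 0.89), identically 1 for identical
images, and an independent-noise null whose 95th percentile is 0.38 (tests
use 0.45 as the ceiling). Same-anatomy MRA/DSA-like pairs score ≈ 0.9
versus ≈ 0.28 for different anatomy and ≈ 0.17 for mirrored anatomy.

`compare_modality()` fixes the preprocessing order: percentile-clip (1st to
99th) each image to [0,1], bilinearly resample the larger onto the smaller
grid *before* binarization (nearest-neighbour afterwards would destroy thin
vessels), Otsu-binarize both (the default; grayscale mode exists for
sensitivity analysis), then the pyramid comparison. Every step is appended
to the result's `preprocessing_log`.

Otsu's threshold maximizes between-class variance over a 256-bin histogram,
ties broken toward the lower threshold; the exhaustive scan is the test
oracle and an independent implementation (EBImage) is cross-checked within
histogram-bin resolution.

## The protocol-comparison study design

`run_protocol_comparison()` mirrors a resolution-ladder experiment: three
7-T regimes (0.2×0.2×0.5, ×0.4, ×0.3 mm³) whose noise grows inversely with
voxel volume — finer sampling costs SNR — plus a clinical 3-T reference
(0.4×0.4×0.5 mm³). The 3-T regime's noise is matched to the finest 7-T
regime, encoding the design premise that resolution is increased until SNR
parity with the clinical protocol; its background intensity is raised
(120 versus 60), a deliberate one-parameter stand-in for the weaker
background suppression at lower field, which costs vessel–parenchyma
contrast. Under these defaults the report reproduces the qualitative
pattern such studies show: mean SNR decreasing monotonically along the 7-T
ladder to approximate parity with 3 T, CNR significantly higher at 7 T
(paired Wilcoxon p < 0.001), and more vessel-border pixels on the
fine-voxel MIPs. Directions, not numeric values, are the claim; the
absolute numbers are properties of the phantom configuration.

Problem sizes follow the same philosophy: 17 paired ROIs (the standard
configuration here), 96³-voxel finest grids for the protocol study, 60³ for
registration validation, 256² projections for the similarity analyses —
large enough for the estimators' asymptotics to show, small enough to run
in minutes on one CPU.

All randomness derives from one global seed via a fixed rule
(`stage_seed(global, stage, item) = global·10⁴ + stage·100 + item`), so any
reported number is regenerable from its provenance block, and reruns of a
report are byte-identical.

## Known limitations

* Gaussian (not Rician) noise; no flow, slab, or coil physics.
* The DSA stand-in is a perturbed projection of the same volume, not a
  projective radiograph; CW-SSI values against it characterize the index,
  not clinical MRA/DSA agreement.
* Registration is rigid only, and its robustness statements hold for
  head-like geometry (object inside the FOV, motions ≤ 5 mm / 5°).
* Reader scores are input data; the package aggregates them but models no
  reader behaviour.
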