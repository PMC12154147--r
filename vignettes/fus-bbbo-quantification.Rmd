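---
title: "Quantifying focused-ultrasound blood-brain barrier opening: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focused-ultrasound blood-brain barrier opening: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusbbbo)
```

Focused ultrasound (FUS) applied through the skull together with circulating
microbubbles opens the blood-brain barrier (BBB) locally and transiently.
Studies of this effect combine four very different measurements: acoustic
emissions recorded during sonication, contrast-enhanced MRI of the opened
region, confocal microscopy of vessels, tracer leakage and endothelial tight
junctions (TJs), and transcriptomics of the affected endothelial cells. This
package implements the quantification step of each modality as tested,
reusable functions, and pairs every pipeline with a synthetic-data generator
whose ground truth is exact, so the pipelines can be validated end to end
without animal data. This vignette explains the models, the tunable
parameters, the numerical choices, and what the validation does and does not
establish.

## Cavitation dose decomposition

During sonication, microbubbles oscillating stably re-emit energy at
harmonics of the driving frequency (n·f~c~) and, closer to their stability
limit, at ultraharmonics ((n/2)·f~c~ for odd n). Violent inertial collapse
instead produces broadband noise. A passive cavitation detector (PCD)
records one trace per transmitted pulse; the decomposition works entirely on
the magnitude of its discrete Fourier transform.

For each pulse the pipeline:

1. computes the one-sided energy-spectral-density amplitude
   |FFT(x)|/f~s~ (`compute_spectrum()`); the analysis bandpass
   (3–9 MHz by default) is a mask on this spectrum, not a time-domain
   filter — doses are defined on the spectral density;
2. finds the peak amplitude in a 20 kHz window (±10 kHz) centred on every
   in-band tonal frequency (`locate_tonal_peaks()`). With f~c~ = 1.5 MHz and
   the 3–9 MHz band, the in-band tones are harmonics {3, 4.5, 6, 7.5, 9} MHz
   and ultraharmonics {3.75, 5.25, 6.75} MHz; the 1.5 MHz fundamental and the
   2.25 MHz ultraharmonic fall below the band and are excluded (and
   reported), because the bandpass is applied first;
3. computes the stable harmonic dose SCDh as the RMS spectral amplitude over
   the union of harmonic windows, the ultraharmonic dose SCDu over the
   ultraharmonic windows, and the inertial dose ICD over every in-band bin
   not claimed by a tonal window — "any energy not contributing to the
   stable doses" (`compute_pulse_dose()`). Windows are disjoint by
   construction (harmonics take precedence on overlap), so the squared
   amplitudes of the three regions sum exactly to the in-band total; the
   test suite holds this partition to 10^-9^ relative error;
4. sums the per-pulse doses over the sonication and divides by the baseline
   per-pulse mean times the pulse count (`accumulate_doses()`). The baseline
   is recorded before microbubble injection, so a sonication without bubbles
   normalizes to ≈ 1 in every component. The amplitude sum is the primary
   cumulative measure; the squared-amplitude (energy) sums are reported
   alongside, since either convention appears in practice.

One dose per pulse is the natural time resolution at a 10 Hz pulse
repetition frequency; the cumulative dose is the discrete integral of that
per-pulse series. No window function is applied before the DFT by default
(a Hann option exists to probe the sensitivity); with the default pulse
lengths every tonal frequency completes an integer number of cycles per
pulse, so a rectangular window causes no leakage in the synthetic setting.

The synthetic sonication (`gen_pcd_sonication()`) mirrors a murine protocol:
1.5 MHz centre frequency, 10 Hz PRF, 120 s duration (1200 pulses), 50 MHz
sampling, preceded by 10 noise-only baseline pulses. Emission amplitudes are
free parameters — microbubble emission spectra are not calibrated in
absolute units — and the defaults (harmonic amplitude 1, ultraharmonic 0.5,
broadband noise sd 0.02 per sample) put tones two to three orders of
magnitude above the broadband floor, as seen with stable cavitation.
Validation uses 1 ms pulses rather than the protocol's 10 ms: the dose
definitions are per-spectrum and scale predictably with pulse length, while
FFT sizes stay small (the 50 MHz rate is kept, so all band arithmetic is
unchanged). A harmonic-only sonication yields baseline-normalized SCDh two
to three orders of magnitude above 1 with SCDu and ICD within sampling
noise of 1, and raising the broadband level strictly raises ICD — the
discriminations the dose decomposition exists to make.

## MRI opening volume

Gadolinium crossing the opened BBB enhances T1-weighted images. The opening
volume is quantified exactly as in small-animal practice: a threshold equal
to the mean plus two standard deviations of a contralateral
(untreated-hemisphere) reference ROI (`compute_threshold()`), a binary mask
of supra-threshold voxels inside the brain mask and a 15-slice analysis
range (`segment_enhancement()`), and per-slice mask areas summed across
slices (`opening_volume()`). Two conventions are reported: the summed area
(mm²) and the volume (mm³, summed area × 0.4 mm slice spacing) — published
"volumes" do not always state whether slice thickness was included, so both
are emitted. The standard deviation uses the population (n) denominator by
default; a flag switches to n−1, a difference that is negligible at the ROI
sizes used. The threshold comparison is strictly greater-than: mean + 2 sd
is read as a lower bound of "enhancing". Skull stripping is out of scope —
the pipeline requires a brain mask, and the shipped convex-hull fallback
(`brain_mask_naive()`) is explicitly not equivalent to manual segmentation.

The phantom (`gen_mri_volume()`) is Gaussian background noise plus an
ellipsoidal lesion of additive contrast on a 96 × 96 × 15 grid of
0.1 × 0.1 × 0.4 mm voxels, with an elliptical "brain" mask and a mirrored
contralateral reference box. Defaults (contrast 50, noise sd 5) give a
contrast-to-noise ratio of 10. Ground truth is the exact voxel count inside
the ellipsoid times the voxel volume; for the default lesion
(radii 1.5 × 1.5 × 2.0 mm) this agrees with the analytic ellipsoid volume
to better than 1%, while much smaller lesions are dominated by the 0.4 mm
slice discretization — a property of the voxel grid, not of the estimator.

A mean + 2 sd threshold leaves, by construction, ≈ 2.28% of *background*
voxels above threshold. On a real image a rater analyzes a manually
skull-stripped, focal region and the spatially correlated noise does not
produce isolated hot voxels the way white Gaussian noise does; on the
phantom, that false-positive floor is real signal for the estimator and
inflates the volume by 2.28% of the brain-minus-lesion volume. The
module therefore exposes an optional per-slice minimum-component-size
filter (off by default, matching the published procedure, which applies no
connectivity filtering). The recovery benchmark runs with
`min_component_size = 3`, which removes uncorrelated one- and two-voxel
speckle and nothing else; with it, the estimated volume lands within ±5% of
truth at CNR 10 across seeds. The false-positive control — zero-contrast
phantoms must yield masks covering no more than the Gaussian-tail 2.5% of
brain voxels — is deliberately checked *without* the filter, at the
published defaults.

## Vessel, leakage and tight-junction morphometry

The confocal generator (`gen_vessel_image()`) renders a 2-D field (the
maximum-intensity projection of a thin stack) with three channels in a
documented order: a pan-endothelial vessel marker (GLUT-1), a leakage
tracer that forms halos only around leaky vessels, and a junction reporter
drawn as strands along the two long edges of each vessel — where junctional
eGFP appears in projections — with programmable gaps. Tubes use an
anti-aliased profile with a 1 px Gaussian edge, which makes the full width
at half maximum equal the nominal diameter to sub-pixel accuracy and hence
makes "diameter" well defined on the rendered image. The default pixel size
is 0.2 µm/px; gaps shorter than 2 px are rendered but flagged as
unresolvable in the output metadata.

Quantification follows the field's conventions:

* **Vessel segmentation and diameter** (`segment_vessels()`): foreground at
  mean + 2 sd of a background ROI, connected components, centreline by
  Zhang–Suen thinning (implemented in the package; no installed library
  provides 2-D skeletonization), local radius from the Euclidean distance
  transform sampled along the centreline, diameter = 2 × median radius ×
  pixel size. Because the detection threshold sits near the noise floor —
  far below a tube's half-maximum — a mask cut there is systematically wider
  than the FWHM diameter. Each component is therefore re-cut at half its
  robust (99th percentile) peak intensity before the radius measurement, so
  the reported diameter is an FWHM measure independent of the detection
  threshold. Calibration on noiseless tubes across sub-pixel offsets and
  orientations shows the estimator is then exact; with default noise the
  mean absolute error stays near half a pixel over 4–20 µm tubes.
* **Caliber** (`classify_caliber()`): small below 10 µm, large above; the
  published classes ("<10", ">10") leave 10 µm unassigned, and this package
  assigns the boundary to "large".
* **Leakage** (`leakage_mask()`, `detect_leaky_vessels()`): the tracer
  threshold is a required explicit configuration value — the original value
  is not published and refusing to guess a silent constant is the safer
  contract; synthetic analyses use half the halo amplitude. A vessel is
  leaky when its 1 px-dilated mask overlaps the leakage mask by at least
  `min_overlap` pixels (default 5, guarding against single-pixel noise);
  per-vessel leakage area and summed tracer intensity are measured in a
  square ROI centred on the vessel (half-width configurable, default 20 µm;
  the original ROI size is unpublished). Per-caliber leaky fractions and
  raw counts come from `fraction_leaky()`.
* **Tight junctions** (`trace_tj_strands()`, `measure_gaps()`,
  `bin_gaps_and_fractions()`): for each vessel edge, the expected strand
  path is the centreline offset by the local radius along the path normal;
  the junction channel is sampled along that path (maximum over a ±2 px
  perpendicular probe, robust to sub-pixel path error) and compared with the
  mean + 2 sd foreground threshold. A gap is a maximal sub-threshold run
  between the first and last supra-threshold points; runs shorter than
  0.4 µm are below the assay's detection floor and discarded. Strands count
  once per bin — gaps in [0.4, 2.5] µm (closed, mirroring the printed
  range) and gaps above 2.5 µm (the "pathological" cutoff chosen from the
  bimodal gap-length distribution). A vessel with no junction signal on
  either edge is reported as a single `absent` record, capturing vessels
  that have lost their strands entirely; absent strands are tallied
  separately from the gap fractions. Gap measurement is invariant under
  joint rescaling of image and threshold, and programmed gaps are recovered
  within 2 px.
* **Intensities** (`corrected_intensity()`, `if_area_mask()`,
  `normalized_optical_density()`): background-corrected integrated
  intensity Σ(ROI) − |ROI| × mean(background), the mean + 2 sd
  immunofluorescence area mask, and the ipsilateral/contralateral corrected
  ratio used to normalize tracer optical density.

Vessel subtype (arteriole vs capillary vs venule) is an input annotation,
not computed: in practice subtypes are identified by expert inspection of
junction morphology and α-SMA staining, which a geometric pipeline should
not imitate.

## QC filtering and preranked enrichment

Endothelial single-cell libraries are filtered with the standard strict
cuts — detected genes > 200, total molecules strictly between 1000 and
50000, mitochondrial fraction < 20% (`filter_cells_qc()`); rejected cells
carry every violated rule, and the boundary values themselves are rejected
because the inequalities are strict as printed.

Differential-expression results are scored per gene as
−log10(p) × sign(log2FC) (`gene_score()`): the most significant genes get
the largest magnitudes, the fold-change direction supplies the sign, and
p = 1 (or log2FC = 0) scores zero. Zero p-values are clamped to a
configurable floor (10^−300^) so scores stay finite. Ranking sorts scores
descending with deterministic lexicographic tie-breaking (`rank_genes()`),
and the two-column RNK writer feeds any preranked tool.

`preranked_es()` is the classic weighted Kolmogorov–Smirnov running sum:
hits add |score|^w^ normalized by the total hit weight, misses subtract
1/(N − N~hits~), and the enrichment score is the signed extremum. The
weight exponent defaults to w = 1, the preranked default. `permutation_fdr()`
builds a gene-label permutation null (re-drawing each set's positions
uniformly), computes the nominal p as the fraction of same-sign null scores
at least as extreme — the denominator is the same-sign permutation count,
the standard preranked convention, without which null p-values cannot
exceed ≈ 0.5 — normalizes ES by the mean same-sign null magnitude (NES),
and estimates FDR q with the usual NES-ratio estimator over the pooled
null, clipped to [0, 1]. Published settings are the defaults: 1000
permutations, sets larger than 1500 genes excluded (and reported, as are
sets below the minimum size of 5), significance flagged at q ≤ 0.3. Which
exact q-value variant the original GSEA build used is not recoverable; the
standard estimator is implemented and labelled as such. Inside the
permutation loop the ES is computed from sorted hit positions in O(k log k);
tests pin it to a brute-force O(N) loop (and to an independent
implementation) at 10^−12^.

The DE generator plants "true" genes with p log-uniform in
[10^−10^, 10^−6^] — safely below the expected minimum (~10^−4^) of 10^4^
uniform null p-values, so planted genes provably outrank all nulls — while
null p-values stay exactly Uniform(0, 1), which the null-calibration test
exploits: nominal p over random sets on a null list must pass a
goodness-of-fit test for uniformity.

## Validation scope and limitations

Every pipeline is validated against generators whose ground truth is exact,
covering the logic of the procedures: spectral bookkeeping, threshold
arithmetic, geometry recovery, rank statistics. The generators deliberately
do not model microbubble physics (no Rayleigh–Plesset dynamics), MRI
physics (no k-space, no bias fields, no spatially correlated noise), or
optics (no 3-D PSF, no depth attenuation); vessels are straight tubes and
lesions are ellipsoids. Passing tests therefore demonstrate that the
implementations compute the stated quantities correctly — not that those
quantities are unbiased on real data, where skull stripping, staining
variability and rater ROI choices dominate. Group-level inferential
statistics across animals are likewise out of scope. Problem sizes in the
validation scripts (1 ms pulses, 20-seed benchmarks, 2000-gene universes
with 200 null sets at 200 permutations for the calibration check) were
chosen to exercise the estimators well past their asymptotic regimes while
keeping a full validation run to a few minutes on one core.
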