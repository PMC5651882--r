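---
title: "Quantitative ultrasound parametric maps and texture biomarkers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ultrasound parametric maps and texture biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the models, estimators and numerical choices behind
`qusmap`, in the spirit of a methods section: what each stage assumes, which
parameters matter, and what the synthetic validation can and cannot show.

## The analysis chain

Beamformed radiofrequency (RF) ultrasound data retain the frequency content
that B-mode rendering discards. Quantitative ultrasound (QUS) spectroscopy
exploits it: within a small tissue window, the power spectrum of the echo,
normalized against a reference medium recorded with identical system
settings, is a fingerprint of the local scatterer microstructure. `qusmap`
implements a six-parameter characterization chain over a lesion region of
interest (ROI):

1. **Sliding windows.** A 2 mm x 2 mm window slides over the ROI with 94%
   overlap, giving parametric images with a nominal 0.12 mm isotropic pixel
   pitch. With the default acquisition (512 lines / 6 cm, 40 MHz sampling,
   1540 m/s) a window spans 17 scan lines and 105 axial samples; the integer
   strides implied by the physical step are recorded as the true pitch.
   Window centres (not whole windows) gate ROI membership by default, so
   pixels reach the lesion boundary; full containment is available by flag.
2. **Window spectra.** Each scan line in the window is Hanning-apodized;
   squared-magnitude DFTs are averaged across the 17 lines. The transform
   length is the next power of two at least four times the window length,
   which stabilizes regression at the band edges.
3. **Reference-phantom normalization.** The mean phantom spectrum at the
   matching depth (averaged over hundreds of independent phantom windows) is
   subtracted in dB. This cancels the transmit pulse, the transducer
   response, beamforming and diffraction to first order. The simulated
   reference phantom mirrors a glass-bead calibration medium: attenuation
   0.576 dB/MHz/cm, speed of sound 1488 m/s, 10 um mean bead radius.
4. **Attenuation estimation and compensation.** The tumour attenuation
   coefficient estimate (ACE) comes from the spectral-difference method: for
   each in-band frequency, the depth slope of normalized dB power over ROI
   windows is fitted; `slope = -4 * delta_alpha(f)` under the package's
   two-way power convention, `delta_alpha(f) = a f` is fitted through the
   origin, and the reference attenuation (scaled by the phantom-to-tissue
   speed-of-sound ratio, which maps equal echo times to different depths) is
   added back. Point compensation then adds `4 f sum_l (alpha_l -
   alpha_ref) t_l` dB per window through a two-layer path: intervening
   tissue above the lesion at the standard 1 dB/MHz/cm, tumour at the
   estimated ACE. ACE is estimated once per frame (per-window estimates at
   2 mm are far too noisy) and clamped to [0, 3] dB/MHz/cm with a flag.
5. **Spectral line fit.** Ordinary least squares of dBr vs MHz over the
   analysis band gives the spectral slope (SS) and 0 MHz intercept (SI); the
   mid-band fit (MBF) is the fitted value at band centre, so
   `MBF = SI + SS * f_c` holds identically. The band defaults to the -6 dB
   band of the pulse (4.2-7.8 MHz at 6 MHz centre frequency and 60%
   fractional bandwidth); the band-centre reference frequency for MBF is a
   package choice, as is the band itself - normalization is only
   trustworthy where the reference has energy.
6. **Backscatter coefficient and scatterer sizing.** The BSC follows the
   reference-phantom method, `bsc(f) = bsc_phantom(f) 10^(dBr/10)`, with the
   phantom BSC tabulated from its known microstructure. A spherical Gaussian
   form factor `bsc = C f^4 exp(-0.827 k^2 a^2)` is fitted by regressing
   `ln(bsc) - 4 ln f` on `k^2`: the slope gives the effective scatterer
   radius (ESD = 2a), the intercept the effective acoustic concentration
   (EAC, dB). The fit is exact on noise-free forward-model curves. The EAC
   constant convention is `EAC = 10 log10(density x impedance_contrast^2)`,
   fixed by self-consistency with the simulator's forward model rather than
   by a literature constant (no formula is otherwise pinned down).
   Non-physical (rising) form factors pin ESD to the search-range edge with
   a flag.
7. **Scatterer spacing (SAS).** Coherent, quasi-periodically arranged
   scatterers imprint a comb of period `delta_f = c / (2 d)` on the
   spectrum. Per window, a Burg autoregressive (AR) spectrum is computed per
   line and averaged, normalized (in dB) to a planar-reflector spectrum
   recorded at the nearest depth, detrended (mean and linear tilt), and its
   autocorrelation over frequency lag is searched for a dominant peak;
   `SAS = c / (2 delta_f*)`. Windows without a dominant peak are recorded
   as missing pixels rather than guesses.

Per map, the lesion biomarkers are the mean over valid pixels plus four
gray-level co-occurrence (GLCM) texture features - contrast, correlation,
energy, homogeneity - computed on the map quantized to 16 levels over its
own min-max range, averaged over 20 symmetric GLCMs (distances 1-5 pixels,
directions 0/45/90/135 degrees; 0 degrees is the lateral neighbour). Pixel
pairs touching missing pixels are excluded; degenerate zero-variance
correlations are skipped and counted rather than silently set to 1.
Per-image (not cohort-wide) quantization makes all four texture features
invariant to affine map transforms, which the tests assert.

Patient-level vectors average each biomarker over all imaging planes of the
lesion ("volume averaging"). Group differences use two-sided Mann-Whitney U
tests (exact for small untied samples). A Wilks-lambda stepwise linear
discriminant analysis (entry F 3.84, removal F 2.71 - the classical
SPSS-style defaults) selects the hybrid biomarker combination, reported as
standardized coefficients sorted by contribution. Classification is k-NN
(k = 5, Euclidean distance on z-scored features) under leave-one-patient-out
cross-validation. Two hybrid designs are computed and reported side by side.
The headline hybrid follows the classical clinical workflow: the stepwise
selection is performed once on the whole cohort (the composition such
reports list with standardized coefficients) and the k-NN on that fixed
feature subset is then cross-validated - a design that leaks feature-selection information and is
therefore optimistic. The leak-free variant refits the stepwise selection
inside every fold (`knn_lopo(select = "stepwise")`, the function default);
at desk-scale cohort sizes fold-to-fold selection is unstable, and an
unweighted Euclidean k-NN on unstable subsets can underperform its own
component biomarkers, which is itself a finding worth reporting. The
malignancy score is the malignant fraction
among the k neighbours; sensitivity, specificity and accuracy use malignant
as positive, and the AUC is the rank (Mann-Whitney) statistic of the
scores, which equals the trapezoidal area under the threshold-swept ROC.

## The forward simulator

Patient RF data for the original clinical question are not publicly
deposited, so the package ships a point-scatterer forward simulator that
generates sample frames, reference-phantom frames and planar-reflector
echoes under known ground truth, standing in for the acquisitions.

Each frame is a superposition of per-scatterer impulse responses: a
Gaussian-envelope pulse at 6 MHz (60% fractional -6 dB bandwidth, unit peak),
filtered by the per-scatterer frequency response `f^2 sqrt(F(f; a))` - so
the ensemble BSC is proportional to `f^4 F(f)`, exactly the spherical
Gaussian form-factor model the estimators invert - and by two-way path
attenuation, delayed by the two-way travel time, weighted by a Gaussian
lateral beam profile (1 mm -6 dB width), and deposited onto the 40 MHz
sample grid with linear interpolation. Simulation is 2-D (one plane, a
nominal 1 mm elevational slice); there is no full 3-D wave propagation,
nonlinearity, or phase aberration - enough forward realism for the
estimators to have a well-posed inverse, no more.

Numerical choices worth knowing:

* **Attenuation convention.** The package uses a factor-4 two-way power
  convention consistently: one-way amplitude loss `2 alpha f z` dB, so
  compensation adds `4 f alpha z` dB of power and the spectral-difference
  slope is `-4 delta_alpha f`. Simulator and estimators share the
  convention, and round-trip tests (attenuate, then compensate) verify it;
  the recovered ACE values are therefore directly comparable to the
  package's own ground truth.
* **Kernel quantization.** Per-scatterer responses are drawn from a kernel
  table quantized to 1 um in radius and 0.02 dB/MHz in cumulative path loss
  (amplitude error < 0.1 dB at the band edge); kernels are 145 taps with a
  cosine edge taper to suppress truncation leakage.
* **Scatterer field.** Diffuse scatterers are uniform with >= 5 per
  resolution cell at the default density (30 / mm^3), which the tests verify
  produces Rayleigh-distributed envelopes. The coherent component sits on
  an axial lattice with 5% pitch jitter and a shared random phase;
  `periodic_fraction` splits the population.
* **Heterogeneity.** Within a lesion, patches of `patch_size` (2.5 mm)
  modulate local impedance contrast (full strength) and scatterer radius
  (half strength) by a normal multiplier scaled by `heterogeneity`. This is
  what the texture biomarkers detect.
* **Windowed spectra in dB.** Averaging per-window dB values under-reads
  the mean normalized spectrum by a constant (Jensen's inequality on
  speckle), which shifts MBF/SI/EAC levels identically everywhere; it
  cancels in group comparisons and classification, and tests that assert
  absolute levels average in linear power first.
* **Spectral leakage bound.** The Hanning window's sidelobe floor (about
  -50 dB) limits how much in-band dynamic range survives very strong
  attenuation; round-trip compensation is verified to 1 dB for tumour-like
  attenuation (about 1 dB/MHz/cm) over the imaging depth, and degrades
  beyond roughly 60 dB of in-band dynamic range, as it would on a real
  system.

### SAS estimator design

Two choices depart from a first-cut implementation and are worth recording.
First, the AR order: an AR(p) spectrum cannot express a spectral comb whose
underlying echo delay exceeds p samples, and the 0.25-3 mm search range maps
to delays of 13-156 samples at 40 MHz. A small fixed order (common in older
spacing work on longer gates) locks onto an AR-ripple artifact near 0.65 mm
regardless of truth at this window length; the default order is therefore
3/4 of the window length (78 at the default window), and the spacing
detection band is widened to `fc (1 +/- 0.5)` (3-9 MHz) so the
autocorrelation sees more comb periods. Second, peak prominence: the
normalized autocorrelation of pure speckle routinely reaches 0.2 through
random pair-echo interference, so an absolute peak-height floor does not
discriminate. Prominence is instead topographic - the best local maximum
must exceed the runner-up local maximum by the floor (0.1) - which flags
ambiguous windows as missing instead of letting an arbitrary speckle mode
through. With these choices the median SAS over a frame recovers lattice
pitches of 0.7 / 1.0 / 1.5 mm to within a few percent across seeds, and
diffuse media yield mostly-missing, widely scattered estimates with visibly
lower prominence.

## The default synthetic cohort

The default two-class cohort (`cohort_spec()`) is sized for a desk-scale
end-to-end run: 20 benign + 20 malignant patients, three planes at 3.5 mm
spacing across a spherical lesion of diameter 1.2 +/- 0.2 cm (planes whose
cross-section falls below one analysis window are dropped; the plane
interval is scaled with the lesion so the stack covers the tumour volume
the way a 5 mm stack covers a 2.2 cm lesion). The clinical study this
emulates is larger (78 patients, 2.2 +/- 1.7 cm lesions); running it at
that scale is a matter of budget, not code.

Class means anchor to reported benign/malignant breast group values: ESD
about 103 vs 111 um (radius 51.3 vs 55.6 um), SAS 0.7 vs 0.8 mm, EAC 38.8
vs 34.5 dB/cm^3, ACE 1.3 vs 0.8 dB/MHz/cm, with benign lesions the more
heterogeneous class (their reported texture contrast is double the
malignant value). Between-patient standard deviations are package choices
set so that the observed biomarker effect sizes mirror the reported
structure - many features separating at moderate effect sizes (d about
0.5-1.2), with no single dominant biomarker: radius SD 8 um, acoustic
concentration log-normal with about 4.3 dB SD (a positive scale parameter
varies between patients on a dB scale; a linear-normal draw of the
impedance contrast occasionally produces near-zero outliers that distort
every z-scored feature), lattice SD 0.15 mm, periodic fraction 0.40 vs 0.30
(SD 0.06; the classes differ in spacing regularity as well as pitch),
heterogeneity 0.30 (SD 0.09) vs 0.20 (SD 0.07), ACE SD 0.2 / 0.1.

What passing the end-to-end check shows: the full chain - simulation,
spectral estimation, texture, selection, leave-one-patient-out
classification - recovers a multivariate class structure that no single
biomarker captures, with leak-free cross-validation. What it does not show:
biological fidelity. There is no quantitative histology-to-acoustics map
for benign vs malignant microstructure; the simulator's class contrasts are
calibrated to reported group statistics, not to tissue physics, and real
breast data add system effects (aberration, nonlinearity, inhomogeneous
speed of sound, operator variability) that the forward model deliberately
omits.

## Degenerate inputs and edge policies

* Empty scattering media produce silent frames flagged with a warning.
* All-zero analysis windows yield invalid spectra and missing pixels.
* ROIs thinner than four window rows fall back to a configured ACE
  (default 1 dB/MHz/cm) with a warning; ROIs smaller than one window are
  rejected with the minimum usable lesion size.
* Constant maps quantize to level 1; zero-variance GLCM correlations are
  missing, not 1; empty GLCMs are excluded from the 20-GLCM average with
  counts recorded.
* All scores tied gives AUC 0.5; odd k makes k-NN vote ties impossible, and
  distance ties break by patient order for reproducibility.
* Identical cohort + seed reproduce outputs bit-for-bit; per-patient
  substreams are derived from the root seed so any patient subset is
  reproducible independently of cohort order.

## Problem sizes used by the validation suite

Estimator-recovery checks run on single frames with a coarse window overlap
(50%), giving 200-1300 windows per condition; the end-to-end check runs the
default 40-patient cohort at the full 94% overlap (about 110 imaging
planes, 10^4 windows per plane). These sizes were chosen to make every check a
few minutes at most on a single core while keeping the recovery medians
stable across seeds.
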