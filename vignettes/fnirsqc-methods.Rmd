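---
title: "Signal quality control for fNIRS recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal quality control for fNIRS recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through scalp optodes at two near-infrared wavelengths. When an optode is well
coupled to the scalp, the optical signal carries a clear, continuous cardiac
pulsation; when coupling degrades (hair, motion, detector saturation) the
pulsation disappears or is buried under artifacts. Identifying low-quality
channels is a prerequisite for valid group analyses, yet common index-based
rules — a coefficient-of-variation (CV) cutoff on raw intensity, or the scalp
coupling index (SCI) thresholded at a fixed value — sit at opposite ends of a
sensitivity/specificity trade-off and depend on arbitrary thresholds.

`fnirsqc` implements an image-classification alternative: each channel segment
is rendered as a standardized time–frequency image of its oxyhemoglobin
signal, restricted to a *subject-specific* cardiac frequency band, and a
compact convolutional network classifies the segment as high or low quality.
The package also ships the CV and SCI baselines, a statistical comparison
suite, and a seeded synthetic-recording generator used for all testing.

## Preprocessing model

Raw intensity is converted to optical density as
`OD(t) = -ln(I(t) / mean(I))` per channel and wavelength (natural log,
temporal-mean reference — the Homer convention; the base only rescales the
extinction coefficients). The modified Beer–Lambert law then yields
oxy-/deoxyhemoglobin concentration changes by solving, per channel and sample,

```
dOD_lambda = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)
```

with source–detector separation `d` (cm) and differential pathlength factor
`DPF` (default 6; when a subject age is available, the general age- and
wavelength-dependent regression can be selected with `dpf = "age"`). Extinction
coefficients default to standard compiled values at 760/850 nm
(HbO 0.586/1.058, HbR 1.548/0.691 cm⁻¹·mM⁻¹) and may be overridden. Although
deoxyhemoglobin is computed and returned, all downstream stages operate on the
oxyhemoglobin signal, which carries the stronger cardiac contrast. One
deliberate interface decision: the `.nirs` field `d` is read as **raw
intensity** (the `.nirs` convention) even though some descriptions label it
"optical density" — the pipeline's first step is the intensity-to-OD
conversion, so a consistent starting point matters more than the label.

## Subject-specific cardiac band

The cardiac band is fitted per subject instead of assuming the fixed
0.5–2.5 Hz window, because resting heart rates vary (and infant rates can
exceed 2 Hz):

1. **Channel preselection.** Each channel is scored with a windowed composite
   quality index (CQI): the record is cut into 5-s windows, and a window
   passes when its SCI ≥ 0.8 *and* its cardiac peak spectral power (PSP)
   ≥ 0.1; the CQI is the passing fraction. Channels require CQI > 0.9,
   SCI > 0.8 and PSP > 0.1, where the channel-level SCI/PSP are **medians over
   the windows** — a single artifactual segment must not disqualify an
   otherwise well-coupled channel. If no channel passes, the CQI threshold
   alone is relaxed in steps of 0.05 (floor 0) until one does.
2. **Spectral estimate.** Welch periodogram of the oxyhemoglobin signal
   (Hamming window, 60 s, 50% overlap), averaged across windows by the
   **median** — motion bursts occupy a minority of windows and a mean
   estimate lets their broadband power bury the cardiac peak. Power in dB,
   floored at −120 dB.
3. **Smoothing and flattening.** Third-order Savitzky–Golay smoothing
   (11 bins), then removal of the aperiodic 1/f background by a cubic fit in
   dB over 0.01 Hz–Nyquist. The fit is two-pass: bins more than 1 dB above
   the first-pass cubic are treated as peak candidates and excluded from the
   second pass, so strong peaks do not drag the background estimate.
4. **Peak detection and fitting.** Local maxima with topographic prominence
   > 0.5 dB are retained over the whole spectrum. Per channel, the most
   prominent retained peak within a configurable plausibility range
   (0.5–3.5 Hz by default — wide enough for infant heart rates, narrow
   enough to exclude respiration) is the cardiac candidate; ties break toward
   lower frequency. A Gaussian `a exp(-(f-cf)^2 / (2 sigma^2))` is fitted by
   direct least squares (`optim`; `nls` cannot handle the zero-residual
   case), giving `FWHM = 2 sigma sqrt(2 ln 2)` and
   `FW10M = 2 sigma sqrt(2 ln 10)`. Fits whose centre or width escape the
   local fitting window are rejected in favour of empirical widths (flagged
   `fitted = FALSE`), and candidates whose fitted centre leaves the
   plausibility range are dropped — unconstrained nonlinear fits occasionally
   run away on plateau-like spectra.
5. **Subject band.** `CF_median ± FW10M_median / 2` across contributing
   channels; medians make the band robust to a single outlier channel. FW10M
   is used instead of FWHM as the deliberately conservative bandwidth.

## Standardized scalograms

Each segment is band-pass filtered in the subject band (zero-phase Butterworth
of prototype order 4, i.e. `butter(4, band)`; fitted bands narrower than
0.3 Hz are widened to that minimum — an 8-pole filter on a few-millihertz band
is numerically fragile and physiologically meaningless given heart-rate
variability). The Morlet continuous wavelet transform (centre frequency
parameter 6, 12 voices/octave over 0.2 Hz to min(5, 0.95·Nyquist), L1-type
normalization so a unit tone has equal ridge magnitude at every frequency)
yields a magnitude scalogram.

Scalograms are min–max normalized with the minimum and maximum pooled over all
segments *of that channel* (preserving relative contrast between a channel's
segments), shifted along the frequency axis by an integer row offset so the
row nearest `CF_median` lands at row 30 (1-based from the top; vacated rows
zero-padded, overflow cropped, frequency extent padded to 224 rows), rescaled
along time to 224 columns with an antialiased linear kernel, and only then
jet-colormapped to 224×224×3 RGB. Colormapping after resizing avoids colormap
interpolation artifacts; the antialiased kernel (triangle widened by the
shrink factor, the behaviour of standard image resizers) matters because a
one-pixel cardiac ridge would otherwise alias away when shrinking.

## Classifier

The four large pretrained backbones of typical transfer-learning pipelines are
replaced by a compact CNN trained from scratch — the contribution exercised
here is the pipeline and protocol, not pretrained weights, and the model
interface is pluggable. Architecture: three conv(3×3)–batchnorm–ReLU–maxpool
blocks (8/16/32 filters), then **time-axis pooling of the first and second
moments per (row, filter)** and a 2-way softmax head. Two deliberate
departures from a generic image classifier, both driven by what the images
mean:

* pooling is over time only — the frequency axis is anchored (row 30 *is* the
  cardiac band), so row position is signal, not nuisance;
* both the mean and the mean of squares are pooled, because a band-passed
  noise burst and a stable cardiac ridge can share the time-mean but not the
  temporal variance — "continuous and stable" versus "intermittent" is
  exactly a second-moment property.

Inputs are cropped to the top 64 image rows (rows below the CWT grid extent
are structural zero padding) and downsampled to 64×64 — full frequency
resolution at a fraction of the compute; pure-R training at 112 or 224 px does
not fit a single-CPU budget. Each input image is z-scored (the channel-pooled
scalogram normalization leaves large between-image brightness differences
that carry no quality information).

Training: Adam, initial learning rate 1e-4 with the usual tenfold multiplier
for newly initialised layers (all layers are new in a from-scratch model, so
the effective rate is 1e-3), batch 32, at most 50 epochs, L2 decay 1e-4,
inverse-frequency class weights `N / (2 N_c)`, on-the-fly augmentation
(horizontal translation ±8 px and vertical ±2 px at 224-px scale — large
vertical shifts would destroy the row-30 anchor — and scaling 0.9–1.1 with
crop back), early stopping when validation *accuracy* has not improved for 15
consecutive epochs (accuracy ties with lower validation loss update the
retained best model but do not reset the patience counter). All randomness is
seeded; identical seeds give identical training curves.

Splits are subject-wise throughout: a subject's segments never cross a
train/evaluation boundary. `make_split()` builds a holdout (10% of subjects)
plus k-fold plan, `split_80_10_10()` the train/validation/test partition;
"stratification" orders subjects by their low-quality fraction and assigns
them by snake order, since the natural stratification variable is the
subject-level class balance.

## Evaluation and statistics

Low quality is the positive class. `confusion_metrics()` reports accuracy,
precision, recall, specificity and F1 in percent; zero-denominator ratios are
returned as `NaN` with a warning rather than silently coerced — degenerate
test sets should be visible. The comparison suite implements McNemar's test
with continuity correction, the tie-corrected Friedman test, the Wilcoxon
signed-rank test (exact by enumeration up to n = 12 — correct under ties —
normal approximation with continuity correction above; the 12-sample cutoff is
a documented choice, as R and Python defaults differ), Benjamini–Hochberg
step-up adjustment, and Cliff's δ. All are validated against brute-force or
`stats::` oracles in the test suite; tests are two-sided by default.

## The synthetic world

The generator (`sim_config()` / `simulate_dataset()`) emulates adult
resting-state recordings and is the package's only test bed — the real
datasets the method was developed on are not redistributed here. Defaults,
with rationale:

* heart rate uniform in 0.83–1.5 Hz (50–90 bpm); cardiac HbO amplitude
  lognormal around 0.2 µM (sdlog 0.35) with 20% slow amplitude modulation and
  a 20% second harmonic; ΔHbR = −0.3·ΔHbO plus independent noise of 0.005 µM
  (larger values are unphysical: at 760 nm they exceed the cardiac optical
  density itself and, entering the two wavelengths with different extinction
  ratios, destroy the wavelength correlation that well-coupled channels show);
* Mayer waves (0.1 Hz, 0.1 µM), respiration (0.25 Hz, 0.08 µM), and 1/f²
  drift of 0.5 µM total sd (Brownian-like; a 1/f¹ exponent would place
  ~0.1 µM rms *inside* the cardiac band and make even clean channels look
  blotchy, contradicting the premise that high quality means a continuous
  stable oscillation);
* relative sensor noise 1e-4 per wavelength at unit baseline intensity;
* low-quality segments drawn at rate 0.3 and realised as coupling loss
  (no shared hemodynamics, uncorrelated optical noise of 0.05 OD), motion
  bursts (correlated broadband random-walk excursions of 0.1–0.4 OD with
  spikes, covering 55–90% of the segment) or detector saturation (constant
  clipped intensity); high-quality segments additionally carry *minor* motion
  (10–40% coverage) at rate 0.15. Motion is correlated across wavelengths —
  the physics of optode displacement — which is precisely why the SCI baseline
  misses motion-masked segments while flagging weak-amplitude good channels,
  reproducing the qualitative failure modes of the index-based baselines.

Ground truth follows the operational rule: a segment is low quality iff the
cardiac component is suppressed or masked over more than 50% of its duration.
Segments near that boundary (a 40%-coverage minor artifact versus a
55%-coverage burst) are genuinely ambiguous, for the network as for a human
rater.

What a green test does *not* establish: the generator contains no real
optode physics (no photon transport, no skin/hair heterogeneity, no systemic
physiology beyond three oscillators), its artifact taxonomy is a three-mode
idealisation, and channels are spatially independent. Results on synthetic
data demonstrate that the pipeline is implemented correctly and that the
protocol separates the stated failure modes — not field performance.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-reflection padding with steady-state initial
  conditions (verified against an independent reference implementation at
  1e-14).
* Welch PSDs floor at −120 dB so silent signals stay finite; SCI/PSP return 0
  with a warning on zero-variance (saturated) input — a flat channel carries
  no cardiac evidence and *is* the low-quality target; constant windows inside
  the CQI likewise score zero (their filtered numerical residues are identical
  across wavelengths and would otherwise score a spurious 1).
* The PSP "peak" is the best 3-bin cluster of the normalised cross-correlation
  spectrum: the biased cross-correlation has a triangular envelope whose
  leakage splits even a pure shared tone across adjacent bins (a single-bin
  peak saturates at ~0.7).
* The CQI relaxation schedule is rounded to 10 decimals per step so that
  floating-point drift cannot blur the strict `>` threshold comparisons.
* Remainder samples after equal segmentation are dropped from the end of the
  recording; sample intervals are 0-based half-open everywhere.

## Known limitations

* The CNN is small by design; swapping in a larger backbone only requires
  honouring the `train_classifier()`/`predict_quality()` interfaces.
* SNIRF support is a minimal continuous-wave dialect (`dataTimeSeries`,
  `measurementList`, probe geometry, a few metaDataTags); other SNIRF blocks
  are ignored with a message. `.nirs`/`.mat` support runs through a small
  Python `scipy.io` bridge, as no MATLAB-file reader exists in the R
  dependency set used here.
* Channel preselection can legitimately fail on a recording with no usable
  channel; pipelines treat that subject as unusable rather than guessing a
  band.
* Only [O2Hb] is analysed downstream; [HHb] is computed and returned for
  future two-chromophore extensions.
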