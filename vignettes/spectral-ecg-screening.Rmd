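---
title: "Spectral deep-learning screening of pediatric 12-lead ECGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral deep-learning screening of pediatric 12-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolECG)
```

## The screening problem

School-age ECG screening asks a single question of every record: does
this 12-lead resting ECG contain *any* guideline-defined abnormal
finding?  Rule-based interpreters answer it with high sensitivity but
poor specificity, so most flagged children are false alarms.
`schoolECG` implements an alternative: a convolutional classifier that
reads a compact *spectral* representation of the waveform together with
age and sex, plus the full comparator-aware evaluation toolkit needed
to decide whether such a model is actually better than the incumbent
algorithm at the same sensitivity.

Because real pediatric screening waveforms cannot be shared, the
package ships a physiologically structured simulator.  Every stage of
the pipeline is exercised end-to-end on simulated cohorts; what that
does and does not demonstrate about real data is discussed at the end.

## From waveform to tensor

A record is 12 leads x 5,000 samples (10 s at 500 Hz, millivolts).  The
preprocessing chain reduces it to a `2 x 12 x 400` tensor:

1. **QRS delimitation.**  The Pan-Tompkins detector (5-15 Hz band-pass,
   five-point derivative, squaring, 150 ms moving-window integration,
   adaptive dual thresholds with a 200 ms refractory period and
   search-back) locates the R peaks; the analysed segment runs from the
   *second* R peak to the *last* (half-open), so it always covers a
   whole number of cardiac cycles and the spectrum is dominated by the
   heart's periodicity rather than by window truncation.
2. **Fourier transform.**  Each lead's segment is transformed with a
   real-input DFT.  Amplitudes are scaled `2/L` (DC and Nyquist `1/L`)
   so a unit sinusoid reads as about 1 mV regardless of segment length;
   phases come from the same coefficients.  Only bins at or below 50 Hz
   are kept — the diagnostic content of a pediatric ECG lies below
   that, and the cut also removes mains interference.
3. **Cabrera ordering.**  The lead axis is arranged `aVL, I, -aVR, II,
   aVF, III, V1..V6`: frontal leads in contiguous anatomical angle
   order with aVR inverted, chest leads appended.  Neighbouring rows of
   the tensor are then anatomically adjacent, which is what lets small
   convolution kernels see the inter-lead geometry.
4. **Resize.**  The retained bins (their count `B` depends on the
   segment length) are linearly interpolated onto 400 equally spaced
   frequencies over [0, 50] Hz.  Phase is interpolated after
   unwrapping and rewrapped to `(-pi, pi]`; interpolating wrapped phase
   directly would manufacture discontinuities at the +-pi boundary.

The tensor retains everything needed to invert the transform (segment
length, sampling rate, original per-lead phase spectra), which the
saliency mapping later reuses.

Decisions the pipeline takes where more than one convention exists:

* the detector signal is the cross-lead vector magnitude (RMS of the
  12 median-centred leads) rather than a single named lead — a single
  lead loses the QRS entirely when the electrical axis rotates towards
  its null direction, and axis deviation is one of the findings to be
  detected; a named lead remains available via
  `preprocessConfig(detector_lead = "II")`;
* "resize" is interpolation on the retained grid, not zero-padding or
  cropping, because the transform precedes the resize and the retained
  grid is irregular in length across records;
* aVR is sign-inverted in the Cabrera sequence (the standard display
  convention), with the flip carried in the phase channel (+pi) so the
  amplitude channel stays non-negative.

## The classifier

The network is VGG-style with 21 weight layers: two private
2-convolution stems read the amplitude and phase channels of the
`12 x 400` input and are fused by channel concatenation; a trunk of 14
convolutions in blocks of widths `64x2, 128x3, 256x3, 512x3, 512x3`
(3 x 3 kernels, ReLU) follows, with max-pools at block boundaries that
halve the frequency axis each block and the lead axis twice; after
flattening, the age/sex vector `(age/18, sex)` is concatenated and
dense layers `128 -> 32 -> 1` end in a sigmoid that outputs the
probability the record is abnormal.

Training is five-fold cross-validation with folds split at the
*patient* level (all ECGs of one patient stay in one fold, preventing
leakage through repeat recordings), binary cross-entropy, Adam, batch
32, and per-fold checkpointing at the minimum validation loss.  The
five fold models are kept; test-time prediction is their mean sigmoid
output — the simplest aggregation consistent with using all five.

Two presets are provided:

* `full`: full widths, learning rate 1e-7, 100 epochs — the
  configuration appropriate for a hospital-scale waveform archive;
* `desk` (default): width multiplier 1/16 (trunk widths 4..32), an
  extra (1 x 4) frequency pool after the stems, learning rate 1e-3,
  4 epochs.  This is the package's own CPU-scale operating point: the
  compiled engine trains it on a 2,000-record cohort, five folds, in a
  few minutes on one core, and on the simulated task the thin network
  is nowhere near its capacity limit (held-out AUC is about 0.94 at
  that size, and the tests only require the desk model to clear 0.85).

The engine itself (forward/backward convolutions as shifted BLAS
matrix products on zero-padded channel-major maps, max-pooling with
argmax routing, Adam, and the gradient capture used by grad-CAM) is
compiled C++ included in the package, single-threaded and deterministic
given the seed; its gradients are verified against central finite
differences in the test suite.

## Evaluation against a comparator

All screening statistics live in the evaluation module and are exact
re-implementations of the standard definitions:

* accuracy, sensitivity, specificity, PPV and NPV from a 2 x 2 table,
  with percentile-bootstrap confidence intervals (B = 2,000, record
  resampling via a multinomial redraw of the counts, seeded).  A
  statistic with a zero denominator is reported as undefined, never 0.
* ROC by threshold sweep over the unique predicted probabilities (ties
  grouped), AUC by the trapezoid — equal to the tie-corrected rank-sum
  statistic, which the tests assert on random instances.
* Two operating points: the Youden maximiser of `J = tpr - fpr` (ties
  towards the higher, more specific threshold; the returned value is
  the midpoint to the next lower probability so that under perfect
  separation it falls strictly between the classes), and the
  matched-sensitivity threshold — the largest threshold whose
  sensitivity is at least the comparator's, i.e. the most specific
  operating point at which the comparison is fair.
* McNemar's paired test on the discordant counts: exact two-sided
  binomial below `b + c = 25`, continuity-corrected chi-square above —
  the conventional split.  `b = c = 0` returns p = 1 by convention.
* Decision curves: net benefit `TP/n - (FP/n) pt/(1-pt) - harm` over a
  threshold-probability grid, with treat-all, treat-none and a
  fixed-flag comparator; the test harm defaults to 0.
* Per-finding reports dichotomise the cohort on each finding F with
  *all* other records as negatives — including records carrying other
  abnormalities.  This convention matches how per-finding screening
  tables are tabulated from an overall-abnormality flag; it also means
  a perfect overall classifier can be imperfectly "specific" for F when
  other abnormalities are present, which is a property of the
  convention, not a bug.  The per-finding McNemar pairing is restricted
  to the negative records, since the comparison of interest at matched
  sensitivity is specificity.

The bootstrap CI method is a deliberate choice: simple binomial
intervals ignore the record-resampling structure, and published
interval widths for such tables are often not reproducible from the
printed counts alone, so the package states its method explicitly and
seeds it.

## The synthetic cohort generator

Each beat is a sum of Gaussian wavelets (P, Q, R, S, T and optional
extras) on a single time-varying cardiac dipole; each wavelet has a
time offset, width, magnitude and a direction given by frontal and
horizontal plane angles.  Limb leads are frontal projections with
III, aVR, aVL, aVF derived through the Einthoven/Goldberger identities
(so `II = I + III` holds to machine precision at zero noise — a test
anchor), and V1..V6 project onto fixed horizontal-plane vectors at
-60..+40 degrees.  RR intervals are `60/HR (1 + e)` with Gaussian
jitter; heart rate follows a linear pediatric schedule `120 - 4 (age -
6)` bpm +-10%; white noise plus a low-frequency wander are added per
lead.  True R-peak indices are stored in the record as ground truth for
detector validation.

Injectable abnormalities follow textbook morphology and scale linearly
with a severity in [0, 1] (severity 0 is the identity): widened QRS
with an rsR' towards V1 for complete right bundle branch block (a
milder version for incomplete RBBB), frontal rotation by `severity x
90` degrees for axis deviation, V1-directed extra R for right
ventricular hypertrophy, QRS voltage scaling for left ventricular
hypertrophy, ST-segment shift with T inversion for ST-T abnormality, a
delta wave with short PR for WPW, coved right-precordial ST elevation
for the Brugada pattern, a fast regular P-less rhythm for SVT,
dissociated P waves over a slow ventricular escape for third-degree AV
block, and interleaved wide ectopics for PVCs.

Cohort defaults emulate a screening test group: 27% of records
abnormal, finding mixture weights proportional to the counts observed
in such a cohort (ST-T abnormality dominating; WPW and Brugada at
single counts), ages uniform on 6-18, severities drawn from
[0.7, 1].  A toy rule-based comparator (QRS width, axis, V1/V6
voltage, ST level and rate rules on jittered measurements) provides
the "conventional algorithm" flags for end-to-end demonstrations; it
is deliberately sensitive and unspecific and is never used as ground
truth.

**What passing tests on this simulator do and do not show.**  They show
the pipeline is internally correct: the detector finds the beats the
generator placed, the spectral transform inverts, the classifier learns
a separable task, and every statistic matches its independent oracle.
They do not show clinical performance: the simulator's abnormalities
are cleaner and more stereotyped than real pathology, its noise model
is white noise plus wander (no muscle artefact, electrode pops or
baseline drift bursts), and real label noise — experts disagreeing on
about a third of abnormal records — is absent.  AUC values on the
synthetic task are therefore an upper bound on what the same
architecture could do on real data at this sample size.

## Saliency

Grad-CAM is computed at a configurable convolution (default the 12th,
counting the amplitude stem then the trunk): channel weights are the
spatial mean of the abnormality logit's gradient on the layer's feature
maps, the weighted sum is ReLU'd, bilinearly upsampled to `12 x 400`
and max-normalised; ensemble maps are averaged across folds.  The map
is then carried back to the time domain by treating each CAM row as a
surrogate amplitude spectrum: resampled from the 400-bin grid to the
record's retained bins (the inverse of the resize interpolation),
combined with the record's *original* phase, inverse-FFT'd to the
segment length, rectified, smoothed with a 40 ms moving average and
max-normalised.  The 40 ms window is a rendering choice (about half a
pediatric QRS); the mapping is linear in the CAM up to the final
normalisation, which the tests verify.

## Numerical and degenerate-input conventions

* Fewer than three detected QRS complexes is an error ("insufficient
  beats"): the between-second-and-last window is undefined.
* Segment lengths are arbitrary; the retained-bin count
  `B = floor(50 L / fs) + 1` varies per record, and the resize to 400
  bins is what standardises the model input.
* Bootstrap, fold assignment, initialisation, batch shuffling and the
  simulator all consume seeds derived from one global seed by a fixed
  scheme (`seed * 31 + stage`, mod 2^31); no stage reads system
  entropy.  Training is bit-reproducible under single-threaded BLAS.
* The engine computes in single precision; parameter round-trips
  through R are exact to float precision (about 1e-7 relative), which
  is the tolerance the reproducibility tests use.
* Problem sizes in the test suite are the package's own choices: unit
  tests use a thin 128-bin variant of the architecture; the end-to-end
  check trains the desk preset on one simulated 2,000-record cohort
  and evaluates on 310 held-out records for three training seeds.

## Known limitations

* The full-scale preset is provided but not exercised by the tests;
  its learning rate (1e-7, 100 epochs) is tuned to data volumes the
  simulator is not intended to emulate.
* The comparator is a toy; per-finding comparisons against it
  demonstrate the machinery, not any clinical claim.
* Only overall abnormality is modelled; per-finding rows evaluate the
  single overall score against each finding, so a finding that the
  score ranks poorly cannot be recovered by thresholding.
* WFDB support covers format 16 with a fixed 1 uV gain — enough for
  interchange with standard tooling, not a general WFDB reader.
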