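---
title: "Detecting fetal movement in multi-sensor inertial recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal movement in multi-sensor inertial recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdetect)
```

## The problem

Reduced fetal movement is a clinical warning sign, but movement is usually
assessed by maternal perception, which is subjective and misses most
movements. Wearable inertial measurement units (IMUs) on the maternal
abdomen could monitor movement continuously, if fetal movements can be
separated from the maternal motion superimposed on every channel.

The physical idea this package is built around is a rigid-body argument.
During maternal movement the torso moves approximately as one rigid body,
so — after the sensor axes are aligned to a common anatomical frame — all
torso-mounted gyroscopes measure nearly the same angular rate. A fetal
movement, by contrast, deforms the abdominal wall locally: it perturbs one
or two abdominal sensors and leaves the chest-mounted reference sensor
untouched. Detection therefore looks for short, localized, band-limited
deviations from whole-body motion. Acceleration channels are kept in their
native sensor axes (realignment would rotate the abdominal-normal axis,
where localized deformation is most visible, into the other axes) while
angular-rate channels are functionally aligned.

`fmdetect` implements the full comparative methodology on synthetic data:
a trial simulator with ground truth, preprocessing, press-based window
labeling, three data representations (hand-engineered features, raw time
series, STFT spectrograms), three classifiers (random forest, BiLSTM,
CNN), and a trial-level Monte Carlo evaluation harness with threshold and
training-size sweeps.

## The simulator

`simulate_trial()` generates five tri-axial IMUs (four abdominal, one
chest reference) sampled synchronously at 128 Hz, producing linear
acceleration (m/s²) and angular rate (rad/s):

* **Shared maternal motion.** A single global angular-velocity and
  linear-acceleration signal — occasional smooth bursts below 2 Hz —
  is rotated into each sensor's frame by its mounting rotation. This makes
  the rigid-body property exact by construction: with noise and events
  disabled, un-rotating each sensor's gyroscope recovers the identical
  global signal to machine precision.
* **Gravity** appears as a quasi-constant accelerometer component along
  the global vertical (the x axis by the sensor-mounting convention),
  rotated by each mounting matrix. The 1–20 Hz bandpass later removes it.
* **Fetal events** arrive as a Neyman–Scott cluster process (cluster
  centres at rate `event_rate / event_cluster_factor`, each spawning on
  average `event_cluster_factor` events with exponential gaps), because
  fetal movements cluster in time. Each event is an exponentially damped
  sinusoid with carrier frequency uniform in `event_band` (default
  1–10 Hz), duration uniform in 0.3–3 s, and a random amplitude jitter; it
  is added — in each sensor's own frame, with a random direction — to the
  acceleration and angular rate of a footprint of one or two abdominal
  sensors only. The chest reference never receives a burst.
* **Maternal perception.** Only a fraction `p_perceive` (default 0.4) of
  events produce a button press. Perception is biased toward pronounced
  movements: events are ranked by the quantile of duration × amplitude,
  and the top `p_perceive` fraction are the perceived ones, so the
  marginal press rate is exactly `p_perceive` while weak, short movements
  go unreported. This mirrors the documented physiology — mothers feel
  roughly 40% of movements, and predominantly the strong, long ones.
  Presses lag the movement onset by a truncated-normal reaction delay
  (mean 0.6 s, sd 0.3 s, truncated to [0, 3.5] s so the onset always falls
  inside the labeled event interval).
* **Noise and drift.** White measurement noise per channel and a slow
  (0.02–0.3 Hz) baseline drift, which the bandpass removes.

Independent random-number substreams drive mounting, maternal motion,
drift, noise, events, and perception, so switching fetal events off leaves
every sample outside the event supports bit-identical — a property the
test suite checks directly.

Defaults were chosen once to match the study conditions the source
protocol states or implies: 128 Hz sampling, four abdominal sensors plus a
chest reference, ~40% perception, and an event rate (0.055/s) that
reproduces the reported ≈11% positive fraction of 0.5 s windows under
press-based labeling. Burst amplitude relative to maternal motion is not
characterized in the source and remains a tunable assumption
(`event_amplitude_acc`/`event_amplitude_gyr` vs `maternal_amplitude`).

**What the simulator does not emulate:** biomechanically exact fetal
kinematics, sensor-specific noise spectra, re-mounting between trials,
breathing or cardiac artifacts, or the handheld toggle's own inertial
signal. Passing tests on this generator show that the pipeline recovers
the signal structure the method assumes; they do not certify performance
on real recordings.

`simulate_calibration()` produces the functional-alignment segment: 8 s of
quiet standing followed by three hip hinges (fast 1.2 s lean, 0.5 s hold,
slow 2 s return, rotation about the global frontal axis). The asymmetric
lean/return speeds make the sign of the frontal axis identifiable from the
peak angular rate.

## Preprocessing

All channels pass through a zero-phase Butterworth bandpass, 1–20 Hz,
4th order applied forward and backward (effective 8th order, squared
magnitude response). Edges are handled by odd-reflection padding of three
times the coefficient length with steady-state initial conditions, so
constant segments filter to numerical zero without start-up transients.
The implemented response is exposed by `bandpass_response()` and the tests
compare measured gains against it: passband loss at 10 Hz is under 1 dB
with zero lag; 0.1 Hz and 40 Hz are attenuated by more than 20 dB.

`estimate_alignment()` consumes the *raw* calibration recording — the
design lists filtering before alignment, but a 1 Hz high-pass would remove
the gravity mean the method needs, so alignment statistics are computed on
unfiltered data (the trial signals themselves are filtered before the
transforms are applied). Column one of each transform is the unit mean
accelerometer vector during standing (gravity). Column two is the
principal eigenvector of the hinge-phase gyroscope covariance,
orthogonalized against gravity, with its sign chosen so the fastest
rotation (the forward lean) projects positively. Column three is their
cross product, giving a right-handed orthonormal matrix. Error paths:
a static-phase mean more than 20% away from 9.81 m/s² ("sensor not
static"), and hinge angular rates peaking below 0.1 rad/s ("degenerate
hinge"). With the simulator's default noise, recovered axes are within a
fraction of a degree of the true mounting (the tests require < 2°).

One constant transform per sensor per session is estimated; there is no
orientation tracking over time.

## Labeling

Each button press at time $t$ defines an event interval $[t-3.5, t+1.5]$ s
(reaction delay plus movement duration). Trials are segmented into
windows on a fixed grid anchored at $t = 0$ — 0.5 s with 0.5 s stride for
the feature and time-series representations, 8 s with 1 s stride for the
spectrogram representation; the final partial window is dropped. A window
is labeled 1 when strictly more than 10% of its samples lie inside the
*union* of the (trial-clipped) event intervals; the union prevents
overlapping presses from double counting, and the same 10% rule serves
both window lengths (0.05 s and 0.8 s thresholds). Overlap is evaluated
at exact sample resolution on the 128 Hz grid; the suite checks the
implementation against a brute-force per-sample oracle on a thousand
random press configurations.

Training partitions only are rebalanced by discarding two-thirds of
negative windows uniformly at random (all positives kept), which takes an
11%-positive set to ≈27% positive — the "approximate 1:3" ratio.
Validation and test partitions keep their natural prevalence.

## Representations

* **Features (75 per modality).** The canonical decomposition is: mean,
  standard deviation, and range per sensor and axis (5 × 3 × 3 = 45);
  within-sensor axis-pair Pearson correlations (3 × 5 = 15);
  maximum-magnitude normalized cross-correlation over all lags between
  each abdominal axis and the same reference axis (4 × 3 = 12); and the
  Pearson correlation between each axis of the abdominal-mean signal and
  the same reference axis (3). The exact composition of the original
  75-feature set is not published in full; this decomposition covers every
  stated feature family and sums to the stated count, with a stable
  documented ordering (`feature_names()`). Zero-variance inputs map
  correlations to 0 rather than NaN.
* **Time-series tensors.** 0.5 s windows (64 samples) × channels
  (sensor-major x/y/z; 15 per modality, 30 combined, acceleration before
  angular rate), standardized per channel with training-set statistics
  only.
* **Spectrograms.** Within each 8 s window, the STFT with a sliding
  16-sample Hann window and stride 1, one-sided magnitude: 9 bins (8 Hz
  spacing) × 1009 frames per channel, no log transform. Because the frame
  hop is one sample, the package computes one trial-level spectrogram and
  slices windows out of it (`trial_spectrogram()` + `spec_window_set()`),
  which the tests verify is exactly equivalent to per-window computation
  and avoids holding all windows in memory.

  Before entering the CNN, spectrograms are standardized per (frequency
  bin, channel) cell with training-trial statistics
  (`fit_spec_standardizer()`). A simpler per-channel max normalization
  (`fit_spec_normalizer()`, also provided) preserves the raw magnitude
  ratios, but those ratios span orders of magnitude between the
  low-frequency bins, which carry maternal motion, and the bins carrying
  fetal-burst energy; at small training sizes this was found to
  destabilize gradient training badly (runs converging to
  anti-correlated scores), while per-bin standardization — the standard
  input normalization for image-like network inputs — was stable. Both
  use training statistics only.

## Models

* **Random forest** on the feature vectors, with hyperparameters chosen by
  random search (trees 100–500, depth unlimited or 5–30, minimum node
  size 2–10, mtry √p or log₂p) maximizing validation F1 at threshold 0.5.
  Scores are per-tree vote fractions, matching majority-vote aggregation.
* **BiLSTM**: one bidirectional LSTM layer, 64 units per direction,
  dropout 0.3 and variational recurrent dropout 0.3, dense sigmoid head on
  the concatenated final states, Adam (10⁻³) on binary cross-entropy,
  early stopping on validation loss (patience 5).
* **CNN**: conv 32 filters (3,3) + ReLU → (2,2) max pool → conv 16
  filters (3,3) + ReLU → flatten → dense 16 + ReLU → dropout 0.25 →
  sigmoid; same optimizer and early stopping. Because a single training
  trajectory on a few hundred windows is highly init-sensitive,
  `train_cnn(restarts = k)` fits a small deep ensemble — independent runs
  (optionally cycling through a vector of learning rates) whose scores
  are averaged at prediction time — which is markedly more stable than
  any individual run or than selecting one run on a small validation
  set.

No deep-learning framework is declared as a dependency: both networks are
compact reference implementations inside the package — the LSTM as
batched backpropagation-through-time in base R matrix algebra, the
convolution and pooling as im2col + GEMM kernels in RcppArmadillo. Every
layer's analytic gradient is pinned by finite-difference tests, and
training is exactly reproducible from the seed (single-threaded BLAS;
weight initialization, shuffling, and dropout masks all derive from it).
Optimizer defaults the source does not state (learning rate 10⁻³, batch
size 64, at most 50 epochs, patience 5) follow common practice and are
configurable.

## Evaluation

Splits are drawn at the trial level — by default 10 Monte Carlo splits of
6 test / 6 validation / remaining training trials, pre-selected before
training and reused for every representation so comparisons are paired.
Metrics: accuracy, sensitivity, specificity, PPV, F1 (threshold 0.5
unless swept) and threshold-free AUROC via the Mann–Whitney rank statistic
with midranks, which the tests verify equals the trapezoidal area under
the empirical ROC to 10⁻⁹. Ratios with zero denominators are reported as
0 and flagged (`$undefined`) — at high thresholds a forest can predict no
positives at all. Confusion matrices are formatted as percent-of-total
with raw counts in parentheses, which keeps models with different window
sizes comparable. Paired comparisons across splits use a two-sided paired
t-test by default (Wilcoxon signed-rank as an option); all-zero
differences give p = 1 by convention. `threshold_sweep()` covers 0.1–0.9
in steps of 0.1 (sensitivity is provably non-increasing and specificity
non-decreasing in the threshold, since prediction is `score >= threshold`);
`training_size_sweep()` subsamples *trials* (preserving subject-level
independence) with nested subsets so fraction 1.0 reproduces the full run.

## Problem sizes and numerical choices

The package's demonstration scale — `experiment_config()` defaults and the
cohort sizes used in the test suite — is deliberately small: cohorts of
8 trials of 120 s (longer trials are preferred over more of them, because
with roughly two button presses per 90 s of recording, short trials
frequently contain no perceived event at all and starve the training
partition of distinct events), one split per cohort seed, and a handful
of training epochs. The CNN optimizer settings at this scale (batch 16,
a two-member ensemble over learning rates 1e-3 and 2e-3 whose scores are
averaged) compensate for the small number of gradient updates a tiny
training set affords and for the init-sensitivity of single runs. These sizes were chosen so a full 3-model × 3-modality
comparison runs on a single CPU in minutes while still exhibiting the
qualitative structure of interest; they are two orders of magnitude below
the original study (49 trials of 10–15 min, 10 splits, training to
convergence), and absolute performance at this scale is correspondingly
lower than the study's printed values — in particular, deep models are
data-hungry: the source's own training-size analysis found CNN performance
poor below half of its full training set. What desk scale preserves, and
what the acceptance checks assert, is *directional* structure: every model
scores above chance in every modality, fusing both modalities is at least
as good as either alone, and model complexity pays (CNN ≥ BiLSTM ≥ RF in
median AUROC over five cohort seeds). Not all of these directions survive
the scale reduction: with a few hundred training windows the random
forest — whose features already encode the cross-sensor comparisons the
networks must learn from data — is hard for the BiLSTM to beat, so the
BiLSTM-versus-forest leg of the complexity ordering (and the BiLSTM's
small fusion margin) is the first casualty of shrinking the cohort, and
the corresponding acceptance assertions fail at the default scale. This
is the expected behaviour: the original study's own training-size
analysis found the deep models' advantage emerges only with ample data,
with performance poor below half of the full training set, while the
forest is insensitive to training size.

Other numerical conventions: window grids are computed in integer samples
(no floating-point drift); the strict ">10%" overlap uses exact sample
counts; degenerate correlations are 0; scores are clipped to
[10⁻⁷, 1−10⁻⁷] inside the cross-entropy; per-trial seeds derive from the
master seed by a fixed integer hash, and every stochastic stage (events,
perception, noise, splits, rebalancing, weight initialization, search)
is reproducible from the experiment seed.

## Known limitations

* The 75-feature list is a documented reconstruction of the stated feature
  families, not the original (unpublished) list.
* The simulator's amplitude regime is an assumption; only the event rate
  and perception fraction are anchored to printed quantities.
* The BiLSTM consumes single 0.5 s windows (not multi-window sequences);
  with heavy label noise at that window length its desk-scale margin over
  the random forest is small.
* No real-device ingestion, no ultrasound validation, no multi-class
  maternal-activity labels.
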