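---
title: "Modeling deep-brain BOLD from single-electrode EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deep-brain BOLD from single-electrode EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cefp)
```

## The model

fMRI can localize activity in deep limbic structures such as the amygdala but
is expensive and immobile; EEG is cheap and portable but spatially blind to
deep sources. The EEG-fingerprint (EFP) approach bridges the two with a
purely statistical device: during simultaneous EEG/fMRI, the BOLD signal of a
target region (here a right-amygdala ROI, z-scored and resampled to 4 Hz) is
regressed on the recent history of single-electrode (Pz) EEG band power.

The predictor at BOLD time $t$ is the delay-embedded band-power matrix: with
10 frequency bands $b$ and 48 delays $d \in \{0, 0.25, \dots, 11.75\}$ s at
4 Hz,

$$\hat y(t) \;=\; c_0 + \sum_{b=1}^{10}\sum_{d=0}^{47} C_{bd}\, P_b(t - d/4),$$

so a model is a $10 \times 48$ coefficient matrix $C$ — the "fingerprint" —
plus an intercept. $C$ is estimated by ridge regression on column-centered
data (the intercept is not penalized):
$\hat w = (X_c^\top X_c + \lambda I)^{-1} X_c^\top y_c$, solved via an
eigendecomposition of the centered Gram matrix so one decomposition serves a
whole penalty grid. At $\lambda = 0$ with a rank-deficient design the
minimum-norm solution is returned with a warning.

Band power comes from a fixed chain: 50 Hz notch (RBJ biquad, 1 Hz
bandwidth), Stockwell transform at 1 Hz steps over 1-40 Hz, averaging of
1 Hz rows into 10 bands, mean over 250 ms blocks down to 4 Hz, then an
affine normalization $(P - \mu_\text{ref})/\sigma_\text{ref}$ against
rest-period reference statistics. The 1-40 Hz range is a configurable
default: it spans delta through low gamma while staying far below the 125 Hz
Nyquist of 250 Hz recordings.

### Frequency banding

Bands are not fixed canonical rhythms; they divide the *log-mean spectrum*
into ten intervals of equal area, so frequency resolution is spent where the
spectrum carries energy. Edges snap to the 1 Hz grid at the cumulative-area
crossing nearest each ideal multiple of one tenth, with collisions pushed
left-to-right; each band's area then deviates from the ideal share by at
most about one bin's area. A flat spectrum yields exact 4 Hz-wide bands.
Note a grid consequence: if essentially all mass sits below 8 Hz, at most
the seven grid points below 8 Hz are available as edges, so the remaining
cuts necessarily land just above the mass region.

Two distinct schemes appear in the workflow: the *comparison* scheme (built
from the log-mean spectrum across **all** sessions) used only to bring
fingerprints into one space before clustering, and the *common-model* scheme
(built from the **selected** sessions only) used to featurize training data
for the final model.

## Model selection: nested cross-validation

The penalty $\lambda$ is chosen by repeated block cross-validation: 30
random splits, each holding out one contiguous window of 20% of the rows
(time-series data are autocorrelated, so a scattered validation set would
leak). The $\lambda$ minimizing mean validation NMSE — mean squared error
over the population variance of the held-out target — wins; ties go to the
larger penalty. The default grid is 25 log-spaced values in
$[10^{-2}, 10^4]$.

The common model (cEFP) adds an outer leave-one-session-out loop over the
$k$ selected sessions: each fold concatenates $k-1$ sessions as one training
unit and validates on the held-out session. Because 20% of a concatenated
pool is longer than any single session, the inner validation "window" is
drawn as one contiguous 20% window *within each* training session, never
spanning a session boundary. The final refit on all $k$ sessions uses the
$\lambda$ most often selected across folds (ties toward more
regularization).

## One-class session selection

Sessions differ; a common model should be trained only on the homogeneous
majority. Individual fingerprints are rebinned onto the comparison scheme
(replicate each band row onto its 1 Hz rows, average into the comparison
bands, flatten band-major), and clustered agglomeratively under the
correlation distance $1 - r$. A merged cluster is represented by the plain
mean of its member leaf vectors; merge heights are reported as computed and
are not guaranteed monotone under this representative linkage. Ties break
toward the lexicographically lowest pair of cluster labels.

The stopping level defaults to a knee rule: the merge step with the largest
discrete second difference of the merge-distance curve is the last step
executed (a flat curve falls back to 24 clusters per 39 leaves, scaled
proportionally). From the biggest remaining cluster, the $n$ sessions with
the smallest maximum internal distance are selected greedily — start from
the closest pair, repeatedly add the member minimizing the resulting maximum
internal distance. Exhaustive subset search is combinatorial; on random
12-member clusters the greedy set's objective is verified to sit within 10%
of the exhaustive optimum over all $\binom{12}{10}$ subsets.

## The streaming engine

At run time the model becomes a virtual machine: every 3 s (one fMRI TR) a
packet of raw EEG arrives, a 15 s rolling buffer is re-featurized with the
same chain as offline, and the newest valid 12 s window of band power is
multiplied element-wise by $C$ and summed to emit one predicted BOLD value.

Two choices make the streamed values *exactly* equal the offline pipeline at
common time points (verified to ~1e-13):

* the notch filter carries its two-sample IIR state across packets, so the
  streamed filter output is sample-identical to filtering the whole record
  at once;
* the Stockwell window is truncated at $\pm 1$ s (and renormalized), so any
  time-frequency column at least 1 s from a record edge depends only on
  in-record samples. The 4 Hz columns within 1 s of either buffer end are
  edge-contaminated and excluded identically in both paths; the
  multiplication window therefore ends at the newest non-edge column, a
  fixed 1 s reporting latency. With 3 s packets the first emission occurs at
  the fifth packet (15 s buffered: 12 s window + two 1 s margins + part of a
  packet); until then the engine reports warming-up.

The classic untruncated window remains the default of `stockwell()` itself;
truncation is a property of the featurization pipeline, where locality is
what permits honest streaming.

Feedback maps the emitted value linearly to loudness: 50 dB at the
rest-period mean, 10 dB per rest standard deviation, clipped to [10, 90] dB.
After each feedback period the scaling standard deviation is reset from the
values of that period (sample sd, $n-1$), so subsequent excursions rescale
exactly by the sd ratio.

## Evaluating neurofeedback success

Per subject, success is a one-sided two-sample Welch test of
neurofeedback-period values against baseline values
($p(\text{NF} < \text{BL}) < .05$). The 3 s cEFP series is autocorrelated,
so nominal sample sizes overstate effective ones; no correction is applied
(none is standard for this design) and the caveat stands. Group-level
inference uses a 2x2 mixed ANOVA on per-subject condition means —
between-subject factor group (test vs sham), within-subject factor
condition (BL vs NF), interaction df $(1, n-2)$ — computed from sums of
squares, with planned simple effects of condition within each group on the
pooled within-subject error. Success rates are compared with a two-sided
Fisher exact test computed by full hypergeometric enumeration (every table
with fixed margins at most as probable as the observed one).

## The synthetic-data generator

No public paired EEG/BOLD data accompany this problem, so every stage is
validated on generated sessions with known ground truth:

* **Envelopes.** Per band, a log-normal envelope at 4 Hz: Gaussian noise
  smoothed with a 1 s-sd kernel (about 2 s correlation time), exponentiated
  with log-sd 0.35 around a 10 uV base.
* **Carriers.** One constant-modulus carrier per band whose instantaneous
  frequency wanders slowly inside the band (about 1 s correlation time,
  kept off the edges). Stochastic band-passed noise carriers were rejected:
  their Rayleigh amplitude fluctuations decorrelate in ~0.25 s and cap the
  band-power/envelope correlation near 0.5-0.7 at 4 Hz sampling regardless
  of envelope contrast, which would defeat the generator's purpose of
  making band power controllable and recoverable.
* **BOLD.** The planted linear model applied to the z-scored envelopes plus
  Gaussian noise scaled to a requested variance SNR; the first 47 points
  (incomplete 12 s history) are dropped and the output z-scored. Session
  datasets expose the generator's own normalized envelopes as band power,
  so the true mapping is known exactly at model resolution; the Stockwell
  path is validated separately.
* **Study structure.** A majority of sessions share one smooth random
  coefficient matrix; outliers get independent Gaussian perturbations
  renormalized to equal Frobenius norm, so one scalar controls cluster
  separation.

Defaults are fixed once: SNR 1 (a session predicting at the r = 0.6 quality
threshold corresponds to SNR ~ 0.56), outlier perturbation 1, 300 s
sessions, 250 Hz. Parameter-recovery checks use SNR 10 (the regime in which
coefficient estimates are interpretable); one-class recovery checks use
180 s sessions at SNR 10 so that estimation noise does not swamp the
planted separation — the measured cross-group to within-group distance
ratio (~5) is reported alongside the recovery rate. The common-model
benefit checks use SNR 1, where averaging across sessions matters most.

What the generator does **not** emulate: 1/f background spectra mixed with
the carriers, artifacts (ocular, muscle, MR gradient, cardio-ballistic),
non-stationary coupling, hemodynamic convolution (delays live entirely in
the coefficient matrix, as in the model itself), or multichannel structure.
Passing tests therefore demonstrate correctness of the machinery, not
real-data performance.

The neurofeedback study generator plants a mean NF-vs-BL shift of -0.85
(test group) against a baseline near 0.01, with between-subject
heterogeneity sd 0.3, within-period sample sd 0.5, and 140 3-s samples per
7-minute period. The heterogeneity value is a design-time power choice: the
detection properties this package tests (interaction and Fisher significance
in >= 90% of replicates) are statements about the code's correctness at a
detectable effect size, and at much larger heterogeneity the design's power
drops toward a coin flip, which would test the weather rather than the code.

## Numerical choices and edge cases

* Bands are half-open $[low, high)$ on a 1 Hz grid; time is seconds from
  record start; the 4 Hz column at time $t$ covers $[t, t+0.25)$.
* Downsampling block boundaries may fall between samples (62.5 samples at
  250 Hz); blocks take the samples whose index falls inside them, so a 1000
  sample record yields 16 columns.
* A constant prediction (e.g. an all-zero model) reports r = 0 with a
  warning rather than NA.
* Correlation distance requires positive variance on both sides; degenerate
  rest calibrations (a band with near-zero variance) are refused.
* Clustering ties (exactly equal distances) break toward the
  lexicographically lowest session-id pair, making runs reproducible.
* All simulation entry points derive per-session sub-seeds from one master
  seed; outputs are bitwise-reproducible under a fixed seed.

## Known limitations

* The Stockwell window's bandwidth grows with frequency
  ($\sigma_f = f/2\pi$), so above ~13 Hz it exceeds the 4 Hz width of
  uniform bands: neighbouring bands' dynamics mix, and per-band envelope
  recovery saturates around r ~ 0.55-0.75 there (low bands reach
  r > 0.9; a silenced low band drops to ~3% of its normal power, a
  silenced high band only to ~75%). This is a property of the transform,
  not of the implementation; tests assert recovery where the transform
  resolves bands and identifiability (own envelope is the best match)
  everywhere.
* Ridge coefficient recovery is limited by design-matrix collinearity
  (slow envelopes make neighbouring delays nearly collinear): even
  noiseless sessions recover the planted matrix only up to correlation
  ~0.99, while predictions are exact.
* The mixed ANOVA uses subject-equal weighting in its main effects; with
  unbalanced groups other software may report different main-effect F
  values (the interaction term, the quantity of interest, matches `aov`
  exactly).
* The per-subject Welch test treats 3 s samples as independent; with
  autocorrelated series its nominal p-values are optimistic.

## Problem sizes used in the validation suite

The packaged checks run at desk scale: 10 sessions of 300 s for parameter
recovery; 20 studies of 15x180 s sessions for one-class recovery; 20
replicates of 5+5 sessions of 120 s for the common-model comparison; 60-120 s
streams for the streaming-equivalence check; 50 replicates of the 13-subject
neurofeedback study. These sizes give stable medians and sign tests while
keeping a full run in minutes; all are arguments of the corresponding
`benchmark_*()` functions and scale up freely.
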