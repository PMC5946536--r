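---
title: "Pattern-recognition myoelectric control with MAV threshold switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-recognition myoelectric control with MAV threshold switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgpr)
```

## The problem

After targeted muscle reinnervation (TMR), residual arm nerves are
transferred onto spare muscles so that surface-EMG (sEMG) electrodes over
those muscles pick up the intended motions of the missing limb. The
conventional controller is amplitude-based: each channel has a designated
motion (here Ch1–Ch5 for hand close, hand open, wrist rotation, elbow
flexion and elbow extension) and the prosthesis performs the motion whose
channel mean absolute value (MAV) exceeds a preset threshold. This fails
when the recorded signals are *coupled* — several channels activate
together during a single motion attempt, e.g. because two recording sites
sit on branches of the same muscle, or because of co-contraction. `emgpr`
implements the pattern-recognition (PR) alternative and the post-processing
that makes it usable in real time, together with a synthetic coupled-sEMG
generator that serves as its test bed.

## The pipeline

1. **Windowing.** The signal is band-pass filtered (80–400 Hz default) and
   cut into overlapping analysis windows of 137.6 ms with 50 % overlap. In
   integer samples the window length is `round(0.1376 * fs)`: 256 samples
   at the 1860 Hz real-time rate (the power of two that duration encodes)
   and 138 at 1000 Hz. The step is `round(length / 2)`; trailing partial
   windows are discarded.
2. **Features.** Each window contributes four time-domain features per
   channel: MAV, waveform length, zero crossings and slope-sign changes —
   20 features for the five-channel montage.
3. **Classifier.** A linear discriminant classifier with Bayes decision:
   per-class means $\mu_k$, pooled covariance $\Sigma$, priors $\pi_k$, and
   $g_k(x) = \mu_k^{\top}\Sigma^{-1}x - \tfrac12\mu_k^{\top}\Sigma^{-1}\mu_k
   + \log\pi_k$, predicting the maximal $g_k$.
4. **Post-processing.** Either a majority vote over the last $L$ decisions,
   or the *MAV-based threshold switches*: the final output is
   $M_i = C_i \oplus D_i$ with $D_i = V_i - T_i$, where $C_i$ is the raw
   classification, $V_i$ the MAV of the classified motion's designated
   channel in the same filtered window, and $T_i$ that motion's preset
   threshold. The motion is emitted only when $D_i > 0$ (strictly);
   otherwise the prosthesis stays still. `STILL` is an output token, never
   a trained class.

The rationale for the threshold switches: the classifier is trained only on
steady holds (the labeling protocol cuts the first 4 s of every 7 s
training segment), so most misclassifications occur in the transient state
at motion onset and offset, where amplitudes are still low. Gating on the
designated channel's MAV converts exactly those low-amplitude windows to
stillness.

## Training protocol

A training session attempts the five motions back to back, 7 s each
(35 s total). Per segment the first 4 s are discarded and the last 3 s are
windowed and labeled with the segment's motion — 42 windows per motion at
1860 Hz. `extract_training_set()` implements this; "about 7/4/3 s" are
fixed to exactly 7/4/3 s for determinism, configurable via
`session_plan()`.

## The synthetic generator

No public recordings exist for this setting, so `simulate_emg()` generates
the test bed: each channel is
$\mathrm{env}(t)\,c(t) + \varepsilon(t)$, where $c(t)$ is an independent
unit-RMS Gaussian carrier band-limited to 80–400 Hz (the standard surrogate
for surface EMG), $\varepsilon$ is white baseline noise (0.02 mV RMS), and
the envelope sums trapezoidal contributions of the scheduled motions
through a motions × channels *coupling matrix* in mV. Envelopes ramp
linearly over 0.4 s at onset and offset — the transient state — and hold in
between. During a steady hold with envelope amplitude $a$ the expected MAV
is $\sqrt{a^2+\sigma_\varepsilon^2}\sqrt{2/\pi}$ (Gaussian mean absolute
value), which is what the amplitude tests assert.

Default coupling (chosen once to emulate the motivating clinical case
qualitatively): designated channels at 0.30 mV (0.15 mV for wrist rotation,
whose reinnervated site was markedly weaker), 0.8× coupling between the
anatomically paired channels — hand close with elbow flexion (two biceps
heads) and hand open with elbow extension (two triceps heads), where
amplitudes were reported nearly identical — and 0.2× background
co-contraction elsewhere. Under these defaults the per-motion independence
scores of the MAV grid sit near 1.25 for the paired motions, i.e.
amplitude-based control barely separates them, while the standard
thresholds (0.2 mV, 0.1 mV on Ch3) fall between coupled (~0.19 mV) and
intended (~0.24 mV) steady MAV — the regime in which threshold switching
is informative. Coupling acts multiplicatively on envelopes, so
cross-channel correlation reflects co-activation rather than electrical
cross-talk; motor-unit-level biophysics and volume conduction are
deliberately out of scope.

What passing tests on this generator do **not** show: robustness to
electrode shift, fatigue drift, non-Gaussian interference, or real
transient dynamics (real onsets are not linear ramps). The generator's
purpose is controlled, reproducible structure — coupling strength, phase
boundaries and ground truth are known exactly.

## Evaluation

`score_stream()` classifies each analysis window as steady, transient or
rest from the annotated ground truth; windows overlapping a ramp or
straddling an interval boundary count as transient (conservative, since
transients are where errors concentrate). Steady accuracy is the fraction
of steady windows outputting the held motion; the transient error rate is
the fraction of transient windows emitting a *wrong* motion (`STILL` and
the active motion are both acceptable there).

ARAT functional-testing scores are human observer ratings, so the package
only implements their arithmetic: per-task scores (0–3) are averaged over
three trials and summed per condition (`arat_totals()`), and
`percent_increase()` compares condition totals to the no-post-processing
baseline. The published condition totals are shipped as
`arat_condition_totals()` as inputs to that arithmetic.

## Numerical and design choices

- **Filter.** 4th-order Butterworth; zero-phase (forward–backward) for
  offline analysis, causal single-pass for streaming use. Only the band is
  prescribed by the application; the realization is ours.
- **ZC/SSC deadband.** 0.01 mV by default; the threshold convention is not
  standardized, so `eps` is configurable and `eps = 0` recovers the
  textbook definitions used by the brute-force oracle tests. Zero crossings
  use a strict sign product (exact zeros never count) to avoid
  double-counting runs of zeros.
- **LDA regularization.** `reg_lambda = 1e-6` scaled by `trace(Σ)/d`
  guarantees a positive-definite pooled covariance without noticeably
  biasing the discriminants; priors default to class frequencies, which the
  balanced protocol makes uniform. No rest class is trained — stillness
  arises only from post-processing.
- **Ties.** Prediction ties break to the first label in sorted label
  order; majority-vote ties resolve to the previous output when it is among
  the tied labels, else label order. Both are documented, deterministic
  choices — the underlying schemes do not specify ties.
- **Strictness.** `D = 0` maps to `STILL` ("higher than" is strict), and
  $V_i$ is computed from the same band-pass-filtered window as the
  features.
- **Vote vs. threshold.** The two post-processing modes are evaluated
  separately, as in the motivating study; a combined mode is intentionally
  not implemented.
- **Windows.** Whether the embedded original floored or rounded the 50 %
  step is unknowable; we fix `round` and state it.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
real-time rate (1860 Hz): 35 s training sessions, assessment recordings
with 5 s holds, and three replicate seeds. Between-attempt rests are
shortened from the clinical 10 s to 2 s in simulations — rest windows carry
no information for any reported metric — and grids average 3 sessions
rather than the clinical 10; these sizes keep a full run in seconds while
leaving every estimate's precision comfortably inside the asserted
tolerances. Generator defaults keep the clinical values.

## A worked run

```{r example, eval = FALSE}
plan <- session_plan()
cfg <- sim_config(seed = 1)
train <- make_training_session(cfg, plan)
ts <- extract_training_set(train, plan)
model <- fit_lda(ts$x, ts$y)

test <- simulate_emg(sim_config(seed = 101),
                     assessment_schedule(rest_s = 2))
raw <- run_pipeline(test, model, "none")
gated <- run_pipeline(test, model, "threshold",
                      thresholds = st_thresholds())
score_stream(raw, test)
score_stream(gated, test)
```

The transient error rate collapses under threshold switching (to zero at
most seeds) at the cost of a few percentage points of steady accuracy —
the windows near the gating margin — plus the inherent response delay of
waiting for the amplitude to build up. That trade is the package's central
reproducible result.

## Known limitations

Single-subject-inspired defaults; no simultaneous or proportional control;
no decision-based velocity ramp; no embedded/real-time deployment path; the
simulator's idealizations listed above. The human functional-testing
outcomes themselves are not reproducible computationally — only their score
arithmetic is.
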