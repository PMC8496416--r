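---
title: "Measuring motion contrast sensitivity from optokinetic nystagmus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motion contrast sensitivity from optokinetic nystagmus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okncs)
```

## The measurement problem

Contrast sensitivity (CS) — the reciprocal of the lowest grating contrast a
visual system responds to — is normally measured with button-press
psychophysics, which excludes infants and non-communicative patients. A
large drifting grating, however, elicits optokinetic nystagmus (OKN)
involuntarily: gaze alternates between slow phases (SP) that track the
pattern at a fraction of its velocity (the *gain*, canonically about 0.76
at 2.3 deg/s) and quick phases (QP) that reset the eye against the drift.
Whether OKN occurs at a given contrast is therefore an objective,
response-free indicator of whether the stimulus was seen.

`okncs` implements the complete measurement loop:

1. **Detection** of OKN in binocular horizontal gaze data, both *offline*
   (post hoc, full sampling rate) and *live* (causal, frame by frame, so
   a trial can be aborted the moment a robust response is seen);
2. **Adaptive testing**: a QUEST+ staircase that picks each trial's
   contrast to be maximally informative about the threshold;
3. **Estimation**: cumulative-Weibull psychometric fitting per spatial
   frequency and a log-parabola fit of the contrast-sensitivity function
   (CSF) across frequencies;
4. **Simulation**: seeded generators for labelled OKN/fixation gaze
   traces and psychometrically governed virtual observers, so the whole
   loop runs — and is tested — without an eye tracker or participants.

## OKN detection

### Quick phases

Horizontal velocity is computed with the five-point central-difference
kernel `v[n] = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 dt)`, which is
exact for affine signals and attenuates sample noise. Quick phases are
maximal runs of supra-threshold speed, `|v| > eta`, with a per-eye
threshold `eta = lambda * sigma`. The noise scale uses the median
estimator `sigma^2 = median(v^2) - median(v)^2`, robust against the very
samples it is meant to ignore (the quick phases themselves), and the
multiplier is `lambda = 7`. A detection must be *binocular*: a monocular
run is kept only if it overlaps a run in the other eye by at least one
sample, and the union interval is reported.

`sigma` is estimated from the first 34 display frames (283 ms at 120 Hz)
of each presentation, a window used for nothing else. The window works
because optokinetic tracking builds up over a couple of hundred
milliseconds, so those frames are fixation-like. This matters more than
it looks: the median estimator collapses when every window velocity has
the same sign (then `median(v^2) = median(v)^2` exactly), which is what a
window of pure slow-phase drift with small noise produces. The noise
window must precede tracking, and the simulator reproduces exactly that
(`onset_latency_ms`, default 250 ms).

Two mode-specific defaults follow conventions rather than a stated rule
and are exposed in `detector_config()`: the minimum event duration
(6 ms at 1000 Hz offline, two frames live — the usual multi-sample
minimum of velocity-threshold detectors plus the live frame
quantization) and the offline merging of events separated by less than
50 ms, which protects against saccadic overshoots being counted twice.

### Slow phases and the robust-OKN rule

Every inter-saccadic gap is a slow-phase candidate. The segment is
shrunk by two screen refreshes (~17 ms) at each end so saccadic
overshoot cannot contaminate the estimate, smoothed with a centered
5-sample moving average, and summarized by its mean velocity — by
default the endpoint displacement of the smoothed segment over its
duration, a per-sample mean being available via
`sp_velocity_estimator = "mean"`. Both eyes are estimated separately and
averaged when both are valid. The candidate is accepted iff its velocity
sign matches the stimulus drift and its magnitude reaches
`sp_velocity_threshold_dps`.

No canonical value exists for that threshold; the default **0.5 deg/s**
sits a factor ~3.5 below the expected slow-phase speed
(0.76 × 2.3 ≈ 1.75 deg/s) and far above fixational drift, and the
package warns if it is configured above twice the stimulus speed. A
stimulus counts as *seen* when at least `robust_count = 2` validated
slow phases occur; each validated slow phase is necessarily bracketed by
quick phases, so this is equivalent to requiring two QP→SP sequences.

### Live versus offline

The *offline* analysis runs at the recording's full rate (1000 Hz),
masks blinks (track-loss runs dilated by a 50 ms buffer) before the
velocity transform, scans the entire trace, and merges saccades closer
than 50 ms. The *live* analysis is coupled to the display: gaze is
decimated to one representative sample per frame (the latest sample at
or before each frame boundary), velocities use the same kernel with
`dt = 1/120 s`, and scanning restarts after each detected saccade. It is
strictly causal — the decision at frame *k* depends only on frames up to
*k*, with the kernel imposing a two-frame confirmation latency — and
deliberately performs **no blink masking**, mirroring the real-time
method's limitation; a non-finite frame simply breaks supra-threshold
runs. "Seen" is emitted the moment the second slow phase validates;
"not seen" is emitted at the 4 s timeout. `feed_frame()` exposes the
streaming contract one frame at a time, `run_live()` replays a recording
through the identical scan in one pass, and the test suite asserts the
two are decision-for-decision identical.

## Adaptive contrast selection (QUEST+)

The staircase maintains a posterior over a 39 × 11 grid: thresholds are
identified with the 39-level contrast ladder (log-uniform from 0.03% to
66% Michelson contrast — the displayable set) and slopes span 0.5–5.5 in
steps of 0.5. The outcome model is the zero-asymptote cumulative Weibull
below. After each trial the posterior is multiplied by the outcome's
likelihood and renormalized; the next contrast is the ladder level
minimizing the expected posterior entropy over the two outcomes,
computed on the full joint (threshold × slope) grid, with ties broken
toward the lower contrast (prefer the harder stimulus, deterministically).
The prior is uniform unless specified — the staircase itself contains no
randomness. Sixty-four trials per spatial frequency keep the data volume
constant across conditions.

## Psychometric model and fitting

The probability of an OKN response at contrast `x` is the cumulative
Weibull

    Psi(x) = gamma + (1 - lambda - gamma) *
             (1 - exp(log(0.5) * exp(c * (log x - m) / w)))

with `c = log(-log 0.05) - log(-log 0.95)`. `m` is the log contrast
threshold — `Psi(e^m) = 0.5` when the guess rate `gamma` and lapse rate
`lambda` are zero, as they are fixed here — and `w` is the width of the
5%–95% zone in log-contrast units, related to the slope by `s = c/w`.
All logarithms are natural: the quantile identity
`Psi^{-1}(0.95) - Psi^{-1}(0.05) = w` holds exactly only when every log
in the parametrization shares one base, and the tests assert it at
1e-9. Thresholds convert to contrast threshold `CT = e^m` and
sensitivity `CS = 1/CT`; with contrast as a fraction in (0, 1], CS lands
in the conventional 1–3000 range.

`fit_psychometric()` maximizes the product-binomial likelihood of
`(m, w)` directly — a coarse grid start followed by bounded local
refinement — rather than reproducing any particular toolbox's Bayesian
machinery: only the 50% point is consumed downstream, and the MLE of the
same parametrization reproduces it. `m` is constrained to the ladder
span plus one step on each side. A table whose outcomes are all seen or
all unseen cannot identify an interior threshold; the fit then returns
the corresponding boundary with `converged = FALSE` and a warning, never
a silent interior value.

## The contrast-sensitivity function

Across spatial frequencies the CS values are fitted with a log-parabola,

    log10 CS(SF) = log10(gamma_max)
                   - log10(2) * ((log10 SF - log10 SF_max) / (beta/2))^2

with peak sensitivity `gamma_max`, peak frequency `SF_max` (cpd) and
bandwidth `beta`. Two interpretation choices are fixed here and
documented rather than configurable: the model's left-hand side is read
as the **log10** of sensitivity (the right-hand side is in log10 units,
and fitting plus R² are computed in that space, where the model is a
plain quadratic in `log10 SF`), and `beta` is treated as a bandwidth in
log10-cpd units exactly as written — no octave conversion is applied. No
low-frequency truncation term is included: the model is a pure parabola,
halving sensitivity at `beta/2` log10 units from the peak. The
closed-form quadratic regression provides the start; bounded refinement
keeps `SF_max` within `[min(SF)/2, 2 max(SF)]`. Degenerate constant-CS
input yields `r2 = 0` by the `SS_tot = 0` convention, with a warning.

## What the simulator emulates — and what it does not

`synth_okn_trace()` builds the saw-tooth: slow phases at
`gain x stimulus velocity` (default gain 0.76), quick phases as smooth
raised-cosine resets of 1 deg amplitude and 30 ms duration against the
drift — at the default stimulus speed this reproduces the ~0.6 s
quick-phase cycle of stare-OKN, so a robust response is typically
detectable within 1.5–2 s of stimulus onset. Tracking starts after a
250 ms fixation-like onset latency (see the noise-window discussion
above). Both eyes share the signal plus independent sensor noise and a
slowly varying disparity offset (SD 0.02 deg); blinks arrive at 0.1 Hz
as 150 ms track-loss runs.

Sensor noise is band-limited on purpose. Its marginal SD (0.05 deg)
is split into slow pupil-estimation wander (200 ms correlation, 95% of
the variance) and per-sample white jitter (5%): that is what video eye
trackers deliver, and it yields frame-rate velocity noise of a few
deg/s — large enough that `eta = 7 sigma` clears the 1.75 deg/s
slow-phase speed, small enough that 40–100 deg/s quick phases stand
out. Two failure modes bracket this regime and are worth knowing:
pure *white* noise of the same SD would push `eta` at 1000 Hz above any
realistic quick-phase velocity (detection misses everything), while
*near-zero* noise drops `eta` below the slow-phase speed (everything is
supra-threshold and no slow phase can validate). A velocity-threshold
detector is calibrated by its noise floor; the simulator's defaults keep
it in its operating range, and "cleaner" data would genuinely not help.

The virtual observer is deliberately minimal: OKN presence is a
whole-trial Bernoulli draw with probability `Psi(contrast)` from a
ground-truth parameter table, and the emitted trace is a full saw-tooth
or a fixation trace accordingly. The simulator does **not** model
within-trial OKN onset dynamics, contrast-dependent gain or latency,
pursuit intrusions, vergence, pupil dynamics, or ballistic saccade
kinematics (main-sequence behaviour). Detection metrics computed on this
corpus therefore validate the *pipeline logic* — event extraction,
causality, decision rules, staircase coupling — not the detectors'
performance on physiological data, where gaze quality varies in ways the
generator does not produce. Defocus is represented only as
condition-specific ground-truth CSFs (peak sensitivity and peak
frequency fall with lens power, concentrating threshold elevation at
high spatial frequencies); no optics are simulated.

## Validation choices and problem sizes

The test suite checks every detection and staircase primitive against an
independently written brute-force oracle (exhaustive run enumeration for
saccades, the direct median formula for `sigma`, set dilation for blink
masks, dense product-of-likelihoods and full enumeration for the QUEST+
posterior and selection, dense grid search for the psychometric MLE) on
at least 50 randomized instances each. Detection performance uses a
200-trace labelled corpus (100 OKN, 100 fixation) under the default
generator; closed-loop recovery uses 20 seeded full experiments (six
spatial frequencies × 64 trials) and requires the median absolute
log-threshold error to stay below half a ladder step at every
frequency. These sizes give stable medians while keeping a full
validation run in the minutes range.

Other conventions: gaze positions are standardized to degrees at
ingestion (every threshold in the pipeline is angular); timestamps are
milliseconds; pupil values of 0, `NA` or `.` all map to one track-lost
flag; runs touching a trace boundary count as events if they meet the
minimum duration; kernel-margin samples never start a run; and the
offline noise window defaults to the same first-283 ms as the live one
for comparability, while offline scanning covers the whole trace.

## Known limitations

* The live detector cannot distinguish blinks from track loss, by
  design; its false-negative rate rises with blink rate.
* A quick phase falling inside the noise window is invisible to the
  live detector (that period is used for noise assessment only).
* The slow-phase velocity threshold is a free parameter with a
  heuristic default; on real data it should be checked against each
  laboratory's gain distribution.
* The log-parabola has no low-frequency truncation, so it will
  underestimate sensitivity plateaus below ~0.5 cpd if they exist in
  the data.
* Fitted psychometric widths from 64 adaptive trials are noisy (the
  staircase concentrates sampling near the 50% point, which pins `m`
  but not `w`); threshold estimates are the reliable output.

## A minimal session

```{r example, eval = FALSE}
library(okncs)

# one simulated trial, detected live
stim <- stimulus_spec(sf_cpd = 2.6, contrast = 0.5, direction = 1)
trace <- synth_okn_trace(stim, okn_gen_params(), seed = 7)
run_live(trace, stim)

# a full simulated measurement: staircase, detection, fits
observer <- defocus_observers()[["0D"]]
experiment <- run_closed_loop(observer, experiment_plan(), seed = 1)
summary(experiment)
plot(experiment)
```
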