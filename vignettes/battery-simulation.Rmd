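---
title: "Simulating an auditory profiling test battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an auditory profiling test battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audbattery)
```

## Why simulate a test battery

Clinical characterization of sensorineural hearing loss increasingly relies
on batteries of supra-threshold tests — loudness scaling, speech in quiet and
noise, spectro-temporal modulation detection, tone-in-noise audiometry with
masking-release conditions, and binaural tests — on top of the pure-tone
audiogram. Developing, calibrating and stress-testing such a battery on
human listeners is slow and expensive. `audbattery` re-implements the whole
measurement chain in software: every stimulus is parameterized and
renderable, every adaptive procedure is executable against a *simulated
listener* whose generative parameters are known exactly, and the study-level
statistics (test–retest reliability, correlation structure, factor analysis)
run on the resulting outcome tables. Because the ground truth is known,
every estimator in the chain can be audited for bias and precision —
something impossible with human data.

## The measurement models

### Yes/no tracking with a single-interval adjustment matrix (SIAM)

Most threshold tests in the battery are yes/no tasks: a warble tone in
threshold-equalizing noise (TEN), a spectro-temporally modulated noise
against unmodulated intervals, a high-frequency tone at fixed level. The
tracked variable (level in dB, modulation level in dB, or log2 frequency)
is adjusted by a payoff matrix targeting probability $t$: after a hit the
task gets harder by one step; after a miss easier by $t/(1-t)$ steps; after
a false alarm on a catch trial harder by $1/(1-t)$ steps; a correct
rejection leaves the track unchanged. At $t = 0.8$ the miss and false-alarm
multipliers are 4 and 5; at $t = 0.5$ the procedure behaves like a
1-up/1-down staircase whose step doubles when the listener is "caught".
The balance $t \cdot (-1) + (1-t)\cdot t/(1-t) = 0$ makes the signal-trial
drift vanish exactly where the hit probability equals $t$; catch trials
(20% of trials by default) shift the equilibrium by $-c f/(1-c)$ for
catch rate $c$ and false-alarm rate $f$ — about 0.05 of the psychometric
spread under the defaults, i.e. negligible against the final step size.

Reversal handling is a preset, not a constant: the high-frequency
audibility test discards 4 reversals and averages the next 2; the
tone-in-noise and modulation tests discard 2 and average 4. Tracks that
keep pressing against a tracking bound (three clamps while sitting on the
bound) are invalidated, mirroring how inconsistent runs are discarded in
practice.

### The 2-AFC frequency track for the interaural-phase limit

The upper frequency limit for detecting a 180° interaural phase difference
(IPD) is tracked in log2 frequency with steps shrinking from 2/3 to 1/6
octave per reversal, threshold = mean of the last 6 reversals, two runs
averaged. One design decision deserves emphasis: with a two-interval task
the guessing floor is 50%, so a literal 1-up/1-down rule (which converges
at 50% correct) has *no* equilibrium — simulations show it drifting about
half an octave past any hard detection limit. The package therefore raises
frequency only after two consecutive correct responses (the 70.7% rule
familiar from adaptive-frequency tests); `twoafc_config(n_correct_up = 1)`
restores the literal rule for comparison.

### Categorical loudness scaling and the broken-stick fit

Loudness is scaled on 11 categories mapped to categorical units (CU)
0–50. The simulated listener answers from a broken-stick loudness function:
CU rises with slope $m_{lo}$ (CU/dB) to CU 25 at $L_{cut}$ and with slope
$m_{hi}$ above, plus Gaussian response scatter (3 CU by default), snapped
to the 11 categories. The tracking procedure brackets the dynamic range
(ascending to a high-loudness response, descending to "not heard") and then
places 22 presentations uniformly across it in pseudorandom order — a
simplification of the clinical level-placement rule; fidelity is claimed
for the *fit*, not the trial sequence. The least-squares broken-stick fit
inverts the same model and reports: HTL (level at CU 2.5 via the lower
branch), MCL ($L_{cut}$, the level of CU 25), Slope ($m_{lo}$), and the
dynamic range level(CU 50) − level(CU 0.5). The mixed anchors — CU 2.5 for
the threshold but CU 0.5 for the dynamic-range floor — follow the source
conventions for those outcomes; both are arguments of
`fit_loudness_function()` and can be unified. Which branch "Slope" denotes
is genuinely open; the lower branch is used because it matches the
published normal-hearing range (0.27–0.44 CU/dB).

### Speech psychometrics

Word recognition in quiet is sampled at four fixed levels, PTA + 10, 20,
30, 40 dB, 25 words each, and fitted by maximum likelihood with a logistic
of two *free* asymptotes; the speech reception threshold is the level at
absolute 50% correct and maxDS is the upper asymptote (so a listener whose
curve plateaus at 80% is reported at 80%, not forced to 100%). The fit
restarts from several initial values because the likelihood can trade the
upper asymptote against the spread when the sampled levels barely reach the
plateau. Sentence recognition in noise uses a whole-sentence 1-down/1-up
staircase (4 dB steps for the first four sentences, then 2 dB); the SRT is
the mean presented SNR over sentences 5–20 plus the virtual 21st, and a
separate 20-sentence list at +4 dB SNR yields the sentence score. Speech
material is abstracted: a sentence or word is correct with the probability
given by the listener's psychometric function — no lexical modelling.

### Screening d′ and its correction

The screening modulation test presents 10 modulated and 5 unmodulated
stimuli; sensitivity is $d' = z(H) - z(F)$ with the log-linear correction
$H = (h + 0.5)/11$, $F = (f + 0.5)/6$. The correction is an inference from
the test's published anchor values — it reproduces both the ceiling (3.07)
and the floor (−0.31 ≈ −0.3) of the 10/5 design exactly, which no other
standard correction does.

### Masking release and binaural tests

Tone-in-noise thresholds are measured in a reference TEN condition (N), a
spectrally shifted condition (S, masker centre at 1.1× the tone frequency)
and a temporally modulated condition (T, 4-Hz sinusoidal AM at depth 1 —
deep modulation is required for dip listening; the depth is configurable
because the source leaves it open). Masking release is the plain
difference ref − cond, so SMR = N − S and TMR = N − T; the binaural
masking release is S₀N₀ − SπN₀. Dichotic (Huggins-type) pitch contours are
rendered by applying a frequency-specific interaural phase transition
(16% relative transition bandwidth by default) to otherwise identical
noise channels; the score counts *dichotic* contours only. Diotic contours
are rendered as a 6-dB narrowband increment in both ears — the clinical
original does not document its diotic rendering, so this choice is ours
and no fidelity is claimed for it.

## The simulated cohort

`make_cohort()` draws listeners from a generative model with **two latent
severity dimensions** — low-frequency and high-frequency loss — realized as
piecewise-linear interpolation between the standard audiograms N1–N4
(IEC 60118-15) with 5 dB per-frequency jitter. The two dimensions are what
give the simulated outcome tables their characteristic two-cluster
correlation structure; a single severity scalar would correlate everything
with everything. Supra-threshold truths are affine in the band-pooled
losses plus independent noise (all coefficients live in
`cohort_config()$linkage`):

* recruitment: the loudness function's threshold branch is anchored at the
  audiometric threshold while the uncomfortable level rises only slowly
  with loss, so the lower-branch slope steepens as the dynamic range
  shrinks;
* speech-in-noise, modulation-detection and high-frequency masking-release
  deficits grow with high-frequency loss;
* binaural parameters (IPD limit ~ log-normal around 700 Hz,
  dichotic-pitch detection probability, binaural masking release ~ 15.5 dB)
  are drawn independently of the audiogram;
* response noise: 5% false alarms, 2% lapses, 3 CU loudness scatter.

One linkage is deliberately *not* realistic: the speech-in-quiet threshold
is placed at PTA + 17 dB so that the fixed sampling grid PTA + 10…40 dB
straddles the 50% point. In severe clinical losses the word threshold sits
much closer to the PTA, where the absolute 50% point falls below the lowest
sampled level and is only recoverable by extrapolation; parameter-recovery
audits would then measure the extrapolation, not the estimator. This is a
recoverability design choice, documented here once.

These are simulated listeners answering from smooth psychometric
functions. Passing recovery tests therefore demonstrates that the
procedures and estimators are unbiased and precise *under the stated
response model*; they say nothing about inattention bursts, criterion
drift, learning effects, or lexical structure in real listeners.

A `deterministic = TRUE` cohort replaces every response with its
noise-free step-function limit (no guessing above limits, no scatter).
Such listeners produce bit-identical outcomes across sessions, which pins
the test–retest machinery: all intraclass correlations are exactly 1 and
all standard errors of measurement exactly 0.

## Analysis stage

Test–retest reliability uses the two-way absolute-agreement single-measure
ICC (the form that penalizes systematic session biases) with
SEM = pooled SD × √(1 − ICC). The exploratory stage mirrors the standard
workflow: Spearman correlations with pairwise deletion (t-approximation
p-values; exact below 15 pairs), parallel analysis against 500
standard-normal surrogate datasets at the 95th percentile, and
maximum-likelihood factor analysis with varimax rotation via
`stats::factanal()` (restarted from random loadings with a firmer
uniqueness floor when a near-singular table defeats the default start).
The reduced outcome record keeps all 28 computed variables; the 26-variable
analysis set drops the two high-frequency modulation outcomes (`fSTM_4k`,
at or near floor for most impaired listeners, and its screening
counterpart `sSTM_4k`), which is how the published 26-variable count is
reached. `read_bear3_dataset()` validates that schema on any CSV, so a
deposited outcome table can be dropped into the same pipeline.

## Numerical choices

* Levels are digital dB re RMS 1.0 = 100 dB; absolute SPL calibration is a
  configurable offset table and out of scope.
* Noise synthesis shapes complex Gaussian spectra (PSD ∝ 1/ERB(f) inside
  the band for TEN) and is reproducible from (spec, seed); every stochastic
  routine takes a seed and derives sub-seeds via a 31-bit string hash
  (`derive_seed()`), so whole cohort studies are bit-reproducible.
* Instantaneous frequency comes from the analytic-signal phase derivative
  (FFT Hilbert transform); onset/offset ramps are excluded before
  summarizing.
* Tracked values stay continuous; nothing is rounded until reporting.
* The broken-stick and two-asymptote fits are Nelder–Mead least-squares /
  maximum-likelihood with multiple starts (the kinked and plateau-limited
  surfaces have local minima); tolerances 1e-10…1e-12.
* Repetition policy: two runs by default; an estimate more than three
  scaled median absolute deviations from the run median triggers one extra
  run (at most two); runs that died at a tracking bound count as invalid,
  and an outcome with no valid runs is missing. With exactly two runs the
  scaled-MAD rule cannot fire (both deviations equal the half-range), so
  extra runs in practice follow genuinely inconsistent triples.

## Problem sizes used by the test suite

The packaged tests audit convergence with 30–100 seeded tracks per claim,
parameter recovery on a 50-listener default cohort, reliability on
10–12-listener retest cohorts, and the factor machinery on 300 × 12
synthetic tables (20 replicates). These sizes keep the full suite in the
low minutes on one core while leaving Monte-Carlo margins comfortably
inside the asserted tolerances.

## Known limitations

* Speech tests are Bernoulli abstractions; no corpus audio is rendered.
* The diotic-contour rendering of the dichotic-pitch test is a documented
  guess (see above).
* Audiogram shapes cover the flat-to-sloping standard family only; rising
  or notched audiograms are outside the generator (though any audiogram can
  be given to `listener_profile()` directly).
* The SIAM equilibrium is displaced from the nominal target by the
  catch-trial correction (≈ 0.2 dB under defaults); tests tolerate this.
* Bayesian adaptive procedures are not implemented; the observer/track
  interfaces are the intended extension point.
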