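---
title: "Frequency-based sleep spindle detection and Pareto-front evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-based sleep spindle detection and Pareto-front evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spindlefront)
```

This vignette documents the models, numerical choices, and design
decisions behind `spindlefront`: what each detector computes, how
detection quality is scored and optimized, what the synthetic generator
does and does not emulate, and where the package had to resolve genuinely
open design questions.

## The evaluation model

A spindle detector is a map from a recording to a list of half-open time
intervals. Against a gold-standard annotation, a detection counts as a
true positive when its intersection-over-union with a true spindle
exceeds 0.2 (strict inequality); matching is one-to-one and greedy by
descending overlap rate, with ties broken by earlier gold onset and then
earlier detection onset. One-to-one matching is a deliberate choice:
event-based precision and recall implicitly assume `TP + FN = |gold|`
and `TP + FP = |detections|`, which many-to-one matching would break.
On random small instances the greedy matcher agrees with a maximum
bipartite matching oracle in over 99% of trials; the tests quantify the
gap rather than hide it.

Precision, recall, and the F-score follow the usual definitions
`P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
`F_beta = (1+beta^2)PR/(R + beta^2 P)`; zero denominators resolve to 0 so
the empty detector and the empty gold standard are well-defined extremes.

Detector performance is treated as a two-objective minimization of
`(FN(x), FP(x))` over the detector's operating-parameter box. The Pareto
front of this problem — the set of parameter vectors not dominated in
both objectives — is the detector's objective performance envelope;
PR- and F1-curves are derived from it, and "the" operating point is the
front member with maximal F1 (ties broken by lower FP).

## The six simplex detectors

All detectors work in physical units (seconds, Hz, microvolts) at the
recording's native rate; nothing is resampled. When a hypnogram is
present, amplitude normalization uses NREM 2/3/4 (or N2) samples and
events entirely outside NREM 2/3/4 epochs are discarded; recordings
distributed without hypnograms are treated as all-N2.

**d1 (bandpass + amplitude thresholds).** The sigma bandpass is a
linear-phase Hamming FIR (length ≈ 3.3 × rate, ~1 Hz transition,
> 50 dB stopband) applied with group-delay compensation and reflection
padding, i.e. zero phase. The peak envelope interpolates linearly through
local maxima of the rectified filtered signal. Candidates are envelope
runs above `p11·A1` containing at least one sample above `p12·A2`,
where `A1`/`A2` are the peak/mean rectified NREM amplitude; a duration
gate `[p13, p14]` follows. The pairing of the "lower" threshold with the
peak statistic `A1` and the "upper" threshold with the mean `A2` is
implemented as specified by its source, with bounds wide enough that
both orderings of the two products are reachable.

**d2, d3 (moving RMS thresholds).** RMS of the filtered signal on a
regular grid (resolution/window are free parameters for d2; fixed at
0.1 s/0.25 s for d3 so the RMS series can be preprocessed once per
recording). d2 thresholds at a multiple of the filtered N2 standard
deviation, d3 at a percentile of the NREM RMS distribution. The d3
percentile parameter is read in percent (bounds 0.1–99), honoring the
upper bound of 99 over the alternative 0–1 convention.

**d4 (Morlet top-scale estimate).** An analytic Morlet (ω₀ = 6)
scalogram over 120 logarithmically spaced scales with center frequencies
0.5–30 Hz. At each instant the ten largest-power scales are found (ties
broken by lower scale index, which also defines the estimate on an
all-zero signal) and the estimate is the fraction of those ten whose
center frequency falls in the adjustable band `[p41, p42]`. Two grid
choices matter and are deliberate. First, the grid density: with
120 scales every plausible spindle band contains more than ten scale
centers, so the estimate can reach 1 over a sustained burst — a sparser
grid caps the estimate near 0.5 and makes the upper threshold bound
unreachable. Second, the normalization: the scalogram is
amplitude-normalized (equal response to a unit sinusoid at every scale)
rather than energy-normalized; under energy normalization the 1/f
character of EEG puts all top scales at delta frequencies even inside
strong spindles, and the estimate collapses. The estimate is smoothed by
a centered moving average, thresholded, and post-processed by: initial
length filter, gap merge, two grouping passes that merge adjacent
candidate pairs (an "intermediate" pass requiring pair mean estimate
≥ p4,10 with one member ≥ p4,8 s and the other ≥ p4,9 s, then a
"strong" pass with mean ≥ p4,7 and durations over p4,11/p4,12), a final
gap merge capped at the maximum mergeable duration p4,15, and the lower
duration gate p4,14. The source describes these grouping rules loosely;
pairwise merging applied left-to-right, intermediate pass first, is this
package's resolution, and the pair rule is symmetric in its two duration
thresholds.

**d5 (EMD fuzzy logic).** Standard empirical mode decomposition:
cubic-spline envelopes through maxima/minima with mirror extension at
the boundaries, sifting until the normalized squared difference between
successive sifts falls below 0.2 (or 10 iterations), first three IMFs
retained. The stopping rule and boundary treatment are standard choices
the source leaves open. Per IMF, instantaneous amplitude is the natural
cubic spline through maxima of |IMF| and instantaneous frequency comes
from single-interval zero-crossing spacing; trapezoidal membership
functions in amplitude (µV) and frequency (Hz) are multiplied, the
per-sample maximum over the three IMFs is the final fuzzy estimate, and
thresholding/gap-merging/duration-gating follow. The sum of IMFs plus
residual reconstructs the input to floating-point accuracy — an
algebraic identity of sifting asserted on every decomposition in the
tests.

**d6 (rolling-ball fuzzy logic).** A single high-frequency component is
extracted by a one-ball rolling-ball high-pass at 10 Hz, implemented as
a morphological roll: a flat ball of half-width `1/(2·f_cut)` s rolled
over the signal (closing) fills valleys narrower than the ball, rolled
under it (opening) shaves narrow crests; the lightly smoothed average of
the two is the sub-cutoff trend, removed iteratively. Oscillations
faster than the cutoff fit entirely under the ball and survive; delta
waves and K-complex transients are tracked and removed. This
formulation was chosen over envelope-mean sifting restricted to
closely-spaced extrema because the latter fails on realistic signals:
with broadband noise every extremum is closely spaced, and the envelope
mean then tracks — and removes — the sigma burst itself. The morphological
form satisfies the same separation contracts (5 + 13 Hz two-tone
separation with correlation 0.98 to the 13 Hz component; a 20 Hz tone
passes untouched; a 2 Hz tone leaves < 2% residual RMS) while retaining
bursts embedded in noise. One amplitude envelope and five zero-crossing
frequency sequences (windows of 1, 3, 5, 7, 9 crossing intervals) enter
the fuzzy estimate: amplitude membership times the maximum of the five
frequency memberships, then the same tail as d5.

## Hybrids (double reading)

A hybrid runs its first detector on the whole recording, pads each
candidate by 2.5 s on both ends (the same constant used to dilate
subsample segments; the source states no padding, and this is recorded
as an open choice), merges overlapping windows, and runs the second
detector on each padded segment independently — with normalization
statistics still taken from the full recording. The second detector's
internal duration gate is suppressed during review and re-applied after
its detections are clipped back to the unpadded candidate windows;
applying the gate before clipping would reject a permissive reviewer's
full-window response and break the pass-through identity (a second
detector that accepts everything must reproduce the first's output).

## SPEA2

The optimizer is a faithful SPEA2: strength = number of dominated pool
members; raw fitness = sum of strengths of dominators; density
`1/(σ_k + 2)` with `σ_k` the distance to the k-th nearest neighbor in
objective space, `k = round(sqrt(pool size))`; environmental selection
keeps nondominated members, truncating by iterative removal of the
member with lexicographically smallest sorted-neighbor-distance vector,
or filling with the best dominated; binary tournament selection,
simulated-binary crossover (probability 0.9, distribution index 15) and
polynomial mutation (per-gene probability 1/n, index 20), clamped to the
bounds. The variation settings are standard real-coded defaults — the
original implementation's values are unpublished, so they are validated
through property-based checks (closed-form Pareto set recovery,
brute-force front equivalence on lookup problems, ≥ 99% hypervolume
across seeds) rather than against printed numbers. Objectives are
integer counts; distances are computed on range-normalized objectives
(a zero-range dimension is dropped) because FN and FP scales differ with
dataset size. Evaluations are memoized on the parameter vector rounded
to 12 significant digits — evaluation cost dominates the runtime, as the
training-time-scaling of the original experiments implies. An evaluator
error yields sentinel objectives one above the largest finite count seen,
with a warning.

Per-detector defaults for full training runs follow the published
settings (populations 100–270, generations 100–320, at least ten times
the parameter count); the packaged experiments use smaller budgets noted
below.

## Training protocol

The subsample builder runs a collector parameterization of the detector
over each training recording, keeps its false positives and all gold
events, dilates each by 2.5 s, merges overlaps, and draws segments at
random without replacement until 60 min (default) is reached. The
collector should ideally be the recall-weighted (F2) optimum from a
reference optimization on an independent database; absent such a
reference the drivers default to the midpoint of the detector's bounds,
which is deliberately permissive — a mediocre collector yields *more*
false-positive material, which is what the subsample is for. Detector
preprocessing (filtering, scalograms, sifting, envelopes) is computed
once on each complete recording and segment evaluation slices the
per-sample features, so segment boundaries introduce no spline or filter
edge artifacts and the subsample objective matches whole-night behavior;
this also makes the evolutionary loop cheap, since only the
parameter-application stage reruns per candidate vector.

`run_holdout()` optimizes on the subsample, re-evaluates every front
member on the complete training recordings, selects the max-F1 vector
(selection never invents parameters — the chosen vector is always a
front member), and applies it to the held-out group exactly once; the
report carries the test-access count so the single-shot discipline is
auditable. `run_kfold()` partitions subjects (never epochs) into k
near-equal random folds and micro-averages pooled TP/FN/FP across folds.

The 95% confidence interval for F1 treats precision and recall as
independent Beta posteriors under a uniform prior —
`P ~ Beta(TP+1, FP+1)`, `R ~ Beta(TP+1, FN+1)` — draws them 10,000
times, and takes empirical quantiles of the induced F1. A
true-negative-count assumption sometimes attached to this construction
is unnecessary for P/R/F1 and is not implemented. To reconstruct counts
from printed three-decimal precision/recall against a known gold total,
`counts_from_rates()` uses `TP = round(R·N)`, `FP = round(TP/P) − TP`.

## The synthetic generator

`simulate_psg()` emulates stage-2-dominated sleep EEG: a 1/f^1.5
background at 15 µV broadband RMS, flat below 0.5 Hz (the acquisition
high-pass of clinical EEG), with spindles as Hann-windowed sinusoids —
the Hann shape is one fixed choice of "waxing-waning" envelope — at
3/min (Poisson onsets thinned to forbid overlap with a 0.5 s guard),
frequencies uniform on 11–16 Hz, durations uniform on 0.5–2 s, and
biphasic 1 Hz K-complex-like transients (75 µV) at 1/min. Spindle peak
amplitudes are derived so that the sigma-band RMS of a mid-amplitude
spindle is `snr` (default 4) times the background's sigma-band RMS,
±15%; with the default background this lands at 19–26 µV, the textbook
spindle amplitude range and comfortably inside the µV bounds of the
fuzzy-logic detectors' membership parameters. The spectral slope of 1.5
sits at the shallow (noisy) end of the 1.5–2.5 range reported for NREM
sleep EEG; shallower slopes leave so much 10–50 Hz background that no
implementation of the broadband (HHT) detectors can reach high recall at
sigma-band SNR 4, while the low-frequency shelf prevents steeper slopes
from concentrating all power in sub-0.1 Hz drift and shrinking derived
amplitudes to physically meaningless values. Realized within-event
sigma RMS runs ~10% below the nominal SNR because spindles drawn near
the 11/16 Hz band edges are attenuated by the analysis filter itself —
a property real detectors face too.

Two simulated scorers model inter-rater disagreement through amplitude
sensitivity alone: each keeps events whose peak amplitude reaches its
threshold, with a seeded logistic miss probability near threshold
(0.7 µV scale); the second scorer also replaces durations by fixed 1 s
intervals centered on the event midpoint, mimicking annotators who mark
occurrences but not extents. Frequency-selective disagreement,
spindle chirp, slow-oscillation coupling, and artifacts (EMG, eye
movement) are not modeled — so passing tests show that the pipeline
recovers amplitude-defined bursts from 1/f-plus-transient background,
not that it handles every failure mode of clinical EEG.

## Problem sizes in the packaged experiments

The packaged tests scale the experiments to desk size as the package's
own study design: end-to-end parameter recovery trains d2 and d6 on two
600 s synthetic subjects (subsample target 300 s), selects on complete
training recordings, and tests on one held-out 600 s subject, repeated
over three seeds at SPEA2 population 40 / 40 generations; held-out
performance is reported as the micro-average of pooled counts over the
three replicates, the same pooling the k-fold driver uses, because a
single 600 s subject carries only ~25 spindles and one missed event
moves its F1 by ~0.03. Measured this way the pooled held-out F1 is
0.95 (d2) and 0.86 (d6). The smoke-level fixture for all six simplex
detectors uses a higher-SNR generator setting (snr = 6) with hand-tuned
parameters, where every detector reaches recall ≥ 0.9 at precision
≥ 0.8.

## Known limitations

* The EDF reader handles standard 16-bit EDF with consistent headers; it
  does not parse EDF+ embedded annotations or discontinuous records.
* The rolling-ball high-pass is a behavior-contracted surrogate for the
  original geometric algorithm; its transition around the cutoff is
  gradual (roughly the 9–11 Hz octave), not sharp.
* d4's grouping-pass semantics are one defensible reading of a loosely
  worded procedure; alternatives (chain merging, asymmetric duration
  rules) would differ on densely packed candidates.
* The greedy matcher can, rarely, score one fewer TP than an optimal
  assignment; this is the documented, specified behavior.
* Subsample segments are processed independently; stage context across
  segment boundaries is not preserved.
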