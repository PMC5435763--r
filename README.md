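# spindlefront

Sleep spindles are brief (≥ 0.5 s) bursts of 11–16 Hz ("sigma band") EEG
activity with a waxing-and-waning envelope, a defining feature of NREM
stage 2 sleep and a biomarker of interest in aging, memory consolidation,
and several neurological disorders. Automatic spindle detectors abound,
but their reported performance is hard to compare: every detector has
several operating parameters, and a single default operating point says
little about what the algorithm could do against a given reference
("gold standard") annotation.

`spindlefront` evaluates and improves spindle detectors in a
multi-objective optimization frame. A detector with parameter vector
**x** is scored event-by-event against a gold standard: a detection D
matches a true spindle SS when their overlap rate

    R_ov = |SS ∩ D| / |SS ∪ D| > 0.2

(one-to-one greedy matching), giving counts TP, FN, FP and

    P = TP/(TP+FP),  R = TP/(TP+FN),
    F_β = (1+β²) P R / (R + β² P).

Minimizing the two competing objectives F(**x**) = (FN(**x**), FP(**x**))
has no single optimum; the package traces the Pareto front of
nondominated parameter vectors with SPEA2 (Strength Pareto Evolutionary
Algorithm 2) and derives PR-curves, F1-curves, and the max-F1 operating
point from the front.

The package provides, per module:

* **I/O** — a 16-bit EDF reader/writer, plain-text spindle annotation and
  hypnogram files, and by-sample ↔ by-event conversions used for
  union/intersection gold-standard fusion.
* **Detectors** — six classic frequency-based detectors: bandpass +
  amplitude thresholding (`d1`), two RMS thresholding variants
  (`d2`, `d3`), a Morlet-wavelet top-scale probabilistic estimate (`d4`),
  and two Hilbert–Huang fuzzy-logic detectors built on EMD sifting (`d5`)
  and one-ball rolling-ball high-pass sifting (`d6`); plus three
  sequential "double reading" hybrids (`d7` = d6→d2, `d8` = d2→d6,
  `d9` = d4→d6) in which the second detector reviews only the first's
  padded candidates.
* **Scoring** — overlap-rate matching, P/R/F-beta, scorer fusion.
* **Optimization** — `spea2()` with box bounds (the published per-detector
  bounds ship as defaults), memoized objective evaluations, and
  `front_metrics()` for Pareto-front-derived performance curves.
* **Protocol** — detector-dependent 60-min subsample construction,
  hold-out and k-fold cross-validation drivers with an auditable
  touch-test-once discipline, and Monte-Carlo 95% confidence intervals
  for F1 from Beta-distributed precision and recall.
* **Synthetic PSG** — a seeded generator of NREM-like recordings with
  planted spindles, K-complex confounders, and two simulated scorers, so
  the whole pipeline is testable without clinical data.

## Worked example

```r
library(spindlefront)

sim <- simulate_psg(sim_config(duration = 600, seed = 42))
sim
#> <psg_sim> 600 s @ 100 Hz: 28 spindles, 14 K-complexes, sigma bg RMS 2.4 uV

spec <- detector_spec("d2", c(0.1, 0.25, 2, 0.4, 2.5))
det <- detect_spindles(sim$rec, spec, sim$stages)
m <- match_events(sim$truth[, c("onset", "duration")], det)
m
#> <match_result> TP=27 FN=1 FP=0
round(prf_metrics(m), 3)
#> precision    recall   f_score
#>     1.000     0.964     0.982
```

27 of the 28 planted spindles are recovered with no false detections at
these hand-set parameters. Optimizing the detector instead of fixing
them:

```r
sf <- spindle_features(sim$rec, spec, sim$stages)
gold <- sim$truth[, c("onset", "duration")]
evaluate <- function(x) {
  mm <- match_events(gold, detect_with_features(sf, x))
  c(mm$fn, mm$fp)
}
fr <- spea2(evaluate, spec$lower, spec$upper,
            spea2_control(pop_size = 40, max_gen = 40, seed = 1))
summary(fr, n_gold = nrow(gold))
#> SPEA2 Pareto front: 1 members, 5 parameter(s), 1514 evaluations
#> max-F1 operating point: P=1.000 R=1.000 F1=1.000 (FN=0 FP=0)
```

The front spans the FN/FP trade-off; here the optimizer finds parameter
vectors that separate planted spindles from background perfectly on the
training recording. `run_holdout()` and `run_kfold()` wrap the honest
version of this experiment: train on subsampled recordings, select the
max-F1 front member on complete training nights, and evaluate exactly
once on held-out subjects.

A thin command-line front end over the same functions is installed at
`inst/cli/spindlefront` (subcommands `simulate`, `detect`, `score`,
`optimize`, `cv`, `ci`).

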