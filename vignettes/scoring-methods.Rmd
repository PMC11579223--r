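---
title: "Scoring event-related skin conductance responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring event-related skin conductance responses: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrscore)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are.  It covers the preprocessing chain, the
trough-to-peak detection rules and their edge cases, the agreement
statistics, the synthetic-session generator and what passing tests on it do
and do not establish, and the design decisions that were genuinely open.

## Signal model and preprocessing

A skin-conductance recording is modelled as a slowly varying tonic level
(SCL) plus event-related phasic responses (SCRs) plus noise and movement
artifacts.  Scoring operates on a high-passed, resampled copy of the trace:

* **High-pass filter.** A linear-phase FIR high-pass with a 0.5 Hz cutoff
  (−6 dB point) removes the tonic level and slow drift.  The realization is
  a windowed-sinc: the ideal low-pass impulse response truncated by a
  symmetric Hamming window, normalized to unit DC gain, and spectrally
  inverted (a delta minus the low-pass).  This gives *exactly* zero DC gain.
  The default length is 3001 taps at 1000 Hz (a 3 s window), scaled in
  proportion to the sampling rate so the realized analog response — and
  hence every scored amplitude — is rate-independent.  The length was chosen
  so that the filter meets a concrete contract, verifiable from the tap
  sequence: 2 Hz content passes within 5% while 0.05 Hz drift is attenuated
  below 0.1 (a short 251-tap filter at 1000 Hz, for comparison, has a
  transition band more than ten hertz wide and passes 0.05 Hz almost
  unattenuated, which defeats the purpose of filtering).  The filter is
  applied by FFT convolution on a reflect-padded copy of the trace with the
  group delay of (taps − 1)/2 samples removed, so trough and peak latencies
  are unbiased and the first trial is not swallowed by a start-up transient.
* **Segmentation.** One window of `segment_len_s` seconds is cut after each
  event marker.  The default is 18 s: the latest permissible peak time is
  the TIR window end (CS 6 s + 4 s) plus the 4 s peak horizon = 14 s, and
  peak *confirmation* (below) needs a few further seconds of decay tail.
  Scoring never reads past the next event's onset, so a generous segment
  length costs nothing at realistic inter-trial intervals.  A segment
  reaching past the end of the recording is truncated and any latency
  window falling outside it yields a `missing_artifact` record.
* **Resampling.** The segment is reduced to 50 Hz by contiguous time-bin
  means (each output sample is the mean of the input samples whose
  timestamps fall in its 20 ms bin).  Bins are defined on the time axis, so
  non-integer rate ratios work.  Bin means, not decimation or
  interpolation, so single-sample noise spikes are averaged down rather
  than sampled.

An important measured fact: this 0.5 Hz high-pass is *not* amplitude
transparent for SCRs.  A biexponential response with a 0.75 s rise and 3 s
decay keeps only about a third of its trough-to-peak amplitude after
filtering, and the filter adds a post-response undershoot.  Scored
amplitudes are therefore on the filtered scale — consistent across trials,
raters and sessions, which is what agreement statistics need, but not equal
to the unfiltered rise.  The simulator's ground truth accounts for this
explicitly (below).

The pipeline order is filter → segment → resample.  A configuration switch
(`order = "resample_first"`) runs resample → filter instead; because the
filter realization is rate-consistent, the switch changes no scored
amplitude by more than 2% on noise-free synthetic sessions (a regression
property in the test suite).

## Trough-to-peak detection

All scoring reduces to one rule set on the 50 Hz segment
\(x_1,\dots,x_n\), with detection threshold \(\delta\) (default 0.02 µS,
user-adjustable) and latency window \([s, e)\):

1. A candidate is a sample pair \(i < j\): trough (response onset) and
   peak.
2. **Window membership is decided by the onset**: \(t_i \in [s, e)\),
   half-open, so an onset exactly on a boundary belongs to the later
   interval.  The peak may complete after the window: \(t_j \le e + h\)
   with horizon \(h = 4\) s by default, clipped at the segment end and the
   next event onset.
3. **Amplitude rule**: \(x_j - x_i \ge \delta\).
4. **Clean rise**: every strictly interior sample lies strictly between
   \(x_i\) and \(x_j\).  This makes the trough the *last* sample at the
   pre-rise minimum and the peak the *first* sample at the maximum — on a
   flat baseline the onset is the point where the rise actually begins, so
   a response onsetting early in SIR can never be claimed by the FIR
   window via a tied plateau sample.
5. **Flank validation**: walking left from the trough, an anchor
   \(\ge x_i + \delta\) must appear before any sample below \(x_i\); the
   segment start counts as an anchor (a response already rising when the
   segment begins is scoreable, which matters for FIR onsets shortly after
   CS onset).  Walking right from the peak, the trace must fall to
   \(\le x_j - \delta\) before any sample above \(x_j\); the segment end
   does **not** confirm — a monotone rise has no peak.
6. Among valid pairs, the one with the largest amplitude wins (the most
   prominent peak with its deepest connected trough).  Exact ties go to the
   earliest trough, then the earliest peak, so results are deterministic.
7. No valid pair → the trial × window is a non-response, scored 0 with
   status `zero`.  Statuses `zero` and `missing_artifact` are distinct:
   zeros enter averages and agreement statistics as 0; missing/artifact
   records are excluded pairwise.

Consequence of rule 6 worth knowing: when a response runs into a second,
higher response without a \(\delta\)-deep dip in between, the two merge
into a single trough-to-peak event credited to the window containing the
onset.  This mirrors how a human scorer reads a "peak shoulder", and it is
the documented behaviour on merged SCRs.

`find_extrema()` exposes the underlying delta-prominence walker (single
left-to-right scan tracking the running extremum).  Following the
confirmation logic, a trough only becomes definitive once a subsequent peak
is confirmed; the pending final extremum is emitted with
`confirmed = FALSE` so a reviewer can see a trailing, not-yet-validated
trough.

Degenerate inputs: flat and monotone series yield no extrema and score
zero; series shorter than three samples yield no extrema; windows that are
(partly) outside truncated data yield `missing_artifact`.  Window
membership comparisons carry a 1 ns-scale epsilon so grid-aligned onsets on
an exact boundary are classified by the half-open rule, not by float
round-off.

The detector is verified against an independent brute-force oracle — an
exhaustive scan over all sample pairs applying rules 1–6 literally — with
exact equality required, on hundreds of randomized segments with up to
three overlapping responses and noise.

## Manual review

Interactive dragging of markers is replaced by two programmatic routes:
`apply_overrides()` takes a table of corrected trough/peak coordinates (or
`zero` / `missing_artifact` re-classifications), recomputes amplitudes and
revalidates every invariant; alternatively the annotation CSV written by
`write_scores()` is hand-editable and `read_scores()` revalidates on
re-import, rejecting rows whose coordinates or status are inconsistent.
Overridden records carry status `adjusted` so the provenance of every
number is visible in the output file.

## Agreement statistics

* `icc_oneway()` computes the one-way random-effects agreement ICC from the
  direct sums of squares, with \(F = MS_B/MS_W\) on \((n-1, n(k-1))\)
  degrees of freedom.  The one-way (agreement) form charges systematic
  rater offsets to error, which is the conservative choice for method
  comparison; two-way consistency variants are deliberately out of scope.
  Degenerate input (all cells identical) is defined as ICC 1 with a
  warning; rows with missing cells are dropped pairwise-complete with a
  message.  The implementation is tested to 1e-10 against `stats::aov`.
* `bland_altman()` reports the mean difference, its 95% CI, and limits of
  agreement at mean ± 1.96 × sample SD (n − 1 denominator).  The *limits*,
  a dispersion band, do the outlier flagging — a CI of the mean narrows
  with n and would flag nearly everything at large n; both are reported.
* `average_scores()` aggregates per participant × interval (and any further
  grouping columns), counting non-responses as 0 and excluding
  missing/artifact trials; `agreement_report()` wires pairing, ICC and
  Bland–Altman together for trial-by-trial or averaged comparisons.  Both
  groupings are exposed because the field uses both; the report labels
  which one was used.
* `pareto_table()` tabulates reviewer-assigned discrepancy labels in
  descending order with cumulative percentages; ties break alphabetically
  for stable output.  Categorization itself is human judgment; the package
  only counts.

## The session simulator

`sim_design()` + `simulate_session()` emulate a differential
fear-conditioning paradigm: two CSs (CS+/CS−), 4/8/24 trials per CS across
habituation/acquisition/extinction, 6 s CS duration, ITIs jittered
uniformly in 10–14 s, sampled at 1000 Hz, with habituation and acquisition
in one continuous recording and extinction in a second.  On top of the
paradigm sit invented-but-fixed generative choices, all config-exposed:

* biexponential SCR kernel (difference of exponentials, rise 0.75 s, decay
  3 s, peak-normalized) — the canonical gradual-rise/long-tail shape;
* per-trial amplitudes: interval means FIR 0.30 / SIR 0.20 / TIR 0.40 µS
  for CS+, a 0.6 gain for CS− from acquisition on, exponential habituation
  with an 8-trial constant, lognormal trial-to-trial variability
  (sdlog 0.25), and a 0.85 response probability;
* response onsets jittered uniformly within their latency window but kept
  0.2 s away from the half-open boundaries (boundary behaviour is tested
  separately and deliberately, not by accident of jitter), snapped to the
  50 Hz scoring grid;
* tonic level 5 µS, two slow sinusoidal drift components (97 s and 211 s
  periods, 0.5 µS scale), Gaussian noise (SD 0.005 µS), and step/spike
  artifacts at 0.3 per minute.

`write_session()` emits the session as columnar CSV or a classic v5
MAT-file, both round-tripped by `read_session()`, so the file readers are
tested against fixtures the package generates itself.

### Ground truth on the processed scale

Because the 0.5 Hz filter is not amplitude transparent, truth is defined as
what an ideal scorer applying the stated rules would read off the
*noise-free, preprocessed* trace — measured by plain argmin/argmax scans on
the whole-session clean trace (no segmentation, no walker, no pair
enumeration, so it stays mechanically independent of the detector): the
trough is the deepest point from the window start to the response's local
peak; the peak is extended along the envelope up to window end + horizon,
which reproduces the merged-response reading of rule 6.  Truth also records
the two confirmation quantities the scoring rules depend on: the post-peak
drop before the trace re-exceeds the peak, and the trough's left-flank
anchor rise.

Each programmed response is then classified: **detectable** when amplitude,
confirmation drop and left anchor all clear the threshold with a 10%
margin; **undetectable by construction** when the amplitude falls 5% short
of the threshold; and a thin **borderline** band in between that is
asserted neither way — at 50 Hz discretization a response within a few
percent of the detection boundary can legitimately land on either side, and
pretending otherwise would turn an honest test into a coin flip.  The
margins come from the observed discretization error scale (≤ 0.2% on
amplitudes) with an order-of-magnitude safety factor, fixed before the
acceptance tests were frozen.

What passing these tests shows: the detector finds exactly the structures
the rules define, assigns them to the right windows, and measures them to
within a fraction of a percent on clean data; the statistics recover known
agreement levels.  What it does not show: robustness to real skin — contact
artifacts, electrode drift nonlinearity, respiration-coupled fluctuations,
overlapping spontaneous SCRs — which is precisely the part the
semi-automated design delegates to a human reviewer.  The simulator's
artifacts are crude step/spike injections meant to exercise the
`missing_artifact` workflow, not a physiological artifact model, and the
respiration channel is a placeholder for visual inspection workflows only.

## Problem sizes and test budget

The suite scores full simulated sessions (24 and 48 events at 1000 Hz),
runs 200-segment detector-vs-oracle sweeps, 100-matrix ICC cross-checks,
and 1000-pair Bland–Altman coverage, completing in well under a minute;
`scripts/acceptance.R` repeats these end to end from a single seed.  These
sizes were chosen to keep full verification cheap enough to run on every
change while still exercising every rule path (multi-response segments,
merges, truncation, boundaries, missing data).

## Known limitations

* Only classic (v5) MAT-files are read, not the HDF5-based v7.3 dialect;
  columnar text is the universal fallback, and variable names/marker
  encodings are explicit user configuration because acquisition software
  disagrees on both.
* Scored amplitudes live on the high-passed scale (see above); compare them
  across analyses only under the same preprocessing configuration.
* Entire-interval (EIR) scoring, baseline-correction scoring and
  deconvolution-based estimation are out of scope by design.
* The trial-by-trial agreement pairing assumes both score sets index the
  same trials of the same recording; cross-study pooling is the caller's
  responsibility (`average_scores()` accepts arbitrary grouping columns for
  that reason).
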