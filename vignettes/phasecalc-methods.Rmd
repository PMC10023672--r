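---
title: "Methods: phase-specific calcium imaging and behaviour analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-specific calcium imaging and behaviour analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecalc)
```

# Scope

`phasecalc` implements the analysis chain used to separate *seeking*
(appetitive) from *consummatory* neural activity in lateral hypothalamic
LepR neurons recorded during feeding behaviour: fibre-photometry
preprocessing, derivative-based neural-onset detection, single-cell phase
phenotyping from micro-endoscope trace matrices, slice-imaging and sIPSC
analysis rules, pose-based extraction of consummatory behaviour, a
population-composition simulation, and single-cell RNA-seq quality-control
rules. Every stage is exercised end to end on seeded synthetic data with
stored ground truth; this vignette explains the models, the tunable
parameters, and the choices made where the published description left the
procedure open.

# Photometry preprocessing

Two channels are recorded: the calcium-dependent 465 nm signal and the
calcium-independent 405 nm isosbestic signal. Motion and bleaching act
multiplicatively and (to first order) identically on both, so the ratio
correction

$$\text{corrected} = \frac{F_{465} - F_{405}}{F_{405}}$$

cancels any shared multiplicative envelope exactly; `correctIsosbestic()`
refuses non-positive 405 nm samples, for which the ratio is undefined.
Correction is applied at the native rate and *then* decimated
(`decimateToRate()`, mean-binning with bin width `round(rate/25)`), because
artifact cancellation is a per-sample identity. Mean-binning doubles as the
anti-alias smoother; when the computed bin width is 1 (native rate below
~37.5 samples/s) the trace is returned unchanged.

`alignTrials()` cuts the corrected trace into trials around a behavioural
event (t = 0) and Z-scores each trial against its own baseline window,
default −10 to −5 s: $Z = (x - m)/\sigma$ with $m, \sigma$ the baseline
mean and SD. Exclusion rules are flags, never silent drops: trials longer
than the per-paradigm limit (15 s multi-phase, 10 s otherwise, 25 s
endoscope), trials whose window leaves the recording, and trials with a
zero baseline SD (`degenerate_baseline`). Degenerate baselines exclude
rather than abort so batch runs survive pathological trials. Heatmap rows
are min–max normalised per trial; a constant row maps to zeros with a
warning rather than NaN so matrices stay plottable.

# Neural-onset detection

Onset is defined as the time at which the third derivative ("jolt") of the
fitted activity is maximal: for a firing rate that ramps up linearly from
the true onset, convolved with a causal calcium kernel, the continuous
jolt peaks exactly at the ramp start, which motivates the definition.

`fitPolynomial()` fits by least squares on a scaled abscissa
($s = (t-c)/h$) for conditioning and returns coefficients in original time
units. Degrees below 3 are refused (the third derivative of a quadratic is
constant). The automatic degree takes the grid 4–9 and selects the first
degree whose fit is already essentially exact or for which one more degree
improves the RMS residual by less than 5% — a reproducible stand-in for a
visual "best fit" choice.

`detectOnset()` reports the analytic global argmax of the jolt over the
search window (default −10 to 0 s relative to behavioural onset), found
through the roots of the fourth derivative rather than a grid scan. Two
flags guard the result: `edge` when the argmax sits on the window boundary
(boundary maxima are artefacts of polynomial edge oscillation and are
never accepted into summaries), and `flat` when the jolt's range is
negligible relative to the data scale (the threshold scales with the data
so the flag is invariant under affine rescaling of the trace).

In practice the *global* argmax of a noisy fit lands on the boundary in
the large majority of trials, which is why the original procedure
restricted the maximum "around the neural onset" by hand.
`detectOnsetRobust()` is the declared reproducible surrogate for that
manual step: stage 1 takes, for each fit degree 6–8, the largest interior
local maximum of the jolt and medians the three estimates; stage 2 refits
with degrees 4–6 on a ±3.5 s window around the stage-1 estimate and
returns the median. The degree grids and window half-width were calibrated
on noiseless and low-noise synthetic ramps before being frozen; on the
synthetic study conditions (100 trials, onset lead 6 ± 0.5 s, channel
noise SD 0.5) the estimator recovers per-trial onsets with a mean absolute
error of roughly 0.3–0.5 s and a mean latency within ±0.2 s of truth.
`onsetLatencyStats()` summarises latencies (mean, SEM, empirical CDF) over
`ok`-flagged results only and reports how many flagged results were
excluded.

# Micro-endoscope phase phenotyping

Raw per-cell traces (the `Craw` output of constrained source extraction)
are Z-scored per trial against the −10..−5 s baseline (`zscoreCells()`);
endoscope trials longer than 25 s are excluded. When a baseline is exactly
constant — which happens only in noise-free synthetic data — the Z trace
is taken as the noise→0 limit (signed infinity where the trace departs the
baseline mean), flagged degenerate; this keeps noiseless ground-truth
recovery well defined without special-casing downstream rules.

A cell is *responsive* when the maximum of its trial-averaged Z over the
response window (0–10 s after behavioural initiation; the window is a
declared default because the published rule does not state one) strictly
exceeds 4σ. The four-way food-specificity classification combines three
food tests and one non-food test; response patterns not covered by the
four printed definitions (partial food responders) receive an explicit
fifth label `unclassified` rather than being forced into a class.

Phase scores are computed on the min–max normalised trace
$NF_0 = (C_\text{raw} - \min)/(\max - \min)$. The normalisation range is
taken over the union of the food and no-food sessions of a cell (both come
from one recording), so a cell silent in one session still has a defined
NF0 there; `nf0Normalize()` accepts the range explicitly and
`nf0Range()` computes the joint one. Averaged over included trials:

* seeking-score-1 `s1`: NF0 at food contact in food trials;
* seeking-score-2 `s2`: NF0 at the food-zone-arrival moment of no-food
  trials — the contact-equivalent moment, since no food exists to contact;
* consummatory score `c`: NF0 at the food-trial end minus `s1`.

The phase rule (`classifyPhase()`) is applied with strict inequalities: a
responsive cell is *seeking* iff `s1 > c` and `s2 > 0.4`; *consummatory*
iff `c > s1` or `s2 < 0.4`; exact ties are *ambiguous*. Non-responsive
cells are labelled as such regardless of scores.

# Slice imaging and sIPSC rules

`preprocessSlice()` drops the first 2 min of the recording (camera
bleach-in), Z-scores each cell against the −480..0 s pre-drug baseline,
fits a straight line to the slice-mean Z over that baseline and subtracts
it (extrapolated) from every cell, removing common photobleaching and
drift. `callExcited()` calls a cell excited iff its post-drug adjusted Z
strictly exceeds 4σ; decreases are not called. Note that with strictly
white per-frame noise and thousands of post-drug frames the strict
threshold admits occasional false positives — the rule is reproduced as
printed, not re-derived.

`sipscMetrics()` reports event frequency and mean amplitude over the
baseline and analysis (last post-drug minute) windows and each as percent
of baseline; a zero baseline frequency is an error because the
normalisation is undefined. `sipscInclusion()` keeps a neuron iff its
baseline frequency exceeds 5 Hz and the control-period change is within
20%. Which change the stability criterion refers to is genuinely ambiguous
in the source; it is therefore an explicit `controlChange` argument rather
than a hard-coded quantity.

# Pose-based consummatory extraction

Keypoints below the 0.9 likelihood cutoff are replaced by linear
interpolation between the nearest confident frames (held at the ends), and
flagged. A frame is consummatory iff all three posture criteria hold
(conjunction — the strictest consistent reading of the three listed
criteria, validated against scripted ground truth): front-paw distance
smaller than hind-paw distance (bottom view); y decreasing strictly from
tail base through the hind-paw midpoint to the front-paw midpoint (image
coordinates, y down); snout inside the food-zone polygon in both views,
boundary included. `extractBouts()` merges runs separated by at most
0.25 s and drops bouts shorter than 0.5 s (12 frames at 24 fps) — declared
defaults, configurable, as the published account reports bout counts
without stating segmentation rules. `successRate(S1, S2)` is
$S_2/(S_1+S_2)$.

# Population composition and scRNA QC

`vennSimulation()` reproduces the deterministic composition arithmetic:
with 1000 GABA neurons, 10% LepR, 8% food-specific overall and 63% of LepR
neurons food-specific, the counts are 100/80/63 and LepR neurons account
for 63/80 = 78.75% ≈ 79% of food-specific GABA neurons. Fractional counts
round half-to-even; parameter corners where the implied LepR food count
exceeds the total food count are refused as inconsistent.

`vennSimulationStochastic()` samples memberships per neuron under the Venn
structure: LepR with probability `pLepr`; food-specific with probability
`pFoodLepr` inside the LepR set and with the complement rate
$(p_\text{foodGABA} - p_\text{LepR} p_\text{foodLepR})/(1-p_\text{LepR})$
outside it, so every food-specific LepR cell is part of the food-specific
GABA denominator. Sampling numerator and denominator independently instead
would allow fractions above 1 and biases the expected ratio upward; the
subset-consistent decomposition is unbiased to ~1e-4 and converges to the
deterministic fraction.

The QC filter discards cells with <500 UMIs or >40% mitochondrial reads —
strict inequalities as printed, so boundary cells (exactly 500 UMIs,
exactly 40%) are kept. Mitochondrial genes are recognised by a
configurable name prefix (default `mt-`). Cluster neurotransmitter labels
compare per-cluster medians of Slc32a1 vs Slc17a6 with strict
inequalities; ties are `unclassified`. Clustering itself is an input, not
re-implemented.

# The synthetic-data generators

The generators define the simulated study conditions and are not tuning
knobs. Shared defaults: onset lead 6 s (SD 0.5 s), GCaMP-like
difference-of-exponentials kernel with 0.2 s rise and 1.5 s decay
(slow-indicator realism), transient amplitude 5 on a baseline fluorescence
of 10, additive Gaussian sensor noise, multiplicative artifact (two slow
sinusoids, gain 0.05) and exponential bleaching (−2×10⁻⁴/s) shared by both
photometry channels. The photometry generator runs at 1000 samples/s, a
typical acquisition rate ahead of the ~25/s decimation. Activity is a
linear firing-rate ramp from the neural onset to the behavioural onset,
convolved with the kernel in closed form; this shape's third derivative
peaks exactly at the ramp start, so the stored truth is the mathematical
signal onset the detector is defined to find.

Endoscope populations default to 25% seeking / 39% consummatory cells with
the remainder non-responsive. The `ambiguous` class defaults to zero:
under the strict-inequality phase rule, ambiguity requires exact score
ties, which are measure-zero in any noisy recording; a population with a
sizeable tie-built class would be an artificial construction, not a
realistic condition. Tie cells (linear ramps whose contact-moment NF0
exactly halves the end-of-trial NF0) can still be generated by setting the
proportion explicitly and are recovered exactly in noise-free tests.

Pose sessions script static consummatory and non-consummatory postures
(all three criteria true inside bouts, all three individually false
outside), with optional degradation of a fraction of keypoints below the
likelihood cutoff. Slice recordings share a linear bleach across cells
with responders ramping after drug delivery at t = 720 s. Count matrices
put ~3000 UMIs in clean cells and generate the designated low-UMI
(<500) and high-mitochondrial (>40%) cells, across one GABAergic and one
glutamatergic cluster.

What the generators do *not* emulate: cross-channel hemodynamic
differences, motion artifacts that differ between 465 and 405 nm,
source-extraction crosstalk between neighbouring cells, pose-estimation
identity swaps, ambient-correlated camera noise, or batch effects in
counts. Passing tests therefore validate the implemented rules and their
numerical behaviour, not robustness to every failure mode of real
recordings.

# Numerical choices and degenerate inputs

* Polynomial fits run on a scaled abscissa; coefficients are converted
  back exactly, and argmaxima come from `polyroot` on the derivative
  rather than grid scans.
* The `flat` jolt tolerance scales as `1e-8 × data range / half-width³`,
  making the flag affine-invariant; an exactly constant trace is flat by
  definition.
* σ = 0 baselines: excluded (photometry trials) or limit-valued and
  flagged (endoscope cells, where noiseless synthetic data must stay
  analysable).
* Constant heatmap rows → zeros + warning; constant NF0 cells → `NA` +
  degenerate flag, excluded from scoring.
* CSV writers append a `# rows=N` footer that readers verify, so silently
  truncated files fail loudly.
* All stochastic code paths take explicit integer seeds; identical
  parameters reproduce bit-identical outputs.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run: 100 photometry trials at
1000 samples/s (onset recovery), 100-cell endoscope populations at 10
samples/s with 6 trials per session (phase recovery, noiseless and at
noise SD 0.3), 40-cell slice recordings at 10 samples/s, 60 s pose
sessions at 24 fps with 3 scripted bouts, 10⁴ stochastic composition
replicates, and 100-cell count matrices. These sizes give stable
statistics for every recovered quantity while keeping a full run in the
low tens of seconds on a single core.

# Known limitations

* The two-stage onset surrogate reproduces the *definition* (jolt maximum
  of a polynomial fit) but not the authors' trial-by-trial judgement; on
  low-SNR trials late in a bleached session its per-trial error tail
  reaches a few seconds, and boundary-flagged trials are excluded from
  summaries rather than rescued.
* The phase rule inherits the strict-inequality semantics of its printed
  definition; scores lying exactly on a threshold are classified
  `ambiguous` by design, which real noisy data essentially never produce.
* The sIPSC stability filter's reference change is caller-supplied because
  the printed rule is ambiguous.
* `venn_simulation` validates only the arithmetic consistency of its
  inputs; it is a composition model, not an inference procedure.
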