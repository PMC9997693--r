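---
title: "Methods: simulating and analyzing two-sequence serial-choice recordings"
author: "seqpev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing two-sequence serial-choice recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpev)
```

## The task and what the simulator reproduces

The package models a serial-choice task in which a subject executes one of
two four-element response sequences over four screen locations (top,
bottom, left, right). Elements I and III present a vertical pair of discs,
elements II and IV a horizontal pair; across the two sequences every
location is the correct target of exactly two (sequence, element)
conjunctions, so the correct choice is determined only by knowing *which
sequence is active* and *which element is current* — the conjunction the
downstream analyses probe.

Blocks of one sequence end on a pseudorandom criterion: a per-block
minimum of correct trials drawn uniformly from {16, 20, 24}, plus strictly
more than 80% correct over the last 10 trials, and a block can only end on
a correct trial. Transitions are uncued, so an agent following the old
sequence necessarily commits an error on element I of the first trial of
the new block; that error feedback is the only cue to switch.

The trial timeline is: a 4 s intertrial interval (ITI), initiation
stimulus, initiation peck, 700 ms delay, then the four choice elements
with a 700 ms interstimulus interval (ISI) after each correct peck. Reward
lasts 700 ms and the error signal 2 s. Two timing quantities are not fixed
by the protocol and are package choices:

* **Reward-period duration, 700 ms.** The protocol compares the reward
  period against "an equally long period" of the ITI, which pins the
  analysis window to 700 ms; we use the same value for the simulated
  feedback duration.
* **Feedback latency, 50 ms.** The feedback signal (reward or error
  light) follows the triggering peck by a small fixed hardware-style
  delay so that all event timestamps are strictly increasing.
* **Peck latencies** are log-normal (median 0.5 s, log-SD 0.25) with a
  50 ms floor. They only place timestamps; no behavioral claim attaches
  to them.

The **agent** is a fixed trained policy, not a learner: it pecks the
location it believes correct, with per-element slip probabilities
(element I: 0.08; elements II–IV: 0.012 by default, giving the
characteristic pattern of lowest accuracy on element I and near-ceiling
accuracy later in the sequence). After an *on-plan* error — it pecked its
believed-correct location and was told it erred — it adopts the other
sequence with probability 0.5; motor slips do not change its belief.
This reproduces fast switching (about 2–3 trials) and near-immediate
recovery from within-block errors. The true policy of a trained animal
is unknown; these are configuration values, not claims.

## The spike-train generator and what it does (not) emulate

Each synthetic neuron is an inhomogeneous Poisson process. Tuning is
**multiplicative**: the instantaneous rate is

rate(t) = baseline × ∏ over active gain windows (1 + (gain − 1)·e(t)),

where a gain window opens a configurable latency after its aligning event
(element peck for sequence/element/interaction/location/orientation
tuning; feedback onset for outcome tuning; one second before the
initiation peck for switch tuning), lasts a configurable duration
(default 0.5 s), and has raised-cosine edges (width 50 ms) to avoid
binning artifacts at window boundaries. Multiplicative gains keep rates
non-negative and make mixed selectivity — a neuron modulated by several
factors at once — a simple product. Spikes are drawn by thinning against
a sweep-line upper bound of the rate, so the envelope provably bounds the
rate; a violation is an internal error, not a silent bias.

Default populations mimic the recorded scale: 110 NCL + 152 NIML
neurons with log-normal baselines (median 5 spikes/s).

What the generator does **not** emulate: spike-history effects
(refractoriness, bursting), slow drifts in excitability, correlated
noise across neurons, and electrode artifacts. Passing the recovery and
calibration tests therefore shows that the analysis chain is correct and
calibrated for Poisson-like data under the task's event structure — not
that real recordings satisfy those assumptions.

An important structural property of the task carries over to the
synthetic data: response **location** (and stimulus orientation) is a
deterministic function of the (sequence, element) conjunction, exactly
as in the real task. A neuron tuned purely to one location is therefore
statistically indistinguishable, in correct trials, from a particular
sequence-by-element interaction pattern. The classifier reports both
flags in that case; this is a property of the design, not a defect of
the analysis, and the category table's "sequential-only" row (sequential
information without stimulus or location modulation) exists precisely to
quantify the neurons for which this alternative explanation fails.

## Effect sizes, windows, and tests

Task modulation is quantified as percent explained variance (PEV):
omega-squared for one-way designs,

ω² = (SS_effect − df_effect·MS_error) / (SS_total + MS_error),

and partial omega-squared for factorial designs,

ω²_p = (SS_effect − df_effect·MS_error) /
       (SS_effect + (N − df_effect)·MS_error).

Negative values are legitimate small-sample outcomes and are never
clipped. One published rendering of the partial formula defines the
denominator's mean square as the "factor-specific" SS_effect/df_effect,
which would make the numerator identically zero; the package implements
the standard MS_error reading and exposes the literal one behind
`literalMSf = TRUE` for audit only.

Sums of squares for unbalanced two-way designs default to **Type III**
with sum-to-zero contrasts (the common default of the commercial
environment in which such analyses are usually run), with Type II as an
option; on balanced data all types coincide, and both are verified
against independent full-vs-reduced least-squares fits. Internally the
per-term SS is the squared norm of the response projected onto the
orthonormal basis the term adds over its reduced model; because the
design is fixed across sliding bins and label permutations, those bases
are computed once and every bin or permutation costs one small matrix
product. This fast path is cross-checked against `car::Anova` in the
test suite.

Analysis windows (configured in milliseconds, converted to seconds once
at the boundary; bins half-open `[t, t+width)`; bin *centers* reported):

| epoch | event | window | bin/step |
|---|---|---|---|
| `isi_selectivity` | element peck | 0 … +700 ms | single window |
| `iti_baseline` | initiation onset | −1000 … −300 ms | single window |
| `iti_mid` | initiation onset | −2350 … −1650 ms | single window |
| `peri_response` | element peck | −700 … +700 ms | 100 ms / 10 ms (131 bins) |
| `outcome_window` | feedback-triggering peck | −1000 … +5000 ms | 100 ms / 100 ms (60 bins) |
| `switch_window` | initiation peck | −3000 … +1000 ms | 10 ms / 10 ms |
| `switch_perm_window` | initiation peck | ±1000 ms | 100 ms / 100 ms |

Two window conventions were genuinely open and are fixed as follows.
First, the "700 ms of the ITI starting 1000 ms before the start of the
next trial" baseline is anchored to the initiation-stimulus onset — in
the package's timeline the trial formally begins with the ITI, and only
the initiation anchor places the window inside the ITI as described.
Second, the sliding grids place bin *left edges* on the window endpoints
(first bin `[−700, −600)`, last `[+600, +700)`), which yields 131
peri-response positions; the alternative center-anchored convention
would shift counts by one bin and is not used.

Per-neuron classification runs one observation per (correct trial,
element) ISI window with element as a design factor; reward compares the
700 ms reward period of correct trials against the mid-ITI window;
outcome (element-I errors vs element-IV-rewarded correct trials) and
switch (first correct trial of a new block vs other correct trials) use
two-way designs on trial sets equalized by subsampling the majority
condition — per sequence, so that all four design cells stay populated.
Subsampling defaults to a single seeded draw; a repeat-and-average mode
(`subsampleRepeats`) is available and reported separately. No
multiple-testing correction is applied across the nine factor tests;
that choice is deliberate and recorded in the output rather than
silently changed.

The **permutation test** shuffles condition labels jointly across
observations (preserving trial-count imbalance), recomputes the PEV each
time, and reports the upper-tail Monte-Carlo p-value
`(k + 1)/(nPerm + 1)` with 1000 permutations by default; constant
responses give p = 1 by convention. For small samples the test switches
to exhaustive enumeration over distinct labelings (p = k/m without the
+1 correction), which the suite checks against a brute-force oracle.
The switch subpopulation uses the stricter 2.5% permutation level of the
switch analyses; the general PEV permutation level is 5%. Both are named
configuration constants.

**Latencies** are first crossings of mean + 3 SD of a neuron's own PEV
curve, both computed over the full ±700 ms peri-response curve (the
alternative — a separate baseline epoch — is a documented non-choice),
on the 100 ms/10 ms grid; a flat curve never crosses (strict
inequality) and contributes no latency. Region comparisons use the
tie-corrected Wilcoxon rank-sum z without continuity correction and an
unpaired Cohen's d, on crossing neurons only. Per-bin region tests are
pooled-variance t tests; a "significant stretch" requires a run of
consecutive significant bins whose extremes are at least one bin width
apart, so that two genuinely non-overlapping windows are significant.
The family-wise false-positive rate of this run rule under the null is
measured in the test suite, not asserted to a fixed value.

The switch time course is computed on the 10 ms grid of the switch
window while the switch permutation runs on 100 ms bins in the ±1 s
window — the two conventions used by the corresponding published tables
— and both grids are configurable.

## Repeated-measures effect size

The sequence comparison for elements II–IV is a repeated-measures ANOVA
with the (session, element) pair as the repeated unit. Its effect size
applies the one-way omega-squared formula to the within-unit
decomposition. Published repeated-measures effect sizes for this design
are inconsistent with any standard one-way formula and their exact
formula is unstated; no numerical agreement with them is claimed or
enforced.

## Validation scales and numerical choices

The test suite validates the chain at sizes chosen to finish in minutes
while keeping Monte-Carlo noise well below the tested tolerances: null
calibration uses 1000 untuned neurons on a 200-trial session (false
positive rates per factor, binomial SE ≈ 0.007, asserted inside
0.05 ± 0.02; permutation uniformity at 500 permutations per neuron);
latency recovery uses 100 replicates of two 50-neuron populations with a
200 ms injected offset on 60-trial sessions (the offset must be
recovered within one 100 ms bin and detected in ≥80% of replicates);
switch recovery plants a 20% switch-only subpopulation in 150 neurons
on a 300-trial session with a gain of 4 over a 700 ms pre-initiation
window (recovery within ±5 percentage points, 1000 permutations).
Behavioral soundness replays the block criterion over 100 sessions of
400 trials. Exhaustive-oracle checks run the permutation test against
full enumeration, the two-way SS against independent least-squares model
comparisons (tolerance 1e-8), and the latency extraction against a
brute-force scan of 1000 random curves.

Tolerances and tie-breaks: SS conservation is asserted to 1e-9
relative; the strict `>` in threshold crossings means flat curves yield
no latency; the permutation comparison uses `>= observed − 1e-12` to be
robust to float noise at ties; equalized subsampling is without
replacement and deterministic given its seed; degenerate ANOVA inputs
(constant responses, empty cells, fewer than two observations in a
required cell) are reported as not-computable with a reason, never as a
zero effect.

## Known limitations

* The agent is stationary; session-long learning or fatigue trends are
  out of scope, so analyses of slow covariates cannot be validated here.
* The Poisson generator cannot produce the over/under-dispersion of real
  spike counts; ANOVA calibration on real data may differ from the
  calibration demonstrated on synthetic data (the permutation test is
  distribution-free and unaffected).
* The location/interaction confound discussed above is inherent to the
  task design; no analysis can fully separate pure location tuning from
  matched interaction tuning using correct trials alone.
* The importer reads the package's own columnar format; converters from
  proprietary acquisition formats are deliberately out of the core.
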