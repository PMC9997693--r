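# seqpev

Sliding-window explained-variance analysis of single-unit activity
recorded during a two-sequence serial-choice task — with a built-in task
simulator and a ground-truth spike-train generator, so the entire
analysis chain can be exercised and validated without any recording.

## The problem

In the task this package models, a subject executes one of two
four-element response sequences over four screen locations. Blocks of
one sequence end on a pseudorandom criterion (16/20/24 correct trials,
plus >80% correct over the last 10), and transitions are uncued: the
subject discovers a switch only through error feedback on the first
element of the new block. Answering where, in a pair of recorded brain
regions (NCL, the avian analog of prefrontal cortex, and NIML), the
activity carries information about *sequence*, *element*, their
conjunction, trial *outcome*, and the upcoming *switch* — and which
region carries it first — requires a chain of analyses whose behavior is
hard to trust without ground truth: sliding-window effect sizes,
permutation tests, trial-count equalization, and threshold-crossing
latencies.

`seqpev` provides that chain, plus the synthetic substrate to prove it
recovers what it should:

* **Task simulator** — trial-by-trial sessions with the block criterion,
  event timestamps, and a parameterized trained agent
  (`runSession()`).
* **Spike generator** — inhomogeneous Poisson neurons with known
  multiplicative tuning to task factors and controllable response
  latency (`tuningProfile()`, `generateSpikes()`).
* **Effect sizes** — ANOVA decompositions and the percent-explained-
  variance (PEV) statistics:

  ω² = (SS_eff − df·MS_err) / (SS_tot + MS_err),
  ω²_p = (SS_eff − df·MS_err) / (SS_eff + (N − df)·MS_err)

  (`onewayAnova()`, `twowayAnova()`, `omegaSquared()`,
  `partialOmegaSquared()`, `omegaSquaredFromF()`, `cohensD()`,
  `ranksumZ()`).
* **Alignment** — event-aligned half-open binning on the published
  window grids (`builtinEpochs()`, `alignAndBin()`, `epochCounts()`).
* **Selectivity** — the nine per-neuron factor tests, label-permutation
  significance for PEV, subsample equalization, and the population
  category table (`classifyNeuron()`, `permutationPvalue()`,
  `categoryTable()`).
* **Time courses and latency** — sliding-bin PEV curves, population
  mean ± SEM, per-bin region tests with a non-overlapping-run rule,
  first-crossing latencies (mean + 3 SD threshold) and their region
  comparison, and the switch-only subpopulation
  (`seqElePevCurves()`, `crossingLatencies()`, `compareLatencies()`,
  `regionwiseBinTests()`, `switchSubpopulation()`).
* **Pipeline** — one deterministic simulate → analyze → report run
  (`runPipeline()`; CLI wrapper in `inst/scripts/run_pipeline.R`).

## Worked example

```r
library(seqpev)

## a 200-trial session and a neuron tuned to one sequence-by-element cell
session <- runSession(200, seed = 1)
blockLengths(session)
#> [1] 17 34 29 33 24 23 32

gains <- matrix(1, 2, 4); gains[1, 2] <- 3   # sequence 1, element II
neuron <- tuningProfile("demo", region = "NIML",
                        gains = list(seq_ele = gains))
spikes <- generateSpikes(neuron, session, seed = 2)
spikes
#> SpikeTrain demo ( NIML ): 10024 spikes over 1941.7 s (5.16 spikes/s)

cl <- classifyNeuron(session, spikes)
cl$p_seq_ele_interaction
#> [1] 1.359279e-31

## effect-size reconstruction from printed F and dfs
omegaSquaredFromF(127, 3, 56)
#> [1] 0.8630137
```

The classifier flags the planted conjunction (p ≪ 0.05 for the
sequence × element interaction), and the ω²-from-F helper reproduces a
textbook one-way effect size of 0.86 for F(3,56) = 127.

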