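#' @import methods
NULL

TASK_LOCATIONS <- c("top", "bottom", "left", "right")
TASK_REGIONS <- c("NCL", "NIML")

## ---------------------------------------------------------------------------
## SeqSession
## ---------------------------------------------------------------------------

#' Session of the two-sequence serial-choice task
#'
#' Container for one simulated (or imported) behavioral session: a trial
#' table with one row per trial, a block table with one row per sequence
#' block, the two sequence definitions, and the generating parameters.
#'
#' The trial table carries, per trial: indices (`trial_idx`, `block_idx`,
#' both 0-based), the active sequence, the number of elements attempted,
#' the chosen location per attempted element (`chosen_loc_1` ...
#' `chosen_loc_4`), the outcome (`"correct"`/`"error"`), the element at
#' which an error occurred (`error_element`, NA on correct trials), flags
#' for block-transition and switch trials, and the event timestamps in
#' seconds on the session clock (`t_trial_start`, `t_init_on`,
#' `t_init_peck`, `t_elemK_on`, `t_elemK_peck`, `t_feedback_on`,
#' `t_feedback_off`).
#'
#' @slot trials data.frame, one row per trial.
#' @slot blocks data.frame, one row per block (`block_idx`, `sequence_id`,
#'   `min_correct`, `first_trial`, `last_trial`, `n_trials`, `n_correct`,
#'   `completed`).
#' @slot sequences list of two sequence specifications (see
#'   [defaultSequences()]).
#' @slot agent list of agent parameters used to generate the session.
#' @slot seed integer seed the session was generated from.
#'
#' @seealso [runSession()], [blockLengths()], [eventTimeline()]
#' @export
setClass("SeqSession",
  representation(
    trials = "data.frame",
    blocks = "data.frame",
    sequences = "list",
    agent = "list",
    seed = "integer"
  )
)

setValidity("SeqSession", function(object) {
  tr <- object@trials
  bl <- object@blocks
  msgs <- character()
  need <- c("trial_idx", "block_idx", "active_sequence", "elements_attempted",
            "outcome", "error_element", "is_block_transition_trial",
            "is_switch_trial", "t_trial_start", "t_init_on", "t_init_peck",
            "t_feedback_on", "t_feedback_off")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    msgs <- c(msgs, paste0("trial table misses columns: ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs) && nrow(tr)) {
    if (!all(tr$outcome %in% c("correct", "error")))
      msgs <- c(msgs, "outcome must be 'correct' or 'error'")
    bad <- tr$outcome == "correct" & tr$elements_attempted != 4L
    if (any(bad))
      msgs <- c(msgs, "correct trials must have 4 attempted elements")
    if (any(tr$outcome == "error" & is.na(tr$error_element)))
      msgs <- c(msgs, "error trials must record error_element")
    if (any(tr$outcome == "correct" & !is.na(tr$error_element)))
      msgs <- c(msgs, "error_element must be NA on correct trials")
  }
  if (length(unique(c(nrow(bl) > 0, TRUE))) && nrow(bl)) {
    if (any(bl$n_trials < 0)) msgs <- c(msgs, "negative block length")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SeqSession trial table accessor
#' @param session,x a `SeqSession`
#' @export
trialTable <- function(session) session@trials

#' @describeIn SeqSession block table accessor
#' @export
blockTable <- function(session) session@blocks

#' @describeIn SeqSession number of trials
#' @export
nTrials <- function(session) nrow(session@trials)

#' @describeIn SeqSession session duration in seconds (end of last trial)
#' @export
sessionDuration <- function(session) {
  if (!nrow(session@trials)) return(0)
  max(session@trials$t_feedback_off)
}

setMethod("show", "SeqSession", function(object) {
  bl <- object@blocks
  cat("SeqSession:", nrow(object@trials), "trials,",
      nrow(bl), "blocks (", sum(bl$completed), "completed ),",
      sprintf("%.1f%% correct\n",
              100 * mean(object@trials$outcome == "correct")))
  cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SpikeTrain
## ---------------------------------------------------------------------------

#' Spike train of a single neuron on the session clock
#'
#' @slot neuronId character scalar.
#' @slot region character scalar, one of `"NCL"` or `"NIML"` (extensible).
#' @slot times strictly increasing spike times in seconds.
#' @slot duration session duration in seconds; all times must lie in
#'   `[0, duration]`.
#' @export
setClass("SpikeTrain",
  representation(
    neuronId = "character",
    region = "character",
    times = "numeric",
    duration = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  msgs <- character()
  t <- object@times
  if (length(t) && any(diff(t) <= 0))
    msgs <- c(msgs, "spike times must be strictly increasing")
  if (length(t) && (min(t) < 0 || max(t) > object@duration))
    msgs <- c(msgs, "spike times must lie within [0, duration]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeTrain
#' @param neuronId neuron identifier.
#' @param region recording region label.
#' @param times sorted spike times (s).
#' @param duration session duration (s).
#' @export
spikeTrain <- function(neuronId, region, times, duration) {
  new("SpikeTrain", neuronId = as.character(neuronId),
      region = as.character(region),
      times = as.numeric(times), duration = as.numeric(duration))
}

#' @describeIn spikeTrain spike time accessor
#' @param x a `SpikeTrain`
#' @export
spikeTimes <- function(x) x@times

#' @describeIn spikeTrain region accessor
#' @export
neuronRegion <- function(x) x@region

setMethod("show", "SpikeTrain", function(object) {
  cat("SpikeTrain", object@neuronId, "(", object@region, "):",
      length(object@times), "spikes over",
      sprintf("%.1f s (%.2f spikes/s)\n", object@duration,
              length(object@times) / max(object@duration, .Machine$double.eps)))
})

## ---------------------------------------------------------------------------
## TuningProfile
## ---------------------------------------------------------------------------

#' Ground-truth tuning of a synthetic neuron
#'
#' Multiplicative (gain) tuning: the instantaneous rate is the baseline
#' times the product of the gains of all factor levels active at a time
#' point. A gain window opens `latency` seconds after its aligning event,
#' lasts `duration` seconds, and has raised-cosine edges of width
#' `smoothWidth`.
#'
#' @slot neuronId character scalar.
#' @slot region character scalar.
#' @slot baseline baseline rate in spikes/s (>= 0).
#' @slot gains named list of per-factor gain maps; see [tuningProfile()].
#' @slot latency seconds from aligning event to gain onset (>= 0).
#' @slot duration gain-window duration in seconds (> 0).
#' @slot smoothWidth raised-cosine edge width in seconds.
#' @export
setClass("TuningProfile",
  representation(
    neuronId = "character",
    region = "character",
    baseline = "numeric",
    gains = "list",
    latency = "numeric",
    duration = "numeric",
    smoothWidth = "numeric"
  )
)

setValidity("TuningProfile", function(object) {
  msgs <- character()
  if (object@baseline < 0) msgs <- c(msgs, "baseline must be >= 0")
  if (object@latency < 0) msgs <- c(msgs, "latency must be >= 0")
  if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
  for (f in names(object@gains)) {
    g <- object@gains[[f]]
    if (any(unlist(g) < 0))
      msgs <- c(msgs, paste0("gains for factor '", f, "' must be >= 0"))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TuningProfile", function(object) {
  tuned <- vapply(object@gains, function(g) any(abs(unlist(g) - 1) > 1e-12),
                  logical(1))
  cat("TuningProfile", object@neuronId, "(", object@region, "):",
      sprintf("baseline %.2f spikes/s;", object@baseline),
      if (any(tuned)) paste("tuned to", paste(names(tuned)[tuned],
                                              collapse = ", "))
      else "untuned", "\n")
})

## ---------------------------------------------------------------------------
## AnovaTable
## ---------------------------------------------------------------------------

#' ANOVA decomposition with the quantities the effect sizes need
#'
#' Holds, per model term, the sum of squares, degrees of freedom, mean
#' square, F statistic and p value, plus the error and total rows and the
#' total number of observations. Produced by [onewayAnova()] and
#' [twowayAnova()]; consumed by [omegaSquared()] and
#' [partialOmegaSquared()].
#'
#' @slot terms data.frame with columns `term`, `ss`, `df`, `ms`,
#'   `statistic`, `p`.
#' @slot ssError,dfError,msError error (within) sum of squares, df, mean
#'   square.
#' @slot ssTotal total sum of squares.
#' @slot n total number of observations.
#' @slot type `"oneway"`, `"II"` or `"III"`.
#' @export
setClass("AnovaTable",
  representation(
    terms = "data.frame",
    ssError = "numeric",
    dfError = "numeric",
    msError = "numeric",
    ssTotal = "numeric",
    n = "numeric",
    type = "character"
  )
)

setValidity("AnovaTable", function(object) {
  msgs <- character()
  if (any(object@terms$ss < -1e-8)) msgs <- c(msgs, "negative term SS")
  if (object@ssError < -1e-8) msgs <- c(msgs, "negative error SS")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AnovaTable term table accessor
#' @param x an `AnovaTable`
#' @export
anovaTerms <- function(x) x@terms

setMethod("show", "AnovaTable", function(object) {
  cat("AnovaTable (", object@type, "), N =", object@n, "\n")
  tt <- object@terms
  tt$ss <- signif(tt$ss, 6); tt$ms <- signif(tt$ms, 6)
  tt$statistic <- signif(tt$statistic, 4); tt$p <- signif(tt$p, 4)
  print(tt, row.names = FALSE)
  cat(sprintf("  Error: SS = %.6g, df = %d, MS = %.6g\n",
              object@ssError, as.integer(object@dfError), object@msError))
})

## ---------------------------------------------------------------------------
## EpochSpec
## ---------------------------------------------------------------------------

#' Analysis epoch: aligning event, window, and bin grid
#'
#' Offsets and bin sizes are given in milliseconds (the configuration
#' unit) and stored in seconds. Bins are half-open `[t, t + width)`; the
#' grid places bin left edges at `start, start + step, ...` with the last
#' left edge at `end - width`.
#'
#' @slot name epoch name.
#' @slot event name of the aligning event column (without the `t_` prefix).
#' @slot start,end window offsets relative to the event, seconds.
#' @slot binWidth,binStep bin width and step, seconds.
#' @export
setClass("EpochSpec",
  representation(
    name = "character",
    event = "character",
    start = "numeric",
    end = "numeric",
    binWidth = "numeric",
    binStep = "numeric"
  )
)

setValidity("EpochSpec", function(object) {
  msgs <- character()
  if (object@end <= object@start) msgs <- c(msgs, "end must exceed start")
  if (object@binWidth <= 0) msgs <- c(msgs, "bin width must be > 0")
  if (object@binStep > object@binWidth)
    msgs <- c(msgs, "step must not exceed bin width")
  if (object@binWidth > (object@end - object@start) + 1e-12)
    msgs <- c(msgs, "bin width exceeds the window")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EpochSpec (offsets in milliseconds)
#'
#' @param name epoch name.
#' @param event aligning event (e.g. `"elem_peck"`, `"init_peck"`,
#'   `"init_on"`, `"feedback_on"`, `"feedback_peck"`).
#' @param start_ms,end_ms window offsets relative to the event, ms.
#' @param bin_ms bin width, ms; defaults to the full window (one bin).
#' @param step_ms bin step, ms; defaults to `bin_ms` (non-overlapping).
#' @return an [EpochSpec-class] object.
#' @export
epochSpec <- function(name, event, start_ms, end_ms,
                      bin_ms = end_ms - start_ms, step_ms = bin_ms) {
  new("EpochSpec", name = name, event = event,
      start = start_ms / 1000, end = end_ms / 1000,
      binWidth = bin_ms / 1000, binStep = step_ms / 1000)
}

#' Left edges of the bin grid of an epoch (seconds relative to the event)
#' @param epoch an [EpochSpec-class]
#' @export
binEdges <- function(epoch) {
  n <- floor((epoch@end - epoch@start - epoch@binWidth) /
               epoch@binStep + 1e-9) + 1
  epoch@start + (seq_len(n) - 1) * epoch@binStep
}

#' Bin centers of the grid of an epoch (seconds relative to the event)
#' @param epoch an [EpochSpec-class]
#' @export
binCenters <- function(epoch) binEdges(epoch) + epoch@binWidth / 2

setMethod("show", "EpochSpec", function(object) {
  cat(sprintf(
    "EpochSpec '%s': %+.0f to %+.0f ms around %s; bin %.0f ms, step %.0f ms (%d bins)\n",
    object@name, 1000 * object@start, 1000 * object@end, object@event,
    1000 * object@binWidth, 1000 * object@binStep, length(binEdges(object))))
})

## ---------------------------------------------------------------------------
## AlignedRates
## ---------------------------------------------------------------------------

#' Event-aligned binned firing rates of one neuron
#'
#' @slot neuronId character scalar.
#' @slot trialIdx trial indices (rows of the rate matrix).
#' @slot binCenters bin centers in seconds relative to the aligning event;
#'   reported as centers (convention flagged here, not configurable).
#' @slot counts integer matrix trials x bins of spike counts.
#' @slot rates numeric matrix trials x bins, counts / bin width, spikes/s.
#' @slot binWidth bin width in seconds.
#' @slot epochName name of the generating epoch.
#' @export
setClass("AlignedRates",
  representation(
    neuronId = "character",
    trialIdx = "integer",
    binCenters = "numeric",
    counts = "matrix",
    rates = "matrix",
    binWidth = "numeric",
    epochName = "character"
  )
)

setValidity("AlignedRates", function(object) {
  msgs <- character()
  if (nrow(object@rates) != length(object@trialIdx))
    msgs <- c(msgs, "rate rows must match trialIdx")
  if (ncol(object@rates) != length(object@binCenters))
    msgs <- c(msgs, "rate columns must match binCenters")
  if (length(object@binCenters) > 1 && any(diff(object@binCenters) <= 0))
    msgs <- c(msgs, "bin centers must be strictly increasing")
  if (length(object@rates) && min(object@rates) < 0)
    msgs <- c(msgs, "rates must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AlignedRates rate matrix accessor (trials x bins, spikes/s)
#' @param x an `AlignedRates`
#' @export
rateMatrix <- function(x) x@rates

#' @describeIn AlignedRates count matrix accessor (trials x bins)
#' @export
countMatrix <- function(x) x@counts

setMethod("show", "AlignedRates", function(object) {
  cat("AlignedRates", object@neuronId, "| epoch", object@epochName, ":",
      nrow(object@rates), "trials x", ncol(object@rates), "bins;",
      sprintf("mean rate %.2f spikes/s\n",
              mean(object@rates)))
})

## ---------------------------------------------------------------------------
## PevCurves
## ---------------------------------------------------------------------------

#' Per-neuron explained-variance time courses
#'
#' One matrix (neurons x bins) per design term, all on a common bin grid.
#' Values are partial omega-squared (dimensionless, may be negative).
#'
#' @slot neuronId character vector, one per row.
#' @slot region character vector parallel to `neuronId`.
#' @slot binCenters common grid, seconds relative to the aligning event.
#' @slot pev named list of neuron x bin matrices, one per term.
#' @slot binWidth bin width of the grid, seconds.
#' @slot epochName generating epoch.
#' @export
setClass("PevCurves",
  representation(
    neuronId = "character",
    region = "character",
    binCenters = "numeric",
    pev = "list",
    binWidth = "numeric",
    epochName = "character"
  )
)

setValidity("PevCurves", function(object) {
  msgs <- character()
  for (term in names(object@pev)) {
    m <- object@pev[[term]]
    if (nrow(m) != length(object@neuronId))
      msgs <- c(msgs, paste0("term '", term, "': rows must match neuronId"))
    if (ncol(m) != length(object@binCenters))
      msgs <- c(msgs, paste0("term '", term, "': cols must match grid"))
  }
  if (length(object@region) != length(object@neuronId))
    msgs <- c(msgs, "region must parallel neuronId")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PevCurves matrix of PEV values for one term
#' @param x a `PevCurves`
#' @param term design term name
#' @export
pevMatrixOf <- function(x, term) {
  if (!term %in% names(x@pev))
    stop("unknown term '", term, "'; available: ",
         paste(names(x@pev), collapse = ", "))
  x@pev[[term]]
}

#' @describeIn PevCurves terms available
#' @export
pevTerms <- function(x) names(x@pev)

setMethod("show", "PevCurves", function(object) {
  cat("PevCurves | epoch", object@epochName, ":",
      length(object@neuronId), "neurons x", length(object@binCenters),
      "bins; terms:", paste(names(object@pev), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## DatasetBundle
## ---------------------------------------------------------------------------

#' On-disk dataset: trials, blocks, spikes, neurons, optional ground truth
#'
#' @slot trials,blocks behavioral tables (see [SeqSession-class]).
#' @slot spikes data.frame with columns `neuron_id`, `region`,
#'   `spike_time_s`, sorted within neuron.
#' @slot neurons data.frame with columns `neuron_id`, `region`.
#' @slot groundTruth data.frame of generative tuning (may have 0 rows).
#' @slot meta list of provenance fields (seed, config hash, version).
#' @seealso [readBundle()], [writeBundle()]
#' @export
setClass("DatasetBundle",
  representation(
    trials = "data.frame",
    blocks = "data.frame",
    spikes = "data.frame",
    neurons = "data.frame",
    groundTruth = "data.frame",
    meta = "list"
  )
)

setValidity("DatasetBundle", function(object) {
  v <- validateBundleTables(object@trials, object@blocks, object@spikes,
                            object@neurons,
                            regions = bundleRegions(object@meta))
  if (length(v)) v else TRUE
})

setMethod("show", "DatasetBundle", function(object) {
  cat("DatasetBundle:", nrow(object@trials), "trials,",
      nrow(object@neurons), "neurons,", nrow(object@spikes), "spikes",
      if (nrow(object@groundTruth)) "(with ground truth)" else "", "\n")
})
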