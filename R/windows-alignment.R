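## Event-aligned spike extraction and binning. Bins are half-open
## [t, t + width): a spike exactly on the left edge counts, one on the
## right edge does not. Reported bin timestamps are bin centers.

#' Built-in analysis epochs
#'
#' The named epochs used throughout the analyses (all offsets in ms
#' relative to the aligning event):
#' \describe{
#'   \item{isi_selectivity}{0 to +700 after each element response; the
#'     interstimulus-interval window the selectivity ANOVAs use.}
#'   \item{iti_baseline}{-1000 to -300 before the initiation-stimulus
#'     onset; baseline inside the 4 s intertrial interval.}
#'   \item{iti_mid}{700 ms centered in the 4 s intertrial interval
#'     (-2350 to -1650 before initiation onset).}
#'   \item{peri_response}{-700 to +700 around each element response,
#'     bin 100 ms, step 10 ms (the sliding population grid, 131 bins).}
#'   \item{outcome_window}{-1000 to +5000 around the feedback-triggering
#'     peck, bin 100 ms, step 100 ms (60 non-overlapping bins).}
#'   \item{switch_window}{-3000 to +1000 around the initiation peck,
#'     bin 10 ms, step 10 ms (the switch time course).}
#'   \item{switch_perm_window}{-1000 to +1000 around the initiation
#'     peck, bin 100 ms, step 100 ms (the switch permutation window).}
#' }
#'
#' @return named list of [EpochSpec-class] objects.
#' @export
builtinEpochs <- function() {
  list(
    isi_selectivity = epochSpec("isi_selectivity", "elem_peck", 0, 700),
    iti_baseline = epochSpec("iti_baseline", "init_on", -1000, -300),
    iti_mid = epochSpec("iti_mid", "init_on", -2350, -1650),
    peri_response = epochSpec("peri_response", "elem_peck", -700, 700,
                              bin_ms = 100, step_ms = 10),
    outcome_window = epochSpec("outcome_window", "feedback_peck",
                               -1000, 5000, bin_ms = 100, step_ms = 100),
    switch_window = epochSpec("switch_window", "init_peck", -3000, 1000,
                              bin_ms = 10, step_ms = 10),
    switch_perm_window = epochSpec("switch_perm_window", "init_peck",
                                   -1000, 1000, bin_ms = 100, step_ms = 100)
  )
}

## spikes strictly before each x
countBefore <- function(x, times) findInterval(x, times, left.open = TRUE)

#' Align spikes to events and bin them
#'
#' @param spikes a [SpikeTrain-class].
#' @param events numeric vector of aligning-event times (s), one per
#'   observation; `NA` entries are dropped with a notice, never silently.
#' @param epoch an [EpochSpec-class].
#' @param trialIdx optional observation labels recorded in the result
#'   (defaults to positions in `events`).
#' @return an [AlignedRates-class] (rows follow the kept events).
#' @export
alignAndBin <- function(spikes, events, epoch, trialIdx = seq_along(events)) {
  stopifnot(is(spikes, "SpikeTrain"), is(epoch, "EpochSpec"))
  trialIdx <- as.integer(trialIdx)
  keep <- !is.na(events)
  if (any(!keep))
    message(sum(!keep), " event(s) missing; corresponding trials dropped")
  events <- events[keep]; trialIdx <- trialIdx[keep]
  edges <- binEdges(epoch)
  w <- epoch@binWidth
  t <- spikes@times
  counts <- matrix(0L, length(events), length(edges))
  for (i in seq_along(events)) {
    lo <- countBefore(events[i] + edges, t)
    hi <- countBefore(events[i] + edges + w, t)
    counts[i, ] <- hi - lo
  }
  new("AlignedRates", neuronId = spikes@neuronId, trialIdx = trialIdx,
      binCenters = edges + w / 2, counts = counts, rates = counts / w,
      binWidth = w, epochName = epoch@name)
}

#' Per-observation spike counts over a whole epoch window
#'
#' One half-open window `[event + start, event + end)` per observation;
#' the binning grid of the epoch is ignored.
#'
#' @param spikes a [SpikeTrain-class].
#' @param events aligning-event times; `NA` entries yield `NA` counts
#'   (reported with a notice).
#' @param epoch an [EpochSpec-class].
#' @return integer vector parallel to `events`.
#' @export
epochCounts <- function(spikes, events, epoch) {
  stopifnot(is(spikes, "SpikeTrain"), is(epoch, "EpochSpec"))
  out <- rep(NA_integer_, length(events))
  keep <- !is.na(events)
  if (any(!keep))
    message(sum(!keep), " event(s) missing; counts reported as NA")
  t <- spikes@times
  out[keep] <- countBefore(events[keep] + epoch@end, t) -
    countBefore(events[keep] + epoch@start, t)
  out
}
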