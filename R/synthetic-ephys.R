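## Ground-truth spike-train generation. Tuning is multiplicative: the
## instantaneous rate is the baseline times the product of the gains of
## all task-factor levels active at that moment, which keeps rates
## non-negative and makes mixed selectivity the product of factors.
## Spikes are drawn from the resulting inhomogeneous Poisson process by
## thinning.

GAIN_FACTORS <- c("sequence", "element", "seq_ele", "location",
                  "orientation", "outcome", "switch")

defaultGains <- function() {
  list(sequence = c("1" = 1, "2" = 1),
       element = c("1" = 1, "2" = 1, "3" = 1, "4" = 1),
       seq_ele = matrix(1, 2, 4, dimnames = list(c("1", "2"), 1:4)),
       location = c(top = 1, bottom = 1, left = 1, right = 1),
       orientation = c(vertical = 1, horizontal = 1),
       outcome = c(correct = 1, error = 1),
       switch = c(switch = 1, nonswitch = 1))
}

#' Construct a ground-truth tuning profile
#'
#' @param neuronId neuron identifier.
#' @param region region label (default `"NCL"`).
#' @param baseline baseline rate, spikes/s.
#' @param gains named list overriding entries of the identity gain set;
#'   factors: `sequence` (levels "1","2"), `element` ("1"-"4"),
#'   `seq_ele` (2 x 4 matrix), `location` (top/bottom/left/right),
#'   `orientation` (vertical/horizontal), `outcome` (correct/error),
#'   `switch` (switch/nonswitch).
#' @param latency seconds from the aligning event to gain onset.
#' @param duration gain-window duration, seconds.
#' @param smoothWidth raised-cosine edge width, seconds.
#' @return a [TuningProfile-class].
#' @examples
#' p <- tuningProfile("n1", gains = list(seq_ele = {
#'   m <- matrix(1, 2, 4); m[1, 2] <- 3; m
#' }))
#' groundTruthFlags(p)
#' @export
tuningProfile <- function(neuronId, region = "NCL", baseline = 5,
                          gains = list(), latency = 0.05, duration = 0.5,
                          smoothWidth = 0.05) {
  g <- defaultGains()
  for (f in names(gains)) {
    if (!f %in% GAIN_FACTORS)
      stop("unknown gain factor '", f, "'")
    if (is.matrix(g[[f]])) {
      m <- as.matrix(gains[[f]])
      if (!all(dim(m) == dim(g[[f]])))
        stop("gain matrix for '", f, "' must be ",
             paste(dim(g[[f]]), collapse = " x "))
      dimnames(m) <- dimnames(g[[f]])
      g[[f]] <- m
    } else {
      v <- gains[[f]]
      if (is.null(names(v)) && length(v) == length(g[[f]]))
        names(v) <- names(g[[f]])
      bad <- setdiff(names(v), names(g[[f]]))
      if (length(bad)) stop("unknown levels for '", f, "': ",
                            paste(bad, collapse = ", "))
      g[[f]][names(v)] <- v
    }
  }
  new("TuningProfile", neuronId = as.character(neuronId),
      region = as.character(region), baseline = baseline, gains = g,
      latency = latency, duration = duration, smoothWidth = smoothWidth)
}

## Gain windows of a profile over a session: data.frame(start, end, gain).
## Element-aligned factors collapse into one window per (trial, element)
## with the product gain; outcome windows align to feedback onset; the
## switch window covers the second preceding the initiation peck.
tuningWindows <- function(profile, session) {
  tr <- trialTable(session)
  g <- profile@gains
  lat <- profile@latency; dur <- profile@duration

  start <- c(); end <- c(); gain <- c()
  seqTab <- lapply(session@sequences, function(s) s$elements)
  names(seqTab) <- vapply(session@sequences,
                          function(s) as.character(s$sequence_id),
                          character(1))
  for (i in seq_len(nrow(tr))) {
    s <- as.character(tr$active_sequence[i])
    for (k in seq_len(tr$elements_attempted[i])) {
      pk <- tr[[paste0("t_elem", k, "_peck")]][i]
      loc <- tr[[paste0("chosen_loc_", k)]][i]
      ori <- seqTab[[s]]$orientation[k]
      gg <- g$sequence[[s]] * g$element[[as.character(k)]] *
        g$seq_ele[s, k] * g$location[[loc]] * g$orientation[[ori]]
      if (abs(gg - 1) > 1e-12) {
        start <- c(start, pk + lat); end <- c(end, pk + lat + dur)
        gain <- c(gain, gg)
      }
    }
    go <- g$outcome[[tr$outcome[i]]]
    if (abs(go - 1) > 1e-12) {
      fb <- tr$t_feedback_on[i]
      start <- c(start, fb + lat); end <- c(end, fb + lat + dur)
      gain <- c(gain, go)
    }
    if (tr$outcome[i] == "correct") {
      gs <- g$switch[[if (tr$is_switch_trial[i]) "switch" else "nonswitch"]]
      if (abs(gs - 1) > 1e-12) {
        a <- tr$t_init_peck[i] - 1 + lat
        start <- c(start, a); end <- c(end, a + dur)
        gain <- c(gain, gs)
      }
    }
  }
  data.frame(start = start, end = end, gain = gain)
}

## Raised-cosine edge envelope on [a, b], 0 outside, 1 in the interior.
cosEnvelope <- function(t, a, b, w) {
  w <- min(w, (b - a) / 2)
  e <- numeric(length(t))
  inside <- t >= a & t <= b
  e[inside] <- 1
  if (w > 0) {
    up <- t >= a & t < a + w
    e[up] <- 0.5 * (1 - cos(pi * (t[up] - a) / w))
    down <- t > b - w & t <= b
    e[down] <- 0.5 * (1 - cos(pi * (b - t[down]) / w))
  }
  e
}

#' Instantaneous firing rate of a tuned synthetic neuron
#'
#' `rate(t) = baseline * prod over active gain windows of
#' (1 + (gain - 1) * envelope(t))`; a window opens `latency` seconds
#' after its aligning event, lasts `duration` seconds, and its envelope
#' has raised-cosine edges.
#'
#' @param profile a [TuningProfile-class].
#' @param session a [SeqSession-class].
#' @param t query times, seconds on the session clock (within session).
#' @return numeric vector of rates, spikes/s.
#' @export
rateFunction <- function(profile, session, t) {
  dur <- sessionDuration(session)
  if (any(t < 0 | t > dur))
    stop("query times must lie within the session [0, ",
         sprintf("%.3f", dur), "]")
  win <- tuningWindows(profile, session)
  ord <- order(t)
  ts <- t[ord]
  r <- rep(profile@baseline, length(ts))
  for (i in seq_len(nrow(win))) {
    lo <- findInterval(win$start[i], ts, left.open = TRUE) + 1
    hi <- findInterval(win$end[i], ts)
    if (lo > hi) next
    idx <- lo:hi
    e <- cosEnvelope(ts[idx], win$start[i], win$end[i], profile@smoothWidth)
    r[idx] <- r[idx] * (1 + (win$gain[i] - 1) * e)
  }
  r[order(ord)]
}

## Least upper bound of the rate over the session: sweep over window
## overlaps, taking max(1, gain) per open window.
rateBound <- function(profile, session) {
  win <- tuningWindows(profile, session)
  lg <- log(pmax(1, win$gain))
  if (!nrow(win) || all(lg == 0)) return(profile@baseline)
  ev <- rbind(data.frame(t = win$start, d = lg),
              data.frame(t = win$end, d = -lg))
  ev <- ev[order(ev$t, -ev$d), ]
  profile@baseline * exp(max(cumsum(ev$d)))
}

#' Generate a spike train by Poisson thinning
#'
#' Inhomogeneous Poisson sampling against the envelope bound of
#' [rateFunction()]; deterministic given the seed.
#'
#' @param profile a [TuningProfile-class].
#' @param session a [SeqSession-class].
#' @param seed integer seed.
#' @return a [SpikeTrain-class].
#' @export
generateSpikes <- function(profile, session, seed) {
  if (missing(seed)) stop("a seed is required")
  dur <- sessionDuration(session)
  bound <- rateBound(profile, session)
  if (bound <= 0 || profile@baseline <= 0)
    return(spikeTrain(profile@neuronId, profile@region, numeric(0), dur))
  withSeed(seed, {
    n <- stats::rpois(1, bound * dur)
    cand <- sort(stats::runif(n, 0, dur))
    r <- rateFunction(profile, session, cand)
    if (any(r > bound * (1 + 1e-9)))
      stop("internal error: rate exceeds the thinning envelope")
    keep <- stats::runif(n) < r / bound
    spikeTrain(profile@neuronId, profile@region, unique(cand[keep]), dur)
  })
}

#' Expected selectivity flags of a tuning profile
#'
#' A factor is flagged when any of its gains differs from 1 by more than
#' the contrast threshold.
#'
#' @param profile a [TuningProfile-class].
#' @param contrast minimal absolute gain deviation from 1 to count as
#'   tuned.
#' @return named logical vector over the gain factors.
#' @export
groundTruthFlags <- function(profile, contrast = 0) {
  vapply(profile@gains, function(g) any(abs(unlist(g) - 1) > contrast),
         logical(1))
}

#' Random tuning profiles for a simulated population
#'
#' Baseline rates are log-normal (median 5 spikes/s). Each factor is
#' tuned independently with probability `tunedProb`; a tuned factor gets
#' one modulated level (one cell for the sequence-by-element interaction)
#' with a gain drawn log-uniformly from `[1/maxGain, 1/minGain] U
#' [minGain, maxGain]`.
#'
#' @param nNCL,nNIML population sizes per region (defaults mimic a
#'   110 + 152 recording).
#' @param seed integer seed.
#' @param tunedProb per-factor tuning probability.
#' @param minGain,maxGain gain magnitude range (> 1).
#' @param latencyRange uniform range of response latencies, seconds.
#' @return list of [TuningProfile-class] objects.
#' @export
randomProfiles <- function(nNCL = 110, nNIML = 152, seed = 1,
                           tunedProb = 0.3, minGain = 1.5, maxGain = 3,
                           latencyRange = c(0.03, 0.15)) {
  withSeed(seed, {
    regions <- rep(c("NCL", "NIML"), c(nNCL, nNIML))
    lapply(seq_along(regions), function(i) {
      gains <- list()
      drawGain <- function() {
        m <- exp(stats::runif(1, log(minGain), log(maxGain)))
        if (stats::runif(1) < 0.5) 1 / m else m
      }
      if (stats::runif(1) < tunedProb)
        gains$sequence <- stats::setNames(drawGain(), sample(c("1", "2"), 1))
      if (stats::runif(1) < tunedProb)
        gains$element <- stats::setNames(drawGain(),
                                         sample(as.character(1:4), 1))
      if (stats::runif(1) < tunedProb) {
        m <- matrix(1, 2, 4)
        m[sample(2, 1), sample(4, 1)] <- drawGain()
        gains$seq_ele <- m
      }
      if (stats::runif(1) < tunedProb)
        gains$location <- stats::setNames(drawGain(),
                                          sample(TASK_LOCATIONS, 1))
      if (stats::runif(1) < tunedProb)
        gains$orientation <- stats::setNames(
          drawGain(), sample(c("vertical", "horizontal"), 1))
      if (stats::runif(1) < tunedProb)
        gains$outcome <- c(error = drawGain())
      if (stats::runif(1) < tunedProb)
        gains$switch <- c(switch = drawGain())
      tuningProfile(sprintf("%s_%03d", regions[i], i),
                    region = regions[i],
                    baseline = stats::rlnorm(1, log(5), 0.5),
                    gains = gains,
                    latency = stats::runif(1, latencyRange[1],
                                           latencyRange[2]))
    })
  })
}

#' Generate spike trains for a population of profiles
#'
#' Per-neuron seeds are derived deterministically from the master seed.
#'
#' @param profiles list of [TuningProfile-class] objects.
#' @param session a [SeqSession-class].
#' @param seed master integer seed.
#' @return list of [SpikeTrain-class] objects, parallel to `profiles`.
#' @export
simulatePopulation <- function(profiles, session, seed) {
  lapply(seq_along(profiles), function(i)
    generateSpikes(profiles[[i]], session, seed = (seed * 7919L + i) %%
                     .Machine$integer.max))
}
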