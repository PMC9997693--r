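## Simulator for the two-sequence serial-choice task: four ordered choice
## elements over four screen locations, blocks ending on a pseudorandom
## criterion, uncued sequence transitions discovered through error
## feedback, and a parameterized trained agent standing in for the birds.

ITI_S <- 4.0          # intertrial interval before the initiation stimulus
POST_INIT_DELAY_S <- 0.7
ISI_S <- 0.7          # delay between a correct peck and the next element
ERROR_FEEDBACK_S <- 2.0
REWARD_PERIOD_S <- 0.7
FEEDBACK_LATENCY_S <- 0.05  # feeder/screen latency after the final peck

#' Default pair of task sequences
#'
#' Four elements per sequence; the choice display of elements I and III is
#' a vertical pair of discs (top/bottom), of elements II and IV a
#' horizontal pair (left/right). Across the two sequences every location
#' is the correct target of exactly two (sequence, element) pairs, so the
#' correct location is determined only by the conjunction of active
#' sequence and ordinal element.
#'
#' @return list of two sequence specifications, each with `sequence_id`
#'   and an `elements` data.frame (`element`, `orientation`,
#'   `correct_location`).
#' @export
defaultSequences <- function() {
  list(
    list(sequence_id = 1L,
         elements = data.frame(
           element = 1:4,
           orientation = c("vertical", "horizontal", "vertical", "horizontal"),
           correct_location = c("top", "left", "bottom", "right"),
           stringsAsFactors = FALSE)),
    list(sequence_id = 2L,
         elements = data.frame(
           element = 1:4,
           orientation = c("vertical", "horizontal", "vertical", "horizontal"),
           correct_location = c("bottom", "right", "top", "left"),
           stringsAsFactors = FALSE))
  )
}

validateSequences <- function(specs) {
  if (length(specs) != 2) stop("exactly two sequences are required")
  ids <- vapply(specs, function(s) as.integer(s$sequence_id), integer(1))
  if (!setequal(ids, 1:2)) stop("sequence ids must be {1, 2}")
  for (s in specs) {
    el <- s$elements
    if (nrow(el) != 4) stop("each sequence must have exactly 4 elements")
    want <- rep(c("vertical", "horizontal"), 2)
    if (!identical(el$orientation, want))
      stop("orientations must alternate vertical/horizontal starting vertical")
    pair <- ifelse(el$orientation == "vertical",
                   list(c("top", "bottom")), list(c("left", "right")))
    for (k in 1:4)
      if (!el$correct_location[k] %in% pair[[k]])
        stop("correct location of element ", k,
             " must match its display orientation")
  }
  usage <- table(unlist(lapply(specs, function(s) s$elements$correct_location)))
  if (!(length(usage) == 4 && all(usage == 2)))
    stop("every location must be the correct target of exactly two",
         " (sequence, element) pairs")
  invisible(specs)
}

#' Block-termination criterion parameters
#'
#' A block may only end on a correct trial, and only once the number of
#' correct trials in the block reached the block's drawn minimum and the
#' fraction correct over the last `recentWindow` trials strictly exceeds
#' `recentThreshold`.
#'
#' @param minCorrectSet candidate minimum-correct counts; one is drawn
#'   uniformly per block.
#' @param recentWindow number of most recent trials entering the
#'   performance check.
#' @param recentThreshold exclusive lower bound on recent performance.
#' @export
blockCriterion <- function(minCorrectSet = c(16L, 20L, 24L),
                           recentWindow = 10L, recentThreshold = 0.8) {
  if (any(minCorrectSet < 1)) stop("minCorrectSet must be positive")
  if (recentThreshold < 0 || recentThreshold >= 1)
    stop("recentThreshold must lie in [0, 1)")
  list(minCorrectSet = as.integer(minCorrectSet),
       recentWindow = as.integer(recentWindow),
       recentThreshold = recentThreshold)
}

#' Agent parameters for the task simulator
#'
#' The agent always pecks the location it believes correct, except for
#' intrinsic motor slips (per-element, per-sequence error probabilities).
#' After an on-plan error (it pecked its believed-correct location and
#' received error feedback) it switches its sequence belief with
#' probability `switchProb`; slips do not change the belief. Peck
#' latencies are log-normal with a hard floor so timestamps stay strictly
#' increasing even in degenerate configurations.
#'
#' @param errElem1 length-2 slip probability on element I (sequence 1, 2).
#' @param errLater length-2 slip probability on elements II-IV.
#' @param switchProb probability of adopting the other sequence after an
#'   on-plan error.
#' @param latencyMeanlog,latencySdlog log-normal peck-latency parameters
#'   (default median 0.5 s).
#' @param minLatency minimum peck latency in seconds (> 0).
#' @export
agentParams <- function(errElem1 = c(0.08, 0.08),
                        errLater = c(0.012, 0.012),
                        switchProb = 0.5,
                        latencyMeanlog = log(0.5), latencySdlog = 0.25,
                        minLatency = 0.05) {
  p <- c(errElem1, errLater, switchProb)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  if (minLatency <= 0) stop("minLatency must be > 0")
  list(errElem1 = rep_len(errElem1, 2), errLater = rep_len(errLater, 2),
       switchProb = switchProb, latencyMeanlog = latencyMeanlog,
       latencySdlog = latencySdlog, minLatency = minLatency)
}

otherLocation <- function(orientation, loc) {
  pair <- if (orientation == "vertical") c("top", "bottom")
          else c("left", "right")
  pair[pair != loc]
}

#' Simulate one session of the task
#'
#' Runs `nTrials` trials of the block-design task. The active sequence is
#' never cued: when a block ends the sequence flips silently, so a
#' sequence-following agent necessarily errs on element I of the first
#' trial of the new block (the forced discovery error).
#'
#' @param nTrials number of trials (>= 1).
#' @param seed integer seed; sessions are deterministic given the seed.
#' @param sequences two sequence specifications (see [defaultSequences()]).
#' @param criterion block criterion (see [blockCriterion()]).
#' @param agent agent parameters (see [agentParams()]).
#' @return a [SeqSession-class].
#' @examples
#' s <- runSession(60, seed = 1)
#' blockLengths(s)
#' @export
runSession <- function(nTrials, seed, sequences = defaultSequences(),
                       criterion = blockCriterion(),
                       agent = agentParams()) {
  if (missing(seed)) stop("a seed is required")
  nTrials <- as.integer(nTrials)
  if (is.na(nTrials) || nTrials < 1) stop("nTrials must be >= 1")
  validateSequences(sequences)
  seqTab <- lapply(sequences, function(s) s$elements)
  names(seqTab) <- vapply(sequences, function(s)
    as.character(s$sequence_id), character(1))

  err <- rbind(elem1 = agent$errElem1, later = agent$errLater)

  withSeed(seed, {
    lat <- function() max(agent$minLatency,
                          stats::rlnorm(1, agent$latencyMeanlog,
                                        agent$latencySdlog))
    drawMin <- function() {
      set <- criterion$minCorrectSet
      if (length(set) == 1) set else sample(set, 1)
    }

    tr <- vector("list", nTrials)
    blocks <- list()
    tClock <- 0
    active <- 1L; belief <- 1L
    blockIdx <- 0L; blockStart <- 1L
    minCorrect <- drawMin()
    blockOutcomes <- logical(0)
    transitionNext <- FALSE
    switchSeen <- TRUE  # first block: no preceding transition

    for (i in seq_len(nTrials)) {
      ts <- c(trial_start = tClock,
              init_on = tClock + ITI_S)
      ts["init_peck"] <- ts["init_on"] + lat()
      chosen <- rep(NA_character_, 4)
      outcome <- "correct"; errorElement <- NA_integer_
      onPlanError <- FALSE
      tcur <- ts[["init_peck"]] + POST_INIT_DELAY_S
      for (k in 1:4) {
        ts[paste0("elem", k, "_on")] <- tcur
        ts[paste0("elem", k, "_peck")] <- tcur + lat()
        el <- seqTab[[as.character(belief)]][k, ]
        intended <- el$correct_location
        slipP <- if (k == 1) err["elem1", belief] else err["later", belief]
        slip <- stats::runif(1) < slipP
        chosen[k] <- if (slip) otherLocation(el$orientation, intended)
                     else intended
        ok <- chosen[k] == seqTab[[as.character(active)]]$correct_location[k]
        if (!ok) {
          outcome <- "error"; errorElement <- k
          onPlanError <- !slip
          ts["feedback_on"] <- ts[[paste0("elem", k, "_peck")]] +
            FEEDBACK_LATENCY_S
          ts["feedback_off"] <- ts[["feedback_on"]] + ERROR_FEEDBACK_S
          break
        }
        if (k < 4) {
          tcur <- ts[[paste0("elem", k, "_peck")]] + ISI_S
        } else {
          ts["feedback_on"] <- ts[[paste0("elem4_peck")]] + FEEDBACK_LATENCY_S
          ts["feedback_off"] <- ts[["feedback_on"]] + REWARD_PERIOD_S
        }
      }
      attempted <- if (outcome == "error") errorElement else 4L

      isSwitch <- outcome == "correct" && !switchSeen
      if (isSwitch) switchSeen <- TRUE

      tr[[i]] <- data.frame(
        trial_idx = i - 1L, block_idx = blockIdx,
        active_sequence = active, elements_attempted = attempted,
        chosen_loc_1 = chosen[1], chosen_loc_2 = chosen[2],
        chosen_loc_3 = chosen[3], chosen_loc_4 = chosen[4],
        outcome = outcome, error_element = errorElement,
        is_block_transition_trial = transitionNext,
        is_switch_trial = isSwitch,
        t_trial_start = ts[["trial_start"]], t_init_on = ts[["init_on"]],
        t_init_peck = ts[["init_peck"]],
        t_elem1_on = ts["elem1_on"][[1]], t_elem1_peck = ts["elem1_peck"][[1]],
        t_elem2_on = if ("elem2_on" %in% names(ts)) ts[["elem2_on"]] else NA,
        t_elem2_peck = if ("elem2_peck" %in% names(ts)) ts[["elem2_peck"]] else NA,
        t_elem3_on = if ("elem3_on" %in% names(ts)) ts[["elem3_on"]] else NA,
        t_elem3_peck = if ("elem3_peck" %in% names(ts)) ts[["elem3_peck"]] else NA,
        t_elem4_on = if ("elem4_on" %in% names(ts)) ts[["elem4_on"]] else NA,
        t_elem4_peck = if ("elem4_peck" %in% names(ts)) ts[["elem4_peck"]] else NA,
        t_feedback_on = ts[["feedback_on"]],
        t_feedback_off = ts[["feedback_off"]],
        stringsAsFactors = FALSE)
      transitionNext <- FALSE

      ## belief update: only on-plan errors are evidence of a transition
      if (outcome == "error" && onPlanError &&
          stats::runif(1) < agent$switchProb)
        belief <- 3L - belief

      ## block bookkeeping
      blockOutcomes <- c(blockOutcomes, outcome == "correct")
      nCorrect <- sum(blockOutcomes)
      recent <- utils::tail(blockOutcomes, criterion$recentWindow)
      done <- outcome == "correct" && nCorrect >= minCorrect &&
        length(blockOutcomes) >= criterion$recentWindow &&
        mean(recent) > criterion$recentThreshold
      if (done || i == nTrials) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          block_idx = blockIdx, sequence_id = active,
          min_correct = minCorrect, first_trial = blockStart - 1L,
          last_trial = i - 1L, n_trials = length(blockOutcomes),
          n_correct = nCorrect, completed = done)
        if (done && i < nTrials) {
          blockIdx <- blockIdx + 1L
          blockStart <- i + 1L
          active <- 3L - active
          minCorrect <- drawMin()
          blockOutcomes <- logical(0)
          transitionNext <- TRUE
          switchSeen <- FALSE
        }
      }
      tClock <- ts[["feedback_off"]]
    }

    new("SeqSession",
        trials = do.call(rbind, tr),
        blocks = do.call(rbind, blocks),
        sequences = sequences, agent = agent, seed = as.integer(seed))
  })
}

#' Trials per completed block
#'
#' @param session a [SeqSession-class] with at least one completed block.
#' @return integer vector of completed-block lengths in trials.
#' @export
blockLengths <- function(session) {
  bl <- blockTable(session)
  if (!any(bl$completed)) stop("session has no completed block")
  bl$n_trials[bl$completed]
}

#' Replay the block-termination criterion over an emitted session
#'
#' Independently re-checks every completed block: it ends on a correct
#' trial, its correct count reached the drawn minimum, and performance
#' over the criterion window at termination strictly exceeded the
#' threshold. Used for criterion soundness audits.
#'
#' @param session a [SeqSession-class].
#' @param criterion the criterion the session was generated under.
#' @return logical vector, one entry per completed block.
#' @export
verifyBlockCriterion <- function(session, criterion = blockCriterion()) {
  tr <- trialTable(session)
  bl <- blockTable(session)
  done <- bl[bl$completed, , drop = FALSE]
  vapply(seq_len(nrow(done)), function(i) {
    b <- done[i, ]
    ok <- tr$outcome[tr$block_idx == b$block_idx] == "correct"
    last <- utils::tail(ok, criterion$recentWindow)
    ok[length(ok)] && sum(ok) >= b$min_correct &&
      length(ok) >= criterion$recentWindow &&
      mean(last) > criterion$recentThreshold
  }, logical(1))
}

#' Ordered event timeline of one trial
#'
#' @param session a [SeqSession-class].
#' @param trialIdx 0-based trial index.
#' @return data.frame with columns `event` and `time` (seconds), in
#'   strictly increasing order. A complete correct trial carries 13
#'   events (trial_start, init_on, init_peck, four element on/peck pairs,
#'   feedback_on, feedback_off); an error trial at element k carries the
#'   events up to `elemk_peck` plus the feedback pair.
#' @export
eventTimeline <- function(session, trialIdx) {
  tr <- trialTable(session)
  row <- tr[tr$trial_idx == trialIdx, , drop = FALSE]
  if (nrow(row) != 1) stop("no trial with index ", trialIdx)
  k <- row$elements_attempted
  evs <- c("trial_start", "init_on", "init_peck",
           as.vector(rbind(paste0("elem", seq_len(k), "_on"),
                           paste0("elem", seq_len(k), "_peck"))),
           "feedback_on", "feedback_off")
  times <- as.numeric(row[, paste0("t_", evs)])
  if (anyNA(times)) stop("trial ", trialIdx, " is incomplete")
  if (any(diff(times) <= 0))
    stop("timestamps of trial ", trialIdx, " are not strictly increasing")
  data.frame(event = evs, time = times, stringsAsFactors = FALSE)
}
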