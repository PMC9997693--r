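## Shared fixtures, all generated in code.

.fixtures <- new.env(parent = emptyenv())

## memoized default-agent session
demoSession <- function(nTrials = 200, seed = 11) {
  key <- paste0("s", nTrials, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- runSession(nTrials, seed = seed)
  .fixtures[[key]]
}

## a deterministic sequence-following agent: no slips, always switches
## belief after an on-plan error
deterministicAgent <- function() {
  agentParams(errElem1 = c(0, 0), errLater = c(0, 0), switchProb = 1)
}

## minimal hand-scripted session: outcomes / block indices / error
## elements are prescribed, timestamps are synthetic but valid
scriptedSession <- function(outcome, block_idx,
                            error_element = ifelse(outcome == "error", 1L,
                                                   NA_integer_)) {
  n <- length(outcome)
  stopifnot(length(block_idx) == n)
  t0 <- (seq_len(n) - 1) * 20
  correct <- outcome == "correct"
  tr <- data.frame(
    trial_idx = seq_len(n) - 1L, block_idx = as.integer(block_idx),
    active_sequence = 1L,
    elements_attempted = ifelse(correct, 4L, error_element),
    chosen_loc_1 = "top", chosen_loc_2 = "left", chosen_loc_3 = "bottom",
    chosen_loc_4 = "right",
    outcome = outcome, error_element = error_element,
    is_block_transition_trial = c(FALSE, diff(block_idx) > 0),
    is_switch_trial = FALSE,
    t_trial_start = t0, t_init_on = t0 + 4, t_init_peck = t0 + 4.5,
    t_elem1_on = t0 + 5.2, t_elem1_peck = t0 + 5.7,
    t_elem2_on = t0 + 6.4, t_elem2_peck = t0 + 6.9,
    t_elem3_on = t0 + 7.6, t_elem3_peck = t0 + 8.1,
    t_elem4_on = t0 + 8.8, t_elem4_peck = t0 + 9.3,
    t_feedback_on = t0 + 9.35, t_feedback_off = t0 + 10.05,
    stringsAsFactors = FALSE)
  bl <- do.call(rbind, lapply(sort(unique(block_idx)), function(b) {
    sel <- block_idx == b
    data.frame(block_idx = b, sequence_id = 1L, min_correct = 16L,
               first_trial = min(tr$trial_idx[sel]),
               last_trial = max(tr$trial_idx[sel]),
               n_trials = sum(sel), n_correct = sum(correct[sel]),
               completed = b < max(block_idx))
  }))
  new("SeqSession", trials = tr, blocks = bl,
      sequences = defaultSequences(), agent = agentParams(), seed = 0L)
}

## independent one-way omega-squared used as an oracle (no shared code
## with the package computation path)
oracleOmega2 <- function(values, groups) {
  g <- factor(groups)
  fit <- stats::lm(values ~ g)
  a <- stats::anova(fit)
  ssE <- a["g", "Sum Sq"]; dfE <- a["g", "Df"]
  msErr <- a["Residuals", "Mean Sq"]
  ssTot <- ssE + a["Residuals", "Sum Sq"]
  (ssE - dfE * msErr) / (ssTot + msErr)
}
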