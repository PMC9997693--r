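## Per-neuron factor classification: the ANOVAs over the interstimulus
## windows, permutation significance for the explained-variance
## statistic, trial subsampling, and the population category table.

#' Observation tables for the selectivity analyses
#'
#' `elementObservations`: one row per (correct trial, element) with the
#' active sequence, the ordinal element, its display orientation, the
#' pecked location and the peck time — the design the sequential ANOVAs
#' run on (one observation per element window, element as a design
#' factor).
#'
#' `outcomeObservations`: element-I error trials (aligned to the
#' erroneous peck) versus correct trials (aligned to the element-IV peck
#' that triggers reward), with the active sequence.
#'
#' `switchObservations`: correct trials with the switch flag (first
#' correct trial of a new sequence block vs all other correct trials)
#' and the initiation-peck time.
#'
#' @param session a [SeqSession-class].
#' @return data.frame; see Details.
#' @export
elementObservations <- function(session) {
  tr <- trialTable(session)
  tr <- tr[tr$outcome == "correct", , drop = FALSE]
  seqTab <- lapply(session@sequences, function(s) s$elements)
  names(seqTab) <- vapply(session@sequences,
                          function(s) as.character(s$sequence_id),
                          character(1))
  do.call(rbind, lapply(1:4, function(k) {
    data.frame(trial_idx = tr$trial_idx,
               sequence = tr$active_sequence,
               element = k,
               orientation = vapply(as.character(tr$active_sequence),
                                    function(s) seqTab[[s]]$orientation[k],
                                    character(1)),
               location = tr[[paste0("chosen_loc_", k)]],
               t_peck = tr[[paste0("t_elem", k, "_peck")]],
               stringsAsFactors = FALSE)
  }))
}

#' @rdname elementObservations
#' @export
outcomeObservations <- function(session) {
  tr <- trialTable(session)
  err <- tr[tr$outcome == "error" & tr$error_element == 1L, , drop = FALSE]
  cor <- tr[tr$outcome == "correct", , drop = FALSE]
  rbind(
    data.frame(trial_idx = err$trial_idx, sequence = err$active_sequence,
               outcome = "error", t_peck = err$t_elem1_peck,
               stringsAsFactors = FALSE),
    data.frame(trial_idx = cor$trial_idx, sequence = cor$active_sequence,
               outcome = "correct", t_peck = cor$t_elem4_peck,
               stringsAsFactors = FALSE)
  )
}

#' @rdname elementObservations
#' @export
switchObservations <- function(session) {
  tr <- trialTable(session)
  tr <- tr[tr$outcome == "correct", , drop = FALSE]
  data.frame(trial_idx = tr$trial_idx, sequence = tr$active_sequence,
             switch = ifelse(tr$is_switch_trial, "switch", "nonswitch"),
             t_init_peck = tr$t_init_peck, stringsAsFactors = FALSE)
}

#' Selectivity-analysis configuration
#'
#' @param alpha significance level for the ANOVA flags.
#' @param ssType sum-of-squares type for unbalanced two-way designs.
#' @param subsampleSeed seed for the trial-equalizing subsample.
#' @param subsampleRepeats number of subsample draws; 1 reproduces the
#'   single-draw analysis, larger values average the p-values over
#'   repeated draws (reported separately as `p_*` of the averaged run).
#' @export
selectivityConfig <- function(alpha = 0.05, ssType = "III",
                              subsampleSeed = 1L, subsampleRepeats = 1L) {
  stopifnot(alpha > 0, alpha < 1, subsampleRepeats >= 1)
  list(alpha = alpha, ssType = ssType,
       subsampleSeed = as.integer(subsampleSeed),
       subsampleRepeats = as.integer(subsampleRepeats))
}

SELECTIVITY_FACTORS <- c("visual_stimulus", "response_location", "sequence",
                         "element", "seq_ele_interaction", "reward",
                         "outcome", "switch", "seq_switch_interaction")

#' Classify the task selectivity of one neuron
#'
#' Runs the nine factor tests on a neuron's spike counts:
#' one-way ANOVAs for visual stimulus (display orientation) and response
#' location on the 700 ms interstimulus windows of correct trials; a
#' two-way ANOVA sequence x element (with interaction) on the same
#' windows; a one-way ANOVA comparing the 700 ms reward period of
#' correct trials against an equally long window in the middle of the
#' intertrial interval; a two-way sequence x outcome ANOVA on
#' trial-equalized element-I-error vs correct trials (700 ms after the
#' feedback-triggering peck); and a two-way sequence x switch ANOVA on
#' trial-equalized counts in the +/- 1 s window around the initiation
#' peck. Factors whose design cannot be filled (fewer than 2 trials in a
#' required cell) are reported as not-computable (`NA`) with a reason.
#'
#' @param session a [SeqSession-class].
#' @param spikes the neuron's [SpikeTrain-class].
#' @param config see [selectivityConfig()].
#' @return one-row data.frame with `neuron_id`, `region`, per-factor
#'   `p_*` and `sig_*` columns, trial counts, and a `notes` column
#'   collecting not-computable reasons.
#' @export
classifyNeuron <- function(session, spikes, config = selectivityConfig()) {
  ep <- builtinEpochs()
  isi <- ep$isi_selectivity
  p <- stats::setNames(rep(NA_real_, length(SELECTIVITY_FACTORS)),
                       SELECTIVITY_FACTORS)
  notes <- character()

  safeP <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }

  ## sequential + nonsequential factors on the ISI windows
  eo <- elementObservations(session)
  nCorrect <- length(unique(eo$trial_idx))
  if (nrow(eo) >= 8) {
    cnt <- epochCounts(spikes, eo$t_peck, isi)
    if (stats::var(cnt) == 0) {
      notes <- c(notes, "ISI counts constant; sequential factors not computable")
    } else {
      p["visual_stimulus"] <- safeP(
        anovaTerms(onewayAnova(cnt, eo$orientation))$p, "visual_stimulus")
      p["response_location"] <- safeP(
        anovaTerms(onewayAnova(cnt, eo$location))$p, "response_location")
      tt <- tryCatch(
        anovaTerms(twowayAnova(cnt, eo$sequence, eo$element,
                               ssType = config$ssType,
                               nameA = "sequence", nameB = "element")),
        error = function(e) conditionMessage(e))
      if (is.character(tt)) {
        notes <- c(notes, paste0("sequence/element: ", tt))
        tt <- NULL
      }
      if (!is.null(tt)) {
        p["sequence"] <- tt$p[tt$term == "sequence"]
        p["element"] <- tt$p[tt$term == "element"]
        p["seq_ele_interaction"] <- tt$p[tt$term == "sequence:element"]
      }
    }
  } else notes <- c(notes, "too few correct trials for the ISI ANOVAs")

  ## reward vs mid-ITI baseline (correct trials)
  tr <- trialTable(session)
  cor <- tr[tr$outcome == "correct", , drop = FALSE]
  if (nrow(cor) >= 2) {
    rewardEpoch <- epochSpec("reward", "feedback_on", 0, 700)
    rew <- epochCounts(spikes, cor$t_feedback_on, rewardEpoch)
    mid <- epochCounts(spikes, cor$t_init_on, ep$iti_mid)
    vals <- c(rew, mid)
    if (stats::var(vals) > 0)
      p["reward"] <- safeP(
        anovaTerms(onewayAnova(vals, rep(c("reward", "baseline"),
                                         each = nrow(cor))))$p, "reward")
    else notes <- c(notes, "reward counts constant")
  } else notes <- c(notes, "too few correct trials for the reward test")

  ## outcome: element-I errors vs correct trials, trial-equalized per
  ## sequence so every sequence x outcome cell stays populated
  oo <- outcomeObservations(session)
  nError <- sum(oo$outcome == "error")
  p["outcome"] <- safeP({
    pv <- equalizedTwowayP(
      spikes, oo, timeCol = "t_peck", factorB = "outcome",
      minority = "error", window = epochSpec("outcome", "feedback_peck",
                                             0, 700),
      config = config, terms = "outcome")
    pv[["outcome"]]
  }, "outcome")

  ## switch: switch vs nonswitch correct trials, +/- 1 s around initiation
  so <- switchObservations(session)
  nSwitch <- sum(so$switch == "switch")
  sw <- safeP(
    equalizedTwowayP(spikes, so, timeCol = "t_init_peck",
                     factorB = "switch", minority = "switch",
                     window = epochSpec("switch_win", "init_peck",
                                        -1000, 1000),
                     config = config,
                     terms = c("switch", "sequence:switch")),
    "switch")
  if (length(sw) == 2) {
    p["switch"] <- sw[["switch"]]
    p["seq_switch_interaction"] <- sw[["sequence:switch"]]
  }

  out <- data.frame(neuron_id = spikes@neuronId, region = spikes@region,
                    n_correct_trials = nCorrect,
                    n_error_trials = nError, n_switch_trials = nSwitch,
                    stringsAsFactors = FALSE)
  for (f in SELECTIVITY_FACTORS) {
    out[[paste0("p_", f)]] <- p[[f]]
    out[[paste0("sig_", f)]] <- !is.na(p[[f]]) && p[[f]] < config$alpha
  }
  out$notes <- paste(notes, collapse = "; ")
  out
}

## Two-way sequence x B ANOVA on trial-equalized counts; returns the
## p-values of the requested terms (averaged over subsample repeats).
equalizedTwowayP <- function(spikes, obs, timeCol, factorB, minority,
                             window, config, terms) {
  reps <- config$subsampleRepeats
  acc <- matrix(NA_real_, reps, length(terms),
                dimnames = list(NULL, terms))
  for (r in seq_len(reps)) {
    rows <- lapply(c(1, 2), function(s) {
      mino <- which(obs$sequence == s & obs[[factorB]] == minority)
      majo <- which(obs$sequence == s & obs[[factorB]] != minority)
      if (length(mino) < 2 || length(majo) < 2)
        stop("fewer than 2 trials in a required sequence x ", factorB,
             " cell")
      eq <- subsampleEqualize(majo, mino,
                              seed = config$subsampleSeed + 1000L * r + s)
      c(eq$majority, eq$minority)
    })
    d <- obs[unlist(rows), , drop = FALSE]
    cnt <- epochCounts(spikes, d[[timeCol]], window)
    if (stats::var(cnt) == 0) stop("counts constant in the ",
                                   factorB, " window")
    tab <- twowayAnova(cnt, d$sequence, d[[factorB]],
                       ssType = config$ssType,
                       nameA = "sequence", nameB = factorB)
    tt <- anovaTerms(tab)
    for (tm in terms) acc[r, tm] <- tt$p[match(tm, tt$term)]
  }
  colMeans(acc)
}

#' Permutation p-value for an explained-variance statistic
#'
#' Shuffles the condition labels across observations (jointly for all
#' terms of the design, preserving the trial-count imbalance) and
#' compares the observed effect size with the permutation distribution.
#' One-way designs use omega-squared, factorial designs the partial
#' omega-squared of the named term. The Monte-Carlo p-value is
#' `(#{permuted >= observed} + 1) / (nPerm + 1)`, upper tail only.
#'
#' @param values numeric per-observation responses.
#' @param labels factor vector (one-way) or data.frame/list of factors.
#' @param term term whose effect size is tested (model-formula notation
#'   over the label names, e.g. `"sequence"` or `"sequence:element"`);
#'   defaults to the first factor.
#' @param nPerm number of permutations.
#' @param seed integer seed; the test is deterministic given the seed.
#' @param ssType sum-of-squares type for factorial designs.
#' @param exact enumerate all distinct labelings instead of sampling
#'   (feasible for small samples; p is then `#{>= observed} / #labelings`
#'   without the +1 correction). `"auto"` switches to enumeration when
#'   there are at most `exactLimit` distinct labelings.
#' @param exactLimit cap for `exact = "auto"`.
#' @return list with `p`, `observed`, `nPerm` (or `nLabelings`), and
#'   `exact`.
#' @export
permutationPvalue <- function(values, labels, term = NULL, nPerm = 1000,
                              seed = 1, ssType = "III", exact = "auto",
                              exactLimit = 5000) {
  values <- as.numeric(values)
  if (is.data.frame(labels) || (is.list(labels) && !is.factor(labels))) {
    labs <- as.data.frame(lapply(labels, factor))
  } else {
    labs <- data.frame(group = factor(labels))
  }
  if (nrow(labs) != length(values))
    stop("labels must parallel values")
  if (any(vapply(labs, nlevels, integer(1)) < 2))
    stop("every factor needs at least 2 levels present")
  if (stats::var(values) == 0)
    return(list(p = 1, observed = NA_real_, nPerm = 0L, exact = FALSE))

  oneway <- ncol(labs) == 1
  terms <- if (oneway) names(labs)[1]
           else c(names(labs), paste(names(labs), collapse = ":"))
  if (is.null(term)) term <- terms[1]
  if (!term %in% terms) stop("unknown term '", term, "'")
  des <- pevDesign(labs, terms = terms, ssType = ssType)
  ssTotal <- sum((values - mean(values))^2)

  statOf <- function(y) {
    ss <- pevTermSS(des, y)
    if (oneway) {
      mse <- ss$ssError / des$dfError
      st <- if (is.matrix(ss$ssTerm)) ss$ssTerm[term, ] else ss$ssTerm[[term]]
      (st - des$dfTerm[[term]] * mse) / (ssTotal + mse)
    } else {
      pevFromSS(des, ss)[[term]]
    }
  }
  obs <- statOf(values)

  patterns <- do.call(paste, c(labs, sep = "\r"))
  nDistinct <- exp(lgamma(length(values) + 1) -
                     sum(lgamma(table(patterns) + 1)))
  doExact <- isTRUE(exact) ||
    (identical(exact, "auto") && nDistinct <= exactLimit)
  if (doExact) {
    if (length(values) > 10)
      stop("exact enumeration supported for at most 10 observations")
    perms <- permutationsAll(length(values))
    ## applying pi to the values induces the labeling labels o pi^-1 of
    ## the original values; deduplicate on that induced labeling
    inv <- t(apply(perms, 1, order))
    key <- apply(matrix(patterns[inv], nrow(perms)), 1, paste,
                 collapse = "\r")
    perms <- perms[!duplicated(key), , drop = FALSE]
    stats <- statOf(apply(perms, 1, function(ix) values[ix]))
    pv <- mean(stats >= obs - 1e-12)
    return(list(p = pv, observed = obs, nLabelings = nrow(perms),
                exact = TRUE))
  }

  withSeed(seed, {
    Y <- vapply(seq_len(nPerm), function(i) values[sample.int(length(values))],
                numeric(length(values)))
    stats <- statOf(Y)
    k <- sum(stats >= obs - 1e-12)
    list(p = (k + 1) / (nPerm + 1), observed = obs, nPerm = nPerm,
         exact = FALSE)
  })
}

## all permutations of 1..n (n small)
permutationsAll <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Equalize two trial sets by subsampling the majority
#'
#' Samples, without replacement, as many majority trials as there are
#' minority trials; deterministic given the seed. Equal sizes pass
#' through unchanged.
#'
#' @param majority,minority vectors (e.g. trial indices).
#' @param seed integer seed.
#' @return list with `majority` (subsampled) and `minority` (unchanged).
#' @export
subsampleEqualize <- function(majority, minority, seed = 1) {
  if (!length(minority)) stop("minority set is empty; not computable")
  if (length(majority) < length(minority))
    stop("majority set smaller than minority set")
  if (length(majority) == length(minority))
    return(list(majority = majority, minority = minority))
  withSeed(seed, {
    list(majority = majority[sort(sample.int(length(majority),
                                             length(minority)))],
         minority = minority)
  })
}

#' Population category table from selectivity records
#'
#' Percentage of significant neurons per factor and for the derived
#' categories, per region, with a 2 x 2 chi-square region comparison
#' (df = 1, no continuity correction) per row.
#'
#' Derived rows: `interaction_and_any_main` (sequence-by-element
#' interaction plus at least one of sequence/element) and
#' `sequential_only` (at least one of sequence/element/interaction while
#' neither visual stimulus nor response location reached significance).
#'
#' @param records data.frame of rows from [classifyNeuron()].
#' @return data.frame with one row per category: per-region percentages
#'   and counts, chi-square statistic and p.
#' @export
categoryTable <- function(records) {
  if (!nrow(records)) stop("need at least one record")
  regions <- sort(unique(records$region))
  preds <- c(
    stats::setNames(lapply(SELECTIVITY_FACTORS, function(f)
      function(r) r[[paste0("sig_", f)]]), SELECTIVITY_FACTORS),
    list(
      interaction_and_any_main = function(r)
        r$sig_seq_ele_interaction & (r$sig_sequence | r$sig_element),
      sequential_only = function(r)
        (r$sig_sequence | r$sig_element | r$sig_seq_ele_interaction) &
          !r$sig_visual_stimulus & !r$sig_response_location))

  rows <- lapply(names(preds), function(nm) {
    hit <- preds[[nm]](records)
    out <- data.frame(category = nm, stringsAsFactors = FALSE)
    counts <- integer(length(regions)); totals <- integer(length(regions))
    for (j in seq_along(regions)) {
      sel <- records$region == regions[j]
      counts[j] <- sum(hit[sel]); totals[j] <- sum(sel)
      out[[paste0("pct_", regions[j])]] <- 100 * counts[j] / totals[j]
      out[[paste0("n_", regions[j])]] <- counts[j]
    }
    if (length(regions) == 2) {
      ct <- chisq2x2(counts[1], totals[1] - counts[1],
                     counts[2], totals[2] - counts[2])
      out$chisq <- ct$statistic; out$chisq_p <- ct$p
    }
    out
  })
  do.call(rbind, rows)
}

## 2x2 chi-square without continuity correction; degenerate margins give
## statistic 0 / p 1 (no evidence of a difference).
chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  if (m == 0) return(list(statistic = 0, p = 1))
  stat <- n * (a * d - b * c)^2 / m
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
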