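## Behavioral statistics over one or more sessions: per-element
## performance with binomial tests against chance, one-way ANOVA of
## element with omega-squared and Tukey-Kramer post hocs, the
## sequence-1-vs-2 comparisons, and the switch/recovery metrics.

asSessionList <- function(sessions) {
  if (is(sessions, "SeqSession")) list(sessions)
  else if (is.list(sessions) &&
           all(vapply(sessions, is, logical(1), "SeqSession"))) sessions
  else stop("sessions must be a SeqSession or a list of them")
}

## Per (session, sequence, element): reached / correct counts.
## Chance per element is 0.5 (two discs, one correct), conditioned on
## the element being reached.
elementCounts <- function(session) {
  tr <- trialTable(session)
  out <- expand.grid(sequence = 1:2, element = 1:4)
  out$n_reached <- 0L; out$n_correct <- 0L
  for (i in seq_len(nrow(out))) {
    s <- out$sequence[i]; k <- out$element[i]
    reached <- tr$active_sequence == s & tr$elements_attempted >= k
    correctK <- reached & (is.na(tr$error_element) | tr$error_element > k)
    out$n_reached[i] <- sum(reached)
    out$n_correct[i] <- sum(correctK)
  }
  out
}

#' Per-element performance table with tests
#'
#' Pools trials across sessions into a per (sequence, element) performance
#' table, tests each cell against the 0.5 chance level (exact binomial,
#' alternative "greater", conditioned on the element being reached), and
#' runs, per sequence, a one-way ANOVA of element on the per-session
#' performance fractions with an omega-squared effect size and
#' Tukey-Kramer post hoc comparisons (studentized-range distribution on
#' unequal n).
#'
#' @param sessions a [SeqSession-class] or list of them (>= 2 sessions for
#'   the ANOVA).
#' @return list with elements `table` (per-cell `n_reached`, `n_correct`,
#'   `fraction_correct`, `se`, `binom_p`; cells never reached are `NA`),
#'   `anova` (per sequence: [AnovaTable-class] plus `omega2`), and
#'   `tukey` (per sequence: data.frame of pairwise element comparisons).
#' @export
elementPerformanceTests <- function(sessions) {
  sessions <- asSessionList(sessions)
  counts <- lapply(sessions, elementCounts)

  pooled <- Reduce(function(x, y) {
    x$n_reached <- x$n_reached + y$n_reached
    x$n_correct <- x$n_correct + y$n_correct
    x
  }, counts)
  pooled$fraction_correct <- ifelse(pooled$n_reached > 0,
                                    pooled$n_correct / pooled$n_reached, NA)
  pooled$se <- ifelse(pooled$n_reached > 0,
                      sqrt(pooled$fraction_correct *
                             (1 - pooled$fraction_correct) /
                             pooled$n_reached), NA)
  pooled$binom_p <- vapply(seq_len(nrow(pooled)), function(i) {
    if (pooled$n_reached[i] == 0) return(NA_real_)
    stats::binom.test(pooled$n_correct[i], pooled$n_reached[i], p = 0.5,
                      alternative = "greater")$p.value
  }, numeric(1))

  anovas <- NULL; tukeys <- NULL
  if (length(sessions) >= 2) {
    perSession <- do.call(rbind, lapply(seq_along(counts), function(j) {
      d <- counts[[j]]
      d$session <- j
      d$fraction <- ifelse(d$n_reached > 0, d$n_correct / d$n_reached, NA)
      d
    }))
    anovas <- list(); tukeys <- list()
    for (s in 1:2) {
      d <- perSession[perSession$sequence == s & !is.na(perSession$fraction), ]
      ## a sequence whose elements were never reached (or reached in a
      ## single element group only) has no ANOVA; report it as missing
      res <- tryCatch({
        tab <- onewayAnova(d$fraction, d$element, term = "element")
        list(anova = tab, omega2 = omegaSquared(tab))
      }, error = function(e) NULL)
      anovas[[as.character(s)]] <- res
      tukeys[[as.character(s)]] <- if (is.null(res)) NULL
        else tukeyKramer(d$fraction, d$element)
    }
  }
  list(table = pooled, anova = anovas, tukey = tukeys)
}

#' Tukey-Kramer pairwise comparisons after a one-way ANOVA
#'
#' Studentized-range test on all group pairs, with the Kramer adjustment
#' for unequal group sizes.
#'
#' @param values,groups as in [onewayAnova()].
#' @return data.frame with columns `group1`, `group2`, `diff`, `q`, `p`.
#' @export
tukeyKramer <- function(values, groups) {
  g <- factor(groups)
  tab <- onewayAnova(values, g)
  mse <- tab@msError
  means <- tapply(as.numeric(values), g, mean)
  ns <- tabulate(g)
  k <- nlevels(g)
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, q = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ia <- match(a, levels(g)); ib <- match(b, levels(g))
    se <- sqrt(mse / 2 * (1 / ns[ia] + 1 / ns[ib]))
    d <- means[[a]] - means[[b]]
    out$diff[i] <- d
    if (se > 0) {
      out$q[i] <- abs(d) / se
      out$p[i] <- stats::ptukey(out$q[i], nmeans = k, df = tab@dfError,
                                lower.tail = FALSE)
    } else {
      out$q[i] <- if (d == 0) 0 else Inf
      out$p[i] <- if (d == 0) 1 else 0
    }
  }
  out
}

#' Sequence-1 versus sequence-2 performance comparisons
#'
#' Elements II-IV: repeated-measures ANOVA of factor sequence with the
#' (session, element) pair as the repeated unit, reporting F, dfs, p and
#' a repeated-measures omega-squared (one-way formula applied to the
#' within-unit decomposition; reported effect sizes from other
#' formulations may differ). Element I: dependent t test across sessions
#' with paired Cohen's d.
#'
#' @param sessions list of >= 2 [SeqSession-class] objects.
#' @return list with `rm_anova` (statistics for elements II-IV) and
#'   `element1` (paired t results).
#' @export
sequenceComparisonTests <- function(sessions) {
  sessions <- asSessionList(sessions)
  if (length(sessions) < 2) stop("need at least 2 sessions")
  perSession <- do.call(rbind, lapply(seq_along(sessions), function(j) {
    d <- elementCounts(sessions[[j]])
    d$session <- j
    d$fraction <- ifelse(d$n_reached > 0, d$n_correct / d$n_reached, NA)
    d
  }))

  ## elements II-IV, both sequences, repeated over (session, element)
  d <- perSession[perSession$element >= 2, ]
  d$unit <- interaction(d$session, d$element)
  keep <- stats::ave(!is.na(d$fraction), d$unit, FUN = all)
  d <- d[keep & !is.na(d$fraction), ]
  d$sequence <- factor(d$sequence)
  fit <- stats::aov(fraction ~ sequence + Error(unit), data = d)
  sm <- summary(fit)
  within <- sm[["Error: Within"]][[1]]
  ssSeq <- within["sequence", "Sum Sq"]
  dfSeq <- within["sequence", "Df"]
  ssErr <- within["Residuals", "Sum Sq"]
  dfErr <- within["Residuals", "Df"]
  msErr <- ssErr / dfErr
  ssTot <- sum((d$fraction - mean(d$fraction))^2)
  rm <- list(F = (ssSeq / dfSeq) / msErr, df = c(dfSeq, dfErr),
             p = stats::pf((ssSeq / dfSeq) / msErr, dfSeq, dfErr,
                           lower.tail = FALSE),
             omega2 = (ssSeq - dfSeq * msErr) / (ssTot + msErr))

  ## element I: paired across sessions
  e1 <- perSession[perSession$element == 1, ]
  x1 <- e1$fraction[e1$sequence == 1][order(e1$session[e1$sequence == 1])]
  x2 <- e1$fraction[e1$sequence == 2][order(e1$session[e1$sequence == 2])]
  ok <- !is.na(x1) & !is.na(x2)
  tt <- pairedTTest(x1[ok], x2[ok])
  tt$d <- cohensD(x1[ok], x2[ok], paired = TRUE)
  list(rm_anova = rm, element1 = tt)
}

## dependent t test; identical vectors give t = 0, p = 1 rather than the
## degenerate zero-variance error
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (s / sqrt(n))
  }
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Trials-to-switch and within-block error recovery
#'
#' Trials-to-switch counts, per non-initial block, the forced transition
#' error and all consecutive error trials until the first correct trial
#' of the new sequence (minimum 1). The recovery metric counts, per
#' within-block error run (a run of consecutive error trials not at the
#' start of a non-initial block), the additional incorrect trials after
#' the first error of the run (minimum 0).
#'
#' @param session a [SeqSession-class].
#' @return list with `trials_to_switch` (mean, se, n; `NA` when the
#'   session has no block transition) and `recovery` (mean, se, n).
#' @export
switchRecoveryMetrics <- function(session) {
  tr <- trialTable(session)
  err <- tr$outcome == "error"
  blocks <- sort(unique(tr$block_idx))

  tts <- c(); rec <- c()
  for (b in blocks) {
    o <- err[tr$block_idx == b]
    ## split into runs of consecutive errors
    r <- rle(o)
    pos <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      if (b > 0 && pos[j] == 1) {
        tts <- c(tts, max(1L, r$lengths[j]))
      } else {
        rec <- c(rec, r$lengths[j] - 1L)
      }
    }
    ## non-initial block whose first trial was (accidentally) correct
    ## still performed a switch in a single trial
    if (b > 0 && !o[1]) tts <- c(tts, 1L)
  }
  summ <- function(x) {
    if (!length(x)) return(list(mean = NA_real_, se = NA_real_, n = 0L))
    list(mean = mean(x),
         se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
         n = length(x))
  }
  list(trials_to_switch = summ(tts), recovery = summ(rec))
}
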