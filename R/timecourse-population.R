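## Sliding-window explained-variance time courses, population summaries,
## between-region per-bin tests, information-onset latencies, and the
## outcome/switch population analyses.

#' Explained-variance time course of one neuron
#'
#' Per sliding bin, a factorial ANOVA of the configured terms on the
#' binned rates, summarized as the partial omega-squared of each term.
#' The design is identical across bins, so the sums of squares are
#' computed through precomputed projections (equivalent to refitting the
#' ANOVA in every bin).
#'
#' @param aligned an [AlignedRates-class] (observations x bins).
#' @param labels data.frame of design factors, rows parallel to the
#'   observations of `aligned`.
#' @param terms model terms; default: all main effects plus the
#'   two-factor interaction when two factors are given.
#' @param ssType sum-of-squares type.
#' @param region region label recorded in the result.
#' @return a [PevCurves-class] with a single neuron row.
#' @export
pevTimecourse <- function(aligned, labels, terms = NULL, ssType = "III",
                          region = NA_character_) {
  stopifnot(is(aligned, "AlignedRates"))
  labs <- as.data.frame(lapply(labels, factor))
  if (nrow(labs) != nrow(aligned@rates))
    stop("labels must parallel the rows of the rate matrix")
  if (any(vapply(labs, nlevels, integer(1)) < 2))
    stop("every factor needs at least 2 levels with observations")
  if (is.null(terms)) {
    terms <- names(labs)
    if (ncol(labs) == 2) terms <- c(terms, paste(terms, collapse = ":"))
  }
  des <- pevDesign(labs, terms = terms, ssType = ssType)
  pev <- pevOfTerms(des, aligned@rates)
  new("PevCurves",
      neuronId = aligned@neuronId, region = region,
      binCenters = aligned@binCenters,
      pev = lapply(pev, function(v) matrix(v, nrow = 1)),
      binWidth = aligned@binWidth,
      epochName = aligned@epochName)
}

stackCurves <- function(curves) {
  if (!length(curves)) stop("no curves to stack")
  terms <- pevTerms(curves[[1]])
  new("PevCurves",
      neuronId = unlist(lapply(curves, function(x) x@neuronId)),
      region = unlist(lapply(curves, function(x) x@region)),
      binCenters = curves[[1]]@binCenters,
      pev = stats::setNames(lapply(terms, function(tm)
        do.call(rbind, lapply(curves, pevMatrixOf, term = tm))), terms),
      binWidth = curves[[1]]@binWidth,
      epochName = curves[[1]]@epochName)
}

#' Population PEV time courses for the sequence-by-element analysis
#'
#' Aligns every neuron to the element responses of correct trials on the
#' sliding peri-response grid and computes, per bin, the partial
#' omega-squared of sequence, element, and their interaction.
#'
#' @param session a [SeqSession-class].
#' @param trains list of [SpikeTrain-class] objects.
#' @param epoch the sliding grid (default the built-in peri-response
#'   epoch: -700 to +700 ms, 100 ms bins, 10 ms step).
#' @param ssType sum-of-squares type.
#' @return a [PevCurves-class] with terms `sequence`, `element`,
#'   `sequence:element`.
#' @export
seqElePevCurves <- function(session, trains,
                            epoch = builtinEpochs()$peri_response,
                            ssType = "III") {
  eo <- elementObservations(session)
  curves <- lapply(trains, function(tr) {
    al <- alignAndBin(tr, eo$t_peck, epoch, trialIdx = eo$trial_idx)
    pevTimecourse(al, eo[c("sequence", "element")], ssType = ssType,
                  region = tr@region)
  })
  stackCurves(curves)
}

#' @describeIn seqElePevCurves sequence x outcome population curves on
#'   the outcome grid (element-I errors vs correct trials, subsampled to
#'   equal counts per sequence).
#' @param config see [selectivityConfig()] (supplies the subsample seed).
#' @export
outcomePevCurves <- function(session, trains,
                             epoch = builtinEpochs()$outcome_window,
                             ssType = "III",
                             config = selectivityConfig()) {
  oo <- equalizeBySequence(outcomeObservations(session), "outcome",
                           "error", config)
  curves <- lapply(trains, function(tr) {
    al <- alignAndBin(tr, oo$t_peck, epoch, trialIdx = oo$trial_idx)
    pevTimecourse(al, oo[c("sequence", "outcome")], ssType = ssType,
                  region = tr@region)
  })
  stackCurves(curves)
}

#' @describeIn seqElePevCurves sequence x switch population curves on
#'   the switch grid (switch vs non-switch correct trials, subsampled to
#'   equal counts per sequence).
#' @export
switchPevCurves <- function(session, trains,
                            epoch = builtinEpochs()$switch_window,
                            ssType = "III",
                            config = selectivityConfig()) {
  so <- equalizeBySequence(switchObservations(session), "switch",
                           "switch", config)
  curves <- lapply(trains, function(tr) {
    al <- alignAndBin(tr, so$t_init_peck, epoch, trialIdx = so$trial_idx)
    pevTimecourse(al, so[c("sequence", "switch")], ssType = ssType,
                  region = tr@region)
  })
  stackCurves(curves)
}

## subsample the majority level of `col` to the minority count within
## each sequence, keeping all four design cells populated
equalizeBySequence <- function(obs, col, minority, config) {
  keep <- unlist(lapply(c(1, 2), function(s) {
    mino <- which(obs$sequence == s & obs[[col]] == minority)
    majo <- which(obs$sequence == s & obs[[col]] != minority)
    if (length(mino) < 2 || length(majo) < 2)
      stop("fewer than 2 trials in a required sequence x ", col, " cell")
    eq <- subsampleEqualize(majo, mino, seed = config$subsampleSeed + s)
    c(eq$majority, eq$minority)
  }))
  obs[sort(keep), , drop = FALSE]
}

#' First crossing of the information threshold
#'
#' The threshold is the mean of the curve plus `k` standard deviations,
#' both computed over the full curve; the latency is the center of the
#' first bin whose value strictly exceeds the threshold, or `NA` when
#' the curve never exceeds it (a flat curve has SD 0 and the strict
#' inequality is never met).
#'
#' @param values PEV values on the grid.
#' @param centers bin centers (s).
#' @param k threshold in standard deviations above the mean.
#' @return list with `latency` (s or `NA`) and `threshold`.
#' @export
crossingLatency <- function(values, centers, k = 3) {
  if (length(values) < 2) stop("need at least 2 bins")
  thr <- mean(values) + k * stats::sd(values)
  i <- which(values > thr)
  list(latency = if (length(i)) centers[min(i)] else NA_real_,
       threshold = thr)
}

#' Per-neuron information latencies of a curve set
#'
#' @param curves a [PevCurves-class].
#' @param term design term.
#' @param k threshold in SDs.
#' @return data.frame with `neuron_id`, `region`, `factor`, `latency`,
#'   `threshold`.
#' @export
crossingLatencies <- function(curves, term, k = 3) {
  m <- pevMatrixOf(curves, term)
  res <- lapply(seq_len(nrow(m)), function(i)
    crossingLatency(m[i, ], curves@binCenters, k = k))
  data.frame(neuron_id = curves@neuronId, region = curves@region,
             factor = term,
             latency = vapply(res, function(x) x$latency, numeric(1)),
             threshold = vapply(res, function(x) x$threshold, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Compare information latencies between two regions
#'
#' Wilcoxon rank-sum z (tie-corrected normal approximation) and
#' unpaired Cohen's d on the latencies of neurons that crossed their
#' threshold; neurons without a crossing are excluded.
#'
#' @param latA,latB latency vectors (s), `NA` = no crossing.
#' @return list with `z`, `p`, `d`, `medianA`, `medianB`, `nA`, `nB`.
#' @export
compareLatencies <- function(latA, latB) {
  a <- latA[!is.na(latA)]; b <- latB[!is.na(latB)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 crossing neurons per region")
  rs <- ranksumZ(a, b)
  list(z = rs$z, p = rs$p, d = cohensD(a, b),
       medianA = stats::median(a), medianB = stats::median(b),
       nA = length(a), nB = length(b))
}

#' Population mean and SEM of PEV curves
#'
#' @param curves a [PevCurves-class].
#' @param term design term.
#' @param byRegion split by region (default) or pool all neurons.
#' @return data.frame with `region`, `bin_center_s`, `mean_pev`, `sem`,
#'   `n` (SEM is `NA` for a single neuron).
#' @export
populationPev <- function(curves, term, byRegion = TRUE) {
  m <- pevMatrixOf(curves, term)
  groups <- if (byRegion) curves@region else rep("all", nrow(m))
  do.call(rbind, lapply(unique(groups), function(g) {
    mm <- m[groups == g, , drop = FALSE]
    n <- nrow(mm)
    data.frame(region = g, bin_center_s = curves@binCenters,
               mean_pev = colMeans(mm),
               sem = if (n > 1) apply(mm, 2, stats::sd) / sqrt(n)
                     else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
}

#' Per-bin region comparison with the non-overlapping-run rule
#'
#' Pooled-variance two-sample t tests across neurons at every bin, plus
#' the run rule: a significant stretch requires a run of consecutive
#' significant bins long enough to contain two bins whose windows do not
#' overlap (centers at least one bin width apart). On a non-overlapping
#' grid any two consecutive significant bins qualify.
#'
#' @param curves a [PevCurves-class] containing both regions.
#' @param term design term.
#' @param regionA,regionB region labels to compare.
#' @param alpha per-bin significance level.
#' @return list with `bins` (data.frame `bin_center_s`, `t`, `df`, `p`,
#'   `significant`) and `stretches` (data.frame `start_s`, `end_s` of
#'   qualifying runs; zero rows when none).
#' @export
regionwiseBinTests <- function(curves, term, regionA = "NCL",
                               regionB = "NIML", alpha = 0.05) {
  m <- pevMatrixOf(curves, term)
  a <- m[curves@region == regionA, , drop = FALSE]
  b <- m[curves@region == regionB, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 neurons per region")
  na <- nrow(a); nb <- nrow(b); df <- na + nb - 2
  sp2 <- ((na - 1) * apply(a, 2, stats::var) +
            (nb - 1) * apply(b, 2, stats::var)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (colMeans(a) - colMeans(b)) / se, 0)
  pv <- 2 * stats::pt(-abs(tstat), df)
  sig <- pv < alpha
  bins <- data.frame(bin_center_s = curves@binCenters, t = tstat, df = df,
                     p = pv, significant = sig)
  list(bins = bins,
       stretches = significantStretches(curves@binCenters, sig,
                                        curves@binWidth))
}

## maximal runs of consecutive significant bins spanning >= one bin
## width between first and last center
significantStretches <- function(centers, sig, binWidth) {
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    if (centers[ends[j]] - centers[starts[j]] >= binWidth - 1e-9)
      out <- rbind(out, data.frame(start_s = centers[starts[j]],
                                   end_s = centers[ends[j]]))
  }
  out
}

#' Switch-only subpopulation via permutation tests
#'
#' For every neuron, spike counts in the +/- 1 s window around the
#' initiation peck (switch vs non-switch correct trials, subsampled to
#' equal counts per sequence) enter a sequence x switch design; the
#' partial omega-squared of `switch`, `sequence` and their interaction
#' is tested with the label-permutation test. The subpopulation keeps
#' neurons with significant switch information but no significant
#' sequence or interaction information.
#'
#' @param session a [SeqSession-class].
#' @param trains list of [SpikeTrain-class] objects.
#' @param nPerm permutations per test.
#' @param seed master seed (per-neuron seeds derive from it).
#' @param alphaPerm permutation significance level (default 0.025,
#'   the convention of the switch tables; the general PEV permutation
#'   level is 0.05).
#' @param config see [selectivityConfig()].
#' @return list with `table` (per neuron: permutation p-values, the
#'   `selected` flag), and `pct` (percentage selected per region).
#' @export
switchSubpopulation <- function(session, trains, nPerm = 1000, seed = 1,
                                alphaPerm = 0.025,
                                config = selectivityConfig()) {
  so <- equalizeBySequence(switchObservations(session), "switch",
                           "switch", config)
  win <- builtinEpochs()$switch_perm_window
  single <- epochSpec("switch_perm", "init_peck",
                      1000 * win@start, 1000 * win@end)
  labs <- so[c("sequence", "switch")]
  rows <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    cnt <- epochCounts(tr, so$t_init_peck, single)
    ps <- vapply(c("switch", "sequence", "sequence:switch"), function(tm) {
      if (stats::var(cnt) == 0) return(1)
      permutationPvalue(cnt, labs, term = tm, nPerm = nPerm,
                        seed = seed * 131L + i, exact = FALSE)$p
    }, numeric(1))
    data.frame(neuron_id = tr@neuronId, region = tr@region,
               p_switch = ps[["switch"]], p_sequence = ps[["sequence"]],
               p_interaction = ps[["sequence:switch"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$selected <- switchOnlySelection(tab, alphaPerm)
  pct <- vapply(split(tab$selected, tab$region),
                function(x) 100 * mean(x), numeric(1))
  list(table = tab, pct = pct)
}

## significant switch information without sequence or interaction
## information
switchOnlySelection <- function(tab, alphaPerm) {
  tab$p_switch < alphaPerm & tab$p_sequence >= alphaPerm &
    tab$p_interaction >= alphaPerm
}
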