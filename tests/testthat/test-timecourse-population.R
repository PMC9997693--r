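test_that("an untuned neuron's PEV curve fluctuates about zero", {
  s <- demoSession(200, seed = 11)
  cv <- seqElePevCurves(s, list(generateSpikes(tuningProfile("u"), s,
                                               seed = 1)))
  m <- pevMatrixOf(cv, "sequence:element")
  expect_lt(mean(abs(m)), 0.01)
})

test_that("planted interaction tuning elevates PEV only inside its window", {
  s <- demoSession(200, seed = 11)
  m <- matrix(1, 2, 4); m[1, 2] <- 3
  p <- tuningProfile("t", gains = list(seq_ele = m), latency = 0.1,
                     duration = 0.3)
  cv <- seqElePevCurves(s, list(generateSpikes(p, s, seed = 2)))
  pev <- pevMatrixOf(cv, "sequence:element")[1, ]
  centers <- cv@binCenters
  inWin <- centers > 0.0 & centers < 0.5
  preWin <- centers < -0.2
  expect_gt(max(pev[inWin]), 0.05)
  expect_equal(centers[which.max(pev)], 0.25, tolerance = 0.2)
  expect_lt(mean(abs(pev[preWin])), 0.02)
})

test_that("shuffled labels destroy the planted information", {
  s <- demoSession(200, seed = 11)
  m <- matrix(1, 2, 4); m[1, 2] <- 3
  p <- tuningProfile("t", gains = list(seq_ele = m))
  tr <- generateSpikes(p, s, seed = 3)
  eo <- elementObservations(s)
  al <- alignAndBin(tr, eo$t_peck, builtinEpochs()$peri_response,
                    trialIdx = eo$trial_idx)
  labs <- eo[c("sequence", "element")]
  set.seed(4)
  shuffled <- labs[sample.int(nrow(labs)), ]
  cvTrue <- pevTimecourse(al, labs)
  cvNull <- pevTimecourse(al, shuffled)
  expect_gt(max(pevMatrixOf(cvTrue, "sequence:element")), 0.05)
  expect_lt(mean(abs(pevMatrixOf(cvNull, "sequence:element"))), 0.01)
})

test_that("crossing latency follows its definition and a brute-force oracle", {
  ## constant curve: threshold equals the mean, never strictly exceeded
  expect_true(is.na(crossingLatency(rep(0.2, 50),
                                    seq_len(50) / 100)$latency))
  ## a brief elevation (under 10% of bins, so the threshold stays below
  ## the plateau) crosses at its first elevated bin
  centers <- (-65:65) / 100
  v <- ifelse(centers >= 0.55 - 1e-9, 1, 0)
  expect_equal(crossingLatency(v, centers)$latency, 0.55)

  ## 1000 random curves against an independent first-crossing scan
  set.seed(6)
  for (i in 1:1000) {
    v <- rnorm(40)
    centers <- seq_len(40) / 10
    got <- crossingLatency(v, centers)$latency
    thr <- mean(v) + 3 * sd(v)
    idx <- which(v > thr)
    want <- if (length(idx)) centers[idx[1]] else NA_real_
    expect_identical(got, want)
  }
})

test_that("latency comparison reduces to the rank-sum machinery", {
  expect_error(compareLatencies(c(0.1, NA), c(0.2, 0.3)), "at least 2")
  res <- compareLatencies(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(res$z, 0)
  expect_equal(res$d, 0)
  ## fully separated latencies attain the exhaustive extreme
  res2 <- compareLatencies(c(0.1, 0.12, 0.15), c(0.3, 0.4, 0.5))
  zs <- apply(utils::combn(6, 3), 2, function(ix)
    ranksumZ((1:6)[ix], (1:6)[-ix])$z)
  expect_equal(res2$z, min(zs))
})

test_that("population mean and SEM match direct recomputation", {
  curves <- new("PevCurves", neuronId = c("a", "b", "c"),
                region = c("NCL", "NCL", "NCL"),
                binCenters = c(0.1, 0.2),
                pev = list(term = rbind(c(0.1, 0.2), c(0.3, 0.4),
                                        c(0.2, 0.6))),
                binWidth = 0.1, epochName = "x")
  pp <- populationPev(curves, "term")
  expect_equal(pp$mean_pev, c(0.2, 0.4))
  expect_equal(pp$sem, c(sd(c(0.1, 0.3, 0.2)), sd(c(0.2, 0.4, 0.6))) /
                 sqrt(3))
  ## two identical curves: SEM 0; single curve: SEM not computable
  c2 <- new("PevCurves", neuronId = c("a", "b"), region = c("r", "r"),
            binCenters = c(0.1, 0.2),
            pev = list(term = rbind(c(0.5, 0.6), c(0.5, 0.6))),
            binWidth = 0.1, epochName = "x")
  expect_true(all(populationPev(c2, "term")$sem == 0))
  c1 <- new("PevCurves", neuronId = "a", region = "r",
            binCenters = c(0.1, 0.2),
            pev = list(term = rbind(c(0.5, 0.6))),
            binWidth = 0.1, epochName = "x")
  p1 <- populationPev(c1, "term")
  expect_equal(p1$mean_pev, c(0.5, 0.6))
  expect_true(all(is.na(p1$sem)))
})

makeCurveSet <- function(a, b, centers, width) {
  new("PevCurves",
      neuronId = as.character(seq_len(nrow(a) + nrow(b))),
      region = rep(c("NCL", "NIML"), c(nrow(a), nrow(b))),
      binCenters = centers, pev = list(term = rbind(a, b)),
      binWidth = width, epochName = "x")
}

test_that("the non-overlapping-run rule matches a brute-force scanner", {
  ## independent scanner over all significant pairs
  bruteHasStretch <- function(centers, sig, width) {
    r <- rle(sig); e <- cumsum(r$lengths); s <- e - r$lengths + 1
    any(r$values & (centers[e] - centers[s] >= width - 1e-9))
  }
  set.seed(8)
  for (i in 1:200) {
    nb <- 30
    sig <- runif(nb) < 0.3
    ## step-100/width-100 grid: two consecutive bins qualify
    c100 <- seq_len(nb) * 0.1
    got <- nrow(seqpev:::significantStretches(c100, sig, 0.1)) > 0
    expect_identical(got, bruteHasStretch(c100, sig, 0.1))
    ## step-10/width-100 grid: a run must span 11 positions
    c10 <- seq_len(nb) * 0.01
    got10 <- nrow(seqpev:::significantStretches(c10, sig, 0.1)) > 0
    expect_identical(got10, bruteHasStretch(c10, sig, 0.1))
  }
  ## explicit: 2 consecutive bins suffice at step = width ...
  expect_equal(nrow(seqpev:::significantStretches(
    c(0.1, 0.2, 0.3), c(TRUE, TRUE, FALSE), 0.1)), 1)
  ## ... but not on a step-10 grid
  expect_equal(nrow(seqpev:::significantStretches(
    seq(0.01, 0.03, by = 0.01), c(TRUE, TRUE, FALSE), 0.1)), 0)
})

test_that("region bin tests find a planted offset and ignore the null", {
  set.seed(12)
  centers <- seq(0.05, 1.0, by = 0.05)
  nb <- length(centers)
  ## planted: region A sits 0.2 above region B everywhere
  a <- matrix(rnorm(12 * nb, 0.2, 0.02), 12)
  b <- matrix(rnorm(12 * nb, 0.0, 0.02), 12)
  res <- regionwiseBinTests(makeCurveSet(a, b, centers, 0.05), "term")
  expect_true(all(res$bins$significant))
  expect_equal(nrow(res$stretches), 1)
  expect_equal(res$bins$df[1], 22)

  ## null: stretches are rare
  hits <- vapply(1:30, function(i) {
    a <- matrix(rnorm(10 * nb, 0, 1), 10)
    b <- matrix(rnorm(10 * nb, 0, 1), 10)
    nrow(regionwiseBinTests(makeCurveSet(a, b, centers, 0.05),
                            "term")$stretches) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("switch-only selection excludes neurons with sequence information", {
  tab <- data.frame(
    neuron_id = c("a", "b", "c", "d"),
    region = "NCL",
    p_switch = c(0.01, 0.01, 0.5, 0.02),
    p_sequence = c(0.5, 0.01, 0.5, 0.9),
    p_interaction = c(0.5, 0.5, 0.5, 0.01))
  sel <- seqpev:::switchOnlySelection(tab, 0.025)
  expect_identical(sel, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("a planted switch subpopulation is recovered at small scale", {
  s <- demoSession(300, seed = 19)
  profiles <- c(
    lapply(1:4, function(i)
      tuningProfile(paste0("sw", i), region = "NCL",
                    gains = list(switch = c(switch = 4)),
                    latency = 0.05, duration = 0.7)),
    lapply(1:6, function(i)
      tuningProfile(paste0("u", i), region = "NCL")))
  trains <- simulatePopulation(profiles, s, seed = 77)
  res <- switchSubpopulation(s, trains, nPerm = 300, seed = 5)
  sel <- res$table$selected
  expect_gte(sum(sel[1:4]), 3)     # planted neurons found
  expect_lte(sum(sel[5:10]), 1)    # untuned neurons stay out
})
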