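test_that("identity gains give a flat rate at baseline", {
  s <- demoSession(60, seed = 12)
  p <- tuningProfile("flat", baseline = 7)
  tq <- seq(0, sessionDuration(s), length.out = 500)
  expect_true(all(rateFunction(p, s, tq) == 7))
  expect_error(rateFunction(p, s, -1), "within the session")
})

test_that("a sequence-by-element gain opens only in its own cell", {
  s <- demoSession(120, seed = 13)
  m <- matrix(1, 2, 4); m[1, 2] <- 3
  p <- tuningProfile("int", baseline = 4, gains = list(seq_ele = m),
                     latency = 0.05, duration = 0.4, smoothWidth = 0.05)
  tr <- trialTable(s)
  cor <- tr[tr$outcome == "correct", ]
  t1 <- cor$t_elem2_peck[cor$active_sequence == 1][1] + 0.25  # plateau
  t2 <- cor$t_elem2_peck[cor$active_sequence == 2][1] + 0.25
  expect_equal(rateFunction(p, s, t1), 12)
  expect_equal(rateFunction(p, s, t2), 4)
})

test_that("the integrated rate matches the analytic window areas", {
  s <- demoSession(40, seed = 14)
  m <- matrix(1, 2, 4); m[1, 3] <- 2.5
  p <- tuningProfile("q", baseline = 3, gains = list(seq_ele = m),
                     latency = 0.1, duration = 0.4, smoothWidth = 0.05)
  dur <- sessionDuration(s)
  tq <- seq(0, dur, by = 0.002)
  numInt <- sum(rateFunction(p, s, tq)) * 0.002
  win <- seqpev:::tuningWindows(p, s)
  ## raised-cosine edges: each window integrates to (len - smoothWidth)
  analytic <- 3 * dur + sum(3 * (win$gain - 1) * (win$end - win$start - 0.05))
  expect_equal(numInt, analytic, tolerance = 0.01 * analytic)
})

test_that("zero baseline yields an empty train; seeds are reproducible", {
  s <- demoSession(60, seed = 12)
  p0 <- tuningProfile("z", baseline = 0)
  expect_length(spikeTimes(generateSpikes(p0, s, seed = 1)), 0)
  p <- tuningProfile("r", baseline = 6)
  a <- generateSpikes(p, s, seed = 42)
  b <- generateSpikes(p, s, seed = 42)
  c <- generateSpikes(p, s, seed = 43)
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_false(identical(spikeTimes(a), spikeTimes(c)))
})

test_that("constant-rate spike counts follow Poisson moments", {
  s <- demoSession(60, seed = 12)
  dur <- sessionDuration(s)
  p <- tuningProfile("p", baseline = 10)
  counts <- vapply(1:200, function(i)
    length(spikeTimes(generateSpikes(p, s, seed = i))), numeric(1))
  expected <- 10 * dur
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / 200))
})

test_that("inter-spike intervals at constant rate are exponential", {
  s <- demoSession(60, seed = 12)
  p <- tuningProfile("p", baseline = 8)
  rej <- vapply(1:120, function(i) {
    isi <- diff(spikeTimes(generateSpikes(p, s, seed = 1000 + i)))
    ## float rounding can duplicate an interval; the KS tie warning is
    ## immaterial to the calibration being checked
    suppressWarnings(stats::ks.test(isi, stats::pexp,
                                    rate = 8)$p.value < 0.05)
  }, logical(1))
  expect_lt(mean(rej), 0.10)   # nominal 5% rejection
})

test_that("the empirical PSTH converges to the rate function", {
  s <- demoSession(40, seed = 14)
  m <- matrix(1, 2, 4); m[2, 1] <- 2
  p <- tuningProfile("c", baseline = 6, gains = list(seq_ele = m),
                     latency = 0.05, duration = 0.5)
  pts <- c(50.1, 150.2, 300.3)
  w <- 0.05
  nRep <- 300
  counts <- matrix(0, nRep, length(pts))
  for (i in seq_len(nRep)) {
    tt <- spikeTimes(generateSpikes(p, s, seed = 5000 + i))
    counts[i, ] <- vapply(pts, function(x)
      sum(tt >= x - w & tt < x + w), numeric(1))
  }
  for (j in seq_along(pts)) {
    expected <- mean(rateFunction(p, s, seq(pts[j] - w, pts[j] + w,
                                            length.out = 101))) * 2 * w
    se <- stats::sd(counts[, j]) / sqrt(nRep)
    expect_lt(abs(mean(counts[, j]) - expected), 3 * max(se, 1e-3))
  }
})

test_that("ground-truth flags follow the gain contrasts", {
  expect_false(any(groundTruthFlags(tuningProfile("a"))))
  m <- matrix(1, 2, 4); m[1, 2] <- 2
  f <- groundTruthFlags(tuningProfile("b", gains = list(seq_ele = m)))
  expect_true(f[["seq_ele"]])
  expect_false(f[["sequence"]])
  expect_false(f[["element"]])
  f2 <- groundTruthFlags(tuningProfile("c", gains = list(
    location = c(top = 2), element = c("2" = 2))))
  expect_true(f2[["location"]] && f2[["element"]])
  ## contrast threshold
  f3 <- groundTruthFlags(tuningProfile("d", gains = list(
    location = c(top = 1.1))), contrast = 0.2)
  expect_false(f3[["location"]])
})

test_that("spike trains respect their invariants", {
  s <- demoSession(60, seed = 12)
  tr <- generateSpikes(tuningProfile("v", baseline = 20), s, seed = 3)
  expect_true(all(diff(spikeTimes(tr)) > 0))
  expect_true(all(spikeTimes(tr) >= 0 &
                    spikeTimes(tr) <= sessionDuration(s)))
  expect_error(spikeTrain("x", "NCL", c(2, 1), 10), "increasing")
  expect_error(spikeTrain("x", "NCL", c(1, 11), 10), "within")
})
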