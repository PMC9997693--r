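test_that("classification recovers identifiable planted tuning", {
  s <- demoSession(200, seed = 11)
  m <- matrix(1, 2, 4); m[1, 2] <- 3
  hits <- vapply(1:12, function(i) {
    p <- tuningProfile("n", gains = list(seq_ele = m), latency = 0.05,
                       duration = 0.5)
    cl <- classifyNeuron(s, generateSpikes(p, s, seed = 100 + i))
    c(interaction = cl$sig_seq_ele_interaction,
      outcome = cl$sig_outcome, switch = cl$sig_switch)
  }, logical(3))
  ## the planted interaction is found; the untuned outcome/switch factors
  ## stay mostly silent
  expect_gte(mean(hits["interaction", ]), 0.9)
  expect_lte(mean(hits["outcome", ]), 0.25)
  expect_lte(mean(hits["switch", ]), 0.25)
})

test_that("an outcome-tuned neuron is flagged for outcome only", {
  s <- demoSession(200, seed = 11)
  hits <- vapply(1:10, function(i) {
    p <- tuningProfile("n", gains = list(outcome = c(error = 4)),
                       latency = 0.05, duration = 0.6)
    cl <- classifyNeuron(s, generateSpikes(p, s, seed = 300 + i))
    c(outcome = cl$sig_outcome,
      interaction = cl$sig_seq_ele_interaction)
  }, logical(2))
  expect_gte(mean(hits["outcome", ]), 0.9)
  expect_lte(mean(hits["interaction", ]), 0.3)
})

test_that("a silent neuron is not computable for any factor", {
  s <- demoSession(120, seed = 13)
  silent <- spikeTrain("s", "NCL", numeric(0), sessionDuration(s))
  cl <- classifyNeuron(s, silent)
  pcols <- grep("^p_", names(cl), value = TRUE)
  expect_true(all(is.na(unlist(cl[pcols]))))
  expect_true(all(!unlist(cl[grep("^sig_", names(cl))])))
  expect_match(cl$notes, "constant")
})

test_that("false-positive rates of untuned neurons are near alpha", {
  ## small-scale calibration (the full-scale one lives in the acceptance
  ## suite)
  s <- demoSession(200, seed = 11)
  flags <- t(vapply(1:60, function(i) {
    cl <- classifyNeuron(s, generateSpikes(tuningProfile("u"), s,
                                           seed = 700 + i))
    unlist(cl[grep("^sig_", names(cl))])
  }, logical(9)))
  fpr <- colMeans(flags)
  expect_true(all(fpr <= 0.20))
  expect_lt(mean(fpr), 0.12)
})

test_that("the permutation p-value honors its contracts", {
  ## constant data: p = 1 by convention
  expect_equal(permutationPvalue(rep(3, 10), rep(c("a", "b"), 5))$p, 1)

  ## exhaustive oracle: {0,0,0,10,10,10} with labels AAABBB has 20
  ## labelings, 2 of which reach the observed effect size
  res <- permutationPvalue(c(0, 0, 0, 10, 10, 10),
                           rep(c("A", "B"), each = 3))
  expect_true(res$exact)
  expect_equal(res$nLabelings, 20)
  expect_equal(res$p, 2 / 20)

  ## the Monte-Carlo estimate converges to the exhaustive value
  mc <- permutationPvalue(c(0, 0, 0, 10, 10, 10),
                          rep(c("A", "B"), each = 3), nPerm = 4000,
                          seed = 2, exact = FALSE)
  expect_lt(abs(mc$p - 0.1), 0.03)

  ## determinism under the seed
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  p1 <- permutationPvalue(v, g, nPerm = 200, seed = 5, exact = FALSE)$p
  p2 <- permutationPvalue(v, g, nPerm = 200, seed = 5, exact = FALSE)$p
  expect_identical(p1, p2)
})

test_that("exact permutation p matches an independent enumeration oracle", {
  set.seed(77)
  for (rep in 1:3) {
    v <- rnorm(6)
    g <- rep(c("A", "B"), each = 3)
    res <- permutationPvalue(v, g, exact = TRUE)
    ## oracle: enumerate the C(6,3) assignments directly
    obs <- oracleOmega2(v, g)
    stats <- apply(utils::combn(6, 3), 2, function(ix) {
      gg <- rep("B", 6); gg[ix] <- "A"
      oracleOmega2(v, gg)
    })
    expect_equal(res$p, mean(stats >= obs - 1e-12))
  }
})

test_that("permutation p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(300, {
    v <- rnorm(24)
    permutationPvalue(v, rep(c("a", "b"), 12), nPerm = 99, seed =
                        sample.int(1e6, 1), exact = FALSE)$p
  })
  ## p-values live on the (nPerm + 1) grid; the KS tie warning is expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("subsampling equalizes sizes deterministically", {
  eq <- subsampleEqualize(1:50, 101:107, seed = 3)
  expect_length(eq$majority, 7)
  expect_true(all(eq$majority %in% 1:50))
  expect_identical(eq$minority, 101:107)
  expect_identical(subsampleEqualize(1:50, 101:107, seed = 3)$majority,
                   eq$majority)
  expect_false(identical(subsampleEqualize(1:50, 101:107, seed = 4)$majority,
                         eq$majority))
  ## equal sizes pass through
  expect_identical(subsampleEqualize(1:5, 6:10, seed = 1),
                   list(majority = 1:5, minority = 6:10))
  expect_error(subsampleEqualize(1:5, integer(0)), "empty")
})

test_that("the category table counts factor combinations per region", {
  mk <- function(region, ...) {
    flags <- list(...)
    row <- data.frame(neuron_id = "x", region = region)
    for (f in seqpev:::SELECTIVITY_FACTORS) {
      row[[paste0("sig_", f)]] <- isTRUE(flags[[f]])
      row[[paste0("p_", f)]] <- ifelse(isTRUE(flags[[f]]), 0.01, 0.5)
    }
    row
  }
  recs <- rbind(
    mk("NCL", seq_ele_interaction = TRUE, element = TRUE),
    mk("NCL", seq_ele_interaction = TRUE, element = TRUE),
    mk("NCL"), mk("NCL"),
    mk("NIML", sequence = TRUE), mk("NIML"))
  ct <- categoryTable(recs)
  iam <- ct[ct$category == "interaction_and_any_main", ]
  expect_equal(iam$pct_NCL, 50)
  expect_equal(iam$pct_NIML, 0)
  sonly <- ct[ct$category == "sequential_only", ]
  expect_equal(sonly$pct_NCL, 50)
  expect_equal(sonly$pct_NIML, 50)

  ## all flags false: all rows 0 percent, chi-square p = 1
  recs0 <- rbind(mk("NCL"), mk("NCL"), mk("NIML"))
  ct0 <- categoryTable(recs0)
  expect_true(all(ct0$pct_NCL == 0 & ct0$pct_NIML == 0))
  expect_true(all(ct0$chisq_p == 1))

  ## identical flag tables in both regions: chi-square finds nothing
  recs1 <- rbind(mk("NCL", element = TRUE), mk("NCL"),
                 mk("NIML", element = TRUE), mk("NIML"))
  expect_true(all(categoryTable(recs1)$chisq_p == 1))
})

test_that("flag rates grow with gain contrast and trial count", {
  gains <- c(1.3, 2, 3.5)
  sessionsN <- c(80, 200)
  rates <- matrix(NA_real_, length(gains), length(sessionsN))
  for (gi in seq_along(gains)) {
    for (ni in seq_along(sessionsN)) {
      s <- demoSession(sessionsN[ni], seed = 11)
      hit <- vapply(1:8, function(i) {
        m <- matrix(1, 2, 4); m[1, 2] <- gains[gi]
        cl <- classifyNeuron(s, generateSpikes(
          tuningProfile("n", gains = list(seq_ele = m)), s,
          seed = 900 + 37 * gi + i))
        cl$sig_seq_ele_interaction
      }, logical(1))
      rates[gi, ni] <- mean(hit)
    }
  }
  ## monotone (allowing ties) in both directions
  expect_true(all(diff(rates[, 2]) >= -0.15))
  expect_gte(rates[3, 2], rates[1, 1])
  expect_gte(rates[3, 2], 0.9)
})
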