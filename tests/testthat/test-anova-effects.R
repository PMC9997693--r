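test_that("one-way ANOVA matches the hand-computed decomposition", {
  tab <- onewayAnova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  tt <- anovaTerms(tab)
  expect_equal(tt$ss, 1.5)
  expect_equal(tab@ssError, 4)
  expect_equal(c(tt$df, tab@dfError), c(1, 4))
  expect_equal(tt$statistic, 1.5)
  expect_equal(omegaSquared(tab), (1.5 - 1) / (5.5 + 1))
})

test_that("one-way SS conservation holds on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(50)
    g <- sample(letters[1:5], 50, replace = TRUE)
    if (length(unique(g)) < 2) next
    tab <- onewayAnova(y, g)
    expect_lt(abs(sum(anovaTerms(tab)$ss) + tab@ssError - tab@ssTotal),
              1e-9 * tab@ssTotal)
  }
})

test_that("identical observations give an undefined F, not zero", {
  tab <- onewayAnova(rep(2, 8), rep(c("a", "b"), 4))
  expect_true(is.na(anovaTerms(tab)$statistic))
  expect_true(is.na(anovaTerms(tab)$p))
})

test_that("balanced two-way ANOVA matches the hand-computed cells", {
  y <- c(1, 1, 3, 3, 3, 3, 5, 5)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(c("b1", "b2", "b1", "b2"), each = 2)
  tt <- anovaTerms(twowayAnova(y, a, b))
  expect_equal(tt$ss[tt$term == "A"], 8)
  expect_equal(tt$ss[tt$term == "B"], 8)
  expect_equal(tt$ss[tt$term == "A:B"], 0, tolerance = 1e-12)
})

test_that("swapping the factors swaps their sums of squares", {
  set.seed(9)
  y <- rnorm(40)
  a <- sample(c("x", "y"), 40, TRUE)
  b <- sample(c("p", "q"), 40, TRUE)
  t1 <- anovaTerms(twowayAnova(y, a, b))
  t2 <- anovaTerms(twowayAnova(y, b, a))
  expect_equal(t1$ss[t1$term == "A"], t2$ss[t2$term == "B"])
  expect_equal(t1$ss[t1$term == "B"], t2$ss[t2$term == "A"])
  expect_equal(t1$ss[t1$term == "A:B"], t2$ss[t2$term == "A:B"])
})

test_that("unbalanced two-way SS match the least-squares model-comparison oracle", {
  skip_if_not_installed("car")
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30 + seed
    a <- factor(sample(c("x", "y"), n, TRUE))
    b <- factor(sample(c("p", "q", "r"), n, TRUE))
    if (any(table(a, b) == 0)) next
    y <- rnorm(n) + 0.6 * (a == "x") + 0.8 * (b == "q")
    for (tp in c("III", "II")) {
      mine <- anovaTerms(twowayAnova(y, a, b, ssType = tp))
      fit <- stats::lm(y ~ A * B,
                       data = data.frame(A = a, B = b),
                       contrasts = list(A = "contr.sum", B = "contr.sum"))
      ref <- car::Anova(fit, type = ifelse(tp == "III", 3, 2))
      expect_lt(max(abs(mine$ss - ref[c("A", "B", "A:B"), "Sum Sq"])), 1e-8)
    }
  }
})

test_that("Type II and Type III agree on balanced designs", {
  set.seed(3)
  y <- rnorm(24)
  a <- rep(c("x", "y"), each = 12)
  b <- rep(rep(c("p", "q", "r"), each = 4), 2)
  t3 <- anovaTerms(twowayAnova(y, a, b, ssType = "III"))
  t2 <- anovaTerms(twowayAnova(y, a, b, ssType = "II"))
  expect_equal(t3$ss, t2$ss, tolerance = 1e-10)
})

test_that("empty design cells are rejected with the cell named", {
  y <- rnorm(6)
  a <- c("x", "x", "x", "y", "y", "y")
  b <- c("p", "p", "q", "p", "p", "p")
  expect_error(twowayAnova(y, a, b), "empty design cells.*y,q")
})

test_that("omega-squared from F reproduces the worked examples", {
  expect_equal(round(omegaSquaredFromF(127, 3, 56), 2), 0.86)
  expect_equal(round(omegaSquaredFromF(441, 3, 152), 2), 0.89)
  expect_equal(omegaSquaredFromF(1, 3, 20), 0)
  expect_equal(omegaSquaredFromF(127, 3, 56), 378 / 438)
})

test_that("omega-squared from F equals omega-squared on reconstructed data", {
  ## reconstruct one-way layouts with prescribed F and dfs and compare
  buildOneway <- function(f, k, nPer) {
    resid <- c(rep(-1, (nPer - 1) %/% 2), rep(1, (nPer - 1) %/% 2),
               rep(0, nPer - 2 * ((nPer - 1) %/% 2)))
    dfE <- k - 1; dfR <- k * nPer - k
    ssErr <- k * sum(resid^2)
    ssEff <- f * dfE * (ssErr / dfR)
    base <- seq_len(k) - (k + 1) / 2
    a <- sqrt(ssEff / (nPer * sum(base^2)))
    list(values = as.vector(vapply(seq_len(k), function(i)
           base[i] * a + resid, numeric(nPer))),
         groups = rep(seq_len(k), each = nPer))
  }
  set.seed(13)
  for (i in 1:100) {
    f <- stats::runif(1, 0.2, 200)
    k <- sample(2:5, 1)
    nPer <- sample(c(5, 9, 15), 1)
    d <- buildOneway(f, k, nPer)
    tab <- onewayAnova(d$values, d$groups)
    expect_equal(anovaTerms(tab)$statistic, f, tolerance = 1e-8)
    expect_equal(omegaSquared(tab),
                 omegaSquaredFromF(f, k - 1, k * nPer - k),
                 tolerance = 1e-8)
  }
  ## the published-scale reconstruction: F = 127 with df = (3, 56)
  d <- buildOneway(127, 4, 15)
  expect_equal(round(omegaSquared(onewayAnova(d$values, d$groups)), 2), 0.86)
})

test_that("negative omega-squared values are preserved, never clipped", {
  ## F < 1 implies a negative bias-corrected effect size
  expect_lt(omegaSquaredFromF(0.23, 1, 43), 0)
  set.seed(5)
  found <- FALSE
  for (i in 1:50) {
    y <- rnorm(20)
    g <- rep(c("a", "b"), 10)
    om <- omegaSquared(onewayAnova(y, g))
    if (om < 0) found <- TRUE
  }
  expect_true(found)
})

test_that("partial omega-squared follows the corrected formula", {
  expect_equal(partialOmegaSquared(2, 2, 1, 20), 0)       # null numerator
  expect_equal(partialOmegaSquared(10, 2, 0, 20), 1)      # zero error
  expect_equal(partialOmegaSquared(10, 2, 1, 20), 8 / 28)
  ## literal reading of the printed denominator: numerator identically 0
  expect_equal(partialOmegaSquared(10, 2, 1, 20, literalMSf = TRUE), 0)
  expect_equal(partialOmegaSquared(7, 1, 3, 12, literalMSf = TRUE), 0)
})

test_that("null omega-squared is centred at zero", {
  set.seed(31)
  oms <- replicate(2000, {
    y <- rnorm(40)
    omegaSquared(onewayAnova(y, rep(1:4, each = 10)))
  })
  expect_lt(abs(mean(oms)), 0.005)
})

test_that("Cohen's d handles the paired/unpaired and degenerate cases", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_true(is.na(cohensD(c(0, 0), c(1, 1))))           # zero pooled SD
  expect_true(is.na(cohensD(c(2, 3, 4), c(1, 2, 3), paired = TRUE)))
  expect_equal(cohensD(c(2, 2, 5), c(1, 2, 3), paired = TRUE), 1)
  set.seed(2)
  a <- rnorm(1e5, 1, 1); b <- rnorm(1e5, 0, 1)
  expect_equal(cohensD(a, b), 1, tolerance = 0.01)
})

test_that("rank-sum z is antisymmetric and calibrated", {
  a <- c(1.2, 5.3, 2.2, 8); b <- c(0.1, 4.4, 9.9)
  expect_equal(ranksumZ(a, b)$z, -ranksumZ(b, a)$z)
  ## agreement with the uncorrected normal-approximation Wilcoxon test
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(ranksumZ(a, b)$p, w$p.value, tolerance = 1e-12)
  ## ties: still matches the tie-corrected reference
  a2 <- c(1, 2, 2, 3); b2 <- c(2, 3, 3, 4)
  w2 <- stats::wilcox.test(a2, b2, exact = FALSE, correct = FALSE)
  expect_equal(ranksumZ(a2, b2)$p, w2$p.value, tolerance = 1e-12)
  ## null calibration
  set.seed(17)
  inside <- mean(replicate(1000, abs(ranksumZ(rnorm(20), rnorm(20))$z) < 1.96))
  expect_gte(inside, 0.93)
})

test_that("fully separated groups reach the exhaustive extreme z", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  obs <- ranksumZ(a, b)$z
  ## enumerate all assignments of ranks 1..6 into the two groups
  zs <- apply(utils::combn(6, 3), 2, function(ix) {
    ranksumZ((1:6)[ix], (1:6)[-ix])$z
  })
  expect_equal(obs, min(zs))
})
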