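## Effect-size machinery: ANOVA decompositions, omega-squared, partial
## omega-squared, omega-squared from F, Cohen's d and the rank-sum z.
## These are the PEV ("percent explained variance") statistics used by
## the selectivity and time-course modules.

#' One-way ANOVA decomposition
#'
#' Standard between/within decomposition of a single-factor design,
#' returning all quantities the effect-size formulas need.
#'
#' @param values numeric observations.
#' @param groups parallel vector of group labels (coerced to factor).
#' @return an [AnovaTable-class] with one term named `"group"` (or the
#'   factor's deparsed name via `term`).
#' @param term name to give the single term.
#' @details If all observations are identical the F statistic is
#'   undefined and reported as `NA`, never as 0.
#' @examples
#' tab <- onewayAnova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' anovaTerms(tab)      # SS = 1.5, df = 1, F = 1.5
#' omegaSquared(tab)
#' @export
onewayAnova <- function(values, groups, term = "group") {
  values <- as.numeric(values)
  g <- factor(groups)
  if (length(values) != length(g))
    stop("values and groups must have equal length")
  if (anyNA(values) || anyNA(g)) stop("missing values are not supported")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- tabulate(g)
  if (any(sizes < 1)) stop("every group needs at least 1 observation")
  if (sum(sizes) - nlevels(g) < 1)
    stop("need at least one group with 2 observations for the error term")

  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, g, mean)
  ssEffect <- sum(sizes * (means[levels(g)] - gm)^2)
  ssTotal <- sum((values - gm)^2)
  ssError <- ssTotal - ssEffect
  ssError <- max(ssError, 0)
  dfEffect <- nlevels(g) - 1
  dfError <- n - nlevels(g)
  msError <- ssError / dfError
  msEffect <- ssEffect / dfEffect
  if (ssTotal <= 0) {
    f <- NA_real_; p <- NA_real_
  } else {
    f <- msEffect / msError
    p <- stats::pf(f, dfEffect, dfError, lower.tail = FALSE)
  }
  new("AnovaTable",
      terms = data.frame(term = term, ss = ssEffect, df = dfEffect,
                         ms = msEffect, statistic = f, p = p,
                         stringsAsFactors = FALSE),
      ssError = ssError, dfError = dfError, msError = msError,
      ssTotal = ssTotal, n = n, type = "oneway")
}

#' Two-way ANOVA with interaction
#'
#' Crossed two-factor design with interaction. For unbalanced data the
#' sums of squares follow the configured type (default Type III with
#' sum-to-zero contrasts, option Type II); on balanced data all types
#' agree. Sums of squares are computed by full-vs-reduced least-squares
#' model comparison.
#'
#' @param values numeric observations.
#' @param a,b parallel factor labels.
#' @param ssType `"III"` (default) or `"II"`.
#' @param nameA,nameB term names in the output.
#' @return an [AnovaTable-class] with terms `nameA`, `nameB` and
#'   `nameA:nameB`.
#' @details Empty design cells make the interaction model rank deficient;
#'   the function stops with an error listing the empty cells.
#' @export
twowayAnova <- function(values, a, b, ssType = c("III", "II"),
                        nameA = "A", nameB = "B") {
  ssType <- match.arg(ssType)
  values <- as.numeric(values)
  fa <- factor(a); fb <- factor(b)
  if (length(values) != length(fa) || length(values) != length(fb))
    stop("values, a and b must have equal length")
  if (anyNA(values) || anyNA(fa) || anyNA(fb))
    stop("missing values are not supported")
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("need at least 2 levels per factor")
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cells with interaction requested: ",
         paste(sprintf("(%s,%s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  n <- length(values)
  dfError <- n - nlevels(fa) * nlevels(fb)
  if (dfError < 1)
    stop("need at least one cell with 2 observations for the error term")

  des <- pevDesign(data.frame(fa, fb), terms = c("fa", "fb", "fa:fb"),
                   ssType = ssType)
  ss <- pevTermSS(des, values)
  ssError <- ss$ssError
  msError <- ssError / dfError
  termNames <- c(nameA, nameB, paste0(nameA, ":", nameB))
  dfs <- des$dfTerm
  msTerm <- ss$ssTerm / dfs
  if (msError > 0) {
    f <- msTerm / msError
    p <- stats::pf(f, dfs, dfError, lower.tail = FALSE)
  } else {
    f <- rep(NA_real_, 3); p <- rep(NA_real_, 3)
  }
  new("AnovaTable",
      terms = data.frame(term = termNames, ss = ss$ssTerm, df = dfs,
                         ms = msTerm, statistic = f, p = p,
                         stringsAsFactors = FALSE),
      ssError = ssError, dfError = dfError, msError = msError,
      ssTotal = sum((values - mean(values))^2), n = n, type = ssType)
}

#' Omega-squared effect size from an ANOVA table
#'
#' `(SS_effect - df_effect * MS_error) / (SS_total + MS_error)`: the
#' bias-corrected fraction of total variance explained by the term.
#' Negative values arise for F < 1 and are preserved, never clipped.
#'
#' @param table an [AnovaTable-class].
#' @param term term name; defaults to the first term.
#' @return numeric scalar; `NA` when `SS_total + MS_error` is 0.
#' @export
omegaSquared <- function(table, term = anovaTerms(table)$term[1]) {
  tt <- anovaTerms(table)
  i <- match(term, tt$term)
  if (is.na(i)) stop("unknown term '", term, "'")
  denom <- table@ssTotal + table@msError
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  (tt$ss[i] - tt$df[i] * table@msError) / denom
}

#' Partial omega-squared effect size
#'
#' `(SS_effect - df_effect * MS_error) /
#'  (SS_effect + (N - df_effect) * MS_error)`: isolates one term of a
#' multifactor design. Negative values are preserved.
#'
#' The printed definition of the denominator's mean square ("factor
#' specific mean squares") would make the numerator identically zero if
#' read as `SS_effect / df_effect`; that literal reading is available via
#' `literalMSf = TRUE` for audit, the corrected reading (`MS_error`) is
#' the default.
#'
#' @param ssEffect,dfEffect term sum of squares and df.
#' @param msError error mean square.
#' @param n total number of observations.
#' @param literalMSf use the literal (degenerate) reading of the
#'   denominator mean square.
#' @return numeric scalar; `NA` when the denominator is 0.
#' @export
partialOmegaSquared <- function(ssEffect, dfEffect, msError, n,
                                literalMSf = FALSE) {
  if (n <= dfEffect) stop("n must exceed dfEffect")
  msf <- if (literalMSf) ssEffect / dfEffect else msError
  denom <- ssEffect + (n - dfEffect) * msf
  num <- ssEffect - dfEffect * msf
  ifelse(denom == 0, NA_real_, num / denom)
}

#' @describeIn partialOmegaSquared partial omega-squared for a term of an
#'   [AnovaTable-class].
#' @param table an `AnovaTable`
#' @param term term name
#' @export
partialOmegaSquaredOf <- function(table, term) {
  tt <- anovaTerms(table)
  i <- match(term, tt$term)
  if (is.na(i)) stop("unknown term '", term, "'")
  partialOmegaSquared(tt$ss[i], tt$df[i], table@msError, table@n)
}

#' Omega-squared from an F statistic and its degrees of freedom
#'
#' Algebraic rearrangement of the one-way omega-squared formula:
#' `df_effect * (F - 1) / (df_effect * F + df_error + 1)`. Identical to
#' [omegaSquared()] on any one-way dataset with this F and these dfs.
#'
#' @param f F statistic (>= 0).
#' @param dfEffect,dfError numerator and denominator df (>= 1).
#' @return numeric scalar.
#' @examples
#' omegaSquaredFromF(127, 3, 56)   # 0.863
#' @export
omegaSquaredFromF <- function(f, dfEffect, dfError) {
  if (any(f < 0)) stop("F must be >= 0")
  if (any(dfEffect < 1) || any(dfError < 1)) stop("dfs must be >= 1")
  dfEffect * (f - 1) / (dfEffect * f + dfError + 1)
}

#' Cohen's d
#'
#' Unpaired: mean difference over the pooled standard deviation.
#' Paired: mean difference over the standard deviation of the differences.
#'
#' @param a,b numeric samples (paired: equal length).
#' @param paired logical.
#' @return numeric scalar; `NA` when the relevant SD is 0.
#' @export
cohensD <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (length(a) < 2) stop("need at least 2 pairs")
    d <- a - b
    s <- stats::sd(d)
    if (s == 0) return(NA_real_)
    mean(d) / s
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need at least 2 per group")
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
      (na + nb - 2)
    if (sp2 == 0) return(NA_real_)
    (mean(a) - mean(b)) / sqrt(sp2)
  }
}

#' Wilcoxon rank-sum z statistic (normal approximation, tie-corrected)
#'
#' Positive z means `a` is stochastically larger than `b`. Two-sided p
#' from the normal approximation without continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with elements `z`, `p`, and the Mann-Whitney `U`.
#' @export
ranksumZ <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tieTerm <- sum(ties^3 - ties)
  sig2 <- na * nb / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  if (sig2 <= 0) return(list(z = 0, p = 1, U = u))
  z <- (u - mu) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), U = u)
}
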