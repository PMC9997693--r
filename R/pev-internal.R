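## Internal least-squares projection machinery.
##
## For a fixed design the sum of squares of every term is a quadratic
## form ||C_t' y||^2 where C_t is an orthonormal basis of the column
## space added by the term over its reduced model (model-comparison SS:
## Type III drops the term's columns from the full model; Type II obeys
## marginality). Precomputing the bases once makes per-bin sliding
## analyses and label permutations cheap matrix products, and is cross-
## checked against car::Anova in the test suite.

withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

orthBasis <- function(x) {
  qrx <- qr(x)
  r <- qrx$rank
  if (r == 0) return(matrix(0, nrow(x), 0))
  qr.Q(qrx)[, seq_len(r), drop = FALSE]
}

## Basis of col([small, extra]) orthogonal to col(small).
addedBasis <- function(small, extra) {
  if (ncol(small)) {
    qs <- orthBasis(small)
    extra <- extra - qs %*% (t(qs) %*% extra)
  }
  orthBasis(extra)
}

## Build the projection structure for a factorial design.
## factors: data.frame of factors; terms: character vector in
## model-formula notation over the column names (e.g. "fa", "fa:fb").
pevDesign <- function(factors, terms, ssType = c("III", "II")) {
  ssType <- match.arg(ssType)
  factors <- as.data.frame(lapply(factors, factor))
  form <- stats::as.formula(paste("~", paste(terms, collapse = "+")))
  contr <- stats::setNames(rep(list("contr.sum"), ncol(factors)),
                           names(factors))
  mm <- stats::model.matrix(form, data = factors, contrasts.arg = contr)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(form), "term.labels")
  nTermVars <- vapply(strsplit(labs, ":", fixed = TRUE), length, integer(1))

  C <- vector("list", length(labs))
  names(C) <- labs
  for (i in seq_along(labs)) {
    cols <- asg == i
    if (ssType == "III") {
      small <- mm[, !cols, drop = FALSE]
    } else {
      ## Type II: adjust for all terms not containing this one
      keep <- asg == 0
      for (j in seq_along(labs)) {
        if (j == i) next
        vi <- strsplit(labs[i], ":", fixed = TRUE)[[1]]
        vj <- strsplit(labs[j], ":", fixed = TRUE)[[1]]
        if (!all(vi %in% vj)) keep <- keep | (asg == j)
      }
      small <- mm[, keep, drop = FALSE]
    }
    C[[i]] <- addedBasis(small, mm[, cols, drop = FALSE])
  }
  qFull <- orthBasis(mm)
  list(C = C, qFull = qFull, n = nrow(mm),
       dfTerm = stats::setNames(vapply(C, ncol, integer(1)), labs),
       dfError = nrow(mm) - ncol(qFull), ssType = ssType)
}

## Term and error SS for a response vector or an N x m response matrix.
pevTermSS <- function(des, y) {
  y <- as.matrix(y)
  ssTerm <- vapply(des$C, function(C) {
    if (!ncol(C)) return(numeric(ncol(y)))
    .colSums((t(C) %*% y)^2, ncol(C), ncol(y))
  }, numeric(ncol(y)))
  if (ncol(y) == 1) {
    ssTerm <- stats::setNames(as.numeric(ssTerm), names(des$C))
  } else {
    ssTerm <- t(matrix(ssTerm, ncol = length(des$C),
                       dimnames = list(NULL, names(des$C))))
  }
  fit <- .colSums((t(des$qFull) %*% y)^2, ncol(des$qFull), ncol(y))
  ssError <- pmax(.colSums(y^2, nrow(y), ncol(y)) - fit, 0)
  list(ssTerm = ssTerm, ssError = ssError)
}

## Partial omega^2 per term from pevTermSS output (vector y or matrix Y).
pevFromSS <- function(des, ss) {
  msError <- ss$ssError / des$dfError
  out <- lapply(names(des$C), function(term) {
    df <- des$dfTerm[[term]]
    st <- if (is.matrix(ss$ssTerm)) ss$ssTerm[term, ] else ss$ssTerm[[term]]
    num <- st - df * msError
    den <- st + (des$n - df) * msError
    ifelse(den == 0, NA_real_, num / den)
  })
  names(out) <- names(des$C)
  out
}

## One-shot: partial omega^2 of every term for response y under design.
pevOfTerms <- function(des, y) pevFromSS(des, pevTermSS(des, y))
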