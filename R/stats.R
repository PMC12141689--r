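.tailP <- function(t, df, tail) {
  switch(tail,
    two = 2 * stats::pt(-abs(t), df),
    one_neg = stats::pt(t, df),
    one_pos = stats::pt(t, df, lower.tail = FALSE),
    stop("tail must be 'two', 'one_neg' or 'one_pos'")
  )
}

.testResult <- function(statistic, df, p, tail, n, method, degenerate = FALSE) {
  structure(
    list(statistic = statistic, df = df, p = p, tail = tail, n = n,
         method = method, degenerate = degenerate),
    class = "lateralizeTest"
  )
}

#' @export
print.lateralizeTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g (%s-tailed%s)\n",
              x$method, x$statistic, paste(x$df, collapse = ","), x$p,
              ifelse(x$tail == "two", "two", "one"),
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Pooled-variance independent-samples t test
#'
#' Classic equal-variance two-sample t with df = n_x + n_y - 2 (so two
#' groups of 27 and 29 give df = 54). Zero pooled variance with unequal
#' means yields an infinite statistic flagged as degenerate.
#'
#' @param x,y numeric samples.
#' @param tail "two", "one_neg" (alternative: mean(x) < mean(y)) or
#'   "one_pos".
#' @return a test-result list: statistic, df, p, tail, n, degenerate.
#' @examples
#' independentT(c(1, 2, 3), c(2, 3, 4))
#' @export
independentT <- function(x, y, tail = "two") {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 observations")
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  d <- mean(x) - mean(y)
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    return(.testResult(t, df, if (d == 0) 1 else 0, tail, c(nx, ny),
                       "pooled independent t", degenerate = TRUE))
  }
  t <- d / se
  .testResult(t, df, .tailP(t, df, tail), tail, c(nx, ny), "pooled independent t")
}

#' Paired-samples t test
#'
#' t on the within-subject differences with df = n - 1. A zero-variance
#' nonzero difference is flagged as degenerate.
#'
#' @param x,y paired numeric samples of equal length.
#' @inheritParams independentT
#' @return a test-result list.
#' @export
pairedT <- function(x, y, tail = "two") {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs required")
  d <- x - y
  df <- n - 1L
  se <- stats::sd(d) / sqrt(n)
  if (se == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(.testResult(t, df, if (mean(d) == 0) 1 else 0, tail, n,
                       "paired t", degenerate = TRUE))
  }
  t <- mean(d) / se
  .testResult(t, df, .tailP(t, df, tail), tail, n, "paired t")
}

#' Uncorrected Pearson chi-square for a 2x2 table
#'
#' Plain Pearson chi-square on observed vs expected counts, 1 df, with no
#' continuity correction. Invariant under transposition and row/column
#' swaps.
#'
#' @param table 2x2 numeric matrix of counts.
#' @return a test-result list (statistic, df = 1, p, n = total count).
#' @examples
#' chiSquare2x2(matrix(c(15, 12, 18, 11), 2, byrow = TRUE))
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(table < 0) || sum(table) <= 0) stop("counts must be >= 0 with a positive total")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in the 2x2 table")
  expd <- outer(rs, cs) / n
  stat <- sum((table - expd)^2 / expd)
  .testResult(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE), "two",
              n, "Pearson chi-square (uncorrected)")
}

# Orthonormal within-subject design: for each 2-level factor a mean vector
# (1,1)/sqrt(2) and a contrast (1,-1)/sqrt(2); effects are Kronecker
# products over factors. Projecting each subject's cell means onto a unit
# contrast gives scores whose between/within-group sums of squares are
# exactly the classical split-plot sums of squares.
.withinContrasts <- function(within, levelsList) {
  base <- lapply(within, function(f) {
    list(mean = rep(1 / sqrt(2), 2), ctr = c(1, -1) / sqrt(2))
  })
  names(base) <- within
  effects <- list()
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(within)))
  names(combos) <- within
  for (i in seq_len(nrow(combos))) {
    useCtr <- stats::setNames(as.logical(combos[i, , drop = FALSE]), within)
    v <- 1
    for (f in rev(within)) {           # first factor varies slowest
      v <- kronecker(if (useCtr[[f]]) base[[f]]$ctr else base[[f]]$mean, v)
    }
    label <- paste(within[useCtr], collapse = ":")
    if (label == "") label <- "(mean)"
    effects[[label]] <- v
  }
  effects
}

#' Mixed repeated-measures ANOVA (one between, up to two within factors)
#'
#' Univariate split-plot sums of squares for a design with one
#' between-subjects factor (any number of groups, unequal sizes pooled via
#' subjects-within-groups) and up to two fully-crossed two-level
#' within-subjects factors. The between effect is tested against
#' subjects-within-groups; each within effect and its group interaction
#' against that effect's subject-interaction error term, giving the
#' familiar (1, N - g) degrees of freedom for two-level factors.
#' Within factors with more than two levels are rejected (no sphericity
#' machinery is provided). For a single two-level within factor with no
#' between factor, F equals the squared paired t; for a between-only
#' design with two groups, F equals the squared pooled independent t.
#'
#' @param data data.frame of cell means, one row per subject x within-cell.
#' @param dv name of the response column.
#' @param subject name of the subject id column.
#' @param between name of the between-subjects factor column, or NULL.
#' @param within character vector (length 0-2) of within-factor columns.
#' @return data.table: effect, F, df_num, df_den, p, error_term.
#' @export
mixedAnova <- function(data, dv = "value", subject = "subject",
                       between = "group", within = character()) {
  dt <- as.data.table(data)
  for (col in c(dv, subject, between, within)) {
    if (!col %in% names(dt)) stop("column not found: ", col)
  }
  if (length(within) > 2L) stop("at most two within-subject factors are supported")
  levelsList <- lapply(within, function(f) sort(unique(as.character(dt[[f]]))))
  names(levelsList) <- within
  for (f in within) {
    if (length(levelsList[[f]]) != 2L) {
      stop("within factor '", f, "' must have exactly 2 levels ",
           "(sphericity corrections are not provided)")
    }
  }
  # subject x cell matrix, cells ordered with the first factor slowest
  if (length(within)) {
    form <- stats::as.formula(paste(
      paste(c(subject, between), collapse = " + "), "~",
      paste(within, collapse = " + ")
    ))
    wide <- dcast(dt, form, value.var = dv)
    cellCols <- setdiff(names(wide), c(subject, between))
    expect <- do.call(CJ, c(levelsList, sorted = FALSE))
    expect <- apply(expect, 1L, paste, collapse = "_")
    if (!setequal(cellCols, expect) || anyNA(wide[, cellCols, with = FALSE])) {
      stop("design is not fully crossed: every subject needs every within cell")
    }
    Y <- as.matrix(wide[, expect, with = FALSE])
  } else {
    wide <- dt
    if (anyDuplicated(wide[[subject]])) {
      stop("one observation per subject expected when there is no within factor")
    }
    Y <- matrix(wide[[dv]], ncol = 1L)
  }
  N <- nrow(Y)
  grp <- if (is.null(between)) rep("all", N) else as.character(wide[[between]])
  if (anyNA(grp)) stop("missing between-group labels")
  g <- length(unique(grp))
  if (is.null(between)) g <- 1L
  res <- list()
  addRow <- function(effect, ssEff, dfN, ssErr, dfD, errLabel) {
    # a literally zero effect sum of squares is reported as F = 0 even when
    # the error sum of squares is also zero (all-equal degenerate input)
    Fv <- if (ssEff <= 0) 0 else (ssEff / dfN) / (ssErr / dfD)
    res[[length(res) + 1L]] <<- data.table(
      effect = effect, F = Fv, df_num = as.integer(dfN), df_den = as.integer(dfD),
      p = stats::pf(Fv, dfN, dfD, lower.tail = FALSE), error_term = errLabel
    )
  }
  if (length(within)) {
    eff <- .withinContrasts(within, levelsList)
  } else {
    eff <- list(`(mean)` = 1)
  }
  for (label in names(eff)) {
    z <- as.vector(Y %*% eff[[label]])
    zbarG <- tapply(z, grp, mean)[unique(grp)]
    nG <- tapply(z, grp, length)[unique(grp)]
    ssTotalEff <- sum(nG * (zbarG - 0)^2)          # SS of group means about zero
    ssGrand <- sum(z)^2 / N
    ssBetweenGroups <- ssTotalEff - ssGrand
    ssErr <- sum((z - ave(z, grp))^2)
    if (label == "(mean)") {
      if (!is.null(between)) {
        addRow(between, ssBetweenGroups, g - 1L, ssErr, N - g,
               "subjects-within-groups")
      }
    } else {
      errLabel <- paste0(label, " x subjects-within-groups")
      addRow(label, ssGrand, 1L, ssErr, N - g, errLabel)
      if (!is.null(between)) {
        addRow(paste(between, label, sep = ":"), ssBetweenGroups,
               g - 1L, ssErr, N - g, errLabel)
      }
    }
  }
  rbindlist(res)
}
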