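#' Standardize molecular values within acquisition batch
#'
#' value_z = (value - batch-feature mean) / batch-feature sample SD,
#' computed per (measure_type, feature, batch). After standardization the
#' batches are on a common scale and can be pooled: any batch-specific
#' affine transform of the underlying quantity is removed exactly.
#'
#' @param table long MolecularTable (subject, measure_type, feature, batch,
#'   value).
#' @return the table with a value_z column added.
#' @export
zscoreWithinBatch <- function(table) {
  dt <- data.table::copy(as.data.table(table))
  bad <- dt[, .(n = .N, s = stats::sd(value)), by = .(measure_type, feature, batch)]
  bad <- bad[n < 2L | s == 0 | is.na(s)]
  if (nrow(bad)) {
    stop("cannot z-score batch/feature with <2 subjects or zero variance: ",
         paste(paste(bad$feature, bad$batch, sep = "/"), collapse = ", "))
  }
  dt[, value_z := (value - mean(value)) / stats::sd(value),
     by = .(measure_type, feature, batch)]
  dt[]
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper: requires equal length n >= 3 and nonzero
#' variance in both arguments.
#'
#' @param x,y numeric vectors.
#' @return the correlation coefficient.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations required")
  if (anyNA(x) || anyNA(y)) stop("missing values; apply listwise deletion first")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Correlation test from r and n
#'
#' t = r sqrt(n - 2) / sqrt(1 - r^2), referred to the t distribution with
#' n - 2 df. For directional alternatives the one-tailed p equals half the
#' two-tailed p when the observed sign matches the stated direction and
#' 1 - p/2 otherwise. |r| = 1 is reported at the smallest positive double
#' with a degenerate flag.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @param tail "two", "one_neg" (alternative rho < 0) or "one_pos".
#' @return list: r, n, t_stat, df, p, tail, degenerate.
#' @export
correlationTest <- function(r, n, tail = c("two", "one_neg", "one_pos")) {
  tail <- match.arg(tail)
  if (n < 3L) stop("n must be >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  df <- n - 2L
  if (abs(r) == 1) {
    dirOk <- tail == "two" || (tail == "one_neg" && r < 0) ||
      (tail == "one_pos" && r > 0)
    return(list(r = r, n = n, t_stat = sign(r) * Inf, df = df,
                p = if (dirOk) .Machine$double.xmin else 1,
                tail = tail, degenerate = TRUE))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, n = n, t_stat = t, df = df, p = .tailP(t, df, tail),
       tail = tail, degenerate = FALSE)
}

#' Multiple-comparison adjustment
#'
#' Bonferroni (m * p capped at 1) or Holm step-down with monotonicity
#' enforcement, over the family supplied.
#'
#' @param p numeric vector of p values in (0, 1].
#' @param method "bonferroni" or "holm".
#' @return adjusted p values.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Correlate molecular features with laterality phenotypes
#'
#' Runs one directional Pearson test per plan row, with listwise deletion
#' per (feature, phenotype) pair and multiple-comparison adjustment applied
#' per declared family (default: features sharing a phenotype form one
#' family). Expression features are correlated on their batch-standardized
#' values (value_z) when available; methylation beta values are used
#' untransformed.
#'
#' @param mol long MolecularTable, ideally after [zscoreWithinBatch()].
#' @param phen per-subject phenotype table (subject plus numeric columns,
#'   e.g. LI, S_R, S_L from [lateralityIndex()]).
#' @param plan data.frame with columns feature, phenotype, tail.
#' @param method adjustment method for [adjustPvalues()].
#' @param family "phenotype" (adjust across features within a phenotype) or
#'   "all" (one family).
#' @return data.table: feature, phenotype, n, r, t_stat, p, tail,
#'   p_adjusted, method.
#' @export
correlateGrid <- function(mol, phen, plan, method = "bonferroni",
                          family = c("phenotype", "all")) {
  family <- match.arg(family)
  mol <- as.data.table(mol)
  phen <- as.data.table(phen)
  plan <- as.data.frame(plan, stringsAsFactors = FALSE)
  if (!all(c("feature", "phenotype", "tail") %in% names(plan))) {
    stop("plan needs columns feature, phenotype, tail")
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    f <- plan$feature[i]; ph <- plan$phenotype[i]; tl <- plan$tail[i]
    m <- mol[feature == f]
    if (nrow(m) == 0L) stop("feature not present in the molecular table: ", f)
    useZ <- m$measure_type[1] == "expression" && "value_z" %in% names(m)
    m <- m[, .(subject, mval = if (useZ) value_z else value)]
    if (!ph %in% names(phen)) stop("phenotype not present: ", ph)
    p2 <- phen[, .(subject, pval = get(ph))]
    mm <- merge(m, p2, by = "subject")
    mm <- mm[is.finite(mval) & is.finite(pval)]
    if (nrow(mm) < 3L) {
      stop("insufficient subject overlap for ", f, " vs ", ph,
           " (n = ", nrow(mm), ")")
    }
    r <- pearsonR(mm$mval, mm$pval)
    ct <- correlationTest(r, nrow(mm), tail = tl)
    data.table(feature = f, phenotype = ph, n = nrow(mm), r = r,
               t_stat = ct$t_stat, p = ct$p, tail = tl)
  })
  out <- rbindlist(rows)
  if (family == "phenotype") {
    out[, p_adjusted := adjustPvalues(p, method), by = phenotype]
  } else {
    out[, p_adjusted := adjustPvalues(p, method)]
  }
  out[, method := method]
  out[]
}

#' Split-cohort replication analysis
#'
#' Replicates the two-stage design: the cohort is split by acquisition
#' order into its two batches, each batch analyzed separately with a
#' directional one-tailed test, and the batch-standardized values pooled
#' for a combined two-tailed analysis.
#'
#' @param mol long MolecularTable for a single expression feature.
#' @param phen phenotype table (subject plus the phenotype column).
#' @param feature feature to analyze.
#' @param phenotype phenotype column name.
#' @param tail directional tail used within each batch.
#' @return data.table with one row per batch (one-tailed) plus the combined
#'   two-tailed row.
#' @export
splitBatchAnalysis <- function(mol, phen, feature, phenotype, tail = "one_pos") {
  feat <- feature
  mol <- as.data.table(mol)[feature == feat]
  if (nrow(mol) == 0L) stop("feature not found")
  molz <- zscoreWithinBatch(mol)
  rows <- list()
  for (b in sort(unique(molz$batch))) {
    sub <- molz[batch == b]
    rows[[b]] <- correlateGrid(
      sub, phen, data.frame(feature = feature, phenotype = phenotype, tail = tail),
      method = "bonferroni"
    )[, batch := b]
  }
  comb <- correlateGrid(
    molz, phen, data.frame(feature = feature, phenotype = phenotype, tail = "two"),
    method = "bonferroni"
  )[, batch := "combined"]
  rbindlist(c(rows, list(comb)))
}
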