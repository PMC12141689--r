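#' Per-hemisphere sensitivity to motion direction
#'
#' From the four N2 measures per subject, computes
#' S_R = A_RH(SL) - A_RH(SR) and S_L = A_LH(SR) - A_LH(SL): the
#' contralateral-minus-ipsilateral N2 mean-amplitude difference for each
#' hemisphere. Negative values mean the contralateral motion direction
#' evoked the larger (more negative) N2, i.e. greater sensitivity. The
#' per-hemisphere paired t-tests of A_h(SL) vs A_h(SR) across subjects
#' (overall and per group) are attached as the `"tests"` attribute.
#'
#' @param n2 the measure table from [measureN2()].
#' @return a data.table: subject, group, S_R, S_L (microvolts).
#' @export
hemisphereSensitivity <- function(n2) {
  wide <- dcast(as.data.table(n2), subject + group ~ hemisphere + condition,
                value.var = "mean_amplitude_uV")
  need <- c("RH_M_SL", "RH_M_SR", "LH_M_SL", "LH_M_SR")
  miss <- setdiff(need, names(wide))
  if (length(miss)) {
    stop("missing N2 measures: ", paste(miss, collapse = ", "))
  }
  if (anyNA(wide[, need, with = FALSE])) {
    stop("some subjects lack one of the four N2 measures")
  }
  out <- wide[, .(subject, group,
                  S_R = RH_M_SL - RH_M_SR,
                  S_L = LH_M_SR - LH_M_SL)]
  tests <- list()
  addT <- function(label, x, y) {
    if (length(x) >= 2L) tests[[label]] <<- pairedT(x, y)
  }
  addT("RH_all", wide$RH_M_SL, wide$RH_M_SR)
  addT("LH_all", wide$LH_M_SL, wide$LH_M_SR)
  for (g in unique(wide$group)) {
    addT(paste0("RH_", g), wide[group == g, RH_M_SL], wide[group == g, RH_M_SR])
    addT(paste0("LH_", g), wide[group == g, LH_M_SL], wide[group == g, LH_M_SR])
  }
  data.table::setattr(out, "tests", tests)
  out[]
}

#' Laterality Index and specialization class
#'
#' LI = S_R - S_L: the RH N2 difference (scroll left minus scroll right)
#' minus the LH difference (scroll right minus scroll left). Negative
#' values indicate right-hemisphere-dominant specialization, positive
#' left-dominant, zero equal sensitivity (no specialization). Subjects are
#' classed RH_specialized if LI < -epsilon, LH_specialized if
#' LI > +epsilon, otherwise none; the default dead-band epsilon = 0
#' classifies any nonzero LI. LI_z standardizes LI with the sample (n-1)
#' SD, by default within the combined analysis cohort.
#'
#' @param sens sensitivity table from [hemisphereSensitivity()].
#' @param epsilon microvolts, specialization dead-band.
#' @param zReference "combined" (default) or "group".
#' @param covariates optional data.table with columns subject, handedness
#'   (and any others), merged into the result.
#' @return a data.table: subject, group, handedness (if supplied), S_R,
#'   S_L, LI, LI_z, class.
#' @export
lateralityIndex <- function(sens, epsilon = 0, zReference = c("combined", "group"),
                            covariates = NULL) {
  zReference <- match.arg(zReference)
  out <- as.data.table(sens)[, .(subject, group, S_R, S_L)]
  if (!all(is.finite(out$S_R)) || !all(is.finite(out$S_L))) {
    stop("non-finite sensitivities")
  }
  out[, LI := S_R - S_L]
  if (zReference == "combined") {
    out[, LI_z := (LI - mean(LI)) / stats::sd(LI)]
  } else {
    out[, LI_z := (LI - mean(LI)) / stats::sd(LI), by = group]
  }
  out[, class := data.table::fifelse(LI < -epsilon, "RH_specialized",
         data.table::fifelse(LI > epsilon, "LH_specialized", "none"))]
  if (!is.null(covariates)) {
    out <- merge(out, as.data.table(covariates), by = "subject", all.x = TRUE,
                 suffixes = c("", ".cov"))
  }
  setorderv(out, "subject")
  out[]
}

#' Cohort-level laterality summary
#'
#' Per group: the percentage of subjects in each specialization class
#' (overall and split by handedness when available), the Pearson
#' correlation between the two hemispheric sensitivities with a two-tailed
#' p value (the inverse-interhemispheric-strength summary), the z-scored
#' LI distribution, and the between-group pooled-df t test on LI.
#'
#' @param results table from [lateralityIndex()].
#' @param sens table from [hemisphereSensitivity()] (defaults to the S_R,
#'   S_L columns carried in `results`).
#' @return object of class `lateralityCohortSummary`: list with elements
#'   classPct, classByHand, sensitivityCorr, groupTest, zSummary.
#' @export
cohortSummary <- function(results, sens = NULL) {
  res <- as.data.table(results)
  if (is.null(sens)) sens <- res
  sens <- as.data.table(sens)
  groups <- sort(unique(res$group))
  if (any(res[, .N, by = group]$N < 3L)) {
    stop("at least 3 subjects per group are required")
  }
  classPct <- res[, .(n = .N), by = .(group, class)]
  classPct[, pct := 100 * n / sum(n), by = group]
  classByHand <- NULL
  if ("handedness" %in% names(res)) {
    ok <- res[, .(nR = sum(handedness == "R")), by = group]
    if (any(ok$nR == 0L)) {
      warning("a group has no right-handed members; handedness breakdown omitted")
    } else {
      classByHand <- res[, .(n = .N), by = .(group, handedness, class)]
      classByHand[, pct := 100 * n / sum(n), by = .(group, handedness)]
    }
  }
  sensCorr <- sens[, {
    r <- pearsonR(S_R, S_L)
    ct <- correlationTest(r, .N, tail = "two")
    .(r = r, n = .N, t = ct$t_stat, p = ct$p)
  }, by = group]
  groupTest <- NULL
  if (length(groups) == 2L) {
    groupTest <- independentT(res[group == groups[1], LI],
                              res[group == groups[2], LI])
  }
  zSummary <- res[, .(mean_LI = mean(LI), sd_LI = stats::sd(LI),
                      mean_LI_z = mean(LI_z), median_LI_z = stats::median(LI_z)),
                  by = group]
  structure(
    list(classPct = classPct[], classByHand = classByHand,
         sensitivityCorr = sensCorr[], groupTest = groupTest,
         zSummary = zSummary[], groups = groups),
    class = "lateralityCohortSummary"
  )
}

#' @export
print.lateralityCohortSummary <- function(x, ...) {
  cat("Laterality cohort summary\n")
  cat("  specialization (% within group):\n")
  print(x$classPct, row.names = FALSE)
  cat("  S_R vs S_L correlation per group:\n")
  print(x$sensitivityCorr, row.names = FALSE)
  if (!is.null(x$groupTest)) {
    cat(sprintf("  between-group LI t(%d) = %.3f, p = %.4f\n",
                x$groupTest$df, x$groupTest$statistic, x$groupTest$p))
  }
  invisible(x)
}
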