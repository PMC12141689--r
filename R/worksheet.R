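# Exact-correlation construction helpers. All moments use the n-1
# denominator so sample Pearson correlations hit the targets exactly.
.std <- function(x) as.vector(scale(x))

.orthNoise <- function(n, basis) {
  g <- stats::rnorm(n)
  for (b in basis) g <- g - sum(g * b) / sum(b * b) * b
  .std(g)
}

#' Synthetic per-subject worksheet (replication stand-in)
#'
#' Builds a SYNTHETIC stand-in for a deposited per-subject worksheet
#' holding ERP laterality phenotypes together with combined qRT-PCR
#' expression z scores (n = 26) and, for a separate small sub-cohort
#' (n = 6), promoter CpG methylation beta values. The numbers are not
#' measurements: vectors are constructed by Gram-Schmidt orthogonalization
#' so the sample correlations equal the requested targets exactly, which
#' makes the table a fixture for verifying that the correlation grid
#' reproduces published-scale coefficients from worksheet-style input.
#'
#' The default targets use a self-consistent sign set: because
#' LI = S_R - S_L, the correlations of one variable with LI, S_R and S_L
#' cannot have arbitrary independent signs; the defaults keep the
#' magnitudes 0.465 / 0.441 / 0.423 with expression correlating positively
#' with LI and S_R and negatively with S_L, and solve the S_R-S_L
#' correlation (about -0.73) that makes all three exact simultaneously.
#'
#' @param n number of subjects in the expression cohort.
#' @param nMeth number of subjects in the methylation sub-cohort.
#' @param rLI,rSR,rSL expression correlation targets with LI, S_R, S_L.
#' @param rMeth named methylation-vs-LI correlation targets per probe.
#' @param seed integer seed (construction is deterministic given the seed).
#' @return list: `phenotypes` (subject, group, LI, S_R, S_L),
#'   `expression` (long MolecularTable with the combined z in `value`),
#'   `methPhenotypes` and `methylation` (the n = 6 sub-cohort).
#' @export
syntheticWorksheet <- function(n = 26, nMeth = 6,
                               rLI = 0.465, rSR = 0.441, rSL = -0.423,
                               rMeth = c(cg12099727 = -0.942,
                                         cg09265173 = 0.898),
                               seed = 20240901) {
  if (n < 5L) stop("n must be at least 5")
  # corr(u, v) making corr(y, u - v) = rLI exact given corr(y,u), corr(y,v)
  cfun <- function(c) (rSR - rSL) / sqrt(2 - 2 * c) - rLI
  cc <- stats::uniroot(cfun, c(-0.999, 0.999), tol = 1e-14)$root
  alpha <- (rSR - rSL * cc) / (1 - cc^2)
  gamma <- (rSL - rSR * cc) / (1 - cc^2)
  d2 <- 1 - (alpha^2 + gamma^2 + 2 * alpha * gamma * cc)
  if (d2 < 0) stop("correlation targets are jointly infeasible")
  .withSeed(seed, {
    u <- .std(stats::rnorm(n))
    v0 <- .orthNoise(n, list(u))
    v <- cc * u + sqrt(1 - cc^2) * v0
    e <- .orthNoise(n, list(u, v0))
    y <- alpha * u + gamma * v + sqrt(d2) * e
    subj <- sprintf("WS%02d", seq_len(n))
    phen <- data.table(
      subject = subj, group = "WS",
      S_R = -1 + u, S_L = -2 + v
    )
    phen[, LI := S_R - S_L]
    expr <- data.table(
      subject = subj, measure_type = "expression", feature = "BUD23",
      batch = ifelse(seq_len(n) %% 2L == 1L, "B1", "B2"),
      value = y
    )
    msub <- sprintf("WM%02d", seq_len(nMeth))
    zli <- .std(stats::rnorm(nMeth))
    mphen <- data.table(subject = msub, group = "WS", LI = 1.2 * zli + 0.3)
    mrows <- lapply(names(rMeth), function(p) {
      r <- rMeth[[p]]
      w <- r * zli + sqrt(1 - r^2) * .orthNoise(nMeth, list(zli))
      data.table(subject = msub, measure_type = "methylation", feature = p,
                 batch = "array1", value = 0.5 + 0.08 * w)
    })
    list(phenotypes = phen[], expression = expr[],
         methPhenotypes = mphen[], methylation = rbindlist(mrows))
  })
}
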