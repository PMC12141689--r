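test_that("truth table satisfies the LI identity and is seed-deterministic", {
  cfg <- smallConfig(nTC = 10L, nWS = 10L, seed = 3L)
  tr <- simulateTruth(cfg)
  expect_identical(tr$LI_true, tr$S_R_true - tr$S_L_true)
  expect_true(all(tr$S_R_true <= 0) && all(tr$S_L_true <= 0))
  expect_identical(tr, simulateTruth(cfg))
  cfg2 <- smallConfig(nTC = 10L, nWS = 10L, seed = 4L)
  expect_false(isTRUE(all.equal(tr$LI_true, simulateTruth(cfg2)$LI_true)))
  # configured covariate counts are hit exactly
  expect_identical(tr[, sum(handedness == "L"), by = group]$V1, c(1L, 1L))
})

test_that("degenerate allocations give deterministic laterality", {
  cfg <- smallConfig(seed = 5L, sensitivityScale = 0,
                     allocationParams = list(TC = 0.2, WS = 0.8))
  tr <- simulateTruth(cfg)
  expect_equal(tr[group == "TC", unique(round(LI_true, 12))], -1.5)
  expect_equal(tr[group == "WS", unique(round(LI_true, 12))], 0.8)
  # pi = 0.5: both hemispheres equally sensitive, LI 0 regardless of T
  cfg2 <- smallConfig(seed = 5L, groupMeans = c(TC = 0, WS = 0),
                      allocationParams = list(TC = 0.5, WS = 0.5))
  tr2 <- simulateTruth(cfg2)
  expect_equal(tr2$LI_true, rep(0, nrow(tr2)))
  expect_true(all(tr2$S_R_true < 0))
})

test_that("group mean LI hits its target within the analytic Monte-Carlo CI", {
  n <- 1000L
  cfg <- SimulationConfig(
    nPerGroup = c(TC = n), groupMeans = c(TC = -1.5),
    allocationParams = list(TC = c(a = 0.45804, b = 1.54196)),
    leftHanded = c(TC = 2L), femaleCount = c(TC = 15L), seed = 11L
  )
  tr <- simulateTruth(cfg)
  # closed-form Var(LI) from the Gamma and Beta moments
  a <- 0.45804; b <- 1.54196
  e <- a / (a + b); v <- a * b / ((a + b)^2 * (a + b + 1))
  muT <- -1.5 / (2 * e - 1); sdT <- 0.7
  m2T <- muT^2 + sdT^2
  m2pi <- 4 * (v + e^2) - 4 * e + 1          # E[(2pi-1)^2]
  varLI <- m2T * m2pi - (muT * (2 * e - 1))^2
  hw <- stats::qnorm(0.995) * sqrt(varLI / n)
  expect_lt(abs(mean(tr$LI_true) - (-1.5)), hw)
})

test_that("hemispheric sensitivities are anticorrelated under the default allocation", {
  cfg <- SimulationConfig(nPerGroup = c(TC = 1000L, WS = 1000L),
                          leftHanded = c(TC = 74L, WS = 276L),
                          femaleCount = c(TC = 556L, WS = 621L), seed = 13L)
  tr <- simulateTruth(cfg)
  cors <- tr[, .(r = cor(S_R_true, S_L_true)), by = group]
  expect_true(all(cors$r < 0))
  expect_true(all(cors$r < -0.4))   # strongly inverse, not borderline
})

test_that("zero-amplitude noise-free epochs are flat and same-seed synthesis is identical", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L, componentParams = list(
    P1 = list(latency = 155, width = 15, amplitude = 0),
    N1 = list(latency = 148, width = 15, amplitude = 0),
    N2 = list(latency = 190, width = 15, amplitude = 0)
  ))
  tr <- simulateTruth(cfg)
  tr[, c("S_R_true", "S_L_true", "LI_true") := 0]
  ep <- synthesizeEpochs(tr, cfg)
  expect_equal(max(abs(epochsData(ep)$amplitude_uV)), 0)
  cfgN <- smallConfig(nTC = 2L, nWS = 2L, noiseSd = 3, eogNoiseSd = 2)
  trN <- simulateTruth(cfgN)
  e1 <- synthesizeEpochs(trN, cfgN)
  e2 <- synthesizeEpochs(trN, cfgN)
  expect_identical(epochsData(e1), epochsData(e2))
  cfgN2 <- smallConfig(nTC = 2L, nWS = 2L, noiseSd = 3, eogNoiseSd = 2, seed = 8L)
  e3 <- synthesizeEpochs(trN, cfgN2)
  expect_false(identical(epochsData(e1)$amplitude_uV, epochsData(e3)$amplitude_uV))
})

test_that("component latency outside the epoch window is rejected", {
  expect_error(
    smallConfig(componentParams = list(
      P1 = list(latency = 1500, width = 15, amplitude = 4),
      N1 = list(latency = 148, width = 15, amplitude = -4),
      N2 = list(latency = 190, width = 15, amplitude = -5)
    )),
    "latency outside"
  )
})

test_that("window-mean sensitivities are recovered within the analytic SE bound", {
  # White noise only: averaging over 10 window samples x 3 channels x
  # nTrials gives Var(A) = sd^2/(30 nTrials) per condition and
  # Var(S) = 2 Var(A); no re-referencing/baseline so the bound is exact.
  nTr <- 100L; sdN <- 5
  cfg <- smallConfig(nTC = 2L, nWS = 2L, nTrials = nTr, seed = 19L,
                     noiseSd = sdN, pinkFraction = 0,
                     conditions = c("M_SL", "M_SR"))
  tr <- simulateTruth(cfg)
  ep <- synthesizeEpochs(tr, cfg)
  avgs <- averageConditions(ep, minTrials = 1)
  sens <- hemisphereSensitivity(measureN2(avgs))
  m <- merge(sens, tr, by = "subject")
  se <- sdN * sqrt(2 / (30 * nTr))
  expect_true(all(abs(m$S_R - m$S_R_true) < 3 * se))
  expect_true(all(abs(m$S_L - m$S_L_true) < 3 * se))
})

test_that("artifact injection respects the configured rate", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 15L, seed = 23L,
                     conditions = c("M_SL", "M_SR"), artifactRate = 0)
  tr <- simulateTruth(cfg)
  ep <- synthesizeEpochs(tr, cfg)
  inj0 <- injectArtifacts(ep, cfg)
  expect_identical(epochsData(inj0$epochs), epochsData(ep))
  expect_true(all(!inj0$flags$artifact))

  cfg1 <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 15L, seed = 23L,
                      conditions = c("M_SL", "M_SR"), artifactRate = 1)
  inj1 <- injectArtifacts(ep, cfg1)
  expect_true(all(inj1$flags$artifact))
  expect_warning(rej <- rejectArtifacts(inj1$epochs), "all trials rejected")
  expect_true(all(rej$log$rejected))

  # rate 0.1 over 300 trials: count inside the central 99% binomial interval
  cfg2 <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 75L, seed = 29L,
                      conditions = c("M_SL"), artifactRate = 0.1)
  tr2 <- simulateTruth(cfg2)
  ep2 <- synthesizeEpochs(tr2, cfg2)
  inj2 <- injectArtifacts(ep2, cfg2)
  nFlag <- sum(inj2$flags$artifact)
  expect_gte(nFlag, qbinom(0.005, 300, 0.1))
  expect_lte(nFlag, qbinom(0.995, 300, 0.1))
})

test_that("molecular generator reproduces the requested correlation structure", {
  # rho = 1, noise-free: within each batch the z-scored value tracks LI exactly
  cfg <- smallConfig(nTC = 6L, nWS = 6L, seed = 31L,
                     rhoExpression = c(BUD23 = 1))
  tr <- simulateTruth(cfg)
  mol <- zscoreWithinBatch(simulateMolecular(tr, cfg))
  m <- merge(mol[feature == "BUD23"], tr, by = "subject")
  for (b in unique(m$batch)) {
    expect_equal(m[batch == b, cor(value_z, LI_true)], 1, tolerance = 1e-12)
  }
  # null rho at n = 10000: |r| below the 2.58/sqrt(n) bound (with slack to 0.05)
  cfg0 <- SimulationConfig(nPerGroup = c(WS = 10000L), groupMeans = c(WS = 0.8),
    allocationParams = list(WS = c(a = 1.26607, b = 0.73393)),
    rhoExpression = c(GENE = 0), leftHanded = c(WS = 0L),
    femaleCount = c(WS = 0L), seed = 37L)
  tr0 <- simulateTruth(cfg0)
  mol0 <- zscoreWithinBatch(simulateMolecular(tr0, cfg0))
  m0 <- merge(mol0[feature == "GENE"], tr0, by = "subject")
  expect_lt(abs(cor(m0$value_z, m0$LI_true)), 0.05)
})

test_that("recovered correlation is unbiased over seeds (Monte-Carlo oracle)", {
  rs <- vapply(1:500, function(s) {
    cfg <- SimulationConfig(nPerGroup = c(WS = 200L), groupMeans = c(WS = 0.8),
      allocationParams = list(WS = c(a = 1.26607, b = 0.73393)),
      rhoExpression = c(GENE = 0.5), leftHanded = c(WS = 0L),
      femaleCount = c(WS = 0L), seed = 40000L + s)
    tr <- simulateTruth(cfg)
    mol <- zscoreWithinBatch(simulateMolecular(tr, cfg))
    m <- merge(mol[feature == "GENE"], tr, by = "subject")
    cor(m$value_z, m$LI_true)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.03)
})

test_that("batch affine scales are removed exactly by within-batch z-scoring", {
  cfg <- smallConfig(nTC = 8L, nWS = 8L, seed = 41L)
  tr <- simulateTruth(cfg)
  mol <- simulateMolecular(tr, cfg)
  lat <- attr(mol, "latent")
  mz <- zscoreWithinBatch(mol)
  m <- merge(mz[measure_type == "expression"], lat, by = c("subject", "feature"))
  for (b in unique(m$batch)) {
    expect_equal(m[batch == b, cor(value_z, latent)], 1, tolerance = 1e-12)
  }
  # methylation stays within [0, 1]
  expect_true(all(mol[measure_type == "methylation", value >= 0 & value <= 1]))
})
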