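test_that("mean amplitude averages the window inclusively", {
  av <- directAverages(function(su, ch, t, cond) rep(5, length(t)))
  w <- defaultWindows()$N2_RH
  ma <- meanAmplitude(av, w)
  expect_equal(unique(ma$mean_amplitude_uV), 5)

  # linear ramp: mean equals the value at the window midpoint of the grid
  av2 <- directAverages(function(su, ch, t, cond) 0.1 * t)
  ma2 <- meanAmplitude(av2, w, conditions = "M_SL")
  grid <- seq(-100, 996, by = 4)
  mid <- mean(grid[grid >= 155 & grid <= 195])
  expect_equal(ma2$mean_amplitude_uV, 0.1 * mid, tolerance = 1e-12)

  # endpoints inclusive: grid samples 156..192 at 250 Hz
  expect_equal(sum(grid >= 155 & grid <= 195), 10L)
  expect_error(meanAmplitude(av, ComponentWindow("X", 1000, 1100, "rhSet")),
               "no samples")
})

test_that("measures are linear in the waveform", {
  f1 <- function(su, ch, t, cond) sin(t / 40)
  f2 <- function(su, ch, t, cond) -exp(-(t - 180)^2 / 500)
  a <- 2.5; b <- -1.25
  w <- defaultWindows()$N2_LH
  m1 <- meanAmplitude(directAverages(f1), w, conditions = "M_SL")$mean_amplitude_uV
  m2 <- meanAmplitude(directAverages(f2), w, conditions = "M_SL")$mean_amplitude_uV
  mc <- meanAmplitude(directAverages(function(su, ch, t, cond) {
    a * f1(su, ch, t, cond) + b * f2(su, ch, t, cond)
  }), w, conditions = "M_SL")$mean_amplitude_uV
  expect_equal(mc, a * m1 + b * m2, tolerance = 1e-12)
})

test_that("peak latency picks the polarity-matched extremum with earliest-tie rule", {
  w <- ComponentWindow("N2", 155, 195, "rhSet", "negative")
  av <- directAverages(function(su, ch, t, cond) -exp(-(t - 190)^2 / 450))
  pl <- peakLatency(av, w, conditions = "M_SL")
  expect_true(pl$peak_latency_ms %in% c(188, 192))
  expect_false(pl$degenerate)

  # two equal minima at 160 and 180: earliest wins
  av2 <- directAverages(function(su, ch, t, cond) {
    x <- rep(0, length(t)); x[t == 160] <- -3; x[t == 180] <- -3; x
  })
  expect_equal(peakLatency(av2, w, conditions = "M_SL")$peak_latency_ms, 160)

  # flat waveform: tStart with degenerate flag
  av3 <- directAverages(function(su, ch, t, cond) rep(0, length(t)))
  pl3 <- peakLatency(av3, w, conditions = "M_SL")
  expect_equal(pl3$peak_latency_ms, 155)
  expect_true(pl3$degenerate)

  # positive-polarity window on a pure negative deflection: flagged
  wp <- ComponentWindow("X", 155, 195, "rhSet", "positive")
  av4 <- directAverages(function(su, ch, t, cond) -1 - exp(-(t - 175)^2 / 200))
  pl4 <- peakLatency(av4, wp, conditions = "M_SL")
  expect_true(pl4$degenerate)
  win <- seq(156, 192, 4)
  expect_equal(pl4$peak_amplitude_uV, max(-1 - exp(-(win - 175)^2 / 200)))
})

test_that("electrode-set averaging commutes with time averaging", {
  av <- directAverages(function(su, ch, t, cond) {
    match(ch, defaultChannelLayout()@channels) * sin(t / 25)
  })
  w <- defaultWindows()$N2_RH
  d <- epochsData(av)[condition == "M_SL"]
  lay <- defaultChannelLayout()
  sub <- d[channel %in% lay@rhSet & time_ms >= 155 & time_ms <= 195]
  byChannelFirst <- mean(sub[, mean(amplitude_uV), by = channel]$V1)
  byTimeFirst <- mean(sub[, mean(amplitude_uV), by = time_ms]$V1)
  ours <- meanAmplitude(av, w, conditions = "M_SL")$mean_amplitude_uV
  expect_equal(byChannelFirst, byTimeFirst, tolerance = 1e-12)
  expect_equal(ours, byChannelFirst, tolerance = 1e-12)
})

test_that("visual component measurement pools motion conditions by trial count", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 4L, seed = 3L)
  tr <- simulateTruth(cfg)
  ep <- synthesizeEpochs(tr, cfg)
  av <- averageConditions(ep, minTrials = 1)
  vis <- measureVisualComponents(av)
  # noise-free: P1 mean amplitude = base amplitude x kernel window mean
  grid <- seq(-100, 996, by = 4)
  kWin <- mean(exp(-(grid[grid >= 130 & grid <= 170] - 155)^2 / (2 * 15^2)))
  expect_equal(vis[group == "TC" & window == "M_P1", unique(round(mean_amplitude_uV, 9))],
               round(4 * kWin, 9))
  expect_equal(vis[group == "WS" & window == "M_P1", unique(round(mean_amplitude_uV, 9))],
               round(2.2 * kWin, 9))
  # N1 identical across groups (no group effect configured)
  expect_equal(vis[window == "P_N1", var(mean_amplitude_uV)], 0, tolerance = 1e-20)
  # peak latencies on the sampling grid near the planted peaks
  expect_true(all(abs(vis[window == "M_P1", peak_latency_ms] - 155) <= 2))
  expect_true(all(abs(vis[window == "P_N1", peak_latency_ms] - 148) <= 2))
  # pooled motion trial counts are the sum over scroll directions
  expect_equal(unique(vis[window == "M_P1", n_trials]), 8L)
  avNoP <- averageConditions(
    new("ErpEpochs", data = epochsData(ep)[condition != "P_CHANGE"],
        samplingRate = 250, layout = ep@layout), minTrials = 1)
  expect_error(measureVisualComponents(avNoP), "required")
})

test_that("group-attenuated P1 yields a motion-selective group difference", {
  cfg <- smallConfig(nTC = 10L, nWS = 10L, nTrials = 30L, seed = 47L,
                     noiseSd = 3, pinkFraction = 0.2)
  tr <- simulateTruth(cfg)
  av <- averageConditions(synthesizeEpochs(tr, cfg), minTrials = 1)
  vis <- measureVisualComponents(av)
  p1 <- independentT(vis[window == "M_P1" & group == "TC", mean_amplitude_uV],
                     vis[window == "M_P1" & group == "WS", mean_amplitude_uV])
  n1 <- independentT(vis[window == "P_N1" & group == "TC", mean_amplitude_uV],
                     vis[window == "P_N1" & group == "WS", mean_amplitude_uV])
  expect_gt(p1$statistic, 0)      # TC P1 larger than WS
  expect_lt(p1$p, 0.01)
  expect_gt(n1$p, 0.05)           # color N1 intact
})

test_that("N2 measurement recovers planted asymmetries and mirror symmetry", {
  cfg <- smallConfig(nTC = 3L, nWS = 3L, nTrials = 2L, seed = 51L,
                     conditions = c("M_SL", "M_SR"))
  tr <- simulateTruth(cfg)
  av <- averageConditions(synthesizeEpochs(tr, cfg), minTrials = 1)
  n2 <- measureN2(av)
  wide <- dcast(n2, subject ~ hemisphere + condition, value.var = "mean_amplitude_uV")
  m <- merge(wide, tr, by = "subject")
  expect_equal(m[, RH_M_SL - RH_M_SR], m$S_R_true, tolerance = 1e-12)
  expect_equal(m[, LH_M_SR - LH_M_SL], m$S_L_true, tolerance = 1e-12)

  # hemispherically symmetric planted signal: A_LH(d) = A_RH(mirror d)
  lay <- defaultChannelLayout()
  avSym <- directAverages(function(su, ch, t, cond) {
    hemi <- if (ch %in% lay@lhSet) "LH" else if (ch %in% lay@rhSet) "RH" else NA
    if (is.na(hemi)) return(rep(0, length(t)))
    contra <- (hemi == "RH" && cond == "M_SL") || (hemi == "LH" && cond == "M_SR")
    -(4 + 2 * contra) * exp(-(t - 190)^2 / 450)
  })
  n2s <- measureN2(avSym)
  ws <- dcast(n2s, subject ~ hemisphere + condition, value.var = "mean_amplitude_uV")
  expect_equal(ws$LH_M_SR, ws$RH_M_SL, tolerance = 1e-12)
  expect_equal(ws$LH_M_SL, ws$RH_M_SR, tolerance = 1e-12)
})
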