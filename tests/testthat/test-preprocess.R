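test_that("mastoid re-referencing removes common-mode activity", {
  ep <- flatEpochs(7)
  out <- rereferenceToMastoids(ep)
  expect_equal(max(abs(epochsData(out)$amplitude_uV)), 0)

  # zero mastoids: identity
  lay <- defaultChannelLayout()
  ep2 <- flatEpochs(function(ch, t) {
    if (ch %in% lay@mastoids) rep(0, length(t)) else sin(t / 50)
  })
  out2 <- rereferenceToMastoids(ep2)
  expect_equal(epochsData(out2)$amplitude_uV, epochsData(ep2)$amplitude_uV)

  # differences between non-mastoid channels are reference-invariant
  ep3 <- flatEpochs(function(ch, t) sin(t / 30) * match(ch, lay@channels))
  d3 <- epochsData(rereferenceToMastoids(ep3))
  raw <- epochsData(ep3)
  dif <- function(d) d[channel == "O1", amplitude_uV] - d[channel == "PO7", amplitude_uV]
  expect_equal(dif(d3), dif(raw), tolerance = 1e-12)

  epBad <- flatEpochs(1)
  epBad@data <- epBad@data[channel != "M1"]
  expect_error(rereferenceToMastoids(epBad), "mastoid")
})

test_that("baseline correction zeroes the pre-stimulus mean and preserves slope", {
  ep <- flatEpochs(7)
  out <- baselineCorrect(ep)
  expect_equal(max(abs(epochsData(out)$amplitude_uV)), 0)

  # already baseline-zero: idempotent
  ep2 <- flatEpochs(function(ch, t) ifelse(t >= 0, 5, 0) - mean(ifelse(t >= 0, 5, 0)[t < 0]))
  b1 <- baselineCorrect(ep2)
  b2 <- baselineCorrect(b1)
  expect_equal(epochsData(b2)$amplitude_uV, epochsData(b1)$amplitude_uV,
               tolerance = 1e-12)

  # ramp a + b t: slope preserved, window mean exactly zero
  ep3 <- flatEpochs(function(ch, t) 2 + 0.03 * t)
  d3 <- epochsData(baselineCorrect(ep3))[channel == "O1"]
  fit <- coef(lm(amplitude_uV ~ time_ms, d3))
  expect_equal(unname(fit[2]), 0.03, tolerance = 1e-12)
  expect_equal(d3[time_ms >= -100 & time_ms < 0, mean(amplitude_uV)], 0,
               tolerance = 1e-12)
  expect_error(baselineCorrect(ep, window = c(-500, -400)), "no samples")
})

test_that("zero-phase low-pass meets its magnitude contract", {
  # DC gain 1
  dc <- lowpassFilter(flatEpochs(7))
  expect_lt(max(abs(epochsData(dc)$amplitude_uV - 7)), 1e-9)

  fftAmp <- function(x, f, fs = 250) {
    n <- length(x)
    bin <- round(f * n / fs) + 1L
    abs(fft(x))[bin]
  }
  # 60 Hz suppressed to <= 10% (DFT magnitude oracle)
  s60 <- flatEpochs(function(ch, t) sin(2 * pi * 60 * t / 1000))
  f60 <- lowpassFilter(s60)
  x0 <- epochsData(s60)[channel == "O1", amplitude_uV]
  x1 <- epochsData(f60)[channel == "O1", amplitude_uV]
  expect_lt(fftAmp(x1, 60) / fftAmp(x0, 60), 0.10)
  # 5 Hz preserved within 5%
  s5 <- flatEpochs(function(ch, t) sin(2 * pi * 5 * t / 1000))
  f5 <- lowpassFilter(s5)
  y0 <- epochsData(s5)[channel == "O1", amplitude_uV]
  y1 <- epochsData(f5)[channel == "O1", amplitude_uV]
  expect_lt(abs(fftAmp(y1, 5) / fftAmp(y0, 5) - 1), 0.05)
  # peak latency of a slow component shifts by < 1 sample
  g <- flatEpochs(function(ch, t) -exp(-(t - 190)^2 / 450))
  fg <- lowpassFilter(g)
  pk0 <- epochsData(g)[channel == "O1"][which.min(amplitude_uV), time_ms]
  pk1 <- epochsData(fg)[channel == "O1"][which.min(amplitude_uV), time_ms]
  expect_lte(abs(pk1 - pk0), 4)
  expect_error(lowpassFilter(flatEpochs(1), cutoff = 125), "Nyquist")
})

test_that("threshold rejection removes exactly the offending trials", {
  lay <- defaultChannelLayout()
  ep <- flatEpochs(function(ch, t) rep(0, length(t)), nTrials = 110L)
  dt <- epochsData(ep)
  # trials 1..10 get a 250 uV spike on O1 at 400 ms
  dt[channel == "O1" & time_ms == 400 & trial <= 10, amplitude_uV := 250]
  # trial 11 peaks exactly at the threshold: retained (strictly-greater rule)
  dt[channel == "O1" & time_ms == 400 & trial == 11, amplitude_uV := 200]
  ep2 <- new("ErpEpochs", data = dt, samplingRate = 250, layout = lay)
  res <- rejectArtifacts(ep2)
  expect_equal(sum(!res$log$rejected), 100L)
  expect_equal(sort(res$log[rejected == TRUE, trial]), 1:10)
  expect_true(all(res$log[rejected == TRUE, reason] == "amplitude"))
  expect_false(res$log[trial == 11, rejected])
  # retained trials unmodified; counts reconcile
  expect_equal(nrow(epochsData(res$epochs)) / (length(lay@channels) * 275), 100)
  ret <- attr(res$log, "retention")
  expect_equal(ret$n_total, ret$n_retained + res$log[, sum(rejected)])
})

test_that("EOG criteria catch ocular artifacts with the documented reasons", {
  lay <- defaultChannelLayout()
  ep <- flatEpochs(function(ch, t) rep(0, length(t)), nTrials = 3L)
  dt <- epochsData(ep)
  dt[channel == "HEOG" & trial == 1 & time_ms >= 300, amplitude_uV := 60]
  dt[channel == "VEOG" & trial == 2, amplitude_uV := 300 * exp(-(time_ms - 400)^2 / 1250)]
  ep2 <- new("ErpEpochs", data = dt, samplingRate = 250, layout = lay)
  res <- rejectArtifacts(ep2, ampChannels = c(lay@occipitalSet, lay@lhSet, lay@rhSet))
  lg <- res$log[order(trial)]
  expect_equal(lg$reason, c("HEM", "VEOG", "none"))
})

test_that("rejection recovers simulator truth flags with high accuracy", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 75L, seed = 21L,
                     conditions = c("M_SL"), artifactRate = 0.12,
                     noiseSd = 6, eogNoiseSd = 5, pinkFraction = 0.2)
  tr <- simulateTruth(cfg)
  inj <- injectArtifacts(synthesizeEpochs(tr, cfg), cfg)
  res <- rejectArtifacts(inj$epochs)
  lg <- merge(res$log, inj$flags, by = c("subject", "condition", "trial"))
  expect_gte(lg[artifact == TRUE, mean(rejected)], 0.95)
  expect_gte(lg[artifact == FALSE, mean(!rejected)], 0.95)
})

test_that("condition averaging is the arithmetic mean with trial accounting", {
  lay <- defaultChannelLayout()
  ep <- flatEpochs(function(ch, t) rep(0, length(t)), nTrials = 2L)
  dt <- epochsData(ep)
  dt[trial == 1, amplitude_uV := 1]
  dt[trial == 2, amplitude_uV := 3]
  ep2 <- new("ErpEpochs", data = dt, samplingRate = 250, layout = lay)
  expect_warning(av <- averageConditions(ep2), "floor")
  expect_equal(unique(epochsData(av)$amplitude_uV), 2)
  expect_equal(nTrials(av)$n_trials, 2L)
  expect_identical(av@flaggedSubjects, "s1")
  # identical trials: average equals any trial
  av2 <- averageConditions(ep2, minTrials = 1)
  expect_equal(unique(epochsData(av2)$amplitude_uV), 2)

  # CLT bound: n noisy trials of a planted constant
  n <- 64L; sdn <- 4
  set.seed(1)
  ep3 <- flatEpochs(function(ch, t) rep(5, length(t)), nTrials = n)
  d3 <- epochsData(ep3)
  d3[, amplitude_uV := amplitude_uV + rnorm(.N, 0, sdn)]
  av3 <- averageConditions(new("ErpEpochs", data = d3, samplingRate = 250,
                               layout = lay), minTrials = 1)
  grandMean <- epochsData(av3)[, mean(amplitude_uV)]
  expect_lt(abs(grandMean - 5), 3 * sdn / sqrt(n * 275 * 15))
})

test_that("a common waveform added to all channels leaves component measures unchanged", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L, nTrials = 2L, seed = 43L)
  tr <- simulateTruth(cfg)
  ep <- synthesizeEpochs(tr, cfg)
  common <- function(t) 12 * sin(2 * pi * 3 * t / 1000) + 4
  d2 <- epochsData(ep)
  d2[, amplitude_uV := amplitude_uV + common(time_ms)]
  ep2 <- new("ErpEpochs", data = d2, samplingRate = 250, layout = ep@layout)
  measure <- function(e) {
    pr <- preprocessEpochs(e, minTrials = 1)
    measureN2(pr$averages)$mean_amplitude_uV
  }
  expect_equal(measure(ep2), measure(ep), tolerance = 1e-9)
})

test_that("the preprocessing step list is validated and ordered as requested", {
  cfg <- smallConfig(nTC = 2L, nWS = 2L)
  ep <- synthesizeEpochs(simulateTruth(cfg), cfg)
  expect_error(preprocessEpochs(ep, steps = c("rereference", "despike")),
               "unknown preprocessing step")
  out <- preprocessEpochs(ep, steps = c("rereference", "baseline"))
  expect_s4_class(out$averages, "ErpEpochs")
  expect_null(out$rejectionLog)
})
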