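library(data.table)

# Small cohort config; noise-free unless stated.
smallConfig <- function(nTC = 3L, nWS = 3L, nTrials = 2L, seed = 7L, ...) {
  args <- list(
    nPerGroup = c(TC = nTC, WS = nWS), nTrials = nTrials,
    noiseSd = 0, eogNoiseSd = 0, artifactRate = 0,
    leftHanded = c(TC = 1L, WS = 1L),
    femaleCount = c(TC = min(2L, nTC), WS = min(2L, nWS)),
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(SimulationConfig, args)
}

# One-subject ErpEpochs whose every channel carries f(t) (or a per-channel
# function of channel name and t).
flatEpochs <- function(f, layout = defaultChannelLayout(), nTrials = 1L,
                       condition = "M_SL", fs = 250) {
  t <- seq(-100, 996, by = 1000 / fs)
  rows <- lapply(seq_len(nTrials), function(tr) {
    dt <- data.table(channel = rep(layout@channels, each = length(t)),
                     time_ms = rep(t, length(layout@channels)))
    dt[, amplitude_uV := if (is.function(f)) {
      unlist(lapply(layout@channels, function(ch) f(ch, t)))
    } else rep(f, .N)]
    dt[, `:=`(subject = "s1", group = "TC", handedness = "R",
              condition = condition, trial = tr)]
    dt
  })
  new("ErpEpochs", data = rbindlist(rows), samplingRate = fs, layout = layout)
}

# SubjectAverages built directly from a channel-wise waveform function
# f(channel, t, condition); one subject unless subjects given.
directAverages <- function(f, conditions = c("M_SL", "M_SR"),
                           subjects = "s1", group = "TC",
                           layout = defaultChannelLayout(), fs = 250,
                           nTrials = 10L) {
  t <- seq(-100, 996, by = 1000 / fs)
  rows <- list()
  for (su in subjects) for (cond in conditions) {
    dt <- data.table(channel = rep(layout@channels, each = length(t)),
                     time_ms = rep(t, length(layout@channels)))
    dt[, amplitude_uV := unlist(lapply(layout@channels, function(ch) f(su, ch, t, cond)))]
    dt[, `:=`(subject = su, group = group, condition = cond)]
    rows[[length(rows) + 1L]] <- dt
  }
  nU <- CJ(subject = subjects, condition = conditions)[, n_trials := nTrials]
  new("SubjectAverages", data = rbindlist(rows), nTrialsUsed = nU,
      samplingRate = fs, layout = layout, flaggedSubjects = character())
}

# Measurement-table row builder for laterality tests.
n2Table <- function(subject, group, aRhSl, aRhSr, aLhSl, aLhSr) {
  aRhSl <- rep_len(aRhSl, length(subject)); aRhSr <- rep_len(aRhSr, length(subject))
  aLhSl <- rep_len(aLhSl, length(subject)); aLhSr <- rep_len(aLhSr, length(subject))
  rbindlist(lapply(seq_along(subject), function(i) {
    data.table(
      subject = subject[i], group = group[i], window = "N2",
      hemisphere = c("RH", "RH", "LH", "LH"),
      condition = c("M_SL", "M_SR", "M_SL", "M_SR"),
      mean_amplitude_uV = c(aRhSl[i], aRhSr[i], aLhSl[i], aLhSr[i]),
      peak_latency_ms = 190, n_trials = 100L
    )
  }))
}
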