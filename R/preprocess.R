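# Odd-reflection padded forward-backward filtering of one series.
.filtfiltPadded <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 100L)
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np)]
  y <- c(pre, x, post)
  y <- signal::filter(b, a, y)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}

#' Re-reference epochs to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels, sample by sample, from
#' every channel (including the mastoids themselves). Because the same
#' waveform is removed from every channel, differences between channels --
#' and therefore every downstream component measure -- are invariant to any
#' common-mode activity.
#'
#' @param epochs an [ErpEpochs-class] object.
#' @return an [ErpEpochs-class] object.
#' @export
rereferenceToMastoids <- function(epochs) {
  layout <- epochs@layout
  if (!all(layout@mastoids %in% unique(epochs@data$channel))) {
    stop("mastoid channel(s) missing from the epochs: ",
         paste(setdiff(layout@mastoids, unique(epochs@data$channel)),
               collapse = ", "))
  }
  dt <- data.table::copy(epochs@data)
  ref <- dt[channel %in% layout@mastoids,
            .(.ref = mean(amplitude_uV)),
            by = .(subject, condition, trial, time_ms)]
  dt[ref, amplitude_uV := amplitude_uV - i..ref,
     on = c("subject", "condition", "trial", "time_ms")]
  new("ErpEpochs", data = dt, samplingRate = epochs@samplingRate, layout = layout)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' pre-stimulus baseline window. The window is half-open, `[from, to)`,
#' matching the sample-covers-`[t, t + delta)` time convention, so the
#' default `c(-100, 0)` uses exactly the pre-stimulus samples. After
#' correction the window mean is zero to floating point.
#'
#' @param epochs an [ErpEpochs-class] object.
#' @param window ms pair.
#' @return an [ErpEpochs-class] object.
#' @export
baselineCorrect <- function(epochs, window = c(-100, 0)) {
  tt <- unique(epochs@data$time_ms)
  sel <- tt >= window[1] & tt < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  dt <- data.table::copy(epochs@data)
  base <- dt[time_ms >= window[1] & time_ms < window[2],
             .(.bl = mean(amplitude_uV)),
             by = .(subject, condition, trial, channel)]
  dt[base, amplitude_uV := amplitude_uV - i..bl,
     on = c("subject", "condition", "trial", "channel")]
  new("ErpEpochs", data = dt, samplingRate = epochs@samplingRate,
      layout = epochs@layout)
}

#' Reject trials containing artifacts
#'
#' A trial is removed iff any screened channel's absolute amplitude exceeds
#' `ampThreshold` (strictly greater: a trial peaking exactly at the
#' threshold is retained), or the peak-to-peak excursion on the horizontal
#' EOG exceeds `heogThreshold`, or on the vertical EOG exceeds
#' `veogThreshold`. The EOG peak-to-peak is computed on a trace smoothed
#' with a centered moving average of `eogSmoothMs` so the criterion responds
#' to sustained ocular deflections rather than single-sample noise. The log
#' records the first matching reason per trial (amplitude, then HEM, then
#' VEOG); retained trials are unmodified.
#'
#' @param epochs an [ErpEpochs-class] object.
#' @param ampThreshold microvolts, absolute amplitude criterion.
#' @param heogThreshold,veogThreshold microvolts, EOG peak-to-peak criteria.
#' @param ampChannels channels screened by the amplitude criterion; defaults
#'   to the analysis channels plus EOG.
#' @param eogSmoothMs width of the EOG smoothing window, ms.
#' @return list with `epochs` (retained trials) and `log`, a data.table of
#'   per-trial decisions plus per-(subject, condition) retention counts as
#'   the `"retention"` attribute. Subjects losing every trial of a condition
#'   are flagged with a warning.
#' @export
rejectArtifacts <- function(epochs, ampThreshold = 200, heogThreshold = 40,
                            veogThreshold = 100, ampChannels = NULL,
                            eogSmoothMs = 40) {
  layout <- epochs@layout
  if (any(c(ampThreshold, heogThreshold, veogThreshold) <= 0)) {
    stop("rejection thresholds must be positive")
  }
  if (is.null(ampChannels)) ampChannels <- analysisChannels(layout, includeEog = TRUE)
  dt <- epochs@data
  k <- max(1L, as.integer(round(eogSmoothMs / (1000 / epochs@samplingRate))))
  smoothPP <- function(x) {
    if (length(x) >= k && k > 1L) {
      x <- stats::filter(x, rep(1 / k, k), sides = 2)
      x <- x[!is.na(x)]
    }
    diff(range(x))
  }
  amp <- dt[channel %in% ampChannels,
            .(.amp = max(abs(amplitude_uV))),
            by = .(subject, condition, trial)]
  heog <- dt[channel == layout@heog,
             .(.heog = smoothPP(amplitude_uV)),
             by = .(subject, condition, trial)]
  veog <- dt[channel %in% layout@veog,
             .(.veog = smoothPP(amplitude_uV)),
             by = .(subject, condition, trial, channel)][
             , .(.veog = max(.veog)), by = .(subject, condition, trial)]
  log <- Reduce(function(a, b) merge(a, b, by = c("subject", "condition", "trial"),
                                     all = TRUE),
                list(amp, heog, veog))
  log[, reason := data.table::fifelse(
    !is.na(.amp) & .amp > ampThreshold, "amplitude",
    data.table::fifelse(!is.na(.heog) & .heog > heogThreshold, "HEM",
      data.table::fifelse(!is.na(.veog) & .veog > veogThreshold, "VEOG", "none"))
  )]
  log[, rejected := reason != "none"]
  log[, c(".amp", ".heog", ".veog") := NULL]
  keep <- log[rejected == FALSE, .(subject, condition, trial)]
  out <- dt[keep, on = c("subject", "condition", "trial")]
  retention <- log[, .(n_total = .N, n_retained = sum(!rejected)),
                   by = .(subject, condition)]
  lost <- retention[n_retained == 0L]
  if (nrow(lost)) {
    warning("all trials rejected for: ",
            paste(unique(paste(lost$subject, lost$condition, sep = "/")),
                  collapse = ", "),
            "; subject(s) should be excluded downstream")
  }
  data.table::setattr(log, "retention", retention)
  list(
    epochs = new("ErpEpochs", data = out, samplingRate = epochs@samplingRate,
                 layout = layout),
    log = log[]
  )
}

#' Average retained trials into per-condition subject waveforms
#'
#' Arithmetic mean over retained trials per (subject, condition, channel,
#' sample). Subjects with fewer than `minTrials` retained trials in any
#' condition are flagged (and reported in the returned object) but kept.
#'
#' @param epochs an [ErpEpochs-class] object (after rejection).
#' @param minTrials permissive floor on retained trials per condition.
#' @return a [SubjectAverages-class] object.
#' @export
averageConditions <- function(epochs, minTrials = 40) {
  dt <- epochs@data
  if (nrow(dt) == 0L) stop("no retained trials to average")
  avg <- dt[, .(amplitude_uV = mean(amplitude_uV)),
            by = .(subject, group, condition, channel, time_ms)]
  nUsed <- dt[, .(n_trials = data.table::uniqueN(trial)),
              by = .(subject, condition)]
  flagged <- unique(nUsed[n_trials < minTrials, subject])
  if (length(flagged)) {
    warning("subjects below the ", minTrials, "-trial floor: ",
            paste(flagged, collapse = ", "))
  }
  new("SubjectAverages", data = avg, nTrialsUsed = nUsed,
      samplingRate = epochs@samplingRate, layout = epochs@layout,
      flaggedSubjects = as.character(flagged))
}

.lowpassSeries <- function(dt, by, fs, cutoff, order) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (order %% 2 != 0) stop("filter order must be even")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- data.table::copy(dt)
  out[, amplitude_uV := .filtfiltPadded(bf$b, bf$a, amplitude_uV), by = by]
  out
}

#' @rdname lowpassFilter
#' @export
setMethod("lowpassFilter", "ErpEpochs", function(x, cutoff = 30, order = 4) {
  dt <- .lowpassSeries(x@data, c("subject", "condition", "trial", "channel"),
                       x@samplingRate, cutoff, order)
  new("ErpEpochs", data = dt, samplingRate = x@samplingRate, layout = x@layout)
})

#' @rdname lowpassFilter
#' @export
setMethod("lowpassFilter", "SubjectAverages", function(x, cutoff = 30, order = 4) {
  dt <- .lowpassSeries(x@data, c("subject", "condition", "channel"),
                       x@samplingRate, cutoff, order)
  new("SubjectAverages", data = dt, nTrialsUsed = x@nTrialsUsed,
      samplingRate = x@samplingRate, layout = x@layout,
      flaggedSubjects = x@flaggedSubjects)
})

#' Run the preprocessing chain
#'
#' Default order: re-reference to mastoids, baseline-correct, reject
#' artifact trials, average per condition, then low-pass filter the
#' averages (filtering the averages rather than single trials follows the
#' convention of filtering averaged ERPs; for a linear zero-phase filter
#' the two orders are equivalent in expectation). Any subset or reordering
#' of steps can be requested; "lowpass" before "average" filters the
#' single trials instead. Deterministic for fixed input.
#'
#' @param epochs an [ErpEpochs-class] object.
#' @param steps character, ordered subset of "rereference", "baseline",
#'   "reject", "average", "lowpass".
#' @param baselineWindow ms pair for [baselineCorrect()].
#' @param cutoff Hz for [lowpassFilter()].
#' @param minTrials floor for [averageConditions()].
#' @param ... passed to [rejectArtifacts()].
#' @return list: `averages` (a [SubjectAverages-class], or the processed
#'   [ErpEpochs-class] if "average" was not requested) and `rejectionLog`
#'   (NULL if "reject" was not requested).
#' @export
preprocessEpochs <- function(epochs,
                             steps = c("rereference", "baseline", "reject",
                                       "average", "lowpass"),
                             baselineWindow = c(-100, 0),
                             cutoff = 30, minTrials = 40, ...) {
  bad <- setdiff(steps, c("rereference", "baseline", "reject", "average", "lowpass"))
  if (length(bad)) stop("unknown preprocessing step(s): ", paste(bad, collapse = ", "))
  obj <- epochs
  rlog <- NULL
  for (s in steps) {
    obj <- switch(s,
      rereference = rereferenceToMastoids(obj),
      baseline = baselineCorrect(obj, baselineWindow),
      reject = {
        res <- rejectArtifacts(obj, ...)
        rlog <- res$log
        res$epochs
      },
      average = averageConditions(obj, minTrials = minTrials),
      lowpass = lowpassFilter(obj, cutoff = cutoff)
    )
  }
  list(averages = obj, rejectionLog = rlog)
}
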