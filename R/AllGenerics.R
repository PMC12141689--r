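#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLayout", function(x) standardGeneric("channelLayout"))

#' @rdname accessors
#' @export
setGeneric("epochsData", function(x) standardGeneric("epochsData"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))

#' Zero-phase low-pass filtering
#'
#' Applies an even-order Butterworth filter forward and backward (zero net
#' phase) to every waveform. The default 4th-order design at 30 Hz gives a
#' two-pass magnitude response of about -6 dB at the cutoff, better than
#' 20 dB attenuation at twice the cutoff, and under 0.04 dB ripple below
#' half the cutoff at a 250 Hz sampling rate. Edge transients are controlled
#' by odd-reflection padding, so a constant (DC) trace is reproduced to
#' floating-point accuracy.
#'
#' @param x an [ErpEpochs-class] or [SubjectAverages-class] object.
#' @param cutoff numeric cutoff frequency, Hz; must be below Nyquist.
#' @param order even filter order per pass.
#' @return an object of the same class with filtered amplitudes.
#' @export
setGeneric("lowpassFilter", function(x, cutoff = 30, order = 4) {
  standardGeneric("lowpassFilter")
})

#' Mean amplitude of a component window
#'
#' Averages the waveform over every sample with tStart <= t <= tEnd (both
#' endpoints inclusive) and every channel of the window's electrode set.
#'
#' @param x a [SubjectAverages-class] object.
#' @param window a [ComponentWindow-class].
#' @param conditions optional character, restrict to these conditions.
#' @return a data.table: subject, group, condition, mean_amplitude_uV.
#' @export
setGeneric("meanAmplitude", function(x, window, conditions = NULL) {
  standardGeneric("meanAmplitude")
})

#' Peak latency of a component window
#'
#' Finds the extremum matching the window polarity (most negative sample for
#' a negative component) of the electrode-set-averaged waveform within the
#' window; ties are broken by the earliest sample. A flat waveform returns
#' tStart flagged as degenerate; a waveform whose extremum does not match
#' the expected polarity is returned but flagged.
#'
#' @inheritParams meanAmplitude
#' @return a data.table: subject, group, condition, peak_latency_ms,
#'   peak_amplitude_uV, degenerate.
#' @export
setGeneric("peakLatency", function(x, window, conditions = NULL) {
  standardGeneric("peakLatency")
})
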