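#' Construct a channel layout
#'
#' @param occipitalSet,lhSet,rhSet,mastoids,veog,heog character vectors of
#'   channel names; see [ChannelLayout-class].
#' @param extra character, additional channels carried through untouched.
#' @return a [ChannelLayout-class] object.
#' @examples
#' ChannelLayout()
#' @export
ChannelLayout <- function(occipitalSet = c("O1", "I1", "IZ", "I2", "O2"),
                          lhSet = c("P5", "PO3", "PO7"),
                          rhSet = c("P4", "PO4", "PO8"),
                          mastoids = c("M1", "M2"),
                          veog = "VEOG",
                          heog = "HEOG",
                          extra = character()) {
  new("ChannelLayout",
    channels = unique(c(occipitalSet, lhSet, rhSet, mastoids, veog, heog, extra)),
    occipitalSet = occipitalSet, lhSet = lhSet, rhSet = rhSet,
    mastoids = mastoids, veog = veog, heog = heog
  )
}

#' Default montage for the motion-laterality analysis
#'
#' Five midline occipital channels for the P1/N1, the printed left
#' (P5, PO3, PO7) and right (P4, PO4, PO8) parieto-occipital sets for the
#' N2, two mastoids and two EOG channels. The printed left/right sets are
#' asymmetric (P5 vs P4) and are kept exactly as printed; every set is
#' configurable through [ChannelLayout()].
#'
#' @return a [ChannelLayout-class] object.
#' @export
defaultChannelLayout <- function() ChannelLayout()

#' Channels used for amplitude-threshold artifact screening
#'
#' @param layout a [ChannelLayout-class].
#' @param includeEog include the EOG channels (the default).
#' @return character vector of channel names.
#' @export
analysisChannels <- function(layout, includeEog = TRUE) {
  ch <- c(layout@occipitalSet, layout@lhSet, layout@rhSet)
  if (includeEog) ch <- c(ch, layout@veog, layout@heog)
  ch
}

#' Resolve an electrode-set role to channel names
#' @param layout a [ChannelLayout-class].
#' @param role one of "occipitalSet", "lhSet", "rhSet".
#' @return character vector of channel names.
#' @export
electrodeSet <- function(layout, role) {
  slot(layout, match.arg(role, c("occipitalSet", "lhSet", "rhSet")))
}

setMethod("show", "ChannelLayout", function(object) {
  cat("ChannelLayout with", length(object@channels), "channels\n")
  cat("  occipital:", paste(object@occipitalSet, collapse = " "), "\n")
  cat("  LH set:   ", paste(object@lhSet, collapse = " "), "\n")
  cat("  RH set:   ", paste(object@rhSet, collapse = " "), "\n")
  cat("  mastoids: ", paste(object@mastoids, collapse = " "),
      " EOG:", object@veog, object@heog, "\n")
})

#' @rdname accessors
#' @param x an [ErpEpochs-class] or [SubjectAverages-class] object.
#' @export
setMethod("samplingRate", "ErpEpochs", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("samplingRate", "SubjectAverages", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("channelLayout", "ErpEpochs", function(x) x@layout)

#' @rdname accessors
#' @export
setMethod("channelLayout", "SubjectAverages", function(x) x@layout)

#' Accessors for ERP containers
#'
#' `epochsData()` returns the underlying long-format data.table (a copy),
#' `samplingRate()` the sampling rate in Hz, `channelLayout()` the montage,
#' and `nTrials()` the per-(subject, condition) trial counts.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("epochsData", "ErpEpochs", function(x) data.table::copy(x@data))

#' @rdname accessors
#' @export
setMethod("epochsData", "SubjectAverages", function(x) data.table::copy(x@data))

#' @rdname accessors
#' @param ... unused.
#' @export
setMethod("nTrials", "ErpEpochs", function(x, ...) {
  x@data[, .(n_trials = data.table::uniqueN(trial)), by = .(subject, condition)]
})

#' @rdname accessors
#' @export
setMethod("nTrials", "SubjectAverages", function(x, ...) {
  data.table::copy(x@nTrialsUsed)
})

setMethod("show", "ErpEpochs", function(object) {
  d <- object@data
  cat("ErpEpochs:", data.table::uniqueN(d$subject), "subjects,",
      data.table::uniqueN(d$condition), "conditions,",
      data.table::uniqueN(d$channel), "channels @", object@samplingRate, "Hz\n")
  tt <- range(d$time_ms)
  cat("  epoch:", tt[1], "to", tt[2], "ms;", nrow(d), "rows\n")
})

setMethod("show", "SubjectAverages", function(object) {
  d <- object@data
  cat("SubjectAverages:", data.table::uniqueN(d$subject), "subjects x",
      data.table::uniqueN(d$condition), "conditions @", object@samplingRate, "Hz\n")
  if (length(object@flaggedSubjects)) {
    cat("  flagged (low trial count):",
        paste(object@flaggedSubjects, collapse = ", "), "\n")
  }
})
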