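#' @import methods
#' @importFrom data.table data.table as.data.table := setkeyv setorderv copy
#'   rbindlist dcast fread fwrite CJ setnames
NULL

#' Channel layout for the ERP montage
#'
#' Names the channels the analysis uses: the occipital set over which the
#' early visual P1/N1 are averaged, the left- and right-hemisphere
#' parieto-occipital sets over which the motion-sensitive N2 is averaged,
#' the two mastoid reference channels, and the vertical/horizontal EOG
#' channels used for ocular artifact screening.
#'
#' @slot channels character, every channel name in the montage.
#' @slot occipitalSet character, midline occipital channels (P1/N1 window).
#' @slot lhSet,rhSet character, left/right parieto-occipital channels
#'   (N2 window); must be disjoint and equal-sized.
#' @slot mastoids character(2), reference channels.
#' @slot veog,heog character, vertical / horizontal EOG channel name(s).
#' @exportClass ChannelLayout
setClass("ChannelLayout",
  representation(
    channels = "character",
    occipitalSet = "character",
    lhSet = "character",
    rhSet = "character",
    mastoids = "character",
    veog = "character",
    heog = "character"
  )
)

setValidity("ChannelLayout", function(object) {
  msg <- character()
  eog <- c(object@veog, object@heog)
  sets <- list(
    occipitalSet = object@occipitalSet, lhSet = object@lhSet,
    rhSet = object@rhSet, mastoids = object@mastoids
  )
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L) msg <- c(msg, paste0(nm, " is empty"))
    if (any(sets[[nm]] %in% eog)) {
      msg <- c(msg, paste0(nm, " overlaps the EOG channels"))
    }
    if (!all(sets[[nm]] %in% object@channels)) {
      msg <- c(msg, paste0(nm, " contains channels absent from 'channels'"))
    }
  }
  if (length(intersect(object@lhSet, object@rhSet)) > 0L) {
    msg <- c(msg, "lhSet and rhSet overlap")
  }
  if (length(object@lhSet) != length(object@rhSet)) {
    msg <- c(msg, "lhSet and rhSet must be equal-sized")
  }
  if (length(object@mastoids) != 2L) msg <- c(msg, "exactly two mastoids required")
  if (!all(eog %in% object@channels)) {
    msg <- c(msg, "EOG channels absent from 'channels'")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic cohort generator
#'
#' Holds every tunable of the generator: cohort composition, trial and
#' sampling structure, the latent allocation law that splits a subject's
#' total motion-direction sensitivity between hemispheres, the ERP component
#' kernels, the noise and artifact model, and the target correlations of the
#' molecular covariates with the true Laterality Index.
#'
#' @slot nPerGroup named integer, subjects per group (e.g. c(TC=27, WS=29)).
#' @slot nTrials integer, trials per condition.
#' @slot samplingRate numeric, Hz.
#' @slot epochWindow numeric(2), epoch limits in ms (half-open on the right).
#' @slot conditions character, conditions to synthesize.
#' @slot groupMeans named numeric, mean true LI per group in microvolts.
#' @slot sensitivityScale numeric, SD of total sensitivity T in microvolts.
#' @slot allocationParams named list, per-group Beta (a, b) shape pair for
#'   the hemispheric allocation proportion.
#' @slot componentParams named list, per component (P1, N1, N2): latency ms,
#'   width ms (Gaussian SD), and base amplitude in microvolts (scalar or
#'   named per-group).
#' @slot noiseSd numeric, trial noise SD on scalp channels, microvolts.
#' @slot eogNoiseSd numeric, white-noise SD on the EOG channels, microvolts.
#' @slot pinkFraction numeric in [0,1], fraction of noise variance taken by
#'   the low-frequency (cumulative-sum) component.
#' @slot artifactRate numeric in [0,1], per-trial artifact probability.
#' @slot artifactAmplitudes named numeric: blink, hem, spike, microvolts.
#' @slot rhoExpression named numeric, target correlation of each expression
#'   feature with the true LI.
#' @slot rhoMethylation named numeric, target correlation of each CpG probe
#'   beta value with the true LI (conventionally opposite in sign).
#' @slot leftHanded named integer, left-handed count per group.
#' @slot femaleCount named integer, female count per group.
#' @slot seed integer.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nPerGroup = "integer",
    nTrials = "integer",
    samplingRate = "numeric",
    epochWindow = "numeric",
    conditions = "character",
    groupMeans = "numeric",
    sensitivityScale = "numeric",
    allocationParams = "list",
    componentParams = "list",
    noiseSd = "numeric",
    eogNoiseSd = "numeric",
    pinkFraction = "numeric",
    artifactRate = "numeric",
    artifactAmplitudes = "numeric",
    rhoExpression = "numeric",
    rhoMethylation = "numeric",
    leftHanded = "integer",
    femaleCount = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  num_ok <- function(x) length(x) > 0L && all(is.finite(x))
  if (!num_ok(object@nPerGroup) || any(object@nPerGroup < 2L)) {
    msg <- c(msg, "nPerGroup must be finite and >= 2 per group")
  }
  if (is.null(names(object@nPerGroup))) msg <- c(msg, "nPerGroup must be named by group")
  if (!num_ok(object@nTrials) || object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (!num_ok(object@samplingRate) || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be positive")
  }
  if (length(object@epochWindow) != 2L || !num_ok(object@epochWindow) ||
      diff(object@epochWindow) <= 0) {
    msg <- c(msg, "epochWindow must be an increasing ms pair")
  }
  if (!num_ok(object@artifactRate) || object@artifactRate < 0 || object@artifactRate > 1) {
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  }
  if (!num_ok(object@pinkFraction) || object@pinkFraction < 0 || object@pinkFraction > 1) {
    msg <- c(msg, "pinkFraction must lie in [0, 1]")
  }
  if (length(object@rhoExpression) && (!num_ok(object@rhoExpression) ||
      any(abs(object@rhoExpression) > 1))) {
    msg <- c(msg, "rhoExpression must be finite with |rho| <= 1")
  }
  if (length(object@rhoMethylation) && (!num_ok(object@rhoMethylation) ||
      any(abs(object@rhoMethylation) > 1))) {
    msg <- c(msg, "rhoMethylation must be finite with |rho| <= 1")
  }
  if (!num_ok(object@noiseSd) || object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!num_ok(object@sensitivityScale) || object@sensitivityScale < 0) {
    msg <- c(msg, "sensitivityScale must be >= 0")
  }
  for (cp in object@componentParams) {
    lat <- cp$latency
    if (!is.null(lat) && (lat < object@epochWindow[1] || lat >= object@epochWindow[2])) {
      msg <- c(msg, "component latency outside the epoch window")
    }
  }
  if (object@epochWindow[1] > -1e-9) {
    msg <- c(msg, "epochWindow must include a pre-stimulus baseline")
  }
  if (length(msg)) msg else TRUE
})

#' Trial-level epoched EEG
#'
#' Long-format trial-level amplitudes: one row per (subject, condition,
#' trial, channel, sample). The time grid is uniform at 1000/samplingRate ms
#' with the half-open convention that the sample at time t covers
#' [t, t + delta).
#'
#' @slot data a data.table with columns subject, group, handedness,
#'   condition, trial, channel, time_ms, amplitude_uV.
#' @slot samplingRate numeric, Hz.
#' @slot layout a [ChannelLayout-class].
#' @exportClass ErpEpochs
setClass("ErpEpochs",
  representation(
    data = "data.table",
    samplingRate = "numeric",
    layout = "ChannelLayout"
  )
)

.epoch_cols <- c(
  "subject", "group", "handedness", "condition", "trial", "channel",
  "time_ms", "amplitude_uV"
)

setValidity("ErpEpochs", function(object) {
  msg <- character()
  miss <- setdiff(.epoch_cols, names(object@data))
  if (length(miss)) {
    msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  } else {
    tt <- sort(unique(object@data$time_ms))
    if (length(tt) > 1L) {
      step <- 1000 / object@samplingRate
      if (max(abs(diff(tt) - step)) > 1e-6) {
        msg <- c(msg, "time grid is not uniform at 1000/samplingRate ms")
      }
    }
  }
  if (!is.finite(object@samplingRate) || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject, per-condition averaged ERP waveforms
#'
#' @slot data a data.table with columns subject, group, condition, channel,
#'   time_ms, amplitude_uV.
#' @slot nTrialsUsed a data.table with columns subject, condition, n_trials.
#' @slot samplingRate numeric, Hz.
#' @slot layout a [ChannelLayout-class].
#' @slot flaggedSubjects character, subjects below the retained-trial floor.
#' @exportClass SubjectAverages
setClass("SubjectAverages",
  representation(
    data = "data.table",
    nTrialsUsed = "data.table",
    samplingRate = "numeric",
    layout = "ChannelLayout",
    flaggedSubjects = "character"
  )
)

setValidity("SubjectAverages", function(object) {
  need <- c("subject", "group", "condition", "channel", "time_ms", "amplitude_uV")
  miss <- setdiff(need, names(object@data))
  if (length(miss)) {
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(object@data$amplitude_uV))) {
    return("averaged waveforms must be finite")
  }
  TRUE
})

#' A component measurement window
#'
#' A named time window, the electrode-set role it is measured over, and the
#' expected polarity of the component (used by peak picking).
#'
#' @slot name character, e.g. "M_P1", "P_N1", "N2".
#' @slot tStart,tEnd numeric, window limits in ms (both endpoints inclusive).
#' @slot electrodeRole character, one of "occipitalSet", "lhSet", "rhSet".
#' @slot polarity character, "positive" or "negative".
#' @exportClass ComponentWindow
setClass("ComponentWindow",
  representation(
    name = "character",
    tStart = "numeric",
    tEnd = "numeric",
    electrodeRole = "character",
    polarity = "character"
  )
)

setValidity("ComponentWindow", function(object) {
  msg <- character()
  if (!object@tStart < object@tEnd) msg <- c(msg, "tStart must be < tEnd")
  if (!object@polarity %in% c("positive", "negative")) {
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  }
  if (!object@electrodeRole %in% c("occipitalSet", "lhSet", "rhSet")) {
    msg <- c(msg, "electrodeRole must name a layout set")
  }
  if (length(msg)) msg else TRUE
})
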