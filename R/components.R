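#' Construct a component measurement window
#'
#' @param name window label, e.g. "N2".
#' @param tStart,tEnd ms, both endpoints inclusive when measuring.
#' @param electrodeRole layout set the window is measured over.
#' @param polarity expected component polarity.
#' @return a [ComponentWindow-class] object.
#' @export
ComponentWindow <- function(name, tStart, tEnd,
                            electrodeRole = c("occipitalSet", "lhSet", "rhSet"),
                            polarity = c("negative", "positive")) {
  new("ComponentWindow", name = name, tStart = tStart, tEnd = tEnd,
      electrodeRole = match.arg(electrodeRole), polarity = match.arg(polarity))
}

setMethod("show", "ComponentWindow", function(object) {
  cat(sprintf("ComponentWindow %s: %g-%g ms over %s (%s)\n", object@name,
              object@tStart, object@tEnd, object@electrodeRole, object@polarity))
})

#' Default measurement windows
#'
#' The early visual components are measured from 130 to 170 ms over the
#' occipital set (P1 positive for motion, N1 negative for color change);
#' the motion-direction N2 from 155 to 195 ms over each parieto-occipital
#' hemisphere set, a window chosen to capture the rise and peak of the N2
#' but not the following positivity.
#'
#' @return named list of [ComponentWindow-class] objects (M_P1, P_N1,
#'   N2_LH, N2_RH).
#' @export
defaultWindows <- function() {
  list(
    M_P1 = ComponentWindow("M_P1", 130, 170, "occipitalSet", "positive"),
    P_N1 = ComponentWindow("P_N1", 130, 170, "occipitalSet", "negative"),
    N2_LH = ComponentWindow("N2", 155, 195, "lhSet", "negative"),
    N2_RH = ComponentWindow("N2", 155, 195, "rhSet", "negative")
  )
}

.windowSlice <- function(x, window) {
  chans <- electrodeSet(x@layout, window@electrodeRole)
  miss <- setdiff(chans, unique(x@data$channel))
  if (length(miss)) {
    stop("window channels missing from averages: ", paste(miss, collapse = ", "))
  }
  d <- x@data[channel %in% chans & time_ms >= window@tStart &
                time_ms <= window@tEnd]
  if (nrow(d) == 0L) stop("no samples fall inside the ", window@name, " window")
  d
}

#' @rdname meanAmplitude
#' @export
setMethod("meanAmplitude", "SubjectAverages",
  function(x, window, conditions = NULL) {
    d <- .windowSlice(x, window)
    if (!is.null(conditions)) d <- d[condition %in% conditions]
    d[, .(mean_amplitude_uV = mean(amplitude_uV)), by = .(subject, group, condition)]
  }
)

#' @rdname peakLatency
#' @export
setMethod("peakLatency", "SubjectAverages",
  function(x, window, conditions = NULL) {
    d <- .windowSlice(x, window)
    if (!is.null(conditions)) d <- d[condition %in% conditions]
    w <- d[, .(amplitude_uV = mean(amplitude_uV)),
           by = .(subject, group, condition, time_ms)]
    pick <- function(t, a) {
      flat <- diff(range(a)) == 0
      i <- if (window@polarity == "negative") which.min(a) else which.max(a)
      ext <- a[i]
      # earliest sample among ties
      i <- which(a == ext)[1]
      wrongPol <- if (window@polarity == "negative") ext > 0 else ext < 0
      list(peak_latency_ms = if (flat) window@tStart else t[i],
           peak_amplitude_uV = ext,
           degenerate = flat || wrongPol)
    }
    w[order(time_ms), pick(time_ms, amplitude_uV), by = .(subject, group, condition)]
  }
)

#' Measure the early visual components (P1 to motion, N1 to color)
#'
#' Per subject: mean amplitude and peak latency from 130 to 170 ms over the
#' occipital set, for the motion condition (P1; the two scroll directions
#' pooled, weighted by retained trial counts) and the color-change
#' condition (N1).
#'
#' @param avgs a [SubjectAverages-class] object with conditions M_SL, M_SR
#'   and P_CHANGE.
#' @param windows named list from [defaultWindows()] (entries M_P1, P_N1).
#' @param poolMotion pool M_SL and M_SR into a single motion measure
#'   (the default) or measure them separately.
#' @return a data.table: subject, group, window, hemisphere, condition,
#'   mean_amplitude_uV, peak_latency_ms, n_trials.
#' @export
measureVisualComponents <- function(avgs, windows = defaultWindows(),
                                    poolMotion = TRUE) {
  have <- unique(avgs@data$condition)
  if (!all(c("M_SL", "M_SR") %in% have) || !"P_CHANGE" %in% have) {
    stop("conditions M_SL, M_SR and P_CHANGE are required")
  }
  nu <- avgs@nTrialsUsed
  if (poolMotion) {
    m <- avgs@data[condition %in% c("M_SL", "M_SR")]
    m <- merge(m, nu, by = c("subject", "condition"))
    pooled <- m[, .(amplitude_uV = sum(amplitude_uV * n_trials) / sum(n_trials),
                    condition = "M"),
                by = .(subject, group, channel, time_ms)]
    nM <- nu[condition %in% c("M_SL", "M_SR"),
             .(condition = "M", n_trials = sum(n_trials)), by = subject]
    dat <- rbind(pooled, avgs@data[condition == "P_CHANGE"], fill = TRUE)
    nAll <- rbind(nM, nu[condition == "P_CHANGE"])
  } else {
    dat <- avgs@data[condition %in% c("M_SL", "M_SR", "P_CHANGE")]
    nAll <- nu[condition %in% c("M_SL", "M_SR", "P_CHANGE")]
  }
  pooledAvgs <- new("SubjectAverages", data = dat, nTrialsUsed = nAll,
                    samplingRate = avgs@samplingRate, layout = avgs@layout,
                    flaggedSubjects = avgs@flaggedSubjects)
  out <- list()
  specs <- list(
    list(win = windows$M_P1, conds = if (poolMotion) "M" else c("M_SL", "M_SR")),
    list(win = windows$P_N1, conds = "P_CHANGE")
  )
  for (sp in specs) {
    ma <- meanAmplitude(pooledAvgs, sp$win, conditions = sp$conds)
    pl <- peakLatency(pooledAvgs, sp$win, conditions = sp$conds)
    res <- merge(ma, pl[, .(subject, condition, peak_latency_ms)],
                 by = c("subject", "condition"))
    res[, window := sp$win@name]
    res[, hemisphere := "midline-pooled"]
    out[[length(out) + 1L]] <- res
  }
  out <- rbindlist(out)
  out <- merge(out, nAll, by = c("subject", "condition"))
  setorderv(out, c("subject", "window"))
  out[, .(subject, group, window, hemisphere, condition,
          mean_amplitude_uV, peak_latency_ms, n_trials)]
}

#' Measure the motion-direction N2 per hemisphere and scroll direction
#'
#' Four measures per subject: the 155-195 ms mean amplitude over the LH and
#' RH parieto-occipital sets for each scroll direction (M_SL, M_SR), plus
#' peak latencies of the set-averaged waveforms.
#'
#' @param avgs a [SubjectAverages-class] object with conditions M_SL, M_SR.
#' @param windows named list from [defaultWindows()] (entries N2_LH, N2_RH).
#' @return a data.table: subject, group, window, hemisphere, condition,
#'   mean_amplitude_uV, peak_latency_ms, n_trials.
#' @export
measureN2 <- function(avgs, windows = defaultWindows()) {
  have <- unique(avgs@data$condition)
  if (!all(c("M_SL", "M_SR") %in% have)) {
    stop("conditions M_SL and M_SR are required")
  }
  out <- list()
  for (hemi in c("LH", "RH")) {
    win <- if (hemi == "LH") windows$N2_LH else windows$N2_RH
    ma <- meanAmplitude(avgs, win, conditions = c("M_SL", "M_SR"))
    pl <- peakLatency(avgs, win, conditions = c("M_SL", "M_SR"))
    res <- merge(ma, pl[, .(subject, condition, peak_latency_ms)],
                 by = c("subject", "condition"))
    res[, `:=`(window = win@name, hemisphere = hemi)]
    out[[length(out) + 1L]] <- res
  }
  out <- rbindlist(out)
  out <- merge(out, avgs@nTrialsUsed, by = c("subject", "condition"))
  setorderv(out, c("subject", "hemisphere", "condition"))
  out[, .(subject, group, window, hemisphere, condition,
          mean_amplitude_uV, peak_latency_ms, n_trials)]
}
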