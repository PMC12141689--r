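# Delimiter-tolerant, header-case-insensitive reader that skips '#' comment
# lines (used for the run-manifest header written by writeResultTable).
.readDelim <- function(path, canonical) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  dt <- fread(text = paste(lines, collapse = "\n"))
  lownames <- tolower(names(dt))
  for (cn in canonical) {
    hit <- which(lownames == tolower(cn))
    if (length(hit)) setnames(dt, hit[1], cn)
  }
  dt
}

#' Write epochs to the canonical long-format delimited file
#'
#' Columns: subject, group, handedness, condition, trial, channel, time_ms,
#' amplitude_uV. Rows are ordered deterministically (subject, condition,
#' trial, channel, time).
#'
#' @param epochs an [ErpEpochs-class] object.
#' @param path output file; ".csv" uses commas, anything else tabs.
#' @return the path, invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  dt <- data.table::copy(epochs@data)
  setorderv(dt, c("subject", "condition", "trial", "channel", "time_ms"))
  fwrite(dt, path, sep = if (grepl("\\.csv$", path)) "," else "\t")
  invisible(path)
}

#' Read epochs from a long-format delimited file
#'
#' Accepts comma- or tab-delimited input with case-insensitive headers and
#' '#' comment lines.
#'
#' @param path input file.
#' @param layout a [ChannelLayout-class] describing the montage.
#' @param samplingRate Hz; inferred from the time grid when NULL.
#' @return an [ErpEpochs-class] object.
#' @export
readEpochs <- function(path, layout = defaultChannelLayout(),
                       samplingRate = NULL) {
  dt <- .readDelim(path, .epoch_cols)
  miss <- setdiff(.epoch_cols, names(dt))
  if (length(miss)) {
    stop("epochs file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(samplingRate)) {
    tt <- sort(unique(dt$time_ms))
    if (length(tt) < 2L) stop("cannot infer sampling rate from one sample")
    samplingRate <- 1000 / min(diff(tt))
  }
  new("ErpEpochs", data = dt[, .epoch_cols, with = FALSE],
      samplingRate = samplingRate, layout = layout)
}

#' Read a long-format molecular table
#'
#' @param path delimited file with columns subject, measure_type, feature,
#'   batch, value (any case, comma or tab delimited).
#' @return a data.table.
#' @export
readMolecularTable <- function(path) {
  need <- c("subject", "measure_type", "feature", "batch", "value")
  dt <- .readDelim(path, need)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("molecular table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(dt$measure_type == "methylation" &
          (dt$value < 0 | dt$value > 1))) {
    stop("methylation beta values must lie in [0, 1]")
  }
  dt
}

#' Write a result table with a run-manifest header
#'
#' Prepends '#'-prefixed manifest lines (seed, package version, config
#' hash) so every emitted table carries its provenance; the package readers
#' skip such lines.
#'
#' @param dt a data.frame/data.table.
#' @param path output file.
#' @param manifest named list, e.g. from a pipeline run.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(dt, path, manifest = NULL) {
  con <- file(path, "w")
  if (!is.null(manifest)) {
    writeLines(sprintf("# %s: %s", names(manifest),
                       vapply(manifest, function(x) paste(format(x), collapse = " "),
                              character(1))), con)
  }
  close(con)
  fwrite(dt, path, sep = if (grepl("\\.csv$", path)) "," else "\t",
         append = !is.null(manifest), col.names = TRUE)
  invisible(path)
}
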