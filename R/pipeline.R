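#' Default pipeline configuration
#'
#' A nested list mirroring every stage's tunables, suitable for dumping to
#' and reading from YAML. The simulation block holds the
#' [SimulationConfig()] arguments; preprocess holds the step order and
#' rejection thresholds; laterality the dead-band and z reference;
#' molecular the correlation plan and adjustment family.
#'
#' The default simulation block is a demonstration-scale cohort (10 + 10
#' subjects, 40 trials per condition) so an end-to-end run fits in ordinary
#' memory; a full study-scale cohort (27 + 29 subjects, 300 trials, the
#' [SimulationConfig()] defaults) holds roughly half a billion trial-level
#' samples and should be synthesized per subject or on a large machine.
#'
#' @param seed integer seed recorded in every output manifest.
#' @return a named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(
      nPerGroup = c(TC = 10L, WS = 10L),
      nTrials = 40L,
      leftHanded = c(TC = 1L, WS = 3L),
      femaleCount = c(TC = 6L, WS = 6L),
      artifactRate = 0.1
    ),
    preprocess = list(
      steps = c("rereference", "baseline", "reject", "average", "lowpass"),
      amp_threshold = 200,
      heog_threshold = 40,
      veog_threshold = 100,
      baseline_window = c(-100, 0),
      cutoff = 30,
      min_trials = 20   # permissive floor for the demo-scale default cohort
    ),
    laterality = list(epsilon = 0, z_reference = "combined"),
    molecular = list(
      plan = list(
        list(feature = "BUD23", phenotype = "LI", tail = "two"),
        list(feature = "BUD23", phenotype = "S_R", tail = "two"),
        list(feature = "BUD23", phenotype = "S_L", tail = "two"),
        list(feature = "cg12099727", phenotype = "LI", tail = "two")
      ),
      method = "bonferroni",
      family = "phenotype"
    ),
    log_level = "info"
  )
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `readPipelineConfig`: the config list merged over the defaults.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(defaultPipelineConfig(), user)
}

#' @rdname readPipelineConfig
#' @param config a config list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.planTable <- function(plan) {
  rbindlist(lapply(plan, as.data.table))
}

.simConfigFromList <- function(sim, seed) {
  args <- sim
  args$seed <- seed
  do.call(SimulationConfig, args)
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, preprocess the epochs, measure the
#' visual components and the N2, derive hemispheric sensitivities and the
#' Laterality Index, correlate molecular features with the laterality
#' phenotypes, and run the group-level tests (2x2 and 2x2x2 mixed ANOVAs,
#' the between-group LI t test and the participant-table chi-squares).
#' Bit-reproducible for a fixed seed. Stage failures abort with the stage
#' name.
#'
#' @param config list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @param cohort optional pre-built cohort list (truth, epochs, flags,
#'   molecular) as from [simulateCohort()]; when NULL one is simulated.
#' @param layout a [ChannelLayout-class].
#' @param outDir when non-NULL, [writeReport()] is called on the bundle.
#' @param stages ordered subset of simulate, preprocess, components,
#'   laterality, correlate, stats; later stages require earlier ones.
#' @return a `resultsBundle` list: truth, rejectionLog, retention,
#'   components, n2, sensitivity, laterality, summary, correlations,
#'   anovas, tests, manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), cohort = NULL,
                        layout = defaultChannelLayout(), outDir = NULL,
                        stages = c("simulate", "preprocess", "components",
                                   "laterality", "correlate", "stats")) {
  allStages <- c("simulate", "preprocess", "components", "laterality",
                 "correlate", "stats")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  bundle <- list(manifest = list(
    seed = config$seed,
    package = paste("lateralize", as.character(utils::packageVersion("lateralize"))),
    config_hash = rlang::hash(config),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ))
  if ("simulate" %in% stages || is.null(cohort)) {
    cohort <- runStage("simulate", {
      sc <- .simConfigFromList(config$simulation, config$seed)
      simulateCohort(sc, layout = layout)
    })
  }
  bundle$truth <- cohort$truth
  pp <- config$preprocess
  if ("preprocess" %in% stages) {
    prep <- runStage("preprocess", preprocessEpochs(
      cohort$epochs, steps = pp$steps,
      baselineWindow = pp$baseline_window, cutoff = pp$cutoff,
      minTrials = pp$min_trials,
      ampThreshold = pp$amp_threshold, heogThreshold = pp$heog_threshold,
      veogThreshold = pp$veog_threshold
    ))
    bundle$rejectionLog <- prep$rejectionLog
    bundle$retention <- if (!is.null(prep$rejectionLog)) {
      attr(prep$rejectionLog, "retention")
    }
    avgs <- prep$averages
  } else {
    return(structure(bundle, class = "resultsBundle"))
  }
  if ("components" %in% stages) {
    bundle$components <- runStage("components",
                                  measureVisualComponents(avgs))
    bundle$n2 <- runStage("components", measureN2(avgs))
  } else {
    return(structure(bundle, class = "resultsBundle"))
  }
  if ("laterality" %in% stages) {
    lat <- config$laterality
    bundle$sensitivity <- runStage("laterality", hemisphereSensitivity(bundle$n2))
    bundle$laterality <- runStage("laterality", lateralityIndex(
      bundle$sensitivity, epsilon = lat$epsilon,
      zReference = lat$z_reference,
      covariates = bundle$truth[, .(subject, handedness, sex)]
    ))
    bundle$summary <- runStage("laterality",
                               cohortSummary(bundle$laterality, bundle$sensitivity))
  }
  if ("correlate" %in% stages && !is.null(cohort$molecular)) {
    mc <- config$molecular
    bundle$correlations <- runStage("correlate", {
      molz <- zscoreWithinBatch(cohort$molecular)
      correlateGrid(molz, bundle$laterality, .planTable(mc$plan),
                    method = mc$method, family = mc$family)
    })
  }
  if ("stats" %in% stages) {
    bundle$anovas <- runStage("stats", {
      n2cells <- bundle$n2[, .(subject, group, direction = condition,
                               hemisphere, value = mean_amplitude_uV)]
      n2an <- mixedAnova(n2cells, dv = "value", between = "group",
                         within = c("direction", "hemisphere"))
      viscells <- bundle$components[, .(subject, group, component = window,
                                        value = mean_amplitude_uV)]
      visan <- mixedAnova(viscells, dv = "value", between = "group",
                          within = "component")
      rbindlist(list(
        n2an[, analysis := "N2 amplitude 2x2x2"],
        visan[, analysis := "P1/N1 amplitude 2x2"]
      ), use.names = TRUE)
    })
    bundle$tests <- runStage("stats", {
      li <- bundle$laterality
      groups <- sort(unique(li$group))
      tests <- list()
      if (length(groups) == 2L) {
        tests$LI_group <- independentT(li[group == groups[1], LI],
                                       li[group == groups[2], LI])
      }
      tr <- bundle$truth
      if ("sex" %in% names(tr) && length(groups) == 2L) {
        tests$sex_by_group <- chiSquare2x2(table(tr$group, tr$sex))
        tests$handedness_by_group <- chiSquare2x2(table(tr$group, tr$handedness))
      }
      tests
    })
  }
  bundle <- structure(bundle, class = "resultsBundle")
  if (!is.null(outDir)) writeReport(bundle, outDir)
  bundle
}

#' @export
print.resultsBundle <- function(x, ...) {
  cat("resultsBundle (seed", x$manifest$seed, ")\n")
  cat("  elements:", paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a human-readable report and machine-readable tables
#'
#' Emits the rejection log, component measures, laterality results,
#' correlation grid and ANOVA tables as delimited files carrying the run
#' manifest, plus a plain-text summary (group sizes, retention, percentage
#' specialized per class, correlation grid with adjusted p values).
#'
#' @param bundle a `resultsBundle` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- bundle$manifest
  wt <- function(x, name) {
    if (!is.null(x)) writeResultTable(x, file.path(dir, name), manifest = mf)
  }
  wt(bundle$rejectionLog, "rejection_log.csv")
  wt(bundle$components, "component_measures.csv")
  wt(bundle$n2, "n2_measures.csv")
  wt(bundle$laterality, "laterality.csv")
  wt(bundle$correlations, "correlations.csv")
  wt(bundle$anovas, "anova.csv")
  rp <- file.path(dir, "report.txt")
  con <- file(rp, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Motion-direction laterality pipeline report")
  w("seed: %s  config: %s  created: %s", mf$seed, mf$config_hash, mf$created)
  if (!is.null(bundle$truth)) {
    ng <- bundle$truth[, .N, by = group]
    w("groups: %s", paste(ng$group, ng$N, sep = "=", collapse = ", "))
  }
  if (!is.null(bundle$retention)) {
    ret <- bundle$retention[, .(pct = 100 * sum(n_retained) / sum(n_total))]
    w("trial retention: %.1f%%", ret$pct)
  }
  if (!is.null(bundle$summary)) {
    cp <- bundle$summary$classPct
    for (g in unique(cp$group)) {
      row <- cp[group == g]
      w("%s specialization: %s", g,
        paste(sprintf("%s %.0f%%", row$class, row$pct), collapse = ", "))
    }
    sc <- bundle$summary$sensitivityCorr
    for (i in seq_len(nrow(sc))) {
      w("%s S_R vs S_L: r = %.3f (n = %d, p = %.4f)",
        sc$group[i], sc$r[i], sc$n[i], sc$p[i])
    }
    if (!is.null(bundle$summary$groupTest)) {
      gt <- bundle$summary$groupTest
      w("between-group LI: t(%d) = %.3f, p = %.4f", gt$df, gt$statistic, gt$p)
    }
  }
  if (!is.null(bundle$correlations) && nrow(bundle$correlations)) {
    w("correlation grid:")
    cg <- bundle$correlations
    for (i in seq_len(nrow(cg))) {
      w("  %s vs %s: r = %.3f (n = %d, p = %.4f, adj = %.4f, %s)",
        cg$feature[i], cg$phenotype[i], cg$r[i], cg$n[i], cg$p[i],
        cg$p_adjusted[i], cg$tail[i])
    }
  }
  invisible(dir)
}
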