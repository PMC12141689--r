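# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

.gaussKernel <- function(t, latency, width) exp(-(t - latency)^2 / (2 * width^2))

# Per-group amplitude lookup: scalar applies to all groups.
.groupAmp <- function(amp, group) {
  if (is.null(names(amp))) return(amp[1])
  if (!group %in% names(amp)) stop("no amplitude configured for group ", group)
  unname(amp[group])
}

#' Construct a simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for: two
#' groups (typical controls, TC, n = 27; Williams syndrome, WS, n = 29),
#' 300 trials per condition sampled at 250 Hz over a -100..1000 ms epoch,
#' visual component kernels peaking at 155 ms (P1, motion), 148 ms (N1,
#' color change) and 190 ms (N2, motion direction), and molecular covariates
#' whose correlation with the true Laterality Index defaults to 0.47 for
#' BUD23 expression and -0.40 for its promoter CpG methylation.
#'
#' The latent laterality model draws, per subject, a non-negative total
#' sensitivity T (Gamma, SD `sensitivityScale`) and an allocation proportion
#' pi (Beta, per group), and sets the hemispheric sensitivities
#' S_R = -T (1 - pi), S_L = -T pi, so LI = S_R - S_L = T (2 pi - 1) exactly.
#' The default allocation Betas (concentration 2; TC mean pi 0.2290, WS
#' 0.6330) put 84% of TC subjects at pi < 0.5 (right-hemisphere specialized)
#' and 68% of WS at pi > 0.5, and make the two hemispheric sensitivities
#' strongly anticorrelated within each group. The Gamma mean is derived from
#' `groupMeans` so each group's expected LI is met exactly.
#'
#' @param nPerGroup named counts per group.
#' @param nTrials trials per condition.
#' @param samplingRate Hz.
#' @param epochWindow ms pair, half-open on the right.
#' @param conditions conditions to synthesize (M_SL, M_SR, P_CHANGE).
#' @param groupMeans named mean true LI per group, microvolts.
#' @param sensitivityScale SD of total sensitivity T, microvolts.
#' @param allocationParams per-group Beta shape pair `c(a, b)`; a length-1
#'   entry fixes pi at that value (degenerate allocation).
#' @param componentParams per-component list(latency, width, amplitude);
#'   amplitude may be named per group.
#' @param noiseSd,eogNoiseSd,pinkFraction trial noise model, microvolts.
#' @param artifactRate per-trial artifact probability.
#' @param artifactAmplitudes named blink/hem/spike amplitudes, microvolts;
#'   defaults straddle the 200 uV rejection threshold.
#' @param rhoExpression,rhoMethylation named target correlations of each
#'   molecular feature with the true LI.
#' @param leftHanded,femaleCount named per-group covariate counts.
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nPerGroup = c(TC = 4, WS = 4), nTrials = 10)
#' truth <- simulateTruth(cfg)
#' @export
SimulationConfig <- function(nPerGroup = c(TC = 27L, WS = 29L),
                             nTrials = 300L,
                             samplingRate = 250,
                             epochWindow = c(-100, 1000),
                             conditions = c("M_SL", "M_SR", "P_CHANGE"),
                             groupMeans = c(TC = -1.5, WS = 0.8),
                             sensitivityScale = 0.7,
                             allocationParams = list(
                               TC = c(a = 0.45804, b = 1.54196),
                               WS = c(a = 1.26607, b = 0.73393)
                             ),
                             componentParams = list(
                               P1 = list(latency = 155, width = 15,
                                         amplitude = c(TC = 4, WS = 2.2)),
                               N1 = list(latency = 148, width = 15,
                                         amplitude = -4),
                               N2 = list(latency = 190, width = 15,
                                         amplitude = -5)
                             ),
                             noiseSd = 6,
                             eogNoiseSd = 5,
                             pinkFraction = 0.2,
                             artifactRate = 0.1,
                             artifactAmplitudes = c(blink = 300, hem = 60,
                                                    spike = 250),
                             rhoExpression = c(BUD23 = 0.47),
                             rhoMethylation = c(cg12099727 = -0.40),
                             leftHanded = c(TC = 2L, WS = 8L),
                             femaleCount = c(TC = 15L, WS = 18L),
                             seed = 1L) {
  grp <- names(nPerGroup)
  new("SimulationConfig",
    nPerGroup = stats::setNames(as.integer(nPerGroup), grp),
    nTrials = as.integer(nTrials),
    samplingRate = samplingRate,
    epochWindow = as.numeric(epochWindow),
    conditions = conditions,
    groupMeans = groupMeans,
    sensitivityScale = sensitivityScale,
    allocationParams = allocationParams,
    componentParams = componentParams,
    noiseSd = noiseSd,
    eogNoiseSd = eogNoiseSd,
    pinkFraction = pinkFraction,
    artifactRate = artifactRate,
    artifactAmplitudes = artifactAmplitudes,
    rhoExpression = rhoExpression,
    rhoMethylation = rhoMethylation,
    leftHanded = stats::setNames(as.integer(leftHanded[grp]), grp),
    femaleCount = stats::setNames(as.integer(femaleCount[grp]), grp),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      paste(names(object@nPerGroup), object@nPerGroup, sep = "=", collapse = ", "),
      "|", object@nTrials, "trials/condition @", object@samplingRate, "Hz\n")
  cat("  group mean LI:",
      paste(names(object@groupMeans), object@groupMeans, sep = "=", collapse = ", "),
      "uV; noise", object@noiseSd, "uV; artifact rate", object@artifactRate, "\n")
})

#' Simulate ground-truth hemispheric sensitivities
#'
#' Draws, per subject, total sensitivity T >= 0 and allocation pi in (0,1)
#' from the per-group laws in `config`, and sets S_R_true = -T (1 - pi),
#' S_L_true = -T pi, LI_true = S_R_true - S_L_true (exact identity).
#' Negative sensitivity means the contralateral motion direction evoked the
#' larger (more negative) N2, i.e. a more sensitive hemisphere. Handedness
#' and sex are assigned to match the configured per-group counts exactly.
#' Deterministic given `config@seed`.
#'
#' @param config a [SimulationConfig-class] object.
#' @return a data.table: subject, group, handedness, sex, S_R_true,
#'   S_L_true, LI_true.
#' @export
simulateTruth <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    out <- lapply(names(config@nPerGroup), function(g) {
      n <- config@nPerGroup[[g]]
      ap <- config@allocationParams[[g]]
      if (is.null(ap)) stop("no allocation parameters for group ", g)
      if (length(ap) == 1L) {               # degenerate: pi fixed
        pim <- unname(ap)
        pi <- rep(pim, n)
      } else {
        pim <- unname(ap[1] / (ap[1] + ap[2]))
        pi <- stats::rbeta(n, ap[1], ap[2])
      }
      gm <- config@groupMeans[[g]]
      if (abs(2 * pim - 1) < 1e-12) {
        if (abs(gm) > 1e-12) {
          stop("group ", g, ": mean allocation 0.5 cannot target a nonzero mean LI")
        }
        muT <- 2                              # arbitrary positive scale
      } else {
        muT <- gm / (2 * pim - 1)
        if (muT <= 0) {
          stop("group ", g, ": groupMeans sign incompatible with allocation skew")
        }
      }
      if (config@sensitivityScale == 0) {
        T <- rep(muT, n)
      } else {
        shape <- (muT / config@sensitivityScale)^2
        T <- stats::rgamma(n, shape = shape, scale = config@sensitivityScale^2 / muT)
      }
      hand <- rep("R", n)
      hand[sample.int(n, min(n, config@leftHanded[[g]]))] <- "L"
      sex <- rep("M", n)
      sex[sample.int(n, min(n, config@femaleCount[[g]]))] <- "F"
      S_R <- -T * (1 - pi)
      S_L <- -T * pi
      data.table(
        subject = sprintf("%s%02d", g, seq_len(n)), group = g,
        handedness = hand, sex = sex,
        S_R_true = S_R, S_L_true = S_L, LI_true = S_R - S_L
      )
    })
    rbindlist(out)
  })
}

#' Synthesize trial-level ERP epochs from ground truth
#'
#' Each trial's waveform is a sum of Gaussian-in-time component kernels plus
#' white/low-frequency noise. The P1 (positive, occipital channels) appears
#' in the motion conditions; the N1 (negative, occipital) in the
#' color-change condition; the N2 (negative, parieto-occipital sets) in the
#' motion conditions with hemisphere-by-direction amplitude offsets scaled
#' so that the noise-free mean amplitude in the N2 measurement window gives
#' contralateral-minus-ipsilateral differences exactly equal to S_R_true and
#' S_L_true. Mastoid and EOG channels carry no stimulus-locked signal.
#' Deterministic given `config@seed`.
#'
#' @param truth ground-truth table from [simulateTruth()].
#' @param config a [SimulationConfig-class] object.
#' @param layout a [ChannelLayout-class]; must include the occipital,
#'   LH/RH parieto-occipital, mastoid and EOG channels.
#' @param n2Window ms pair: the measurement window the N2 offsets are
#'   normalized against (inclusive endpoints).
#' @return an [ErpEpochs-class] object.
#' @export
synthesizeEpochs <- function(truth, config, layout = defaultChannelLayout(),
                             n2Window = c(155, 195)) {
  validObject(config)
  step <- 1000 / config@samplingRate
  nt <- as.integer(round(diff(config@epochWindow) / step))
  tgrid <- config@epochWindow[1] + step * (0:(nt - 1L))
  cp <- config@componentParams
  for (nm in names(cp)) {
    lat <- cp[[nm]]$latency
    if (lat < config@epochWindow[1] || lat >= config@epochWindow[2]) {
      stop("component ", nm, " latency outside the epoch window")
    }
  }
  channels <- layout@channels
  nch <- length(channels)
  occ <- match(layout@occipitalSet, channels)
  lh <- match(layout@lhSet, channels)
  rh <- match(layout@rhSet, channels)
  eogIdx <- match(c(layout@veog, layout@heog), channels)
  scalpIdx <- setdiff(seq_len(nch), eogIdx)

  kP1 <- .gaussKernel(tgrid, cp$P1$latency, cp$P1$width)
  kN1 <- .gaussKernel(tgrid, cp$N1$latency, cp$N1$width)
  kN2 <- .gaussKernel(tgrid, cp$N2$latency, cp$N2$width)
  inWin <- tgrid >= n2Window[1] & tgrid <= n2Window[2]
  if (!any(inWin)) stop("n2Window contains no samples")
  mw <- mean(kN2[inWin])                      # window-averaging gain of the kernel

  ntr <- config@nTrials
  pf <- config@pinkFraction
  mkNoise <- function(ncol_, sd_, pink) {
    if (sd_ == 0) return(matrix(0, nt, ncol_))
    w <- matrix(stats::rnorm(nt * ncol_), nt, ncol_)
    if (pink && pf > 0) {
      p <- apply(matrix(stats::rnorm(nt * ncol_), nt, ncol_), 2L, cumsum)
      p <- scale(p)                            # per-trial unit SD, zero mean
      sd_ * (sqrt(1 - pf) * w + sqrt(pf) * p)
    } else {
      sd_ * w
    }
  }

  .withSeed(config@seed + 1L, {
    pieces <- vector("list", nrow(truth) * length(config@conditions))
    k <- 0L
    for (i in seq_len(nrow(truth))) {
      su <- truth$subject[i]; g <- truth$group[i]; hd <- truth$handedness[i]
      for (cond in config@conditions) {
        base <- matrix(0, nt, nch)
        if (cond %in% c("M_SL", "M_SR")) {
          base[, occ] <- kP1 * .groupAmp(cp$P1$amplitude, g)
          n2amp <- .groupAmp(cp$N2$amplitude, g)
          sgn <- if (cond == "M_SL") 1 else -1
          # window mean difference (SL - SR) over rh equals S_R_true exactly
          base[, rh] <- kN2 * (n2amp + sgn * truth$S_R_true[i] / (2 * mw))
          base[, lh] <- kN2 * (n2amp - sgn * truth$S_L_true[i] / (2 * mw))
        } else if (cond == "P_CHANGE") {
          base[, occ] <- kN1 * .groupAmp(cp$N1$amplitude, g)
        }
        amp <- matrix(rep(base, ntr), nt, nch * ntr)
        if (config@noiseSd > 0) {
          amp[, rep(scalpIdx, ntr) + rep((0:(ntr - 1L)) * nch, each = length(scalpIdx))] <-
            amp[, rep(scalpIdx, ntr) + rep((0:(ntr - 1L)) * nch, each = length(scalpIdx))] +
            mkNoise(length(scalpIdx) * ntr, config@noiseSd, pink = TRUE)
        }
        if (config@eogNoiseSd > 0) {
          amp[, rep(eogIdx, ntr) + rep((0:(ntr - 1L)) * nch, each = length(eogIdx))] <-
            amp[, rep(eogIdx, ntr) + rep((0:(ntr - 1L)) * nch, each = length(eogIdx))] +
            mkNoise(length(eogIdx) * ntr, config@eogNoiseSd, pink = FALSE)
        }
        k <- k + 1L
        pieces[[k]] <- data.table(
          subject = su, group = g, handedness = hd, condition = cond,
          trial = rep(seq_len(ntr), each = nch * nt),
          channel = rep(rep(channels, each = nt), ntr),
          time_ms = rep(tgrid, nch * ntr),
          amplitude_uV = as.vector(amp)
        )
      }
    }
    new("ErpEpochs", data = rbindlist(pieces),
        samplingRate = config@samplingRate, layout = layout)
  })
}

#' Superimpose ocular and amplitude artifacts on epochs
#'
#' Flags a Bernoulli(`artifactRate`) subset of trials and adds one artifact
#' per flagged trial, drawn uniformly from: blink (large slow deflection on
#' the vertical EOG), horizontal eye movement (a sustained step on the
#' horizontal EOG) and spike (a brief excursion beyond the rejection
#' threshold on a random analysis channel). Amplitudes come from
#' `config@artifactAmplitudes` and default to 300 / 60 / 250 microvolts,
#' straddling the 200 uV amplitude criterion and the conventional EOG
#' peak-to-peak criteria. Returns the contaminated epochs together with the
#' truth flags so rejection accuracy can be scored. Deterministic given
#' `config@seed`.
#'
#' @param epochs an [ErpEpochs-class] object.
#' @param config a [SimulationConfig-class] object.
#' @return list with elements `epochs` (contaminated [ErpEpochs-class]) and
#'   `flags` (data.table: subject, condition, trial, artifact, kind).
#' @export
injectArtifacts <- function(epochs, config) {
  trials <- unique(epochs@data[, .(subject, condition, trial)])
  if (config@artifactRate == 0) {
    flags <- data.table(trials, artifact = FALSE, kind = "none")
    return(list(epochs = epochs, flags = flags))
  }
  layout <- epochs@layout
  tgrid <- sort(unique(epochs@data$time_ms))
  .withSeed(config@seed + 2L, {
    flags <- data.table(trials)
    flags[, artifact := stats::runif(.N) < config@artifactRate]
    flags[, kind := "none"]
    flags[artifact == TRUE,
          kind := sample(c("blink", "hem", "spike"), .N, replace = TRUE)]
    dt <- data.table::copy(epochs@data)
    setkeyv(dt, c("subject", "condition", "trial", "channel"))
    amps <- config@artifactAmplitudes
    hit <- flags[artifact == TRUE]
    for (j in seq_len(nrow(hit))) {
      su <- hit$subject[j]; cd <- hit$condition[j]; tr <- hit$trial[j]
      if (hit$kind[j] == "blink") {
        center <- stats::runif(1, 100, 800)
        pulse <- amps[["blink"]] * .gaussKernel(tgrid, center, 25)
        for (ch in layout@veog) {
          dt[.(su, cd, tr, ch), amplitude_uV := amplitude_uV + pulse]
        }
      } else if (hit$kind[j] == "hem") {
        onset <- stats::runif(1, 0, 700)
        stepw <- ifelse(tgrid >= onset, amps[["hem"]], 0) * sample(c(-1, 1), 1)
        dt[.(su, cd, tr, layout@heog), amplitude_uV := amplitude_uV + stepw]
      } else {
        ch <- sample(analysisChannels(layout, includeEog = FALSE), 1)
        at <- sample(seq_along(tgrid), 1)
        spike <- numeric(length(tgrid))
        spike[at] <- amps[["spike"]] * sample(c(-1, 1), 1)
        dt[.(su, cd, tr, ch), amplitude_uV := amplitude_uV + spike]
      }
    }
    list(
      epochs = new("ErpEpochs", data = dt,
                   samplingRate = epochs@samplingRate, layout = layout),
      flags = flags
    )
  })
}

#' Simulate molecular covariates tied to the true Laterality Index
#'
#' Gene expression for each configured feature f is built on a latent scale
#' as rho_f * standardize(LI_true) + sqrt(1 - rho_f^2) * noise, then mapped
#' onto two batch-specific affine scales (distinct mean and SD per batch,
#' exercising batch correction downstream). Batches split subjects by parity
#' of acquisition order. Promoter CpG methylation is generated through an
#' inverse-logit link on a latent combining the primary expression latent
#' and noise, so its beta value lies in [0, 1] and correlates with LI_true
#' at approximately the configured (conventionally negative) rho on the
#' latent scale. Deterministic given `config@seed`.
#'
#' @param truth ground-truth table from [simulateTruth()].
#' @param config a [SimulationConfig-class] object.
#' @return a data.table (long MolecularTable): subject, measure_type,
#'   feature, batch, value; latent feature values are attached as the
#'   `"latent"` attribute.
#' @export
simulateMolecular <- function(truth, config) {
  li <- truth$LI_true
  if (stats::sd(li) == 0) {
    stop("degenerate LI variance: all LI_true equal, cannot standardize")
  }
  z <- as.vector(scale(li))
  n <- length(z)
  batch <- ifelse(seq_len(n) %% 2L == 1L, "B1", "B2")
  batchScale <- list(B1 = c(mean = 10, sd = 2), B2 = c(mean = 20, sd = 5))
  .withSeed(config@seed + 3L, {
    rows <- list(); latents <- list()
    exprLatent <- NULL
    for (f in names(config@rhoExpression)) {
      rho <- config@rhoExpression[[f]]
      lat <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      if (is.null(exprLatent)) {
        exprLatent <- lat; exprRho <- rho
      }
      val <- ifelse(batch == "B1",
                    batchScale$B1["mean"] + batchScale$B1["sd"] * lat,
                    batchScale$B2["mean"] + batchScale$B2["sd"] * lat)
      rows[[length(rows) + 1L]] <- data.table(
        subject = truth$subject, measure_type = "expression", feature = f,
        batch = batch, value = val
      )
      latents[[length(latents) + 1L]] <- data.table(
        subject = truth$subject, feature = f, latent = lat
      )
    }
    for (p in names(config@rhoMethylation)) {
      rho <- config@rhoMethylation[[p]]
      if (!is.null(exprLatent) && abs(rho) <= abs(exprRho)) {
        cc <- rho / exprRho
        lat <- cc * exprLatent + sqrt(1 - cc^2) * stats::rnorm(n)
      } else {
        lat <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      }
      beta <- stats::plogis(0.6 * lat)         # centered at 0.5, within (0,1)
      rows[[length(rows) + 1L]] <- data.table(
        subject = truth$subject, measure_type = "methylation", feature = p,
        batch = batch, value = beta
      )
      latents[[length(latents) + 1L]] <- data.table(
        subject = truth$subject, feature = p, latent = lat
      )
    }
    out <- rbindlist(rows)
    data.table::setattr(out, "latent", rbindlist(latents))
    out[]
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulateTruth()], [synthesizeEpochs()],
#' [injectArtifacts()] and [simulateMolecular()] under one configuration.
#'
#' @inheritParams synthesizeEpochs
#' @param artifacts logical, contaminate the epochs?
#' @return list: truth, epochs, flags (NULL when `artifacts = FALSE`),
#'   molecular.
#' @export
simulateCohort <- function(config, layout = defaultChannelLayout(),
                           artifacts = TRUE) {
  truth <- simulateTruth(config)
  epochs <- synthesizeEpochs(truth, config, layout)
  flags <- NULL
  if (artifacts && config@artifactRate > 0) {
    inj <- injectArtifacts(epochs, config)
    epochs <- inj$epochs
    flags <- inj$flags
  }
  list(truth = truth, epochs = epochs, flags = flags,
       molecular = simulateMolecular(truth, config))
}
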