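## Workflow layer: configuration, logging, and the three analysis
## workflows (chromatic-aberration determination, per-recording ratio
## analysis, calibration + inference). A thin command-line wrapper around
## these functions ships in inst/cli/dcc.R.

#' Pipeline configuration
#'
#' Returns the default analysis configuration as a named list; pass
#' overrides as arguments (nested lists are merged). The defaults follow
#' standard DCC-SMLM practice: beads are found with a high intensity
#' threshold and a min_samples of a quarter of the frame count (beads emit
#' in every frame), protein signals with low thresholds; the
#' colocalization cutoff defaults to 100 nm.
#'
#' @param ... overrides, e.g. \code{signal = list(eps = 60)}.
#' @return a named list with class \code{"dccConfig"}.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        dialect = "csv",
        pixelSizeNm = 100,
        referenceChannel = "green",
        correctedChannel = "red",
        bead = list(intensityThreshold = 5000, minSamples = NA_integer_,
                    eps = 100, minFrames = NA_integer_),
        signal = list(intensityThreshold = 0, minSamples = 2L, eps = 30),
        beadPairingCutoff = 500,
        colocCutoff = 100,
        rois = NULL,
        minBeadPositions = 500L,
        minRecordingsPerProtein = 12L,
        maxZOffset = 100,
        nBootstrap = 1000L,
        nMax = 6L,
        seed = 1L)
    overrides <- list(...)
    if (length(overrides) == 1L && is.null(names(overrides)) &&
        is.list(overrides[[1L]]))
        overrides <- overrides[[1L]]
    cfg <- modifyList(cfg, overrides)
    class(cfg) <- "dccConfig"
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror \code{\link{pipelineConfig}}; unknown keys are kept so that
#' site-specific column mappings can ride along.
#'
#' @param path YAML file.
#' @return a \code{"dccConfig"} list.
#' @export
readPipelineConfig <- function(path) {
    pipelineConfig(yaml::read_yaml(path))
}

## bead min_samples defaults to a quarter of the frames when unset
beadParams <- function(config, nFrames) {
    b <- config$bead
    if (is.na(b$minSamples))
        b$minSamples <- max(2L, as.integer(nFrames / 4))
    if (is.na(b$minFrames))
        b$minFrames <- max(2L, as.integer(nFrames / 2))
    b
}

configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(unclass(config)), tmp)
    unname(tools::md5sum(tmp))
}

outputComments <- function(config) {
    c(paste0("seed: ", config$seed),
      paste0("config_hash: ", configHash(config)))
}

dccLog <- function(logFile, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    message(line)
    if (!is.null(logFile))
        cat(line, "\n", file = logFile, append = TRUE, sep = "")
    invisible(line)
}

asLocTable <- function(x, config, channel) {
    if (is(x, "LocalizationTable"))
        return(x)
    readLocalizations(x, dialect = config$dialect, channel = channel,
                      pixelSize = config$pixelSizeNm)
}

#' Determine chromatic aberration from bead recordings
#'
#' Clusters the beads of each two-color bead recording per channel, pairs
#' them across channels (mutual nearest neighbours within
#' \code{beadPairingCutoff}), pools the pairs of all recordings and fits
#' the linear chromatic-aberration model. A warning is emitted when fewer
#' than \code{minBeadPositions} pooled positions are available.
#'
#' @param recordings list of recordings, each a list with elements
#'   \code{green} and \code{red} (\linkS4class{LocalizationTable}s or file
#'   paths).
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outPath optional CSV path for the fitted parameters.
#' @param logFile optional log file.
#' @return a \linkS4class{CAModel}.
#' @export
runCAFit <- function(recordings, config = pipelineConfig(),
                     outPath = NULL, logFile = NULL) {
    if (!length(recordings))
        stop("need at least one bead recording")
    pairs <- do.call(rbind, lapply(recordings, function(rec) {
        g <- asLocTable(rec$green, config, config$referenceChannel)
        r <- asLocTable(rec$red, config, config$correctedChannel)
        bp <- beadParams(config, nFrames(g))
        cg <- findClusters(g, bp$intensityThreshold, bp$minSamples, bp$eps)
        cr <- findClusters(r, bp$intensityThreshold, bp$minSamples, bp$eps)
        pairBeads(cg, cr, config$beadPairingCutoff)
    }))
    if (is.null(pairs) || nrow(pairs) == 0L)
        stop("no bead pairs found across the recordings; ",
             "check bead thresholds and the pairing cutoff")
    if (nrow(pairs) < config$minBeadPositions)
        warning("only ", nrow(pairs), " pooled bead positions; at least ",
                config$minBeadPositions, " spread across the field of ",
                "view are recommended for the CA fit")
    model <- fitChromaticAberration(pairs,
                                    referenceChannel =
                                        config$referenceChannel,
                                    correctedChannel =
                                        config$correctedChannel)
    dccLog(logFile, "CA fit on ", nrow(pairs), " bead pairs: residual ",
           signif(model@residualRms, 4), " nm RMS")
    if (!is.null(outPath))
        writeCAParams(model, outPath, comments = outputComments(config))
    model
}

#' Analyze one dual-color recording into a colocalization ratio
#'
#' The single-recording workflow: load both channels (applying the
#' chromatic-aberration correction to the corrected channel), identify
#' fiducial beads per channel, extract and subtract the drift, cluster the
#' protein signals (beads removed by intensity/persistence), and compute
#' the colocalization ratio within the configured ROIs.
#'
#' @param marker,indicator \linkS4class{LocalizationTable}s or file paths
#'   (marker = reference/green channel, indicator = corrected/red).
#' @param caModel a \linkS4class{CAModel}, a CA params CSV path, or
#'   \code{NULL} to skip the correction.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param recordingId identifier for the output row.
#' @param zOffset axial focus offset of the recording in nm (\code{NA} to
#'   skip the check); recordings beyond \code{maxZOffset} are rejected
#'   with a logged reason and \code{NULL} is returned.
#' @param logFile optional log file.
#' @return a \linkS4class{ColocRecord}, or \code{NULL} for a recording
#'   excluded by quality control.
#' @export
analyzeRecording <- function(marker, indicator, caModel = NULL,
                             config = pipelineConfig(), recordingId = "",
                             zOffset = NA_real_, logFile = NULL) {
    if (!is.na(zOffset) && abs(zOffset) > config$maxZOffset) {
        dccLog(logFile, "recording '", recordingId, "' excluded: z ",
               "offset ", zOffset, " nm exceeds ", config$maxZOffset,
               " nm")
        return(NULL)
    }
    mk <- asLocTable(marker, config, config$referenceChannel)
    ind <- asLocTable(indicator, config, config$correctedChannel)
    if (!is.null(caModel)) {
        if (is.character(caModel))
            caModel <- readCAParams(caModel)
        ind <- applyChromaticAberration(ind, caModel)
    }
    correctChannel <- function(tab) {
        bp <- beadParams(config, nFrames(tab))
        beads <- findClusters(tab, bp$intensityThreshold, bp$minSamples,
                              bp$eps)
        if (nClusters(beads) == 0L)
            stop("no fiducial beads found in channel '",
                 channelLabel(tab), "' of recording '", recordingId,
                 "'; drift correction is impossible")
        mem <- clusterMembers(tab, beads)
        trace <- extractDrift(mem$table, mem$labels)
        applyDrift(tab, trace)
    }
    mk <- correctChannel(mk)
    ind <- correctChannel(ind)

    findSignals <- function(tab) {
        sp <- config$signal
        bp <- beadParams(config, nFrames(tab))
        cl <- findClusters(tab, sp$intensityThreshold, sp$minSamples,
                           sp$eps)
        splitBeadsAndSignals(cl, bp$intensityThreshold,
                             bp$minFrames)$signals
    }
    rec <- getColocalizationRatio(findSignals(mk), findSignals(ind),
                                  distanceCutoff = config$colocCutoff,
                                  rois = config$rois,
                                  recordingId = recordingId)
    dccLog(logFile, "recording '", recordingId, "': N_M = ", rec@nMarker,
           ", N_MF = ", rec@nColoc, ", R = ",
           if (is.na(rec@ratio)) "NA" else signif(rec@ratio, 4))
    rec
}

#' Calibrate (p, m) from a ratio table of reference proteins
#'
#' @param ratios a ratio \code{data.frame} (from \code{\link{ratioTable}}
#'   or \code{\link{readRatioTable}}) with a \code{known_state} column, or
#'   a CSV path.
#' @param config a \code{\link{pipelineConfig}} list (bootstrap count and
#'   seed are taken from it unless overridden).
#' @param nBootstrap,seed overrides of the config values.
#' @param outPath optional CSV output (p, m, CI bounds, seed, bootstraps).
#' @param logFile optional log file.
#' @return a \linkS4class{CalibrationFit}.
#' @export
calibrateReferences <- function(ratios, config = pipelineConfig(),
                                nBootstrap = config$nBootstrap,
                                seed = config$seed, outPath = NULL,
                                logFile = NULL) {
    if (is.character(ratios))
        ratios <- readRatioTable(ratios)
    if (!"known_state" %in% names(ratios))
        stop("calibration requires a known_state column")
    perState <- table(ratios$known_state)
    if (any(perState < config$minRecordingsPerProtein))
        warning("fewer than ", config$minRecordingsPerProtein,
                " recordings for state(s) ",
                paste(names(perState)[perState <
                      config$minRecordingsPerProtein], collapse = ", "),
                "; the calibration may be unstable")
    fit <- referenceBootstrap(ratios$ratio, ratios$known_state,
                              nBootstrap = nBootstrap, seed = seed)
    dccLog(logFile, "calibration: p = ", signif(fit@p, 4), ", m = ",
           signif(fit@m, 4))
    if (!is.null(outPath))
        writeCalibration(fit, outPath, comments = outputComments(config))
    fit
}

#' Write / read a calibration result as CSV
#'
#' Columns: \code{p, m, ci_p_low, ci_p_high, ci_m_low, ci_m_high,
#' n_bootstrap, seed}.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param path CSV file.
#' @param comments optional leading \code{# ...} lines.
#' @return \code{writeCalibration}: \code{path} invisibly;
#'   \code{readCalibration}: a list with the stored fields.
#' @export
writeCalibration <- function(fit, path, comments = NULL) {
    stopifnot(is(fit, "CalibrationFit"))
    writeLines(c(commentLines(comments),
                 "p,m,ci_p_low,ci_p_high,ci_m_low,ci_m_high,n_bootstrap,seed",
                 sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%d,%d",
                         fit@p, fit@m, fit@ciP[1L], fit@ciP[2L],
                         fit@ciM[1L], fit@ciM[2L], fit@nBootstrap,
                         fit@seed)), path)
    invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
    d <- freadNoComments(path)
    requireColumns(d, c("p", "m"), path)
    as.list(d[1L, ])
}

#' Infer the oligomeric state of a protein of interest
#'
#' Runs the COM bootstrap against the calibrated model and the
#' Kolmogorov-Smirnov comparison against each reference state.
#'
#' @param poiRatios ratio \code{data.frame} or CSV path for the protein of
#'   interest.
#' @param referenceRatios ratio \code{data.frame} or CSV path with
#'   \code{known_state} for the calibration proteins.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param nBootstrap,seed,nMax overrides of the config values.
#' @param referenceBootstrap also resample the calibration dataset per
#'   replicate (error propagation)?
#' @param outPrefix optional path prefix; writes
#'   \code{<prefix>_com.csv} (n, com, elect_fraction) and
#'   \code{<prefix>_ks.csv}.
#' @param logFile optional log file.
#' @return list with \code{com} (a \linkS4class{COMProfile}) and \code{ks}
#'   (the \code{\link{ksCompare}} table).
#' @export
inferState <- function(poiRatios, referenceRatios,
                       config = pipelineConfig(),
                       nBootstrap = config$nBootstrap, seed = config$seed,
                       nMax = config$nMax, referenceBootstrap = TRUE,
                       outPrefix = NULL, logFile = NULL) {
    if (is.character(poiRatios))
        poiRatios <- readRatioTable(poiRatios)
    if (is.character(referenceRatios))
        referenceRatios <- readRatioTable(referenceRatios)
    if (nrow(poiRatios) < config$minRecordingsPerProtein)
        warning("only ", nrow(poiRatios), " recordings for the protein ",
                "of interest; at least ", config$minRecordingsPerProtein,
                " are recommended")
    profile <- comBootstrap(poiRatios$ratio, referenceRatios$ratio,
                            referenceRatios$known_state,
                            nBootstrap = nBootstrap,
                            referenceBootstrap = referenceBootstrap,
                            seed = seed, nMax = nMax)
    ks <- ksCompare(poiRatios$ratio, referenceRatios$ratio,
                    referenceRatios$known_state)
    dccLog(logFile, "inference: best state n = ", bestState(profile),
           " (elected in ", signif(100 *
               electFraction(profile)[bestState(profile)], 3),
           "% of replicates); KS-most-compatible state = ",
           attr(ks, "bestState"))
    if (!is.null(outPrefix)) {
        cm <- data.frame(n = profile@states, com = profile@com,
                         elect_fraction = profile@electFraction)
        writeLines(c(commentLines(outputComments(config)),
                     "n,com,elect_fraction",
                     sprintf("%d,%.17g,%.17g", cm$n, cm$com,
                             cm$elect_fraction)),
                   paste0(outPrefix, "_com.csv"))
        writeLines(c(commentLines(outputComments(config)),
                     "state,D,p_value",
                     sprintf("%d,%.17g,%.17g", ks$state, ks$D,
                             ks$p_value)),
                   paste0(outPrefix, "_ks.csv"))
    }
    list(com = profile, ks = ks)
}
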