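## Validation harness: full-pipeline simulation studies with known ground
## truth. These functions drive the whole chain — bead-field simulation,
## chromatic-aberration fit, per-recording drift correction, clustering,
## colocalization, calibration and COM inference — at a scaled-down
## acquisition size suitable for routine verification runs.

#' Default analysis configuration for simulation studies
#'
#' The pipeline settings used to analyze recordings produced by
#' \code{\link{simulateRecording}}: signal clustering with eps of four
#' times the simulator's localization sigma and min_samples 1 (the
#' simulated background is prebleached-clean and excluded by the cell
#' ROI, and min_samples 1 keeps per-fluorophore detectability independent
#' of oligomer size, an assumption of the DCC model), colocalization
#' cutoff 100 nm, ROI equal to the simulated cell region.
#'
#' @param cellRoi cell rectangle (x, y, width, height) in nm.
#' @param locPrecision simulator localization sigma in nm.
#' @return a \code{\link{pipelineConfig}} list.
#' @export
studyConfig <- function(cellRoi = c(8000, 8000, 25000, 25000),
                        locPrecision = 15) {
    pipelineConfig(signal = list(eps = 4 * locPrecision,
                                 minSamples = 1L),
                   rois = matrix(cellRoi, nrow = 1L))
}

#' Run one full-pipeline oligomeric-state inference study
#'
#' Simulates a complete experiment with a known true oligomeric state and
#' analyzes it blind: a two-color bead field is simulated and fit for
#' chromatic aberration; reference proteins of states \code{1..nStates}
#' and the protein of interest are each simulated as dual-color
#' recordings, chromatic-aberration corrected, drift corrected via their
#' fiducial beads, clustered and reduced to colocalization ratios; the
#' references calibrate (p, m) and the COM profile of the protein of
#' interest elects a state.
#'
#' Acquisition is scaled down relative to a full recording session (fewer frames
#' and beads per recording); detection physics are unchanged.
#'
#' @param nTrue true oligomeric state of the protein of interest.
#' @param seed study seed (all per-recording seeds derive from it).
#' @param nStates number of reference states (1..nStates).
#' @param recordingsPerProtein recordings per protein.
#' @param nComplexes complexes per recording.
#' @param pIndicator,mModification detection-model truth.
#' @param caField chromatic-aberration field applied by the simulator and
#'   re-estimated from the simulated bead field.
#' @param nFramesMarker,nFramesIndicator,nBeads scaled acquisition size.
#' @param nBeadPositions bead positions for the CA fit.
#' @return list with \code{bestState}, \code{calibration} (named p, m),
#'   \code{poiRatios}, \code{referenceTable}, \code{caModel} and
#'   \code{comProfile}.
#' @export
simulateInferenceStudy <- function(nTrue, seed, nStates = 4L,
                                   recordingsPerProtein = 12L,
                                   nComplexes = 300L,
                                   pIndicator = 0.5, mModification = 0.1,
                                   caField = c(0.002, 5, -0.001, 2),
                                   nFramesMarker = 150L,
                                   nFramesIndicator = 250L,
                                   nBeads = 3L,
                                   nBeadPositions = 520L) {
    seeds <- withSeed(seed, sample.int(2^30, 2L +
        (nStates + 1L) * recordingsPerProtein))
    cfg <- studyConfig()

    ## chromatic aberration from a simulated bead field
    bf <- simulateBeadField(nBeadPositions, caField = caField,
                            pairingNoise = 5, seed = seeds[1L])
    bp <- beadParams(cfg, nFrames(bf$green))
    cg <- findClusters(bf$green, bp$intensityThreshold, bp$minSamples,
                       bp$eps)
    cr <- findClusters(bf$red, bp$intensityThreshold, bp$minSamples,
                       bp$eps)
    caModel <- fitChromaticAberration(
        pairBeads(cg, cr, cfg$beadPairingCutoff))

    oneRatio <- function(state, recSeed, id) {
        sim <- simulateRecording(simConfig(
            nSubunits = state, nComplexes = nComplexes,
            pIndicator = pIndicator, mModification = mModification,
            caField = caField, nFramesMarker = nFramesMarker,
            nFramesIndicator = nFramesIndicator, nBeads = nBeads,
            seed = recSeed))
        suppressMessages(analyzeRecording(sim$marker, sim$indicator,
                                          caModel, config = cfg,
                                          recordingId = id))
    }

    si <- 2L
    refRecords <- list()
    refStates <- integer()
    for (s in seq_len(nStates)) {
        for (r in seq_len(recordingsPerProtein)) {
            si <- si + 1L
            refRecords[[length(refRecords) + 1L]] <-
                oneRatio(s, seeds[si], sprintf("ref_n%d_%02d", s, r))
            refStates <- c(refStates, s)
        }
    }
    refTab <- ratioTable(refRecords, knownState = refStates)

    poiRecords <- lapply(seq_len(recordingsPerProtein), function(r) {
        oneRatio(nTrue, seeds[2L + nStates * recordingsPerProtein + r],
                 sprintf("poi_%02d", r))
    })
    poiTab <- ratioTable(poiRecords)

    fit <- fitPM(refTab$ratio, refTab$known_state)
    profile <- com(poiTab$ratio, list(p = fit[["p"]], m = fit[["m"]]),
                   nMax = nStates + 2L)
    list(bestState = bestState(profile),
         calibration = c(p = fit[["p"]], m = fit[["m"]]),
         poiRatios = poiTab$ratio, referenceTable = refTab,
         caModel = caModel, comProfile = profile)
}
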