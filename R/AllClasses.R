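## Central S4 containers. All coordinates are nanometres, origin at the
## field-of-view corner (0, 0), x to the right, y down; frame indices are
## 0-based. Drift and chromatic-aberration fits carry their own intercepts,
## so the origin convention never enters a correction.

#' LocalizationTable: one channel's emission events
#'
#' One row per fitted emission event (localization): 0-based frame index,
#' x and y in nm, and fluorescence intensity in arbitrary camera units.
#' Rows are kept sorted by frame (ties keep input order).
#'
#' @slot channel channel label, e.g. \code{"green"} or \code{"red"}.
#' @slot data \code{data.frame} with columns \code{frame} (integer),
#'   \code{x}, \code{y} (nm), \code{intensity}.
#' @slot pixelSize camera pixel size in nm, kept as metadata for dialects
#'   that store coordinates in pixels.
#' @slot nFrames number of frames in the recording; every \code{frame} is
#'   in \code{[0, nFrames)}.
#' @exportClass LocalizationTable
setClass("LocalizationTable",
    slots = c(
        channel = "character",
        data = "data.frame",
        pixelSize = "numeric",
        nFrames = "integer"
    )
)

setValidity("LocalizationTable", function(object) {
    d <- object@data
    msg <- character()
    if (!identical(names(d), c("frame", "x", "y", "intensity")))
        msg <- c(msg, "data must have columns frame, x, y, intensity")
    else {
        if (nrow(d)) {
            if (!is.numeric(d$frame) || any(d$frame < 0) ||
                any(d$frame >= object@nFrames) || any(d$frame != floor(d$frame)))
                msg <- c(msg, "frame indices must be integers in [0, nFrames)")
            if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
                msg <- c(msg, "x and y must be finite")
            if (any(d$intensity < 0))
                msg <- c(msg, "intensity must be >= 0")
            if (is.unsorted(d$frame))
                msg <- c(msg, "rows must be sorted by frame")
        }
    }
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a positive scalar")
    if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
        object@nFrames < 0L)
        msg <- c(msg, "nFrames must be a non-negative integer")
    if (length(msg)) msg else TRUE
})

#' Construct a LocalizationTable
#'
#' @param frame integer vector of 0-based frame indices.
#' @param x,y coordinates in nm.
#' @param intensity fluorescence intensities (arbitrary units, >= 0).
#' @param channel channel label.
#' @param pixelSize pixel size in nm (metadata; coordinates are always nm).
#' @param nFrames number of frames; defaults to \code{max(frame) + 1}.
#' @return a \linkS4class{LocalizationTable}.
#' @examples
#' lt <- LocalizationTable(frame = c(0L, 0L, 2L), x = c(10, 20, 30),
#'                         y = c(5, 5, 5), intensity = c(100, 90, 80))
#' nLocalizations(lt)
#' @export
LocalizationTable <- function(frame = integer(), x = numeric(),
                              y = numeric(), intensity = numeric(),
                              channel = "", pixelSize = 100,
                              nFrames = NULL) {
    frame <- as.integer(frame)
    if (is.null(nFrames))
        nFrames <- if (length(frame)) max(frame) + 1L else 0L
    d <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y),
                    intensity = as.numeric(intensity))
    if (nrow(d) && is.unsorted(d$frame))
        d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
    new("LocalizationTable", channel = as.character(channel), data = d,
        pixelSize = as.numeric(pixelSize), nFrames = as.integer(nFrames))
}

#' ClusterSet: labelled clusters of localizations
#'
#' Output of \code{\link{findClusters}}: one row per cluster with its
#' centroid (unweighted mean of member coordinates), size, frame span and
#' mean intensity, plus the per-localization labels of the input table.
#'
#' @slot clusters \code{data.frame} with columns \code{cluster_id}
#'   (0-based, contiguous), \code{x}, \code{y} (centroid, nm), \code{n},
#'   \code{first_frame}, \code{last_frame}, \code{mean_intensity}.
#' @slot channel channel label inherited from the input table.
#' @slot noiseCount localizations that passed the intensity filter but were
#'   assigned to no cluster.
#' @slot labels integer vector aligned with the input table rows: cluster id,
#'   \code{-1} for noise, \code{NA} for rows removed by the intensity filter
#'   (or belonging to the other part after \code{\link{splitBeadsAndSignals}}).
#' @exportClass ClusterSet
setClass("ClusterSet",
    slots = c(
        clusters = "data.frame",
        channel = "character",
        noiseCount = "integer",
        labels = "integer"
    )
)

setValidity("ClusterSet", function(object) {
    cl <- object@clusters
    msg <- character()
    need <- c("cluster_id", "x", "y", "n", "first_frame", "last_frame",
              "mean_intensity")
    if (!all(need %in% names(cl)))
        msg <- c(msg, paste("clusters must have columns",
                            paste(need, collapse = ", ")))
    else if (nrow(cl)) {
        if (!identical(as.integer(cl$cluster_id), seq_len(nrow(cl)) - 1L))
            msg <- c(msg, "cluster_ids must be contiguous from 0")
        if (any(cl$n < 1L))
            msg <- c(msg, "clusters must have >= 1 localization")
        if (any(cl$last_frame < cl$first_frame))
            msg <- c(msg, "last_frame must be >= first_frame")
    }
    if (object@noiseCount < 0L)
        msg <- c(msg, "noiseCount must be >= 0")
    if (length(msg)) msg else TRUE
})

#' DriftTrace: per-frame cumulative sample drift
#'
#' @slot drift \code{data.frame} with columns \code{frame} (0..nFrames-1),
#'   \code{dx}, \code{dy} (nm, cumulative displacement, (0,0) at frame 0).
#' @slot nBeads number of fiducial beads averaged.
#' @exportClass DriftTrace
setClass("DriftTrace",
    slots = c(drift = "data.frame", nBeads = "integer")
)

setValidity("DriftTrace", function(object) {
    d <- object@drift
    msg <- character()
    if (!all(c("frame", "dx", "dy") %in% names(d)))
        msg <- c(msg, "drift must have columns frame, dx, dy")
    else if (nrow(d)) {
        if (!identical(as.integer(d$frame), seq_len(nrow(d)) - 1L))
            msg <- c(msg, "drift must cover frames 0..n-1 contiguously")
        if (abs(d$dx[1L]) > 1e-12 || abs(d$dy[1L]) > 1e-12)
            msg <- c(msg, "displacement at frame 0 must be (0, 0)")
        if (!all(is.finite(d$dx)) || !all(is.finite(d$dy)))
            msg <- c(msg, "displacements must be finite")
    }
    if (object@nBeads < 1L)
        msg <- c(msg, "nBeads must be >= 1")
    if (length(msg)) msg else TRUE
})

#' CAModel: linear lateral chromatic-aberration field
#'
#' Lateral chromatic aberration displaces the corrected channel relative to
#' the reference channel by an amount that varies linearly with position.
#' The model is separable: the x-deviation is a linear function of x only,
#' the y-deviation of y only, both evaluated at the corrected channel's
#' observed coordinate, so that subtracting the prediction inverts a linear
#' field exactly.
#'
#' @slot slopeX,interceptX dx = slopeX * x + interceptX (nm).
#' @slot slopeY,interceptY dy = slopeY * y + interceptY (nm).
#' @slot residualRms root-mean-square 2-D fit residual in nm (\code{NA} for
#'   models read from file).
#' @slot nPairs number of bead pairs used in the fit (\code{NA} when read
#'   from file).
#' @slot referenceChannel,correctedChannel channel labels; the corrected
#'   channel is moved onto the reference channel.
#' @exportClass CAModel
setClass("CAModel",
    slots = c(
        slopeX = "numeric", interceptX = "numeric",
        slopeY = "numeric", interceptY = "numeric",
        residualRms = "numeric", nPairs = "integer",
        referenceChannel = "character", correctedChannel = "character"
    ),
    prototype = list(residualRms = NA_real_, nPairs = NA_integer_,
                     referenceChannel = "green", correctedChannel = "red")
)

setValidity("CAModel", function(object) {
    msg <- character()
    pars <- c(object@slopeX, object@interceptX, object@slopeY,
              object@interceptY)
    if (length(pars) != 4L || !all(is.finite(pars)))
        msg <- c(msg, "slopes and intercepts must be finite scalars")
    if (!is.na(object@residualRms) && object@residualRms < 0)
        msg <- c(msg, "residualRms must be >= 0")
    if (!is.na(object@nPairs) && object@nPairs < 2L)
        msg <- c(msg, "nPairs must be >= 2")
    if (identical(object@referenceChannel, object@correctedChannel))
        msg <- c(msg, "reference and corrected channels must be distinct")
    if (length(msg)) msg else TRUE
})

#' Construct a CAModel
#'
#' @param slopeX,interceptX,slopeY,interceptY linear field parameters; the
#'   deviation at observed coordinate (x, y) of the corrected channel is
#'   (slopeX*x + interceptX, slopeY*y + interceptY) nm.
#' @param residualRms,nPairs fit diagnostics (optional).
#' @param referenceChannel,correctedChannel channel labels (distinct).
#' @return a \linkS4class{CAModel}.
#' @export
CAModel <- function(slopeX = 0, interceptX = 0, slopeY = 0, interceptY = 0,
                    residualRms = NA_real_, nPairs = NA_integer_,
                    referenceChannel = "green", correctedChannel = "red") {
    new("CAModel", slopeX = as.numeric(slopeX),
        interceptX = as.numeric(interceptX), slopeY = as.numeric(slopeY),
        interceptY = as.numeric(interceptY),
        residualRms = as.numeric(residualRms), nPairs = as.integer(nPairs),
        referenceChannel = referenceChannel,
        correctedChannel = correctedChannel)
}

#' ColocRecord: one recording's colocalization count
#'
#' @slot recordingId recording identifier.
#' @slot nMarker N_M, marker clusters inside the regions of interest.
#' @slot nColoc N_MF, marker clusters with an indicator cluster within the
#'   distance cutoff (one-to-one greedy matching).
#' @slot ratio R = N_MF / N_M (\code{NA} when N_M = 0; such recordings are
#'   excluded downstream).
#' @slot distanceCutoff matching cutoff in nm.
#' @slot rois \code{data.frame} of rectangles (x, y, width, height) in nm;
#'   zero rows means the whole field.
#' @exportClass ColocRecord
setClass("ColocRecord",
    slots = c(
        recordingId = "character",
        nMarker = "integer", nColoc = "integer", ratio = "numeric",
        distanceCutoff = "numeric", rois = "data.frame"
    )
)

setValidity("ColocRecord", function(object) {
    msg <- character()
    if (object@nColoc < 0L || object@nColoc > object@nMarker)
        msg <- c(msg, "need 0 <= nColoc <= nMarker")
    if (object@nMarker > 0L) {
        if (!isTRUE(all.equal(object@ratio,
                              object@nColoc / object@nMarker,
                              tolerance = 1e-9)))
            msg <- c(msg, "ratio must equal nColoc / nMarker")
    } else if (!is.na(object@ratio))
        msg <- c(msg, "ratio must be NA when nMarker = 0")
    if (object@distanceCutoff <= 0)
        msg <- c(msg, "distanceCutoff must be > 0")
    if (length(msg)) msg else TRUE
})

#' CalibrationFit: recall rate p and modification coefficient m
#'
#' Result of fitting the DCC detection model to reference proteins of known
#' oligomeric state, with percentile-bootstrap confidence intervals.
#'
#' @slot p indicator recall rate, in (0, 1].
#' @slot m coefficient of modification, in [0, 1).
#' @slot ciP,ciM length-2 percentile intervals (2.5/97.5%).
#' @slot bootstrap \code{data.frame} of per-replicate (p, m).
#' @slot nBootstrap number of bootstrap replicates.
#' @slot seed RNG seed used.
#' @exportClass CalibrationFit
setClass("CalibrationFit",
    slots = c(
        p = "numeric", m = "numeric",
        ciP = "numeric", ciM = "numeric",
        bootstrap = "data.frame", nBootstrap = "integer", seed = "integer"
    )
)

setValidity("CalibrationFit", function(object) {
    msg <- character()
    if (object@p <= 0 || object@p > 1)
        msg <- c(msg, "p must be in (0, 1]")
    if (object@m < 0 || object@m >= 1)
        msg <- c(msg, "m must be in [0, 1)")
    for (ci in list(p = object@ciP, m = object@ciM)) {
        if (length(ci) != 2L || any(is.na(ci)) || ci[1L] > ci[2L])
            msg <- c(msg, "confidence intervals must be ordered length-2")
        else if (ci[1L] < 0 || ci[2L] > 1)
            msg <- c(msg, "confidence intervals must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' COMProfile: coefficient of mismatch per candidate oligomeric state
#'
#' COM(n) is the squared relative deviation of the mean observed
#' colocalization ratio from the model-expected ratio for candidate state
#' n; the minimizing state is the call. Bootstrap replicates quantify how
#' often each state would have been elected.
#'
#' @slot states candidate oligomeric states 1..n_max.
#' @slot com COM value per state (finite, >= 0).
#' @slot bestState argmin state (ties toward smaller n).
#' @slot electFraction fraction of bootstrap replicates electing each state
#'   (\code{NA} when no bootstrap was run).
#' @slot bootstrap replicate x state matrix of COM values (0 rows when no
#'   bootstrap was run).
#' @slot nBootstrap,seed bootstrap bookkeeping.
#' @exportClass COMProfile
setClass("COMProfile",
    slots = c(
        states = "integer", com = "numeric",
        bestState = "integer", electFraction = "numeric",
        bootstrap = "matrix", nBootstrap = "integer", seed = "integer"
    )
)

setValidity("COMProfile", function(object) {
    msg <- character()
    if (length(object@com) != length(object@states))
        msg <- c(msg, "com and states must have equal length")
    if (any(!is.finite(object@com)) || any(object@com < 0))
        msg <- c(msg, "com values must be finite and >= 0")
    if (!(object@bestState %in% object@states))
        msg <- c(msg, "bestState must be one of the candidate states")
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of a simulated dual-color SMLM recording
#'
#' Defaults emulate a typical DCC-SMLM acquisition:
#' 4,000 marker frames and 9,000 indicator frames per recording, 3-6
#' fiducial beads around the cell, complexes restricted to a central cell
#' region, a linear lateral chromatic-aberration field on the indicator
#' (red) channel, slow random-walk drift, and sparse background impurities
#' kept outside a clean margin around the cell.
#'
#' @slot nSubunits oligomeric state n of the simulated complexes.
#' @slot nComplexes complexes per recording.
#' @slot fieldSize c(width, height) of the field of view, nm.
#' @slot cellRoi c(x, y, width, height) rectangle containing the complexes.
#' @slot pIndicator indicator recall rate p.
#' @slot mModification coefficient of modification m; a modified subunit
#'   contributes neither marker nor indicator fluorophore.
#' @slot markerRecall probability a complex with >= 1 intact subunit shows a
#'   marker burst (near 1 for the bright marker).
#' @slot blinkFramesMean mean length (frames) of the geometric emission
#'   burst of one fluorophore.
#' @slot locPrecision isotropic localization noise sigma, nm. Beads use
#'   \code{locPrecision / sqrt(beadIntensityFactor)} (photon scaling).
#' @slot nBeads always-on fiducial beads placed outside the cell.
#' @slot beadIntensityFactor bead intensity relative to single-fluorophore
#'   signals.
#' @slot driftModel one of "none", "linear", "random-walk".
#' @slot driftRate nm/frame: c(dx, dy) for "linear", sigma for "random-walk".
#' @slot caField c(slopeX, interceptX, slopeY, interceptY) applied to the
#'   indicator channel at the true coordinate.
#' @slot backgroundDensity impurity localizations per frame per um^2.
#' @slot cleanMargin nm margin around the cell ROI kept free of impurities
#'   (set to 0 for the crowded stress mode).
#' @slot minSeparation minimum distance between complexes, nm (blue-noise
#'   placement; 0 disables and places complexes uniformly).
#' @slot nFramesMarker,nFramesIndicator frames per channel.
#' @slot seed RNG seed; identical configs give bit-identical recordings.
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        nSubunits = "integer", nComplexes = "integer",
        fieldSize = "numeric", cellRoi = "numeric",
        pIndicator = "numeric", mModification = "numeric",
        markerRecall = "numeric", blinkFramesMean = "numeric",
        locPrecision = "numeric", nBeads = "integer",
        beadIntensityFactor = "numeric", driftModel = "character",
        driftRate = "numeric", caField = "numeric",
        backgroundDensity = "numeric", cleanMargin = "numeric",
        minSeparation = "numeric",
        nFramesMarker = "integer", nFramesIndicator = "integer",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@pIndicator, object@mModification, object@markerRecall)
    if (any(probs < 0) || any(probs > 1))
        msg <- c(msg, "probabilities must be in [0, 1]")
    if (object@mModification >= 1)
        msg <- c(msg, "m must be < 1")
    if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
        msg <- c(msg, "fieldSize must be two positive lengths")
    if (length(object@cellRoi) != 4L || any(object@cellRoi[3:4] <= 0))
        msg <- c(msg, "cellRoi must be (x, y, width, height) with positive size")
    if (!object@driftModel %in% c("none", "linear", "random-walk"))
        msg <- c(msg, "driftModel must be none, linear or random-walk")
    if (length(object@caField) != 4L || !all(is.finite(object@caField)))
        msg <- c(msg, "caField must be 4 finite numbers")
    if (object@blinkFramesMean < 1)
        msg <- c(msg, "blinkFramesMean must be >= 1")
    if (object@nFramesMarker < 1L || object@nFramesIndicator < 1L)
        msg <- c(msg, "frame counts must be >= 1")
    if (length(msg)) msg else TRUE
})
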