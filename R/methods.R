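## Accessors and show() methods.

#' @rdname LocalizationTable-class
#' @aliases locData channelLabel nFrames pixelSize nLocalizations
#' @exportMethod locData
setMethod("locData", "LocalizationTable", function(object) object@data)

#' @rdname LocalizationTable-class
setMethod("channelLabel", "LocalizationTable",
          function(object) object@channel)

#' @rdname LocalizationTable-class
setMethod("nFrames", "LocalizationTable", function(object) object@nFrames)

#' @rdname LocalizationTable-class
setMethod("pixelSize", "LocalizationTable", function(object) object@pixelSize)

#' @rdname LocalizationTable-class
setMethod("nLocalizations", "LocalizationTable",
          function(object) nrow(object@data))

setMethod("show", "LocalizationTable", function(object) {
    cat("LocalizationTable '", object@channel, "': ",
        nrow(object@data), " localizations over ", object@nFrames,
        " frames (pixel size ", object@pixelSize, " nm)\n", sep = "")
    if (nrow(object@data))
        print(head(object@data, 4L))
    invisible(NULL)
})

#' @rdname ClusterSet-class
#' @aliases clusters clusterLabels noiseCount nClusters
setMethod("clusters", "ClusterSet", function(object) object@clusters)

#' @rdname ClusterSet-class
setMethod("clusterLabels", "ClusterSet", function(object) object@labels)

#' @rdname ClusterSet-class
setMethod("noiseCount", "ClusterSet", function(object) object@noiseCount)

#' @rdname ClusterSet-class
setMethod("nClusters", "ClusterSet", function(object) nrow(object@clusters))

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet '", object@channel, "': ", nrow(object@clusters),
        " clusters, ", object@noiseCount, " noise localizations\n",
        sep = "")
    if (nrow(object@clusters))
        print(head(object@clusters, 4L))
    invisible(NULL)
})

#' @rdname DriftTrace-class
#' @aliases driftTable
setMethod("driftTable", "DriftTrace", function(object) object@drift)

setMethod("show", "DriftTrace", function(object) {
    d <- object@drift
    cat("DriftTrace: ", nrow(d), " frames from ", object@nBeads,
        " bead(s); final displacement (",
        round(d$dx[nrow(d)], 2), ", ", round(d$dy[nrow(d)], 2),
        ") nm\n", sep = "")
    invisible(NULL)
})

setMethod("show", "CAModel", function(object) {
    cat("CAModel (", object@correctedChannel, " -> ",
        object@referenceChannel, "):\n",
        "  dx = ", signif(object@slopeX, 6), " * x + ",
        signif(object@interceptX, 6), " nm\n",
        "  dy = ", signif(object@slopeY, 6), " * y + ",
        signif(object@interceptY, 6), " nm\n", sep = "")
    if (!is.na(object@nPairs))
        cat("  fitted on ", object@nPairs, " bead pairs, residual RMS ",
            signif(object@residualRms, 4), " nm\n", sep = "")
    invisible(NULL)
})

#' @rdname ColocRecord-class
#' @aliases colocRatio
setMethod("colocRatio", "ColocRecord", function(object) object@ratio)

setMethod("show", "ColocRecord", function(object) {
    cat("ColocRecord '", object@recordingId, "': N_M = ", object@nMarker,
        ", N_MF = ", object@nColoc, ", R = ",
        if (is.na(object@ratio)) "NA (no marker clusters)"
        else signif(object@ratio, 4),
        " (cutoff ", object@distanceCutoff, " nm)\n", sep = "")
    invisible(NULL)
})

#' @rdname CalibrationFit-class
#' @aliases recallRate modificationCoef
setMethod("recallRate", "CalibrationFit", function(object) object@p)

#' @rdname CalibrationFit-class
setMethod("modificationCoef", "CalibrationFit", function(object) object@m)

setMethod("show", "CalibrationFit", function(object) {
    cat("CalibrationFit: p = ", signif(object@p, 4), " [",
        signif(object@ciP[1L], 4), ", ", signif(object@ciP[2L], 4),
        "], m = ", signif(object@m, 4), " [", signif(object@ciM[1L], 4),
        ", ", signif(object@ciM[2L], 4), "] (",
        object@nBootstrap, " bootstraps, seed ", object@seed, ")\n",
        sep = "")
    invisible(NULL)
})

#' @rdname COMProfile-class
#' @aliases bestState comValues electFraction
setMethod("bestState", "COMProfile", function(object) object@bestState)

#' @rdname COMProfile-class
setMethod("comValues", "COMProfile",
          function(object) setNames(object@com, object@states))

#' @rdname COMProfile-class
setMethod("electFraction", "COMProfile",
          function(object) setNames(object@electFraction, object@states))

setMethod("show", "COMProfile", function(object) {
    cat("COMProfile: best state n = ", object@bestState, "\n", sep = "")
    d <- data.frame(n = object@states, COM = signif(object@com, 4))
    if (!all(is.na(object@electFraction)))
        d$elected <- signif(object@electFraction, 3)
    print(d, row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: n = ", object@nSubunits, ", ", object@nComplexes,
        " complexes, p = ", object@pIndicator, ", m = ",
        object@mModification, ", frames ", object@nFramesMarker, "/",
        object@nFramesIndicator, " (marker/indicator), ",
        object@nBeads, " beads, drift '", object@driftModel,
        "', seed ", object@seed, "\n", sep = "")
    invisible(NULL)
})
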