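#' @rdname LocalizationTable-class
#' @param object,x a package object.
#' @export
setGeneric("locData", function(object) standardGeneric("locData"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname LocalizationTable-class
#' @export
setGeneric("nLocalizations",
           function(object) standardGeneric("nLocalizations"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterSet-class
#' @export
setGeneric("noiseCount", function(object) standardGeneric("noiseCount"))

#' @rdname ClusterSet-class
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname DriftTrace-class
#' @export
setGeneric("driftTable", function(object) standardGeneric("driftTable"))

#' @rdname CalibrationFit-class
#' @export
setGeneric("recallRate", function(object) standardGeneric("recallRate"))

#' @rdname CalibrationFit-class
#' @export
setGeneric("modificationCoef",
           function(object) standardGeneric("modificationCoef"))

#' @rdname COMProfile-class
#' @export
setGeneric("bestState", function(object) standardGeneric("bestState"))

#' @rdname COMProfile-class
#' @export
setGeneric("comValues", function(object) standardGeneric("comValues"))

#' @rdname COMProfile-class
#' @export
setGeneric("electFraction", function(object) standardGeneric("electFraction"))

#' @rdname ColocRecord-class
#' @export
setGeneric("colocRatio", function(object) standardGeneric("colocRatio"))
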