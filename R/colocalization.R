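#' Per-recording colocalization ratio R = N_MF / N_M
#'
#' Marker clusters are filtered to those whose centroid lies inside one of
#' the regions of interest (half-open containment: x in [x0, x0+w), y in
#' [y0, y0+h); an empty ROI list means the whole field). A marker cluster
#' counts as colocalized iff at least one indicator-cluster centroid lies
#' within \code{distanceCutoff} (Euclidean, inclusive). Matching is
#' one-to-one and greedy by ascending pair distance, so each indicator
#' cluster can satisfy at most one marker — the conservative choice when
#' counting complexes. Indicator clusters are deliberately not
#' ROI-filtered, so a marker near an ROI edge keeps its partner.
#'
#' @param markerClusters,indicatorClusters \linkS4class{ClusterSet}s of the
#'   marker (M) and indicator (F) channels after registration.
#' @param distanceCutoff colocalization cutoff in nm.
#' @param rois \code{NULL}, or a \code{data.frame}/matrix with columns
#'   (x, y, width, height) in nm.
#' @param recordingId identifier stored in the result.
#' @return a \linkS4class{ColocRecord}. When no marker cluster lies in the
#'   ROIs the ratio is \code{NA} and a warning flags the recording for
#'   exclusion downstream.
#' @examples
#' mk <- data.frame(cluster_id = 0:1, x = c(0, 1000), y = 0, n = 5L,
#'                  first_frame = 0L, last_frame = 4L, mean_intensity = 1)
#' fl <- mk; fl$x <- fl$x + 20
#' ms <- new("ClusterSet", clusters = mk, channel = "green",
#'           noiseCount = 0L, labels = integer())
#' fs <- new("ClusterSet", clusters = fl, channel = "red",
#'           noiseCount = 0L, labels = integer())
#' colocRatio(getColocalizationRatio(ms, fs, distanceCutoff = 100))
#' @export
getColocalizationRatio <- function(markerClusters, indicatorClusters,
                                   distanceCutoff = 100, rois = NULL,
                                   recordingId = "") {
    stopifnot(is(markerClusters, "ClusterSet"),
              is(indicatorClusters, "ClusterSet"))
    if (distanceCutoff <= 0) stop("distanceCutoff must be > 0")
    roiFrame <- normalizeRois(rois)
    mk <- clusters(markerClusters)
    fl <- clusters(indicatorClusters)
    if (nrow(roiFrame)) {
        inside <- rep(FALSE, nrow(mk))
        for (r in seq_len(nrow(roiFrame))) {
            inside <- inside |
                (mk$x >= roiFrame$x[r] &
                 mk$x < roiFrame$x[r] + roiFrame$width[r] &
                 mk$y >= roiFrame$y[r] &
                 mk$y < roiFrame$y[r] + roiFrame$height[r])
        }
        mk <- mk[inside, , drop = FALSE]
    }
    nM <- nrow(mk)
    if (nM == 0L) {
        warning("no marker clusters in the regions of interest; ",
                "recording '", recordingId, "' flagged (ratio NA)")
        return(new("ColocRecord", recordingId = as.character(recordingId),
                   nMarker = 0L, nColoc = 0L, ratio = NA_real_,
                   distanceCutoff = as.numeric(distanceCutoff),
                   rois = roiFrame))
    }
    nMF <- 0L
    if (nrow(fl)) {
        nMF <- greedyMatchCount(mk$x, mk$y, fl$x, fl$y, distanceCutoff)
    }
    new("ColocRecord", recordingId = as.character(recordingId),
        nMarker = nM, nColoc = nMF, ratio = nMF / nM,
        distanceCutoff = as.numeric(distanceCutoff), rois = roiFrame)
}

## one-to-one greedy matching by ascending distance; ties broken by
## (marker id, indicator id) order, which is the candidate sort order
greedyMatchCount <- function(mx, my, fx, fy, cutoff) {
    dmat <- sqrt(outer(mx, fx, "-")^2 + outer(my, fy, "-")^2)
    cand <- which(dmat <= cutoff, arr.ind = TRUE)
    if (nrow(cand) == 0L)
        return(0L)
    ord <- order(dmat[cand], cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    usedM <- rep(FALSE, length(mx))
    usedF <- rep(FALSE, length(fx))
    n <- 0L
    for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!usedM[i] && !usedF[j]) {
            usedM[i] <- TRUE
            usedF[j] <- TRUE
            n <- n + 1L
        }
    }
    n
}

normalizeRois <- function(rois) {
    if (is.null(rois) || (is.data.frame(rois) && nrow(rois) == 0L))
        return(data.frame(x = numeric(), y = numeric(),
                          width = numeric(), height = numeric()))
    if (is.numeric(rois) && is.null(dim(rois)))
        rois <- matrix(rois, ncol = 4L, byrow = TRUE)
    rois <- as.data.frame(rois)
    names(rois) <- c("x", "y", "width", "height")[seq_len(ncol(rois))]
    if (!all(c("x", "y", "width", "height") %in% names(rois)))
        stop("rois must provide x, y, width, height")
    if (any(rois$width <= 0) || any(rois$height <= 0))
        stop("ROI rectangles must have positive width and height")
    rois[c("x", "y", "width", "height")]
}

#' Collect ColocRecords into a ratio table
#'
#' @param records list of \linkS4class{ColocRecord}s.
#' @param knownState optional integer oligomeric state recycled across
#'   records (for calibration proteins).
#' @param dropUndefined drop records with N_M = 0 (ratio NA)? Default TRUE,
#'   with a message naming the dropped recordings.
#' @return \code{data.frame} with columns \code{recording_id},
#'   \code{n_marker}, \code{n_coloc}, \code{ratio} and, when given,
#'   \code{known_state}.
#' @export
ratioTable <- function(records, knownState = NULL, dropUndefined = TRUE) {
    stopifnot(all(vapply(records, is, TRUE, "ColocRecord")))
    tab <- data.frame(
        recording_id = vapply(records, slot, "", "recordingId"),
        n_marker = vapply(records, slot, 0L, "nMarker"),
        n_coloc = vapply(records, slot, 0L, "nColoc"),
        ratio = vapply(records, slot, 0, "ratio"))
    if (!is.null(knownState))
        tab$known_state <- as.integer(knownState)
    if (dropUndefined && anyNA(tab$ratio)) {
        bad <- is.na(tab$ratio)
        message("dropping ", sum(bad),
                " recording(s) with no marker clusters: ",
                paste(tab$recording_id[bad], collapse = ", "))
        tab <- tab[!bad, , drop = FALSE]
        rownames(tab) <- NULL
    }
    tab
}
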