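#' Cluster localizations into beads or protein emission clusters
#'
#' Discards localizations below an intensity threshold, then clusters the
#' survivors purely spatially with DBSCAN on (x, y). Frames play no role in
#' the clustering itself; they enter only through the reported frame span
#' (used by \code{\link{splitBeadsAndSignals}} to demand bead persistence).
#'
#' DBSCAN is run deterministically: points are visited in ascending row
#' order and a border point reachable from two clusters goes to the cluster
#' discovered first. Cluster ids are contiguous from 0 in discovery order.
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param intensityThreshold minimum intensity per localization (arbitrary
#'   units); rows below it are discarded before clustering.
#' @param minSamples DBSCAN \code{min_samples}: minimum neighbourhood size
#'   (the point itself included) for a core point. For always-on fiducial
#'   beads this is effectively the minimum number of frames the bead must
#'   be recorded in.
#' @param eps DBSCAN neighbourhood radius in nm.
#' @return a \linkS4class{ClusterSet}; the \code{labels} slot aligns with
#'   the rows of \code{locData(table)} (\code{NA} = intensity-filtered,
#'   \code{-1} = noise).
#' @examples
#' set.seed(1)
#' lt <- LocalizationTable(frame = rep(0:9, 2),
#'                         x = c(rnorm(10, 0, 5), rnorm(10, 5000, 5)),
#'                         y = rnorm(20, 0, 5), intensity = rep(100, 20))
#' cs <- findClusters(lt, intensityThreshold = 0, minSamples = 5, eps = 100)
#' nClusters(cs)
#' @export
findClusters <- function(table, intensityThreshold = 0, minSamples = 5L,
                         eps = 30) {
    stopifnot(is(table, "LocalizationTable"))
    if (eps <= 0) stop("eps must be > 0")
    if (minSamples < 1L) stop("minSamples must be >= 1")
    d <- locData(table)
    keep <- d$intensity >= intensityThreshold
    labels <- rep(NA_integer_, nrow(d))
    kept <- d[keep, , drop = FALSE]
    if (nrow(kept) == 0L) {
        return(new("ClusterSet", clusters = emptyClusterFrame(),
                   channel = channelLabel(table), noiseCount = 0L,
                   labels = labels))
    }
    lab <- .dbscan_cpp(kept$x, kept$y, eps, as.integer(minSamples))
    labels[keep] <- lab
    clusters <- summarizeClusters(kept, lab)
    new("ClusterSet", clusters = clusters,
        channel = channelLabel(table),
        noiseCount = sum(lab == -1L), labels = labels)
}

emptyClusterFrame <- function() {
    data.frame(cluster_id = integer(), x = numeric(), y = numeric(),
               n = integer(), first_frame = integer(),
               last_frame = integer(), mean_intensity = numeric())
}

summarizeClusters <- function(kept, lab) {
    inCl <- lab >= 0L
    if (!any(inCl))
        return(emptyClusterFrame())
    dt <- data.table(frame = kept$frame[inCl], x = kept$x[inCl],
                     y = kept$y[inCl], intensity = kept$intensity[inCl],
                     id = lab[inCl])
    s <- dt[, list(x = mean(x), y = mean(y), n = .N,
                   first_frame = min(frame), last_frame = max(frame),
                   mean_intensity = mean(intensity)), by = "id"]
    setorderv(s, "id")
    data.frame(cluster_id = s$id, x = s$x, y = s$y, n = as.integer(s$n),
               first_frame = as.integer(s$first_frame),
               last_frame = as.integer(s$last_frame),
               mean_intensity = s$mean_intensity)
}

#' Partition clusters into fiducial beads and protein signals
#'
#' Fiducial beads are much brighter than fluorescent proteins and emit in
#' (almost) every frame; a cluster is classified as a bead iff its mean
#' intensity reaches \code{beadIntensityThreshold} and its frame span
#' \code{last_frame - first_frame + 1} reaches \code{beadMinFrames}. The
#' partition is exhaustive and disjoint.
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param beadIntensityThreshold minimum mean intensity of a bead cluster.
#' @param beadMinFrames minimum frame span of a bead cluster.
#' @return list with elements \code{beads} and \code{signals}, each a
#'   \linkS4class{ClusterSet} relabelled contiguously from 0; in each part's
#'   \code{labels} slot, localizations of the other part are \code{NA}.
#' @export
splitBeadsAndSignals <- function(clusterSet, beadIntensityThreshold,
                                 beadMinFrames) {
    stopifnot(is(clusterSet, "ClusterSet"))
    if (beadIntensityThreshold <= 0 || beadMinFrames <= 0)
        stop("bead thresholds must be positive")
    cl <- clusters(clusterSet)
    isBead <- cl$mean_intensity >= beadIntensityThreshold &
        (cl$last_frame - cl$first_frame + 1L) >= beadMinFrames
    list(beads = subsetClusterSet(clusterSet, isBead),
         signals = subsetClusterSet(clusterSet, !isBead))
}

## keep rows of `take`, relabel 0..K-1 preserving order, remap labels
subsetClusterSet <- function(clusterSet, take) {
    cl <- clusters(clusterSet)
    sub <- cl[take, , drop = FALSE]
    old <- sub$cluster_id
    sub$cluster_id <- seq_len(nrow(sub)) - 1L
    rownames(sub) <- NULL
    map <- rep(NA_integer_, nrow(cl))
    map[old + 1L] <- sub$cluster_id
    lab <- clusterLabels(clusterSet)
    newlab <- lab
    pos <- !is.na(lab) & lab >= 0L
    newlab[pos] <- map[lab[pos] + 1L]
    newlab[!is.na(lab) & lab == -1L] <- -1L
    new("ClusterSet", clusters = sub, channel = clusterSet@channel,
        noiseCount = clusterSet@noiseCount, labels = newlab)
}

#' Extract the localizations belonging to a set of clusters
#'
#' @param table the \linkS4class{LocalizationTable} that was clustered.
#' @param clusterSet the matching \linkS4class{ClusterSet} (labels aligned
#'   with \code{table}).
#' @return list with \code{table} (a subset \linkS4class{LocalizationTable})
#'   and \code{labels} (cluster id per retained row).
#' @export
clusterMembers <- function(table, clusterSet) {
    lab <- clusterLabels(clusterSet)
    if (length(lab) != nLocalizations(table))
        stop("labels do not align with the localization table")
    keep <- !is.na(lab) & lab >= 0L
    d <- locData(table)[keep, , drop = FALSE]
    sub <- LocalizationTable(d$frame, d$x, d$y, d$intensity,
                             channel = channelLabel(table),
                             pixelSize = pixelSize(table),
                             nFrames = nFrames(table))
    ## LocalizationTable() keeps frame order; rows within a frame keep
    ## input order, so labels stay aligned after the stable sort
    ord <- order(d$frame)
    list(table = sub, labels = lab[keep][ord])
}
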