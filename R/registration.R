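#' Extract sample drift from fiducial bead trajectories
#'
#' For each labelled bead the per-frame position (mean of its localizations
#' in that frame) is computed; frames where a bead is missing are filled by
#' linear interpolation of its observed positions, with constant
#' extrapolation at the sequence ends. Frame-to-frame displacements are
#' averaged across beads and cumulatively summed, anchored to (0, 0) at
#' frame 0. Each bead's displacement series telescopes to (position -
#' position at frame 0), so noise does not accumulate over frames.
#'
#' @param beadTable a \linkS4class{LocalizationTable} containing the bead
#'   localizations.
#' @param beadLabels integer bead id per row of \code{locData(beadTable)}
#'   (ids < 0 or \code{NA} are ignored), e.g. from
#'   \code{\link{clusterMembers}}.
#' @return a \linkS4class{DriftTrace} covering frames
#'   \code{0..nFrames(beadTable)-1}.
#' @export
extractDrift <- function(beadTable, beadLabels) {
    stopifnot(is(beadTable, "LocalizationTable"))
    d <- locData(beadTable)
    if (length(beadLabels) != nrow(d))
        stop("beadLabels must align with the bead localization table")
    use <- !is.na(beadLabels) & beadLabels >= 0L
    d <- d[use, , drop = FALSE]
    ids <- beadLabels[use]
    if (nrow(d) == 0L)
        stop("no labelled beads: drift correction is impossible ",
             "(record fiducial beads around the cell)")
    nf <- nFrames(beadTable)
    frames <- seq_len(nf) - 1L

    dt <- data.table(id = ids, frame = d$frame, x = d$x, y = d$y)
    perFrame <- dt[, list(x = mean(x), y = mean(y)), by = c("id", "frame")]
    beadIds <- sort(unique(perFrame$id))

    dxs <- matrix(0, nrow = nf, ncol = length(beadIds))
    dys <- matrix(0, nrow = nf, ncol = length(beadIds))
    for (j in seq_along(beadIds)) {
        b <- perFrame[perFrame$id == beadIds[j], ]
        if (nrow(b) < 2L)
            stop("bead ", beadIds[j], " seen in fewer than 2 frames")
        ## rule = 2: constant extrapolation before first / after last sight
        px <- approx(b$frame, b$x, xout = frames, rule = 2)$y
        py <- approx(b$frame, b$y, xout = frames, rule = 2)$y
        dxs[, j] <- px - px[1L]
        dys[, j] <- py - py[1L]
    }
    trace <- data.frame(frame = frames,
                        dx = rowMeans(dxs), dy = rowMeans(dys))
    new("DriftTrace", drift = trace, nBeads = length(beadIds))
}

#' Apply (subtract) a drift trace to a localization table
#'
#' @param table a \linkS4class{LocalizationTable}.
#' @param drift a \linkS4class{DriftTrace} covering all frames in
#'   \code{table}.
#' @return the corrected \linkS4class{LocalizationTable}.
#' @export
applyDrift <- function(table, drift) {
    stopifnot(is(table, "LocalizationTable"), is(drift, "DriftTrace"))
    d <- locData(table)
    tr <- driftTable(drift)
    if (nrow(d) && max(d$frame) >= nrow(tr))
        stop("drift trace does not cover all frames of the table")
    idx <- d$frame + 1L
    LocalizationTable(d$frame, d$x - tr$dx[idx], d$y - tr$dy[idx],
                      d$intensity, channel = channelLabel(table),
                      pixelSize = pixelSize(table),
                      nFrames = nFrames(table))
}

#' Pair fiducial beads across the two color channels
#'
#' Returns mutually-nearest pairs of bead centroids with distance at most
#' \code{distanceCutoff}; each bead appears in at most one pair. Ties are
#' broken toward the smallest bead id.
#'
#' @param beadsA,beadsB \linkS4class{ClusterSet}s of beads in the reference
#'   and corrected channels.
#' @param distanceCutoff maximum pairing distance in nm.
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{xa}, \code{ya}, \code{xb}, \code{yb}, \code{dx = xb - xa},
#'   \code{dy = yb - ya} and \code{dist}; zero rows when nothing pairs.
#' @export
pairBeads <- function(beadsA, beadsB, distanceCutoff) {
    stopifnot(is(beadsA, "ClusterSet"), is(beadsB, "ClusterSet"))
    if (distanceCutoff <= 0) stop("distanceCutoff must be > 0")
    a <- clusters(beadsA); b <- clusters(beadsB)
    empty <- data.frame(id_a = integer(), id_b = integer(),
                        xa = numeric(), ya = numeric(), xb = numeric(),
                        yb = numeric(), dx = numeric(), dy = numeric(),
                        dist = numeric())
    if (nrow(a) == 0L || nrow(b) == 0L)
        return(empty)
    dmat <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    ## mutual nearest neighbours (ties toward smallest id via which.min)
    nnA <- apply(dmat, 1L, which.min)
    nnB <- apply(dmat, 2L, which.min)
    i <- seq_len(nrow(a))
    mutual <- nnB[nnA[i]] == i & dmat[cbind(i, nnA[i])] <= distanceCutoff
    if (!any(mutual))
        return(empty)
    ai <- i[mutual]; bi <- nnA[i][mutual]
    data.frame(id_a = a$cluster_id[ai], id_b = b$cluster_id[bi],
               xa = a$x[ai], ya = a$y[ai], xb = b$x[bi], yb = b$y[bi],
               dx = b$x[bi] - a$x[ai], dy = b$y[bi] - a$y[ai],
               dist = dmat[cbind(ai, bi)])
}

#' Fit the linear lateral chromatic-aberration model
#'
#' Ordinary least squares of the pair deviation \code{dx} against the
#' corrected channel's x-coordinate and, independently, \code{dy} against
#' its y-coordinate. Regressing on the corrected channel's observed
#' coordinate makes \code{\link{applyChromaticAberration}} an exact inverse
#' of a noiseless linear field.
#'
#' @param pairs bead pairs from \code{\link{pairBeads}} (needs >= 2 pairs
#'   with distinct \code{xb} and distinct \code{yb}).
#' @param referenceChannel,correctedChannel channel labels stored in the
#'   model.
#' @return a \linkS4class{CAModel}.
#' @export
fitChromaticAberration <- function(pairs, referenceChannel = "green",
                                   correctedChannel = "red") {
    if (nrow(pairs) < 2L)
        stop("need at least 2 bead pairs to fit chromatic aberration")
    if (length(unique(pairs$xb)) < 2L || length(unique(pairs$yb)) < 2L)
        stop("bead pairs are rank deficient (need distinct x and y)")
    fx <- lm(dx ~ xb, data = pairs)
    fy <- lm(dy ~ yb, data = pairs)
    res2 <- fx$residuals^2 + fy$residuals^2
    CAModel(slopeX = coef(fx)[[2L]], interceptX = coef(fx)[[1L]],
            slopeY = coef(fy)[[2L]], interceptY = coef(fy)[[1L]],
            residualRms = sqrt(mean(res2)), nPairs = nrow(pairs),
            referenceChannel = referenceChannel,
            correctedChannel = correctedChannel)
}

#' Apply a chromatic-aberration correction to a localization table
#'
#' Subtracts the model-predicted deviation evaluated at the observed
#' coordinate: \code{x <- x - (slopeX * x + interceptX)}, likewise for y.
#'
#' @param table a \linkS4class{LocalizationTable} of the corrected channel.
#' @param model a \linkS4class{CAModel}.
#' @return the corrected \linkS4class{LocalizationTable}.
#' @export
applyChromaticAberration <- function(table, model) {
    stopifnot(is(table, "LocalizationTable"), is(model, "CAModel"))
    d <- locData(table)
    LocalizationTable(d$frame,
                      d$x - (model@slopeX * d$x + model@interceptX),
                      d$y - (model@slopeY * d$y + model@interceptY),
                      d$intensity, channel = channelLabel(table),
                      pixelSize = pixelSize(table),
                      nFrames = nFrames(table))
}

#' Quality-control filter on axial focus offset
#'
#' A recording whose axial focus check (bead intensity refocus at the end
#' of acquisition) reports an offset larger than \code{maxZOffset} is
#' considered invalid due to z drift and is excluded; exclusions are
#' reported via \code{message()} (and a log file when \code{logFile} is
#' given).
#'
#' @param recordings \code{data.frame} with columns \code{recording_id} and
#'   \code{z_offset_nm}.
#' @param maxZOffset maximum tolerated axial offset in nm.
#' @param logFile optional path appended with one line per exclusion.
#' @return list with \code{keep} and \code{dropped} data.frames.
#' @export
qcFilterRecordings <- function(recordings, maxZOffset = 100,
                               logFile = NULL) {
    stopifnot(all(c("recording_id", "z_offset_nm") %in% names(recordings)))
    bad <- !is.na(recordings$z_offset_nm) &
        abs(recordings$z_offset_nm) > maxZOffset
    for (id in recordings$recording_id[bad]) {
        line <- sprintf(
            "recording '%s' excluded: z offset %.1f nm exceeds %.0f nm",
            id, recordings$z_offset_nm[recordings$recording_id == id],
            maxZOffset)
        message(line)
        if (!is.null(logFile))
            cat(line, "\n", file = logFile, append = TRUE, sep = "")
    }
    list(keep = recordings[!bad, , drop = FALSE],
         dropped = recordings[bad, , drop = FALSE])
}
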