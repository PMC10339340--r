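#' Construct a SimConfig
#'
#' See \linkS4class{SimConfig} for the meaning of every field. Defaults
#' emulate a typical DCC-SMLM acquisition on a two-camera TIRF setup:
#' a 41 x 41 um field (512 x 512 pixels at 80 nm), 4,000
#' marker frames, 9,000 indicator frames, 4 beads around the cell, a
#' linear chromatic-aberration field on the indicator channel, slow
#' random-walk drift and a prebleached (clean) background.
#'
#' @param nSubunits,nComplexes,fieldSize,cellRoi,pIndicator,mModification
#'   see \linkS4class{SimConfig}.
#' @param markerRecall,blinkFramesMean,locPrecision,nBeads see
#'   \linkS4class{SimConfig}.
#' @param beadIntensityFactor,driftModel,driftRate,caField see
#'   \linkS4class{SimConfig}.
#' @param backgroundDensity,cleanMargin,minSeparation see
#'   \linkS4class{SimConfig}.
#' @param nFramesMarker,nFramesIndicator,seed see \linkS4class{SimConfig}.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nSubunits = 2L, nComplexes = 300L,
                      fieldSize = c(41000, 41000),
                      cellRoi = c(8000, 8000, 25000, 25000),
                      pIndicator = 0.5, mModification = 0.1,
                      markerRecall = 1.0, blinkFramesMean = 3,
                      locPrecision = 15, nBeads = 4L,
                      beadIntensityFactor = 10,
                      driftModel = "random-walk", driftRate = 0.5,
                      caField = c(0.002, 5, -0.001, 2),
                      backgroundDensity = 2e-5, cleanMargin = 1000,
                      minSeparation = 400,
                      nFramesMarker = 4000L, nFramesIndicator = 9000L,
                      seed = 1L) {
    new("SimConfig", nSubunits = as.integer(nSubunits),
        nComplexes = as.integer(nComplexes),
        fieldSize = as.numeric(fieldSize), cellRoi = as.numeric(cellRoi),
        pIndicator = pIndicator, mModification = mModification,
        markerRecall = markerRecall, blinkFramesMean = blinkFramesMean,
        locPrecision = locPrecision, nBeads = as.integer(nBeads),
        beadIntensityFactor = beadIntensityFactor,
        driftModel = driftModel, driftRate = as.numeric(driftRate),
        caField = as.numeric(caField),
        backgroundDensity = backgroundDensity,
        cleanMargin = cleanMargin, minSeparation = minSeparation,
        nFramesMarker = as.integer(nFramesMarker),
        nFramesIndicator = as.integer(nFramesIndicator),
        seed = as.integer(seed))
}

## baseline single-fluorophore localization intensity (arbitrary units)
.SIGNAL_INTENSITY <- 1000

#' Draw per-complex subunit intactness and detection outcomes
#'
#' The generative counterpart of the DCC detection model: each of the n
#' subunits is intact with probability 1 - m (a modified subunit
#' contributes neither fluorophore); a complex with >= 1 intact subunit is
#' marker-visible with probability \code{markerRecall}; each intact
#' subunit's indicator fires independently with probability p.
#'
#' Uses the current RNG state (wrap in your own \code{set.seed} for
#' reproducibility); \code{\link{simulateRecording}} seeds internally.
#'
#' @param nComplexes number of complexes to draw.
#' @param n oligomeric state.
#' @param p indicator recall rate.
#' @param m coefficient of modification.
#' @param markerRecall marker detection probability given >= 1 intact
#'   subunit.
#' @return \code{data.frame} with columns \code{k} (intact subunits),
#'   \code{marker_visible}, \code{n_fired} (fired indicators) and
#'   \code{indicator_detected} (= n_fired >= 1).
#' @export
simulateComplexDetections <- function(nComplexes, n, p, m = 0,
                                      markerRecall = 1.0) {
    k <- rbinom(nComplexes, n, 1 - m)
    markerVisible <- k >= 1L & runif(nComplexes) < markerRecall
    fired <- rbinom(nComplexes, k, p)
    data.frame(k = k, marker_visible = markerVisible, n_fired = fired,
               indicator_detected = fired >= 1L)
}

#' Simulate a ratio table of recordings at the detection level
#'
#' Draws per-recording colocalization counts directly from the DCC
#' detection law (no imaging): N_M is the number of marker-visible
#' complexes, N_MF the number of those with >= 1 fired indicator. This is
#' the exact sampling distribution of a ratio table under perfect
#' registration and clustering, and is used for fast calibration studies.
#'
#' @param states integer vector of oligomeric states (one entry per
#'   reference protein).
#' @param recordingsPerState recordings simulated per state.
#' @param complexesPerRecording complexes per recording.
#' @param p,m,markerRecall detection-model parameters.
#' @param seed RNG seed.
#' @return ratio \code{data.frame} with columns \code{recording_id},
#'   \code{n_marker}, \code{n_coloc}, \code{ratio}, \code{known_state}.
#' @export
simulateRatioTable <- function(states, recordingsPerState = 12L,
                               complexesPerRecording = 300L,
                               p = 0.5, m = 0.1, markerRecall = 1.0,
                               seed = 1L) {
    withSeed(seed, {
        rows <- lapply(states, function(s) {
            do.call(rbind, lapply(seq_len(recordingsPerState),
                                  function(r) {
                det <- simulateComplexDetections(complexesPerRecording, s,
                                                 p, m, markerRecall)
                nM <- sum(det$marker_visible)
                nMF <- sum(det$marker_visible & det$indicator_detected)
                data.frame(
                    recording_id = sprintf("n%d_rec%02d", s, r),
                    n_marker = nM, n_coloc = nMF,
                    ratio = if (nM > 0) nMF / nM else NA_real_,
                    known_state = s)
            }))
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}

#' Simulate one dual-color SMLM recording
#'
#' Generates the marker (green) and indicator (red) localization tables of
#' one recording together with full ground truth:
#' \itemize{
#'   \item complexes placed in the cell ROI with blue-noise separation
#'     \code{minSeparation} (a jittered-grid placement; set 0 for the
#'     crowded stress mode with uniform placement);
#'   \item per-subunit intactness (prob. 1 - m), marker visibility and
#'     indicator firing (prob. p per intact subunit) as in
#'     \code{\link{simulateComplexDetections}};
#'   \item every detected fluorophore emits one burst spanning a geometric
#'     number of consecutive frames (mean \code{blinkFramesMean}), each
#'     frame contributing one localization with isotropic Gaussian noise;
#'   \item always-on fiducial beads outside the cell, visible in both
#'     channels in every frame at \code{beadIntensityFactor} times the
#'     signal intensity (and correspondingly better localization
#'     precision);
#'   \item per-channel cumulative drift (the two channels are recorded
#'     sequentially, so their drift realizations are independent);
#'   \item the linear chromatic-aberration field applied to the indicator
#'     channel at the emitter's physical (drifted) position;
#'   \item background impurities as a spatial Poisson process outside a
#'     clean margin around the cell.
#' }
#'
#' @param config a \linkS4class{SimConfig}; its \code{seed} makes the
#'   output bit-identical across calls.
#' @return list with \code{marker} and \code{indicator}
#'   (\linkS4class{LocalizationTable}s) and \code{truth} (list with
#'   \code{complexes}, \code{beads}, \code{driftMarker},
#'   \code{driftIndicator}, \code{caField}).
#' @export
simulateRecording <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    withSeed(config@seed, {
        roi <- config@cellRoi
        pos <- placeComplexes(config)
        det <- simulateComplexDetections(config@nComplexes,
                                         config@nSubunits,
                                         config@pIndicator,
                                         config@mModification,
                                         config@markerRecall)
        beads <- placeBeads(config)
        driftM <- makeDrift(config, config@nFramesMarker)
        driftI <- makeDrift(config, config@nFramesIndicator)
        sigma <- config@locPrecision
        sigmaBead <- sigma / sqrt(config@beadIntensityFactor)

        ## ---- marker channel ----
        vis <- det$marker_visible
        mLocs <- burstLocalizations(pos$x[vis], pos$y[vis],
                                    config@nFramesMarker,
                                    config@blinkFramesMean, sigma)
        mBead <- beadLocalizations(beads, config@nFramesMarker, sigmaBead,
                                   config@beadIntensityFactor)
        mBg <- backgroundLocalizations(config, config@nFramesMarker)
        marker <- assembleChannel(rbind(mLocs, mBead, mBg), driftM,
                                  caField = NULL, "green", config,
                                  config@nFramesMarker)

        ## ---- indicator channel ----
        nFired <- det$n_fired
        idx <- rep(seq_len(config@nComplexes), nFired)
        iLocs <- burstLocalizations(pos$x[idx], pos$y[idx],
                                    config@nFramesIndicator,
                                    config@blinkFramesMean, sigma)
        iBead <- beadLocalizations(beads, config@nFramesIndicator,
                                   sigmaBead, config@beadIntensityFactor)
        iBg <- backgroundLocalizations(config, config@nFramesIndicator)
        indicator <- assembleChannel(rbind(iLocs, iBead, iBg), driftI,
                                     caField = config@caField, "red",
                                     config, config@nFramesIndicator)

        list(marker = marker, indicator = indicator,
             truth = list(
                 complexes = data.frame(id = seq_len(config@nComplexes) - 1L,
                                        x = pos$x, y = pos$y,
                                        k = det$k,
                                        marker_visible = det$marker_visible,
                                        n_fired = det$n_fired,
                                        indicator_detected =
                                            det$indicator_detected),
                 beads = beads,
                 driftMarker = driftM, driftIndicator = driftI,
                 caField = config@caField))
    })
}

## blue-noise placement: complexes on a shuffled jittered grid so that any
## two are >= minSeparation apart; uniform when minSeparation == 0
placeComplexes <- function(config) {
    roi <- config@cellRoi
    n <- config@nComplexes
    sep <- config@minSeparation
    if (sep <= 0) {
        return(data.frame(x = roi[1L] + runif(n) * roi[3L],
                          y = roi[2L] + runif(n) * roi[4L]))
    }
    jitter <- sep / 4
    pitch <- 2 * sep - 2 * jitter  # grid pitch minus jitter >= sep
    nx <- floor(roi[3L] / pitch); ny <- floor(roi[4L] / pitch)
    if (nx * ny < n)
        stop("cell ROI too small for ", n, " complexes at separation ",
             sep, " nm; enlarge the ROI or set minSeparation = 0")
    sites <- sample.int(nx * ny, n)
    gx <- (sites - 1L) %% nx
    gy <- (sites - 1L) %/% nx
    data.frame(
        x = roi[1L] + (gx + 0.5) * pitch + runif(n, -jitter, jitter),
        y = roi[2L] + (gy + 0.5) * pitch + runif(n, -jitter, jitter))
}

## beads sit outside the cell ROI, pairwise >= 2 um apart
placeBeads <- function(config) {
    fs <- config@fieldSize; roi <- config@cellRoi
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < config@nBeads && tries < 10000L) {
        tries <- tries + 1L
        x <- runif(1L) * fs[1L]; y <- runif(1L) * fs[2L]
        inCell <- x >= roi[1L] && x < roi[1L] + roi[3L] &&
            y >= roi[2L] && y < roi[2L] + roi[4L]
        if (inCell) next
        if (length(xs) && min((xs - x)^2 + (ys - y)^2) < 2000^2) next
        xs <- c(xs, x); ys <- c(ys, y)
    }
    if (length(xs) < config@nBeads)
        stop("could not place ", config@nBeads, " beads outside the cell")
    data.frame(id = seq_along(xs) - 1L, x = xs, y = ys)
}

## one burst per emitter: geometric length (mean blinkFramesMean), uniform
## start, clipped at the last frame; one localization per covered frame
burstLocalizations <- function(cx, cy, nFrames, blinkMean, sigma) {
    nb <- length(cx)
    if (nb == 0L)
        return(data.frame(frame = integer(), x = numeric(),
                          y = numeric(), intensity = numeric()))
    start <- sample.int(nFrames, nb, replace = TRUE) - 1L
    len <- rgeom(nb, 1 / blinkMean) + 1L
    len <- pmin(len, nFrames - start)
    idx <- rep(seq_len(nb), len)
    frame <- rep(start, len) + sequence(len) - 1L
    nl <- length(frame)
    data.frame(frame = frame,
               x = cx[idx] + rnorm(nl, 0, sigma),
               y = cy[idx] + rnorm(nl, 0, sigma),
               intensity = rlnorm(nl, log(.SIGNAL_INTENSITY), 0.3))
}

beadLocalizations <- function(beads, nFrames, sigmaBead, factor) {
    nb <- nrow(beads)
    if (nb == 0L)
        return(data.frame(frame = integer(), x = numeric(),
                          y = numeric(), intensity = numeric()))
    idx <- rep(seq_len(nb), each = nFrames)
    nl <- length(idx)
    data.frame(frame = rep(seq_len(nFrames) - 1L, nb),
               x = beads$x[idx] + rnorm(nl, 0, sigmaBead),
               y = beads$y[idx] + rnorm(nl, 0, sigmaBead),
               intensity = rlnorm(nl, log(factor * .SIGNAL_INTENSITY), 0.1))
}

## spatial Poisson impurities, kept outside cellRoi + cleanMargin
backgroundLocalizations <- function(config, nFrames) {
    fs <- config@fieldSize
    areaUm2 <- prod(fs) / 1e6
    lambda <- config@backgroundDensity * areaUm2 * nFrames
    nTot <- rpois(1L, lambda)
    if (nTot == 0L)
        return(data.frame(frame = integer(), x = numeric(),
                          y = numeric(), intensity = numeric()))
    x <- runif(nTot) * fs[1L]
    y <- runif(nTot) * fs[2L]
    if (config@cleanMargin > 0) {
        roi <- config@cellRoi
        m <- config@cleanMargin
        inClean <- x >= roi[1L] - m & x < roi[1L] + roi[3L] + m &
            y >= roi[2L] - m & y < roi[2L] + roi[4L] + m
        x <- x[!inClean]; y <- y[!inClean]
    }
    nl <- length(x)
    data.frame(frame = sample.int(nFrames, nl, replace = TRUE) - 1L,
               x = x, y = y,
               intensity = rlnorm(nl, log(.SIGNAL_INTENSITY), 0.3))
}

## drift + (indicator only) CA at the physical position, then package up
assembleChannel <- function(locs, drift, caField, channel, config,
                            nFrames) {
    x <- locs$x + drift$dx[locs$frame + 1L]
    y <- locs$y + drift$dy[locs$frame + 1L]
    if (!is.null(caField)) {
        x <- x + caField[1L] * x + caField[2L]
        y <- y + caField[3L] * y + caField[4L]
    }
    LocalizationTable(locs$frame, x, y, locs$intensity, channel = channel,
                      pixelSize = config@fieldSize[1L] / 512,
                      nFrames = nFrames)
}

makeDrift <- function(config, nFrames) {
    f <- seq_len(nFrames) - 1L
    switch(config@driftModel,
        "none" = data.frame(frame = f, dx = rep(0, nFrames),
                            dy = rep(0, nFrames)),
        "linear" = {
            r <- rep_len(config@driftRate, 2L)
            data.frame(frame = f, dx = r[1L] * f, dy = r[2L] * f)
        },
        "random-walk" = {
            s <- config@driftRate[1L]
            data.frame(frame = f,
                       dx = c(0, cumsum(rnorm(nFrames - 1L, 0, s))),
                       dy = c(0, cumsum(rnorm(nFrames - 1L, 0, s))))
        })
}

#' Simulate a two-color fiducial bead field for CA determination
#'
#' Bead positions are uniform over the field; the green channel records
#' each position for \code{nFramesPerPosition} frames at the true
#' coordinate, the red channel displaced by the linear chromatic-aberration
#' field (evaluated at the true coordinate) plus a per-position pairing
#' noise that models stage and registration jitter between the stacked
#' recordings. Both channels add per-localization bead noise.
#'
#' @param nPositions bead positions (>= 2; aim for ~500 pooled positions
#'   across stacked recordings for a stable fit).
#' @param caField c(slopeX, interceptX, slopeY, interceptY).
#' @param pairingNoise per-position deviation noise sigma in nm.
#' @param seed RNG seed.
#' @param fieldSize field of view c(width, height) in nm.
#' @param nFramesPerPosition frames recorded per channel.
#' @param beadPrecision per-localization bead noise sigma in nm.
#' @return list with \code{green}, \code{red}
#'   (\linkS4class{LocalizationTable}s) and \code{truth} (positions and
#'   applied deviations).
#' @export
simulateBeadField <- function(nPositions = 500L,
                              caField = c(0.002, 5, -0.001, 2),
                              pairingNoise = 5, seed = 1L,
                              fieldSize = c(41000, 41000),
                              nFramesPerPosition = 50L,
                              beadPrecision = 2) {
    if (nPositions < 2L) stop("need at least 2 bead positions")
    withSeed(seed, {
        px <- runif(nPositions) * fieldSize[1L]
        py <- runif(nPositions) * fieldSize[2L]
        devX <- caField[1L] * px + caField[2L] + rnorm(nPositions, 0,
                                                       pairingNoise)
        devY <- caField[3L] * py + caField[4L] + rnorm(nPositions, 0,
                                                       pairingNoise)
        nf <- as.integer(nFramesPerPosition)
        idx <- rep(seq_len(nPositions), each = nf)
        frame <- rep(seq_len(nf) - 1L, nPositions)
        nl <- length(idx)
        intens <- rlnorm(nl, log(10 * .SIGNAL_INTENSITY), 0.1)
        green <- LocalizationTable(frame,
                                   px[idx] + rnorm(nl, 0, beadPrecision),
                                   py[idx] + rnorm(nl, 0, beadPrecision),
                                   intens, channel = "green",
                                   pixelSize = fieldSize[1L] / 512,
                                   nFrames = nf)
        red <- LocalizationTable(frame,
                                 px[idx] + devX[idx] +
                                     rnorm(nl, 0, beadPrecision),
                                 py[idx] + devY[idx] +
                                     rnorm(nl, 0, beadPrecision),
                                 intens, channel = "red",
                                 pixelSize = fieldSize[1L] / 512,
                                 nFrames = nf)
        list(green = green, red = red,
             truth = data.frame(x = px, y = py, devX = devX, devY = devY))
    })
}
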