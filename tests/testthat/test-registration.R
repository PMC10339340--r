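driftTableOf <- function(trace) driftTable(trace)

test_that("noiseless linear drift is recovered exactly", {
    f <- 0:99
    lt <- LocalizationTable(f, 100 + f, rep(50, 100), rep(1e4, 100),
                            nFrames = 100L)
    trace <- extractDrift(lt, rep(0L, 100))
    d <- driftTableOf(trace)
    expect_equal(d$dx, as.numeric(f), tolerance = 1e-9)
    expect_equal(d$dy, rep(0, 100), tolerance = 1e-9)
})

test_that("linear interpolation bridges missing frames exactly", {
    f <- 0:99
    keep <- !(f %in% 40:60)
    frames <- c(f, f[keep])
    x <- c(100 + f, 500 + f[keep])
    y <- c(rep(50, 100), rep(300, sum(keep)))
    labels <- c(rep(0L, 100), rep(1L, sum(keep)))
    ord <- order(frames)
    lt <- LocalizationTable(frames[ord], x[ord], y[ord],
                            rep(1e4, length(frames)), nFrames = 100L)
    trace <- extractDrift(lt, labels[ord])
    expect_identical(trace@nBeads, 2L)
    expect_equal(driftTableOf(trace)$dx, as.numeric(f), tolerance = 1e-9)
})

test_that("drift from noisy beads is recovered within the averaging bound", {
    set.seed(21)
    nf <- 200L
    truth <- cbind(cumsum(c(0, rnorm(nf - 1L, 0, 2))),
                   cumsum(c(0, rnorm(nf - 1L, 0, 2))))
    nb <- 5L
    bx <- runif(nb, 0, 1e4); by <- runif(nb, 0, 1e4)
    frames <- rep(0:(nf - 1L), nb)
    idx <- rep(seq_len(nb), each = nf)
    lt <- LocalizationTable(frames,
                            bx[idx] + truth[frames + 1L, 1L] +
                                rnorm(nf * nb, 0, 5),
                            by[idx] + truth[frames + 1L, 2L] +
                                rnorm(nf * nb, 0, 5),
                            rep(1e4, nf * nb), nFrames = nf)
    ## LocalizationTable sorts by frame; labels must be sorted alike
    lab <- (idx - 1L)[order(frames)]
    trace <- extractDrift(lt, lab)
    d <- driftTableOf(trace)
    rms <- sqrt(mean((d$dx - truth[, 1L])^2 + (d$dy - truth[, 2L])^2) / 2)
    expect_lt(rms, 3 * 5 / sqrt(5))
})

test_that("applying a zero trace is the identity; apply then re-extract is ~0", {
    f <- 0:49
    lt <- LocalizationTable(f, 10 + 2 * f, 5 - f, rep(1e4, 50),
                            nFrames = 50L)
    zero <- new("DriftTrace",
                drift = data.frame(frame = f, dx = 0, dy = 0),
                nBeads = 1L)
    expect_identical(locData(applyDrift(lt, zero)), locData(lt))
    trace <- extractDrift(lt, rep(0L, 50))
    corrected <- applyDrift(lt, trace)
    res <- driftTableOf(extractDrift(corrected, rep(0L, 50)))
    expect_lt(max(abs(c(res$dx, res$dy))), 1e-6)
})

test_that("drift extraction without beads is an explicit error", {
    lt <- LocalizationTable(0:1, c(0, 1), c(0, 1), c(1, 1))
    expect_error(extractDrift(lt, c(-1L, NA)), "impossible")
    expect_error(applyDrift(lt, new("DriftTrace",
                                    drift = data.frame(frame = 0L, dx = 0,
                                                       dy = 0),
                                    nBeads = 1L)),
                 "cover")
})

test_that("beads at identical coordinates pair with zero deviation", {
    a <- makeClusterSet(c(0, 1000, 5000), c(0, 200, 100))
    pairs <- pairBeads(a, a, distanceCutoff = 500)
    expect_identical(nrow(pairs), 3L)
    expect_equal(pairs$dist, rep(0, 3))
    expect_identical(nrow(pairBeads(a, makeClusterSet(numeric(),
                                                      numeric()), 500)),
                     0L)
})

test_that("pairing is mutual-nearest and one-to-one", {
    ## two A beads near one B bead: only the closer A pairs
    a <- makeClusterSet(c(0, 60), c(0, 0))
    b <- makeClusterSet(10, 0)
    pairs <- pairBeads(a, b, 500)
    expect_identical(pairs$id_a, 0L)
    expect_identical(nrow(pairs), 1L)
})

test_that("a known linear CA field is recovered through pairing and OLS", {
    sim <- simulateBeadField(nPositions = 100L,
                             caField = c(0.002, 5, -0.001, 2),
                             pairingNoise = 0, seed = 5L,
                             beadPrecision = 0)
    cg <- findClusters(sim$green, 0, 10L, 100)
    cr <- findClusters(sim$red, 0, 10L, 100)
    pairs <- pairBeads(cg, cr, 500)
    expect_identical(nrow(pairs), 100L)
    fit <- fitChromaticAberration(pairs)
    ## the field is applied at the true coordinate; regressing on the
    ## observed (corrected-channel) coordinate reparametrizes it as
    ## s' = s / (1 + s), i' = i / (1 + s)
    expect_equal(fit@slopeX, 0.002 / 1.002, tolerance = 1e-9)
    expect_equal(fit@interceptX, 5 / 1.002, tolerance = 1e-6)
    expect_equal(fit@slopeY, -0.001 / 0.999, tolerance = 1e-9)
    expect_equal(fit@interceptY, 2 / 0.999, tolerance = 1e-6)
    expect_lt(fit@residualRms, 1e-6)
})

test_that("deviations given at observed coordinates are fit exactly", {
    xb <- seq(0, 40000, length.out = 50)
    yb <- seq(0, 30000, length.out = 50)
    pairs <- data.frame(xb = xb, yb = yb,
                        dx = 0.002 * xb + 5, dy = -0.001 * yb + 2)
    fit <- fitChromaticAberration(pairs)
    expect_equal(fit@slopeX, 0.002, tolerance = 1e-9)
    expect_equal(fit@interceptX, 5, tolerance = 1e-9)
    ## all-zero deviations give the zero model
    z <- fitChromaticAberration(data.frame(xb = xb, yb = yb, dx = 0,
                                           dy = 0))
    expect_equal(abs(c(z@slopeX, z@interceptX, z@slopeY, z@interceptY)),
                 rep(0, 4), tolerance = 1e-12)
    expect_error(fitChromaticAberration(
        data.frame(xb = c(1, 1), yb = c(1, 1), dx = 0, dy = 0)),
        "rank deficient")
})

test_that("correct-then-fit leaves no residual aberration (noiseless)", {
    sim <- simulateBeadField(nPositions = 200L,
                             caField = c(0.002, 5, -0.001, 2),
                             pairingNoise = 0, seed = 6L,
                             beadPrecision = 0)
    cg <- findClusters(sim$green, 0, 10L, 100)
    cr <- findClusters(sim$red, 0, 10L, 100)
    fit <- fitChromaticAberration(pairBeads(cg, cr, 500))
    corrected <- applyChromaticAberration(sim$red, fit)
    cr2 <- findClusters(corrected, 0, 10L, 100)
    refit <- fitChromaticAberration(pairBeads(cg, cr2, 500))
    expect_lt(abs(refit@slopeX), 1e-9)
    expect_lt(abs(refit@slopeY), 1e-9)
    expect_lt(abs(refit@interceptX), 1e-6)
    expect_lt(abs(refit@interceptY), 1e-6)
})

test_that("fit-apply-fit contracts the residual RMS on noisy fields", {
    sim <- simulateBeadField(nPositions = 300L,
                             caField = c(0.002, 5, -0.001, 2),
                             pairingNoise = 5, seed = 8L)
    cg <- findClusters(sim$green, 0, 10L, 100)
    cr <- findClusters(sim$red, 0, 10L, 100)
    pairs <- pairBeads(cg, cr, 500)
    fit <- fitChromaticAberration(pairs)
    ## before correction the deviations carry the full field
    rmsBefore <- sqrt(mean(pairs$dx^2 + pairs$dy^2))
    corrected <- applyChromaticAberration(sim$red, fit)
    cr2 <- findClusters(corrected, 0, 10L, 100)
    pairs2 <- pairBeads(cg, cr2, 500)
    rmsAfter <- sqrt(mean(pairs2$dx^2 + pairs2$dy^2))
    expect_lt(rmsAfter, rmsBefore)
    expect_lt(rmsAfter, 2 * 5)   # down to pairing-noise level
})

test_that("zero chromatic aberration model is the identity", {
    lt <- LocalizationTable(0:2, c(1, 2, 3), c(4, 5, 6), c(1, 1, 1))
    expect_identical(locData(applyChromaticAberration(lt, CAModel())),
                     locData(lt))
})

test_that("recordings with a large axial offset are excluded and logged", {
    meta <- data.frame(recording_id = c("a", "b", "c"),
                       z_offset_nm = c(20, 150, -120))
    log <- withr::local_tempfile(fileext = ".log")
    res <- suppressMessages(qcFilterRecordings(meta, maxZOffset = 100,
                                               logFile = log))
    expect_identical(res$keep$recording_id, "a")
    expect_identical(res$dropped$recording_id, c("b", "c"))
    lines <- readLines(log)
    expect_length(lines, 2L)
    expect_match(lines[1L], "exceeds 100 nm")
})
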