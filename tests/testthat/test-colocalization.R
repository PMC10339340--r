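test_that("hand-counted example: 3 of 4 markers colocalized gives 0.75", {
    mk <- makeClusterSet(c(0, 1000, 2000, 3000), rep(0, 4))
    fl <- makeClusterSet(c(30, 1030, 1970), rep(0, 3))
    rec <- getColocalizationRatio(mk, fl, distanceCutoff = 100,
                                  recordingId = "toy")
    expect_identical(rec@nMarker, 4L)
    expect_identical(rec@nColoc, 3L)
    expect_equal(colocRatio(rec), 0.75)
})

test_that("an empty indicator channel gives R = 0; no markers flags NA", {
    mk <- makeClusterSet(c(0, 1000), c(0, 0))
    none <- makeClusterSet(numeric(), numeric())
    expect_equal(colocRatio(getColocalizationRatio(mk, none, 100)), 0)
    expect_warning(rec <- getColocalizationRatio(none, mk, 100),
                   "flagged")
    expect_true(is.na(colocRatio(rec)))
    expect_identical(rec@nMarker, 0L)
})

test_that("R is invariant under a common rigid translation", {
    set.seed(3)
    mk <- makeClusterSet(runif(30, 0, 5000), runif(30, 0, 5000))
    fl <- makeClusterSet(runif(25, 0, 5000), runif(25, 0, 5000))
    r0 <- getColocalizationRatio(mk, fl, 150)
    shift <- function(cs, dx, dy)
        makeClusterSet(clusters(cs)$x + dx, clusters(cs)$y + dy)
    r1 <- getColocalizationRatio(shift(mk, 1234.5, -987),
                                 shift(fl, 1234.5, -987), 150)
    expect_identical(r1@nColoc, r0@nColoc)
    expect_identical(r1@nMarker, r0@nMarker)
})

test_that("shrinking the cutoff never increases N_MF", {
    set.seed(4)
    mk <- makeClusterSet(runif(40, 0, 3000), runif(40, 0, 3000))
    fl <- makeClusterSet(runif(40, 0, 3000), runif(40, 0, 3000))
    prev <- -1L
    for (cutoff in c(25, 50, 100, 200, 400, 800)) {
        n <- getColocalizationRatio(mk, fl, cutoff)@nColoc
        expect_gte(n, prev)
        prev <- n
    }
})

test_that("ROIs covering the whole field equal the no-ROI result", {
    set.seed(5)
    mk <- makeClusterSet(runif(30, 0, 2000), runif(30, 0, 2000))
    fl <- makeClusterSet(runif(30, 0, 2000), runif(30, 0, 2000))
    a <- getColocalizationRatio(mk, fl, 100)
    b <- getColocalizationRatio(mk, fl, 100,
                                rois = c(0, 0, 2001, 2001))
    expect_identical(a@nMarker, b@nMarker)
    expect_identical(a@nColoc, b@nColoc)
})

test_that("ROI containment is half-open on marker centroids only", {
    mk <- makeClusterSet(c(0, 100), c(0, 0))      # second on right edge
    fl <- makeClusterSet(c(120, 130), c(0, 0))    # outside the ROI
    rec <- getColocalizationRatio(mk, fl, distanceCutoff = 50,
                                  rois = c(0, 0, 100, 100))
    expect_identical(rec@nMarker, 1L)   # x = 100 excluded (half-open)
    ## an indicator outside the ROI may still satisfy an inside marker
    rec2 <- getColocalizationRatio(makeClusterSet(90, 0), fl, 50,
                                   rois = c(0, 0, 100, 100))
    expect_identical(rec2@nColoc, 1L)
})

test_that("greedy matching equals exhaustive matching on sparse toys", {
    set.seed(6)
    cutoff <- 100
    for (r in 1:10) {
        ## grid spacing 3x cutoff guarantees cluster spacing > 2x cutoff
        nm <- sample(3:20, 1L)
        nf <- sample(3:20, 1L)
        sites <- expand.grid(x = seq(0, 12, 1) * 3 * cutoff,
                             y = seq(0, 12, 1) * 3 * cutoff)
        mi <- sites[sample.int(nrow(sites), nm), ]
        fi <- sites[sample.int(nrow(sites), nf), ]
        fi$x <- fi$x + runif(nf, -1.4 * cutoff, 1.4 * cutoff)
        fi$y <- fi$y + runif(nf, -1.4 * cutoff, 1.4 * cutoff)
        got <- getColocalizationRatio(makeClusterSet(mi$x, mi$y),
                                      makeClusterSet(fi$x, fi$y),
                                      cutoff)@nColoc
        expect_identical(got,
                         bruteMaxMatching(mi$x, mi$y, fi$x, fi$y, cutoff))
    }
})

test_that("each indicator cluster satisfies at most one marker", {
    ## two markers flanking one indicator: only one can claim it
    mk <- makeClusterSet(c(0, 40), c(0, 0))
    fl <- makeClusterSet(20, 0)
    rec <- getColocalizationRatio(mk, fl, 100)
    expect_identical(rec@nColoc, 1L)
})

test_that("dimer detection fractions follow the binomial law (p=0.5, m=0)", {
    set.seed(7)
    n <- 1000L
    det <- simulateComplexDetections(n, 2L, p = 0.5, m = 0)
    ## all complexes marker-visible (m = 0, recall 1); place markers on a
    ## sparse grid, indicators at detected complexes
    g <- expand.grid(x = seq_len(40) * 1000, y = seq_len(25) * 1000)
    g <- g[seq_len(n), ]
    mk <- makeClusterSet(g$x, g$y)
    keep <- det$indicator_detected
    fl <- makeClusterSet(g$x[keep] + rnorm(sum(keep), 0, 10),
                         g$y[keep] + rnorm(sum(keep), 0, 10))
    rec <- getColocalizationRatio(mk, fl, 100)
    expect_identical(rec@nMarker, n)
    ci <- qbinom(c(0.005, 0.995), n, 0.75) / n
    expect_gte(colocRatio(rec), ci[1L])
    expect_lte(colocRatio(rec), ci[2L])
})

test_that("ratioTable collects records and drops undefined ratios", {
    mk <- makeClusterSet(c(0, 1000), c(0, 0))
    fl <- makeClusterSet(10, 0)
    ok <- getColocalizationRatio(mk, fl, 100, recordingId = "good")
    bad <- suppressWarnings(
        getColocalizationRatio(makeClusterSet(numeric(), numeric()),
                               fl, 100, recordingId = "bad"))
    tab <- suppressMessages(ratioTable(list(ok, bad), knownState = 2L))
    expect_identical(nrow(tab), 1L)
    expect_identical(tab$recording_id, "good")
    expect_identical(tab$known_state, 2L)
})
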