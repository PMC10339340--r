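test_that("with m = 0 the expected ratio reduces to 1 - (1 - p)^n", {
    for (p in seq(0.05, 0.95, by = 0.1)) {
        e <- expectedRatio(1:10, p, m = 0)
        expect_lt(max(abs(e - (1 - (1 - p)^(1:10)))), 1e-12)
        ## log-linear relationship: ln(1 - R) = n ln(1 - p); checked where
        ## 1 - R is representable well above double rounding of R
        use <- (1 - p)^(1:10) > 1e-8
        expect_lt(max(abs(log(1 - e[use]) -
                          which(use) * log(1 - p))), 1e-7)
    }
    expect_equal(expectedRatio(1, 0.6), 0.6)          # n = 1 gives R = p
    expect_equal(expectedRatio(2, 0.5), 0.75)
})

test_that("the truncated-binomial k-weights sum to one", {
    for (n in 1:8) {
        for (m in c(0.05, 0.2, 0.5, 0.9)) {
            k <- seq_len(n)
            w <- choose(n, k) * (1 - m)^k * m^(n - k) / (1 - m^n)
            expect_equal(sum(w), 1, tolerance = 1e-12)
        }
    }
})

test_that("expected ratio matches term-by-term enumeration with m > 0", {
    ## n = 2, p = 0.5, m = 0.2: [C(2,1)*0.8*0.2*0.5 + 0.64*0.75] / 0.96
    expect_equal(expectedRatio(2, 0.5, 0.2),
                 (2 * 0.8 * 0.2 * 0.5 + 0.8^2 * 0.75) / (1 - 0.04),
                 tolerance = 1e-12)
})

test_that("expected ratio agrees with a Monte-Carlo detection oracle", {
    set.seed(31)
    n <- 3L; p <- 0.4; m <- 0.25
    nSim <- 2e5
    k <- rbinom(nSim, n, 1 - m)
    k <- k[k >= 1L]                       # condition on marker visibility
    detected <- rbinom(length(k), k, p) >= 1L
    expect_equal(mean(detected), expectedRatio(n, p, m),
                 tolerance = 4 / sqrt(nSim) + 0.003)
})

test_that("expected ratio is monotone in n and p, antitone in m", {
    for (p in c(0.2, 0.5, 0.8)) {
        for (m in c(0, 0.3, 0.6)) {
            e <- expectedRatio(1:8, p, m)
            expect_true(all(diff(e) > 0))
        }
    }
    ps <- seq(0.1, 1, by = 0.1)
    expect_true(all(diff(vapply(ps, function(p)
        expectedRatio(3, p, 0.2), 0)) > 0))
    ms <- seq(0, 0.9, by = 0.1)
    expect_true(all(diff(vapply(ms, function(m)
        expectedRatio(3, 0.5, m), 0)) < 0))
})

test_that("parameter domains are enforced", {
    expect_error(expectedRatio(0, 0.5), "n must be")
    expect_error(expectedRatio(2, 0), "p must be")
    expect_error(expectedRatio(2, 1.1), "p must be")
    expect_error(expectedRatio(2, 0.5, 1), "m must be")
})

test_that("noiseless calibration data returns the generating (p, m)", {
    st <- rep(1:4, each = 3)
    fit <- fitPM(expectedRatio(st, 0.3, 0.1), st)
    expect_lt(abs(fit[["p"]] - 0.3), 1e-6)
    expect_lt(abs(fit[["m"]] - 0.1), 1e-6)
    ## m = 0 data is recognised as the reduced model
    fit0 <- fitPM(expectedRatio(st, 0.5, 0), st)
    expect_lt(abs(fit0[["p"]] - 0.5), 1e-6)
    expect_lt(fit0[["m"]], 1e-6)
})

test_that("single-state calibration is rejected as unidentifiable", {
    expect_error(fitPM(c(0.7, 0.72, 0.68), c(2, 2, 2)), "unidentifiable")
})

test_that("reference bootstrap is seed-reproducible with valid intervals", {
    set.seed(51)
    tab <- simulateRatioTable(1:4, recordingsPerState = 8L,
                              complexesPerRecording = 300L,
                              p = 0.5, m = 0.1, seed = 51L)
    a <- referenceBootstrap(tab$ratio, tab$known_state, nBootstrap = 50L,
                            seed = 9L)
    b <- referenceBootstrap(tab$ratio, tab$known_state, nBootstrap = 50L,
                            seed = 9L)
    expect_identical(a@bootstrap, b@bootstrap)
    expect_identical(a@ciP, b@ciP)
    ## point estimates inside their intervals on healthy data
    expect_gte(a@p, a@ciP[1L]); expect_lte(a@p, a@ciP[2L])
    expect_gte(a@m, a@ciM[1L]); expect_lte(a@m, a@ciM[2L])
})

test_that("noiseless data gives intervals degenerate at the estimate", {
    st <- rep(1:4, each = 3)
    r <- expectedRatio(st, 0.4, 0.05)
    fit <- referenceBootstrap(r, st, nBootstrap = 1L, seed = 1L)
    expect_equal(fit@ciP, rep(fit@p, 2L), tolerance = 1e-5)
    expect_equal(fit@ciM, rep(fit@m, 2L), tolerance = 1e-5)
})

test_that("COM is zero at the expected ratio and elects that state", {
    cal <- list(p = 0.45, m = 0.12)
    for (n in c(1L, 2L, 4L)) {
        prof <- com(rep(expectedRatio(n, cal$p, cal$m), 5L), cal,
                    nMax = 6L)
        expect_identical(bestState(prof), n)
        expect_lt(comValues(prof)[n], 1e-20)
    }
})

test_that("COM bootstrap is deterministic and degenerate without variance", {
    tab <- simulateRatioTable(1:4, 6L, 300L, p = 0.5, m = 0.1, seed = 3L)
    poi <- rep(0.74, 8L)   # zero-variance POI ratios
    a <- comBootstrap(poi, tab$ratio, tab$known_state, nBootstrap = 100L,
                      referenceBootstrap = FALSE, seed = 2L)
    b <- comBootstrap(poi, tab$ratio, tab$known_state, nBootstrap = 100L,
                      referenceBootstrap = FALSE, seed = 2L)
    expect_identical(a@bootstrap, b@bootstrap)
    expect_identical(electFraction(a), electFraction(b))
    ## every replicate sees the same mean ratio, so one state takes all
    expect_equal(max(electFraction(a)), 1)
    expect_identical(unname(which(electFraction(a) == 1)),
                     as.integer(bestState(a)))
})

test_that("COM bootstrap matches the 27-way exhaustive resample oracle", {
    st <- rep(1:4, each = 3)
    refR <- expectedRatio(st, 0.5, 0)   # noiseless: p = 0.5, m = 0
    poi <- c(0.50, 0.62, 0.74)          # straddles the monomer/dimer line
    prof <- comBootstrap(poi, refR, st, nBootstrap = 4000L,
                         referenceBootstrap = FALSE, seed = 17L,
                         nMax = 4L)
    exact <- enumerateElections(poi, 0.5, 0, 4L)
    expect_gt(exact[1L], 0.1)   # genuinely split between n = 1 and 2
    expect_gt(exact[2L], 0.1)
    expect_equal(unname(electFraction(prof)), exact, tolerance = 0.035)
})

test_that("KS comparison: identical samples give D = 0, disjoint give D = 1", {
    tab <- data.frame(ratio = c(0.5, 0.55, 0.6, 0.74, 0.76, 0.8),
                      state = rep(1:2, each = 3))
    res <- ksCompare(tab$ratio[tab$state == 2], tab$ratio, tab$state)
    expect_equal(res$D[res$state == 2], 0)
    expect_identical(attr(res, "bestState"), 2L)
    res2 <- ksCompare(0.1, c(0.9, 0.9), c(1L, 1L))
    expect_equal(res2$D, 1)
})

test_that("KS statistic equals the brute-force ECDF scan", {
    set.seed(8)
    for (r in 1:10) {
        a <- runif(10); b <- runif(10)
        D <- suppressWarnings(ks.test(a, b))$statistic
        expect_equal(unname(D), bruteKS(a, b), tolerance = 1e-12)
        res <- ksCompare(a, b, rep(2L, 10))
        expect_equal(res$D, bruteKS(a, b), tolerance = 1e-12)
    }
})
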