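#' Expected colocalization ratio of an n-mer under the DCC model
#'
#' With every subunit intact (m = 0), a complex of n subunits carries n
#' indicator fluorophores, each detected independently with recall rate p,
#' so \code{R = 1 - (1 - p)^n}. Allowing each subunit's fluorophore pair to
#' be modified (non-functional) with probability m, and conditioning on the
#' complex being marker-visible (>= 1 intact subunit), gives
#' \deqn{R = \sum_{k=1}^{n} \binom{n}{k} (1-m)^k m^{n-k} / (1 - m^n)
#'   \cdot (1 - (1-p)^k).}
#' The k-weights are the binomial intact-subunit distribution truncated at
#' k >= 1; they sum to 1. R is strictly increasing in n and p and
#' decreasing in m.
#'
#' @param n oligomeric state(s), integer >= 1 (vectorized).
#' @param p indicator recall rate, in (0, 1].
#' @param m coefficient of modification, in [0, 1).
#' @return expected ratio(s) in (0, 1].
#' @examples
#' expectedRatio(1:4, p = 0.5)           # 1 - 0.5^n
#' expectedRatio(2, p = 0.5, m = 0.2)
#' @export
expectedRatio <- function(n, p, m = 0) {
    if (any(n < 1) || any(n != floor(n)))
        stop("n must be integer >= 1")
    if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        stop("p must be a scalar in (0, 1]")
    if (length(m) != 1L || is.na(m) || m < 0 || m >= 1)
        stop("m must be a scalar in [0, 1)")
    vapply(as.integer(n), function(ni) {
        k <- seq_len(ni)
        w <- choose(ni, k) * (1 - m)^k * m^(ni - k) / (1 - m^ni)
        sum(w * (1 - (1 - p)^k))
    }, numeric(1L))
}

#' Fit recall rate p and modification coefficient m to reference ratios
#'
#' Least-squares fit of the DCC model to per-recording colocalization
#' ratios of reference proteins with known oligomeric state: (p, m)
#' minimize \code{sum((R_obs - expectedRatio(n, p, m))^2)} under the box
#' constraints p in (0, 1], m in [0, 1). The optimizer is L-BFGS-B started
#' from a small (p, m) grid to guard against the shallow p/m trade-off
#' valley; single-state input is rejected as unidentifiable.
#'
#' @param ratios per-recording observed colocalization ratios.
#' @param states known oligomeric state per recording (>= 2 distinct
#'   values required).
#' @param multistart start from a grid of initial values (default) or only
#'   from \code{start}.
#' @param start optional single starting point \code{c(p, m)}.
#' @return named numeric \code{c(p, m)} with attributes \code{objective}
#'   (residual sum of squares) and \code{convergence} (0 = success).
#' @examples
#' st <- rep(1:4, each = 3)
#' fitPM(expectedRatio(st, p = 0.3, m = 0.1), st)
#' @export
fitPM <- function(ratios, states, multistart = TRUE, start = NULL) {
    ratios <- as.numeric(ratios)
    states <- as.integer(states)
    if (length(ratios) != length(states))
        stop("ratios and states must have equal length")
    ok <- complete.cases(ratios, states)
    ratios <- ratios[ok]; states <- states[ok]
    if (length(unique(states)) < 2L)
        stop("need reference proteins of >= 2 distinct oligomeric states; ",
             "the (p, m) model is unidentifiable from a single state")
    sTab <- sort(unique(states))
    idx <- match(states, sTab)
    ## inlined expectedRatio over the distinct states (hot path: called
    ## thousands of times during bootstrap refits)
    kmax <- max(sTab)
    kseq <- seq_len(kmax)
    chooseTab <- lapply(sTab, function(n) choose(n, seq_len(n)))
    obj <- function(par) {
        p <- par[1L]; m <- par[2L]
        e <- vapply(seq_along(sTab), function(j) {
            n <- sTab[j]
            k <- kseq[seq_len(n)]
            w <- chooseTab[[j]] * (1 - m)^k * m^(n - k) / (1 - m^n)
            sum(w * (1 - (1 - p)^k))
        }, numeric(1L))
        sum((ratios - e[idx])^2)
    }
    starts <- if (!is.null(start)) list(start)
        else if (multistart)
            unlist(lapply(c(0.2, 0.5, 0.8),
                          function(p0) lapply(c(0, 0.2),
                                              function(m0) c(p0, m0))),
                   recursive = FALSE)
        else list(c(0.5, 0.05))
    best <- NULL
    for (s in starts) {
        fit <- tryCatch(
            optim(s, obj, method = "L-BFGS-B",
                  lower = c(1e-9, 0), upper = c(1, 1 - 1e-9),
                  control = list(factr = 1, pgtol = 1e-12,
                                 maxit = 500L)),
            error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$value < best$value))
            best <- fit
    }
    if (is.null(best))
        stop("optimizer failed to converge for all starting values; ",
             "check the reference ratio table")
    out <- c(p = best$par[1L], m = best$par[2L])
    attr(out, "objective") <- best$value
    attr(out, "convergence") <- best$convergence
    out
}

#' Calibrate (p, m) with a stratified bootstrap
#'
#' The point estimate is the \code{\link{fitPM}} fit on the full reference
#' data. Bootstrap replicates resample recordings with replacement within
#' each known-state group and refit (starting from the point estimate);
#' confidence intervals are the 2.5/97.5 percentiles of the replicates.
#' Fully reproducible from \code{seed}.
#'
#' @param ratios,states as in \code{\link{fitPM}}.
#' @param nBootstrap number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return a \linkS4class{CalibrationFit}.
#' @export
referenceBootstrap <- function(ratios, states, nBootstrap = 1000L,
                               seed = 1L) {
    if (nBootstrap < 1L) stop("nBootstrap must be >= 1")
    point <- fitPM(ratios, states)
    ok <- complete.cases(ratios, states)
    ratios <- as.numeric(ratios)[ok]
    states <- as.integer(states)[ok]
    groups <- split(seq_along(ratios), states)
    reps <- withSeed(seed, {
        vapply(seq_len(nBootstrap), function(b) {
            take <- unlist(lapply(groups, function(g)
                g[sample.int(length(g), length(g), replace = TRUE)]),
                use.names = FALSE)
            fit <- tryCatch(
                fitPM(ratios[take], states[take], multistart = FALSE,
                      start = unname(point)),
                error = function(e) c(NA_real_, NA_real_))
            as.numeric(fit[1:2])
        }, numeric(2L))
    })
    boot <- data.frame(p = reps[1L, ], m = reps[2L, ])
    good <- complete.cases(boot)
    if (!all(good))
        message(sum(!good), " bootstrap replicate(s) failed to fit and ",
                "were dropped")
    boot <- boot[good, , drop = FALSE]
    new("CalibrationFit", p = unname(point["p"]), m = unname(point["m"]),
        ciP = unname(quantile(boot$p, c(0.025, 0.975), names = FALSE)),
        ciM = unname(quantile(boot$m, c(0.025, 0.975), names = FALSE)),
        bootstrap = boot, nBootstrap = as.integer(nBootstrap),
        seed = as.integer(seed))
}

#' Coefficient of mismatch across candidate oligomeric states
#'
#' For each candidate state n, the COM is the squared relative deviation of
#' the mean observed ratio from the model expectation,
#' \code{COM(n) = ((Rbar - E_n) / E_n)^2} with
#' \code{E_n = expectedRatio(n, p, m)}; it is zero at a perfect fit and
#' scale-free. The state with the smallest COM is the call; ties break
#' toward smaller n.
#'
#' @param observedRatios per-recording ratios of the protein of interest.
#' @param calibration a \linkS4class{CalibrationFit} (or list with elements
#'   \code{p} and \code{m}).
#' @param nMax largest candidate state (default 6, covering the usual
#'   monomer-tetramer standards with margin).
#' @return a \linkS4class{COMProfile} (no bootstrap information).
#' @export
com <- function(observedRatios, calibration, nMax = 6L) {
    observedRatios <- observedRatios[!is.na(observedRatios)]
    if (!length(observedRatios))
        stop("need at least one observed ratio")
    pm <- calibrationPM(calibration)
    states <- seq_len(nMax)
    vals <- comValuesFor(mean(observedRatios), states, pm[1L], pm[2L])
    new("COMProfile", states = as.integer(states), com = vals,
        bestState = as.integer(states[which.min(vals)]),
        electFraction = rep(NA_real_, nMax),
        bootstrap = matrix(numeric(), 0L, nMax,
                           dimnames = list(NULL, paste0("n", states))),
        nBootstrap = 0L, seed = NA_integer_)
}

comValuesFor <- function(rbar, states, p, m) {
    e <- expectedRatio(states, p, m)
    ((rbar - e) / e)^2
}

calibrationPM <- function(calibration) {
    if (is(calibration, "CalibrationFit"))
        c(calibration@p, calibration@m)
    else if (is.list(calibration) && all(c("p", "m") %in% names(calibration)))
        c(calibration$p, calibration$m)
    else stop("calibration must be a CalibrationFit or list(p=, m=)")
}

#' Bootstrap the coefficient of mismatch
#'
#' Per replicate, the protein-of-interest ratios are resampled with
#' replacement and the COM profile recomputed. With
#' \code{referenceBootstrap = TRUE} the reference (calibration) recordings
#' are resampled too (stratified by state) and (p, m) refit per replicate,
#' propagating calibration uncertainty. The election fraction is the share
#' of replicates in which each candidate state had the smallest COM.
#'
#' @param observedRatios per-recording ratios of the protein of interest.
#' @param referenceRatios,referenceStates the calibration dataset.
#' @param nBootstrap replicates (>= 1).
#' @param referenceBootstrap also resample the calibration dataset?
#' @param seed RNG seed.
#' @param nMax largest candidate state.
#' @return a \linkS4class{COMProfile} with election fractions and the
#'   replicate COM matrix; point COM values and \code{bestState} come from
#'   the full (un-resampled) data.
#' @export
comBootstrap <- function(observedRatios, referenceRatios, referenceStates,
                         nBootstrap = 1000L, referenceBootstrap = FALSE,
                         seed = 1L, nMax = 6L) {
    observedRatios <- as.numeric(observedRatios)
    observedRatios <- observedRatios[!is.na(observedRatios)]
    if (!length(observedRatios))
        stop("need at least one observed ratio")
    if (nBootstrap < 1L) stop("nBootstrap must be >= 1")
    point <- fitPM(referenceRatios, referenceStates)
    states <- seq_len(nMax)
    pointCom <- comValuesFor(mean(observedRatios), states,
                             point["p"], point["m"])
    refR <- as.numeric(referenceRatios)
    refS <- as.integer(referenceStates)
    groups <- split(seq_along(refR), refS)
    nPoi <- length(observedRatios)
    bootMat <- withSeed(seed, {
        t(vapply(seq_len(nBootstrap), function(b) {
            rbar <- mean(observedRatios[sample.int(nPoi, nPoi,
                                                   replace = TRUE)])
            pm <- point
            if (referenceBootstrap) {
                take <- unlist(lapply(groups, function(g)
                    g[sample.int(length(g), length(g), replace = TRUE)]),
                    use.names = FALSE)
                pm <- tryCatch(
                    fitPM(refR[take], refS[take], multistart = FALSE,
                          start = unname(point)),
                    error = function(e) point)
            }
            comValuesFor(rbar, states, pm[1L], pm[2L])
        }, numeric(nMax)))
    })
    colnames(bootMat) <- paste0("n", states)
    elected <- states[apply(bootMat, 1L, which.min)]
    new("COMProfile", states = as.integer(states), com = unname(pointCom),
        bestState = as.integer(states[which.min(pointCom)]),
        electFraction = as.numeric(tabulate(elected, nMax) / nrow(bootMat)),
        bootstrap = bootMat, nBootstrap = as.integer(nBootstrap),
        seed = as.integer(seed))
}

#' Kolmogorov-Smirnov comparison against each reference state
#'
#' Compares the distribution of the protein-of-interest colocalization
#' ratios with each reference protein's ratio distribution using the
#' two-sample KS statistic \code{D = sup |ECDF1 - ECDF2|} with asymptotic
#' p-value. The state with the largest p-value (smallest D) is the most
#' compatible.
#'
#' @param poiRatios protein-of-interest ratios.
#' @param referenceRatios,referenceStates the calibration dataset.
#' @return \code{data.frame} with columns \code{state}, \code{D},
#'   \code{p_value}, ordered by state, with attribute \code{bestState}.
#' @export
ksCompare <- function(poiRatios, referenceRatios, referenceStates) {
    poiRatios <- poiRatios[!is.na(poiRatios)]
    if (!length(poiRatios)) stop("need at least one POI ratio")
    states <- sort(unique(as.integer(referenceStates)))
    res <- do.call(rbind, lapply(states, function(s) {
        ref <- referenceRatios[referenceStates == s]
        kt <- suppressWarnings(ks.test(poiRatios, ref))
        data.frame(state = s, D = unname(kt$statistic),
                   p_value = unname(kt$p.value))
    }))
    ## largest p, ties toward smallest D then smaller state
    best <- res$state[order(-res$p_value, res$D, res$state)][1L]
    attr(res, "bestState") <- best
    res
}

## evaluate `expr` under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
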