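## Definition-based oracles, independent of the package's implementations.

## DBSCAN by definition: full pairwise distance matrix, core points, BFS
## over density-connected cores; border points take the smallest cluster id
## among their core neighbours (the first-discovered cluster).
bruteDbscan <- function(x, y, eps, minPts) {
    n <- length(x)
    D <- as.matrix(dist(cbind(x, y)))
    nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
    core <- vapply(nb, length, 0L) >= minPts
    lab <- rep(-1L, n)
    cl <- -1L
    for (i in seq_len(n)) {
        if (!core[i] || lab[i] >= 0L) next
        cl <- cl + 1L
        lab[i] <- cl
        q <- i
        while (length(q)) {
            j <- q[1L]; q <- q[-1L]
            for (k in nb[[j]]) {
                if (core[k] && lab[k] < 0L) {
                    lab[k] <- cl
                    q <- c(q, k)
                }
            }
        }
    }
    for (i in seq_len(n)) {
        if (!core[i]) {
            cn <- nb[[i]][core[nb[[i]]]]
            if (length(cn))
                lab[i] <- min(lab[cn])
        }
    }
    lab
}

## Two-sample KS statistic by scanning the empirical CDFs at every
## observed value.
bruteKS <- function(a, b) {
    ts <- sort(unique(c(a, b)))
    fa <- vapply(ts, function(t) mean(a <= t), 0)
    fb <- vapply(ts, function(t) mean(b <= t), 0)
    max(abs(fa - fb))
}

## Maximum bipartite matching size between markers and indicators with
## edges d <= cutoff, by augmenting paths (small instances only).
bruteMaxMatching <- function(mx, my, fx, fy, cutoff) {
    nm <- length(mx); nf <- length(fx)
    if (nm == 0L || nf == 0L) return(0L)
    adj <- sqrt(outer(mx, fx, "-")^2 + outer(my, fy, "-")^2) <= cutoff
    matchF <- rep(0L, nf)
    tryAugment <- function(i, seen) {
        for (j in which(adj[i, ])) {
            if (seen[j]) next
            seen[j] <- TRUE
            if (matchF[j] == 0L ||
                Recall(matchF[j], seen)) {
                matchF[j] <<- i
                return(TRUE)
            }
        }
        FALSE
    }
    cnt <- 0L
    for (i in seq_len(nm))
        if (tryAugment(i, rep(FALSE, nf))) cnt <- cnt + 1L
    cnt
}

## Wrap centroid coordinates into a minimal ClusterSet.
makeClusterSet <- function(x, y, channel = "", intensity = 1,
                           firstFrame = 0L, lastFrame = 0L, n = 1L) {
    k <- length(x)
    new("ClusterSet",
        clusters = data.frame(cluster_id = seq_len(k) - 1L,
                              x = as.numeric(x), y = as.numeric(y),
                              n = rep_len(as.integer(n), k),
                              first_frame = rep_len(as.integer(firstFrame), k),
                              last_frame = rep_len(as.integer(lastFrame), k),
                              mean_intensity = rep_len(as.numeric(intensity),
                                                       k)),
        channel = channel, noiseCount = 0L, labels = integer())
}

## COM election by exhaustive enumeration of all ordered bootstrap
## resamples of a tiny ratio set (independent of comBootstrap's RNG path).
enumerateElections <- function(ratios, p, m, nMax) {
    idx <- do.call(expand.grid, rep(list(seq_along(ratios)),
                                    length(ratios)))
    e <- expectedRatio(seq_len(nMax), p, m)
    elected <- apply(idx, 1L, function(take) {
        rbar <- mean(ratios[as.integer(take)])
        which.min(((rbar - e) / e)^2)
    })
    tabulate(elected, nMax) / nrow(idx)
}

## Pipeline configuration used across validation studies: eps of 4x the
## simulator's localization sigma, min_samples 1 for signals (clean,
## ROI-restricted background), cell ROI of the default SimConfig.
studyPipelineConfig <- function(cellRoi = c(8000, 8000, 25000, 25000)) {
    pipelineConfig(signal = list(eps = 60, minSamples = 1L),
                   rois = matrix(cellRoi, nrow = 1L))
}

## Scaled-down acquisition: fewer frames and beads than a full recording
## session, same detection physics.
studySimConfig <- function(nSubunits, seed, ...) {
    simConfig(nSubunits = nSubunits, nComplexes = 300L, nBeads = 3L,
              nFramesMarker = 150L, nFramesIndicator = 250L,
              seed = seed, ...)
}
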