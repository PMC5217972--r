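# Coverage profiles and inference of the packaging model: flank enrichment,
# decay/processivity, wave period -> headful size and terminal redundancy,
# pac position, directionality, flank extent.

#' Construct a CoverageProfile
#' @param frame frame name.
#' @param depth per-bin mean depth.
#' @param binSize bin width (bp).
#' @param frameLength frame length (bp).
#' @param topology `"circular"` or `"linear"`.
#' @return a [CoverageProfile-class].
#' @export
coverageProfile <- function(frame, depth, binSize, frameLength,
                            topology = "circular") {
    new("CoverageProfile", frame = frame, binSize = as.integer(binSize),
        depth = as.numeric(depth), frameLength = as.integer(frameLength),
        topology = topology)
}

setMethod("show", "CoverageProfile", function(object) {
    cat("CoverageProfile '", object@frame, "': ", length(object@depth),
        " bins of ", object@binSize, " bp (", object@topology, ")\n",
        "  depth mean ", sprintf("%.3f", mean(object@depth)), ", max ",
        sprintf("%.3f", max(object@depth)), "\n", sep = "")
})

#' @rdname binnedCoverage
#' @export
setGeneric("binnedCoverage",
    function(x, frame, binSize = 1000L, ...) standardGeneric("binnedCoverage"))

# per-base depth (numeric vector of length L) from 0-based half-open
# intervals, wrapping intervals with end > L on circular frames
baseDepth <- function(starts, ends, L, circular = TRUE) {
    d <- numeric(L + 1L)
    if (length(starts)) {
        over <- ends > L
        if (any(over) && circular) {
            extraS <- rep(0, sum(over)); extraE <- ends[over] - L
            ends[over] <- L
            starts <- c(starts, extraS); ends <- c(ends, pmin(extraE, L))
        } else ends <- pmin(ends, L)
        starts <- pmax(starts, 0)
        add <- tabulate(starts + 1L, nbins = L + 1L)
        sub <- tabulate(ends + 1L, nbins = L + 1L)
        d <- cumsum(add - sub)
    }
    d[seq_len(L)]
}

binMeans <- function(depth, L, binSize) {
    nb <- ceiling(L / binSize)
    cs <- c(0, cumsum(as.numeric(depth)))
    ends <- pmin(L, seq_len(nb) * binSize)
    starts <- (seq_len(nb) - 1L) * binSize
    (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
}

#' Binned coverage from classified reads or packaged molecules
#'
#' `depth[i]` is the mean per-base depth in bin `i` (aligned bases divided by
#' bin width).  For classified reads, host-frame coverage uses host and
#' hybrid reads' host intervals (ambiguous and unmapped reads are excluded);
#' phage-frame coverage uses phage reads plus hybrids' phage intervals.  For
#' a [PackagedMoleculeSet-class], coverage counts the packaged molecules
#' themselves (sequencing-free truth depth).
#'
#' @param x classified-read data.frame (from [classifyReads()]) or a
#'   [PackagedMoleculeSet-class].
#' @param frame `"host"` or `"phage"`.
#' @param binSize bin width in bp (> 0).
#' @param frameLength,topology frame geometry (required for read input).
#' @param ... unused.
#' @return a [CoverageProfile-class].
#' @export
setMethod("binnedCoverage", "data.frame",
    function(x, frame, binSize = 1000L, frameLength, topology = "circular",
             ...) {
    if (binSize <= 0) stop("binSize must be > 0")
    if (frame == "host") {
        keep <- x$class %in% c("host", "hybrid-left", "hybrid-right") &
            !is.na(x$refStart)
        s <- x$refStart[keep]; e <- x$refEnd[keep]
    } else {
        ph <- x$class == "phage" & !is.na(x$refStart)
        hy <- grepl("^hybrid", x$class) & !is.na(x$phageRefStart)
        s <- c(x$refStart[ph], x$phageRefStart[hy])
        e <- c(x$refEnd[ph], x$phageRefEnd[hy])
    }
    d <- baseDepth(s, e, frameLength, topology == "circular")
    coverageProfile(frame, binMeans(d, frameLength, binSize), binSize,
                    frameLength, topology)
})

#' @rdname binnedCoverage
#' @export
setMethod("binnedCoverage", "PackagedMoleculeSet",
    function(x, frame, binSize = 1000L, ...) {
    if (binSize <= 0) stop("binSize must be > 0")
    segs <- x@segments[x@segments$frame == frame, ]
    L <- if (frame == "host") x@geometry$Lh else x@geometry$Lp
    d <- baseDepth(segs$start, segs$end, L, TRUE)
    coverageProfile(frame, binMeans(d, L, binSize), binSize, L, "circular")
})

# signed distance from attB along the packaging direction (mod L)
flankDistance <- function(pos, attBPos, direction, L) {
    if (direction == "toward_attL") (attBPos - pos) %% L
    else (pos - attBPos) %% L
}

#' Fraction of host reads near the att site
#'
#' Counts host-classified reads whose midpoint lies within
#' `[attB - flankWindow, attB + offSideMargin]` (orientation-adjusted: the
#' large window is on the packaging side).
#'
#' @param classified data.frame from [classifyReads()].
#' @param attBPos 0-based attB core start.
#' @param direction packaging direction (`"toward_attL"` / `"toward_attR"`).
#' @param hostLength host frame length.
#' @param flankWindow window on the packaging side (bp).
#' @param offSideMargin margin on the other side (bp).
#' @return list: fraction, numerator, denominator.
#' @export
nearAttFraction <- function(classified, attBPos, direction = "toward_attL",
                            hostLength, flankWindow = 8e5,
                            offSideMargin = 1e4) {
    if (flankWindow + offSideMargin > hostLength)
        stop("window larger than genome")
    isHost <- classified$class %in% c("host", "hybrid-left", "hybrid-right")
    mid <- ((classified$refStart + classified$refEnd)[isHost] / 2) %% hostLength
    denom <- sum(isHost)
    if (denom == 0L)
        return(list(fraction = NA_real_, numerator = 0L, denominator = 0L))
    dFlank <- flankDistance(mid, attBPos, direction, hostLength)
    dOff <- flankDistance(mid, attBPos,
                          if (direction == "toward_attL") "toward_attR"
                          else "toward_attL", hostLength)
    num <- sum(dFlank <= flankWindow | dOff <= offSideMargin)
    list(fraction = num / denom, numerator = num, denominator = denom)
}

#' Median background depth away from the att site
#'
#' @param profile host-frame [CoverageProfile-class].
#' @param excludeStart,excludeEnd 0-based half-open interval (bp) to
#'   exclude (may wrap on circular frames: give excludeStart > excludeEnd).
#' @return median depth of the remaining bins.
#' @export
estimateBackground <- function(profile, excludeStart, excludeEnd) {
    bs <- profile@binSize
    L <- profile@frameLength
    centers <- (seq_along(profile@depth) - 0.5) * bs
    inExcl <- if (excludeStart <= excludeEnd)
        centers >= excludeStart & centers < excludeEnd
    else centers >= excludeStart | centers < excludeEnd
    if (all(inExcl)) stop("no bins remain outside the exclusion interval")
    median(profile@depth[!inExcl])
}

#' Extent of host-flank coverage enrichment
#'
#' Largest distance d such that the bins in `[attB, attB +/- d]` exceed
#' `thresholdMult * background`, tolerating up to `runRule` consecutive
#' sub-threshold bins.  With zero background an absolute floor of 0.1X is
#' applied.
#'
#' @param profile host-frame [CoverageProfile-class].
#' @param attBPos 0-based attB position.
#' @param direction packaging direction.
#' @param background depth from [estimateBackground()].
#' @param thresholdMult enrichment multiple.
#' @param runRule tolerated consecutive low bins.
#' @return extent in bp.
#' @export
flankExtent <- function(profile, attBPos, direction = "toward_attL",
                        background, thresholdMult = 2, runRule = 3L) {
    thr <- max(thresholdMult * background, 0.1)
    bs <- profile@binSize
    L <- profile@frameLength
    nb <- length(profile@depth)
    startBin <- floor((attBPos %% L) / bs)            # bin containing attB
    step <- if (direction == "toward_attL") -1L else 1L
    lastGood <- 0L; run <- 0L
    for (i in seq_len(nb - 1L)) {
        b <- ((startBin + step * i) %% nb) + 1L
        if (profile@depth[b] >= thr) { lastGood <- i; run <- 0L }
        else { run <- run + 1L; if (run > runRule) break }
    }
    lastGood * bs
}

#' Mean depth in successive headful windows beyond the att site
#'
#' Window j covers flank distances `[b_{j-1}, b_j)` with `b_0 = 0`,
#' `b_j = firstWidth + (j-1) H`; `firstWidth = H - d` accounts for the
#' first headful's partial-phage content (d = pac-to-junction distance).
#' Under the geometric series model the expected means decay as
#' `(1 - 1/m)^(j-1)`.
#'
#' @param profile host-frame [CoverageProfile-class].
#' @param attBPos 0-based attB position.
#' @param direction packaging direction.
#' @param H headful size (bp).
#' @param nWindows number of windows.
#' @param firstWidth width of the first window (default `H`).
#' @return numeric vector of window mean depths.
#' @export
headfulWindowMeans <- function(profile, attBPos, direction = "toward_attL",
                               H, nWindows = 12L, firstWidth = H) {
    if (H <= 0) stop("H must be > 0")
    bs <- profile@binSize
    L <- profile@frameLength
    bounds <- c(0, firstWidth + (seq_len(nWindows) - 1L) * H)
    if (max(bounds) > L) stop("windows exceed the genome")
    centers <- (seq_along(profile@depth) - 0.5) * bs
    dist <- flankDistance(centers, attBPos, direction, L)
    win <- findInterval(dist, bounds, left.open = FALSE)
    win[dist >= max(bounds)] <- 0L
    means <- rep(NA_real_, nWindows)
    ok <- win >= 1L & win <= nWindows
    agg <- tapply(profile@depth[ok], win[ok], mean)
    means[as.integer(names(agg))] <- agg
    means
}

#' Estimate packaging processivity from headful-window means
#'
#' `m_hat = sum_j max(w_j - background, 0) / (w_1 - background)`: the sum of
#' the background-subtracted geometric decay, which converges to the mean
#' series length m as the number of windows grows.
#'
#' @param windowMeans from [headfulWindowMeans()].
#' @param background depth to subtract.
#' @return estimated mean headfuls per series.
#' @export
estimateProcessivity <- function(windowMeans, background = 0) {
    w <- windowMeans[!is.na(windowMeans)]
    if (length(w) == 0L || w[1] <= background)
        stop("degenerate first window (no enrichment above background)")
    sum(pmax(w - background, 0)) / (w[1] - background)
}

#' Detect the coverage-wave period in the host flank
#'
#' Log-depth over the flank span is detrended by subtracting a centred
#' moving average, the autocorrelation is computed up to `maxLag`, and the
#' period is the first local maximum beyond `minLag` (local over a +/- 5-bin
#' neighbourhood, above `peakThreshold` of the zero-lag normalisation),
#' refined by quadratic interpolation over the three bins around the peak.
#'
#' @param profile host-frame [CoverageProfile-class].
#' @param attBPos 0-based attB position.
#' @param direction packaging direction.
#' @param span flank span analysed (bp); must cover several periods.
#' @param maxLag maximum lag (bp).
#' @param detrendWindow moving-average window (bp).
#' @param minLag smallest admissible period (bp).
#' @param peakThreshold minimum normalised autocorrelation at the peak.
#' @return list: `period` (bp, NA when none), `detected`, `lagAcf`
#'   (named vector of the autocorrelation by lag in bp).
#' @export
detectWavePeriod <- function(profile, attBPos, direction = "toward_attL",
                             span = 9e5, maxLag = 1.5e5,
                             detrendWindow = 1e5, minLag = 2e4,
                             peakThreshold = 0.1) {
    bs <- profile@binSize
    L <- profile@frameLength
    nb <- length(profile@depth)
    nSpan <- min(floor(span / bs), nb - 1L)
    startBin <- floor((attBPos %% L) / bs)
    step <- if (direction == "toward_attL") -1L else 1L
    bins <- ((startBin + step * seq_len(nSpan)) %% nb) + 1L
    x <- log(profile@depth[bins] + 0.5)
    w <- max(3L, round(detrendWindow / bs))
    if (w %% 2L == 0L) w <- w + 1L
    trend <- stats::filter(x, rep(1 / w, w), sides = 2)
    resid <- (x - trend)[!is.na(trend)]
    if (length(resid) < 10L || stats::sd(resid) == 0)
        return(list(period = NA_real_, detected = FALSE, lagAcf = NULL))
    nLag <- min(floor(maxLag / bs), length(resid) - 2L)
    ac <- stats::acf(resid, lag.max = nLag, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    lag0 <- max(2L, ceiling(minLag / bs))
    peak <- NA_integer_
    for (i in seq(lag0, nLag - 1L)) {
        lo <- max(1L, i - 5L); hi <- min(nLag, i + 5L)
        a <- ac[i + 1L]
        if (a >= peakThreshold && a == max(ac[(lo:hi) + 1L])) {
            peak <- i; break
        }
    }
    lagAcf <- setNames(ac[-1], seq_len(nLag) * bs)
    if (is.na(peak))
        return(list(period = NA_real_, detected = FALSE, lagAcf = lagAcf))
    # quadratic interpolation around the peak
    y1 <- ac[peak]; y2 <- ac[peak + 1L]; y3 <- ac[peak + 2L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (y1 - y3) / denom
    delta <- max(-0.5, min(0.5, delta))
    list(period = (peak + delta) * bs, detected = TRUE, lagAcf = lagAcf)
}

#' Terminal redundancy from the wave period
#'
#' The wave spacing estimates the headful `T = Lp (1 + r)`, so
#' `r_hat = (T - Lp) / Lp`.  Negative values (T < Lp) are returned but
#' flagged with a warning.
#'
#' @param periodT detected period (bp).
#' @param Lp phage genome length (bp).
#' @return estimated redundancy fraction.
#' @export
estimateRedundancy <- function(periodT, Lp) {
    if (is.na(periodT) || periodT <= 0) stop("periodT must be > 0")
    r <- (periodT - Lp) / Lp
    if (r < 0) warning("detected period below the phage length (r < 0)")
    r
}

# circular moving average
circularSmooth <- function(x, w) {
    if (w %% 2L == 0L) w <- w + 1L
    n <- length(x)
    pad <- (w - 1L) / 2L
    xx <- c(tail(x, pad), x, head(x, pad))
    as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[pad + seq_len(n)]
}

#' Estimate the packaging-initiation (pac) position
#'
#' The terminally redundant arc beyond one genome length over-represents the
#' region downstream of the initiation cut; the initiation position is read
#' from the rising edge of the smoothed circular phage profile (the argmax
#' of its circular gradient), matching a coverage maximum *starting* at pac.
#' The position of the smoothed maximum itself (`peak`, the centre of the
#' redundant arc) and the down-slope direction over the following quarter
#' genome are also reported.
#'
#' @param profile circular phage-frame [CoverageProfile-class].
#' @param smoothWindow moving-average window (bp).
#' @return list: `pacPos` (bp), `peak` (bp), `downSlope` (+1/-1),
#'   `defined` (FALSE for flat profiles).
#' @export
estimatePacPosition <- function(profile, smoothWindow = 2000L) {
    bs <- profile@binSize
    nb <- length(profile@depth)
    w <- max(3L, round(smoothWindow / bs))
    sm <- circularSmooth(profile@depth, w)
    if (max(sm) - min(sm) < 1e-9 * (max(sm) + 1e-12) || max(sm) == 0)
        return(list(pacPos = NA_real_, peak = NA_real_, downSlope = NA,
                    defined = FALSE))
    grad <- sm - sm[c(nb, seq_len(nb - 1L))]          # circular difference
    riseBin <- which.max(grad)
    peakBin <- which.max(sm)
    quarter <- max(2L, floor(nb / 4))
    after <- ((peakBin - 1L + seq_len(quarter)) %% nb) + 1L
    slope <- if (mean(diff(sm[after])) <= 0) -1 else 1
    list(pacPos = (riseBin - 0.5) * bs, peak = (peakBin - 0.5) * bs,
         downSlope = slope, defined = TRUE)
}

#' Directionality of hybrid junction reads
#'
#' Two-sided exact binomial test of hybrid-left vs hybrid-right counts
#' under P = 0.5.
#'
#' @param hybridLeft,hybridRight counts.
#' @return list: `direction` ("left"/"right"/"none"), `pValue`.
#' @export
directionalityTest <- function(hybridLeft, hybridRight) {
    if (hybridLeft < 0 || hybridRight < 0) stop("counts must be >= 0")
    n <- hybridLeft + hybridRight
    if (n == 0)
        return(list(direction = "none", pValue = NA_real_))
    p <- binomTestTwoSided(hybridLeft, n, 0.5)
    dir <- if (hybridLeft > hybridRight) "left"
           else if (hybridRight > hybridLeft) "right" else "none"
    list(direction = dir, pValue = p)
}
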