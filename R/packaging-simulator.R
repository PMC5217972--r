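# Synthetic-data generator: pac-initiated processive headful packaging with
# occasional att-site integration, episomal circularly-permuted packaging,
# and a uniform background of packaged host DNA.
#
# A packaging series walks a linear "packaging path": for an integrated
# series the path runs from the jittered pac cut through the prophage,
# across the attL (or attR) junction, and on along the circular host; for an
# episomal series it walks an unbounded tandem repeat (concatemer) of the
# phage genome.  Successive molecules tile the path in steps of exactly H.

#' Construct simulation parameters
#'
#' Defaults reproduce the study conditions of the modelled experiment: 10%
#' terminal redundancy, pac at 23,500, initiation jitter sd 2 kb, geometric
#' series with mean 3 headfuls, packaging toward attL.  `condition` presets
#' the integrated-initiation and background rates: the induction values
#' (fInt = 0.018, bgRate = 0.022) and infection values (fInt = 0.0054,
#' bgRate = 0.0049) are calibrated analytically from the observed host-read
#' fractions (2.2% / 0.6%) and near-att shares (67% / 73%); see the package
#' vignette for the closed form.
#'
#' @param condition `"induction"` or `"infection"`; sets fInt/bgRate
#'   defaults (explicit arguments always win).
#' @param redundancy,pacPos,pacJitterSd,meanHeadfuls,fInt,direction,bgRate,nSeries,seed
#'   see [SimParams-class].
#' @return a [SimParams-class].
#' @export
simParams <- function(condition = c("induction", "infection"),
                      redundancy = 0.10, pacPos = 23500L,
                      pacJitterSd = 2000, meanHeadfuls = 3,
                      fInt = NULL, direction = "toward_attL",
                      bgRate = NULL, nSeries = 1000L, seed = NULL) {
    condition <- match.arg(condition)
    if (is.null(fInt))
        fInt <- if (condition == "induction") 0.018 else 0.0054
    if (is.null(bgRate))
        bgRate <- if (condition == "induction") 0.022 else 0.0049
    new("SimParams", redundancy = redundancy, pacPos = as.integer(pacPos),
        pacJitterSd = pacJitterSd, meanHeadfuls = meanHeadfuls,
        fInt = fInt, direction = direction, bgRate = bgRate,
        nSeries = as.integer(nSeries),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
    cat("SimParams: r =", object@redundancy, " pac =", object@pacPos,
        " jitter sd =", object@pacJitterSd, "\n  m =", object@meanHeadfuls,
        " fInt =", object@fInt, " bgRate =", object@bgRate,
        " n =", object@nSeries, " dir =", object@direction, "\n")
})

#' Headful size
#'
#' H = round(Lp * (1 + r)): the capsid holds one phage genome plus the
#' terminally redundant excess.
#'
#' @param Lp phage genome length (bp).
#' @param redundancy terminal redundancy r.
#' @return integer headful size in bp.
#' @export
headfulSize <- function(Lp, redundancy) as.integer(round(Lp * (1 + redundancy)))

#' Draw packaging-series lengths
#'
#' Series length is geometric on {1, 2, ...} with mean `m`: after each
#' completed headful the motor continues with probability 1 - 1/m
#' (memoryless continuation), so P(k) = (1/m) (1 - 1/m)^(k-1).
#'
#' @param n number of draws.
#' @param m mean series length (>= 1).
#' @return integer vector of lengths (all >= 1).
#' @export
drawSeriesLength <- function(n, m) {
    if (m < 1) stop("m must be >= 1")
    if (m == 1) return(rep(1L, n))
    rgeom(n, prob = 1 / m) + 1L
}

# geometry of the packaging path, all in the phage frame ALIGNED to the host
# (reverse-orientation phages are flipped once here, and segments are
# converted back to original phage coordinates on output)
packagingGeometry <- function(hostLength, phageLength, att, params) {
    c <- nchar(att@core)
    attPFwd <- if (att@orientation == "forward") att@attPPos
               else phageLength - att@attPPos - c
    pacFwd <- if (att@orientation == "forward") params@pacPos
              else phageLength - params@pacPos
    list(Lh = hostLength, Lp = phageLength, attB = att@attBPos,
         attPFwd = attPFwd, pacFwd = pacFwd, coreLen = c,
         orientation = att@orientation, direction = params@direction)
}

# distance (bp) along the packaging path from the pac cut to the att
# junction, for an un-jittered cut
pacJunctionDistance <- function(geom) {
    if (geom$direction == "toward_attL")
        (geom$pacFwd - geom$attPFwd - geom$coreLen) %% geom$Lp
    else
        (geom$attPFwd - geom$pacFwd) %% geom$Lp
}

# split the bases of one walk (from `from`, `len` bp, direction `dir`) on a
# frame of length L into non-wrapping 0-based half-open intervals, in path
# order.  dir = -1 walks are reported with strand "-".
walkIntervals <- function(from, len, dir, L, pathStart) {
    out <- list(); t <- 0
    p <- from %% L
    while (len > 0) {
        if (dir > 0) {
            take <- min(len, L - p)
            out[[length(out) + 1L]] <-
                c(start = p, end = p + take, strand = 1,
                  pathStart = pathStart + t)
            p <- (p + take) %% L
        } else {
            take <- min(len, p + 1)
            out[[length(out) + 1L]] <-
                c(start = p - take + 1, end = p + 1, strand = -1,
                  pathStart = pathStart + t)
            p <- (p - take) %% L
        }
        len <- len - take; t <- t + take
    }
    out
}

# convert an aligned-phage-frame interval to original phage coordinates
fwdToOriginal <- function(start, end, strand, Lp, orientation) {
    if (orientation == "forward") list(start = start, end = end,
                                       strand = strand)
    else list(start = Lp - end, end = Lp - start, strand = -strand)
}

#' Generate one packaging series
#'
#' Lays down `k` consecutive headfuls of exactly `H` bp along the packaging
#' path starting at the (jittered) pac cut.  Integrated series cross the att
#' junction into the host flank selected by `direction` and continue along
#' the circular host; episomal series walk the phage concatemer, producing
#' circularly permuted, terminally redundant molecules.
#'
#' @param params a [SimParams-class].
#' @param origin `"integrated"` or `"episomal"`.
#' @param geom internal geometry list from `packagingGeometry()`.
#' @param k series length (number of headfuls).
#' @param cut0 0-based aligned-frame position of the first cut (already
#'   jittered).
#' @param seriesId integer series identifier.
#' @return data.frame of molecule segments (see [PackagedMoleculeSet-class]).
#' @keywords internal
generateSeriesSegments <- function(params, origin, geom, k, cut0, seriesId) {
    H <- headfulSize(geom$Lp, params@redundancy)
    total <- k * H
    pieces <- list()
    if (origin == "episomal") {
        # walk the concatemer: direction matches the integrated walk
        dir <- if (geom$direction == "toward_attL") -1 else 1
        from <- if (dir > 0) cut0 %% geom$Lp else (cut0 - 1) %% geom$Lp
        walk <- walkIntervals(from, total, dir, geom$Lp, 0)
        for (w in walk) {
            o <- fwdToOriginal(w[["start"]], w[["end"]], w[["strand"]],
                               geom$Lp, geom$orientation)
            pieces[[length(pieces) + 1L]] <-
                data.frame(frame = "phage", start = o$start, end = o$end,
                           strand = o$strand, pathStart = w[["pathStart"]])
        }
    } else {
        d <- if (geom$direction == "toward_attL")
                 (cut0 - geom$attPFwd - geom$coreLen) %% geom$Lp
             else (geom$attPFwd - cut0) %% geom$Lp
        d <- min(d, total)
        if (d > 0) {
            dir <- if (geom$direction == "toward_attL") -1 else 1
            from <- if (dir > 0) cut0 %% geom$Lp else (cut0 - 1) %% geom$Lp
            walk <- walkIntervals(from, d, dir, geom$Lp, 0)
            for (w in walk) {
                o <- fwdToOriginal(w[["start"]], w[["end"]], w[["strand"]],
                                   geom$Lp, geom$orientation)
                pieces[[length(pieces) + 1L]] <-
                    data.frame(frame = "phage", start = o$start, end = o$end,
                               strand = o$strand, pathStart = w[["pathStart"]])
            }
        }
        if (total > d) {
            # cross the junction into the host; the single junction core copy
            # is attributed to the host frame
            if (geom$direction == "toward_attL") {
                from <- (geom$attB + geom$coreLen - 1) %% geom$Lh
                walk <- walkIntervals(from, total - d, -1, geom$Lh, d)
            } else {
                walk <- walkIntervals(geom$attB %% geom$Lh, total - d, 1,
                                      geom$Lh, d)
            }
            for (w in walk)
                pieces[[length(pieces) + 1L]] <-
                    data.frame(frame = "host", start = w[["start"]],
                               end = w[["end"]], strand = w[["strand"]],
                               pathStart = w[["pathStart"]])
        }
    }
    path <- do.call(rbind, pieces)
    path$pathEnd <- path$pathStart + (path$end - path$start)
    # slice the path into k headfuls of exactly H
    segs <- list()
    for (i in seq_len(k)) {
        t0 <- (i - 1) * H; t1 <- i * H
        ov <- path[path$pathEnd > t0 & path$pathStart < t1, , drop = FALSE]
        lo <- pmax(ov$pathStart, t0); hi <- pmin(ov$pathEnd, t1)
        plus <- ov$strand > 0
        s <- ifelse(plus, ov$start + (lo - ov$pathStart),
                          ov$end - (hi - ov$pathStart))
        e <- ifelse(plus, ov$start + (hi - ov$pathStart),
                          ov$end - (lo - ov$pathStart))
        segs[[i]] <- data.frame(
            moleculeId = paste0("S", seriesId, ".", i),
            seriesId = seriesId, headfulIndex = i, origin = origin,
            frame = ov$frame, start = s, end = e,
            strand = ifelse(plus, "+", "-"),
            pathStart = lo, pathEnd = hi, stringsAsFactors = FALSE)
    }
    do.call(rbind, segs)
}

#' Simulate a packaging experiment
#'
#' Draws `nSeries` packaging series: with probability `bgRate` a series
#' instead packages one uniformly random fragment of the circular host
#' (background generalized transduction); otherwise it initiates from an
#' integrated phage copy with probability `fInt`, else from the episomal
#' concatemer.  The first cut falls at pac + Normal(0, pacJitterSd)
#' (truncated at 3 sd); successive headfuls tile the packaging path in steps
#' of exactly H.
#'
#' @param params a [SimParams-class].
#' @param host,phage [ReplicatedGenome-class] references.
#' @param att an [AttSite-class] present in both references.
#' @return a [PackagedMoleculeSet-class]; its `summary()` reports true
#'   phage/host base totals.
#' @export
simulateExperiment <- function(params, host, phage, att) {
    if (!is.na(params@seed)) set.seed(params@seed)
    geom <- packagingGeometry(length(host), length(phage), att, params)
    H <- headfulSize(geom$Lp, params@redundancy)
    n <- params@nSeries
    u <- runif(n)
    isBg <- u < params@bgRate
    isInt <- !isBg & (runif(n) < params@fInt)
    k <- drawSeriesLength(n, params@meanHeadfuls)
    k[isBg] <- 1L
    jit <- rnorm(n, 0, params@pacJitterSd)
    if (params@pacJitterSd > 0) {
        lim <- 3 * params@pacJitterSd
        jit <- pmin(pmax(jit, -lim), lim)
    }
    cut0 <- (geom$pacFwd + round(jit)) %% geom$Lp
    bgStart <- floor(runif(n, 0, geom$Lh))
    segs <- vector("list", n)
    for (i in seq_len(n)) {
        if (isBg[i]) {
            walk <- walkIntervals(bgStart[i], H, 1, geom$Lh, 0)
            rows <- lapply(walk, function(w)
                data.frame(moleculeId = paste0("S", i, ".1"), seriesId = i,
                           headfulIndex = 1L, origin = "background",
                           frame = "host", start = w[["start"]],
                           end = w[["end"]], strand = "+",
                           pathStart = w[["pathStart"]],
                           pathEnd = w[["pathStart"]] +
                               (w[["end"]] - w[["start"]]),
                           stringsAsFactors = FALSE))
            segs[[i]] <- do.call(rbind, rows)
        } else {
            segs[[i]] <- generateSeriesSegments(
                params, if (isInt[i]) "integrated" else "episomal",
                geom, k[i], cut0[i], i)
        }
    }
    segments <- do.call(rbind, segs)
    rownames(segments) <- NULL
    geom$d <- pacJunctionDistance(geom)
    new("PackagedMoleculeSet", segments = segments, headful = H,
        geometry = geom, params = params)
}

#' @describeIn simulateExperiment number of packaged molecules.
#' @param x a PackagedMoleculeSet.
#' @export
setMethod("length", "PackagedMoleculeSet",
          function(x) length(unique(x@segments$moleculeId)))

setMethod("show", "PackagedMoleculeSet", function(object) {
    s <- moleculeSummary(object)
    cat("PackagedMoleculeSet:", s$nMolecules, "molecules in", s$nSeries,
        "series (H =", object@headful, "bp)\n  phage bases:", s$phageBases,
        " host bases:", s$hostBases,
        sprintf(" (host fraction %.4f)\n", s$hostFraction))
})

#' Segment table accessor
#' @param x a [PackagedMoleculeSet-class].
#' @return the segments data.frame.
#' @export
moleculeSegments <- function(x) x@segments

#' True base totals of a simulated experiment
#'
#' @param x a [PackagedMoleculeSet-class].
#' @return list with molecule/series counts, phage/host base totals and the
#'   true host-base fraction.
#' @export
moleculeSummary <- function(x) {
    segs <- x@segments
    len <- segs$end - segs$start
    phage <- sum(len[segs$frame == "phage"])
    hostAll <- sum(len[segs$frame == "host"])
    hostBg <- sum(len[segs$frame == "host" & segs$origin == "background"])
    list(nMolecules = length(unique(segs$moleculeId)),
         nSeries = length(unique(segs$seriesId)),
         phageBases = phage, hostBases = hostAll,
         hostBackgroundBases = hostBg,
         hostFraction = hostAll / (hostAll + phage),
         originCounts = table(segs$origin[!duplicated(segs$moleculeId)]))
}

#' Molecule segments as GRanges
#'
#' @param x a [PackagedMoleculeSet-class].
#' @return a [GenomicRanges::GRanges] on seqnames "host"/"phage" with the
#'   simulation truth in its metadata columns.
#' @export
moleculeGRanges <- function(x) {
    segs <- x@segments
    si <- Seqinfo(seqnames = c("host", "phage"),
                  seqlengths = c(x@geometry$Lh, x@geometry$Lp),
                  isCircular = c(TRUE, TRUE))
    gr <- GRanges(segs$frame,
                  IRanges(start = segs$start + 1L, end = segs$end),
                  strand = segs$strand, seqinfo = si)
    mcols(gr) <- DataFrame(moleculeId = segs$moleculeId,
                           seriesId = segs$seriesId,
                           headfulIndex = segs$headfulIndex,
                           origin = segs$origin)
    gr
}
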