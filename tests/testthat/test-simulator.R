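# Packaging simulator: series-length law, headful tiling across the att
# junction, base conservation, episomal permutation, and read generation.

test_that("series lengths follow the geometric law with mean m", {
    expect_true(all(drawSeriesLength(1000, 1) == 1L))

    set.seed(1)
    k <- drawSeriesLength(1e5, 3)
    expect_true(all(k >= 1L))
    # sample mean within 3 sd of 3 (geometric variance m(m-1))
    expect_lt(abs(mean(k) - 3), 3 * sqrt(3 * 2 / 1e5))
    # tail mass P(k >= 11) = (2/3)^10, within 3 binomial sd
    pTail <- (2 / 3)^10
    expect_lt(abs(mean(k >= 11) - pTail),
              3 * sqrt(pTail * (1 - pTail) / 1e5))
    expect_error(drawSeriesLength(10, 0.5), "m")
})

test_that("a single integrated headful splits into phage d + host H-d", {
    # full-scale geometry: pac 23,500, attP 62,750 (reverse orientation),
    # d = 39,250; H = 71,664 leaves 32,414 bp of host
    trio <- makeFullScaleTrio(seed = 71)
    p <- simParams(redundancy = 0.10, pacPos = 23500L, pacJitterSd = 0,
                   meanHeadfuls = 1, fInt = 1, bgRate = 0, nSeries = 2L,
                   seed = 1L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    expect_equal(mols@geometry$d, 39250)
    expect_equal(mols@headful, 71664L)
    segs <- moleculeSegments(mols)
    one <- segs[segs$moleculeId == segs$moleculeId[1], ]
    expect_equal(sum(one$end - one$start), 71664)
    expect_equal(sum((one$end - one$start)[one$frame == "phage"]), 39250)
    expect_equal(sum((one$end - one$start)[one$frame == "host"]), 32414)
    # host part hugs the left flank of attB (attL side), core included
    hostSeg <- one[one$frame == "host", ]
    expect_equal(max(hostSeg$end), trio$att@attBPos + 17)
})

test_that("later headfuls of an integrated series are pure host", {
    trio <- makeSmallTrio(seed = 72)
    p <- simParams(redundancy = 0.10, pacPos = 5000L, pacJitterSd = 0,
                   meanHeadfuls = 3, fInt = 1, bgRate = 0, nSeries = 30L,
                   seed = 2L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    segs <- moleculeSegments(mols)
    later <- segs[segs$headfulIndex >= 2, ]
    expect_true(all(later$frame == "host"))
    # base conservation: every series totals k * H
    perSeries <- tapply(segs$end - segs$start, segs$seriesId, sum)
    ks <- tapply(segs$headfulIndex, segs$seriesId, max)
    expect_true(all(perSeries == ks * mols@headful))
})

test_that("episomal molecules cover the circle once plus the redundant arc", {
    trio <- makeSmallTrio(seed = 73)
    Lp <- 20000L
    p <- simParams(redundancy = 0.10, pacPos = 5000L, pacJitterSd = 500,
                   meanHeadfuls = 2, fInt = 0, bgRate = 0, nSeries = 20L,
                   seed = 3L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    segs <- moleculeSegments(mols)
    expect_true(all(segs$frame == "phage"))
    for (m in unique(segs$moleculeId)) {
        s <- segs[segs$moleculeId == m, ]
        depth <- integer(Lp)
        for (i in seq_len(nrow(s))) {
            idx <- (s$start[i]:(s$end[i] - 1)) + 1L
            depth[idx] <- depth[idx] + 1L
        }
        expect_true(all(depth >= 1L))
        expect_equal(sum(depth == 2L), mols@headful - Lp)
    }
})

test_that("boundary positions are exactly periodic without jitter", {
    trio <- makeFullScaleTrio(seed = 74)
    p <- simParams(redundancy = 0.10, pacPos = 23500L, pacJitterSd = 0,
                   meanHeadfuls = 4, fInt = 1, bgRate = 0, nSeries = 50L,
                   seed = 4L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    segs <- moleculeSegments(mols)
    host <- segs[segs$frame == "host" & segs$headfulIndex >= 2, ]
    # unwrapped molecules only: one host segment each
    nSeg <- table(host$moleculeId)
    host <- host[host$moleculeId %in% names(nSeg)[nSeg == 1], ]
    expect_gt(nrow(host), 10)
    # flank distance of each molecule boundary from attB+core takes a single
    # value modulo H: boundaries fall exactly at j*H - d
    bnd <- (trio$att@attBPos + 17 - host$start) %% mols@headful
    expect_equal(length(unique(bnd)), 1L)
    expect_equal(unique(bnd) %% mols@headful,
                 (-mols@geometry$d) %% mols@headful)
})

test_that("origin mix and host-base expectation match the closed form", {
    trio <- makeSmallTrio(seed = 75)
    # no integration, no background -> zero host bases
    p0 <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 3,
                    fInt = 0, bgRate = 0, nSeries = 50L, seed = 5L)
    m0 <- simulateExperiment(p0, trio$host, trio$phage, trio$att)
    expect_equal(moleculeSummary(m0)$hostBases, 0)

    # f_int = 1, m = 1: every series is one hybrid molecule
    p1 <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 1,
                    fInt = 1, bgRate = 0, nSeries = 100L, seed = 6L)
    m1 <- simulateExperiment(p1, trio$host, trio$phage, trio$att)
    segs <- moleculeSegments(m1)
    expect_equal(length(unique(segs$moleculeId)), 100L)
    frames <- tapply(segs$frame, segs$moleculeId,
                     function(f) length(unique(f)))
    expect_true(all(frames == 2L))

    # expected host-base fraction: oracle from the closed-form expectation
    # E[host | series] = bg*H + (1-bg)*fInt*(mH - d);
    # E[total | series] = bg*H + (1-bg)*mH
    p2 <- simParams(redundancy = 0.1, pacPos = 5000L, pacJitterSd = 0,
                    meanHeadfuls = 3, fInt = 0.3, bgRate = 0.1,
                    nSeries = 400L, seed = 7L)
    m2 <- simulateExperiment(p2, trio$host, trio$phage, trio$att)
    H <- m2@headful; d <- m2@geometry$d
    fInt <- 0.3; bg <- 0.1; m <- 3
    expHost <- bg * H + (1 - bg) * fInt * (m * H - d)
    segs2 <- moleculeSegments(m2)
    hostPerSeries <- tapply((segs2$end - segs2$start) *
                                (segs2$frame == "host"),
                            segs2$seriesId, sum)
    se <- stats::sd(hostPerSeries) / sqrt(length(hostPerSeries))
    expect_lt(abs(mean(hostPerSeries) - expHost), 3 * se)
})

test_that("error-free reads are exact frame substrings; truth spans junctions", {
    trio <- makeSmallTrio(seed = 76)
    p <- simParams(redundancy = 0.1, pacPos = 5000L, pacJitterSd = 0,
                   meanHeadfuls = 2, fInt = 0.5, bgRate = 0.1,
                   nSeries = 40L, seed = 8L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    reads <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 0.3,
                              errorRate = 0, seed = 9)
    tr <- readTruth(reads)
    all <- readPairs(reads)
    hostChr <- as.character(genomeSeq(trio$host))
    phageChr <- as.character(genomeSeq(trio$phage))
    # single-frame reads: reconstruct from truth intervals and compare
    set.seed(10)
    pick <- sample(unique(tr$readId), 200)
    for (id in pick) {
        rows <- tr[tr$readId == id, ]
        rows <- rows[order(rows$start), ]
        if (length(unique(rows$frame)) > 1) next
        pieces <- vapply(seq_len(nrow(rows)), function(i) {
            s <- if (rows$frame[i] == "host") hostChr else phageChr
            substring(s, rows$start[i] + 1, rows$end[i])
        }, character(1))
        seqTruth <- paste0(pieces, collapse = "")
        obs <- as.character(all[[id]])
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(obs)))
        expect_true(seqTruth == obs || seqTruth == rc)
    }
    # hybrid truth reads exist and cross frames
    hyb <- tr[tr$truthClass == "hybrid-left", ]
    expect_gt(nrow(hyb), 0)
    expect_setequal(unique(tapply(hyb$frame, hyb$readId,
                                  function(f) length(unique(f)))), 2L)
})

test_that("substitution error rate is recovered within 3 sd", {
    trio <- makeSmallTrio(seed = 77, hostLen = 5e4, phageLen = 1e4,
                          attB = 30000L, attP = 5000L)
    p <- simParams(redundancy = 0.1, pacPos = 2000L, meanHeadfuls = 1,
                   fInt = 0, bgRate = 1, nSeries = 60L, seed = 11L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    reads0 <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 1,
                               errorRate = 0, seed = 12)
    reads1 <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 1,
                               errorRate = 0.01, seed = 12)
    s0 <- as.character(readPairs(reads0))
    s1 <- as.character(readPairs(reads1))
    expect_identical(names(s0), names(s1))
    nBases <- sum(nchar(s0))
    expect_gt(nBases, 2e5)
    mism <- sum(vapply(seq_along(s0), function(i) {
        a <- strsplit(s0[i], "")[[1]]; b <- strsplit(s1[i], "")[[1]]
        sum(a != b)
    }, numeric(1)))
    # mutated bases differ from the original with probability 1
    obs <- mism / nBases
    expect_lt(abs(obs - 0.01), 3 * sqrt(0.01 * 0.99 / nBases))
})

test_that("fixed seeds reproduce byte-identical FASTQ output", {
    trio <- makeSmallTrio(seed = 78)
    run <- function() {
        p <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 2,
                       fInt = 0.5, bgRate = 0.1, nSeries = 20L, seed = 13L)
        mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
        moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 0.2,
                         errorRate = 0.005, seed = 14)
    }
    d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
    writeReadPairsFastq(run(), d1)
    writeReadPairsFastq(run(), d2)
    for (s in c("_1.fastq", "_2.fastq"))
        expect_identical(readLines(paste0(d1, s)),
                         readLines(paste0(d2, s)))
})
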