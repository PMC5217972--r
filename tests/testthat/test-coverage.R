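# Coverage profiles and the packaging-model estimators.

test_that("binnedCoverage arithmetic on constructed inputs", {
    cls <- data.frame(readId = "r1", class = "host", refStart = 100,
                      refEnd = 350, phageRefStart = NA, phageRefEnd = NA)
    prof <- binnedCoverage(cls, "host", binSize = 1000L, frameLength = 1000L)
    expect_equal(prof@depth, 0.25)

    empty <- cls[0, ]
    prof0 <- binnedCoverage(empty, "host", binSize = 100L,
                            frameLength = 1000L)
    expect_true(all(prof0@depth == 0))
    expect_equal(length(prof0@depth), 10L)
    expect_error(binnedCoverage(cls, "host", binSize = 0L,
                                frameLength = 1000L), "binSize")
})

test_that("background simulation yields ~1.3X mean depth", {
    # uniform background packaging tuned to the observed floor
    trio <- makeSmallTrio(seed = 91, hostLen = 1e5, phageLen = 2e4,
                          attB = 50000L, attP = 5000L)
    H <- headfulSize(20000, 0.1)
    nSeries <- round(1.3 * 1e5 / H)          # molecule depth ~ n*H/L
    p <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 1,
                   fInt = 0, bgRate = 1, nSeries = nSeries, seed = 20L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    prof <- binnedCoverage(mols, "host", 1000L)
    expect_lt(abs(mean(prof@depth) - 1.3), 0.35)
    bg <- estimateBackground(prof, 45000, 55000)
    expect_lt(abs(bg - 1.3), 0.6)
})

test_that("estimateBackground is the median outside the exclusion zone", {
    depth <- rep(1.3, 100)
    prof <- coverageProfile("host", depth, 1000L, 100000L)
    expect_equal(estimateBackground(prof, 0, 0), 1.3)
    # enrichment confined to the excluded interval does not move it
    depth2 <- depth; depth2[40:60] <- 50
    prof2 <- coverageProfile("host", depth2, 1000L, 100000L)
    expect_equal(estimateBackground(prof2, 35000, 65000), 1.3)
    prof3 <- coverageProfile("host", rep(0, 100), 1000L, 100000L)
    expect_equal(estimateBackground(prof3, 0, 0), 0)
    expect_error(estimateBackground(prof, 0, 100000), "no bins")
})

test_that("flankExtent finds the edge of a step profile", {
    # 10X for 750 kb left of attB at 800 kb, then 1X
    L <- 2e6; bs <- 1000L
    depth <- rep(1, L / bs)
    attB <- 800000
    lo <- (attB - 750000) / bs + 1; hi <- attB / bs
    depth[lo:hi] <- 10
    prof <- coverageProfile("host", depth, bs, as.integer(L))
    expect_equal(flankExtent(prof, attB, "toward_attL", background = 1,
                             thresholdMult = 2), 750000)
    flat <- coverageProfile("host", rep(1, L / bs), bs, as.integer(L))
    expect_equal(flankExtent(flat, attB, "toward_attL", background = 1,
                             thresholdMult = 2), 0)
    # run rule tolerates isolated low bins
    depth3 <- depth; depth3[hi - 100] <- 0.5
    prof3 <- coverageProfile("host", depth3, bs, as.integer(L))
    expect_equal(flankExtent(prof3, attB, "toward_attL", background = 1,
                             thresholdMult = 2), 750000)
})

test_that("headful windows recover the geometric decay and processivity", {
    # geometric profile with ratio 2/3 over windows of width H
    L <- 2e6; bs <- 1000L; H <- 70000; attB <- 1900000
    depth <- rep(0, L / bs)
    centers <- (seq_along(depth) - 0.5) * bs
    dist <- (attB - centers) %% L
    j <- floor(dist / H) + 1
    sel <- j <= 20
    depth[sel] <- 60 * (2 / 3)^(j[sel] - 1)
    prof <- coverageProfile("host", depth, bs, as.integer(L))
    wm <- headfulWindowMeans(prof, attB, "toward_attL", H, nWindows = 12L)
    expect_equal(wm / wm[1], (2 / 3)^(0:11), tolerance = 1e-6)
    # truncated-sum estimator: 3 * (1 - (2/3)^12)
    expect_equal(estimateProcessivity(wm, 0), 3 * (1 - (2 / 3)^12),
                 tolerance = 1e-6)
    # with enough windows the estimator converges to m
    wm40 <- headfulWindowMeans(prof, attB, "toward_attL", H, nWindows = 20L)
    expect_equal(estimateProcessivity(wm40, 0), 3, tolerance = 1e-3)
    # single headful
    expect_equal(estimateProcessivity(c(50, 0, 0, 0), 0), 1)
    expect_error(estimateProcessivity(c(0, 0), 0), "degenerate")

    flat <- coverageProfile("host", rep(2, L / bs), bs, as.integer(L))
    wmFlat <- headfulWindowMeans(flat, attB, "toward_attL", H, 6L)
    expect_true(all(abs(wmFlat - 2) < 1e-9))
})

test_that("detectWavePeriod recovers a synthetic period and ignores noise", {
    L <- 2e6; bs <- 1000L; attB <- 1900000
    centers <- (seq_len(L / bs) - 0.5) * bs
    dist <- (attB - centers) %% L
    depth <- 5 + 2 * cos(2 * pi * dist / 72000)
    prof <- coverageProfile("host", depth, bs, as.integer(L))
    res <- detectWavePeriod(prof, attB, "toward_attL")
    expect_true(res$detected)
    expect_equal(res$period, 72000, tolerance = 0.02)

    # white noise carries no periodicity: across seeds, any nominal
    # detection sits at the threshold, far below the true signal's peak
    sig <- res$lagAcf[[as.character(round(res$period / 1000) * 1000)]]
    expect_gt(sig, 0.5)
    for (s in 21:25) {
        set.seed(s)
        noise <- coverageProfile("host", rexp(L / bs, 1), bs, as.integer(L))
        resN <- detectWavePeriod(noise, attB, "toward_attL")
        if (resN$detected)
            expect_lt(max(resN$lagAcf), 0.15)
    }
    flat <- coverageProfile("host", rep(3, L / bs), bs, as.integer(L))
    expect_false(detectWavePeriod(flat, attB, "toward_attL")$detected)
})

test_that("estimateRedundancy inverts the headful relation", {
    expect_equal(estimateRedundancy(71664, 65149), 0.1, tolerance = 1e-3)
    expect_equal(estimateRedundancy(65149, 65149), 0)
    expect_equal(estimateRedundancy(72000, 65000), 7000 / 65000)
    # identity on r over [0, 0.3]
    for (r in seq(0, 0.3, by = 0.05)) {
        H <- 65149 * (1 + r)
        expect_equal(estimateRedundancy(H, 65149), r, tolerance = 1e-12)
    }
    expect_warning(estimateRedundancy(60000, 65149), "r < 0")
})

test_that("estimatePacPosition finds peak and onset; flags flat profiles", {
    # sawtooth peaking in bin 23 of 65
    depth <- c(seq(1, 23), seq(22, 1, length.out = 42))
    prof <- coverageProfile("phage", depth, 1000L, 65000L)
    e <- estimatePacPosition(prof)
    expect_true(e$defined)
    expect_lt(abs(e$peak - 22500), 1600)     # within ~1 smoothing bin
    expect_equal(e$downSlope, -1)

    flat <- coverageProfile("phage", rep(4, 65), 1000L, 65000L)
    expect_false(estimatePacPosition(flat)$defined)
})

test_that("pac position is recovered from episomal simulations", {
    trio <- makeFullScaleTrio(seed = 92, hostLen = 2e5, attB = 150000L)
    errs <- c()
    for (s in 1:10) {
        p <- simParams(redundancy = 0.10, pacPos = 23500L,
                       pacJitterSd = 1000, meanHeadfuls = 3, fInt = 0,
                       bgRate = 0, nSeries = 1200L, seed = 100L + s)
        mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
        prof <- binnedCoverage(mols, "phage", 1000L)
        e <- estimatePacPosition(prof)
        errs <- c(errs, abs(e$pacPos - 23500))
    }
    expect_true(all(errs <= 3000))
})

test_that("directionality test matches the exact binomial", {
    d56 <- directionalityTest(56, 0)
    expect_equal(d56$direction, "left")
    expect_equal(d56$pValue, 2 * 0.5^56, tolerance = 1e-12)
    d6 <- directionalityTest(6, 0)
    expect_equal(d6$pValue, 0.03125)
    d55 <- directionalityTest(5, 5)
    expect_equal(d55$direction, "none")
    expect_equal(d55$pValue, 1)
    expect_equal(directionalityTest(0, 0)$direction, "none")
})

test_that("estimates are invariant under host coordinate rotation", {
    trio <- makeSmallTrio(seed = 93)
    p <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 2,
                   fInt = 0.7, bgRate = 0.1, nSeries = 150L, seed = 22L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    reads <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 0.3,
                              errorRate = 0, seed = 23)
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    cls <- classifyReads(reads, idx, trio$att)
    L <- 200000
    shift <- 40000
    clsRot <- cls
    isHost <- cls$frame %in% "host" & !is.na(cls$refStart)
    clsRot$refStart[isHost] <- (cls$refStart[isHost] + shift) %% L
    clsRot$refEnd[isHost] <- clsRot$refStart[isHost] +
        (cls$refEnd[isHost] - cls$refStart[isHost])
    attB <- trio$att@attBPos
    p1 <- binnedCoverage(cls, "host", 1000L, frameLength = L)
    p2 <- binnedCoverage(clsRot, "host", 1000L, frameLength = L)
    bg1 <- estimateBackground(p1, (attB - 6e4) %% L, (attB + 6e4) %% L)
    bg2 <- estimateBackground(p2, (attB + shift - 6e4) %% L,
                              (attB + shift + 6e4) %% L)
    expect_equal(bg1, bg2)
    expect_equal(
        flankExtent(p1, attB, "toward_attL", bg1),
        flankExtent(p2, (attB + shift) %% L, "toward_attL", bg2))
    expect_equal(
        headfulWindowMeans(p1, attB, "toward_attL", 22000, 4L),
        headfulWindowMeans(p2, (attB + shift) %% L, "toward_attL",
                           22000, 4L))
})
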