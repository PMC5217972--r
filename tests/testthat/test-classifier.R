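# k-mer index, seed mapping, origin classification and hybrid junction
# detection.

test_that("kmer index stores and retrieves canonical k-mers", {
    trio <- makeSmallTrio(seed = 81)
    expect_error(kmerIndex(list(host = trio$host, phage = trio$phage),
                           k = 9), "k < 11")
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    phageChr <- as.character(genomeSeq(trio$phage))
    km <- substring(phageChr, 1001, 1031)
    hits <- queryKmers(idx, km)
    expect_true(any(hits$ref == "phage" & hits$pos == 1000 &
                    hits$strand == "+"))
    # reverse complement: same position, opposite strand
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(km)))
    hitsRc <- queryKmers(idx, rc)
    expect_true(any(hitsRc$ref == "phage" & hitsRc$pos == 1000 &
                    hitsRc$strand == "-"))
    # absent k-mer
    expect_equal(nrow(queryKmers(idx, paste(rep("A", 31), collapse = ""))),
                 0L)
})

test_that("mapReads places exact substrings and rejects noise", {
    trio <- makeSmallTrio(seed = 82)
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    hostChr <- as.character(genomeSeq(trio$host))
    reads <- c(r1 = substring(hostChr, 5001, 5250))
    aln <- mapReads(reads, idx)
    expect_equal(nrow(aln), 1L)
    expect_equal(aln$frame, "host")
    expect_equal(aln$matched, 250L)
    expect_equal(aln$refStart, 5000)
    expect_equal(aln$refEnd, 5250)

    set.seed(1)
    noise <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
    expect_equal(nrow(mapReads(c(n = noise), idx)), 0L)
})

test_that("a read straddling attL aligns in both frames", {
    trio <- makeSmallTrio(seed = 83)
    lys <- buildLysogen(trio$host, trio$phage, trio$att)
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    lysChr <- as.character(genomeSeq(lys))
    # 60 bp host + 17 bp core + 60 bp phage around attL
    read <- substring(lysChr, lys@attLPos - 59, lys@attLPos + 17 + 60)
    aln <- mapReads(c(j = read), idx)
    expect_setequal(aln$frame, c("host", "phage"))
    expect_true(all(aln$matched >= 60 + 17))
})

test_that("classification rules: hybrid sides, intact attP, thresholds", {
    trio <- makeSmallTrio(seed = 84)
    lys <- buildLysogen(trio$host, trio$phage, trio$att)
    lysChr <- as.character(genomeSeq(lys))
    phageChr <- as.character(genomeSeq(trio$phage))
    hostChr <- as.character(genomeSeq(trio$host))
    attL <- lys@attLPos; attR <- lys@attRPos
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)

    reads <- c(
        hybL = substring(lysChr, attL - 49, attL + 17 + 50),   # 50 host | core | 50 phage
        hybR = substring(lysChr, attR - 49, attR + 17 + 50),   # 50 phage | core | 50 host
        attP = substring(phageChr, trio$att@attPPos - 99,
                         trio$att@attPPos + 17 + 100),          # intact attP
        attB = substring(hostChr, trio$att@attBPos - 99,
                         trio$att@attBPos + 17 + 100),          # intact attB
        shortAnchor = substring(lysChr, attL - 9, attL + 17 + 200))
    cls <- classifyReads(reads, idx, trio$att, minAnchor = 20)
    got <- setNames(cls$class, cls$readId)
    expect_equal(got[["hybL"]], "hybrid-left")
    expect_equal(got[["hybR"]], "hybrid-right")
    expect_equal(got[["attP"]], "phage")
    expect_equal(got[["attB"]], "host")
    # 10 bp host + core + 200 bp phage: junction evidence without a
    # sufficient second anchor
    expect_equal(got[["shortAnchor"]], "ambiguous")

    # with a smaller k the host-side alignment exists and the anchor rule
    # itself (10 < 20) produces the same call
    idx21 <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 21)
    cls21 <- classifyReads(reads["shortAnchor"], idx21, trio$att,
                           minAnchor = 20)
    expect_equal(cls21$class, "ambiguous")
})

test_that("classification is perfect against simulator truth", {
    trio <- makeSmallTrio(seed = 85)
    p <- simParams(redundancy = 0.1, pacPos = 5000L, pacJitterSd = 500,
                   meanHeadfuls = 2, fInt = 0.6, bgRate = 0.1,
                   nSeries = 60L, seed = 15L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    reads <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 0.4,
                              errorRate = 0, seed = 16)
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    cls <- classifyReads(reads, idx, trio$att, minAnchor = 20)
    m <- merge(truthPerRead(reads), cls[, c("readId", "class")],
               by = "readId")
    # reads whose truth anchors satisfy the rule must be called exactly
    pass <- (m$truthClass %in% c("host", "phage")) |
        (m$hostAnchor >= 20 & m$phageAnchor >= 20)
    expect_gt(sum(pass & grepl("hybrid", m$truthClass)), 5)
    expect_identical(m$class[pass], m$truthClass[pass])
    # and every anchored hybrid-left truth read is called hybrid-left
    hl <- m$truthClass == "hybrid-left" & m$hostAnchor >= 20 &
        m$phageAnchor >= 20
    expect_true(all(m$class[hl] == "hybrid-left"))
})

test_that("class counts are invariant under read order permutation", {
    trio <- makeSmallTrio(seed = 86)
    p <- simParams(redundancy = 0.1, pacPos = 5000L, meanHeadfuls = 2,
                   fInt = 0.5, bgRate = 0.1, nSeries = 20L, seed = 17L)
    mols <- simulateExperiment(p, trio$host, trio$phage, trio$att)
    reads <- moleculesToReads(mols, trio$host, trio$phage, pairsPerKb = 0.2,
                              errorRate = 0, seed = 18)
    idx <- kmerIndex(list(host = trio$host, phage = trio$phage), k = 31)
    all <- readPairs(reads)
    set.seed(19)
    perm <- sample(length(all))
    c1 <- summarizeClasses(classifyReads(all, idx, trio$att))
    c2 <- summarizeClasses(classifyReads(all[perm], idx, trio$att))
    expect_identical(c1$counts, c2$counts)
})

test_that("summarizeClasses reproduces the printed study fractions", {
    mk <- function(host, other) data.frame(
        class = rep(c("host", "phage"), c(host, other)))
    s1 <- summarizeClasses(mk(7844, 1276664))
    expect_equal(s1$percentLabels[["host"]], "0.6%")
    s2 <- summarizeClasses(mk(81578, 3587200))
    expect_equal(s2$percentLabels[["host"]], "2.2%")
    s3 <- summarizeClasses(data.frame(class = rep("phage", 10)))
    expect_equal(s3$percentLabels[["phage"]], "100.0%")
    expect_equal(sum(s3$counts), s3$total)
    s0 <- summarizeClasses(data.frame(class = character()))
    expect_true(all(is.na(s0$fractions)))
    expect_match(s0$note, "empty")
})
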