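# Paired-end read generation from packaged molecules.  Fragments are drawn
# along each molecule's packaging path; sequence is extracted piecewise from
# the reference frames (reverse-complementing pieces walked in the minus
# direction), so molecule sequences are never materialised.

#' Generate paired-end reads from packaged molecules
#'
#' Fragments are placed uniformly along each molecule with
#' Normal(`fragmentMean`, `fragmentSd`) lengths truncated to
#' [`readLength`, molecule length]; the expected number of fragments per
#' molecule is `pairsPerKb` per kilobase of molecule.  Mates are the two
#' fragment ends, the inner mate reverse-complemented; substitution errors
#' are applied at `errorRate`; qualities are constant Phred 40.
#'
#' @param molecules a [PackagedMoleculeSet-class].
#' @param host,phage the [ReplicatedGenome-class] references used to
#'   simulate them.
#' @param pairsPerKb expected read pairs per kb of packaged molecule.
#' @param fragmentMean,fragmentSd fragment length distribution (bp).
#' @param readLength read length (bp).
#' @param errorRate per-base substitution error rate.
#' @param seed optional RNG seed.
#' @return a [ReadPairSet-class] with per-read truth.
#' @export
moleculesToReads <- function(molecules, host, phage, pairsPerKb = 0.05,
                             fragmentMean = 900, fragmentSd = 100,
                             readLength = 250L, errorRate = 0,
                             seed = NULL) {
    if (readLength <= 0) stop("readLength must be > 0")
    if (errorRate < 0 || pairsPerKb < 0) stop("rates must be >= 0")
    if (readLength > fragmentMean) stop("readLength must be <= fragmentMean")
    if (!is.null(seed)) set.seed(seed)
    readLength <- as.integer(readLength)

    segs <- molecules@segments
    molId <- unique(segs$moleculeId)
    molLen <- tapply(segs$end - segs$start, segs$moleculeId, sum)[molId]
    nFrag <- rpois(length(molId), molLen / 1000 * pairsPerKb)
    N <- sum(nFrag)
    if (N == 0L)
        return(new("ReadPairSet", mate1 = DNAStringSet(), mate2 = DNAStringSet(),
                   truth = data.frame(), readLength = readLength))
    fragMol <- rep.int(seq_along(molId), nFrag)
    fl <- pmax(readLength, pmin(round(rnorm(N, fragmentMean, fragmentSd)),
                                molLen[fragMol]))
    fs <- floor(runif(N) * (molLen[fragMol] - fl + 1))  # path offset in molecule

    # map fragments onto segment rows of their molecule
    segRowsByMol <- split(seq_len(nrow(segs)), segs$moleculeId)[molId]
    nSegPerFrag <- lengths(segRowsByMol)[fragMol]
    fragRow <- rep.int(seq_len(N), nSegPerFrag)
    segRow <- unlist(segRowsByMol[fragMol], use.names = FALSE)
    # molecule path offsets are global along the series; shift to per-molecule
    molPath0 <- tapply(segs$pathStart, segs$moleculeId, min)[molId]
    p0 <- segs$pathStart[segRow] - molPath0[fragMol][fragRow]
    p1 <- segs$pathEnd[segRow] - molPath0[fragMol][fragRow]
    lo <- pmax(fs[fragRow], p0)
    hi <- pmin(fs[fragRow] + fl[fragRow], p1)
    keep <- hi > lo
    fragRow <- fragRow[keep]; segRow <- segRow[keep]
    lo <- lo[keep]; hi <- hi[keep]; p0 <- p0[keep]

    plus <- segs$strand[segRow] == "+"
    a <- ifelse(plus, segs$start[segRow] + (lo - p0),
                      segs$end[segRow] - (hi - p0))
    b <- ifelse(plus, segs$start[segRow] + (hi - p0),
                      segs$end[segRow] - (lo - p0))
    frames <- segs$frame[segRow]
    hostChr <- as.character(host@sequence)
    phageChr <- as.character(phage@sequence)
    piece <- character(length(a))
    isH <- frames == "host"
    if (any(isH)) piece[isH] <- substring(hostChr, a[isH] + 1, b[isH])
    if (any(!isH)) piece[!isH] <- substring(phageChr, a[!isH] + 1, b[!isH])
    if (any(!plus))
        piece[!plus] <- as.character(
            reverseComplement(DNAStringSet(piece[!plus])))

    # assemble fragments in path order
    ord <- order(fragRow, lo)
    fragSeq <- vapply(split(piece[ord], fragRow[ord]), paste0,
                      character(1), collapse = "")
    fragSeq <- fragSeq[as.character(seq_len(N))]

    ids <- sprintf("%s_frag%06d", molId[fragMol], seq_len(N))
    m1 <- substr(fragSeq, 1L, readLength)
    m2 <- as.character(reverseComplement(DNAStringSet(
        substr(fragSeq, fl - readLength + 1L, fl))))
    if (errorRate > 0) {
        m1 <- injectSubstitutions(m1, errorRate)
        m2 <- injectSubstitutions(m2, errorRate)
    }
    mate1 <- DNAStringSet(m1); names(mate1) <- paste0(ids, "/1")
    mate2 <- DNAStringSet(m2); names(mate2) <- paste0(ids, "/2")

    truth <- buildReadTruth(molecules, ids, molId[fragMol], fs, fl,
                            readLength)
    new("ReadPairSet", mate1 = mate1, mate2 = mate2, truth = truth,
        readLength = readLength)
}

# substitution errors: each base mutated independently with rate e
injectSubstitutions <- function(reads, e) {
    n <- nchar(reads)
    nerr <- rbinom(length(reads), n, e)
    idx <- which(nerr > 0)
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
        s <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(n[i], nerr[i])
        for (p in pos) {
            s[p] <- sample(setdiff(bases, s[p]), 1)
        }
        reads[i] <- paste0(s, collapse = "")
    }
    reads
}

# per-mate truth: source intervals in reference frames plus a truth class
# and junction anchors, derived from the molecule's path description.
# Fully vectorised: one expansion of (mate x overlapping segment) rows.
buildReadTruth <- function(molecules, ids, fragMolId, fs, fl, readLength) {
    segs <- molecules@segments
    geom <- molecules@geometry
    coreLen <- geom$coreLen
    N <- length(ids)
    # 2N mate intervals in per-molecule path coordinates
    mateId <- c(paste0(ids, "/1"), paste0(ids, "/2"))
    mateMol <- c(fragMolId, fragMolId)
    mLo <- c(fs, fs + fl - readLength)
    mHi <- c(fs + readLength, fs + fl)

    molId <- unique(segs$moleculeId)
    segRowsByMol <- split(seq_len(nrow(segs)), segs$moleculeId)[molId]
    molPath0 <- tapply(segs$pathStart, segs$moleculeId, min)[molId]
    molIdx <- match(mateMol, molId)
    nSeg <- lengths(segRowsByMol)[molIdx]
    mateRow <- rep.int(seq_along(mateId), nSeg)
    segRow <- unlist(segRowsByMol[molIdx], use.names = FALSE)
    p0 <- segs$pathStart[segRow] - molPath0[molIdx][mateRow]
    p1 <- segs$pathEnd[segRow] - molPath0[molIdx][mateRow]
    lo <- pmax(mLo[mateRow], p0)
    hi <- pmin(mHi[mateRow], p1)
    keep <- hi > lo
    mateRow <- mateRow[keep]; segRow <- segRow[keep]
    lo <- lo[keep]; hi <- hi[keep]; p0 <- p0[keep]

    plus <- segs$strand[segRow] == "+"
    a <- ifelse(plus, segs$start[segRow] + (lo - p0),
                      segs$end[segRow] - (hi - p0))
    b <- ifelse(plus, segs$start[segRow] + (hi - p0),
                      segs$end[segRow] - (lo - p0))
    fr <- segs$frame[segRow]
    isHost <- fr == "host"
    # per-mate aggregates
    hostLen <- rowsum((b - a) * isHost, mateRow)
    phageLen <- rowsum((b - a) * !isHost, mateRow)
    coreOv <- rowsum(pmax(0, pmin(b, geom$attB + coreLen) -
                              pmax(a, geom$attB)) * isHost, mateRow)
    mateKey <- as.integer(rownames(hostLen))
    hl <- phl <- cov <- numeric(length(mateId))
    hl[mateKey] <- hostLen[, 1]
    phl[mateKey] <- phageLen[, 1]
    cov[mateKey] <- coreOv[, 1]
    hybridClass <- if (geom$direction == "toward_attL") "hybrid-left"
                   else "hybrid-right"
    cls <- ifelse(hl > 0 & phl > 0, hybridClass,
                  ifelse(hl > 0, "host", "phage"))
    data.frame(readId = mateId[mateRow], moleculeId = mateMol[mateRow],
               frame = fr, start = a, end = b,
               strand = segs$strand[segRow],
               truthClass = cls[mateRow],
               hostAnchor = (hl - cov)[mateRow],
               phageAnchor = phl[mateRow],
               stringsAsFactors = FALSE)
}

#' @describeIn moleculesToReads number of read pairs.
#' @param x a ReadPairSet.
#' @export
setMethod("length", "ReadPairSet", function(x) length(x@mate1))

setMethod("show", "ReadPairSet", function(object) {
    cat("ReadPairSet:", length(object@mate1), "pairs,",
        object@readLength, "bp reads\n")
})

#' Read accessors
#' @param x a [ReadPairSet-class].
#' @param interleave return a single interleaved set.
#' @return a [Biostrings::DNAStringSet].
#' @export
readPairs <- function(x, interleave = TRUE) {
    if (!interleave) return(list(mate1 = x@mate1, mate2 = x@mate2))
    out <- c(x@mate1, x@mate2)
    out[order(rep(seq_along(x@mate1), 2))]
}

#' Truth table accessor
#' @param x a [ReadPairSet-class].
#' @return data.frame of per-read truth intervals and classes.
#' @export
readTruth <- function(x) x@truth
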