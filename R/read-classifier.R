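# Read classification against the host and phage reference frames by exact
# k-mer seeding with ungapped verification, and hybrid attP/B junction
# calling.

#' Build a canonical k-mer index over the reference frames
#'
#' Every reference-position k-mer (canonicalised as the lexicographic
#' minimum of the strand pair) is indexed; circular references include the
#' origin-spanning k-mers.
#'
#' @param references named list of [ReplicatedGenome-class] objects or a
#'   named character vector of sequences.  For classification the names
#'   must include `"host"` and `"phage"`.
#' @param k k-mer size; values below 11 are rejected (too many spurious
#'   matches).
#' @return a [KmerIndex-class].
#' @export
kmerIndex <- function(references, k = 31L) {
    k <- as.integer(k)
    if (k < 11L) stop("k < 11 rejected (spurious matches)")
    if (is.list(references)) {
        seqs <- vapply(references, function(g) as.character(genomeSeq(g)),
                       character(1))
        circ <- vapply(references, function(g) g@topology == "circular",
                       logical(1))
    } else {
        seqs <- as.character(references)
        circ <- rep(TRUE, length(seqs))
    }
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("references must be named")
    if (any(nchar(seqs) < k)) stop("k exceeds the shortest reference")
    ptr <- .kmerIndexBuild(unname(seqs), unname(circ), k)
    new("KmerIndex", ptr = ptr, refNames = names(seqs),
        refLengths = as.integer(nchar(seqs)), circular = unname(circ),
        k = k)
}

setMethod("show", "KmerIndex", function(object) {
    cat("KmerIndex: k =", object@k, "over",
        paste0(object@refNames, " (", object@refLengths, " bp)",
               collapse = ", "), "\n")
})

#' Query raw k-mers against the index
#'
#' @param index a [KmerIndex-class].
#' @param kmers character vector of k-mers (length k each).
#' @return data.frame with columns query, ref, pos (0-based), strand.
#' @export
queryKmers <- function(index, kmers) {
    hits <- .kmerIndexQuery(index@ptr, kmers)
    hits$ref <- index@refNames[hits$ref]
    hits
}

#' Map reads by exact k-mer seeding and ungapped extension
#'
#' Seeds are collected at a fixed stride, grouped per (frame, strand,
#' diagonal), and each candidate placement is verified base-by-base; the
#' reported alignment is the longest contiguous match run (chained across
#' isolated single mismatches).  Reads without any seed hit are absent from
#' the output (unmapped).
#'
#' @param reads a [Biostrings::DNAStringSet] (named) or character vector.
#' @param index a [KmerIndex-class].
#' @param stride seed spacing in bp.
#' @param maxPlacements placements verified per read.
#' @return data.frame: readId, frame, strand, refStart, refEnd (0-based
#'   half-open; refEnd may exceed the frame length when a circular
#'   alignment wraps), readStart, readEnd, matched, nseeds.
#' @export
mapReads <- function(reads, index, stride = 6L, maxPlacements = 8L) {
    nm <- names(reads)
    seqs <- as.character(reads)
    if (is.null(nm)) nm <- as.character(seq_along(seqs))
    aln <- .mapReadsCpp(index@ptr, unname(seqs), as.integer(stride),
                        as.integer(maxPlacements))
    data.frame(readId = nm[aln$read], frame = index@refNames[aln$ref],
               strand = aln$strand, refStart = aln$ref_start,
               refEnd = aln$ref_end, readStart = aln$read_start,
               readEnd = aln$read_end, matched = aln$matched,
               nseeds = aln$nseeds, stringsAsFactors = FALSE)
}

# interval overlap helper (scalar-vectorised)
.ovl <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Classify reads by origin
#'
#' Applies the origin rules to per-read best alignments in each frame:
#' \itemize{
#'   \item \strong{hybrid-left / hybrid-right}: host and phage anchors (both
#'     computed excluding the att core, which is identical in all frames)
#'     each at least `minAnchor`, on opposite sides of the core; the side is
#'     the host flank carrying the host anchor.
#'   \item \strong{phage}: phage-frame alignment only (a read containing the
#'     intact attP with phage on both sides is phage, not hybrid).
#'   \item \strong{host}: host-frame alignment only.
#'   \item \strong{ambiguous}: anchors below `minAnchor`, equal-best
#'     placements in both frames, or an alignment that stops at the att core
#'     with an unexplained terminus (a junction read whose second anchor is
#'     too short).
#'   \item \strong{unmapped}: no alignment.
#' }
#'
#' @param x reads ([Biostrings::DNAStringSet] / [ReadPairSet-class]) or a
#'   precomputed alignment data.frame in the [mapReads()] layout (e.g. from
#'   [readSamAlignments()]).
#' @param index a [KmerIndex-class] (required when `x` holds reads).
#' @param att the [AttSite-class] shared by the references.
#' @param minAnchor minimum informative anchor (bp) outside the core on each
#'   side of a junction.
#' @param readLengths named vector of read lengths; taken from the reads
#'   when available (needed only for alignment-frame input).
#' @return data.frame with one row per read: readId, class, frame, refStart,
#'   refEnd, strand, matched, hostAnchor, phageAnchor, junctionPosHost.
#' @export
classifyReads <- function(x, index = NULL, att, minAnchor = 20L,
                          readLengths = NULL) {
    if (is(x, "ReadPairSet")) {
        reads <- readPairs(x, interleave = TRUE)
        return(classifyReads(reads, index, att, minAnchor))
    }
    if (is(x, "DNAStringSet") || is.character(x)) {
        if (is.null(index)) stop("an index is required to map reads")
        aln <- mapReads(x, index)
        readLengths <- setNames(nchar(as.character(x)), names(x))
        allIds <- names(x)
    } else {
        aln <- x
        if (is.null(readLengths))
            readLengths <- setNames(aln$readEnd + 0, aln$readId) # lower bound
        allIds <- unique(c(aln$readId, names(readLengths)))
    }
    classifyFromAlignments(aln, allIds, readLengths, att, minAnchor)
}

classifyFromAlignments <- function(aln, allIds, readLengths, att,
                                   minAnchor) {
    c <- nchar(att@core)
    attB <- att@attBPos; attP <- att@attPPos
    out <- data.frame(readId = allIds, class = "unmapped",
                      frame = NA_character_, refStart = NA_real_,
                      refEnd = NA_real_, strand = NA_character_,
                      matched = 0, hostAnchor = 0, phageAnchor = 0,
                      junctionPosHost = NA_real_, stringsAsFactors = FALSE)
    if (nrow(aln) == 0L) return(out)

    # best alignment per read per frame
    ord <- order(aln$readId, aln$frame, -aln$matched)
    aln <- aln[ord, ]
    first <- !duplicated(paste(aln$readId, aln$frame))
    best <- aln[first, ]

    h <- best[best$frame == "host", ]
    p <- best[best$frame == "phage", ]
    hi <- match(allIds, h$readId)
    pi <- match(allIds, p$readId)

    n <- length(allIds)
    hs <- h$refStart[hi]; he <- h$refEnd[hi]
    ps <- p$refStart[pi]; pe <- p$refEnd[pi]
    hm <- ifelse(is.na(hi), 0, h$matched[hi])
    pm <- ifelse(is.na(pi), 0, p$matched[pi])

    hostCoreOv <- ifelse(is.na(hi), 0, .ovl(hs, he, attB, attB + c))
    phageCoreOv <- ifelse(is.na(pi), 0, .ovl(ps, pe, attP, attP + c))
    hostLeft <- ifelse(is.na(hi), 0, pmax(0, pmin(he, attB) - hs))
    hostRight <- ifelse(is.na(hi), 0, pmax(0, he - pmax(hs, attB + c)))
    hostAnchor <- hostLeft + hostRight
    phageAnchor <- ifelse(is.na(pi), 0, (pe - ps) - phageCoreOv)

    # read-coordinate intervals of the two placements must not overlap much
    # beyond the shared core for a consistent junction geometry
    hrs <- h$readStart[hi]; hre <- h$readEnd[hi]
    prs <- p$readStart[pi]; pre <- p$readEnd[pi]
    readOv <- ifelse(is.na(hi) | is.na(pi), 0, .ovl(hrs, hre, prs, pre))

    isHybrid <- !is.na(hi) & !is.na(pi) &
        hostAnchor >= minAnchor & phageAnchor >= minAnchor &
        hostCoreOv > 0 & phageCoreOv > 0 & readOv <= c + 6
    side <- ifelse(hostLeft >= hostRight, "hybrid-left", "hybrid-right")

    # junction reads whose second anchor failed: both frames hit but not a
    # clean hybrid -> ambiguous; ties between frames -> ambiguous
    bothFrames <- !is.na(hi) & !is.na(pi)
    ambiguous <- bothFrames & !isHybrid

    # single-frame alignment that stops at the att core with an unexplained
    # read terminus: junction evidence without a second anchor
    hangs <- function(s, e, reS, reE, strand, coreS, coreE, len, coreOv) {
        !is.na(s) & coreOv >= c - 1 &
            ((abs(s - coreS) <= 2 & ifelse(strand == "+", reS, len - reE) >= 4 &
                  ifelse(strand == "+", reS, len - reE) < minAnchor + c) |
             (abs(e - coreE) <= 2 & ifelse(strand == "+", len - reE, reS) >= 4 &
                  ifelse(strand == "+", len - reE, reS) < minAnchor + c))
    }
    lenAll <- readLengths[allIds]
    phageHang <- hangs(ps, pe, prs, pre, p$strand[pi], attP, attP + c,
                       lenAll, phageCoreOv) & is.na(hi)
    hostHang <- hangs(hs, he, hrs, hre, h$strand[hi], attB, attB + c,
                      lenAll, hostCoreOv) & is.na(pi)

    cls <- rep("unmapped", n)
    cls[!is.na(hi) & is.na(pi)] <- "host"
    cls[is.na(hi) & !is.na(pi)] <- "phage"
    cls[phageHang | hostHang] <- "ambiguous"
    cls[ambiguous] <- "ambiguous"
    cls[isHybrid] <- side[isHybrid]

    useHost <- cls %in% c("host", "hybrid-left", "hybrid-right")
    out$class <- cls
    out$frame <- ifelse(useHost, "host", ifelse(cls == "phage", "phage", NA))
    out$refStart <- ifelse(useHost, hs, ifelse(cls == "phage", ps, NA))
    out$refEnd <- ifelse(useHost, he, ifelse(cls == "phage", pe, NA))
    out$strand <- ifelse(useHost, h$strand[hi],
                         ifelse(cls == "phage", p$strand[pi], NA))
    out$matched <- ifelse(useHost, hm, ifelse(cls == "phage", pm, 0))
    out$hostAnchor <- hostAnchor
    out$phageAnchor <- phageAnchor
    out$junctionPosHost <- ifelse(grepl("^hybrid", cls),
                                  ifelse(side == "hybrid-left", attB,
                                         attB + c), NA)
    # phage-frame interval of hybrids, for phage-frame coverage
    out$phageRefStart <- ifelse(grepl("^hybrid", cls), ps, NA)
    out$phageRefEnd <- ifelse(grepl("^hybrid", cls), pe, NA)
    out
}

#' Summarise classified reads
#'
#' @param classified data.frame from [classifyReads()].
#' @return list with `counts` (named, all classes), `fractions`,
#'   `percentLabels` (percentages rounded to one decimal) and `total`.
#' @export
summarizeClasses <- function(classified) {
    levs <- c("phage", "host", "hybrid-left", "hybrid-right", "ambiguous",
              "unmapped")
    counts <- table(factor(classified$class, levels = levs))
    total <- sum(counts)
    if (total == 0L)
        return(list(counts = setNames(rep(0L, length(levs)), levs),
                    fractions = setNames(rep(NA_real_, length(levs)), levs),
                    percentLabels = NULL, total = 0L,
                    note = "empty input: fractions undefined"))
    fr <- as.numeric(counts) / total
    list(counts = setNames(as.integer(counts), levs),
         fractions = setNames(fr, levs),
         percentLabels = setNames(sprintf("%.1f%%", 100 * fr), levs),
         total = total)
}
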