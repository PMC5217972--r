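# Construction of the three coordinate frames (host, phage, lysogen) around
# a shared att core, and the mappings between them.

#' Construct a ReplicatedGenome
#'
#' @param sequence character or [Biostrings::DNAString].
#' @param name identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return a [ReplicatedGenome-class].
#' @export
replicatedGenome <- function(sequence, name = "genome",
                             topology = c("circular", "linear")) {
    topology <- match.arg(topology)
    if (is.character(sequence)) sequence <- DNAString(sequence)
    new("ReplicatedGenome", name = name, sequence = sequence,
        topology = topology)
}

#' @describeIn replicatedGenome sequence length in bp.
#' @param x a ReplicatedGenome.
#' @export
setMethod("length", "ReplicatedGenome", function(x) length(x@sequence))

#' Genome sequence accessor
#' @param x a ReplicatedGenome or LysogenMap.
#' @return a [Biostrings::DNAString].
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname genomeSeq
#' @export
setMethod("genomeSeq", "ReplicatedGenome", function(x) x@sequence)

#' @rdname genomeSeq
#' @export
setMethod("genomeSeq", "LysogenMap", function(x) x@sequence)

setMethod("show", "ReplicatedGenome", function(object) {
    cat("ReplicatedGenome '", object@name, "': ", length(object@sequence),
        " bp, ", object@topology, "\n", sep = "")
})

setMethod("show", "AttSite", function(object) {
    cat("AttSite: ", object@core, " (", nchar(object@core), " bp)\n",
        "  attB @ ", object@attBPos, "  attP @ ", object@attPPos,
        "  orientation: ", object@orientation, "\n", sep = "")
})

setMethod("show", "LysogenMap", function(object) {
    cat("LysogenMap: ", length(object@sequence), " bp (host ",
        object@hostLength, " + phage ", object@phageLength, ")\n",
        "  attL @ ", object@attLPos, "  attR @ ", object@attRPos,
        "  orientation: ", object@orientation, "\n", sep = "")
})

#' Construct an AttSite
#'
#' @param core core sequence (character, >= 8 bp).
#' @param attBPos,attPPos 0-based core start in host / phage frame.  With
#'   `orientation = "reverse"` the phage reference carries the reverse
#'   complement of `core` at `attPPos`.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an [AttSite-class].
#' @export
attSite <- function(core, attBPos, attPPos,
                    orientation = c("forward", "reverse")) {
    new("AttSite", core = as.character(core), attBPos = as.integer(attBPos),
        attPPos = as.integer(attPPos), orientation = match.arg(orientation))
}

#' Generate a random genome with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2.  Used as a stand-in for
#' real host/phage sequences in simulations.
#'
#' @param length genome length in bp (>= 1).
#' @param gc target GC fraction in [0, 1].
#' @param seed optional integer seed (calls [set.seed()]).
#' @param name,topology passed to [replicatedGenome()].
#' @return a [ReplicatedGenome-class].
#' @export
randomGenome <- function(length, gc = 0.5, seed = NULL, name = "genome",
                         topology = "circular") {
    if (length < 1) stop("length must be >= 1")
    if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    replicatedGenome(paste(bases, collapse = ""), name = name,
                     topology = topology)
}

countCoreOccurrences <- function(core, sequence) {
    n <- countPattern(DNAString(core), sequence)
    rc <- reverseComplement(DNAString(core))
    if (as.character(rc) != core) n <- n + countPattern(rc, sequence)
    n
}

#' Plant the att core at a fixed position
#'
#' Substitutes `core` into the genome at `pos` (0-based).  Errors if the core
#' (on either strand) already occurs elsewhere, so that the resulting genome
#' carries exactly one copy.
#'
#' @param genome a [ReplicatedGenome-class].
#' @param core core sequence (character).
#' @param pos 0-based insertion position.
#' @param reverse plant the reverse complement instead (used for phages whose
#'   att site runs opposite to the host).
#' @return the modified [ReplicatedGenome-class].
#' @export
plantAttCore <- function(genome, core, pos, reverse = FALSE) {
    seqs <- genome@sequence
    c <- nchar(core)
    if (pos < 0 || pos + c > length(seqs))
        stop("core does not fit at pos")
    if (countCoreOccurrences(core, seqs) > 0L)
        stop("genome already contains the core sequence; regenerate")
    planted <- if (reverse) reverseComplement(DNAString(core))
               else DNAString(core)
    subseq(seqs, pos + 1L, pos + c) <- planted
    out <- genome
    out@sequence <- seqs
    if (countCoreOccurrences(core, seqs) != 1L)
        stop("substitution created a second core occurrence; regenerate")
    out
}

# phage aligned to host orientation: the strand on which the core reads
# forward.  attPFwd is the core start in that aligned frame.
alignedPhage <- function(phage, att) {
    Lp <- length(phage)
    c <- nchar(att@core)
    if (att@orientation == "forward")
        list(seq = phage@sequence, attPFwd = att@attPPos)
    else
        list(seq = reverseComplement(phage@sequence),
             attPFwd = Lp - att@attPPos - c)
}

#' Integrate the phage into the host by Campbell crossover at the att core
#'
#' Builds the lysogen sequence host(left) + core(attL) + rotated phage +
#' core(attR) + host(right).  Both inputs must carry exactly one core copy
#' (host forward at `attBPos`; phage per `orientation` at `attPPos`).
#'
#' @param host,phage [ReplicatedGenome-class] objects.
#' @param att an [AttSite-class].
#' @return a [LysogenMap-class].
#' @export
buildLysogen <- function(host, phage, att) {
    c <- nchar(att@core)
    Lh <- length(host); Lp <- length(phage)
    if (countCoreOccurrences(att@core, host@sequence) != 1L)
        stop("host must contain the core exactly once")
    if (countCoreOccurrences(att@core, phage@sequence) != 1L)
        stop("phage must contain the core exactly once")
    hostCore <- as.character(subseq(host@sequence, att@attBPos + 1L,
                                    att@attBPos + c))
    if (hostCore != att@core)
        stop("host core not found at attBPos")
    ap <- alignedPhage(phage, att)
    phageCore <- as.character(subseq(ap$seq, ap$attPFwd + 1L,
                                     ap$attPFwd + c))
    if (phageCore != att@core)
        stop("phage core not found at attPPos (check orientation)")
    # phage opened within the core: contributes [attPFwd + c, Lp) + [0, attPFwd)
    rotated <- xscat(subseq(ap$seq, ap$attPFwd + c + 1L, Lp),
                     subseq(ap$seq, 1L, ap$attPFwd))
    lys <- xscat(subseq(host@sequence, 1L, att@attBPos + c),  # incl attL core
                 rotated,
                 DNAString(att@core),                          # attR core
                 subseq(host@sequence, att@attBPos + c + 1L, Lh))
    new("LysogenMap", sequence = DNAString(as.character(lys)),
        attLPos = att@attBPos, attRPos = att@attBPos + Lp,
        hostLength = as.integer(Lh), phageLength = as.integer(Lp),
        attBPos = att@attBPos, attPPos = att@attPPos,
        orientation = att@orientation, coreLength = as.integer(c))
}

#' Map lysogen positions to their source frame
#'
#' Total on all positions; both core copies map to the host core interval
#' (the core is identical in all frames and is attributed to the host), so
#' the map is invertible everywhere outside the two cores.
#'
#' @param map a [LysogenMap-class].
#' @param pos integer vector of 0-based lysogen positions.
#' @return data.frame with columns `frame` ("host"/"phage"), `pos` (0-based,
#'   original frame coordinates) and `strand`.
#' @export
lysogenToSource <- function(map, pos) {
    pos <- as.numeric(pos)
    Lh <- map@hostLength; Lp <- map@phageLength; c <- map@coreLength
    attB <- map@attBPos
    attPFwd <- if (map@orientation == "forward") map@attPPos
               else Lp - map@attPPos - c
    frame <- character(length(pos)); out <- numeric(length(pos))
    strand <- rep("+", length(pos))
    if (any(pos < 0 | pos >= Lh + Lp)) stop("position outside lysogen")
    leftHost <- pos < attB + c
    rightCoreOrHost <- pos >= attB + Lp
    inPhage <- !leftHost & !rightCoreOrHost
    frame[leftHost] <- "host"; out[leftHost] <- pos[leftHost]
    frame[rightCoreOrHost] <- "host"
    out[rightCoreOrHost] <- pos[rightCoreOrHost] - Lp
    if (any(inPhage)) {
        i <- pos[inPhage] - (attB + c)
        q <- (attPFwd + c + i) %% Lp          # aligned-frame coordinate
        if (map@orientation == "forward") {
            out[inPhage] <- q
        } else {
            out[inPhage] <- Lp - q - 1
            strand[inPhage] <- "-"
        }
        frame[inPhage] <- "phage"
    }
    data.frame(frame = frame, pos = out, strand = strand,
               stringsAsFactors = FALSE)
}

#' Map source-frame positions into the lysogen
#'
#' Inverse of [lysogenToSource()] outside the core; host core positions map
#' to the attL copy and phage core positions to the attR copy.
#'
#' @param map a [LysogenMap-class].
#' @param frame `"host"` or `"phage"` (recycled).
#' @param pos integer vector of 0-based source positions.
#' @return numeric vector of 0-based lysogen positions.
#' @export
sourceToLysogen <- function(map, frame, pos) {
    pos <- as.numeric(pos)
    frame <- rep_len(frame, length(pos))
    Lh <- map@hostLength; Lp <- map@phageLength; c <- map@coreLength
    attB <- map@attBPos
    attPFwd <- if (map@orientation == "forward") map@attPPos
               else Lp - map@attPPos - c
    out <- numeric(length(pos))
    h <- frame == "host"
    out[h] <- ifelse(pos[h] < attB + c, pos[h], pos[h] + Lp)
    p <- !h
    if (any(p)) {
        q <- if (map@orientation == "forward") pos[p]
             else Lp - pos[p] - 1               # aligned-frame coordinate
        out[p] <- ifelse(q >= attPFwd + c, attB + c + (q - attPFwd - c),
                  ifelse(q >= attPFwd, attB + Lp + (q - attPFwd),  # core -> attR
                         attB + Lp - attPFwd + q))
    }
    out
}

#' Excise the prophage by attL x attR crossover
#'
#' Exact inverse of [buildLysogen()]: returns the original host and phage
#' sequences.
#'
#' @param map a [LysogenMap-class].
#' @param hostName,phageName names for the reconstructed genomes.
#' @return list with elements `host` and `phage` ([ReplicatedGenome-class]).
#' @export
exciseProphage <- function(map, hostName = "host", phageName = "phage") {
    Lh <- map@hostLength; Lp <- map@phageLength; c <- map@coreLength
    attB <- map@attBPos; lys <- map@sequence
    attPFwd <- if (map@orientation == "forward") map@attPPos
               else Lp - map@attPPos - c
    host <- xscat(subseq(lys, 1L, attB + c),
                  subseq(lys, attB + Lp + c + 1L, Lh + Lp))
    chunk <- subseq(lys, attB + c + 1L, attB + Lp)      # rotated, no core
    nA <- Lp - attPFwd - c                               # [attPFwd+c, Lp) part
    fwd <- xscat(subseq(chunk, nA + 1L, Lp - c),         # [0, attPFwd)
                 subseq(lys, attB + 1L, attB + c),       # core
                 subseq(chunk, 1L, nA))                  # [attPFwd+c, Lp)
    phageSeq <- if (map@orientation == "forward") fwd
                else reverseComplement(DNAString(as.character(fwd)))
    list(host = replicatedGenome(as.character(host), name = hostName),
         phage = replicatedGenome(as.character(phageSeq), name = phageName,
                                  topology = "circular"))
}
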