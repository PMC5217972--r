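# S4 classes for the three coordinate frames, the simulator and the
# inference results.  All coordinates are 0-based, half-open; circular
# frames reduce positions modulo the frame length.  Conversion to 1-based
# coordinates happens only at I/O boundaries.

setOldClass("data.frame")

#' Replicated genome: a named DNA sequence with a topology
#'
#' Minimal container for one reference frame (host or phage): a name, the
#' sequence as a [Biostrings::DNAString], and a topology flag.  Circular
#' frames use arithmetic modulo the length everywhere in the package.
#'
#' @slot name single character identifier.
#' @slot sequence a [Biostrings::DNAString].
#' @slot topology `"circular"` or `"linear"`.
#' @export
setClass("ReplicatedGenome",
    representation(name = "character", sequence = "DNAString",
                   topology = "character"),
    validity = function(object) {
        if (length(object@name) != 1L) return("name must be length 1")
        if (!object@topology %in% c("circular", "linear"))
            return("topology must be 'circular' or 'linear'")
        if (length(object@sequence) < 1L) return("empty sequence")
        TRUE
    })

#' Attachment site shared by host and phage
#'
#' The recombination core sequence and its (0-based) start positions in the
#' host frame (attB) and the phage frame (attP).  `orientation` states how
#' the phage is oriented relative to the host at integration: with
#' `"reverse"` the core occurs in the phage reference as its reverse
#' complement at `attPPos`, and the phage is reverse-complemented before
#' Campbell insertion.
#'
#' @slot core character core sequence (>= 8 bp).
#' @slot attBPos,attPPos integer 0-based core start positions.
#' @slot orientation `"forward"` or `"reverse"`.
#' @export
setClass("AttSite",
    representation(core = "character", attBPos = "integer",
                   attPPos = "integer", orientation = "character"),
    validity = function(object) {
        if (nchar(object@core) < 8L) return("core must be >= 8 bp")
        if (!grepl("^[ACGT]+$", object@core))
            return("core must be over {A,C,G,T}")
        if (object@attBPos < 0L || object@attPPos < 0L)
            return("att positions must be >= 0")
        if (!object@orientation %in% c("forward", "reverse"))
            return("orientation must be 'forward' or 'reverse'")
        TRUE
    })

#' Lysogen map: the integrated prophage and its coordinate correspondence
#'
#' Result of Campbell-type integration of the phage at attB.  Holds the
#' lysogen sequence, the attL/attR core positions, and everything needed to
#' map any lysogen position back to its source frame (see
#' [lysogenToSource()] / [sourceToLysogen()]).
#'
#' @slot sequence lysogen [Biostrings::DNAString] (length = host + phage).
#' @slot attLPos,attRPos integer 0-based core start positions in the lysogen.
#' @slot hostLength,phageLength integer source frame lengths.
#' @slot attBPos,attPPos integer core positions in the source frames.
#' @slot orientation phage orientation at integration.
#' @slot coreLength integer core length.
#' @export
setClass("LysogenMap",
    representation(sequence = "DNAString", attLPos = "integer",
                   attRPos = "integer", hostLength = "integer",
                   phageLength = "integer", attBPos = "integer",
                   attPPos = "integer", orientation = "character",
                   coreLength = "integer"),
    validity = function(object) {
        if (length(object@sequence) !=
            object@hostLength + object@phageLength)
            return("lysogen length must equal host length + phage length")
        if (object@attRPos - object@attLPos != object@phageLength)
            return("attR - attL must equal the phage length")
        TRUE
    })

#' Simulation parameters for pac-initiated headful packaging
#'
#' @slot redundancy terminal redundancy r; headful H = round(Lp * (1 + r)).
#' @slot pacPos 0-based pac position in the phage reference frame.
#' @slot pacJitterSd sd (bp) of the Normal initiation-cleavage jitter,
#'   truncated at +/- 3 sd.
#' @slot meanHeadfuls mean m (>= 1) of the geometric packaging-series length.
#' @slot fInt probability that a (non-background) series initiates from an
#'   integrated phage copy.
#' @slot direction host flank entered by integrated series:
#'   `"toward_attL"` or `"toward_attR"`.
#' @slot bgRate fraction of series that instead package one uniformly random
#'   host fragment (background generalized transduction).
#' @slot nSeries number of packaging series to simulate.
#' @slot seed optional RNG seed.
#' @export
setClass("SimParams",
    representation(redundancy = "numeric", pacPos = "integer",
                   pacJitterSd = "numeric", meanHeadfuls = "numeric",
                   fInt = "numeric", direction = "character",
                   bgRate = "numeric", nSeries = "integer",
                   seed = "integer"),
    validity = function(object) {
        if (object@redundancy < 0 || object@redundancy > 1)
            return("redundancy must be in [0,1]")
        if (object@meanHeadfuls < 1) return("meanHeadfuls must be >= 1")
        if (object@fInt < 0 || object@fInt > 1)
            return("fInt must be in [0,1]")
        if (object@bgRate < 0 || object@bgRate > 1)
            return("bgRate must be in [0,1]")
        if (!object@direction %in% c("toward_attL", "toward_attR"))
            return("direction must be 'toward_attL' or 'toward_attR'")
        if (object@nSeries < 1L) return("nSeries must be >= 1")
        if (object@pacJitterSd < 0) return("pacJitterSd must be >= 0")
        TRUE
    })

#' A set of simulated packaged DNA molecules
#'
#' One row of `segments` per (molecule, segment): the simulator's truth unit.
#' Segments are stored in the host / original phage frames as 0-based
#' half-open intervals (split at the circular origin when they wrap),
#' together with their offsets along the packaging path, so reads can be
#' generated and truth recovered without materialising molecule sequences.
#'
#' @slot segments data.frame with columns moleculeId, seriesId, headfulIndex,
#'   origin, frame, start, end, strand, pathStart, pathEnd.
#' @slot headful integer headful size H in bp.
#' @slot geometry list of frame geometry (lengths, att/pac positions in the
#'   aligned frame, direction, junction distance d).
#' @slot params the [SimParams-class] used.
#' @export
setClass("PackagedMoleculeSet",
    representation(segments = "data.frame", headful = "integer",
                   geometry = "list", params = "SimParams"))

#' Simulated paired-end reads with per-read truth
#'
#' @slot mate1,mate2 [Biostrings::DNAStringSet] of equal length, named by
#'   read id (`<id>/1`, `<id>/2`).
#' @slot truth data.frame, one row per read-piece: readId, moleculeId, frame,
#'   start, end, strand, plus per-read truthClass and truth anchors.
#' @slot readLength integer.
#' @export
setClass("ReadPairSet",
    representation(mate1 = "DNAStringSet", mate2 = "DNAStringSet",
                   truth = "data.frame", readLength = "integer"),
    validity = function(object) {
        if (length(object@mate1) != length(object@mate2))
            return("mate1 and mate2 must have equal length")
        TRUE
    })

#' Canonical k-mer index over the reference frames
#'
#' @slot ptr external pointer to the compiled index.
#' @slot refNames,refLengths,circular reference metadata (in index order).
#' @slot k k-mer size (>= 11).
#' @export
setClass("KmerIndex",
    representation(ptr = "externalptr", refNames = "character",
                   refLengths = "integer", circular = "logical",
                   k = "integer"))

#' Binned per-base depth over one reference frame
#'
#' @slot frame frame name.
#' @slot binSize bin width in bp.
#' @slot depth numeric vector of per-bin mean depth (bases per position).
#' @slot frameLength frame length in bp.
#' @slot topology `"circular"` or `"linear"`.
#' @export
setClass("CoverageProfile",
    representation(frame = "character", binSize = "integer",
                   depth = "numeric", frameLength = "integer",
                   topology = "character"),
    validity = function(object) {
        if (object@binSize <= 0L) return("binSize must be > 0")
        if (length(object@depth) !=
            ceiling(object@frameLength / object@binSize))
            return("number of bins must be ceiling(frameLength/binSize)")
        if (any(object@depth < 0)) return("depths must be >= 0")
        TRUE
    })

#' Inferred packaging model parameters
#'
#' @slot hostFraction fraction of classified reads of host origin.
#' @slot nearAttFraction fraction of host reads near attB, with
#'   `nearAttNumerator` / `nearAttDenominator` for auditability.
#' @slot periodT detected coverage-wave period (bp; NA if none).
#' @slot headfulH estimated headful size (= periodT when detected).
#' @slot redundancy estimated terminal redundancy (T - Lp)/Lp.
#' @slot processivity estimated mean headfuls per series.
#' @slot pacPos estimated packaging-initiation position (phage frame).
#' @slot pacPeak position of the smoothed phage coverage maximum.
#' @slot directionCounts named counts of hybrid-left / hybrid-right reads.
#' @slot directionCall `"left"`, `"right"` or `"none"`.
#' @slot directionP two-sided exact binomial p-value.
#' @slot flankExtent host-flank enrichment extent (bp).
#' @slot backgroundDepth median background depth (X).
#' @slot notes character flags (degenerate inputs etc.).
#' @export
setClass("PackagingEstimates",
    representation(hostFraction = "numeric", nearAttFraction = "numeric",
                   nearAttNumerator = "numeric", nearAttDenominator = "numeric",
                   periodT = "numeric", headfulH = "numeric",
                   redundancy = "numeric", processivity = "numeric",
                   pacPos = "numeric", pacPeak = "numeric",
                   directionCounts = "numeric", directionCall = "character",
                   directionP = "numeric", flankExtent = "numeric",
                   backgroundDepth = "numeric", notes = "character"))

#' Per-condition host-read summary
#'
#' @slot label `"induction"` or `"infection"` (free text allowed).
#' @slot hostReads,totalReads counts.
#' @slot hostFraction point estimate hostReads/totalReads.
#' @slot ci95 Wilson score interval (low, high).
#' @export
setClass("ConditionSummary",
    representation(label = "character", hostReads = "numeric",
                   totalReads = "numeric", hostFraction = "numeric",
                   ci95 = "numeric"),
    validity = function(object) {
        if (object@hostReads > object@totalReads)
            return("hostReads must be <= totalReads")
        if (length(object@ci95) != 2L) return("ci95 must be length 2")
        if (object@hostFraction < object@ci95[1] - 1e-12 ||
            object@hostFraction > object@ci95[2] + 1e-12)
            return("ci95 must contain hostFraction")
        TRUE
    })
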