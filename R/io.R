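# Standard-format readers/writers (FASTA, FASTQ, SAM, bedGraph, TSV, JSON,
# YAML config) and the three pipeline runners.  Internal coordinates are
# 0-based half-open; conversion to the 1-based conventions of FASTA
# headers / SAM happens here only.

#' Write genomes to FASTA
#'
#' @param genomes a [ReplicatedGenome-class] or list of them.
#' @param path output file; sequences wrapped at 70 columns.
#' @return the path, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path) {
    if (is(genomes, "ReplicatedGenome")) genomes <- list(genomes)
    set <- DNAStringSet(lapply(genomes, genomeSeq))
    names(set) <- vapply(genomes, function(g) g@name, character(1))
    writeXStringSet(set, path, width = 70L)
    invisible(path)
}

#' Read genomes from FASTA
#'
#' @param path FASTA file.
#' @param topology applied to all records.
#' @return named list of [ReplicatedGenome-class] objects.
#' @export
readGenomeFasta <- function(path, topology = "circular") {
    set <- readDNAStringSet(path)
    nm <- sub("\\s.*$", "", names(set))
    out <- lapply(seq_along(set), function(i)
        replicatedGenome(as.character(set[[i]]), name = nm[i],
                         topology = topology))
    names(out) <- nm
    out
}

#' Write paired-end reads as two FASTQ files
#'
#' Phred+33, constant quality 'I' (Q40).
#'
#' @param reads a [ReadPairSet-class].
#' @param prefix output prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
writeReadPairsFastq <- function(reads, prefix) {
    paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (i in 1:2) {
        set <- if (i == 1) reads@mate1 else reads@mate2
        qual <- BStringSet(vapply(width(set), function(w)
            paste(rep("I", w), collapse = ""), character(1)))
        writeXStringSet(set, paths[i], format = "fastq", qualities = qual)
    }
    invisible(paths)
}

#' Read a FASTQ pair
#'
#' @param path1,path2 mate FASTQ files.
#' @return list of two named [Biostrings::DNAStringSet]s.
#' @export
readFastqPair <- function(path1, path2) {
    m1 <- readDNAStringSet(path1, format = "fastq")
    m2 <- readDNAStringSet(path2, format = "fastq")
    names(m1) <- sub("\\s.*$", "", names(m1))
    names(m2) <- sub("\\s.*$", "", names(m2))
    list(mate1 = m1, mate2 = m2)
}

#' Write a coverage profile as bedGraph
#'
#' 0-based half-open intervals, one line per bin (matching the package's
#' internal convention exactly).
#'
#' @param profile a [CoverageProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCoverageBedGraph <- function(profile, path) {
    nb <- length(profile@depth)
    starts <- (seq_len(nb) - 1L) * profile@binSize
    ends <- pmin(profile@frameLength, seq_len(nb) * profile@binSize)
    df <- data.frame(chrom = profile@frame, start = starts, end = ends,
                     score = profile@depth)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s coverage\"",
                       profile@frame), con)
    write.table(format(df, scientific = FALSE, trim = TRUE), con,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph coverage track back into a CoverageProfile
#'
#' @param path bedGraph file written by [writeCoverageBedGraph()].
#' @param topology frame topology.
#' @return a [CoverageProfile-class].
#' @export
readCoverageBedGraph <- function(path, topology = "circular") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    frame <- as.character(GenomeInfoDb::seqnames(gr)[1])
    starts <- BiocGenerics::start(gr) - 1L
    ends <- BiocGenerics::end(gr)
    binSize <- as.integer(ends[1] - starts[1])
    coverageProfile(frame, gr$score, binSize, max(ends), topology)
}

#' Write / read an AttSite JSON sidecar
#'
#' Coordinates are stored 0-based with an explicit `coordinate_system` tag.
#'
#' @param att an [AttSite-class].
#' @param path JSON file.
#' @return the path ([writeAttSite()]) or an [AttSite-class]
#'   ([readAttSite()]).
#' @export
writeAttSite <- function(att, path) {
    jsonlite::write_json(list(core = att@core, attB_pos = att@attBPos,
                              attP_pos = att@attPPos,
                              orientation = att@orientation,
                              coordinate_system = "0-based"),
                         path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname writeAttSite
#' @export
readAttSite <- function(path) {
    x <- jsonlite::read_json(path)
    attSite(x$core, x$attB_pos, x$attP_pos, x$orientation)
}

#' Default run configuration
#'
#' All simulator, classifier and analysis parameters in one flat list.
#' The generator defaults are the modelled study conditions: a 2 Mb
#' circular host (attB at 1.6 Mb), a 65,149 bp phage carrying the 17 bp core
#' in reverse orientation at 62,750, pac at 23,500, 10% terminal redundancy,
#' jitter sd 2 kb and geometric mean 3 headfuls; `condition` selects the
#' calibrated integrated/background rates (see [simParams()]).
#'
#' @param condition `"induction"` or `"infection"`.
#' @param ... overrides for any config key.
#' @return named list.
#' @export
defaultRunConfig <- function(condition = c("induction", "infection"), ...) {
    condition <- match.arg(condition)
    sp <- simParams(condition)
    cfg <- list(
        condition = condition, seed = 1L,
        host_length = 2000000L, host_gc = 0.665,
        phage_length = 65149L, phage_gc = 0.635,
        att_core = "TGGTGCGGACGGAGAGA",
        attB_pos = 1600000L, attP_pos = 62750L,
        att_orientation = "reverse",
        pac_pos = sp@pacPos, pac_jitter_sd = sp@pacJitterSd,
        redundancy = sp@redundancy, mean_headfuls = sp@meanHeadfuls,
        f_int = sp@fInt, bg_rate = sp@bgRate,
        direction = sp@direction, n_series = 1000L,
        pairs_per_kb = 0.05, fragment_mean = 900, fragment_sd = 100,
        read_length = 250L, error_rate = 0,
        k = 31L, min_anchor = 20L,
        bin_size = 1000L, flank_window = 800000, off_side_margin = 10000,
        exclude_half = 1000000, threshold_mult = 2, run_rule = 3L,
        n_windows = 12L, span = 900000, max_lag = 150000,
        detrend_window = 100000)
    over <- list(...)
    cfg[names(over)] <- over
    cfg
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take defaults, so a resolved
#' config round-trips losslessly.
#'
#' @param path YAML file.
#' @param config a config list.
#' @return named list ([readRunConfig()]) or the path.
#' @export
readRunConfig <- function(path) {
    user <- yaml::read_yaml(path)
    cfg <- defaultRunConfig(condition = if (is.null(user$condition))
        "induction" else user$condition)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
    cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

configSimParams <- function(cfg) {
    simParams(condition = cfg$condition, redundancy = cfg$redundancy,
              pacPos = cfg$pac_pos, pacJitterSd = cfg$pac_jitter_sd,
              meanHeadfuls = cfg$mean_headfuls, fInt = cfg$f_int,
              direction = cfg$direction, bgRate = cfg$bg_rate,
              nSeries = cfg$n_series, seed = cfg$seed)
}

#' Simulate a full experiment and write all pipeline inputs
#'
#' Builds the host and phage references (planting the shared att core),
#' simulates packaging and reads, and writes FASTA references, the FASTQ
#' pair, per-read and per-molecule truth TSVs, a run summary JSON, the att
#' JSON sidecar and the resolved config.  Deterministic for a fixed seed.
#'
#' @param config list from [defaultRunConfig()] / [readRunConfig()], or a
#'   path to a YAML config.
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
runSimulate <- function(config, outDir) {
    if (is.character(config)) config <- readRunConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    core <- config$att_core
    host <- randomGenome(config$host_length, config$host_gc, name = "host")
    host <- retryPlant(host, core, config$attB_pos, FALSE,
                       config$host_length, config$host_gc)
    phage <- randomGenome(config$phage_length, config$phage_gc,
                          name = "phage")
    phage <- retryPlant(phage, core, config$attP_pos,
                        config$att_orientation == "reverse",
                        config$phage_length, config$phage_gc)
    att <- attSite(core, config$attB_pos, config$attP_pos,
                   config$att_orientation)
    params <- configSimParams(config)
    params@seed <- NA_integer_           # RNG stream already seeded
    mols <- simulateExperiment(params, host, phage, att)
    reads <- moleculesToReads(mols, host, phage,
                              pairsPerKb = config$pairs_per_kb,
                              fragmentMean = config$fragment_mean,
                              fragmentSd = config$fragment_sd,
                              readLength = config$read_length,
                              errorRate = config$error_rate)
    paths <- list(
        host = file.path(outDir, "host.fasta"),
        phage = file.path(outDir, "phage.fasta"),
        att = file.path(outDir, "att.json"),
        fastq = file.path(outDir, "reads"),
        readTruth = file.path(outDir, "read_truth.tsv"),
        molecules = file.path(outDir, "molecules.tsv"),
        summary = file.path(outDir, "summary.json"),
        config = file.path(outDir, "config.yaml"))
    writeGenomeFasta(host, paths$host)
    writeGenomeFasta(phage, paths$phage)
    writeAttSite(att, paths$att)
    fq <- writeReadPairsFastq(reads, paths$fastq)
    write.table(readTruth(reads), paths$readTruth, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(moleculeSegments(mols), paths$molecules, sep = "\t",
                quote = FALSE, row.names = FALSE)
    s <- moleculeSummary(mols)
    jsonlite::write_json(
        list(condition = config$condition, seed = config$seed,
             n_series = s$nSeries, n_molecules = s$nMolecules,
             headful = mols@headful,
             phage_bases = s$phageBases, host_bases = s$hostBases,
             host_fraction = s$hostFraction,
             origin_counts = as.list(s$originCounts),
             n_read_pairs = length(reads)),
        paths$summary, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeRunConfig(config, paths$config)
    invisible(list(host = host, phage = phage, att = att, molecules = mols,
                   reads = reads, paths = c(paths, fastq1 = fq[1],
                                            fastq2 = fq[2])))
}

# the att core must be unique; re-draw the reference if the random sequence
# already contains it
retryPlant <- function(genome, core, pos, reverse, len, gc) {
    for (i in 1:20) {
        ok <- tryCatch({
            genome <- plantAttCore(genome, core, pos, reverse)
            TRUE
        }, error = function(e) FALSE)
        if (ok) return(genome)
        genome <- randomGenome(len, gc, name = genome@name)
    }
    stop("could not plant a unique att core after 20 attempts")
}

#' Analyse reads against the references
#'
#' Classifies reads (internal k-mer mapper, or a SAM file of precomputed
#' alignments), writes per-read classes, coverage bedGraphs per frame, the
#' estimates report (JSON + TSV) and returns the estimates.
#'
#' @param hostFasta,phageFasta reference FASTA paths (single record each;
#'   both must contain the att core).
#' @param attJson att sidecar path (or an [AttSite-class]).
#' @param fastq1,fastq2 read FASTQ paths.
#' @param sam optional SAM file replacing the internal mapper.
#' @param outDir output directory.
#' @param config analysis parameters (defaults from [defaultRunConfig()]).
#' @return invisibly, a list with `estimates` ([PackagingEstimates-class]),
#'   `classified`, `summary` and output paths.
#' @export
runAnalyze <- function(hostFasta, phageFasta, attJson, fastq1, fastq2,
                       sam = NULL, outDir, config = defaultRunConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    host <- readGenomeFasta(hostFasta)[[1]]
    phage <- readGenomeFasta(phageFasta)[[1]]
    att <- if (is(attJson, "AttSite")) attJson else readAttSite(attJson)
    if (countCoreOccurrences(att@core, host@sequence) != 1L ||
        countCoreOccurrences(att@core, phage@sequence) != 1L)
        stop("att core absent (or not unique) in a reference")
    reads <- readFastqPair(fastq1, fastq2)
    all <- c(reads$mate1, reads$mate2)
    if (is.null(sam)) {
        idx <- kmerIndex(list(host = host, phage = phage), k = config$k)
        classified <- classifyReads(all, idx, att,
                                    minAnchor = config$min_anchor)
    } else {
        aln <- readSamAlignments(sam)
        classified <- classifyReads(aln, att = att,
                                    minAnchor = config$min_anchor,
                                    readLengths = setNames(
                                        nchar(as.character(all)),
                                        names(all)))
    }
    est <- analyzePackaging(classified, length(host), length(phage), att,
                            binSize = config$bin_size,
                            flankWindow = config$flank_window,
                            offSideMargin = config$off_side_margin,
                            excludeHalf = config$exclude_half,
                            thresholdMult = config$threshold_mult,
                            runRule = config$run_rule,
                            nWindows = config$n_windows,
                            span = config$span, maxLag = config$max_lag,
                            detrendWindow = config$detrend_window)
    cls <- summarizeClasses(classified)
    paths <- list(classes = file.path(outDir, "read_classes.tsv"),
                  hostBg = file.path(outDir, "coverage_host.bedGraph"),
                  phageBg = file.path(outDir, "coverage_phage.bedGraph"),
                  report = file.path(outDir, "report.json"),
                  reportTsv = file.path(outDir, "report.tsv"))
    write.table(classified, paths$classes, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeCoverageBedGraph(binnedCoverage(classified, "host",
                                         config$bin_size,
                                         frameLength = length(host)),
                          paths$hostBg)
    writeCoverageBedGraph(binnedCoverage(classified, "phage",
                                         config$bin_size,
                                         frameLength = length(phage)),
                          paths$phageBg)
    report <- list(condition = config$condition,
                   host_length = length(host),
                   phage_length = length(phage),
                   class_counts = as.list(cls$counts),
                   class_fractions = as.list(cls$fractions),
                   estimates = estimatesAsList(est))
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    tsv <- data.frame(quantity = names(unlist(report$estimates)),
                      value = as.character(unlist(report$estimates)))
    write.table(tsv, paths$reportTsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(list(estimates = est, classified = classified,
                   summary = cls, report = report, paths = paths))
}

#' Compare two analysis reports (induction vs infection)
#'
#' @param reportA,reportB paths to `report.json` files from [runAnalyze()]
#'   (numerator condition first).
#' @param outDir output directory for `comparison.json`.
#' @return invisibly, the comparison list from [compareConditions()] plus
#'   side-by-side estimates.
#' @export
runCompare <- function(reportA, reportB, outDir) {
    a <- jsonlite::read_json(reportA, simplifyVector = TRUE)
    b <- jsonlite::read_json(reportB, simplifyVector = TRUE)
    if (a$phage_length != b$phage_length)
        stop("reports come from different phage references")
    csA <- conditionSummary(if (is.null(a$condition)) "A" else a$condition,
                            a$class_counts$host,
                            sum(unlist(a$class_counts)))
    csB <- conditionSummary(if (is.null(b$condition)) "B" else b$condition,
                            b$class_counts$host,
                            sum(unlist(b$class_counts)))
    cmp <- compareConditions(csA, csB)
    out <- c(cmp, list(estimates = list(a$estimates, b$estimates)))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(outDir, "comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(out)
}

#' Read alignments from a SAM file
#'
#' Minimal SAM text parser (mandatory fields only) for running the
#' classifier on externally produced alignments.  CIGAR operations M, =, X
#' and S are consumed; any other operation aborts with a message.  The
#' reference names must be `host` and `phage`.
#'
#' @param path SAM file.
#' @return alignment data.frame in the [mapReads()] layout.
#' @export
readSamAlignments <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(readId = character(), frame = character(),
                          strand = character(), refStart = numeric(),
                          refEnd = numeric(), readStart = numeric(),
                          readEnd = numeric(), matched = numeric(),
                          stringsAsFactors = FALSE))
    f <- strsplit(lines, "\t")
    qname <- vapply(f, `[`, character(1), 1L)
    flag <- as.integer(vapply(f, `[`, character(1), 2L))
    rname <- vapply(f, `[`, character(1), 3L)
    pos <- as.numeric(vapply(f, `[`, character(1), 4L))
    cigar <- vapply(f, `[`, character(1), 6L)
    keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
    qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
    pos <- pos[keep]; cigar <- cigar[keep]
    ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
    n <- length(qname)
    refLen <- readLen <- leadS <- numeric(n)
    for (i in seq_len(n)) {
        m <- regmatches(cigar[i], ops[i])[[1]]
        lens <- as.numeric(sub("[A-Z=]$", "", m))
        op <- sub("^\\d+", "", m)
        bad <- setdiff(op, c("M", "=", "X", "S"))
        if (length(bad))
            stop("unsupported CIGAR operation(s) ",
                 paste(bad, collapse = ","), " in SAM record ", qname[i])
        consume <- op %in% c("M", "=", "X")
        refLen[i] <- sum(lens[consume])
        readLen[i] <- sum(lens)
        leadS[i] <- if (op[1] == "S") lens[1] else 0
    }
    data.frame(readId = qname, frame = rname,
               strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
               refStart = pos - 1, refEnd = pos - 1 + refLen,
               readStart = leadS, readEnd = leadS + refLen,
               matched = refLen, stringsAsFactors = FALSE)
}
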