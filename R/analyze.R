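# End-to-end inference: classified reads -> PackagingEstimates.

#' Infer the packaging model from classified reads
#'
#' Runs the full inference chain: class summary, host/phage coverage, pac
#' position and pac-to-junction distance, background depth, near-att
#' fraction, flank extent, wave period -> headful size and terminal
#' redundancy, headful-window decay -> processivity, and hybrid-read
#' directionality.
#'
#' @param classified data.frame from [classifyReads()].
#' @param hostLength,phageLength frame lengths (bp).
#' @param att the [AttSite-class].
#' @param binSize coverage bin width (bp).
#' @param direction packaging direction; `"auto"` (default) takes the side
#'   with more hybrid reads, falling back to `"toward_attL"`.
#' @param flankWindow,offSideMargin near-att window (see
#'   [nearAttFraction()]).
#' @param excludeHalf half-width (bp) of the background exclusion zone
#'   around attB (shrunk automatically on small genomes).
#' @param thresholdMult,runRule flank-extent rule (see [flankExtent()]).
#' @param nWindows headful windows for the processivity estimator.
#' @param span,maxLag,detrendWindow wave-period settings (see
#'   [detectWavePeriod()]).
#' @return a [PackagingEstimates-class].
#' @export
analyzePackaging <- function(classified, hostLength, phageLength, att,
                             binSize = 1000L, direction = "auto",
                             flankWindow = 8e5, offSideMargin = 1e4,
                             excludeHalf = 1e6, thresholdMult = 2,
                             runRule = 3L, nWindows = 12L,
                             span = 9e5, maxLag = 1.5e5,
                             detrendWindow = 1e5) {
    notes <- character()
    cls <- summarizeClasses(classified)
    nHyb <- cls$counts[["hybrid-left"]] + cls$counts[["hybrid-right"]]
    dirTest <- directionalityTest(cls$counts[["hybrid-left"]],
                                  cls$counts[["hybrid-right"]])
    if (direction == "auto") {
        direction <- switch(dirTest$direction,
                            left = "toward_attL", right = "toward_attR",
                            "toward_attL")
        if (dirTest$direction == "none")
            notes <- c(notes, "no hybrid majority; direction defaulted to toward_attL")
    }
    hostFraction <- if (cls$total > 0)
        cls$counts[["host"]] / cls$total else NA_real_
    nHost <- cls$counts[["host"]] + nHyb
    if (nHost == 0L) {
        notes <- c(notes, "no host reads: flank estimates not applicable")
        return(new("PackagingEstimates", hostFraction = hostFraction,
                   nearAttFraction = NA_real_, nearAttNumerator = 0,
                   nearAttDenominator = 0, periodT = NA_real_,
                   headfulH = NA_real_, redundancy = NA_real_,
                   processivity = NA_real_, pacPos = NA_real_,
                   pacPeak = NA_real_,
                   directionCounts = c(left = cls$counts[["hybrid-left"]],
                                       right = cls$counts[["hybrid-right"]]),
                   directionCall = dirTest$direction,
                   directionP = if (is.null(dirTest$pValue)) NA_real_
                                else dirTest$pValue,
                   flankExtent = NA_real_, backgroundDepth = NA_real_,
                   notes = notes))
    }
    hostProf <- binnedCoverage(classified, "host", binSize,
                               frameLength = hostLength)
    phageProf <- binnedCoverage(classified, "phage", binSize,
                                frameLength = phageLength)
    pac <- estimatePacPosition(phageProf)
    if (!pac$defined) notes <- c(notes, "flat phage profile: pac undefined")

    # background outside the exclusion zone (shrunk if the genome is small)
    half <- min(excludeHalf, floor(hostLength * 0.4))
    attB <- att@attBPos
    bg <- estimateBackground(hostProf, (attB - half) %% hostLength,
                             (attB + half) %% hostLength)
    near <- nearAttFraction(classified, attB, direction, hostLength,
                            min(flankWindow, hostLength - offSideMargin - 1),
                            offSideMargin)
    ext <- flankExtent(hostProf, attB, direction, bg, thresholdMult, runRule)

    wave <- detectWavePeriod(hostProf, attB, direction,
                             span = min(span, hostLength * 0.45),
                             maxLag = maxLag, detrendWindow = detrendWindow)
    periodT <- wave$period
    rHat <- if (wave$detected) (periodT - phageLength) / phageLength
            else NA_real_
    if (!wave$detected) notes <- c(notes, "no wave period detected")

    # pac-to-junction distance from the estimated pac position, for the
    # first headful window's partial-phage offset
    mHat <- NA_real_
    if (wave$detected) {
        H <- periodT
        d <- NA_real_
        if (pac$defined) {
            c <- nchar(att@core)
            attPFwd <- if (att@orientation == "forward") att@attPPos
                       else phageLength - att@attPPos - c
            pacFwd <- if (att@orientation == "forward") pac$pacPos
                      else phageLength - pac$pacPos
            d <- if (direction == "toward_attL")
                     (pacFwd - attPFwd - c) %% phageLength
                 else (attPFwd - pacFwd) %% phageLength
        }
        firstWidth <- if (is.na(d)) H else max(binSize, H - d)
        nw <- min(nWindows,
                  floor((hostLength * 0.45 - firstWidth) / H) + 1L)
        if (nw >= 2L) {
            wm <- headfulWindowMeans(hostProf, attB, direction, H, nw,
                                     firstWidth)
            if (!is.na(wm[1]) && wm[1] > bg)
                mHat <- estimateProcessivity(wm, bg)
            else notes <- c(notes, "first headful window not enriched")
        }
    }

    new("PackagingEstimates", hostFraction = hostFraction,
        nearAttFraction = near$fraction,
        nearAttNumerator = near$numerator,
        nearAttDenominator = near$denominator,
        periodT = if (wave$detected) periodT else NA_real_,
        headfulH = if (wave$detected) periodT else NA_real_,
        redundancy = rHat, processivity = mHat,
        pacPos = if (pac$defined) pac$pacPos else NA_real_,
        pacPeak = if (pac$defined) pac$peak else NA_real_,
        directionCounts = c(left = cls$counts[["hybrid-left"]],
                            right = cls$counts[["hybrid-right"]]),
        directionCall = dirTest$direction,
        directionP = if (is.null(dirTest$pValue) || is.na(dirTest$pValue))
            NA_real_ else dirTest$pValue,
        flankExtent = ext, backgroundDepth = bg, notes = notes)
}

setMethod("show", "PackagingEstimates", function(object) {
    cat("PackagingEstimates\n")
    cat(sprintf("  host fraction:      %.4f\n", object@hostFraction))
    cat(sprintf("  near-att fraction:  %.3f (%d / %d)\n",
                object@nearAttFraction, as.integer(object@nearAttNumerator),
                as.integer(object@nearAttDenominator)))
    cat(sprintf("  wave period T:      %.0f bp\n", object@periodT))
    cat(sprintf("  headful H:          %.0f bp\n", object@headfulH))
    cat(sprintf("  redundancy r:       %.3f\n", object@redundancy))
    cat(sprintf("  processivity m:     %.2f\n", object@processivity))
    cat(sprintf("  pac position:       %.0f bp (peak %.0f)\n",
                object@pacPos, object@pacPeak))
    cat(sprintf("  direction:          %s (left %d / right %d, p = %.3g)\n",
                object@directionCall,
                as.integer(object@directionCounts[["left"]]),
                as.integer(object@directionCounts[["right"]]),
                object@directionP))
    cat(sprintf("  flank extent:       %.0f bp\n", object@flankExtent))
    cat(sprintf("  background depth:   %.3f X\n", object@backgroundDepth))
    if (length(object@notes))
        cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' Convert PackagingEstimates to a plain list
#' @param estimates a [PackagingEstimates-class].
#' @return named list suitable for JSON serialisation.
#' @export
estimatesAsList <- function(estimates) {
    list(hostFraction = estimates@hostFraction,
         nearAttFraction = estimates@nearAttFraction,
         nearAttNumerator = estimates@nearAttNumerator,
         nearAttDenominator = estimates@nearAttDenominator,
         periodT = estimates@periodT, headfulH = estimates@headfulH,
         redundancy = estimates@redundancy,
         processivity = estimates@processivity,
         pacPos = estimates@pacPos, pacPeak = estimates@pacPeak,
         directionCounts = as.list(estimates@directionCounts),
         directionCall = estimates@directionCall,
         directionP = estimates@directionP,
         flankExtent = estimates@flankExtent,
         backgroundDepth = estimates@backgroundDepth,
         notes = estimates@notes)
}
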