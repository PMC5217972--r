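# Proportions with Wilson intervals, 2x2 chi-square, exact binomial test,
# and the induction-vs-infection comparison.

#' Proportion with a Wilson score confidence interval
#'
#' @param successes,total counts (0 <= successes <= total, total > 0).
#' @param level confidence level.
#' @return list: estimate, ciLow, ciHigh, level.
#' @export
proportionWithCI <- function(successes, total, level = 0.95) {
    if (total <= 0) stop("total must be > 0")
    if (successes < 0 || successes > total)
        stop("successes must be in [0, total]")
    p <- successes / total
    z <- qnorm(1 - (1 - level) / 2)
    z2 <- z * z
    denom <- 1 + z2 / total
    center <- (p + z2 / (2 * total)) / denom
    half <- z * sqrt(p * (1 - p) / total + z2 / (4 * total * total)) / denom
    list(estimate = p, ciLow = max(0, center - half),
         ciHigh = min(1, center + half), level = level)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic without continuity correction,
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the p-value from the
#' 1-df chi-square upper tail.  p-values below 2.2e-16 are floored and
#' reported as "< 2.2e-16" (`pLabel`), the double-precision convention.
#'
#' @param a,b,c,d cell counts (row-wise).
#' @return list: statistic, pValue, pLabel, df.
#' @export
chisq2x2 <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
    n <- a + b + c + d
    m <- c(a + b, c + d, a + c, b + d)
    if (any(m == 0)) stop("zero margin")
    stat <- n * (a * d - b * c)^2 / prod(m)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    floor22 <- 2.2e-16
    list(statistic = stat,
         pValue = max(p, .Machine$double.xmin),
         pLabel = if (p < floor22) "< 2.2e-16" else format(p, digits = 4),
         df = 1L)
}

#' Exact two-sided binomial test
#'
#' Minimum-likelihood two-sided p: the sum of P(X = i) over all outcomes i
#' with P(X = i) <= P(X = k) under Binomial(n, p0).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return p-value.
#' @export
binomTestTwoSided <- function(k, n, p0 = 0.5) {
    if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
    if (k < 0 || k > n) stop("k must be in [0, n]")
    d <- dbinom(0:n, n, p0)
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Summarise one experimental condition
#'
#' @param label condition label (e.g. "induction", "infection").
#' @param hostReads,totalReads counts.
#' @param level confidence level for the Wilson interval.
#' @return a [ConditionSummary-class].
#' @export
conditionSummary <- function(label, hostReads, totalReads, level = 0.95) {
    ci <- proportionWithCI(hostReads, totalReads, level)
    new("ConditionSummary", label = label, hostReads = hostReads,
        totalReads = totalReads, hostFraction = ci$estimate,
        ci95 = c(ci$ciLow, ci$ciHigh))
}

setMethod("show", "ConditionSummary", function(object) {
    cat(sprintf("ConditionSummary '%s': %d / %d host reads = %.2f%% (95%% CI %.2f-%.2f%%)\n",
                object@label, object@hostReads, object@totalReads,
                100 * object@hostFraction, 100 * object@ci95[1],
                100 * object@ci95[2]))
})

#' Compare packaged host-DNA fractions between two conditions
#'
#' Ratio of host fractions plus an (uncorrected) 2x2 chi-square on
#' (host, non-host) x condition.
#'
#' @param x,y [ConditionSummary-class] objects (numerator condition first).
#' @return list: fractions, ratio, higher (label of the enriched
#'   condition), chisq (statistic), pValue, pLabel, ci (both intervals).
#' @export
compareConditions <- function(x, y) {
    if (x@totalReads == 0 || y@totalReads == 0) stop("zero totals")
    fx <- x@hostFraction; fy <- y@hostFraction
    ratio <- if (fy == 0) NA_real_ else fx / fy
    cs <- chisq2x2(x@hostReads, x@totalReads - x@hostReads,
                   y@hostReads, y@totalReads - y@hostReads)
    list(fractions = setNames(c(fx, fy), c(x@label, y@label)),
         ratio = ratio,
         ratioFlag = if (is.na(ratio)) "undefined (zero denominator)" else
             if (ratio > 1) paste0("higher in ", x@label) else
             if (ratio < 1) paste0("higher in ", y@label) else "equal",
         chisq = cs$statistic, pValue = cs$pValue, pLabel = cs$pLabel,
         ci = list(setNames(x@ci95, c("low", "high")),
                   setNames(y@ci95, c("low", "high"))))
}
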