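#' @importFrom stats lm coef cor
#' @importFrom GenomicRanges distanceToNearest coverage end width strand
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Percent-input RIP recovery
#'
#' Fraction of starting material recovered by an immunoprecipitation,
#' computed from qPCR threshold cycles with the standard percent-input
#' convention: `inputFraction * 2^(ctInput - ctIp)`, assuming perfect
#' amplification efficiency (exact doubling per cycle). `inputFraction` is
#' the share of the lysate reserved as input (e.g. 0.05 for a 5% input).
#' Values above 1 are physically impossible recoveries and are returned
#' as-is but flagged with a warning and in the `"flagged"` attribute.
#'
#' @param ctInput,ctIp finite positive Ct values (vectors recycle).
#' @param inputFraction input share in (0, 1].
#' @return Numeric recovery fraction(s) with a logical `"flagged"` attribute.
#' @examples
#' percentInput(20, 20, 0.05)                 # 0.05
#' percentInput(20 + log2(20), 20, 0.05)      # 1
#' percentInput(23, 20, 0.01)                 # 0.08
#' @export
percentInput <- function(ctInput, ctIp, inputFraction) {
    if (!is.numeric(ctInput) || !is.numeric(ctIp) ||
        any(!is.finite(ctInput)) || any(!is.finite(ctIp)) ||
        any(ctInput <= 0) || any(ctIp <= 0))
        stop("Ct values must be finite and positive")
    if (!is.numeric(inputFraction) || any(!is.finite(inputFraction)) ||
        any(inputFraction <= 0) || any(inputFraction > 1))
        stop("'inputFraction' must be in (0, 1]")
    rec <- inputFraction * 2^(ctInput - ctIp)
    flagged <- rec > 1
    if (any(flagged))
        warning(sum(flagged), " recovery value(s) exceed 1")
    attr(rec, "flagged") <- flagged
    rec
}

#' Normalise recoveries to a reference region
#'
#' Divides each region's recovery by the recovery of a reference region with
#' no detected m6A sites, so the reference maps to exactly 1 and the other
#' regions express fold enrichment over the unmethylated baseline.
#'
#' @param recoveries named numeric vector of per-region recoveries.
#' @param referenceRegion name of the reference region; its recovery must be
#'   positive.
#' @return Named numeric vector of normalised recoveries.
#' @export
regionProfile <- function(recoveries, referenceRegion) {
    if (is.null(names(recoveries)) || !referenceRegion %in% names(recoveries))
        stop("'referenceRegion' not found among recoveries")
    refv <- recoveries[[referenceRegion]]
    if (!is.finite(refv) || refv <= 0)
        stop("reference region recovery must be positive")
    recoveries / refv
}

#' Relative chromatin association by delta-delta-Ct
#'
#' Quantifies how strongly a transcript is retained on chromatin: for each
#' condition the chromatin/input ratio of the target is normalised to the
#' same ratio of a structural normaliser RNA (e.g. 7SL) via
#' `2^-[(Ct_target,chr - Ct_target,input) - (Ct_norm,chr - Ct_norm,input)]`,
#' then expressed relative to the baseline condition, which is therefore
#' exactly 1.
#'
#' @param ctTargetChromatin,ctTargetInput,ctNormChromatin,ctNormInput named
#'   numeric vectors of Ct values, one element per condition, sharing names.
#' @param baseline name of the baseline condition (default: first element).
#' @return Named numeric vector of relative chromatin association.
#' @examples
#' chromatinAssociation(c(WT = 20, mut = 22), c(WT = 18, mut = 18),
#'                      c(WT = 15, mut = 15), c(WT = 15, mut = 15),
#'                      baseline = "WT")
#' @export
chromatinAssociation <- function(ctTargetChromatin, ctTargetInput,
                                 ctNormChromatin, ctNormInput,
                                 baseline = NULL) {
    vecs <- list(ctTargetChromatin, ctTargetInput, ctNormChromatin,
                 ctNormInput)
    nms <- names(ctTargetChromatin)
    if (is.null(nms))
        stop("condition vectors must be named")
    for (v in vecs)
        if (!is.numeric(v) || any(!is.finite(v)) ||
            !identical(sort(names(v)), sort(nms)))
            stop("all four Ct vectors must be finite and share ",
                 "condition names")
    ctTargetInput <- ctTargetInput[nms]
    ctNormChromatin <- ctNormChromatin[nms]
    ctNormInput <- ctNormInput[nms]
    if (is.null(baseline))
        baseline <- nms[1L]
    if (!baseline %in% nms)
        stop("unknown baseline condition: ", baseline)
    ddct <- (ctTargetChromatin - ctTargetInput) -
        (ctNormChromatin - ctNormInput)
    ratio <- 2^(-ddct)
    ratio / ratio[[baseline]]
}

#' Doubling time from a confluence time series
#'
#' Fits log2(confluence) against time by ordinary least squares; under
#' exponential growth the slope is doublings per hour and its reciprocal the
#' doubling time. A non-positive slope means the culture is not growing: the
#' doubling time is undefined (`NA`) and `growing` is `FALSE`.
#'
#' @param time hours, strictly increasing, >= 3 points.
#' @param confluence percent confluence in (0, 100], same length as `time`.
#' @return A list with `hours` (doubling time, `NA` when not growing),
#'   `slope`, `intercept`, `growing` and `r.squared`.
#' @examples
#' tt <- seq(0, 48, by = 2)
#' doublingTime(tt, 5 * 2^(tt / 26.5))$hours  # 26.5
#' @export
doublingTime <- function(time, confluence) {
    if (length(time) < 3L)
        stop("need at least 3 time points")
    if (length(confluence) != length(time))
        stop("'time' and 'confluence' lengths differ")
    if (any(diff(time) <= 0))
        stop("'time' must be strictly increasing")
    if (any(!is.finite(confluence)) || any(confluence <= 0) ||
        any(confluence > 100))
        stop("'confluence' must be in (0, 100]")
    fit <- lm(log2(confluence) ~ time)
    slope <- unname(coef(fit)[2L])
    # slopes within numerical noise of zero are not growth
    growing <- is.finite(slope) && slope > 1e-9
    list(hours = if (growing) 1 / slope else NA_real_,
         slope = slope,
         intercept = unname(coef(fit)[1L]),
         growing = growing,
         r.squared = if (stats::var(log2(confluence)) > 0)
             cor(log2(confluence), time)^2 else NA_real_)
}

#' Count sites with a nearby peak
#'
#' A site is proximal when the nearest peak edge lies within `window`
#' nucleotides (inclusive); distance is the gap between the single-base site
#' and the nearest peak, zero if the peak overlaps the site. Sites on
#' sequences with no peak at all are never proximal.
#'
#' @param sites `GRanges` of single-base sites.
#' @param peaks `GRanges` of peak intervals on the same coordinate system.
#' @param window maximum distance in nt (default 1000).
#' @return A list with `nProximal`, `fraction` (over all sites) and the
#'   logical vector `proximal`.
#' @examples
#' s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5000))
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5791, 5810))
#' peakProximity(s, p)$nProximal  # distance 790 <= 1000
#' @export
peakProximity <- function(sites, peaks, window = 1000L) {
    stopifnot(is(sites, "GRanges"), is(peaks, "GRanges"))
    if (length(window) != 1L || is.na(window) || window < 0)
        stop("'window' must be a single non-negative number")
    proximal <- logical(length(sites))
    if (length(sites) && length(peaks)) {
        hits <- distanceToNearest(sites, peaks, ignore.strand = TRUE)
        proximal[queryHits(hits)] <- mcols(hits)$distance <= window
    }
    list(nProximal = sum(proximal),
         fraction = if (length(sites)) mean(proximal) else NA_real_,
         proximal = proximal)
}

#' Mean signal profile around sites
#'
#' Averages an interval signal as a function of offset from a set of anchor
#' sites: for every site, signal coverage is read at offsets
#' `-halfwidth .. +halfwidth` (offsets falling outside the sequence are
#' dropped, so sites near ends contribute only their valid offsets), the
#' per-offset mean across sites is taken, and offsets are then averaged
#' within `bins` equal-width bins.
#'
#' @param sites `GRanges` of single-base anchor sites; must be non-empty.
#' @param signal `GRanges` of intervals, optionally with a numeric `score`
#'   metadata column (weight 1 when absent).
#' @param halfwidth window half-width in nt (default 1000), > 0.
#' @param bins number of offset bins (default 50), >= 1.
#' @return A `data.frame` with `offsetStart`, `offsetEnd`, `offsetCenter`
#'   and `meanSignal`, one row per bin.
#' @export
metaprofile <- function(sites, signal, halfwidth = 1000L, bins = 50L) {
    stopifnot(is(sites, "GRanges"), is(signal, "GRanges"))
    if (length(sites) == 0L)
        stop("no sites: cannot build a profile")
    if (halfwidth <= 0 || bins < 1)
        stop("'halfwidth' must be > 0 and 'bins' >= 1")
    halfwidth <- as.integer(halfwidth)
    bins <- as.integer(bins)
    w <- if ("score" %in% names(mcols(signal))) mcols(signal)$score
        else rep(1, length(signal))
    cov <- coverage(signal, weight = w)
    seqlens <- vapply(cov, length, integer(1))
    offsets <- seq.int(-halfwidth, halfwidth)
    sumSig <- numeric(length(offsets))
    nSig <- integer(length(offsets))
    for (i in seq_along(sites)) {
        sq <- as.character(seqnames(sites))[i]
        pos <- start(sites)[i]
        posAt <- pos + offsets
        L <- if (sq %in% names(seqlens)) seqlens[[sq]] else {
            sl <- GenomicRanges::seqlengths(sites)[sq]
            if (is.na(sl)) max(posAt) else sl
        }
        valid <- posAt >= 1L & posAt <= L
        vals <- if (sq %in% names(cov))
            as.numeric(cov[[sq]][posAt[valid]])
        else rep(0, sum(valid))
        sumSig[valid] <- sumSig[valid] + vals
        nSig[valid] <- nSig[valid] + 1L
    }
    meanByOffset <- ifelse(nSig > 0L, sumSig / pmax(nSig, 1L), NA_real_)
    breaks <- seq(-halfwidth - 0.5, halfwidth + 0.5, length.out = bins + 1L)
    bin <- cut(offsets, breaks, labels = FALSE, include.lowest = TRUE)
    out <- data.frame(
        offsetStart = vapply(split(offsets, bin), min, numeric(1)),
        offsetEnd = vapply(split(offsets, bin), max, numeric(1)),
        meanSignal = vapply(split(meanByOffset, bin),
                            function(x) mean(x, na.rm = TRUE), numeric(1)))
    out$offsetCenter <- (out$offsetStart + out$offsetEnd) / 2
    rownames(out) <- NULL
    out[, c("offsetStart", "offsetEnd", "offsetCenter", "meanSignal")]
}

#' Classify paired differential-expression contrasts
#'
#' Compares a condition-vs-control contrast (A) with a mutant-vs-control
#' contrast (B) gene by gene. Among genes significant in A (adjusted
#' p < `alpha`): `"same"` when also significant in B with matching fold-change
#' sign, `"opposite"` (the antimorph pattern: the mutant drives the change in
#' the direction opposite to the condition) when significant in B with
#' opposing sign, `"A_only"` otherwise. Genes significant only in B are
#' `"B_only"`; the rest `"not_significant"`. The fold-change correlation is
#' computed on genes whose linear fold change exceeds `fcMin` in either
#' direction in *both* contrasts, as the Pearson r of the two fold-change
#' axes with a least-squares trend line; it is reported on the signed linear
#' scale (default axes) and on the log2 scale.
#'
#' @param table `data.frame` with columns `gene`, `log2fc_a`, `padj_a`,
#'   `log2fc_b`, `padj_b`; gene ids unique, adjusted p in \[0, 1\].
#' @param alpha significance level on adjusted p, in (0, 1) (default 0.1).
#' @param fcMin linear fold-change filter for the correlation (default 1.15).
#' @return A list with `table` (input plus `category`), `counts` (named
#'   vector over all five categories), `correlation` (list `linear`, `log2`),
#'   `fit` (intercept/slope of the linear-scale trend line) and `nFiltered`
#'   (genes entering the correlation).
#' @examples
#' tab <- data.frame(gene = c("SEMA5A", "g2"),
#'                   log2fc_a = c(-1, 2), padj_a = c(0.01, 0.01),
#'                   log2fc_b = c(1, 2),  padj_b = c(0.01, 0.5))
#' antimorphClassify(tab)$counts
#' @export
antimorphClassify <- function(table, alpha = 0.1, fcMin = 1.15) {
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)")
    if (length(fcMin) != 1L || !is.finite(fcMin) || fcMin < 1)
        stop("'fcMin' must be >= 1")
    need <- c("gene", "log2fc_a", "padj_a", "log2fc_b", "padj_b")
    if (!all(need %in% names(table)))
        stop("table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(table$gene))
        stop("gene ids must be unique")
    pj <- c(table$padj_a, table$padj_b)
    if (any(!is.na(pj) & (pj < 0 | pj > 1)))
        stop("adjusted p values must be in [0, 1]")

    sigA <- !is.na(table$padj_a) & table$padj_a < alpha
    sigB <- !is.na(table$padj_b) & table$padj_b < alpha
    sameSign <- sign(table$log2fc_a) == sign(table$log2fc_b) &
        table$log2fc_a != 0 & table$log2fc_b != 0
    category <- rep("not_significant", nrow(table))
    category[sigA & !(sigB)] <- "A_only"
    category[sigA & sigB & sameSign] <- "same"
    category[sigA & sigB & !sameSign] <- "opposite"
    category[!sigA & sigB] <- "B_only"
    table$category <- category
    counts <- vapply(c("same", "opposite", "A_only", "B_only",
                       "not_significant"),
                     function(k) sum(category == k), integer(1))

    ## |linear FC| > fcMin in both contrasts <=> |log2FC| > log2(fcMin)
    filt <- abs(table$log2fc_a) > log2(fcMin) &
        abs(table$log2fc_b) > log2(fcMin)
    linA <- signedLinearFC(table$log2fc_a[filt])
    linB <- signedLinearFC(table$log2fc_b[filt])
    correlation <- list(linear = NA_real_, log2 = NA_real_)
    fit <- c(intercept = NA_real_, slope = NA_real_)
    if (sum(filt) >= 3L) {
        correlation$linear <- cor(linA, linB)
        correlation$log2 <- cor(table$log2fc_a[filt], table$log2fc_b[filt])
        fit <- stats::setNames(coef(lm(linB ~ linA)),
                               c("intercept", "slope"))
    }
    list(table = table, counts = counts, correlation = correlation,
         fit = fit, nFiltered = sum(filt))
}

## signed linear fold change: 2^x for x >= 0, -2^(-x) for x < 0 (the
## "-3.5-fold" reporting convention)
signedLinearFC <- function(log2fc) {
    ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}
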