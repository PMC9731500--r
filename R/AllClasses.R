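#' @import methods
#' @importFrom S4Vectors isSingleNumber
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic eCLIP library generator. `readLength` is the
#' (uniform) read length in nucleotides, `depth` the target mean per-position
#' coverage, `backgroundError` the per-base substitution probability applied
#' uniformly to every read, `ipEnrichment` the fraction of IP reads drawn from
#' antibody-bound methylated molecules at a planted locus, and `seed` the
#' integer seed making every emitted file byte-reproducible.
#'
#' @slot readLength integer(1), >= 20.
#' @slot depth numeric(1), mean reads per position, > 0.
#' @slot backgroundError numeric(1) in \[0, 1\].
#' @slot ipEnrichment numeric(1) in \[0, 1\].
#' @slot seed integer(1).
#'
#' @seealso [simConfig()] for the user-facing constructor.
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        readLength      = "integer",
        depth           = "numeric",
        backgroundError = "numeric",
        ipEnrichment    = "numeric",
        seed            = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@readLength) != 1L || is.na(object@readLength) ||
        object@readLength < 20L)
        msg <- c(msg, "'readLength' must be a single integer >= 20")
    if (!isSingleNumber(object@depth) || object@depth <= 0)
        msg <- c(msg, "'depth' must be a single positive number")
    for (nm in c("backgroundError", "ipEnrichment")) {
        p <- slot(object, nm)
        if (!isSingleNumber(p) || p < 0 || p > 1)
            msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", nm))
    }
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults emulate a compact, well-powered bench-top library: 50 nt reads at
#' 200x coverage with a 1e-3 background substitution rate and full IP
#' enrichment.
#'
#' @param readLength read length in nt (default 50).
#' @param depth mean reads per position (default 200).
#' @param backgroundError per-base substitution probability (default 0.001).
#' @param ipEnrichment fraction of IP reads drawn from methylated molecules
#'   (default 1).
#' @param seed integer seed (default 1).
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(depth = 100, seed = 42)
#' @export
simConfig <- function(readLength = 50L, depth = 200, backgroundError = 0.001,
                      ipEnrichment = 1, seed = 1L) {
    new("SimConfig",
        readLength = as.integer(readLength), depth = as.numeric(depth),
        backgroundError = as.numeric(backgroundError),
        ipEnrichment = as.numeric(ipEnrichment), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: readLength=", object@readLength,
        " depth=", object@depth,
        " backgroundError=", object@backgroundError,
        " ipEnrichment=", object@ipEnrichment,
        " seed=", object@seed, "\n", sep = "")
})

#' Site-calling thresholds
#'
#' Thresholds of the conversion-based m6A caller. A candidate C-to-T signal is
#' called when its event count reaches `minCount` (2 when `reducedMode` is on)
#' and its conversion frequency lies inside the inclusive window
#' \[`minFreq`, `maxFreq`\]. Calls at or above `highConfFreq` with >= 3 events
#' are tiered "high"; 3+ events below it are "low"; 2-event calls admitted by
#' `reducedMode` are "reduced". The upper bound excludes signals mutated in
#' most reads, which behave like genetic variants rather than
#' sub-stoichiometric crosslink chemistry.
#'
#' @slot minCount integer(1) >= 1; minimum C-to-T events (default 3).
#' @slot minFreq numeric(1); lower frequency bound, inclusive (default 0.025).
#' @slot maxFreq numeric(1); upper frequency bound, inclusive (default 0.50).
#' @slot highConfFreq numeric(1); high-confidence frequency (default 0.05).
#' @slot reducedMode logical(1); admit 2-event sites (default FALSE).
#'
#' @seealso [callingParams()], [callSites()], [assignConfidence()]
#' @exportClass CallingParams
setClass("CallingParams",
    slots = c(
        minCount     = "integer",
        minFreq      = "numeric",
        maxFreq      = "numeric",
        highConfFreq = "numeric",
        reducedMode  = "logical"
    )
)

setValidity("CallingParams", function(object) {
    msg <- character()
    if (length(object@minCount) != 1L || is.na(object@minCount) ||
        object@minCount < 1L)
        msg <- c(msg, "'minCount' must be a single integer >= 1")
    f <- c(object@minFreq, object@highConfFreq, object@maxFreq)
    if (length(f) != 3L || anyNA(f) ||
        !(0 < f[1L] && f[1L] <= f[2L] && f[2L] <= f[3L] && f[3L] <= 1))
        msg <- c(msg,
            "need 0 < minFreq <= highConfFreq <= maxFreq <= 1")
    if (length(object@reducedMode) != 1L || is.na(object@reducedMode))
        msg <- c(msg, "'reducedMode' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct calling thresholds
#'
#' @param minCount minimum number of C-to-T events at a site (default 3).
#' @param minFreq lower conversion-frequency bound, inclusive (default 0.025).
#' @param maxFreq upper conversion-frequency bound, inclusive (default 0.50).
#' @param highConfFreq frequency at or above which a 3+ event site is tiered
#'   high confidence (default 0.05).
#' @param reducedMode if `TRUE`, lower the event threshold to 2 (default
#'   `FALSE`); such calls are tiered "reduced".
#' @return A [CallingParams-class] object.
#' @examples
#' callingParams()
#' callingParams(reducedMode = TRUE)
#' @export
callingParams <- function(minCount = 3L, minFreq = 0.025, maxFreq = 0.50,
                          highConfFreq = 0.05, reducedMode = FALSE) {
    new("CallingParams",
        minCount = as.integer(minCount), minFreq = as.numeric(minFreq),
        maxFreq = as.numeric(maxFreq), highConfFreq = as.numeric(highConfFreq),
        reducedMode = as.logical(reducedMode))
}

setMethod("show", "CallingParams", function(object) {
    cat("CallingParams: minCount=", effectiveMinCount(object),
        if (object@reducedMode) " (reduced mode)" else "",
        " freq window=[", object@minFreq, ", ", object@maxFreq, "]",
        " highConfFreq=", object@highConfFreq, "\n", sep = "")
})

## event-count threshold actually applied given the mode flag
effectiveMinCount <- function(params) {
    if (params@reducedMode) 2L else params@minCount
}

PILEUP_BASES <- c("A", "C", "G", "T", "N")

#' Per-position base counts
#'
#' Observed base counts per transcript position, one 5 x length integer matrix
#' per transcript (rows A, C, G, T, N; columns are 1-based positions). The
#' `skipped` slot records alignment records excluded from tallying, by reason.
#'
#' @slot counts named list of 5-row integer matrices, one per transcript.
#' @slot skipped named integer vector of excluded-record counts
#'   (`reverseStrand`, `unsupportedCigar`).
#'
#' @seealso [pileupReads()], [pileupCounts()], [pileupDepth()]
#' @exportClass Pileup
setClass("Pileup",
    slots = c(counts = "list", skipped = "integer")
)

setValidity("Pileup", function(object) {
    msg <- character()
    cnt <- object@counts
    if (length(cnt) && is.null(names(cnt)))
        msg <- c(msg, "'counts' must be a named list")
    for (nm in names(cnt)) {
        m <- cnt[[nm]]
        if (!is.matrix(m) || !identical(rownames(m), PILEUP_BASES))
            msg <- c(msg, sprintf(
                "counts[['%s']] must be a matrix with rows A,C,G,T,N", nm))
        else if (any(m < 0) || anyNA(m))
            msg <- c(msg, sprintf(
                "counts[['%s']] must be non-negative and complete", nm))
    }
    if (length(msg)) msg else TRUE
})

Pileup <- function(counts, skipped = c(reverseStrand = 0L,
                                       unsupportedCigar = 0L)) {
    new("Pileup", counts = counts, skipped = skipped)
}

setMethod("show", "Pileup", function(object) {
    ntx <- length(object@counts)
    tot <- sum(vapply(object@counts, sum, numeric(1)))
    cat("Pileup over ", ntx, " transcript(s); ",
        format(tot, big.mark = ","), " base observations\n", sep = "")
    if (any(object@skipped > 0L))
        cat("  skipped records: ",
            paste(names(object@skipped), object@skipped,
                  sep = "=", collapse = ", "), "\n", sep = "")
})

#' Access pileup base counts
#'
#' @param p a [Pileup-class] object.
#' @param transcript a transcript id; if `NULL`, the full list of matrices.
#' @return A 5 x length integer matrix (rows A, C, G, T, N), or the named
#'   list of all matrices.
#' @export
pileupCounts <- function(p, transcript = NULL) {
    stopifnot(is(p, "Pileup"))
    if (is.null(transcript))
        return(p@counts)
    if (!transcript %in% names(p@counts))
        stop("unknown transcript: ", transcript)
    p@counts[[transcript]]
}

#' Per-position total depth
#'
#' Depth is the column sum of all base counts, N included.
#'
#' @inheritParams pileupCounts
#' @return Integer vector of per-position depth for one transcript.
#' @export
pileupDepth <- function(p, transcript) {
    colSums(pileupCounts(p, transcript))
}
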