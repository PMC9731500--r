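#' Test the RAC methylation context
#'
#' A position can hold m6A in this detection chemistry only inside the RAC
#' trinucleotide: purine (A/G) at -1, the methylated A itself, and C at +1
#' where the crosslink-induced conversion appears. The non-canonical GAACG
#' context passes because its central A sits between a purine and a C.
#' Positions whose context is incomplete (transcript edge) return `FALSE`.
#'
#' @param ref reference `DNAStringSet`.
#' @param transcript transcript id(s), recycled against `aPosition`.
#' @param aPosition 1-based position(s) of the candidate A.
#' @return Logical vector.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(tx1 = "TTGAACGTT"))
#' motifOk(ref, "tx1", 5)  # central A of GAACG
#' @export
motifOk <- function(ref, transcript, aPosition) {
    stopifnot(is(ref, "DNAStringSet"))
    n <- max(length(transcript), length(aPosition))
    transcript <- rep_len(transcript, n)
    aPosition <- rep_len(as.integer(aPosition), n)
    if (!all(transcript %in% names(ref)))
        stop("unknown transcript: ",
             paste(setdiff(transcript, names(ref)), collapse = ", "))
    lens <- Biostrings::width(ref)[match(transcript, names(ref))]
    ok <- aPosition >= 2L & aPosition <= lens - 1L
    if (any(ok)) {
        seqs <- as.character(ref)[transcript[ok]]
        ctx <- substring(seqs, aPosition[ok] - 1L, aPosition[ok] + 1L)
        ok[ok] <- substring(ctx, 1L, 1L) %in% c("A", "G") &
            substring(ctx, 2L, 2L) == "A" &
            substring(ctx, 3L, 3L) == "C"
    }
    ok
}

#' Call m6A sites from conversion signals
#'
#' Applies the motif, event-count and frequency filters to candidate C-to-T
#' signals. A signal at C position `c` is called at A position `c - 1` when
#' (i) the RAC context holds there, (ii) `ct_count` reaches the effective
#' event threshold (2 in reduced mode, else `minCount`), and (iii) its
#' frequency lies inside the inclusive window \[`minFreq`, `maxFreq`\].
#' Signals above the upper bound are dropped as likely genetic variants
#' rather than sub-stoichiometric crosslink chemistry.
#'
#' @param signals signal `data.frame` from [scanCtSignals()].
#' @param ref reference `DNAStringSet`.
#' @param params a [CallingParams-class] (default [callingParams()]).
#' @param replicateId label recorded on every call (default `"rep1"`).
#' @return A [GenomicRanges::GRanges] of width-1 ranges at the methylated A,
#'   sorted, with metadata columns `motif`, `ctCount`, `depth`, `frequency`,
#'   `tier`, `replicate`.
#' @seealso [assignConfidence()], [subtractInput()]
#' @export
callSites <- function(signals, ref, params = callingParams(),
                      replicateId = "rep1") {
    stopifnot(is(ref, "DNAStringSet"), is(params, "CallingParams"))
    validObject(params)
    need <- c("transcript", "c_position", "ct_count", "depth", "frequency")
    if (!all(need %in% names(signals)))
        stop("signals must have columns: ", paste(need, collapse = ", "))
    lens <- Biostrings::width(ref)
    names(lens) <- names(ref)
    if (nrow(signals) == 0L)
        return(emptyCalls(lens))
    aPos <- signals$c_position - 1L
    keep <- aPos >= 2L &
        motifOk(ref, signals$transcript, pmax(aPos, 2L)) &
        signals$ct_count >= effectiveMinCount(params) &
        signals$frequency >= params@minFreq &
        signals$frequency <= params@maxFreq
    kept <- signals[keep, , drop = FALSE]
    aPos <- aPos[keep]
    if (nrow(kept) == 0L)
        return(emptyCalls(lens))
    motif <- substring(as.character(ref)[kept$transcript], aPos - 1L,
                       aPos + 1L)
    gr <- GRanges(kept$transcript, IRanges(aPos, aPos),
                  strand = rep("+", nrow(kept)), seqlengths = lens)
    mcols(gr) <- S4Vectors::DataFrame(
        motif = unname(motif),
        ctCount = as.integer(kept$ct_count),
        depth = as.integer(kept$depth),
        frequency = kept$frequency,
        tier = assignConfidence(kept$ct_count, kept$frequency, params),
        replicate = rep(replicateId, sum(keep)))
    sort(gr)
}

emptyCalls <- function(seqlengths) {
    gr <- GRanges(seqlengths = seqlengths)
    mcols(gr) <- S4Vectors::DataFrame(
        motif = character(0), ctCount = integer(0), depth = integer(0),
        frequency = numeric(0), tier = character(0),
        replicate = character(0))
    gr
}

#' Assign a confidence tier to called sites
#'
#' `"high"`: >= 3 conversion events in at least `highConfFreq` of reads
#' (default 5%). `"low"`: >= 3 events at a frequency below that but inside
#' the calling window (>= 2.5% by default). `"reduced"`: 2-event sites
#' admitted only in reduced mode.
#'
#' @param ctCount integer vector of conversion events.
#' @param frequency numeric vector of conversion frequencies.
#' @param params a [CallingParams-class].
#' @return Character vector of tiers.
#' @examples
#' assignConfidence(c(12, 3, 2), c(0.06, 0.03, 0.05),
#'                  callingParams(reducedMode = TRUE))
#' @export
assignConfidence <- function(ctCount, frequency, params = callingParams()) {
    stopifnot(is(params, "CallingParams"))
    ifelse(ctCount >= 3L & frequency >= params@highConfFreq, "high",
           ifelse(ctCount >= 3L, "low", "reduced"))
}

#' Remove IP calls that also appear in the input library
#'
#' Any site called in both the IP and the input library cannot have been
#' induced by antibody crosslinking and is removed; matching is by exact
#' (transcript, position) identity. IP order is preserved.
#'
#' @param ipCalls,inputCalls call `GRanges` from [callSites()] over the same
#'   reference.
#' @return The `GRanges` subset of `ipCalls` absent from `inputCalls`.
#' @export
subtractInput <- function(ipCalls, inputCalls) {
    stopifnot(is(ipCalls, "GRanges"), is(inputCalls, "GRanges"))
    if (length(inputCalls) == 0L || length(ipCalls) == 0L)
        return(ipCalls)
    ipCalls[!siteKey(ipCalls) %in% siteKey(inputCalls)]
}

#' Write calls as BED
#'
#' 0-based half-open single-base intervals, name `m6A<1-based pos>`, score
#' `round(1000 * frequency)`, sorted lexicographically by chrom then start.
#'
#' @param calls call `GRanges`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCallsBed <- function(calls, path) {
    stopifnot(is(calls, "GRanges"))
    chrom <- as.character(seqnames(calls))
    ord <- order(chrom, start(calls))
    score <- if ("frequency" %in% names(mcols(calls)))
        round(1000 * mcols(calls)$frequency) else 0L
    lines <- paste(chrom[ord], start(calls)[ord] - 1L, start(calls)[ord],
                   paste0("m6A", start(calls)[ord]),
                   rep_len(score, length(calls))[ord], "+", sep = "\t")
    writeLines(lines, path)
    invisible(path)
}
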