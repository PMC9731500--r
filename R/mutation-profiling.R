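#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#'   scanBamHeader BamFile
#' @importFrom Biostrings consensusMatrix
#' @importFrom utils write.table read.delim
NULL

#' Load a transcript reference from FASTA
#'
#' Reads a FASTA file into an uppercased `DNAStringSet`. Headers are trimmed
#' to their first whitespace-delimited word. Duplicate ids, empty sequences
#' and characters outside A/C/G/T/N are rejected; positions holding N are kept
#' but are never callable downstream.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' Biostrings::writeXStringSet(buildReference(1, c(2200, 2200), 7), fa)
#' ref <- loadReference(fa)
#' @export
loadReference <- function(path) {
    ## read without alphabet coercion so foreign characters are caught, not
    ## silently dropped
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA: ",
                                             conditionMessage(e)))
    names(raw) <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(names(raw)))
        stop("duplicate transcript id in FASTA: ",
             paste(unique(names(raw)[duplicated(names(raw))]),
                   collapse = ", "))
    if (any(Biostrings::width(raw) == 0L))
        stop("empty sequence in FASTA")
    seqs <- toupper(as.character(raw))
    if (any(grepl("[^ACGTN]", seqs)))
        stop("reference contains characters outside A/C/G/T/N")
    ref <- DNAStringSet(seqs)
    names(ref) <- names(raw)
    ref
}

#' Tally per-position base counts from aligned reads
#'
#' Converts a SAM file to BAM and tallies, for every transcript position, the
#' bases observed in primary, mapped, forward-strand, match-only alignments.
#' Reverse-strand records are excluded (not complemented) and counted in the
#' `skipped` slot — the libraries this models are stranded, and silently
#' complementing risks double-counting conventions. Records with indel or
#' clipping operations are likewise skipped and counted; the in-scope read
#' source emits match-only CIGARs. Secondary and supplementary alignments are
#' always dropped; no mapping-quality filter is applied unless `minMapq` is
#' raised.
#'
#' @param samPath path to a SAM (or BAM) file whose references match `ref`.
#' @param ref the reference `DNAStringSet` the reads were aligned to.
#' @param minMapq minimum mapping quality to tally (default 0, permissive).
#' @return A [Pileup-class] object with one 5 x length count matrix per
#'   transcript in `ref`.
#' @export
pileupReads <- function(samPath, ref, minMapq = 0L) {
    stopifnot(is(ref, "DNAStringSet"))
    if (!file.exists(samPath))
        stop("no such file: ", samPath)
    bam <- if (grepl("\\.bam$", samPath, ignore.case = TRUE)) samPath
        else suppressWarnings(asBam(samPath, tempfile(), overwrite = TRUE,
                                    indexDestination = FALSE))

    hdr <- scanBamHeader(BamFile(bam, index = character(0)))
    targets <- hdr$targets
    lens <- Biostrings::width(ref)
    names(lens) <- names(ref)
    unknown <- setdiff(names(targets), names(ref))
    if (length(unknown))
        stop("SAM reference not in FASTA: ", paste(unknown, collapse = ", "))
    mismatched <- names(targets)[targets != lens[names(targets)]]
    if (length(mismatched))
        stop("SAM/FASTA length mismatch for: ",
             paste(mismatched, collapse = ", "))

    param <- ScanBamParam(
        what = c("rname", "pos", "strand", "seq", "mapq", "cigar"),
        flag = scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE))
    res <- scanBam(BamFile(bam, index = character(0)), param = param)[[1L]]

    keepQ <- is.na(res$mapq) | res$mapq >= minMapq
    rev <- res$strand == "-"
    matchOnly <- grepl("^[0-9]+[M=X]$", res$cigar)
    skipped <- c(reverseStrand = sum(rev & keepQ),
                 unsupportedCigar = sum(!matchOnly & !rev & keepQ))
    if (skipped[["reverseStrand"]] > 0L)
        warning(skipped[["reverseStrand"]],
                " reverse-strand record(s) skipped")
    if (skipped[["unsupportedCigar"]] > 0L)
        warning(skipped[["unsupportedCigar"]],
                " record(s) with non-match CIGAR skipped")
    keep <- keepQ & !rev & matchOnly

    counts <- lapply(names(ref), function(tx) {
        idx <- keep & !is.na(res$rname) & as.character(res$rname) == tx
        m <- matrix(0L, nrow = length(PILEUP_BASES), ncol = lens[[tx]],
                    dimnames = list(PILEUP_BASES, NULL))
        if (any(idx)) {
            cm <- consensusMatrix(res$seq[idx], shift = res$pos[idx] - 1L,
                                  width = lens[[tx]])
            present <- intersect(PILEUP_BASES, rownames(cm))
            m[present, ] <- cm[present, , drop = FALSE]
        }
        m
    })
    names(counts) <- names(ref)
    Pileup(counts, skipped)
}

#' Extract candidate C-to-T conversion signals
#'
#' Scans every reference C and reports each position where at least one read
#' shows T. Frequency is `ct_count / depth` with depth the total reads
#' covering the position, all bases included. Reference positions holding N
#' are never callable and are not scanned.
#'
#' @param p a [Pileup-class].
#' @param ref the matching reference `DNAStringSet`.
#' @return A `data.frame` with columns `transcript`, `c_position` (1-based),
#'   `ct_count`, `depth`, `frequency`, sorted by transcript then position.
#' @export
scanCtSignals <- function(p, ref) {
    stopifnot(is(p, "Pileup"), is(ref, "DNAStringSet"))
    if (!all(names(p@counts) %in% names(ref)))
        stop("pileup transcripts absent from reference")
    out <- lapply(names(p@counts), function(tx) {
        m <- p@counts[[tx]]
        refc <- strsplit(as.character(ref[[tx]]), "")[[1L]]
        if (ncol(m) != length(refc))
            stop("pileup/reference length mismatch for ", tx)
        hit <- which(refc == "C" & m["T", ] >= 1L)
        if (!length(hit))
            return(NULL)
        depth <- colSums(m)[hit]
        data.frame(transcript = tx, c_position = hit,
                   ct_count = unname(m["T", hit]),
                   depth = unname(as.integer(depth)),
                   frequency = unname(m["T", hit] / depth))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(transcript = character(0), c_position = integer(0),
                          ct_count = integer(0), depth = integer(0),
                          frequency = numeric(0))
    rownames(out) <- NULL
    out[order(match(out$transcript, names(ref)), out$c_position), ,
        drop = FALSE]
}

#' Write a pileup as TSV
#'
#' One row per covered position: `transcript, position, ref_base, A, C, G, T,
#' N, depth`.
#'
#' @param p a [Pileup-class].
#' @param ref the matching reference.
#' @param path output path.
#' @param allPositions write zero-depth positions too (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
exportPileup <- function(p, ref, path, allPositions = FALSE) {
    stopifnot(is(p, "Pileup"), is(ref, "DNAStringSet"))
    rows <- lapply(names(p@counts), function(tx) {
        m <- p@counts[[tx]]
        refc <- strsplit(as.character(ref[[tx]]), "")[[1L]]
        depth <- colSums(m)
        pos <- if (allPositions) seq_len(ncol(m)) else which(depth > 0)
        if (!length(pos)) return(NULL)
        data.frame(transcript = tx, position = pos, ref_base = refc[pos],
                   A = m["A", pos], C = m["C", pos], G = m["G", pos],
                   T = m["T", pos], N = m["N", pos],
                   depth = as.integer(depth[pos]))
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab))
        tab <- data.frame(transcript = character(0), position = integer(0),
                          ref_base = character(0), A = integer(0),
                          C = integer(0), G = integer(0), T = integer(0),
                          N = integer(0), depth = integer(0))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read/write conversion-signal tables
#'
#' Plain TSV with the columns produced by [scanCtSignals()].
#'
#' @param signals a signal `data.frame`.
#' @param path file path.
#' @return `writeSignals` returns `path` invisibly; `readSignals` the
#'   `data.frame`.
#' @export
writeSignals <- function(signals, path) {
    write.table(signals, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSignals
#' @export
readSignals <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
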