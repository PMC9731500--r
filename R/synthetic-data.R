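#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @importFrom GenomicRanges GRanges seqnames start mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom runif
NULL

#' Generate a random transcript reference
#'
#' Builds `nTranscripts` random A/C/G/T sequences with lengths drawn uniformly
#' from `lengthRange`, named `tx1`, `tx2`, ... The sequences serve as the
#' 1-based coordinate system for planted m6A sites (a site at position 783 is
#' reported as "A783"-style coordinates on its transcript).
#'
#' @param nTranscripts number of transcripts, >= 1.
#' @param lengthRange integer pair `c(min, max)` of transcript lengths; both
#'   >= 150 nt (three default read lengths) so reads tile each transcript.
#' @param seed integer seed; identical arguments give identical sequences.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @examples
#' ref <- buildReference(1, c(2200, 2200), seed = 7)
#' width(ref)  # 2200, the length scale of a short spliced lncRNA
#' @export
buildReference <- function(nTranscripts, lengthRange, seed) {
    if (length(nTranscripts) != 1L || is.na(nTranscripts) || nTranscripts < 1)
        stop("'nTranscripts' must be a single integer >= 1")
    if (length(lengthRange) != 2L || anyNA(lengthRange) ||
        lengthRange[1L] > lengthRange[2L] || lengthRange[1L] < 150)
        stop("'lengthRange' must be c(min, max) with 150 <= min <= max")
    nTranscripts <- as.integer(nTranscripts)
    lengthRange <- as.integer(lengthRange)
    withSeed(seed, {
        lens <- if (lengthRange[1L] == lengthRange[2L])
            rep(lengthRange[1L], nTranscripts)
        else
            sample(seq(lengthRange[1L], lengthRange[2L]), nTranscripts,
                   replace = TRUE)
        seqs <- vapply(lens, function(L)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""),
            character(1))
        ref <- DNAStringSet(seqs)
        names(ref) <- paste0("tx", seq_len(nTranscripts))
        ref
    })
}

#' Plant ground-truth m6A sites into a reference
#'
#' Chooses `nSites` positions (spread across transcripts, separated by at
#' least `2 * readLength` within a transcript so reads never span two sites)
#' and locally edits at most 3 nt per site so that each position carries the
#' RAC methylation context: a purine at -1, the methylated A itself, and the C
#' at +1 where reverse transcription will leave the diagnostic conversion.
#' The edited reference is returned alongside the truth set so reads and
#' reference never disagree.
#'
#' @param ref a [Biostrings::DNAStringSet] reference.
#' @param nSites number of sites to plant, >= 0.
#' @param stoichiometry fraction of molecules methylated at each site, in
#'   \[0, 1\].
#' @param conversionProb probability that a read from a methylated, bound
#'   molecule converts the +1 C to T, in \[0, 1\].
#' @param seed integer seed.
#' @param readLength read length the libraries will use (spacing unit;
#'   default 50).
#' @return A list with `reference` (the possibly edited `DNAStringSet`) and
#'   `sites`, a [GenomicRanges::GRanges] of width-1 ranges at the methylated A
#'   with metadata columns `stoichiometry`, `conversionProb` and `edited`
#'   (number of bases changed to create the context).
#' @examples
#' ref <- buildReference(1, c(500, 500), seed = 1)
#' pl <- plantSites(ref, 3, stoichiometry = 1, conversionProb = 0.15, seed = 2)
#' pl$sites
#' @export
plantSites <- function(ref, nSites, stoichiometry, conversionProb, seed,
                       readLength = 50L) {
    stopifnot(is(ref, "DNAStringSet"))
    if (length(nSites) != 1L || is.na(nSites) || nSites < 0)
        stop("'nSites' must be a single integer >= 0")
    for (p in c(stoichiometry, conversionProb))
        if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
            stop("'stoichiometry' and 'conversionProb' must be in [0, 1]")
    nSites <- as.integer(nSites)
    readLength <- as.integer(readLength)
    lens <- Biostrings::width(ref)
    names(lens) <- names(ref)
    empty <- GRanges(seqlengths = lens)
    mcols(empty) <- S4Vectors::DataFrame(
        stoichiometry = numeric(0), conversionProb = numeric(0),
        edited = integer(0))
    if (nSites == 0L)
        return(list(reference = ref, sites = empty))

    spacing <- 2L * readLength
    ## candidate A positions keep a read length away from transcript ends so
    ## coverage at the site is not on the edge ramp
    cand <- lapply(names(ref), function(tx) {
        L <- lens[[tx]]
        lo <- max(2L, readLength)
        hi <- min(L - 1L, L - readLength)
        if (hi < lo) integer(0) else seq.int(lo, hi)
    })
    names(cand) <- names(ref)

    withSeed(seed, {
        chosenTx <- character(nSites)
        chosenPos <- integer(nSites)
        for (i in seq_len(nSites)) {
            open <- names(cand)[vapply(cand, length, integer(1)) > 0L]
            if (!length(open))
                stop("cannot place ", nSites,
                     " sites without overlap at spacing ", spacing, " nt")
            tx <- if (length(open) == 1L) open else sample(open, 1L)
            pos <- cand[[tx]][sample.int(length(cand[[tx]]), 1L)]
            cand[[tx]] <- cand[[tx]][abs(cand[[tx]] - pos) >= spacing]
            chosenTx[i] <- tx
            chosenPos[i] <- pos
        }
        ord <- order(match(chosenTx, names(ref)), chosenPos)
        chosenTx <- chosenTx[ord]
        chosenPos <- chosenPos[ord]

        seqs <- as.character(ref)
        edited <- integer(nSites)
        for (i in seq_len(nSites)) {
            s <- seqs[[chosenTx[i]]]
            pos <- chosenPos[i]
            ctx <- substring(s, pos - 1L, pos + 1L)
            want <- ctx
            if (!substring(ctx, 1L, 1L) %in% c("A", "G"))
                substring(want, 1L, 1L) <- "G"
            substring(want, 2L, 2L) <- "A"
            substring(want, 3L, 3L) <- "C"
            edited[i] <- sum(strsplit(ctx, "")[[1]] != strsplit(want, "")[[1]])
            substring(s, pos - 1L, pos + 1L) <- want
            seqs[[chosenTx[i]]] <- s
        }
        out <- DNAStringSet(seqs)
        names(out) <- names(ref)
        sites <- GRanges(chosenTx, IRanges(chosenPos, width = 1L),
                         strand = "+", seqlengths = lens)
        mcols(sites) <- S4Vectors::DataFrame(
            stoichiometry = rep(stoichiometry, nSites),
            conversionProb = rep(conversionProb, nSites),
            edited = edited)
        list(reference = out, sites = sites)
    })
}

#' Simulate an aligned IP or input eCLIP library
#'
#' Emits sense-strand, ungapped single-end reads tiling each transcript at
#' roughly `depth(cfg)` coverage, as a SAM file of match-only alignments plus
#' the matching FASTQ. Background substitutions hit every base independently
#' at `backgroundError`. In an IP library, each read covering the +1 C of a
#' planted site carries the crosslink-induced C-to-T conversion independently
#' with probability `stoichiometry * ipEnrichment * conversionProb`; an input
#' library has no conversions, which is what makes input subtraction remove
#' every signal not caused by antibody crosslinking.
#'
#' @param ref reference `DNAStringSet` (the edited one returned by
#'   [plantSites()]).
#' @param sites `GRanges` of planted sites with `stoichiometry` and
#'   `conversionProb` metadata columns (may be empty).
#' @param cfg a [SimConfig-class]; its `seed` fixes the whole library.
#' @param kind `"IP"` or `"input"`.
#' @param samPath,fastqPath output file paths.
#' @return Invisibly, a list with `sam`, `fastq` and `nReads`.
#' @examples
#' ref <- buildReference(1, c(400, 400), seed = 1)
#' pl <- plantSites(ref, 1, 1, 0.15, seed = 2)
#' sam <- tempfile(fileext = ".sam"); fq <- tempfile(fileext = ".fastq")
#' simulateLibrary(pl$reference, pl$sites, simConfig(depth = 30), "IP",
#'                 sam, fq)
#' @export
simulateLibrary <- function(ref, sites, cfg = simConfig(),
                            kind = c("IP", "input"), samPath, fastqPath) {
    stopifnot(is(ref, "DNAStringSet"), is(cfg, "SimConfig"))
    kind <- match.arg(kind)
    validObject(cfg)
    lens <- Biostrings::width(ref)
    names(lens) <- names(ref)
    checkSitesAgainstReference(sites, ref)

    rl <- cfg@readLength
    if (any(lens < rl))
        stop("every transcript must be at least one read length long")
    seqs <- as.character(ref)

    withSeed(cfg@seed, {
        samBody <- character(0)
        fqRecs <- character(0)
        nTotal <- 0L
        qual <- strrep("I", rl)
        for (tx in names(ref)) {
            L <- lens[[tx]]
            n <- max(1L, as.integer(round(cfg@depth * L / rl)))
            starts <- sort(sample.int(L - rl + 1L, n, replace = TRUE))
            reads <- substring(seqs[[tx]], starts, starts + rl - 1L)

            ## uniform background substitutions, one event at a time so that
            ## several hits in one read all land
            if (cfg@backgroundError > 0) {
                k <- rbinom(1L, n * rl, cfg@backgroundError)
                if (k > 0L) {
                    idx <- sample.int(n * rl, k)
                    ri <- (idx - 1L) %/% rl + 1L
                    off <- (idx - 1L) %% rl + 1L
                    for (j in seq_len(k)) {
                        cur <- substring(reads[ri[j]], off[j], off[j])
                        alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
                        substring(reads[ri[j]], off[j], off[j]) <- alt
                    }
                }
            }

            ## crosslink chemistry: IP only, at the +1 C of each planted site
            if (kind == "IP" && length(sites)) {
                onTx <- sites[as.character(seqnames(sites)) == tx]
                for (i in seq_along(onTx)) {
                    cpos <- start(onTx)[i] + 1L
                    p <- mcols(onTx)$stoichiometry[i] *
                        cfg@ipEnrichment * mcols(onTx)$conversionProb[i]
                    cov <- which(starts <= cpos & starts + rl - 1L >= cpos)
                    if (!length(cov) || p <= 0)
                        next
                    hit <- cov[runif(length(cov)) < p]
                    if (length(hit)) {
                        sub <- reads[hit]
                        substring(sub, cpos - starts[hit] + 1L,
                                  cpos - starts[hit] + 1L) <- "T"
                        reads[hit] <- sub
                    }
                }
            }

            qn <- sprintf("%s_read%06d", tx, seq_len(n))
            samBody <- c(samBody, paste(qn, 0L, tx, starts, 60L,
                                        paste0(rl, "M"), "*", 0L, 0L,
                                        reads, qual, sep = "\t"))
            fqRecs <- c(fqRecs,
                        as.vector(rbind(paste0("@", qn), reads, "+", qual)))
            nTotal <- nTotal + n
        }
        header <- c("@HD\tVN:1.6\tSO:coordinate",
                    paste0("@SQ\tSN:", names(ref), "\tLN:", lens))
        writeLines(c(header, samBody), samPath)
        writeLines(fqRecs, fastqPath)
        invisible(list(sam = samPath, fastq = fastqPath, nReads = nTotal))
    })
}

## Consistency of a planted truth set with its (edited) reference: position in
## bounds, A at the site, C at +1, purine at -1.
checkSitesAgainstReference <- function(sites, ref) {
    if (is.null(sites) || length(sites) == 0L)
        return(invisible(TRUE))
    stopifnot(is(sites, "GRanges"))
    seqs <- as.character(ref)
    tx <- as.character(seqnames(sites))
    if (!all(tx %in% names(ref)))
        stop("planted site on transcript absent from reference")
    pos <- start(sites)
    lens <- Biostrings::width(ref)[match(tx, names(ref))]
    if (any(pos - 1L < 1L) || any(pos + 1L > lens))
        stop("planted site context extends outside its transcript")
    ctx <- substring(seqs[tx], pos - 1L, pos + 1L)
    ok <- substring(ctx, 2L, 2L) == "A" & substring(ctx, 3L, 3L) == "C" &
        substring(ctx, 1L, 1L) %in% c("A", "G")
    if (!all(ok))
        stop("planted site without RAC context in reference: ",
             paste0(tx[!ok], ":", pos[!ok], collapse = ", "))
    invisible(TRUE)
}

#' Write a planted truth set as BED
#'
#' One record per methylated A, 0-based half-open (a 1-based site 783 becomes
#' the interval \[782, 783)), name `m6A<pos>`, score =
#' `round(1000 * stoichiometry)`.
#'
#' @param sites `GRanges` from [plantSites()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTruthBed <- function(sites, path) {
    stopifnot(is(sites, "GRanges"))
    score <- if ("stoichiometry" %in% names(mcols(sites)))
        round(1000 * mcols(sites)$stoichiometry) else 0L
    lines <- paste(as.character(seqnames(sites)), start(sites) - 1L,
                   start(sites), paste0("m6A", start(sites)),
                   score, "+", sep = "\t")
    writeLines(lines, path)
    invisible(path)
}
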