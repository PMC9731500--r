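# Shared fixture builders, all constructed in code.

# Write a SAM file from hand-specified reads.
writeTestSam <- function(path, refLengths, reads) {
    header <- c("@HD\tVN:1.6",
                paste0("@SQ\tSN:", names(refLengths), "\tLN:", refLengths))
    body <- vapply(reads, function(r) {
        paste(r$qname, r$flag %||% 0L, r$tx, r$pos,
              r$mapq %||% 60L, r$cigar %||% paste0(nchar(r$seq), "M"),
              "*", 0L, 0L, r$seq, strrep("I", nchar(r$seq)), sep = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pileup built directly from a counts specification: uniform coverage of the
# reference base, with per-position overrides giving an alternative base
# `count` reads out of `depth` at `pos`.
makePileup <- function(refSeq, depth = 0L, overrides = list()) {
    sc <- strsplit(refSeq, "")[[1L]]
    bases <- c("A", "C", "G", "T", "N")
    m <- matrix(0L, nrow = 5L, ncol = length(sc),
                dimnames = list(bases, NULL))
    if (depth > 0L)
        for (i in seq_along(sc)) m[sc[i], i] <- depth
    for (ov in overrides) {
        d <- ov$depth %||% depth
        m[, ov$pos] <- 0L
        m[ov$base, ov$pos] <- ov$count
        m[sc[ov$pos], ov$pos] <- d - ov$count
    }
    meclipr:::Pileup(stats::setNames(list(m), "tx1"))
}

refFromString <- function(s, name = "tx1") {
    r <- Biostrings::DNAStringSet(s)
    names(r) <- name
    r
}

# Full simulate -> pileup -> scan -> call -> subtract run for one replicate.
runReplicate <- function(ref, sites, cfgIP, cfgInput, params = callingParams(),
                         replicateId = "rep1") {
    dir <- tempfile("rep")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    ipSam <- file.path(dir, "ip.sam"); ipFq <- file.path(dir, "ip.fastq")
    inSam <- file.path(dir, "in.sam"); inFq <- file.path(dir, "in.fastq")
    simulateLibrary(ref, sites, cfgIP, "IP", ipSam, ipFq)
    simulateLibrary(ref, sites, cfgInput, "input", inSam, inFq)
    ipCalls <- callSites(scanCtSignals(pileupReads(ipSam, ref), ref), ref,
                         params, replicateId)
    inputCalls <- callSites(scanCtSignals(pileupReads(inSam, ref), ref), ref,
                            params, replicateId)
    subtractInput(ipCalls, inputCalls)
}

# Planted-truth consensus experiment under the default study conditions:
# 20 sites over two 2.5 kb transcripts, stoichiometry 1, conversion 0.15,
# depth 200, background 1e-3, 3 replicates, consensus in 2+.
runConsensusExperiment <- function(seed, nSites = 20L, depth = 200,
                                   conversion = 0.15, stoichiometry = 1,
                                   backgroundError = 0.001, nReps = 3L) {
    ref0 <- buildReference(2, c(2500, 2500), seed = seed)
    pl <- plantSites(ref0, nSites, stoichiometry, conversion, seed = seed + 1L)
    callSets <- lapply(seq_len(nReps), function(r) {
        cfgIP <- simConfig(depth = depth, backgroundError = backgroundError,
                           seed = seed * 1000L + r)
        cfgInput <- simConfig(depth = depth,
                              backgroundError = backgroundError,
                              seed = seed * 1000L + 500L + r)
        runReplicate(pl$reference, pl$sites, cfgIP, cfgInput,
                     replicateId = paste0("rep", r))
    })
    names(callSets) <- paste0("rep", seq_len(nReps))
    cons <- buildConsensus(callSets, minReplicates = 2L)
    truthKey <- paste0(as.character(GenomicRanges::seqnames(pl$sites)), ":",
                       GenomicRanges::start(pl$sites))
    called <- cons[GenomicRanges::mcols(cons)$consensus]
    calledKey <- paste0(as.character(GenomicRanges::seqnames(called)), ":",
                        GenomicRanges::start(called))
    list(sensitivity = mean(truthKey %in% calledKey),
         precision = if (length(calledKey)) mean(calledKey %in% truthKey)
                     else NA_real_,
         nConsensus = length(calledKey), truth = pl$sites,
         consensus = cons, callSets = callSets)
}
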