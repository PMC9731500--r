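# Independent brute-force oracles. These re-derive every quantity from raw
# SAM text with plain string handling so they share no code with the package
# path they check.

# Per-position base counts straight from SAM lines: primary, mapped,
# forward-strand records with a pure-match CIGAR.
oracleCounts <- function(samLines, refLengths) {
    bases <- c("A", "C", "G", "T", "N")
    counts <- lapply(refLengths, function(L)
        matrix(0L, nrow = 5L, ncol = L, dimnames = list(bases, NULL)))
    for (ln in samLines) {
        if (startsWith(ln, "@")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        flag <- as.integer(f[2L])
        if (bitwAnd(flag, 4L + 16L + 256L + 2048L) != 0L) next
        if (!grepl("^[0-9]+[M=X]$", f[6L])) next
        tx <- f[3L]
        pos <- as.integer(f[4L])
        chars <- strsplit(f[10L], "")[[1L]]
        for (k in seq_along(chars)) {
            b <- if (chars[k] %in% bases) chars[k] else "N"
            counts[[tx]][b, pos + k - 1L] <- counts[[tx]][b, pos + k - 1L] + 1L
        }
    }
    counts
}

# Threshold caller applied directly to oracle counts: RAC context, event
# count, inclusive frequency window. Returns data.frame(transcript, a_pos).
oracleCall <- function(counts, refSeqs, minCount = 3L, minFreq = 0.025,
                       maxFreq = 0.50) {
    out <- NULL
    for (tx in names(counts)) {
        m <- counts[[tx]]
        sc <- strsplit(refSeqs[[tx]], "")[[1L]]
        for (cpos in which(sc == "C")) {
            ct <- m["T", cpos]
            depth <- sum(m[, cpos])
            if (ct < minCount || depth == 0L) next
            f <- ct / depth
            if (f < minFreq || f > maxFreq) next
            a <- cpos - 1L
            if (a < 2L) next
            if (!(sc[a] == "A" && sc[a - 1L] %in% c("A", "G"))) next
            out <- rbind(out, data.frame(transcript = tx, a_pos = a))
        }
    }
    if (is.null(out))
        data.frame(transcript = character(0), a_pos = integer(0))
    else out
}
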