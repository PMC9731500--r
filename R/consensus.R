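#' Combine replicate call sets into consensus sites
#'
#' Sites are matched across replicates by exact (transcript, position)
#' identity — the method is single-nucleotide, so no fuzzy window is applied.
#' Every site appearing in any replicate appears exactly once in the output;
#' a site is flagged `consensus` when detected in at least `minReplicates`
#' replicates. Tiers are kept per replicate and need not agree for a site to
#' reach consensus.
#'
#' @param callSets named list of call `GRanges` (one per replicate) over the
#'   same reference.
#' @param minReplicates minimum supporting replicates for the consensus flag
#'   (default 2).
#' @return A sorted `GRanges` with metadata columns `nSupporting` (integer),
#'   `consensus` (logical) and `tiers` (a [IRanges::CharacterList] whose
#'   elements are named by replicate).
#' @examples
#' # a site seen in 2 of 3 replicates is consensus; 1 of 3 is not
#' @export
buildConsensus <- function(callSets, minReplicates = 2L) {
    if (length(minReplicates) != 1L || is.na(minReplicates) ||
        minReplicates < 1)
        stop("'minReplicates' must be a single integer >= 1")
    minReplicates <- as.integer(minReplicates)
    stopifnot(is.list(callSets), length(callSets) >= 1L)
    if (is.null(names(callSets)))
        names(callSets) <- paste0("rep", seq_along(callSets))
    for (cs in callSets)
        stopifnot(is(cs, "GRanges"))

    keys <- lapply(callSets, siteKey)
    allKeys <- unique(unlist(keys, use.names = FALSE))
    if (!length(allKeys)) {
        gr <- GRanges(seqinfo = GenomicRanges::seqinfo(callSets[[1L]]))
        mcols(gr) <- S4Vectors::DataFrame(
            nSupporting = integer(0), consensus = logical(0),
            tiers = IRanges::CharacterList())
        return(gr)
    }
    parts <- strsplit(allKeys, ":", fixed = TRUE)
    tx <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    tiers <- lapply(allKeys, function(k) {
        hit <- vapply(keys, function(ks) k %in% ks, logical(1))
        out <- vapply(which(hit), function(i) {
            m <- mcols(callSets[[i]])
            as.character(m$tier[keys[[i]] == k][1L])
        }, character(1))
        names(out) <- names(callSets)[hit]
        out
    })
    gr <- GRanges(tx, IRanges(pos, width = 1L), strand = "+",
                  seqinfo = GenomicRanges::seqinfo(callSets[[1L]]))
    n <- lengths(tiers)
    mcols(gr) <- S4Vectors::DataFrame(
        nSupporting = as.integer(n),
        consensus = n >= minReplicates,
        tiers = IRanges::CharacterList(tiers))
    sort(gr)
}

OCCURRENCE_SYMBOLS <- c(high = "X", low = "x", reduced = "*")

#' Site-by-experiment occurrence matrix
#'
#' Rows are sites (union over experiments, sorted by transcript then
#' position), columns are experiments. Cells carry the tier symbol — "X" for
#' high confidence, "x" for low, "*" for reduced-threshold — or blank where
#' the site was not detected.
#'
#' @param callSets named list of call `GRanges`, one per experiment.
#' @return A character matrix with rownames `transcript:position`.
#' @export
occurrenceMatrix <- function(callSets) {
    stopifnot(is.list(callSets))
    if (is.null(names(callSets)))
        names(callSets) <- paste0("exp", seq_along(callSets))
    keys <- lapply(callSets, siteKey)
    allKeys <- unique(unlist(keys, use.names = FALSE))
    if (!length(allKeys))
        return(matrix(character(0), nrow = 0, ncol = length(callSets),
                      dimnames = list(NULL, names(callSets))))
    parts <- strsplit(allKeys, ":", fixed = TRUE)
    tx <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    ord <- order(tx, pos)
    allKeys <- allKeys[ord]
    m <- matrix("", nrow = length(allKeys), ncol = length(callSets),
                dimnames = list(allKeys, names(callSets)))
    for (j in seq_along(callSets)) {
        tier <- as.character(mcols(callSets[[j]])$tier)
        hit <- match(keys[[j]], allKeys)
        m[hit[!is.na(hit)], j] <-
            unname(OCCURRENCE_SYMBOLS[tier[!is.na(hit)]])
    }
    m
}

#' Export and import site tables
#'
#' `format = "TSV"` writes a lossless table (`transcript`, `a_position`, and
#' every scalar metadata column; per-replicate tiers are serialised as
#' `rep=tier` pairs joined with `;`) that [importSites()] restores exactly.
#' `format = "BED"` writes 0-based half-open single-base intervals named
#' `m6A<1-based pos>`, sorted lexicographically by chrom then start, scored
#' by `round(1000 * frequency)` when a frequency column exists, else by the
#' supporting-replicate count, else 0.
#'
#' @param sites a `GRanges` of calls or consensus sites.
#' @param path output path.
#' @param format `"TSV"` or `"BED"`.
#' @return Invisibly, `path`.
#' @export
exportSites <- function(sites, path, format = c("TSV", "BED")) {
    stopifnot(is(sites, "GRanges"))
    format <- match.arg(format)
    m <- mcols(sites)
    if (format == "BED") {
        chrom <- as.character(seqnames(sites))
        score <- if ("frequency" %in% names(m)) round(1000 * m$frequency)
            else if ("nSupporting" %in% names(m)) m$nSupporting
            else rep(0L, length(sites))
        ord <- order(chrom, start(sites))
        writeLines(paste(chrom[ord], start(sites)[ord] - 1L,
                         start(sites)[ord],
                         paste0("m6A", start(sites)[ord]),
                         score[ord], "+", sep = "\t"), path)
        return(invisible(path))
    }
    tab <- data.frame(transcript = as.character(seqnames(sites)),
                      a_position = start(sites))
    for (nm in names(m)) {
        col <- m[[nm]]
        tab[[nm]] <- if (is(col, "CharacterList"))
            vapply(col, function(x)
                paste(names(x), x, sep = "=", collapse = ";"), character(1))
        else col
    }
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname exportSites
#' @return `importSites` returns the `GRanges` rebuilt from a TSV written by
#'   [exportSites()].
#' @export
importSites <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(transcript = "character"))
    gr <- GRanges(tab$transcript, IRanges(tab$a_position, width = 1L),
                  strand = "+")
    keep <- setdiff(names(tab), c("transcript", "a_position"))
    mc <- S4Vectors::DataFrame(row.names = seq_len(nrow(tab)))
    for (nm in keep) {
        if (nm == "tiers") {
            mc[[nm]] <- IRanges::CharacterList(
                lapply(strsplit(tab[[nm]], ";", fixed = TRUE), function(x) {
                    kv <- strsplit(x, "=", fixed = TRUE)
                    out <- vapply(kv, `[`, character(1), 2L)
                    names(out) <- vapply(kv, `[`, character(1), 1L)
                    out
                }))
        } else {
            mc[[nm]] <- tab[[nm]]
        }
    }
    mcols(gr) <- mc
    gr
}
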