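## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = genv, inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
                    rm(".Random.seed", envir = genv), add = TRUE)
    }
    set.seed(seed)
    expr
}

## seqnames:start key used for exact single-nucleotide site identity
siteKey <- function(gr) {
    if (length(gr) == 0L)
        return(character(0))
    paste0(as.character(GenomicRanges::seqnames(gr)),
           ":", GenomicRanges::start(gr))
}
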