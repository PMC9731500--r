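# meclipr

Single-nucleotide N6-methyladenosine (m6A) site calling from
crosslink-induced C→T conversions, with the downstream quantification
helpers that typically accompany an m6A study of a long noncoding RNA:
percent-input RIP recovery, ΔΔCt chromatin association, growth-curve
doubling times, peak proximity/metaprofiles around sites, and antimorph
classification of paired differential-expression contrasts.

## Who this is for

Groups mapping m6A with an antibody-based eCLIP protocol (meCLIP-style),
where reverse transcription through the antibody–RNA crosslink leaves a
diagnostic C→T substitution at the base immediately 3′ of the methylated
adenosine. The package turns aligned IP and input libraries into a
single-nucleotide site table and reproduces the whole decision rule as
testable code. A bundled, seed-deterministic read simulator with planted
ground-truth sites means every stage can be validated offline, with no
sequencing data download.

## The calling scheme

A candidate site is a reference cytosine where reads show T. Writing `k`
for the number of C→T reads and `n` for the total reads at that position,
the caller keeps a candidate when:

1. **Motif** — the preceding two bases form the RAC context:
   `ref[a-1] ∈ {A, G}`, `ref[a] = A`, `ref[a+1] = C`, where `a` is the
   reported (methylated) adenosine and the conversion sits at `a + 1`;
2. **Events** — `k ≥ 3` (or `k ≥ 2` in reduced mode, tiered separately);
3. **Frequency** — `0.025 ≤ k/n ≤ 0.50`, both bounds inclusive. The upper
   bound discards signals mutated in most reads, which behave like genetic
   variants rather than sub-stoichiometric crosslink chemistry.

Calls with `k ≥ 3` and `k/n ≥ 0.05` are tiered **high** confidence ("X" in
occurrence matrices), other 3-event calls **low** ("x"), and 2-event calls
**reduced** ("*"). Sites also called in the matched input library are
removed (they cannot have been antibody-induced), and sites detected in
2+ replicates form the consensus set.

## Worked example

```r
library(meclipr)

ref0 <- buildReference(1, c(2200, 2200), seed = 7)       # one 2.2 kb transcript
pl   <- plantSites(ref0, 4, stoichiometry = 1,
                   conversionProb = 0.15, seed = 8)

sam <- tempfile(fileext = ".sam")
simulateLibrary(pl$reference, pl$sites, simConfig(depth = 200, seed = 9),
                "IP", sam, tempfile(fileext = ".fastq"))

sig   <- scanCtSignals(pileupReads(sam, pl$reference), pl$reference)
calls <- callSites(sig, pl$reference)
calls
#> GRanges object with 4 ranges and 6 metadata columns:
#>       seqnames    ranges strand |       motif   ctCount     depth frequency
#>          <Rle> <IRanges>  <Rle> | <character> <integer> <integer> <numeric>
#>   [1]      tx1       640      + |         GAC        38       188  0.202128
#>   [2]      tx1      1256      + |         GAC        28       231  0.121212
#>   [3]      tx1      1381      + |         GAC        28       211  0.132701
#>   [4]      tx1      1937      + |         GAC        44       209  0.210526
#>              tier   replicate
#>       <character> <character>
#>   [1]        high        rep1
#>   [2]        high        rep1
#>   [3]        high        rep1
#>   [4]        high        rep1

GenomicRanges::start(pl$sites)   # planted truth
#> [1]  640 1256 1381 1937
```

All four planted adenosines are recovered at their exact positions, in the
RAC context, at conversion frequencies near the planted
`stoichiometry × conversionProb = 0.15`, and tiered high confidence
(≥ 3 events, ≥ 5% of reads). With replicates, `subtractInput()` and
`buildConsensus()` produce the final consensus table, and
`occurrenceMatrix()` the X/x/* site-by-experiment summary.

Downstream helpers follow the same conventions, e.g.:

```r
percentInput(ctInput = 20, ctIp = 21, inputFraction = 0.05)  # 0.025
doublingTime(seq(0, 48, 2), 5 * 2^(seq(0, 48, 2) / 26.5))$hours  # 26.5
```

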