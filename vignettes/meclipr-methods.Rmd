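---
title: "Conversion-based m6A site calling: model, parameters and design notes"
author: "meclipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-based m6A site calling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meclipr)
```

## The detection model

Antibody-based eCLIP of N6-methyladenosine leaves a chemical footprint in
the sequencing data: when reverse transcriptase reads through the
crosslinked antibody–RNA adduct, it misincorporates at the cytosine
immediately 3′ of the methylated adenosine, so an m6A site appears as a
C→T mismatch population at a single known offset. Because methylation is
sub-stoichiometric and crosslinking is inefficient, a genuine site shows
an intermediate conversion frequency — well above sequencing error, well
below the near-100% signature of a genetic variant. The caller encodes
this as three filters applied to every reference C where at least one
read shows T (writing `k` for C→T reads and `n` for total reads at that
position):

* **RAC motif.** m6A in this chemistry occurs as the central A of a
  purine–A–C trinucleotide; the conversion is at the C. A call at
  adenosine `a` therefore requires `ref[a-1] ∈ {A,G}`, `ref[a] = A`,
  `ref[a+1] = C`. Transcript-edge positions with incomplete context are
  never callable. Non-canonical contexts such as GAACG pass, since their
  central A still sits between a purine and a C.
* **Event count.** `k ≥ 3` by default. A *reduced* mode lowers this to 2
  for low-coverage settings; such calls are tiered separately and the
  frequency window still applies (the reduced rule is described only as
  lowering the event count, so we keep every other filter unchanged).
* **Frequency window.** `0.025 ≤ k/n ≤ 0.50`, both bounds inclusive (the
  thresholds are stated as "greater than or equal to" / "less than or
  equal to"). Our reading of the upper bound — that near-fixed C→T
  signals are genetic variants rather than crosslink chemistry — is an
  interpretation, and the simulator's germline-variant construction in
  the test suite exercises exactly that case.

Confidence tiers follow the event count and frequency: **high** for
`k ≥ 3` at `k/n ≥ 0.05`, **low** for `k ≥ 3` below that, **reduced** for
2-event calls. Sites also called in the matched input library (same
thresholds, since no separate input thresholds are defined; an override
is available by passing different `CallingParams`) are subtracted —
whatever appears without the antibody cannot be crosslink-induced. Sites
found in 2 or more replicates form the consensus set; matching is by
exact coordinate, as befits a single-nucleotide method, and tiers need
not agree across replicates.

## Coordinates and depth conventions

All reports are 1-based and inclusive, matching "A783"-style site labels;
BED output alone is 0-based half-open (site 783 → `[782, 783)`). The
frequency denominator is the total read count at the C position with all
bases included (N too): the method statement says "of the total reads at
a given position" without specifying the denominator's composition, and
this is the most literal reading. Reverse-strand alignments are excluded
rather than complemented — the libraries modelled here are stranded, and
silent complementing risks double-counting conventions — and tallied in
the pileup's `skipped` slot. Secondary and supplementary alignments are
always dropped; mapping quality is not filtered by default but a
threshold is exposed. Records with indel or clipping operations are
skipped and counted: the in-scope read source (the simulator) emits
match-only alignments, and indels are an explicit simulator non-goal.

## What the simulator emulates — and what it does not

`buildReference()`, `plantSites()` and `simulateLibrary()` generate the
entire study substrate in code. Reads are sense-strand, ungapped,
uniform-length, tiled uniformly at a configurable mean depth, and written
directly as aligned SAM plus FASTQ — alignment itself is out of scope,
which keeps the pipeline download-free. At a planted site, each IP read
covering the +1 C carries the conversion independently with probability
`stoichiometry × ipEnrichment × conversionProb`; input reads never do.
Background substitutions hit every base uniformly at `backgroundError`.
Planted sites are spaced at least two read lengths apart so no read spans
two sites, keeping the per-site binomial law exact — which is what the
frequency-law test checks against a 4-standard-deviation bound.

Defaults (`simConfig()`: 50 nt reads, depth 200, background 1e-3, full IP
enrichment) are chosen so boundary tests are well-powered at desk scale.
Transcript lengths in examples follow the ~2.2 kb scale of a short
spliced lncRNA. Stoichiometry has no default: it is a free biological
parameter (per-site methylation fractions are rarely known; a single
estimate of roughly 25% minimum exists for the best-characterised site in
one cell line), so experiments state it explicitly.

Passing tests on this generator demonstrate that the decision rule is
implemented exactly and recovers planted truth under its own generative
assumptions. They do not demonstrate robustness to what real libraries
add: PCR duplicates and UMI structure, indels and soft-clipping, uneven
coverage, strand bleed-through, reverse-transcription stops competing
with read-through misincorporation, or genome-space (multi-exon)
coordinates. Those are listed non-goals.

## Downstream quantification

* **Percent input**: `inputFraction × 2^(ctInput − ctIp)`, the standard
  RIP convention with amplification efficiency fixed at 2.0 (the source
  method states only that recovery is computed from input and IP values,
  so the dilution bookkeeping is this package's decision, exposed via
  `inputFraction`). Recoveries above 1 are returned but flagged.
  `regionProfile()` then normalises per-region recoveries to a region
  with no detected sites.
* **Chromatin association**: the ΔΔCt chain
  `2^-[(Ct_target,chr − Ct_target,input) − (Ct_norm,chr − Ct_norm,input)]`
  relative to a baseline condition (exactly 1 by construction). Whether
  the normaliser ratio should use input or total RNA as denominator is
  under-specified in the source; this chain is one consistent reading.
* **Doubling time**: ordinary least squares on `log2(confluence)` vs
  time; the reciprocal slope is the doubling time. This log-linear fit is
  equivalent to the cited least-squares exponential method up to the
  noise model and was chosen for being closed-form and deterministic.
  Slopes within numerical noise of zero (≤ 1e-9 doublings/h) are
  reported as non-growing with an undefined doubling time rather than an
  absurdly large one.
* **Peak proximity**: a site is proximal when the gap to the nearest
  peak edge is at most the window (inclusive; 1,000 nt default). The
  source states the window but not edge-vs-center or inclusivity;
  site-to-edge inclusive is the more generous and simpler rule.
  `metaprofile()` averages interval signal by offset in
  `[-halfwidth, +halfwidth]`, clipping sites near sequence ends to their
  valid offsets.
* **Antimorph classification**: among genes significant (adjusted
  p < 0.1) in the condition-vs-control contrast, those significant in the
  mutant-vs-control contrast with opposing fold-change sign are the
  antimorph ("opposite") class; matching sign is "same"; the rest
  "A_only", with "B_only" for mutant-only responders. Adjusted p values
  are consumed as given — the expression pipeline that produced them is
  out of scope, and re-adjusting would double-count. The fold-change
  correlation uses genes with linear |FC| > 1.15 in **both** contrasts
  ("in either direction" → symmetric on |log2FC| > log2 1.15); whether
  the original analysis plotted linear or log2 axes is not stated, so
  both correlations are returned with linear as the default, on the
  signed linear scale (`2^x` for `x ≥ 0`, `−2^−x` otherwise, the
  "−3.5-fold" reporting convention).

## Numerical and degenerate-input choices

Empty SAM files produce all-zero pileups; empty signal tables produce
empty, fully-typed call sets. Positions holding N in the reference are
never callable. Consensus matching is exact — no fuzzy window — and the
occurrence matrix is pure bookkeeping (X/x/* per tier, blank when
absent). All randomness flows through explicit integer seeds;
identical inputs give byte-identical FASTA/FASTQ/SAM output. Site
placement retries are bounded by construction (candidates are removed as
spacing is consumed), and an impossible request fails loudly rather than
degrading spacing.

## Problem sizes used in validation

The end-to-end recovery check plants 20 sites across two 2.5 kb
transcripts at stoichiometry 1 and conversion probability 0.15, simulates
three IP/input replicate pairs at depth 200 with background 1e-3, and
requires consensus sensitivity and precision of at least 0.9 against the
planted truth, averaged over five seeds. At these settings a site
accumulates ~30 conversion events in ~200 reads, so per-replicate
detection is essentially certain and failures would indicate bookkeeping
errors, not bad luck. A brute-force oracle that re-counts bases straight
from SAM text (sharing no code with the pipeline) must agree exactly on
instances of up to 200 reads. The boundary behaviour of every threshold
is pinned on constructed pileups where `k` and `n` are chosen to land
exactly on, and just off, each bound.

## Known limitations

Single-transcript (transcriptome-space) coordinates only; no
genome↔transcript liftover. No statistical model of conversion counts —
the method is threshold-based by design, so no p-values accompany calls.
The simulator's uniform-coverage, duplicate-free reads make precision
estimates optimistic relative to real libraries. One supplementary-table
exclusion in the source data (a site omitted from downstream mutant
constructs without a stated rule) has no counterpart here: no ad hoc
exclusion logic is implemented.
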