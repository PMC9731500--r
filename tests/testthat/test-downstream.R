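test_that("percent input follows the closed form and flags impossibilities", {
    # equal Cts recover exactly the input fraction
    expect_equal(as.numeric(percentInput(20, 20, 0.05)), 0.05)
    # a Ct gap of log2(20) with a 5% input is complete recovery
    expect_equal(as.numeric(percentInput(20 + log2(20), 20, 0.05)), 1.0)
    # Ct gap of 3 cycles at 1% input: 0.01 * 2^3 = 0.08
    expect_equal(as.numeric(percentInput(23, 20, 0.01)), 0.08)

    # recoveries above 1 are returned but flagged
    expect_warning(r <- percentInput(30, 20, 0.05), "exceed 1")
    expect_true(attr(r, "flagged"))
    expect_equal(as.numeric(r), 0.05 * 2^10)

    expect_error(percentInput(Inf, 20, 0.05), "finite")
    expect_error(percentInput(20, 20, 0), "inputFraction")

    # strictly increasing in the Ct gap, linear in the input fraction
    gaps <- seq(-3, 6, by = 0.5)
    vals <- vapply(gaps, function(g)
        as.numeric(percentInput(20 + g, 20, 0.01)), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_equal(as.numeric(percentInput(22, 20, 0.10)),
                 10 * as.numeric(percentInput(22, 20, 0.01)))
})

test_that("region profiles normalise to the m6A-free reference region", {
    rec <- c(`723-808` = 0.08, `1819-1923` = 0.04, `328-432` = 0.04)
    prof <- regionProfile(rec, "1819-1923")
    expect_equal(unname(prof[["1819-1923"]]), 1.0)
    expect_equal(unname(prof[["723-808"]]), 2.0)
    # uniform recoveries flatten to 1
    expect_equal(unname(regionProfile(c(a = 0.3, b = 0.3), "a")[["b"]]), 1.0)
    expect_error(regionProfile(rec, "missing"), "not found")
    expect_error(regionProfile(c(a = 0, b = 1), "a"), "positive")
})

test_that("chromatin association is a delta-delta-Ct chain over a baseline", {
    # baseline condition is exactly 1 by construction
    r <- chromatinAssociation(c(WT = 20, mut = 20), c(WT = 18, mut = 18),
                              c(WT = 15, mut = 15), c(WT = 14, mut = 14),
                              baseline = "WT")
    expect_equal(unname(r[["WT"]]), 1.0)

    # target enriched 2 cycles beyond the normaliser versus baseline: 2^2
    r2 <- chromatinAssociation(c(WT = 20, mut = 18), c(WT = 18, mut = 18),
                               c(WT = 15, mut = 15), c(WT = 14, mut = 14),
                               baseline = "WT")
    expect_equal(unname(r2[["mut"]]), 4.0)

    # invert the formula: construct Cts encoding a 4.3-fold difference
    delta <- log2(4.3)
    r3 <- chromatinAssociation(
        c(WT = 20, mut = 20 - delta), c(WT = 17, mut = 17),
        c(WT = 16, mut = 16), c(WT = 15, mut = 15), baseline = "WT")
    expect_equal(unname(r3[["mut"]]), 4.3)

    expect_error(chromatinAssociation(c(WT = 20), c(WT = 18),
                                      c(WT = NA), c(WT = 14)), "finite")
    expect_error(chromatinAssociation(20, 18, 15, 14), "named")
})

test_that("doubling time recovers exact exponentials and flags non-growth", {
    tt <- seq(0, 48, by = 2)
    # confluence doubling every 24 h
    fit <- doublingTime(tt, 2 * 2^(tt / 24))
    expect_true(fit$growing)
    expect_lt(abs(fit$hours - 24) / 24, 1e-9)

    # the 26.5 h scale of a typical transformed line
    fit2 <- doublingTime(tt, 5 * 2^(tt / 26.5))
    expect_lt(abs(fit2$hours - 26.5) / 26.5, 1e-9)

    # exactness holds across the plausible range of doubling times,
    # starting each curve low enough to stay within 100% confluence
    for (Td in c(5, 12.5, 33, 71, 100)) {
        f <- doublingTime(tt, 80 / 2^(max(tt) / Td) * 2^(tt / Td))
        expect_equal(f$hours, Td, tolerance = 1e-9)
    }

    # constant confluence is not growth
    flat <- doublingTime(tt, rep(40, length(tt)))
    expect_false(flat$growing)
    expect_true(is.na(flat$hours))

    expect_error(doublingTime(c(0, 2), c(1, 2)), "3 time points")
    expect_error(doublingTime(c(0, 2, 2), c(1, 2, 3)), "increasing")
    expect_error(doublingTime(tt, rep(0, length(tt))), "confluence")

    # 1% multiplicative noise: median |relative error| below 5%
    relerr <- vapply(1:100, function(s) {
        withr::with_seed(s, {
            conf <- pmin(100, 5 * 2^(tt / 26.5) *
                             exp(rnorm(length(tt), 0, 0.01)))
            abs(doublingTime(tt, conf)$hours - 26.5) / 26.5
        })
    }, numeric(1))
    expect_lt(median(relerr), 0.05)
})

test_that("peak proximity measures site-to-edge distance inclusively", {
    s <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5000))
    # BED-style [5790, 5810) is 1-based 5791..5810: edge gap 790
    p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5791, 5810))
    expect_identical(peakProximity(s, p, 1000)$nProximal, 1L)
    # nearest edge at 6500: 1499 nt away, outside a 1000 nt window
    pFar <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6500, 6600))
    expect_identical(peakProximity(s, pFar, 1000)$nProximal, 0L)
    # exactly at the boundary is proximal (inclusive)
    pEdge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6001, 6010))
    expect_identical(peakProximity(s, pEdge, 1000)$nProximal, 1L)

    # planted construction: 100 sites, 4 with peaks inside the window
    sites <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(seq(10000, by = 5000,
                                                         length.out = 100),
                                                     width = 1L))
    near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        GenomicRanges::start(sites)[c(3, 20, 55, 90)] + 400, width = 50L))
    res <- peakProximity(sites, near, 1000)
    expect_identical(res$nProximal, 4L)
    expect_equal(res$fraction, 0.04)

    # widening the window never loses proximal sites
    expect_gte(peakProximity(sites, near, 2000)$nProximal, res$nProximal)
    expect_error(peakProximity(sites, near, -1), "window")
})

test_that("metaprofiles average signal by offset with edge clipping", {
    sites <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(2000L, 6000L, 9000L), width = 1L))
    # uniform signal everywhere: flat profile
    uni <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 20000L))
    GenomicRanges::mcols(uni)$score <- 2
    prof <- metaprofile(sites, uni, halfwidth = 500, bins = 20)
    expect_lt(max(prof$meanSignal) - min(prof$meanSignal), 1e-9)
    expect_identical(nrow(prof), 20L)

    # signal depleted in a central +/-50 nt notch at every site: minimum at 0
    notch <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 20000L))
    GenomicRanges::mcols(notch)$score <- 1
    holes <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(GenomicRanges::start(sites) - 50L,
                                 GenomicRanges::start(sites) + 50L))
    GenomicRanges::mcols(holes)$score <- -1
    profN <- metaprofile(sites, c(notch, holes), halfwidth = 500, bins = 21)
    central <- which.min(abs(profN$offsetCenter))
    expect_identical(which.min(profN$meanSignal), central)

    # single site, single peak at +200: signal confined to that bin
    one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000L, 5000L))
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5200L, 5200L))
    prof1 <- metaprofile(one, pk, halfwidth = 1000, bins = 50)
    nz <- which(prof1$meanSignal > 0)
    expect_length(nz, 1L)
    expect_true(prof1$offsetStart[nz] <= 200 && prof1$offsetEnd[nz] >= 200)

    expect_error(metaprofile(one[0], pk), "no sites")
    expect_error(metaprofile(one, pk, halfwidth = 0), "halfwidth")
})

test_that("antimorph classification matches hand enumeration on a toy table", {
    tab <- data.frame(
        gene = c("SEMA5A", "sameUp", "aOnly", "bOnly", "ns", "oppUp"),
        log2fc_a = c(-1.81, 2.0, 1.5, 0.2, 0.1, 1.32),
        padj_a   = c(0.0002, 0.01, 0.05, 0.5, 0.9, 0.006),
        log2fc_b = c(1.49, 1.8, 0.3, -1.0, -0.1, -1.89),
        padj_b   = c(0.01, 0.02, 0.4, 0.01, 0.8, 9.3e-5))
    res <- antimorphClassify(tab, alpha = 0.1, fcMin = 1.15)
    cat <- setNames(res$table$category, res$table$gene)
    # SEMA5A pattern: down with the condition, up with the mutant
    expect_identical(unname(cat["SEMA5A"]), "opposite")
    expect_identical(unname(cat["oppUp"]), "opposite")
    expect_identical(unname(cat["sameUp"]), "same")
    expect_identical(unname(cat["aOnly"]), "A_only")
    expect_identical(unname(cat["bOnly"]), "B_only")
    expect_identical(unname(cat["ns"]), "not_significant")
    expect_identical(unname(res$counts[c("same", "opposite", "A_only",
                                         "B_only")]),
                     c(1L, 2L, 1L, 1L))

    # categories partition the genes significant in either contrast
    sigEither <- tab$padj_a < 0.1 | tab$padj_b < 0.1
    expect_identical(sum(res$counts[c("same", "opposite", "A_only",
                                      "B_only")]),
                     sum(sigEither))

    expect_error(antimorphClassify(tab, alpha = 1.5), "alpha")
    bad <- tab; bad$gene[2] <- "SEMA5A"
    expect_error(antimorphClassify(bad), "unique")
})

test_that("swapping contrast labels swaps A/B counts, keeps opposites", {
    withr::with_seed(7, {
        n <- 60
        tab <- data.frame(gene = paste0("g", 1:n),
                          log2fc_a = rnorm(n, 0, 1.5),
                          padj_a = runif(n),
                          log2fc_b = rnorm(n, 0, 1.5),
                          padj_b = runif(n))
    })
    fwd <- antimorphClassify(tab)$counts
    swapped <- antimorphClassify(
        data.frame(gene = tab$gene,
                   log2fc_a = tab$log2fc_b, padj_a = tab$padj_b,
                   log2fc_b = tab$log2fc_a, padj_b = tab$padj_a))$counts
    expect_identical(unname(fwd["A_only"]), unname(swapped["B_only"]))
    expect_identical(unname(fwd["B_only"]), unname(swapped["A_only"]))
    expect_identical(unname(fwd["opposite"]), unname(swapped["opposite"]))
    expect_identical(unname(fwd["same"]), unname(swapped["same"]))
})

test_that("fold-change correlation is computed on the 1.15x-filtered set", {
    # plant an exact anticorrelation on the filtered genes; add a gene below
    # the filter that would break it if included
    tab <- data.frame(
        gene = paste0("g", 1:5),
        log2fc_a = c(1, 2, -1, -2, 0.1),
        padj_a = rep(0.01, 5),
        log2fc_b = c(-1, -2, 1, 2, 0.1),
        padj_b = rep(0.01, 5))
    res <- antimorphClassify(tab, fcMin = 1.15)
    expect_identical(res$nFiltered, 4L)
    expect_equal(res$correlation$log2, -1)
    expect_lt(res$correlation$linear, -0.9)
    expect_lt(unname(res$fit["slope"]), 0)
})
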