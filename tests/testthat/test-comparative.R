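test_that("two-set partition does exact interval accounting", {
    asm <- toyAssembly(c(chr1 = 1000))
    A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
    B <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
    part <- partitionDomainSets(A, B, asm)
    bp <- part$summary$bp
    names(bp) <- part$summary$set
    expect_equal(bp[["common"]], 50)
    expect_equal(bp[["aOnly"]], 50)
    expect_equal(bp[["bOnly"]], 50)
    expect_equal(bp[["neither"]], 850)
    # conservation: the four sets tile the determined genome exactly
    expect_equal(sum(bp), 1000)
    expect_equal(sum(part$summary$fraction), 1)
    expect_equal(part$bNoOverlapCount, 0L)

    # A == B: no specific regions
    partAA <- partitionDomainSets(A, A, asm)
    bpAA <- partAA$summary$bp
    names(bpAA) <- partAA$summary$set
    expect_equal(bpAA[["aOnly"]], 0)
    expect_equal(bpAA[["bOnly"]], 0)

    # disjoint B interval counted and measured; undetermined bp excluded
    B2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(51, 901), c(150, 950)))
    undet <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
    part2 <- partitionDomainSets(A, B2, asm, undetermined = undet)
    expect_equal(part2$bNoOverlapCount, 1L)
    expect_equal(part2$bNoOverlapBp, 50)
    expect_equal(sum(part2$summary$bp), 900)
    expect_error(partitionDomainSets(
        GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)), B, asm),
        "absent")
})

test_that("rank tests separate shifted classes and not null ones", {
    asm <- toyAssembly(c(chr1 = 4e6))
    grid <- buildWindowGrid(asm, 2000)
    nWin <- length(gridWindows(grid))
    set.seed(33)
    vals <- stats::rnorm(nWin)
    # class B shifted by +2 in windows 1001..2000
    vals[1001:2000] <- vals[1001:2000] + 2
    regions <- list(
        a = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000 * 1000)),
        b = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(2000 * 1000 + 1, 2000 * 2000)))
    res <- regionwiseRankTests(vals, grid, regions)
    expect_equal(res$summary$n, c(1000L, 1000L))
    expect_lt(res$tests$pAdjusted, 0.01)
    expect_gt(res$summary$median[2] - res$summary$median[1], 1.5)
    expect_true(all(c("q25", "q75", "q01", "q99") %in% names(res$summary)))

    # same distribution: no signal
    vals0 <- stats::rnorm(nWin)
    res0 <- regionwiseRankTests(vals0, grid, regions)
    expect_gt(res0$tests$pvalue, 0.01)
    expect_lt(abs(res0$summary$median[1] - res0$summary$median[2]), 0.2)

    # single usable class: summary only, no tests
    res1 <- suppressWarnings(regionwiseRankTests(vals, grid,
        list(a = regions$a,
             tiny = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)))))
    expect_equal(nrow(res1$tests), 0L)
})

test_that("Wilcoxon p-values match exact enumeration at small n", {
    # independent oracle: enumerate all assignments of ranks
    x <- c(1.3, 2.7, 4.1, 8.2)
    y <- c(0.4, 3.3, 5.5, 9.9, 12.0)
    ranksAll <- rank(c(x, y))
    wObs <- sum(ranksAll[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    combs <- utils::combn(length(x) + length(y), length(x))
    wNull <- apply(combs, 2, function(ix)
        sum(rank(seq_len(9))[ix]) - length(x) * (length(x) + 1) / 2)
    pExact <- mean(abs(wNull - length(x) * length(y) / 2) >=
                   abs(wObs - length(x) * length(y) / 2))
    expect_equal(stats::wilcox.test(x, y)$p.value, pExact)
})

test_that("read subsampling honours size, seed and identity contracts", {
    set.seed(17)
    reads <- readsAt(sample.int(1e6, 5000))
    expect_length(subsampleReads(reads, 0, seed = 1), 0L)
    # full-size subsample is the identity set
    full <- subsampleReads(reads, 5000, seed = 1)
    expect_equal(BiocGenerics::start(full), BiocGenerics::start(BiocGenerics::sort(reads)))
    s1 <- subsampleReads(reads, 2500, seed = 1)
    s1b <- subsampleReads(reads, 2500, seed = 1)
    s2 <- subsampleReads(reads, 2500, seed = 2)
    expect_identical(BiocGenerics::start(s1), BiocGenerics::start(s1b))
    expect_length(s2, 2500L)
    expect_false(identical(BiocGenerics::start(s1), BiocGenerics::start(s2)))
    expect_error(subsampleReads(reads, 5001, seed = 1), "cannot sample")
})

test_that("saturation coverage rises with depth and is exact at full depth", {
    asm <- toyAssembly(c(chr1 = 5e6))
    p <- toyParams()
    truth <- plantDomains(asm, 4, sizeRange = c(5e4, 2e5), seed = 41)
    sim <- simulateDamidReads(asm, truth, foldEnrichment = 5, lambdaBg = 2,
                              seed = 41)
    full <- callDomains(sim$treatment, sim$control, asm, p)
    fullCov <- sum(BiocGenerics::width(domains(full))) / 5e6
    depths <- c(round(0.1 * length(sim$treatment)), length(sim$treatment))
    sat <- saturationCurve(sim$treatment, sim$control, asm, p, depths,
                           replicates = 2, seed = 7)
    expect_equal(nrow(sat$replicates), 4L)
    covLow <- sat$curve$meanCoverage[1]
    covFull <- sat$curve$meanCoverage[2]
    expect_lt(covLow, covFull)
    # a full-depth subsample reproduces the full-data call bit-exactly
    expect_equal(covFull, fullCov)
    expect_true(all(sat$replicates$coverage >= 0 &
                    sat$replicates$coverage <= 1))
})

test_that("window concordance matches direct set arithmetic", {
    lv <- c("sLAD", "non-sLAD", "undetermined")
    full <- factor(c("non-sLAD", "sLAD", "sLAD", "sLAD", rep("non-sLAD", 6)),
                   levels = lv)
    low <- factor(c("sLAD", "sLAD", "sLAD", rep("non-sLAD", 7)), levels = lv)
    res <- windowConcordance(low, full)
    # sLAD_low {1,2,3} vs sLAD_full {2,3,4}: 2/3 concordant; missed 1/7
    expect_equal(res$concordantPct, 100 * 2 / 3)
    expect_equal(res$missedPct, 100 * 1 / 7)

    # self-comparison: 100% / 0%
    self <- windowConcordance(full, full)
    expect_equal(self$concordantPct, 100)
    expect_equal(self$missedPct, 0)

    # empty full-depth sLAD set: nothing can be missed
    none <- factor(rep("non-sLAD", 10), levels = lv)
    expect_equal(windowConcordance(low, none)$missedPct, 0)
    # no sLADs at low depth: concordance undefined
    expect_true(is.na(windowConcordance(none, full)$concordantPct))
})

test_that("probe values spread across overlapped windows and average", {
    grid <- buildWindowGrid(toyAssembly(c(chr1 = 8000)), 2000)
    probes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(100, 1971, 2500, 2600), width = 60))
    probes$value <- c(1, 2, 4, 6)
    v <- mapProbeTrack(probes, grid)
    # probe 2 spans the 2000 boundary: contributes to windows 1 and 2
    expect_equal(v[1], mean(c(1, 2)))
    expect_equal(v[2], mean(c(2, 4, 6)))
    expect_true(is.na(v[3]))
    expect_error(mapProbeTrack(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 4)), grid),
        "value")

    # rank correlation invariances
    a <- c(0.1, 0.5, 0.2, 0.9, NA)
    expect_equal(rankCorrelation(a, a), 1)
    expect_equal(rankCorrelation(a, exp(a)), 1)   # monotone transform
    expect_equal(rankCorrelation(a, -a), -1)
})

test_that("peaks land in compartments by their centers", {
    asm <- toyAssembly(c(chr1 = 10000))
    grid <- buildWindowGrid(asm, 2000)
    lv <- c("sLAD", "non-sLAD", "undetermined")
    labels <- factor(c("sLAD", "sLAD", "non-sLAD", "non-sLAD", "undetermined"),
                     levels = lv)
    # 0-based [1000,3000) -> center 2000 -> window 2 (sLAD)
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1001, 5001, 8601), c(3000, 5400, 8800)))
    res <- assignPeaksToLabels(peaks, grid, labels)
    expect_equal(res$nSlad, 1L)
    expect_equal(res$nNonSlad, 1L)
    expect_equal(res$nUndetermined, 1L)
    # fractions renormalized over determined compartments
    expect_equal(res$fracSlad + res$fracNonSlad, 1)
    expect_equal(res$fracSlad, 0.5)

    allIn <- assignPeaksToLabels(peaks[1], grid, labels)
    expect_equal(allIn$fracSlad, 1)
    expect_error(assignPeaksToLabels(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(10500, 10600)),
        grid, labels), "beyond")
})

test_that("peak density ratios follow the arithmetic, flag degeneracy", {
    r <- peakDensityRatio(10, 90, 1e5, 3e5)
    expect_equal(r$log2Ratio, log2(3))
    expect_false(r$infinite)
    expect_equal(peakDensityRatio(5, 5, 1e5, 1e5)$log2Ratio, 0)
    expect_true(peakDensityRatio(0, 5, 1e5, 1e5)$infinite)
    expect_error(peakDensityRatio(1, 1, 0, 1e5), "coverage")
})

test_that("genic peak profiles count peak centers around anchors", {
    asm <- toyAssembly(c(chr1 = 100000))
    grid <- buildWindowGrid(asm, 2000)
    genes <- data.frame(symbol = c("g1", "g2"), chrom = "chr1",
                        strand = "+", txStart = c(41000, 61000),
                        txEnd = c(51000, 71000), tss = c(41000, 61000),
                        tes = c(50999, 70999), length = 10000)
    # no peaks: all-zero profile
    p0 <- genicPeakProfile(GenomicRanges::GRanges(), grid, genes, "tss")
    expect_equal(p0$mean, rep(0, 13))
    # one peak centered in each gene's TSS window
    peaks <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(40501, 60501), width = 1000))
    p1 <- genicPeakProfile(peaks, grid, genes, "tss")
    expect_equal(p1$mean[p1$position == 0], 1)
    expect_equal(sum(p1$mean), 1)
})
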