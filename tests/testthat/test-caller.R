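test_that("Poisson upper tails match closed forms", {
    expect_equal(poissonUpperTail(0, 3.7), 1.0)
    expect_equal(poissonUpperTail(1, 1), 1 - exp(-1))
    expect_equal(poissonUpperTail(2, 0.25), 1 - exp(-0.25) * (1 + 0.25))
    expect_error(poissonUpperTail(1, 0), "lambda")
})

test_that("background rate follows library size and effective genome fraction", {
    asm2 <- DamAssembly(c(chr1 = 2e9), effectiveGenomeFraction = 1)
    p <- toyParams()
    expect_equal(backgroundLambda(1e6, asm2, p), 1.0)
    asmHalf <- DamAssembly(c(chr1 = 2e9), effectiveGenomeFraction = 0.5)
    expect_equal(backgroundLambda(1e6, asmHalf, p), 2.0)
    expect_error(backgroundLambda(0, asm2, p), "librarySize")
})

test_that("window eligibility threshold is the smallest sub-p0 tail count", {
    # P(X>=1)=0.221 >= 0.2 but P(X>=2)=0.0265 < 0.2
    expect_equal(windowEligibilityThreshold(0.25, 0.2), 2L)
    # p0 near 1: any count with tail < 1, i.e. 1
    expect_equal(windowEligibilityThreshold(0.25, 1 - 1e-12), 1L)
    expect_equal(windowEligibilityThreshold(5, 1 - 1e-12), 1L)
    # non-decreasing in lambda at fixed p0
    l0s <- vapply(c(0.1, 0.5, 1, 2, 4, 8), windowEligibilityThreshold,
                  integer(1), p0 = 0.2)
    expect_true(all(diff(l0s) >= 0))
})

test_that("window scores are -log pmf for eligible windows, else zero", {
    expect_equal(windowScore(1, 0.25, 2), 0)
    expect_equal(windowScore(2, 0.25, 2),
                 -log(exp(-0.25) * 0.25^2 / 2), tolerance = 1e-12)
    expect_equal(round(windowScore(2, 0.25, 2), 2), 3.72)
    # strictly increasing right of the pmf mode
    sc <- windowScore(2:10, 0.25, 2)
    expect_true(all(diff(sc) > 0))
})

test_that("gap merging produces the expected islands on hand patterns", {
    asm <- toyAssembly(c(chr1 = 12000))
    grid <- buildWindowGrid(asm, 2000)
    scores <- rep(1, 6)

    # E,E,.,.,.,E with gap allowance 3 -> one island spanning all six windows
    el <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
    isl <- findCandidateIslands(grid, el, scores, gapWindows = 3)
    expect_length(isl, 1L)
    expect_equal(BiocGenerics::start(isl), 1L)
    expect_equal(BiocGenerics::end(isl), 12000L)
    expect_equal(isl$score, 3)

    # E,.,.,.,.,E with gap allowance 3 -> two single-window islands
    el2 <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
    isl2 <- findCandidateIslands(grid, el2, scores, gapWindows = 3)
    expect_length(isl2, 2L)
    expect_equal(BiocGenerics::width(isl2), c(2000L, 2000L))

    # nothing eligible -> no islands
    expect_length(findCandidateIslands(grid, rep(FALSE, 6), scores, 3), 0L)

    # islands never join across chromosomes
    asm2 <- toyAssembly(c(chrA = 4000, chrB = 4000))
    grid2 <- buildWindowGrid(asm2, 2000)
    isl3 <- findCandidateIslands(grid2, c(FALSE, TRUE, TRUE, FALSE),
                                 rep(1, 4), gapWindows = 3)
    expect_length(isl3, 2L)
    expect_equal(as.character(GenomicRanges::seqnames(isl3)), c("chrA", "chrB"))
})

test_that("island scan agrees with brute-force enumeration on random grids", {
    set.seed(202)
    for (i in 1:10) {
        n <- sample(20:120, 1)
        gap <- sample(0:4, 1)
        grid <- buildWindowGrid(toyAssembly(c(chr1 = n * 2000)), 2000)
        el <- stats::runif(n) < 0.35
        sc <- ifelse(el, stats::rexp(n) + 0.1, 0)
        got <- findCandidateIslands(grid, el, sc, gap)
        want <- bruteForceIslands(el, sc, gap)
        expect_equal(got$firstWindow, want$first)
        expect_equal(got$lastWindow, want$last)
        expect_equal(got$score, want$score)
    }
})

test_that("E-value score threshold matches a Monte-Carlo background oracle", {
    lambda <- 0.25; l0 <- 2L; gap <- 3L
    sStar <- islandExpectationThreshold(lambda, l0, gap, eValue = 0.1,
                                        nWindows = 1e5)
    # empirical: simulate a large background genome, find islands, take the
    # score whose exceedance count scales to the E-value budget
    set.seed(11)
    nSim <- 5e6
    counts <- stats::rpois(nSim, lambda)
    el <- counts >= l0
    sc <- ifelse(el, -stats::dpois(counts, lambda, log = TRUE), 0)
    idx <- which(el)
    newi <- c(TRUE, diff(idx) - 1L > gap)
    iscores <- tapply(sc[idx], factor(cumsum(newi), levels = unique(cumsum(newi))), sum)
    budget <- 0.1 * nSim / 1e5
    ss <- sort(as.numeric(iscores), decreasing = TRUE)
    sEmp <- ss[floor(budget)]   # score of the last island inside the budget
    expect_lt(abs(sStar - sEmp) / sEmp, 0.05)

    # generous budget admits everything
    expect_equal(islandExpectationThreshold(lambda, l0, gap, 1e9, 1e5), 0)
    # budget >= expected eligible windows cannot exclude single windows
    pE <- poissonUpperTail(l0, lambda)
    sMin <- islandExpectationThreshold(lambda, l0, gap, 1e5 * pE, 1e5)
    expect_lte(sMin, windowScore(l0, lambda, l0))
})

test_that("control significance normalizes, floors and FDR-filters", {
    # genome large enough that the per-island background floor (10 reads for
    # a 2 kb island at a 1e6-read normalized library) sits below the observed
    # control counts of interest
    asm <- toyAssembly(c(chr1 = 2e8))
    grid <- buildWindowGrid(asm, 2000)
    p <- toyParams()
    mkIslands <- function(first, last) {
        w <- gridWindows(grid)
        gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(BiocGenerics::start(w)[first],
                             BiocGenerics::end(w)[last]))
        gr$score <- rep(50, length(first))
        gr$nEligible <- last - first + 1L
        gr$firstWindow <- first
        gr$lastWindow <- last
        gr
    }
    nW <- length(gridWindows(grid))
    tCounts <- integer(nW); cCounts <- integer(nW)
    tCounts[10] <- 50L; cCounts[10] <- 10L   # strong enrichment
    tCounts[500] <- 20L; cCounts[500] <- 20L # no enrichment
    isl <- controlSignificance(mkIslands(c(10L, 500L), c(10L, 500L)),
                               tCounts, cCounts, 1e6, 1e6, asm, p,
                               keepAll = TRUE)
    expect_equal(isl$treatmentCount, c(50L, 20L))
    expect_equal(isl$pvalue[1], stats::ppois(49, 10, lower.tail = FALSE))
    expect_lt(isl$fdr[1], 1e-6)
    expect_gt(isl$pvalue[2], 0.4)    # a = b sits near the Poisson median
    filtered <- controlSignificance(mkIslands(c(10L, 500L), c(10L, 500L)),
                                    tCounts, cCounts, 1e6, 1e6, asm, p)
    expect_length(filtered, 1L)

    # control library twice as deep: raw 20 normalizes to b = 10
    isl2 <- controlSignificance(mkIslands(10L, 10L), tCounts,
                                ifelse(seq_len(nW) == 10, 20L, 0L),
                                1e6, 2e6, asm, p, keepAll = TRUE)
    expect_equal(isl2$pvalue, stats::ppois(49, 10, lower.tail = FALSE))

    # zero control count falls back to the genome-average floor
    # (1e6 * 2000 / 2e8 = 10 normalized reads for a 2 kb island)
    cZero <- integer(nW)
    isl3 <- controlSignificance(mkIslands(10L, 10L), tCounts, cZero,
                                1e6, 1e6, asm, p, keepAll = TRUE)
    expect_true(isl3$controlFloored)
    expect_equal(isl3$pvalue,
                 stats::ppois(49, 1e6 * 2000 / 2e8, lower.tail = FALSE))

    # empty candidate list is not an error
    empty <- findCandidateIslands(grid, rep(FALSE, nW), numeric(nW), 3)
    expect_length(controlSignificance(empty, tCounts, cCounts, 1e6, 1e6,
                                      asm, p), 0L)
})

test_that("adding a treatment read inside an island helps, never hurts", {
    asm <- toyAssembly(c(chr1 = 2e6))
    p <- toyParams()
    truth <- GenomicRanges::GRanges("chr1", IRanges::IRanges(800001, 900000))
    sim <- simulateDamidReads(asm, truth, foldEnrichment = 5, lambdaBg = 2,
                              seed = 21)
    ds1 <- callDomains(sim$treatment, sim$control, asm, p)
    isl1 <- domains(ds1)
    hit <- which(IRanges::overlapsAny(isl1, truth))[1]
    expect_false(is.na(hit))
    extra <- readsAt(850001)
    tr2 <- suppressWarnings(BiocGenerics::sort(c(sim$treatment, extra)))
    ds2 <- callDomains(tr2, sim$control, asm, p)
    isl2 <- domains(ds2)
    hit2 <- which(IRanges::overlapsAny(isl2, truth))[1]
    expect_gte(isl2$score[hit2], isl1$score[hit])
    expect_lte(isl2$pvalue[hit2], isl1$pvalue[hit])
})

test_that("end-to-end call recovers a planted domain and rejects the null", {
    asm <- toyAssembly()
    p <- toyParams()
    truth <- plantDomains(asm, 1, sizeRange = c(1e5, 1e5), seed = 31)
    sim <- simulateDamidReads(asm, truth, foldEnrichment = 5, lambdaBg = 2,
                              seed = 31)
    ds <- callDomains(sim$treatment, sim$control, asm, p)
    ov <- IRanges::overlapsAny(domains(ds), truth)
    expect_equal(sum(ov), 1L)
    expect_gt(evaluateRecovery(domains(ds)[ov], truth)$jaccard, 0.9)

    # identical treatment and control: no enrichment anywhere
    ds0 <- callDomains(sim$control, sim$control, asm, p)
    expect_length(ds0, 0L)

    # determinism of the whole call
    ds2 <- callDomains(sim$treatment, sim$control, asm, p)
    expect_identical(as.data.frame(domains(ds)), as.data.frame(domains(ds2)))
})

test_that("tripartition labels partition the genome with island precedence", {
    asm <- toyAssembly(c(chr1 = 9000))
    grid <- buildWindowGrid(asm, 2000)
    undet <- c(FALSE, TRUE, FALSE, FALSE, TRUE)  # incl. trailing partial

    # no domains: everything non-sLAD or undetermined
    noDom <- GenomicRanges::GRanges()
    lab0 <- tripartitionWindows(noDom, grid, rep(FALSE, 5))
    expect_true(all(lab0 == "non-sLAD"))

    isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 6000))
    lab <- tripartitionWindows(isl, grid, undet)
    # window 2 has no reads but sits inside the island: sLAD wins
    expect_equal(as.character(lab),
                 c("non-sLAD", "sLAD", "sLAD", "non-sLAD", "undetermined"))
    # labels always partition the full grid
    expect_false(anyNA(lab))
    w <- BiocGenerics::width(gridWindows(grid))
    expect_equal(sum(tapply(w, lab, sum, default = 0)), sum(w))
})
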