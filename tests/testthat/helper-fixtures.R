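# Shared in-code fixtures: everything is generated at test time.

toyAssembly <- function(lengths = c(chr1 = 5e6, chr2 = 5e6), egf = 1) {
    DamAssembly(lengths, effectiveGenomeFraction = egf)
}

toyParams <- function(...) {
    CallerParams(effectiveGenomeFraction = 1, ...)
}

# width-1 plus-strand reads at given 1-based positions
readsAt <- function(positions, chrom = "chr1", strand = "+") {
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(sort(positions), width = 1L),
        strand = strand)
}

# deterministic uniform background: `perWindow` reads in every full window
uniformBackgroundReads <- function(assembly, perWindow = 2, windowSize = 2000) {
    sl <- GenomeInfoDb::seqlengths(assembly)
    grs <- lapply(names(sl), function(chrom) {
        nWin <- sl[[chrom]] %/% windowSize
        offs <- round(seq(windowSize / (perWindow + 1), by =
                          windowSize / (perWindow + 1), length.out = perWindow))
        pos <- as.vector(outer(offs, (seq_len(nWin) - 1L) * windowSize, "+"))
        readsAt(pos, chrom)
    })
    suppressWarnings(BiocGenerics::sort(do.call(c, grs)))
}

# Brute-force island oracle: enumerates every candidate window run [i, j] and
# keeps those that satisfy the island definition directly (both ends eligible,
# every internal gap <= g, no eligible window within g windows outside).
# Mechanically independent of the scan in findCandidateIslands().
bruteForceIslands <- function(eligible, scores, gapWindows) {
    n <- length(eligible)
    out <- list()
    for (i in seq_len(n)) {
        if (!eligible[i])
            next
        for (j in i:n) {
            if (!eligible[j])
                next
            el <- which(eligible[i:j]) + i - 1L
            if (any(diff(el) - 1L > gapWindows))
                break
            okBefore <- i == 1L ||
                !any(eligible[max(1L, i - gapWindows - 1L):(i - 1L)])
            okAfter <- j == n ||
                !any(eligible[(j + 1L):min(n, j + gapWindows + 1L)])
            if (okBefore && okAfter)
                out[[length(out) + 1L]] <-
                    data.frame(first = i, last = j,
                               score = sum(scores[el]))
        }
    }
    if (length(out) == 0L)
        data.frame(first = integer(0), last = integer(0), score = numeric(0))
    else
        do.call(rbind, out)
}

# A TSS-hotspot fixture: genes on a clean Poisson background whose control
# library is enriched in the TSS-containing window (accessibility hotspot).
makeTssFixture <- function(nGenes = 40, seed = 101, hotspotFold = 5,
                           lambdaBg = 2, geneLength = 30000) {
    asm <- toyAssembly(c(chr1 = 5e6))
    tssPos <- seq(200000, 4500000, length.out = nGenes)
    tssPos <- round(tssPos / 2000) * 2000 + 1000   # mid-window anchors
    strand <- rep(c("+", "-"), length.out = nGenes)
    genes <- data.frame(
        symbol = sprintf("G%02d", seq_len(nGenes)),
        chrom = "chr1",
        strand = strand,
        txStart = ifelse(strand == "+", tssPos, tssPos - geneLength + 1),
        txEnd = ifelse(strand == "+", tssPos + geneLength, tssPos + 1))
    genes$tss <- ifelse(strand == "+", genes$txStart, genes$txEnd - 1)
    genes$tes <- ifelse(strand == "+", genes$txEnd - 1, genes$txStart)
    genes$length <- genes$txEnd - genes$txStart
    hotWin <- (genes$tss %/% 2000) * 2000
    hotspots <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(hotWin + 1, width = 2000))
    sim <- simulateDamidReads(asm, GenomicRanges::GRanges(),
                              lambdaBg = lambdaBg, hotspots = hotspots,
                              hotspotFold = hotspotFold, seed = seed)
    list(assembly = asm, genes = genes, sim = sim, hotspots = hotspots)
}
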