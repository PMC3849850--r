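#' Partition the determined genome by two domain sets
#'
#' Decomposes the determined genome (admitted chromosomes minus undetermined
#' regions) into common (A and B), A-only, B-only and neither, reporting bp
#' coverage and genome fractions per set, plus the count of original B
#' intervals with zero overlap with A (e.g. published LADs never touched by
#' any sLAD).
#'
#' @param A,B Domain interval sets ([DomainSet-class] or `GRanges`).
#' @param assembly A [DamAssembly-class].
#' @param undetermined `GRanges` of undetermined regions (e.g.
#'   `labelRanges(grid, labels, "undetermined")`); default empty.
#' @return List with `sets` (named `GRangesList`: common, aOnly, bOnly,
#'   neither), `summary` data.frame (set, bp, fraction of the admitted
#'   genome), `bNoOverlapCount` and `bNoOverlapBp`.
#' @export
partitionDomainSets <- function(A, B, assembly,
                                undetermined = GenomicRanges::GRanges()) {
    grA <- if (is(A, "DomainSet")) domains(A) else A
    grB <- if (is(B, "DomainSet")) domains(B) else B
    sl <- seqlengths(assembly)
    for (gr in list(grA, grB))
        if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(sl)))
            stop("domain set on chromosomes absent from the assembly")
    det <- GenomicRanges::setdiff(assemblyRanges(assembly),
                                  GenomicRanges::reduce(undetermined),
                                  ignore.strand = TRUE)
    rA <- GenomicRanges::intersect(GenomicRanges::reduce(grA), det,
                                   ignore.strand = TRUE)
    rB <- GenomicRanges::intersect(GenomicRanges::reduce(grB), det,
                                   ignore.strand = TRUE)
    sets <- GenomicRanges::GRangesList(
        common = GenomicRanges::intersect(rA, rB, ignore.strand = TRUE),
        aOnly = GenomicRanges::setdiff(rA, rB, ignore.strand = TRUE),
        bOnly = GenomicRanges::setdiff(rB, rA, ignore.strand = TRUE),
        neither = GenomicRanges::setdiff(
            det, GenomicRanges::union(rA, rB, ignore.strand = TRUE),
            ignore.strand = TRUE))
    bp <- vapply(sets, function(s) sum(BiocGenerics::width(s)), numeric(1))
    noOv <- GenomicRanges::countOverlaps(grB, grA, ignore.strand = TRUE) == 0L
    list(sets = sets,
         summary = data.frame(set = names(bp), bp = unname(bp),
                              fraction = unname(bp) / sum(sl)),
         bNoOverlapCount = sum(noOv),
         bNoOverlapBp = sum(BiocGenerics::width(
             GenomicRanges::reduce(grB[noOv]))))
}

#' Rank statistics of a window track across region classes
#'
#' Assigns each window (by its midpoint) with a defined value to the region
#' class containing it, summarizes each class (median, 25th/75th and
#' 1st/99th percentiles) and runs all pairwise two-sided
#' Wilcoxon-Mann-Whitney tests with Bonferroni correction over the number of
#' pairs tested.
#'
#' @param values Per-window numeric vector in grid order (NA skipped).
#' @param grid The [WindowGrid-class].
#' @param regions Named list or `GRangesList` of region classes (e.g.
#'   `partitionDomainSets(...)$sets`).
#' @return List with `summary` (class, n, median, q25, q75, q01, q99) and
#'   `tests` (classA, classB, pvalue, pAdjusted) data.frames; `tests` has
#'   zero rows when fewer than two usable classes exist.
#' @export
regionwiseRankTests <- function(values, grid, regions) {
    w <- gridWindows(grid)
    mid <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(w),
        IRanges::IRanges(BiocGenerics::start(w) +
                         (BiocGenerics::width(w) - 1L) %/% 2L, width = 1L))
    groups <- lapply(regions, function(rg) {
        idx <- which(IRanges::overlapsAny(mid, rg, ignore.strand = TRUE))
        v <- values[idx]
        v[!is.na(v)]
    })
    usable <- vapply(groups, length, integer(1)) >= 2L
    if (any(!usable))
        warning("region class(es) with < 2 windows excluded: ",
                paste(names(groups)[!usable], collapse = ", "))
    groups <- groups[usable]
    qs <- function(v) stats::quantile(v, c(0.5, 0.25, 0.75, 0.01, 0.99),
                                      names = FALSE)
    summ <- do.call(rbind, lapply(names(groups), function(nm) {
        q <- qs(groups[[nm]])
        data.frame(class = nm, n = length(groups[[nm]]), median = q[1],
                   q25 = q[2], q75 = q[3], q01 = q[4], q99 = q[5])
    }))
    tests <- data.frame(classA = character(0), classB = character(0),
                        pvalue = numeric(0), pAdjusted = numeric(0))
    if (length(groups) >= 2L) {
        pairs <- utils::combn(names(groups), 2L)
        p <- apply(pairs, 2L, function(pr)
            stats::wilcox.test(groups[[pr[1L]]], groups[[pr[2L]]],
                               alternative = "two.sided")$p.value)
        tests <- data.frame(classA = pairs[1L, ], classB = pairs[2L, ],
                            pvalue = p,
                            pAdjusted = pmin(1, p * ncol(pairs)))
    }
    list(summary = summ, tests = tests)
}

#' Subsample a read set without replacement
#'
#' Uniform sampling of exactly `n` reads, reproducible under a fixed seed;
#' `n` equal to the library size returns the full (sorted) set.
#'
#' @param reads Width-1 read `GRanges`.
#' @param n Target read count, `0 <= n <= length(reads)`.
#' @param seed Integer RNG seed.
#' @return Sorted `GRanges` of the sampled reads.
#' @export
subsampleReads <- function(reads, n, seed) {
    if (n > length(reads))
        stop("cannot sample ", n, " reads from a library of ", length(reads))
    if (n == length(reads))
        return(BiocGenerics::sort(reads))
    set.seed(as.integer(seed))
    BiocGenerics::sort(reads[sample.int(length(reads), n)])
}

#' Sequencing-depth saturation of sLAD coverage
#'
#' Subsamples the treatment library to each requested depth (the control
#' stays at full depth), re-calls domains, and records the sLAD genome
#' coverage fraction; each depth is replicated with distinct derived seeds
#' and the replicate mean is reported.
#'
#' @param treatment,control Read `GRanges`.
#' @param assembly A [DamAssembly-class].
#' @param params [CallerParams-class].
#' @param depths Integer vector of target treatment depths.
#' @param replicates Replicates per depth, default 3.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @return List with `replicates` (depth, replicate, seed, coverage) and
#'   `curve` (depth, meanCoverage) data.frames.
#' @export
saturationCurve <- function(treatment, control, assembly, params, depths,
                            replicates = 3, seed = 1) {
    if (any(depths > length(treatment)))
        stop("depth exceeds treatment library size")
    grid <- buildWindowGrid(assembly, windowSize(params))
    total <- assemblyLength(assembly)
    rows <- list()
    k <- 0L
    for (i in seq_along(depths)) {
        for (r in seq_len(replicates)) {
            k <- k + 1L
            subSeed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
            sub <- subsampleReads(treatment, depths[i], subSeed)
            ds <- callDomains(sub, control, assembly, params, grid = grid)
            rows[[k]] <- data.frame(
                depth = depths[i], replicate = r, seed = subSeed,
                coverage = sum(BiocGenerics::width(domains(ds))) / total)
        }
    }
    reps <- do.call(rbind, rows)
    curve <- stats::aggregate(coverage ~ depth, reps, mean)
    names(curve)[2L] <- "meanCoverage"
    list(replicates = reps, curve = curve)
}

#' Window concordance between a reduced-depth and a full-depth call
#'
#' Concordant windows are sLAD windows at the lower depth that are also sLAD
#' at full depth, as a percentage of all lower-depth sLAD windows; missed
#' windows are lower-depth non-sLAD windows that are sLAD at full depth, as
#' a percentage of all lower-depth non-sLAD windows.
#'
#' @param labelsLow,labelsFull Label factors from [tripartitionWindows()] on
#'   the same grid.
#' @return List with `concordantPct` (`NA` when the lower depth called no
#'   sLAD windows), `missedPct`, `nSladLow`, `nNonSladLow`.
#' @export
windowConcordance <- function(labelsLow, labelsFull) {
    if (length(labelsLow) != length(labelsFull))
        stop("label tracks are not on the same grid")
    sladLow <- labelsLow == "sLAD"
    nonLow <- labelsLow == "non-sLAD"
    sladFull <- labelsFull == "sLAD"
    concordant <- if (sum(sladLow) == 0L) NA_real_ else
        100 * sum(sladLow & sladFull) / sum(sladLow)
    missed <- if (sum(nonLow) == 0L) NA_real_ else
        100 * sum(nonLow & sladFull) / sum(nonLow)
    list(concordantPct = concordant, missedPct = missed,
         nSladLow = sum(sladLow), nNonSladLow = sum(nonLow))
}

#' Assign an interval track (e.g. array probes) to windows
#'
#' Each probe's value contributes to every window the probe overlaps (a
#' probe spanning a window boundary contributes to both neighbours); values
#' of multiple probes in a window are averaged.
#'
#' @param probes `GRanges` with a numeric metadata column `value` (or
#'   `score`).
#' @param grid The [WindowGrid-class].
#' @return Numeric per-window vector (`NA` where no probe overlaps).
#' @export
mapProbeTrack <- function(probes, grid) {
    val <- probes$value
    if (is.null(val))
        val <- probes$score
    if (is.null(val))
        stop("probes need a 'value' (or 'score') metadata column")
    if (any(BiocGenerics::width(probes) == 0L))
        stop("zero-length probe")
    w <- gridWindows(grid)
    hits <- GenomicRanges::findOverlaps(w, probes, ignore.strand = TRUE)
    out <- rep(NA_real_, length(w))
    if (length(hits) > 0L) {
        m <- tapply(val[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), mean)
        out[as.integer(names(m))] <- m
    }
    out
}

#' Spearman rank correlation of two window tracks
#'
#' Computed over windows where both tracks are defined.
#'
#' @param trackA,trackB Numeric per-window vectors.
#' @return Spearman correlation coefficient.
#' @export
rankCorrelation <- function(trackA, trackB) {
    stats::cor(trackA, trackB, method = "spearman", use = "complete.obs")
}

#' Peak midpoints (floor convention)
#'
#' @param peaks `GRanges` of peak intervals.
#' @return Width-1 `GRanges` at each peak's center, the floor of the 0-based
#'   midpoint.
#' @export
peakCenters <- function(peaks) {
    center0 <- (BiocGenerics::start(peaks) - 1L + BiocGenerics::end(peaks)) %/% 2L
    GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                           IRanges::IRanges(center0 + 1L, width = 1L))
}

#' Distribute ChIP-seq peaks over the sLAD tripartition
#'
#' Each peak is assigned to the window containing its center; fractions are
#' reported over the determined compartments (sLAD, non-sLAD), renormalized
#' after setting peaks centered in undetermined windows aside (their count is
#' reported).
#'
#' @param peaks Peak `GRanges` (narrowPeak/BED; extra columns ignored).
#' @param grid The [WindowGrid-class].
#' @param labels Label factor from [tripartitionWindows()].
#' @return List with counts `nSlad`, `nNonSlad`, `nUndetermined`, and
#'   fractions `fracSlad`, `fracNonSlad` (over determined peaks).
#' @export
assignPeaksToLabels <- function(peaks, grid, labels) {
    centers <- peakCenters(peaks)
    sl <- seqlengths(gridAssembly(grid))
    chrom <- as.character(GenomicRanges::seqnames(centers))
    if (!all(chrom %in% names(sl)) ||
        any(BiocGenerics::start(centers) > sl[chrom]))
        stop("peak center beyond the gridded chromosomes")
    idx <- anchorWindow(grid, chrom, BiocGenerics::start(centers) - 1L)
    lab <- labels[idx]
    nS <- sum(lab == "sLAD")
    nN <- sum(lab == "non-sLAD")
    nU <- sum(lab == "undetermined")
    det <- nS + nN
    list(nSlad = nS, nNonSlad = nN, nUndetermined = nU,
         fracSlad = if (det > 0L) nS / det else NA_real_,
         fracNonSlad = if (det > 0L) nN / det else NA_real_)
}

#' log2 peak density ratio between compartments
#'
#' Peak density per compartment is the peak count divided by the
#' compartment's bp coverage; the statistic is
#' `log2(density(non-sLAD) / density(sLAD))`. A compartment with zero peaks
#' yields an infinite ratio, flagged in the result.
#'
#' @param nSlad,nNonSlad Peak counts per compartment.
#' @param bpSlad,bpNonSlad Genome coverage (bp) per compartment, > 0.
#' @return List with `log2Ratio`, per-compartment `densitySlad`,
#'   `densityNonSlad`, and `infinite` flag.
#' @export
peakDensityRatio <- function(nSlad, nNonSlad, bpSlad, bpNonSlad) {
    if (bpSlad <= 0 || bpNonSlad <= 0)
        stop("both compartments need nonzero coverage")
    dS <- nSlad / bpSlad
    dN <- nNonSlad / bpNonSlad
    r <- log2(dN / dS)
    list(log2Ratio = r, densitySlad = dS, densityNonSlad = dN,
         infinite = is.infinite(r) || is.nan(r))
}

#' Metagene profile of peak counts around TSS/TES windows
#'
#' The per-window number of peak centers, averaged across a gene group at
#' each of the 13 positions around the anchor window (see
#' [metageneProfile()]).
#'
#' @param peaks Peak `GRanges`.
#' @param grid The [WindowGrid-class].
#' @param genes Gene models subset.
#' @param anchor `"tss"` or `"tes"`.
#' @param flank Windows per side, default 6.
#' @param strandFlip Orient in transcription direction, default `TRUE`.
#' @return data.frame as in [metageneProfile()].
#' @export
genicPeakProfile <- function(peaks, grid, genes, anchor = c("tss", "tes"),
                             flank = 6, strandFlip = TRUE) {
    counts <- GenomicRanges::countOverlaps(gridWindows(grid),
                                           peakCenters(peaks),
                                           ignore.strand = TRUE)
    metageneProfile(as.numeric(counts), grid, genes, anchor = anchor,
                    flank = flank, strandFlip = strandFlip)
}
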