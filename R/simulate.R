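#' Plant disjoint ground-truth domains on a toy assembly
#'
#' Draws domain sizes log-uniformly from `sizeRange`, snaps them to whole
#' windows, and places them disjointly with at least `minSeparation` bp
#' between neighbours (kept above the caller's gap size so distinct planted
#' domains cannot merge into one island). The whole size vector is redrawn
#' if its total would exceed `maxLoad` of the genome, so placement succeeds
#' with overwhelming probability; placement still errors after bounded
#' retries on pathological inputs. Fully reproducible per seed.
#'
#' @param assembly A [DamAssembly-class] (toy genome).
#' @param nDomains Number of domains to plant.
#' @param sizeRange Size range in bp, default 20 kb to 1 Mb.
#' @param windowSize Snap unit, default 2000.
#' @param minSeparation Minimum bp between planted domains (and from
#'   chromosome ends), default 20 kb.
#' @param seed Integer RNG seed.
#' @param maxLoad Maximum fraction of the genome the domains may total,
#'   default 0.35.
#' @param maxTries Placement retries per domain, default 1000.
#' @return Sorted `GRanges` of planted domains, window-aligned.
#' @export
plantDomains <- function(assembly, nDomains, sizeRange = c(20000, 1e6),
                         windowSize = 2000, minSeparation = 20000,
                         seed = 1, maxLoad = 0.35, maxTries = 1000) {
    set.seed(as.integer(seed))
    sl <- seqlengths(assembly)
    if (nDomains == 0L)
        return(GenomicRanges::GRanges())
    total <- sum(sl)
    for (draw in seq_len(100L)) {
        sizes <- exp(stats::runif(nDomains, log(sizeRange[1L]),
                                  log(sizeRange[2L])))
        sizes <- pmax(windowSize, round(sizes / windowSize) * windowSize)
        if (sum(sizes) <= maxLoad * total)
            break
    }
    if (sum(sizes) > maxLoad * total)
        stop("planted domains cannot fit the assembly at maxLoad = ", maxLoad)
    placed <- GenomicRanges::GRanges()
    for (i in order(-sizes)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
            chrom <- sample(names(sl), 1L, prob = sl)
            maxStart <- sl[[chrom]] - sizes[i] - minSeparation
            base <- ceiling(minSeparation / windowSize)
            nSlots <- maxStart %/% windowSize - base
            if (nSlots < 0)
                next
            start0 <- (base + sample.int(nSlots + 1L, 1L) - 1L) * windowSize
            cand <- GenomicRanges::GRanges(
                chrom, IRanges::IRanges(start0 + 1L, width = sizes[i]))
            pad <- GenomicRanges::resize(cand, sizes[i] + 2L * minSeparation,
                                         fix = "center")
            hit <- suppressWarnings(
                IRanges::overlapsAny(pad, placed, ignore.strand = TRUE))
            if (!hit) {
                placed <- suppressWarnings(c(placed, cand))
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("could not place domain of ", sizes[i],
                 " bp disjointly after ", maxTries, " tries")
    }
    BiocGenerics::sort(placed)
}

#' Simulate seeded DamID read sets with planted domains
#'
#' Per-window counts are drawn from independent Poissons: the treatment
#' (Dam-LaminB1) mean is `lambdaBg * foldEnrichment` inside planted domains
#' and `lambdaBg` elsewhere; the control (free Dam) mean is
#' `lambdaBg * hotspotFold` inside accessibility hotspots (emulating the
#' elevated free-Dam signal around open TSS-proximal chromatin) and
#' `lambdaBg` elsewhere. Reads are placed uniformly within their window with
#' random strand. Identical seeds give identical read sets.
#'
#' @param assembly Toy [DamAssembly-class].
#' @param truth Planted domain `GRanges` from [plantDomains()] (may be
#'   empty).
#' @param foldEnrichment Treatment enrichment fold inside planted domains
#'   (scalar or one value per truth interval), >= 1.
#' @param lambdaBg Background mean reads per window, both libraries.
#' @param hotspots `GRanges` of control-library hotspots (default none).
#' @param hotspotFold Control enrichment fold inside hotspots, >= 1.
#' @param windowSize Window width used to structure the simulation,
#'   default 2000.
#' @param seed Integer RNG seed.
#' @return List with `treatment` and `control`, sorted width-1 read
#'   `GRanges` ready for [callDomains()].
#' @export
simulateDamidReads <- function(assembly, truth = GenomicRanges::GRanges(),
                               foldEnrichment = 4, lambdaBg = 2,
                               hotspots = GenomicRanges::GRanges(),
                               hotspotFold = 1, windowSize = 2000,
                               seed = 1) {
    stopifnot(all(foldEnrichment >= 1), all(hotspotFold >= 1), lambdaBg > 0)
    set.seed(as.integer(seed))
    grid <- buildWindowGrid(assembly, windowSize)
    w <- gridWindows(grid)
    nWin <- length(w)

    fold <- rep(1, nWin)
    if (length(truth) > 0L) {
        foldPer <- rep_len(foldEnrichment, length(truth))
        hits <- GenomicRanges::findOverlaps(w, truth, ignore.strand = TRUE,
                                            type = "within")
        fold[S4Vectors::queryHits(hits)] <- foldPer[S4Vectors::subjectHits(hits)]
    }
    ctrlFold <- rep(1, nWin)
    if (length(hotspots) > 0L) {
        ctrlFold[IRanges::overlapsAny(w, hotspots, ignore.strand = TRUE)] <-
            hotspotFold
    }
    drawReads <- function(means) {
        counts <- stats::rpois(nWin, means)
        idx <- rep.int(seq_len(nWin), counts)
        offs <- floor(stats::runif(length(idx)) *
                      BiocGenerics::width(w)[idx])
        gr <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(w)[idx],
            IRanges::IRanges(BiocGenerics::start(w)[idx] + offs, width = 1L),
            strand = sample(c("+", "-"), length(idx), replace = TRUE))
        BiocGenerics::sort(gr)
    }
    list(treatment = drawReads(lambdaBg * fold),
         control = drawReads(lambdaBg * ctrlFold))
}

#' Write simulated fixtures to plain-text files
#'
#' Reads go to BED6 (`treatment.bed`, `control.bed`; score column 60,
#' re-read as MAPQ by [readAlignments()]), the planted truth to BED3
#' (`truth.bed`), and the chromosome sizes to `chrom.sizes`, so a full run
#' round-trips losslessly through the text readers.
#'
#' @param treatment,control Read `GRanges`.
#' @param truth Planted domain `GRanges`.
#' @param assembly The toy [DamAssembly-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixtureFiles <- function(treatment, control, truth, assembly, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeReads <- function(gr, path) {
        if (length(gr) > 0L) {
            gr$name <- "read"
            gr$score <- 60L
        }
        rtracklayer::export(gr, path, format = "BED")
        path
    }
    paths <- c(
        treatment = writeReads(treatment, file.path(dir, "treatment.bed")),
        control = writeReads(control, file.path(dir, "control.bed")),
        truth = {
            p <- file.path(dir, "truth.bed")
            rtracklayer::export(truth, p, format = "BED")
            p
        },
        chromSizes = {
            p <- file.path(dir, "chrom.sizes")
            sl <- seqlengths(assembly)
            utils::write.table(
                data.frame(names(sl), format(sl, scientific = FALSE,
                                             trim = TRUE)),
                p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
            p
        })
    invisible(paths)
}

#' Base-pair-level recovery of planted domains
#'
#' @param called Called domains ([DomainSet-class] or `GRanges`).
#' @param truth Planted truth `GRanges`.
#' @return List with `precision`, `recall` and `jaccard`, all bp-level
#'   (`precision` is `NA` when nothing was called; `recall`/`jaccard` are 0
#'   when the truth is nonempty but nothing was recovered).
#' @export
evaluateRecovery <- function(called, truth) {
    grC <- GenomicRanges::reduce(
        if (is(called, "DomainSet")) domains(called) else called)
    grT <- GenomicRanges::reduce(truth)
    bpC <- sum(BiocGenerics::width(grC))
    bpT <- sum(BiocGenerics::width(grT))
    inter <- sum(BiocGenerics::width(
        GenomicRanges::intersect(grC, grT, ignore.strand = TRUE)))
    uni <- sum(BiocGenerics::width(
        GenomicRanges::union(grC, grT, ignore.strand = TRUE)))
    list(precision = if (bpC > 0) inter / bpC else NA_real_,
         recall = if (bpT > 0) inter / bpT else NA_real_,
         jaccard = if (uni > 0) inter / uni else NA_real_)
}
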