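#' Read alignments from BAM, SAM or BED
#'
#' Loads single-end alignments as a [GenomicRanges::GRanges] with a `mapq`
#' metadata column. BAM/SAM files are read with Rsamtools/GenomicAlignments
#' (SAM files are converted on the fly); for BED6 input the score column is
#' interpreted as the mapping quality, which is how [writeFixtureFiles()] and
#' the filtered-read re-export round-trip read sets through text files.
#'
#' @param file Path to a `.bam`, `.sam` or `.bed` file.
#' @param format `"auto"` (by extension), `"bam"`, `"sam"` or `"bed"`.
#' @return `GRanges` of aligned spans with metadata column `mapq`.
#' @export
readAlignments <- function(file, format = c("auto", "bam", "sam", "bed")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(file))
        format <- switch(ext,
            bam = "bam", sam = "sam", bed = "bed",
            stop("cannot guess alignment format from extension: ", file))
    }
    if (format == "sam") {
        dest <- tempfile(fileext = "")
        file <- Rsamtools::asBam(file, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
        format <- "bam"
    }
    if (format == "bam") {
        param <- Rsamtools::ScanBamParam(
            what = "mapq",
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
        ga <- GenomicAlignments::readGAlignments(file, param = param)
        gr <- GenomicRanges::granges(ga, use.mcols = TRUE)
        gr$mapq[is.na(gr$mapq)] <- 0L
        return(gr)
    }
    gr <- rtracklayer::import(file, format = "BED")
    if (is.null(gr$score))
        stop("BED alignment input needs a score column (read as MAPQ): ", file)
    gr$mapq <- as.integer(gr$score)
    gr$score <- NULL
    gr$name <- NULL
    gr
}

#' Filter alignments to a deduplicated 5'-position read set
#'
#' Applies the read-level filters used before window counting: keep only
#' alignments on the admitted chromosomes with mapping quality at or above
#' `minMapq` (the operational definition of "uniquely mapped"), reduce each
#' alignment to its 5'-most aligned base (start for `+`, end for `-` strand),
#' and collapse likely PCR duplicates by keeping at most
#' `redundancyThreshold` reads per (chromosome, position, strand).
#'
#' @param alignments `GRanges` from [readAlignments()] (metadata column
#'   `mapq`; missing `mapq` treated as 0).
#' @param assembly A [DamAssembly-class]; alignments on chromosomes absent
#'   from it are dropped and tallied in `metadata(result)$droppedChromosomes`.
#' @param minMapq Minimum mapping quality retained (default 40).
#' @param redundancyThreshold Maximum reads kept per (chromosome, position,
#'   strand); default 1. Duplicate collapsing is strand-aware.
#' @return A width-1 `GRanges` of retained 5' positions, sorted, with the
#'   number of reads dropped for being on disallowed chromosomes recorded in
#'   `S4Vectors::metadata()`. The library size is `length()` of the result.
#' @examples
#' asm <- DamAssembly(c(chr1 = 1e4), effectiveGenomeFraction = 1)
#' aln <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1001, 1001, 2001), width = 75),
#'     strand = c("+", "+", "-"), mapq = c(42L, 42L, 39L))
#' filterAlignments(aln, asm, minMapq = 40)
#' @export
filterAlignments <- function(alignments, assembly, minMapq = 40,
                             redundancyThreshold = 1) {
    stopifnot(is(alignments, "GRanges"))
    if (minMapq < 0)
        stop("minMapq must be >= 0")
    if (redundancyThreshold < 1)
        stop("redundancyThreshold must be >= 1")
    sl <- seqlengths(assembly)
    chroms <- as.character(GenomicRanges::seqnames(alignments))
    onAllowed <- chroms %in% names(sl)
    nDropped <- sum(!onAllowed)
    gr <- alignments[onAllowed]
    mapq <- gr$mapq
    if (is.null(mapq))
        mapq <- rep(0L, length(gr))
    mapq[is.na(mapq)] <- 0L
    gr <- gr[mapq >= minMapq]

    # 5'-most aligned base, strand-aware; unstranded records use the start
    pos <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                  BiocGenerics::end(gr), BiocGenerics::start(gr))
    out <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr),
        IRanges::IRanges(pos, width = 1L),
        strand = GenomicRanges::strand(gr))
    out <- BiocGenerics::sort(out)

    chrom <- as.character(GenomicRanges::seqnames(out))
    bad <- BiocGenerics::start(out) < 1L |
        BiocGenerics::start(out) > sl[chrom]
    if (any(bad))
        stop(sum(bad), " read position(s) outside chromosome bounds, e.g. ",
             chrom[which(bad)[1L]], ":", BiocGenerics::start(out)[which(bad)[1L]])

    key <- paste(chrom, BiocGenerics::start(out),
                 as.character(GenomicRanges::strand(out)), sep = "\r")
    rank <- stats::ave(seq_along(key), key, FUN = seq_along)
    out <- out[rank <= redundancyThreshold]
    S4Vectors::metadata(out)$droppedChromosomes <- nDropped
    out
}

#' Partition a genome into fixed windows
#'
#' Tiles every admitted chromosome with contiguous, non-overlapping windows
#' of `windowSize` bp starting at coordinate 0. A chromosome whose length is
#' not a multiple of the window size ends in a shorter trailing window,
#' flagged `partial`; partial windows are excluded from island calling and
#' labelled undetermined downstream.
#'
#' @param assembly A [DamAssembly-class].
#' @param windowSize Window width in bp (default 2000).
#' @return A [WindowGrid-class].
#' @examples
#' asm <- DamAssembly(c(chr1 = 7000), effectiveGenomeFraction = 1)
#' gridWindows(buildWindowGrid(asm, 2000))
#' @export
buildWindowGrid <- function(assembly, windowSize = 2000) {
    if (windowSize <= 0)
        stop("windowSize must be positive")
    windowSize <- as.integer(windowSize)
    sl <- seqlengths(assembly)
    tiles <- GenomicRanges::tileGenome(sl, tilewidth = windowSize,
                                       cut.last.tile.in.chrom = TRUE)
    tiles$partial <- BiocGenerics::width(tiles) < windowSize
    new("WindowGrid", windows = tiles, windowSize = windowSize,
        assembly = assembly)
}

#' @rdname gridWindows
#' @export
setMethod("gridWindows", "WindowGrid", function(x) x@windows)

#' @rdname windowSize
#' @export
setMethod("windowSize", "WindowGrid", function(x) x@windowSize)

#' @describeIn buildWindowGrid Assembly the grid tiles.
#' @param grid A `WindowGrid`.
#' @export
gridAssembly <- function(grid) grid@assembly

setMethod("show", "WindowGrid", function(object) {
    w <- gridWindows(object)
    cat("WindowGrid:", length(w), "windows of", object@windowSize, "bp on",
        length(seqlengths(object@assembly)), "chromosomes (",
        sum(w$partial), "partial )\n")
})

#' Count reads per window
#'
#' Assigns each filtered read to the unique window containing its 5'-most
#' position and returns per-window integer counts in grid order. The counts
#' sum to the library size whenever all reads lie on gridded chromosomes.
#'
#' @param reads Width-1 `GRanges` from [filterAlignments()] (or
#'   [simulateDamidReads()]).
#' @param grid A [WindowGrid-class] on the same assembly.
#' @return Integer vector, one count per window of `gridWindows(grid)`.
#' @export
countWindowReads <- function(reads, grid) {
    stopifnot(is(grid, "WindowGrid"))
    sl <- seqlengths(gridAssembly(grid))
    chrom <- as.character(GenomicRanges::seqnames(reads))
    if (!all(chrom %in% names(sl)))
        stop("reads on chromosomes absent from the grid: ",
             paste(unique(setdiff(chrom, names(sl))), collapse = ", "))
    if (any(BiocGenerics::start(reads) > sl[chrom] |
            BiocGenerics::start(reads) < 1L))
        stop("read position beyond chromosome length (corrupt input)")
    GenomicRanges::countOverlaps(gridWindows(grid), reads,
                                 ignore.strand = TRUE)
}

#' RPKM-normalize window counts
#'
#' Reads per kilobase of window per million mapped reads:
#' `count / ((width/1000) * (librarySize/1e6))`. Trailing partial windows use
#' their true width.
#'
#' @param counts Integer vector of per-window counts (grid order).
#' @param grid The [WindowGrid-class] the counts live on.
#' @param librarySize Total retained reads of the library; must be > 0.
#' @return Numeric vector of RPKM values.
#' @export
rpkmNormalize <- function(counts, grid, librarySize) {
    if (length(counts) != length(gridWindows(grid)))
        stop("counts length does not match the grid")
    if (librarySize <= 0)
        stop("librarySize must be > 0")
    widths <- BiocGenerics::width(gridWindows(grid))
    counts / ((widths / 1000) * (librarySize / 1e6))
}

#' Flag undetermined windows
#'
#' A window is undetermined when neither the treatment (Dam-LaminB1) nor the
#' control (free Dam) library has any read in it — such windows usually sit in
#' assembly gaps or highly repetitive segments — or when it is a trailing
#' partial window. Undetermined windows are excluded from the sLAD /
#' non-sLAD dichotomy and carry no log2 seq ratio.
#'
#' @param treatmentCounts,controlCounts Integer vectors of per-window counts
#'   on the same grid.
#' @param grid The shared [WindowGrid-class].
#' @return Logical vector, `TRUE` where undetermined.
#' @export
flagUndetermined <- function(treatmentCounts, controlCounts, grid) {
    n <- length(gridWindows(grid))
    if (length(treatmentCounts) != n || length(controlCounts) != n)
        stop("count vectors do not match the grid")
    (treatmentCounts == 0L & controlCounts == 0L) | gridWindows(grid)$partial
}

#' Write a per-window numeric track as bedGraph
#'
#' Windows with `NA` values (e.g. undetermined windows of a ratio track) are
#' omitted, as is conventional for sparse bedGraph tracks.
#'
#' @param values Numeric vector in grid order.
#' @param grid The [WindowGrid-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeBedGraph <- function(values, grid, file) {
    w <- gridWindows(grid)
    keep <- !is.na(values)
    gr <- w[keep]
    S4Vectors::mcols(gr) <- NULL
    gr$score <- values[keep]
    rtracklayer::export(gr, file, format = "bedGraph")
    invisible(file)
}
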