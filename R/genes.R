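#' Read a refFlat-like transcript table
#'
#' Expects a headerless TSV with columns symbol, chromosome, strand, txStart,
#' txEnd (txStart/txEnd 0-based half-open, as in refFlat).
#'
#' @param file Path to the TSV.
#' @return data.frame with those five columns.
#' @export
readRefFlat <- function(file) {
    tab <- utils::read.table(file, header = FALSE, sep = "\t",
                             col.names = c("symbol", "chrom", "strand",
                                           "txStart", "txEnd"),
                             colClasses = c("character", "character",
                                            "character", "numeric", "numeric"))
    tab
}

#' Curate a one-transcript-per-symbol gene list
#'
#' Reduces a transcript table to gene models: symbols whose transcripts lie
#' on both strands (or on several chromosomes) are removed as incompatible,
#' as are symbols where some transcript has no overlap with the symbol's
#' longest transcript; the longest transcript is then retained per surviving
#' symbol. Optionally restricted to the admitted chromosomes of an assembly.
#'
#' Coordinates are 0-based half-open throughout. The returned `tss`/`tes`
#' columns are strand-resolved genomic base positions: for `+` genes
#' `tss = txStart`, `tes = txEnd - 1`; for `-` genes `tss = txEnd - 1`,
#' `tes = txStart` (so `tss > tes` on the minus strand).
#'
#' @param transcripts data.frame with columns symbol, chrom, strand, txStart,
#'   txEnd (see [readRefFlat()]).
#' @param assembly Optional [DamAssembly-class] to restrict chromosomes.
#' @return data.frame of gene models: symbol, chrom, strand, txStart, txEnd,
#'   tss, tes, length.
#' @export
curateGeneList <- function(transcripts, assembly = NULL) {
    need <- c("symbol", "chrom", "strand", "txStart", "txEnd")
    if (!all(need %in% names(transcripts)))
        stop("transcript table needs columns: ", paste(need, collapse = ", "))
    bad <- !(transcripts$strand %in% c("+", "-")) |
        is.na(transcripts$txStart) | is.na(transcripts$txEnd) |
        transcripts$txStart >= transcripts$txEnd
    if (any(bad))
        stop("malformed transcript row(s): ",
             paste(utils::head(which(bad), 5L), collapse = ", "))
    if (!is.null(assembly))
        transcripts <- transcripts[
            transcripts$chrom %in% names(seqlengths(assembly)), , drop = FALSE]
    keep <- lapply(split(transcripts, transcripts$symbol), function(tx) {
        if (length(unique(tx$strand)) > 1L ||
            length(unique(tx$chrom)) > 1L)
            return(NULL)
        len <- tx$txEnd - tx$txStart
        longest <- tx[order(-len, tx$txStart, tx$txEnd)[1L], , drop = FALSE]
        overlaps <- tx$txStart < longest$txEnd & tx$txEnd > longest$txStart
        if (!all(overlaps))
            return(NULL)
        longest
    })
    out <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
    if (is.null(out))
        out <- transcripts[0, , drop = FALSE]
    rownames(out) <- NULL
    out$tss <- ifelse(out$strand == "+", out$txStart, out$txEnd - 1)
    out$tes <- ifelse(out$strand == "+", out$txEnd - 1, out$txStart)
    out$length <- out$txEnd - out$txStart
    out
}

#' Classify genes by sLAD coverage of the gene body
#'
#' The gene body is the genomic span from TSS to TES; a gene is an sLAD gene
#' when strictly more than `cutoff` (default 60%) of the body overlaps called
#' sLADs. Base pairs falling in undetermined windows stay in the denominator
#' (conservative).
#'
#' @param genes Gene models from [curateGeneList()].
#' @param domainSet A [DomainSet-class] or island `GRanges`.
#' @param cutoff Strict coverage-fraction threshold, default 0.6.
#' @return `genes` with added columns `sladFraction` and `class`
#'   (`"sLAD"` / `"non-sLAD"`).
#' @export
classifyDomainGenes <- function(genes, domainSet, cutoff = 0.6) {
    isl <- if (is(domainSet, "DomainSet")) domains(domainSet) else domainSet
    isl <- GenomicRanges::reduce(isl)
    if (any(genes$txEnd - genes$txStart <= 0))
        stop("zero-length gene body")
    body <- GenomicRanges::GRanges(
        genes$chrom, IRanges::IRanges(genes$txStart + 1, genes$txEnd))
    hits <- GenomicRanges::findOverlaps(body, isl, ignore.strand = TRUE)
    ovl <- BiocGenerics::width(IRanges::pintersect(
        body[S4Vectors::queryHits(hits)], isl[S4Vectors::subjectHits(hits)]))
    bp <- numeric(length(body))
    if (length(hits) > 0L) {
        agg <- tapply(ovl, S4Vectors::queryHits(hits), sum)
        bp[as.integer(names(agg))] <- agg
    }
    genes$sladFraction <- bp / (genes$txEnd - genes$txStart)
    genes$class <- ifelse(genes$sladFraction > cutoff, "sLAD", "non-sLAD")
    genes
}

#' Expression state from replicate array detection flags
#'
#' A transcript counts as present in a replicate only when every detection
#' flag in every one of its rows is `P`; a gene is expressed only when
#' present in all replicates. Genes absent from every table are `unknown`
#' (and are excluded from expression subgroup analyses); everything else is
#' `silent`.
#'
#' @param symbols Character vector of gene symbols to classify.
#' @param replicates List of data.frames, one per array replicate, each with
#'   a `symbol` column and one or more flag columns with values in
#'   `A`/`M`/`P`.
#' @return Factor over `symbols` with levels `expressed`, `silent`,
#'   `unknown`.
#' @export
parseExpressionFlags <- function(symbols, replicates) {
    stopifnot(is.list(replicates), length(replicates) >= 1L)
    presence <- lapply(replicates, function(tab) {
        if (!"symbol" %in% names(tab))
            stop("replicate table needs a 'symbol' column")
        flagCols <- setdiff(names(tab), "symbol")
        flags <- as.matrix(tab[, flagCols, drop = FALSE])
        if (!all(flags %in% c("A", "M", "P")))
            stop("detection flag outside {A, M, P}")
        allP <- apply(flags == "P", 1L, all)
        tapply(allP, tab$symbol, all)
    })
    onArray <- Reduce(union, lapply(presence, names))
    state <- rep("unknown", length(symbols))
    known <- symbols %in% onArray
    presentAll <- vapply(symbols[known], function(s) {
        all(vapply(presence, function(p) isTRUE(p[[s]]), logical(1)))
    }, logical(1))
    state[known] <- ifelse(presentAll, "expressed", "silent")
    factor(state, levels = c("expressed", "silent", "unknown"))
}

#' Window containing a genomic position
#'
#' Returns the global grid index of the unique window whose half-open
#' interval contains the 0-based position `pos`.
#'
#' @param grid A [WindowGrid-class].
#' @param chrom Chromosome name(s).
#' @param pos 0-based base position(s).
#' @return Integer global window index (vectorized).
#' @export
anchorWindow <- function(grid, chrom, pos) {
    sl <- seqlengths(gridAssembly(grid))
    if (!all(chrom %in% names(sl)))
        stop("chromosome not on the grid: ",
             paste(unique(setdiff(chrom, names(sl))), collapse = ", "))
    if (any(pos < 0 | pos >= sl[chrom]))
        stop("anchor position beyond chromosome bounds")
    w <- gridWindows(grid)
    chromLevels <- names(sl)
    nPer <- ceiling(sl / windowSize(grid))
    offset <- c(0, cumsum(nPer))[match(chrom, chromLevels)]
    idx <- as.integer(offset + pos %/% windowSize(grid) + 1L)
    stopifnot(all(as.character(GenomicRanges::seqnames(w)[idx]) == chrom))
    idx
}

#' Metagene profile around TSS or TES windows
#'
#' For each gene, reads the per-window values of the `flank` windows upstream,
#' the window containing the anchor (TSS or TES) and the `flank` windows
#' downstream, ordered 5' to 3' in the direction of transcription
#' (minus-strand genes reversed unless `strandFlip = FALSE`), then averages
#' per position across genes. Positions running off the chromosome or
#' carrying `NA` values (undetermined windows) are skipped for that gene.
#'
#' @param values Numeric per-window vector in grid order (a log2 seq ratio
#'   track, or per-window peak counts for [genicPeakProfile()]).
#' @param grid The [WindowGrid-class].
#' @param genes Gene models (subset) from [curateGeneList()]; must be
#'   nonempty.
#' @param anchor `"tss"` or `"tes"`.
#' @param flank Windows on each side, default 6 (13 positions in total).
#' @param strandFlip Orient profiles in the transcription direction
#'   (default `TRUE`).
#' @return data.frame with columns `position` (`-flank` to `flank`), `mean`
#'   and `n` (genes contributing at that position).
#' @export
metageneProfile <- function(values, grid, genes, anchor = c("tss", "tes"),
                            flank = 6, strandFlip = TRUE) {
    anchor <- match.arg(anchor)
    if (nrow(genes) == 0L)
        stop("empty gene set")
    if (length(values) != length(gridWindows(grid)))
        stop("values do not match the grid")
    anchorPos <- genes[[anchor]]
    centerIdx <- anchorWindow(grid, genes$chrom, anchorPos)
    w <- gridWindows(grid)
    chromOf <- as.character(GenomicRanges::seqnames(w))
    npos <- 2L * flank + 1L
    mat <- matrix(NA_real_, nrow = nrow(genes), ncol = npos)
    rel <- -flank:flank
    for (j in seq_len(npos)) {
        idx <- centerIdx + rel[j]
        ok <- idx >= 1L & idx <= length(values)
        ok[ok] <- chromOf[idx[ok]] == genes$chrom[ok]
        mat[ok, j] <- values[idx[ok]]
    }
    if (strandFlip) {
        minus <- genes$strand == "-"
        mat[minus, ] <- mat[minus, npos:1, drop = FALSE]
    }
    data.frame(
        position = rel,
        mean = colMeans(mat, na.rm = TRUE),
        n = colSums(!is.na(mat)))
}
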