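#' Summarize a domain call
#'
#' Count, size statistics (kb) and the genome coverage fractions of the
#' sLAD / non-sLAD / undetermined tripartition (which always sum to 1 over
#' the admitted genome).
#'
#' @param domainSet A [DomainSet-class].
#' @param labels Label factor from [tripartitionWindows()].
#' @param grid The [WindowGrid-class].
#' @return List with `count`, `minKb`, `maxKb`, `medianKb`, `meanKb`
#'   (`NA` and `sizesUndefined = TRUE` when no domain was called) and
#'   `coverage`, a named vector of the three label fractions.
#' @export
summarizeDomains <- function(domainSet, labels, grid) {
    isl <- domains(domainSet)
    w <- gridWindows(grid)
    widths <- BiocGenerics::width(w)
    cov <- vapply(levels(labels),
                  function(l) sum(widths[labels == l]) / sum(widths),
                  numeric(1))
    if (length(isl) == 0L)
        return(list(count = 0L, minKb = NA_real_, maxKb = NA_real_,
                    medianKb = NA_real_, meanKb = NA_real_,
                    sizesUndefined = TRUE, coverage = cov))
    kb <- BiocGenerics::width(isl) / 1000
    list(count = length(isl), minKb = min(kb), maxKb = max(kb),
         medianKb = stats::median(kb), meanKb = mean(kb),
         sizesUndefined = FALSE, coverage = cov)
}

#' Export called domains as BED6 plus a statistics TSV
#'
#' BED names are `sLAD_<i>`, the BED score is `min(1000, round(10 * island
#' score))` and the strand is `.`; the TSV carries the full per-island
#' statistics.
#'
#' @param domainSet A [DomainSet-class].
#' @param bedFile,tsvFile Output paths (either may be `NULL` to skip).
#' @return Invisibly, the island data.frame written to the TSV.
#' @export
exportDomains <- function(domainSet, bedFile = NULL, tsvFile = NULL) {
    isl <- domains(domainSet)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(isl)),
        start = BiocGenerics::start(isl) - 1L,
        end = BiocGenerics::end(isl),
        name = if (length(isl)) paste0("sLAD_", seq_along(isl)) else character(0),
        treatmentCount = isl$treatmentCount,
        controlCount = isl$controlCount,
        score = isl$score,
        pvalue = isl$pvalue,
        fdr = isl$fdr)
    if (!is.null(bedFile)) {
        bed <- df[, c("chrom", "start", "end", "name")]
        bed$score <- pmin(1000, round(10 * df$score))
        bed$strand <- "."
        utils::write.table(bed, bedFile, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(tsvFile))
        utils::write.table(df, tsvFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(df)
}

#' Export a window label track as label runs
#'
#' Four-column BED-like output: chrom, 0-based start, end, label, one row
#' per maximal run of a label.
#'
#' @param labels Label factor from [tripartitionWindows()].
#' @param grid The [WindowGrid-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
exportLabelTrack <- function(labels, grid, file) {
    rows <- lapply(levels(labels), function(l) {
        r <- labelRanges(grid, labels, l)
        if (length(r) == 0L)
            return(NULL)
        data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
                   start = BiocGenerics::start(r) - 1L,
                   end = BiocGenerics::end(r), label = l)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

validatePipelineConfig <- function(config) {
    need <- c("treatment", "control", "chromSizes", "outDir")
    missing <- setdiff(need, names(config))
    if (length(missing) > 0L)
        stop("config error: missing field(s): ",
             paste(missing, collapse = ", "))
    for (f in c("treatment", "control", "chromSizes"))
        if (!file.exists(config[[f]]))
            stop("config error: ", f, " file not found: ", config[[f]])
    if (!is.null(config$genes) && !file.exists(config$genes))
        stop("config error: genes file not found: ", config$genes)
    invisible(config)
}

#' Run the full sLAD pipeline
#'
#' Filter and count both libraries, call domains, build the tripartition and
#' the log2 seq ratio track, and write all products to the output directory:
#' `slads.bed`, `islands.tsv`, `labels.bed`, `ratio.bedGraph`,
#' `summary.json`, a verbatim copy of the configuration (`config.yaml`),
#' and — when a gene annotation is configured — `genes.tsv` plus TSS/TES
#' metagene TSVs for the sLAD and non-sLAD gene groups. The run is
#' deterministic: rerunning on identical inputs reproduces every file.
#'
#' @param config Named list (or path to a YAML file) with fields
#'   `treatment`, `control`, `chromSizes` (paths), `outDir`, and optionally
#'   `genes` (refFlat-like TSV), `effectiveGenomeFraction`, `windowSize`,
#'   `gapSize`, `eValue`, `fdrThreshold`, `windowPvalue`, `minMapq`,
#'   `redundancyThreshold`, `allowedChromosomes`.
#' @return Invisibly, a list with the in-memory products (`domainSet`,
#'   `labels`, `ratio`, `summary`, `grid`, `genes`).
#' @export
runFullPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    validatePipelineConfig(config)
    getOr <- function(name, default)
        if (is.null(config[[name]])) default else config[[name]]
    params <- CallerParams(
        windowSize = getOr("windowSize", 2000),
        gapSize = getOr("gapSize", 6000),
        effectiveGenomeFraction = getOr("effectiveGenomeFraction", 0.81),
        eValue = getOr("eValue", 0.1),
        fdrThreshold = getOr("fdrThreshold", 0.001),
        windowPvalue = getOr("windowPvalue", 0.2))
    assembly <- readChromSizes(
        config$chromSizes,
        effectiveGenomeFraction = effectiveGenomeFraction(params),
        allowed = config$allowedChromosomes)
    outDir <- config$outDir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    minMapq <- getOr("minMapq", 40)
    redund <- getOr("redundancyThreshold", 1)
    treatment <- filterAlignments(readAlignments(config$treatment), assembly,
                                  minMapq = minMapq,
                                  redundancyThreshold = redund)
    control <- filterAlignments(readAlignments(config$control), assembly,
                                minMapq = minMapq,
                                redundancyThreshold = redund)
    message("retained reads: treatment ", length(treatment), ", control ",
            length(control))

    grid <- buildWindowGrid(assembly, windowSize(params))
    tCounts <- countWindowReads(treatment, grid)
    cCounts <- countWindowReads(control, grid)
    undet <- flagUndetermined(tCounts, cCounts, grid)
    ds <- callDomains(treatment, control, assembly, params, grid = grid)
    labels <- tripartitionWindows(ds, grid, undet)

    tRpkm <- rpkmNormalize(tCounts, grid, length(treatment))
    cRpkm <- rpkmNormalize(cCounts, grid, length(control))
    pseudo <- computePseudocount(tRpkm, cRpkm, undet)
    ratio <- log2SeqRatio(tRpkm, cRpkm, pseudo, undet)

    exportDomains(ds, bedFile = file.path(outDir, "slads.bed"),
                  tsvFile = file.path(outDir, "islands.tsv"))
    exportLabelTrack(labels, grid, file.path(outDir, "labels.bed"))
    writeBedGraph(ratio, grid, file.path(outDir, "ratio.bedGraph"))

    genes <- NULL
    if (!is.null(config$genes)) {
        genes <- classifyDomainGenes(
            curateGeneList(readRefFlat(config$genes), assembly), ds)
        utils::write.table(genes, file.path(outDir, "genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (cls in intersect(c("sLAD", "non-sLAD"), genes$class)) {
            sub <- genes[genes$class == cls, , drop = FALSE]
            for (anch in c("tss", "tes")) {
                prof <- metageneProfile(ratio, grid, sub, anchor = anch)
                utils::write.table(
                    prof,
                    file.path(outDir, sprintf("metagene_%s_%s.tsv",
                                              gsub("[^A-Za-z]", "", cls), anch)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            }
        }
    }

    summ <- summarizeDomains(ds, labels, grid)
    summ$pseudocount <- pseudo
    summ$librarySizes <- as.list(librarySizes(ds))
    summ$coverage <- as.list(summ$coverage)
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    invisible(list(domainSet = ds, labels = labels, ratio = ratio,
                   summary = summ, grid = grid, genes = genes))
}
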