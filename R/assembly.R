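#' Construct a DamAssembly
#'
#' @param seqlengths Named numeric vector of chromosome lengths in bp. Only
#'   chromosomes named here are admitted to the analysis; reads mapping
#'   elsewhere are dropped (with a logged tally) by [filterAlignments()].
#' @param effectiveGenomeFraction Uniquely mappable proportion of the genome
#'   at the library's read length, in (0, 1]. Default 0.81 (75 bp single-end
#'   reads on mm9). Simulated toy genomes should use 1: every simulated
#'   position is mappable by construction.
#'
#' @return A [DamAssembly-class] object.
#' @examples
#' asm <- DamAssembly(c(chr1 = 5e6, chr2 = 5e6), effectiveGenomeFraction = 1)
#' seqlengths(asm)
#' @export
DamAssembly <- function(seqlengths, effectiveGenomeFraction = 0.81) {
    sl <- as.numeric(seqlengths)
    names(sl) <- names(seqlengths)
    new("DamAssembly", seqlengths = sl,
        effectiveGenomeFraction = as.numeric(effectiveGenomeFraction))
}

#' Read a chrom.sizes table
#'
#' Reads the standard two-column (name, length) tab-separated chromosome
#' sizes file.
#'
#' @param file Path to a two-column TSV.
#' @param effectiveGenomeFraction Passed to [DamAssembly()].
#' @param allowed Optional character vector restricting to a subset of
#'   chromosomes (e.g. `paste0("chr", c(1:19, "X"))` for mouse autosomes + X).
#' @return A [DamAssembly-class].
#' @export
readChromSizes <- function(file, effectiveGenomeFraction = 0.81,
                           allowed = NULL) {
    tab <- utils::read.table(file, header = FALSE, sep = "\t",
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    if (nrow(tab) == 0L)
        stop("empty chrom.sizes file: ", file)
    if (!is.null(allowed)) {
        missing <- setdiff(allowed, tab$chrom)
        if (length(missing) > 0L)
            stop("chromosomes not in ", file, ": ",
                 paste(missing, collapse = ", "))
        tab <- tab[tab$chrom %in% allowed, , drop = FALSE]
    }
    sl <- tab$length
    names(sl) <- tab$chrom
    DamAssembly(sl, effectiveGenomeFraction)
}

#' @describeIn DamAssembly Chromosome lengths of the assembly.
#' @param x A `DamAssembly`.
#' @export
setMethod("seqlengths", "DamAssembly", function(x) x@seqlengths)

#' @rdname effectiveGenomeFraction
#' @export
setMethod("effectiveGenomeFraction", "DamAssembly",
    function(x) x@effectiveGenomeFraction)

setMethod("show", "DamAssembly", function(object) {
    sl <- seqlengths(object)
    cat("DamAssembly with", length(sl), "chromosomes,",
        format(sum(sl), big.mark = ","), "bp total\n")
    cat("  effective genome fraction:", effectiveGenomeFraction(object), "\n")
})

# Total admitted genome length in bp.
assemblyLength <- function(assembly) sum(seqlengths(assembly))

# GRanges spanning every admitted chromosome end to end.
assemblyRanges <- function(assembly) {
    sl <- seqlengths(assembly)
    GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, width = sl))
}
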