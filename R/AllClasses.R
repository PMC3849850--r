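#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

#' Genome assembly description for DamID analysis
#'
#' Holds the chromosome lengths of the analysis assembly restricted to the
#' chromosomes admitted to the analysis (for mouse mm9 runs: chr1-chr19 and
#' chrX), together with the effective genome fraction, i.e. the uniquely
#' mappable proportion of the genome at the library's read length. The
#' effective genome fraction scales the Poisson background rate of the island
#' caller; 0.81 corresponds to 75 bp single-end reads on mm9.
#'
#' @slot seqlengths Named numeric vector of chromosome lengths in bp.
#' @slot effectiveGenomeFraction Numeric scalar in (0, 1].
#'
#' @seealso [DamAssembly()], [readChromSizes()]
#' @exportClass DamAssembly
setClass("DamAssembly",
    representation(
        seqlengths = "numeric",
        effectiveGenomeFraction = "numeric"
    )
)

setValidity("DamAssembly", function(object) {
    msg <- NULL
    sl <- object@seqlengths
    if (length(sl) == 0L || is.null(names(sl)) || any(!nzchar(names(sl))))
        msg <- c(msg, "seqlengths must be a non-empty named vector")
    if (anyDuplicated(names(sl)))
        msg <- c(msg, "duplicated chromosome names")
    if (any(!is.finite(sl)) || any(sl <= 0))
        msg <- c(msg, "all chromosome lengths must be positive")
    egf <- object@effectiveGenomeFraction
    if (length(egf) != 1L || !is.finite(egf) || egf <= 0 || egf > 1)
        msg <- c(msg, "effectiveGenomeFraction must be a scalar in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Fixed-width window partition of a genome
#'
#' A contiguous, non-overlapping tiling of every admitted chromosome into
#' windows of a fixed size (2 kb by default), starting at coordinate 0 of each
#' chromosome. The trailing window of a chromosome whose length is not a
#' multiple of the window size is shorter than the nominal size and is flagged
#' partial; partial windows are never scored by the island caller and are
#' always labelled undetermined.
#'
#' @slot windows A [GenomicRanges::GRanges] of the tiling, in genomic order,
#'   with a logical metadata column `partial`.
#' @slot windowSize Integer nominal window width in bp.
#' @slot assembly The [DamAssembly-class] the grid tiles.
#'
#' @seealso [buildWindowGrid()]
#' @exportClass WindowGrid
setClass("WindowGrid",
    representation(
        windows = "GRanges",
        windowSize = "integer",
        assembly = "DamAssembly"
    )
)

setValidity("WindowGrid", function(object) {
    msg <- NULL
    w <- object@windows
    if (!("partial" %in% colnames(S4Vectors::mcols(w))))
        msg <- c(msg, "windows must carry a 'partial' metadata column")
    if (length(object@windowSize) != 1L || object@windowSize <= 0L)
        msg <- c(msg, "windowSize must be a positive scalar")
    sl <- seqlengths(object@assembly)
    covered <- tapply(BiocGenerics::width(w), as.character(GenomicRanges::seqnames(w)), sum)
    if (!setequal(names(covered), names(sl)) ||
        any(covered[names(sl)] != sl))
        msg <- c(msg, "window tiling must cover every chromosome exactly")
    if (is.null(msg)) TRUE else msg
})

#' Parameters of the Poisson-background island caller
#'
#' @slot windowSize Window width in bp (default 2000).
#' @slot gapSize Maximum internal gap in bp absorbed into an island; must be a
#'   non-negative integer multiple of the window size (default 6000, i.e. up
#'   to three consecutive ineligible windows).
#' @slot effectiveGenomeFraction Uniquely mappable genome proportion used for
#'   the background rate (default 0.81, matching 75 bp reads on mm9).
#' @slot eValue Expected number of background islands tolerated genome-wide;
#'   sets the island score threshold (default 0.1).
#' @slot fdrThreshold Benjamini-Hochberg FDR cutoff on the control-corrected
#'   enrichment p-values (default 0.001).
#' @slot windowPvalue Poisson upper-tail probability below which a window is
#'   eligible (default 0.20).
#' @slot normalizationTarget Library size both libraries are scaled to before
#'   the control-significance test (default 1e6 reads).
#'
#' @seealso [CallerParams()], [callDomains()]
#' @exportClass CallerParams
setClass("CallerParams",
    representation(
        windowSize = "integer",
        gapSize = "integer",
        effectiveGenomeFraction = "numeric",
        eValue = "numeric",
        fdrThreshold = "numeric",
        windowPvalue = "numeric",
        normalizationTarget = "numeric"
    )
)

setValidity("CallerParams", function(object) {
    msg <- NULL
    if (object@windowSize <= 0L)
        msg <- c(msg, "windowSize must be positive")
    if (object@gapSize < 0L || object@gapSize %% object@windowSize != 0L)
        msg <- c(msg, "gapSize must be a non-negative integer multiple of windowSize")
    egf <- object@effectiveGenomeFraction
    if (egf <= 0 || egf > 1)
        msg <- c(msg, "effectiveGenomeFraction must be in (0, 1]")
    if (object@eValue <= 0)
        msg <- c(msg, "eValue must be > 0")
    if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
        msg <- c(msg, "fdrThreshold must be in (0, 1)")
    if (object@windowPvalue <= 0 || object@windowPvalue >= 1)
        msg <- c(msg, "windowPvalue must be in (0, 1)")
    if (object@normalizationTarget <= 0)
        msg <- c(msg, "normalizationTarget must be positive")
    if (is.null(msg)) TRUE else msg
})

#' A called set of sequencing-based lamina-associated domains
#'
#' The result of [callDomains()]: disjoint islands in genomic order, each with
#' its raw treatment and control read counts over the island interval, the
#' summed window score, the control-corrected Poisson enrichment p-value and
#' its Benjamini-Hochberg FDR.
#'
#' @slot islands [GenomicRanges::GRanges] with metadata columns
#'   `treatmentCount`, `controlCount`, `score`, `pvalue`, `fdr`.
#' @slot params The [CallerParams-class] used for the call.
#' @slot librarySizes Named numeric of length 2 (`treatment`, `control`).
#'
#' @seealso [callDomains()], [domains()], [summarizeDomains()]
#' @exportClass DomainSet
setClass("DomainSet",
    representation(
        islands = "GRanges",
        params = "CallerParams",
        librarySizes = "numeric"
    )
)

setValidity("DomainSet", function(object) {
    msg <- NULL
    isl <- object@islands
    need <- c("treatmentCount", "controlCount", "score", "pvalue", "fdr")
    if (!all(need %in% colnames(S4Vectors::mcols(isl))))
        msg <- c(msg, paste("islands must carry metadata columns:",
                            paste(need, collapse = ", ")))
    if (length(isl) > 1L) {
        if (!S4Vectors::isSorted(isl))
            msg <- c(msg, "islands must be in genomic order")
        if (any(GenomicRanges::countOverlaps(isl, isl) > 1L))
            msg <- c(msg, "islands must be pairwise disjoint")
    }
    if (length(isl) > 0L && any(S4Vectors::mcols(isl)$score < 0))
        msg <- c(msg, "island scores must be non-negative")
    if (length(object@librarySizes) != 2L)
        msg <- c(msg, "librarySizes must have length 2 (treatment, control)")
    if (is.null(msg)) TRUE else msg
})
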