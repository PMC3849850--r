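#' @importFrom GenomeInfoDb seqlengths
NULL

#' Extract the window ranges of a grid
#'
#' @param x A [WindowGrid-class].
#' @return A [GenomicRanges::GRanges] of the tiling windows, in genomic order,
#'   with the logical metadata column `partial`.
#' @export
setGeneric("gridWindows", function(x) standardGeneric("gridWindows"))

#' Nominal window width of a grid or parameter set
#'
#' @param x A [WindowGrid-class] or [CallerParams-class].
#' @return Integer window width in bp.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' Effective genome fraction of an assembly or parameter set
#'
#' @param x A [DamAssembly-class] or [CallerParams-class].
#' @return Numeric scalar in (0, 1].
#' @export
setGeneric("effectiveGenomeFraction",
    function(x) standardGeneric("effectiveGenomeFraction"))

#' Called domain intervals of a DomainSet
#'
#' @param x A [DomainSet-class].
#' @return A [GenomicRanges::GRanges] of the islands with their statistics.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' Caller parameters used for a domain call
#'
#' @param x A [DomainSet-class].
#' @return The [CallerParams-class] object.
#' @export
setGeneric("callerParams", function(x) standardGeneric("callerParams"))

#' Library sizes underlying a domain call
#'
#' @param x A [DomainSet-class].
#' @return Named numeric of length 2 (`treatment`, `control`).
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
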