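#' Construct caller parameters
#'
#' Defaults follow the published sLAD analysis: 2 kb windows, 6 kb gap,
#' effective genome fraction 0.81, E-value 0.1, FDR 0.001, and libraries
#' normalized to one million reads for the control-significance test. The
#' window eligibility p-value (0.20) is the island-calling convention the
#' analysis relied on and is exposed as a knob.
#'
#' @param windowSize,gapSize,effectiveGenomeFraction,eValue,fdrThreshold,windowPvalue,normalizationTarget
#'   See [CallerParams-class].
#' @return A [CallerParams-class] object.
#' @examples
#' CallerParams(effectiveGenomeFraction = 1)
#' @export
CallerParams <- function(windowSize = 2000, gapSize = 6000,
                         effectiveGenomeFraction = 0.81, eValue = 0.1,
                         fdrThreshold = 0.001, windowPvalue = 0.2,
                         normalizationTarget = 1e6) {
    new("CallerParams",
        windowSize = as.integer(windowSize),
        gapSize = as.integer(gapSize),
        effectiveGenomeFraction = as.numeric(effectiveGenomeFraction),
        eValue = as.numeric(eValue),
        fdrThreshold = as.numeric(fdrThreshold),
        windowPvalue = as.numeric(windowPvalue),
        normalizationTarget = as.numeric(normalizationTarget))
}

#' @rdname windowSize
#' @export
setMethod("windowSize", "CallerParams", function(x) x@windowSize)

#' @rdname effectiveGenomeFraction
#' @export
setMethod("effectiveGenomeFraction", "CallerParams",
    function(x) x@effectiveGenomeFraction)

setMethod("show", "CallerParams", function(object) {
    cat("CallerParams: window", object@windowSize, "bp, gap", object@gapSize,
        "bp, egf", object@effectiveGenomeFraction, "\n  E-value",
        object@eValue, ", FDR", object@fdrThreshold, ", window p",
        object@windowPvalue, ", normalization",
        format(object@normalizationTarget, scientific = FALSE), "reads\n")
})

#' Poisson background rate per window
#'
#' The expected read count per window under a uniform background:
#' `librarySize * windowSize / (effectiveGenomeFraction * genomeLength)`.
#' Dividing by the effective genome fraction concentrates the library on the
#' mappable part of the genome.
#'
#' @param librarySize Retained reads in the library (> 0).
#' @param assembly A [DamAssembly-class].
#' @param params A [CallerParams-class]; the effective genome fraction is
#'   taken from `assembly`.
#' @return The background rate lambda (reads per window).
#' @export
backgroundLambda <- function(librarySize, assembly, params) {
    if (librarySize <= 0)
        stop("librarySize must be > 0")
    eff <- effectiveGenomeFraction(assembly) * assemblyLength(assembly)
    if (eff <= 0)
        stop("effective genome length must be positive")
    librarySize * windowSize(params) / eff
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, evaluated exactly.
#'
#' @param k Non-negative integer count (vectorized).
#' @param lambda Poisson mean, > 0.
#' @return `P(X >= k)`.
#' @export
poissonUpperTail <- function(k, lambda) {
    if (any(lambda <= 0))
        stop("lambda must be > 0")
    if (any(k < 0))
        stop("k must be >= 0")
    stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Minimum read count for window eligibility
#'
#' The smallest integer count whose Poisson upper-tail probability under the
#' background drops below the window p-value: windows at or above this count
#' are "eligible" (enriched beyond the random background).
#'
#' @param lambda Background rate per window.
#' @param p0 Window p-value threshold in (0, 1).
#' @return Integer threshold `l0` (always >= 1).
#' @export
windowEligibilityThreshold <- function(lambda, p0) {
    if (lambda <= 0)
        stop("lambda must be > 0")
    if (p0 <= 0 || p0 >= 1)
        stop("p0 must be in (0, 1)")
    k <- 1L
    while (poissonUpperTail(k, lambda) >= p0)
        k <- k + 1L
    k
}

#' Score a window against the Poisson background
#'
#' Eligible windows (count >= `l0`) score `-log P(Poisson(lambda) = count)`
#' (natural log); ineligible windows score 0. The score grows with the
#' improbability of the observed count under the background.
#'
#' @param count Integer count(s).
#' @param lambda Background rate.
#' @param l0 Eligibility threshold from [windowEligibilityThreshold()].
#' @return Numeric score(s), >= 0.
#' @export
windowScore <- function(count, lambda, l0) {
    if (lambda <= 0)
        stop("lambda must be > 0")
    ifelse(count >= l0, -stats::dpois(count, lambda, log = TRUE), 0)
}

#' Merge eligible windows into candidate islands
#'
#' Scans each chromosome in genomic order and groups eligible windows into
#' maximal clusters in which consecutive eligible windows are separated by at
#' most `gapSize/windowSize` ineligible windows. The island interval spans
#' the first to the last eligible window, including internal gap windows; gap
#' windows contribute nothing to the island score, which is the sum of the
#' eligible windows' scores.
#'
#' @param grid A [WindowGrid-class].
#' @param eligible Logical vector in grid order (partial windows must already
#'   be `FALSE`).
#' @param scores Numeric vector of window scores in grid order.
#' @param gapWindows Maximum number of consecutive ineligible windows
#'   absorbed inside an island (`gapSize/windowSize`).
#' @return `GRanges` of candidate islands with metadata columns `score`,
#'   `nEligible`, and the global window indices `firstWindow`, `lastWindow`.
#' @export
findCandidateIslands <- function(grid, eligible, scores, gapWindows) {
    w <- gridWindows(grid)
    n <- length(w)
    stopifnot(length(eligible) == n, length(scores) == n)
    chrom <- as.character(GenomicRanges::seqnames(w))
    el <- which(eligible)
    if (length(el) == 0L) {
        out <- GenomicRanges::GRanges()
        out$score <- numeric(0)
        out$nEligible <- integer(0)
        out$firstWindow <- integer(0)
        out$lastWindow <- integer(0)
        return(out)
    }
    # a new island starts at each eligible window whose predecessor is on
    # another chromosome or more than gapWindows ineligible windows away
    newIsland <- c(TRUE,
        chrom[el[-1L]] != chrom[el[-length(el)]] |
        diff(el) - 1L > gapWindows)
    id <- cumsum(newIsland)
    idf <- factor(id, levels = unique(id))
    first <- el[match(unique(id), id)]
    last <- el[length(el) + 1L - match(unique(id), rev(id))]
    score <- as.numeric(tapply(scores[el], idf, sum))
    nEligible <- as.integer(table(idf))
    out <- GenomicRanges::GRanges(
        chrom[first],
        IRanges::IRanges(BiocGenerics::start(w)[first],
                         BiocGenerics::end(w)[last]))
    out$score <- score
    out$nEligible <- nEligible
    out$firstWindow <- first
    out$lastWindow <- last
    out
}

#' Island score threshold for a target E-value
#'
#' Computes the smallest island score `s*` such that the expected number of
#' background islands scoring at least `s*` does not exceed `eValue`.
#'
#' Under the pure Poisson background, a window is eligible with probability
#' `pE = P(Poisson(lambda) >= l0)`; after an eligible window an island
#' continues with probability `c = pE * sum_{j=0..g} (1-pE)^j` (another
#' eligible window within the allowed gap), so the number of eligible windows
#' per island is geometric and the island score is a geometric mixture of
#' m-fold convolutions of the single-eligible-window score distribution
#' (`P(score = -log dpois(k, lambda)) = dpois(k, lambda)/pE`, `k >= l0`). The
#' mixture is evaluated on a discretized score axis by FFT convolution and
#' the expected island count `N * pE * (1-c)` scales its survival function.
#'
#' @param lambda Background rate per window.
#' @param l0 Eligibility threshold.
#' @param gapWindows Gap allowance in windows.
#' @param eValue Tolerated expected number of background islands.
#' @param nWindows Number of scoreable (non-partial) windows genome-wide.
#' @param binWidth Score discretization (default 0.01).
#' @return Numeric score threshold `s*` (0 when the E-value budget already
#'   admits all islands).
#' @export
islandExpectationThreshold <- function(lambda, l0, gapWindows, eValue,
                                       nWindows, binWidth = 0.01) {
    if (eValue <= 0)
        stop("eValue must be > 0")
    pE <- poissonUpperTail(l0, lambda)
    if (pE <= 0)
        return(0)
    q <- 1 - pE
    cont <- pE * sum(q^(0:gapWindows))
    eIslands <- nWindows * pE * (1 - cont)
    if (eIslands <= eValue)
        return(0)
    target <- eValue / eIslands

    # single-eligible-window score distribution, binned
    kmax <- l0
    while (stats::ppois(kmax, lambda, lower.tail = FALSE) > 1e-15)
        kmax <- kmax + 1L
    ks <- l0:kmax
    pk <- stats::dpois(ks, lambda)
    pk <- pk / sum(pk)
    sk <- -stats::dpois(ks, lambda, log = TRUE)
    bins <- as.integer(round(sk / binWidth))
    maxBin <- max(bins)
    single <- numeric(maxBin + 1L)
    for (i in seq_along(bins))
        single[bins[i] + 1L] <- single[bins[i] + 1L] + pk[i]

    # the single-window distribution is supported on ~a handful of bins, so
    # direct sparse convolution beats FFT by orders of magnitude here
    sparseBins <- which(single > 0) - 1L
    sparseProbs <- single[sparseBins + 1L]
    convSingle <- function(f) {
        out <- numeric(length(f) + maxBin)
        n <- length(f)
        for (j in seq_along(sparseBins))
            out[sparseBins[j] + seq_len(n)] <-
                out[sparseBins[j] + seq_len(n)] + sparseProbs[j] * f
        out
    }
    # accumulate the geometric mixture until the residual weight is
    # negligible against the target tail level
    weight <- 1 - cont
    mix <- weight * single
    f <- single
    residual <- cont
    m <- 1L
    while (residual > target * 1e-3 && m < 10000L) {
        f <- convSingle(f)
        term <- (1 - cont) * residual * f
        if (length(term) > length(mix))
            mix <- c(mix, numeric(length(term) - length(mix)))
        mix[seq_along(term)] <- mix[seq_along(term)] + term
        residual <- residual * cont
        m <- m + 1L
    }
    # residual mass belongs to islands with > m windows; treat it as lying
    # beyond any threshold we can return (conservative)
    surv <- rev(cumsum(rev(mix))) + residual
    j <- which(surv <= target)
    if (length(j) == 0L)
        stop("island score threshold did not converge; increase binWidth range")
    (j[1L] - 1L) * binWidth
}

#' Control-corrected enrichment significance of candidate islands
#'
#' Normalizes both libraries to the same size (one million reads by default),
#' then tests each island's normalized treatment count `a` against a Poisson
#' null whose mean is the normalized control count `b`, floored at the
#' normalized genome-average expectation for the island's width (preventing a
#' zero or near-zero control mean). P-values are Benjamini-Hochberg adjusted
#' across all candidate islands and islands with FDR above the threshold are
#' discarded.
#'
#' @param islands Candidate islands from [findCandidateIslands()] (after the
#'   E-value score filter).
#' @param treatmentCounts,controlCounts Per-window counts in grid order.
#' @param treatmentLibrarySize,controlLibrarySize Library sizes.
#' @param assembly The [DamAssembly-class].
#' @param params [CallerParams-class].
#' @param keepAll Keep islands failing the FDR cutoff (default `FALSE`).
#' @return The islands `GRanges` with metadata columns `treatmentCount`,
#'   `controlCount` (raw reads over the island interval), `pvalue`, `fdr`,
#'   `controlFloored` (whether the background floor replaced the observed
#'   control mean), filtered to `fdr <= fdrThreshold` unless `keepAll`.
#' @export
controlSignificance <- function(islands, treatmentCounts, controlCounts,
                                treatmentLibrarySize, controlLibrarySize,
                                assembly, params, keepAll = FALSE) {
    if (length(islands) == 0L) {
        islands$treatmentCount <- integer(0)
        islands$controlCount <- integer(0)
        islands$pvalue <- numeric(0)
        islands$fdr <- numeric(0)
        islands$controlFloored <- logical(0)
        return(islands)
    }
    if (treatmentLibrarySize <= 0 || controlLibrarySize <= 0)
        stop("both libraries must be nonempty")
    spanSum <- function(counts, first, last)
        vapply(seq_along(first),
               function(i) sum(counts[first[i]:last[i]]), numeric(1))
    tCount <- spanSum(treatmentCounts, islands$firstWindow, islands$lastWindow)
    cCount <- spanSum(controlCounts, islands$firstWindow, islands$lastWindow)

    target <- params@normalizationTarget
    a <- tCount * target / treatmentLibrarySize
    b <- cCount * target / controlLibrarySize
    floorB <- target * BiocGenerics::width(islands) /
        (effectiveGenomeFraction(assembly) * assemblyLength(assembly))
    mu <- pmax(b, floorB)
    p <- stats::ppois(ceiling(a) - 1, mu, lower.tail = FALSE)

    islands$treatmentCount <- as.integer(tCount)
    islands$controlCount <- as.integer(cCount)
    islands$pvalue <- p
    islands$fdr <- stats::p.adjust(p, method = "BH")
    islands$controlFloored <- b < floorB
    if (!keepAll)
        islands <- islands[islands$fdr <= params@fdrThreshold]
    islands
}

#' Call sequencing-based lamina-associated domains
#'
#' End-to-end island calling from filtered read sets: build the window grid,
#' count reads, score windows against the Poisson background of the treatment
#' library, merge eligible windows across gaps into candidate islands, drop
#' islands below the E-value score threshold, and keep islands significantly
#' enriched over the normalized control library at the FDR cutoff. Trailing
#' partial windows are never scored. The call is fully deterministic given
#' the inputs and parameters.
#'
#' @param treatment,control Width-1 read `GRanges` (from
#'   [filterAlignments()] or [simulateDamidReads()]).
#' @param assembly A [DamAssembly-class].
#' @param params A [CallerParams-class].
#' @param grid Optional precomputed [WindowGrid-class] (must match
#'   `windowSize(params)`).
#' @return A [DomainSet-class].
#' @examples
#' asm <- DamAssembly(c(chr1 = 2e6), effectiveGenomeFraction = 1)
#' truth <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500001, 600000))
#' sim <- simulateDamidReads(asm, truth, foldEnrichment = 8,
#'                           lambdaBg = 2, seed = 11)
#' callDomains(sim$treatment, sim$control, asm,
#'             CallerParams(effectiveGenomeFraction = 1))
#' @export
callDomains <- function(treatment, control, assembly,
                        params = CallerParams(), grid = NULL) {
    if (is.null(grid))
        grid <- buildWindowGrid(assembly, windowSize(params))
    else if (windowSize(grid) != windowSize(params))
        stop("grid window size does not match params")
    tCounts <- countWindowReads(treatment, grid)
    cCounts <- countWindowReads(control, grid)
    libT <- length(treatment)
    libC <- length(control)
    lambda <- backgroundLambda(libT, assembly, params)
    l0 <- windowEligibilityThreshold(lambda, params@windowPvalue)
    scores <- windowScore(tCounts, lambda, l0)
    partial <- gridWindows(grid)$partial
    eligible <- tCounts >= l0 & !partial
    scores[partial] <- 0
    gapWindows <- params@gapSize %/% params@windowSize
    cand <- findCandidateIslands(grid, eligible, scores, gapWindows)
    sStar <- islandExpectationThreshold(lambda, l0, gapWindows,
                                        params@eValue, sum(!partial))
    cand <- cand[cand$score >= sStar]
    isl <- controlSignificance(cand, tCounts, cCounts, libT, libC,
                               assembly, params)
    isl$firstWindow <- NULL
    isl$lastWindow <- NULL
    isl$nEligible <- NULL
    isl$controlFloored <- NULL
    new("DomainSet", islands = isl, params = params,
        librarySizes = c(treatment = libT, control = libC))
}

#' @rdname domains
#' @export
setMethod("domains", "DomainSet", function(x) x@islands)

#' @rdname callerParams
#' @export
setMethod("callerParams", "DomainSet", function(x) x@params)

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "DomainSet", function(x) x@librarySizes)

setMethod("show", "DomainSet", function(object) {
    isl <- domains(object)
    cat("DomainSet:", length(isl), "sLADs")
    if (length(isl) > 0L) {
        kb <- BiocGenerics::width(isl) / 1000
        cat(", size", min(kb), "-", max(kb), "kb (median",
            stats::median(kb), "kb)")
    }
    cat("\n  libraries:", paste(names(object@librarySizes),
        format(object@librarySizes, scientific = FALSE), collapse = ", "),
        "\n")
})

#' @describeIn domains Number of called domains.
#' @export
setMethod("length", "DomainSet", function(x) length(x@islands))

#' Label every window sLAD / non-sLAD / undetermined
#'
#' Windows inside a called island are labelled `sLAD` (taking precedence over
#' the undetermined mask, so the three coverage fractions always sum to 1);
#' remaining masked windows are `undetermined`; everything else `non-sLAD`.
#'
#' @param domainSet A [DomainSet-class] (or an island `GRanges`).
#' @param grid The [WindowGrid-class].
#' @param undetermined Logical mask from [flagUndetermined()].
#' @return Factor in grid order with levels `sLAD`, `non-sLAD`,
#'   `undetermined`.
#' @export
tripartitionWindows <- function(domainSet, grid, undetermined) {
    isl <- if (is(domainSet, "DomainSet")) domains(domainSet) else domainSet
    w <- gridWindows(grid)
    if (length(undetermined) != length(w))
        stop("undetermined mask does not match the grid")
    inIsland <- IRanges::overlapsAny(w, isl, ignore.strand = TRUE)
    lab <- ifelse(inIsland, "sLAD",
                  ifelse(undetermined, "undetermined", "non-sLAD"))
    factor(lab, levels = c("sLAD", "non-sLAD", "undetermined"))
}

#' Merged genomic ranges carrying a given window label
#'
#' @param grid A [WindowGrid-class].
#' @param labels Factor from [tripartitionWindows()].
#' @param label One of `"sLAD"`, `"non-sLAD"`, `"undetermined"`.
#' @return Reduced `GRanges` of the label's runs.
#' @export
labelRanges <- function(grid, labels, label) {
    GenomicRanges::reduce(gridWindows(grid)[labels == label])
}
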