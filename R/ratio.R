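#' Pseudo-count for the log2 seq ratio
#'
#' The fifth percentile (nearest-rank) of the pooled RPKM values of both
#' libraries over determined windows. Undetermined windows are excluded from
#' the pooling: their zeros reflect missingness (assembly gaps, repeats), not
#' measurement. When the percentile is exactly 0, the smallest positive
#' pooled value is used instead so that the ratio stays defined.
#'
#' @param rpkmA,rpkmB Numeric RPKM vectors in grid order (order of the two
#'   tracks is immaterial).
#' @param undetermined Logical mask from [flagUndetermined()].
#' @param probs Percentile used, default 0.05.
#' @return The pseudo-count, a positive scalar in RPKM units.
#' @export
computePseudocount <- function(rpkmA, rpkmB, undetermined, probs = 0.05) {
    stopifnot(length(rpkmA) == length(rpkmB),
              length(undetermined) == length(rpkmA))
    pooled <- c(rpkmA[!undetermined], rpkmB[!undetermined])
    if (length(pooled) == 0L || all(pooled == 0))
        stop("all pooled RPKM values are zero (degenerate libraries)")
    pooled <- sort(pooled)
    p <- pooled[max(1L, ceiling(probs * length(pooled)))]
    if (p == 0)
        p <- min(pooled[pooled > 0])
    p
}

#' Scaled log2 seq ratio track
#'
#' The per-window nuclear-lamina association score:
#' `log2((treatment RPKM + p) / (control RPKM + p))`. Undetermined windows
#' carry `NA`. Swapping the two tracks negates every value.
#'
#' @param treatmentRpkm,controlRpkm RPKM vectors in grid order.
#' @param pseudocount Positive pseudo-count `p` from [computePseudocount()].
#' @param undetermined Logical mask; `NA` is emitted where `TRUE`.
#' @return Numeric vector in grid order with attribute `pseudocount`.
#' @examples
#' log2SeqRatio(3, 1, pseudocount = 1, undetermined = FALSE)  # log2(4/2) = 1
#' @export
log2SeqRatio <- function(treatmentRpkm, controlRpkm, pseudocount,
                         undetermined = rep(FALSE, length(treatmentRpkm))) {
    if (pseudocount <= 0)
        stop("pseudocount must be > 0")
    stopifnot(length(treatmentRpkm) == length(controlRpkm))
    val <- log2((treatmentRpkm + pseudocount) / (controlRpkm + pseudocount))
    val[undetermined] <- NA_real_
    attr(val, "pseudocount") <- pseudocount
    val
}
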