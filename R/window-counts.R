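#' Count reads overlapping windows
#'
#' Approximates every single-end alignment by an \code{extendTo}-long
#' fragment anchored at its 5' end in read orientation (minus-strand reads
#' extend leftward from their rightmost base), clips it to the chromosome,
#' and counts for each window the reads whose fragment overlaps it by at
#' least 1 bp.  Optionally collapses duplicate intervals or ignores strand
#' (treating every read as forward).
#'
#' @param aln a \linkS4class{GRanges} of stranded alignments.
#' @param grid window grid from [tileWindows()] with seqlengths set.
#' @param extendTo assumed fragment length in bp (>= 1).
#' @param ignoreStrand extend every read rightward from its leftmost base.
#' @param dedup collapse identical (chrom, start, end, strand) records
#'   before counting (off by default; no duplicate handling is assumed).
#' @param label window-count label stored in \code{metadata()$label}.
#' @return the grid \linkS4class{GRanges} with an integer \code{count}
#'   column.
#' @export
countReadsInWindows <- function(aln, grid, extendTo, ignoreStrand = FALSE,
                                dedup = FALSE, label = "y") {
    stopifnot(is(aln, "GRanges"), is(grid, "GRanges"))
    extendTo <- as.integer(extendTo)
    if (extendTo < 1L) stop("extendTo must be >= 1")
    frag <- aln
    if (ignoreStrand)
        strand(frag) <- "+"
    if (dedup)
        frag <- unique(frag)
    sl <- seqlengths(grid)
    seqlengths(frag) <- sl[seqlevels(frag)]
    frag <- trim(suppressWarnings(resize(frag, extendTo, fix = "start")))
    out <- grid
    mcols(out)$count <- countOverlaps(grid, frag, minoverlap = 1L)
    metadata(out)$label <- label
    out
}

#' Windowed pulldown-efficiency ratio
#'
#' The ratio of observed pulldown to input coverage per window, defined
#' wherever the input count is nonzero (NA elsewhere): an unnormalized
#' per-window pulldown efficiency.
#'
#' @param yC,yI window-count \linkS4class{GRanges} (e.g. from
#'   [countReadsInWindows()]) on the identical grid.
#' @return numeric vector of ratios, NA where \code{yI} is zero.
#' @export
windowEfficiencyRatio <- function(yC, yI) {
    stopifnot(is(yC, "GRanges"), is(yI, "GRanges"))
    if (!identical(granges(yC), granges(yI)))
        stop("window grids differ")
    num <- windowValues(yC)
    den <- windowValues(yI)
    ifelse(den > 0, num / den, NA_real_)
}
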