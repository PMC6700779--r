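#' Build a model configuration
#'
#' @param dist a \linkS4class{FragLenDist}; default the fitted MethylMiner
#'   library distribution (Gaussian, L = 100.7, S = 12.98 on [3, 200]).
#' @param cn a \linkS4class{CnTable}; default [defaultCnTable()].
#' @param minSep minimum separation (bp) between simultaneously bound CpGs
#'   (default 3, the MBD2 steric-exclusion estimate).
#' @param prefactor overall depth normalization (default 1; the window
#'   ranking is invariant under it).
#' @param mode window aggregation: "start-in-window" (default) or "overlap".
#' @param lAvg fixed fragment length for overlap mode.
#' @param clipEdges handle fragments running past a chromosome end by
#'   counting CpGs on the clipped intersection (TRUE, default) or by
#'   dropping those lengths (FALSE).
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(dist = fragLenDist(), cn = defaultCnTable(),
                        minSep = 3L, prefactor = 1,
                        mode = c("start-in-window", "overlap"),
                        lAvg = NA_integer_, clipEdges = TRUE) {
    mode <- match.arg(mode)
    new("ModelConfig", dist = dist, cn = cn, minSep = as.integer(minSep),
        prefactor = prefactor, mode = mode, lAvg = as.integer(lAvg),
        clipEdges = clipEdges)
}

setMethod("show", "ModelConfig", function(object) {
    cat("ModelConfig:", object@mode, "\n  ")
    show(object@dist)
    cat(sprintf("  minSep=%d prefactor=%g clipEdges=%s%s\n",
                object@minSep, object@prefactor, object@clipEdges,
                if (!is.na(object@lAvg))
                    paste0(" lAvg=", object@lAvg) else ""))
})

#' Accessible CpGs under steric exclusion
#'
#' The number of CpGs on a fragment that can be bound simultaneously by MBD
#' protein domains: the largest subset of the given C positions in which
#' every pair is separated by at least \code{minSep} bp between the G of
#' one CpG and the C of the next.  Computed greedily left to right -- the
#' first CpG is bound, and a later CpG at c is bound iff
#' \code{(c_last + 1) + minSep < c} -- which attains the maximum subset
#' size.
#'
#' @param positions strictly increasing C positions on one fragment.
#' @param minSep minimum separation in bp (default 3).
#' @return the number of simultaneously bindable CpGs.
#' @examples
#' accessibleCount(c(10, 15))         # 2
#' accessibleCount(c(10, 14))         # 1 (too close)
#' accessibleCount(c(10, 14, 15, 19, 20))  # 2
#' @export
accessibleCount <- function(positions, minSep = 3L) {
    if (length(positions) == 0L) return(0L)
    if (is.unsorted(positions, strictly = TRUE))
        stop("positions must be strictly increasing")
    cpp_accessible_count(as.integer(positions), as.integer(minSep))
}

#' Accessible-CpG count of genomic fragments
#'
#' Counts accessible CpGs on the fragment \code{[start, start + length - 1]}
#' (1-based, inclusive): a CpG is on the fragment iff both its C and G lie
#' inside, i.e. C in \code{[start, start + length - 2]}.  The interval is
#' clipped to the chromosome; the count is returned uncapped (the
#' coefficient cap is applied at lookup time, via [cnLookup()]).
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param chrom chromosome name.
#' @param start fragment start position(s), 1-based.
#' @param length fragment length(s) in bp (recycled against start).
#' @param minSep minimum separation (bp).
#' @return integer vector of accessible-CpG counts.
#' @export
fragmentNCpG <- function(index, chrom, start, length, minSep = 3L) {
    stopifnot(is(index, "CpGIndex"))
    if (any(length < 1L)) stop("length must be >= 1")
    n <- max(base::length(start), base::length(length))
    start <- rep_len(as.integer(start), n)
    len <- rep_len(as.integer(length), n)
    cpp_fragment_ncpg(start, start + len - 1L, cpgPositions(index, chrom),
                      as.integer(minSep))
}

# per-strand expected pulldown over a whole chromosome (no prefactor):
# matrix len x 2 (forward, reverse)
.lambdaStrandMatrix <- function(index, chrom, config) {
    d <- config@dist
    cpp_lambda_track(cpgPositions(index, chrom),
                     seqlengths(index)[[chrom]], d@lmin, d@lmax, d@pmf,
                     config@cn@coefs, config@minSep, config@clipEdges)
}

#' Expected pulldown at single positions
#'
#' The expected number of pulldown alignments to position x from fully
#' methylated (SssI-treated) DNA: a sum over fragment lengths of the
#' length probability times the enrichment coefficient of the fragment's
#' accessible-CpG count, for the forward-strand fragment starting at x and
#' the reverse-strand fragment ending at x, scaled by the prefactor.
#' Implemented by direct enumeration over (length, strand); use
#' [lambdaTrack()] for whole chromosomes.
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param chrom chromosome name.
#' @param x position(s), 1-based.
#' @param config a \linkS4class{ModelConfig}.
#' @return numeric vector of expected pulldown values.
#' @export
lambdaAt <- function(index, chrom, x, config = modelConfig()) {
    stopifnot(is(index, "CpGIndex"), is(config, "ModelConfig"))
    len <- seqlengths(index)[[chrom]]
    if (any(x < 1L | x > len)) stop("x outside the chromosome")
    d <- config@dist
    ls <- d@lmin:d@lmax
    cpg <- cpgPositions(index, chrom)
    vapply(as.integer(x), function(xi) {
        nF <- cpp_fragment_ncpg(rep(xi, length(ls)), xi + ls - 1L, cpg,
                                config@minSep)
        nR <- cpp_fragment_ncpg(xi - ls + 1L, rep(xi, length(ls)), cpg,
                                config@minSep)
        wF <- d@pmf
        wR <- d@pmf
        if (!config@clipEdges) {
            wF[xi + ls - 1L > len] <- 0
            wR[xi - ls + 1L < 1L] <- 0
        }
        config@prefactor * (sum(wF * cnLookup(config@cn, nF)) +
                            sum(wR * cnLookup(config@cn, nR)))
    }, numeric(1))
}

#' Expected pulldown track
#'
#' Computes the expected pulldown at every position of each chromosome with
#' a single scan that reuses the greedy accessible-CpG chain through
#' per-CpG next-accessible pointers.  Values are rounded to 9 decimals
#' (guarding window floors against representation noise) and run-length
#' encoded.
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param config a \linkS4class{ModelConfig}.
#' @param chroms chromosomes to scan (default all indexed).
#' @return a named \linkS4class{RleList} of per-position expected pulldown.
#' @export
lambdaTrack <- function(index, config = modelConfig(), chroms = NULL) {
    stopifnot(is(index, "CpGIndex"), is(config, "ModelConfig"))
    if (is.null(chroms)) chroms <- seqlevels(index)
    out <- lapply(chroms, function(chr) {
        m <- .lambdaStrandMatrix(index, chr, config)
        Rle(round(config@prefactor * (m[, 1L] + m[, 2L]), 9))
    })
    names(out) <- chroms
    methods::as(out, "RleList")
}

#' @describeIn lambdaTrack export the track as bedGraph, merging
#'   constant-value runs into single records.
#' @param track an \linkS4class{RleList} from \code{lambdaTrack}.
#' @param path output bedGraph path.
#' @export
exportLambdaBedGraph <- function(track, path) {
    gr <- methods::as(track, "GRanges")
    gr <- gr[width(gr) > 0L]
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

.windowFloor <- function(sums) as.integer(floor(round(sums, 9)))

# per-chromosome window sums of a numeric vector
.windowSums <- function(values, starts, ends) {
    viewSums(Views(Rle(values), starts, ends))
}

#' Modeled window coverage
#'
#' Sums the expected per-position pulldown over each window and floors the
#' result, yielding an integer count usable like an observed SssI-control
#' window coverage ("start-in-window" aggregation: only fragments starting,
#' on either strand, at positions in the window contribute).
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param grid window grid from [tileWindows()] on the same genome.
#' @param config a \linkS4class{ModelConfig}.
#' @return the grid \linkS4class{GRanges} with an integer \code{count}
#'   column; \code{metadata(x)$label} is "y_lambda".
#' @export
windowLambda <- function(index, grid, config = modelConfig()) {
    stopifnot(is(index, "CpGIndex"), is(grid, "GRanges"))
    counts <- integer(length(grid))
    for (chr in seqlevels(index)) {
        wi <- which(as.character(seqnames(grid)) == chr)
        if (!length(wi)) next
        m <- .lambdaStrandMatrix(index, chr, config)
        lam <- config@prefactor * (m[, 1L] + m[, 2L])
        counts[wi] <- .windowFloor(.windowSums(lam, start(grid)[wi],
                                               end(grid)[wi]))
    }
    out <- grid
    mcols(out)$count <- counts
    metadata(out)$label <- "y_lambda"
    out
}

#' Modeled window coverage, overlap variant
#'
#' For a fixed fragment length, sums the expected strand-specific pulldown
#' over every position whose fragment would overlap the window: forward
#' fragments \code{[x, x + lAvg - 1]} and reverse fragments
#' \code{[x - lAvg + 1, x]} with at least 1 bp inside the window.  Requires
#' \code{mode = "overlap"} and a delta fragment-length distribution.
#'
#' @inheritParams windowLambda
#' @return the grid \linkS4class{GRanges} with an integer \code{count}
#'   column; \code{metadata(x)$label} is "y_lambda_overlap".
#' @export
windowLambdaOverlap <- function(index, grid, config) {
    stopifnot(is(index, "CpGIndex"), is(grid, "GRanges"),
              is(config, "ModelConfig"))
    if (config@mode != "overlap")
        stop("config mode must be 'overlap'")
    if (config@dist@kind != "delta")
        stop("overlap aggregation requires a delta fragment-length ",
             "distribution at lAvg")
    lavg <- config@lAvg
    if (is.na(lavg) || lavg != round(config@dist@L))
        stop("lAvg must equal the delta distribution length")
    counts <- integer(length(grid))
    for (chr in seqlevels(index)) {
        wi <- which(as.character(seqnames(grid)) == chr)
        if (!length(wi)) next
        len <- seqlengths(index)[[chr]]
        m <- .lambdaStrandMatrix(index, chr, config)
        fw <- Rle(config@prefactor * m[, 1L])
        rv <- Rle(config@prefactor * m[, 2L])
        ws <- start(grid)[wi]; we <- end(grid)[wi]
        sF <- pmax(ws - lavg + 1L, 1L)
        sumF <- viewSums(Views(fw, sF, pmin(we, len)))
        sumR <- viewSums(Views(rv, pmax(ws, 1L), pmin(we + lavg - 1L, len)))
        counts[wi] <- .windowFloor(sumF + sumR)
    }
    out <- grid
    mcols(out)$count <- counts
    metadata(out)$label <- "y_lambda_overlap"
    out
}

#' @describeIn windowLambda extract the per-window counts of a window-count
#'   GRanges.
#' @param x a GRanges carrying a \code{count} column.
#' @export
windowValues <- function(x) {
    stopifnot(is(x, "GRanges"), !is.null(mcols(x)$count))
    mcols(x)$count
}

#' @describeIn windowLambda write window counts as TSV
#'   (chrom, start, end, count, label).
#' @param path output path.
#' @export
writeWindowCounts <- function(x, path) {
    stopifnot(is(x, "GRanges"), !is.null(mcols(x)$count))
    lab <- metadata(x)$label
    df <- data.frame(chrom = as.character(seqnames(x)), start = start(x),
                     end = end(x), count = mcols(x)$count,
                     label = if (is.null(lab)) NA_character_ else lab)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
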