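#' Window methylation from per-CpG bisulfite counts
#'
#' Read-weighted window methylation: for each window the total methylated
#' reads over all covered CpGs divided by the total reads, with the total
#' coverage recorded.  Windows without covered CpGs are undefined.  The
#' methylation state is "methylated" when the level exceeds 0.50 and
#' "unmethylated" at or below 0.50.
#'
#' @param counts a width-1 \linkS4class{GRanges} of per-CpG counts with
#'   columns \code{m} and \code{r} (see [loadCpGMethCounts()]).
#' @param grid window grid from [tileWindows()].
#' @param split methylation level above which a window is methylated.
#' @return the grid \linkS4class{GRanges} with columns \code{mu} (level,
#'   NA when undefined), \code{coverage} (total reads) and \code{label}
#'   (factor methylated/unmethylated/undefined).
#' @export
windowMethylation <- function(counts, grid, split = 0.50) {
    stopifnot(is(counts, "GRanges"), is(grid, "GRanges"))
    ov <- findOverlaps(counts, grid)
    M <- numeric(length(grid)); R <- numeric(length(grid))
    msum <- tapply(mcols(counts)$m[S4Vectors::from(ov)],
                   S4Vectors::to(ov), sum)
    rsum <- tapply(mcols(counts)$r[S4Vectors::from(ov)],
                   S4Vectors::to(ov), sum)
    idx <- as.integer(names(msum))
    M[idx] <- msum; R[idx] <- rsum
    mu <- ifelse(R > 0, M / R, NA_real_)
    label <- factor(ifelse(R > 0, ifelse(mu > split, "methylated",
                                         "unmethylated"), "undefined"),
                    levels = c("methylated", "unmethylated", "undefined"))
    out <- grid
    mcols(out)$mu <- mu
    mcols(out)$coverage <- as.integer(R)
    mcols(out)$label <- label
    out
}

#' Select windows for evaluation
#'
#' Keeps windows with bisulfite coverage of at least \code{minCov} reads
#' and a mappable-base fraction of at least \code{minMap} (both inclusive).
#' The defaults reproduce an RRBS-based evaluation (coverage >= 10,
#' mappability >= 0.75); \code{minCov = 33} reproduces a WGBS-based filter.
#' Exclusion counts by reason are reported.
#'
#' @param wm window methylation \linkS4class{GRanges} from
#'   [windowMethylation()].
#' @param mappable per-window mappable fraction from
#'   [windowMappableFraction()] (NULL to skip the filter).
#' @param minCov minimum bisulfite coverage (reads).
#' @param minMap minimum mappable fraction.
#' @return logical vector of selected windows, with an
#'   \code{attr(, "excluded")} breakdown.
#' @export
selectEvalWindows <- function(wm, mappable = NULL, minCov = 10L,
                              minMap = 0.75) {
    stopifnot(is(wm, "GRanges"), !is.null(mcols(wm)$coverage))
    covOk <- mcols(wm)$coverage >= minCov
    mapOk <- if (is.null(mappable)) rep(TRUE, length(wm))
             else mappable >= minMap
    keep <- covOk & mapOk
    excluded <- c(lowCoverage = sum(!covOk),
                  lowMappability = sum(covOk & !mapOk))
    message(sum(keep), " of ", length(wm), " windows selected (",
            excluded[1L], " below coverage, ", excluded[2L],
            " below mappability)")
    attr(keep, "excluded") <- excluded
    keep
}

#' ROC curve and AUC for methylation calls
#'
#' Sweeps a cutoff over the distinct prediction scores in descending order
#' (windows scoring at or above the cutoff are called methylated; tied
#' scores form a single step) and records the true/false positive rates.
#' The AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney U statistic with half credit for ties.
#'
#' @param score numeric prediction per window (higher = more methylated).
#' @param labels true states: logical (TRUE = methylated), or the
#'   \code{label} factor from [windowMethylation()].
#' @return a \linkS4class{ROCCurve}.
#' @examples
#' roc <- rocAuc(c(.9, .8, .2, .1), c(TRUE, TRUE, FALSE, FALSE))
#' rocAuc(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE))@auc  # 0.5
#' @export
rocAuc <- function(score, labels) {
    if (is.factor(labels) || is.character(labels)) {
        if (any(labels == "undefined"))
            stop("labels contain undefined windows; filter them first")
        labels <- labels == "methylated"
    }
    ok <- is.finite(score) & !is.na(labels)
    score <- score[ok]; labels <- labels[ok]
    P <- sum(labels); N <- sum(!labels)
    if (P == 0L || N == 0L)
        stop("need at least one methylated and one unmethylated window")
    o <- order(score, decreasing = TRUE)
    s <- score[o]; y <- labels[o]
    last <- which(!duplicated(s, fromLast = TRUE))   # end of each tie group
    tpr <- c(0, cumsum(y)[last] / P)
    fpr <- c(0, cumsum(!y)[last] / N)
    cutoffs <- c(Inf, s[last])
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    new("ROCCurve", fpr = fpr, tpr = tpr, cutoffs = cutoffs, auc = auc)
}

setMethod("show", "ROCCurve", function(object) {
    cat(sprintf("ROCCurve: %d points, AUC = %.4f\n",
                length(object@fpr), object@auc))
})

#' Most efficient operating point
#'
#' The cutoff at the ROC point furthest from the chance diagonal, i.e.
#' maximizing \eqn{(TPR - FPR)/\sqrt 2}; ties are broken toward the lower
#' false positive rate.
#'
#' @param roc a \linkS4class{ROCCurve}.
#' @return a list with \code{cutoff}, \code{tpr}, \code{fpr} and
#'   \code{distance} (to the diagonal).
#' @export
youdenPoint <- function(roc) {
    stopifnot(is(roc, "ROCCurve"))
    d <- (roc@tpr - roc@fpr) / sqrt(2)
    best <- which(d == max(d))
    best <- best[which.min(roc@fpr[best])]
    list(cutoff = roc@cutoffs[best], tpr = roc@tpr[best],
         fpr = roc@fpr[best], distance = max(d))
}

#' Prediction accuracy in the extremal methylation regimes
#'
#' Summaries over the windows where most bisulfite mass lies: among windows
#' with true methylation at or below \code{lo}, the fraction predicted
#' above \code{split} (miscategorized) and the fraction still predicted at
#' or below \code{lo}; symmetrically for windows at or above \code{hi}.
#'
#' @param pred numeric predicted methylation per window.
#' @param mu true (bisulfite) methylation per window; NAs are dropped.
#' @param lo,hi extremal regime bounds.
#' @param split state cutoff (predictions above it are "methylated").
#' @return a list with elements \code{low} and \code{high}, each holding
#'   \code{n}, \code{miscategorized} and \code{retained} fractions.
#' @export
regimeSummary <- function(pred, mu, lo = 0.10, hi = 0.90, split = 0.50) {
    ok <- !is.na(pred) & !is.na(mu)
    pred <- pred[ok]; mu <- mu[ok]
    lowI <- mu <= lo
    highI <- mu >= hi
    frac <- function(x) if (length(x)) mean(x) else NA_real_
    list(low = list(n = sum(lowI),
                    miscategorized = frac(pred[lowI] > split),
                    retained = frac(pred[lowI] <= lo)),
         high = list(n = sum(highI),
                     miscategorized = frac(pred[highI] <= split),
                     retained = frac(pred[highI] >= hi)))
}

#' AUC under increasing modeled-coverage cutoffs
#'
#' Sweeps a minimum modeled SssI coverage cutoff through the percentiles of
#' \code{yLambda} (nearest-rank convention, computed on the evaluated
#' windows) in steps of \code{step}, restricts the windows to those at or
#' above each cutoff, and recomputes the AUC of every prediction set.
#' Cutoffs leaving a single class yield NA.
#'
#' @param yLambda modeled window coverage (numeric, one value per window).
#' @param predictions named list of numeric score vectors.
#' @param labels true states as in [rocAuc()].
#' @param step percentile increment (default 5; sweeps 0 to 100 - step).
#' @return a data.frame with columns percentile, cutoff, n, method, auc.
#' @export
lambdaCutoffSweep <- function(yLambda, predictions, labels, step = 5) {
    if (!is.list(predictions))
        predictions <- list(score = predictions)
    if (is.factor(labels) || is.character(labels))
        labels <- labels == "methylated"
    n <- length(yLambda)
    srt <- sort(yLambda)
    out <- list()
    for (p in seq(0, 100 - step, by = step)) {
        cut <- if (p == 0) -Inf else srt[ceiling(p / 100 * n)]
        keep <- yLambda >= cut
        for (m in names(predictions)) {
            auc <- if (length(unique(labels[keep])) < 2L) NA_real_
                   else rocAuc(predictions[[m]][keep], labels[keep])@auc
            out[[length(out) + 1L]] <-
                data.frame(percentile = p, cutoff = cut, n = sum(keep),
                           method = m, auc = auc)
        }
    }
    do.call(rbind, out)
}

#' Local CpG density per window
#'
#' The number of CpGs whose C lies within \code{context} bp of the window
#' (i.e. in \code{[start - context, end + context]}, clipped to the
#' chromosome).  Using the average fragment length as context mirrors how a
#' local CpG density is attached to window-level pulldown counts.  This is
#' a plain count (no positional weighting).
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param grid window grid from [tileWindows()].
#' @param context flank added on both sides (bp, >= 0).
#' @return integer vector of CpG counts per window.
#' @export
cpgDensityWindow <- function(index, grid, context = 0L) {
    stopifnot(is(index, "CpGIndex"), is(grid, "GRanges"))
    if (context < 0L) stop("context must be >= 0")
    out <- integer(length(grid))
    for (chr in seqlevels(index)) {
        wi <- which(as.character(seqnames(grid)) == chr)
        if (!length(wi)) next
        cpg <- cpgPositions(index, chr)
        lo <- pmax(start(grid)[wi] - as.integer(context), 1L)
        hi <- pmin(end(grid)[wi] + as.integer(context),
                   seqlengths(index)[[chr]])
        out[wi] <- findInterval(hi, cpg) - findInterval(lo - 1L, cpg)
    }
    out
}

#' Export window-level inputs for Bayesian methylation callers
#'
#' Writes one row per window -- chrom, start, end, sample coverage, control
#' coverage (observed or modeled SssI), local CpG density, mappable
#' fraction -- in grid order, as the input table for an external empirical
#' Bayes methylation caller such as BayMeth.
#'
#' @param path output TSV path.
#' @param grid window grid \linkS4class{GRanges}.
#' @param yS sample-of-interest window counts (numeric vector or
#'   window-count GRanges).
#' @param yControl SssI-control window counts, observed or modeled.
#' @param density per-window CpG density from [cpgDensityWindow()].
#' @param mappable per-window mappable fraction (optional, NA if missing).
#' @return the path, invisibly.
#' @export
exportBaymethTable <- function(path, grid, yS, yControl, density = NULL,
                               mappable = NULL) {
    stopifnot(is(grid, "GRanges"))
    getv <- function(v, what) {
        if (is.null(v)) stop("missing ", what, " counts")
        if (is(v, "GRanges")) {
            if (!identical(granges(v), granges(grid)))
                stop(what, " grid differs from the window grid")
            v <- windowValues(v)
        }
        if (length(v) != length(grid))
            stop(what, " length differs from the window grid")
        v
    }
    df <- data.frame(chrom = as.character(seqnames(grid)),
                     start = start(grid), end = end(grid),
                     y_sample = getv(yS, "sample"),
                     y_control = getv(yControl, "control"),
                     cpg_density = if (is.null(density)) NA_integer_
                                   else density,
                     mappable_fraction = if (is.null(mappable)) NA_real_
                                         else mappable)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @describeIn exportBaymethTable read the table back.
#' @export
readBaymethTable <- function(path) {
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Import external per-window prediction scores
#'
#' Reads a TSV of (chrom, start, end, score) -- e.g. posterior methylation
#' levels produced by an external caller -- and matches it to a window
#' grid, returning NA for windows without a score.
#'
#' @param path TSV path with header columns chrom, start, end, score.
#' @param grid window grid \linkS4class{GRanges}.
#' @return numeric scores aligned with the grid.
#' @export
readWindowScores <- function(path, grid) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
    hit <- findOverlaps(grid, gr, type = "equal")
    out <- rep(NA_real_, length(grid))
    out[S4Vectors::from(hit)] <- gr$score[S4Vectors::to(hit)]
    out
}
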