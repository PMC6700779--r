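#' CpG dinucleotide index
#'
#' Sorted 1-based positions of the C of every CG dinucleotide, per
#' chromosome, together with the chromosome lengths.  This is the backbone
#' of all model arithmetic: fragments are classified by the accessible-CpG
#' count of the positions they cover.
#'
#' @slot positions an \linkS4class{IntegerList}, one strictly increasing
#'   vector of C positions per chromosome.
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @seealso [indexCpGs()], [cpgPositions()]
#' @export
setClass("CpGIndex",
    representation(positions = "IntegerList", seqlengths = "integer"))

setValidity("CpGIndex", function(object) {
    if (!identical(names(object@positions), names(object@seqlengths)))
        return("positions and seqlengths must have identical names")
    for (chr in names(object@positions)) {
        p <- object@positions[[chr]]
        if (length(p) && (is.unsorted(p, strictly = TRUE)))
            return(sprintf("positions on %s are not strictly increasing", chr))
        if (length(p) && (p[1L] < 1L ||
                          p[length(p)] + 1L > object@seqlengths[[chr]]))
            return(sprintf("positions on %s outside [1, length-1]", chr))
    }
    TRUE
})

#' Fragment-length distribution
#'
#' Discrete distribution P(l) of sequenced-fragment lengths on
#' \code{[lmin, lmax]} bp.  The \code{"gaussian"} kind evaluates the Normal
#' (L, S) density at integer lengths and renormalizes over the truncation
#' range; the \code{"delta"} kind puts all mass at \code{round(L)} (used
#' e.g. when only an average fragment length is known for a library).
#'
#' @slot kind "gaussian" or "delta".
#' @slot L mean fragment length (bp).
#' @slot S standard deviation (bp; 0 for delta).
#' @slot lmin,lmax truncation range (bp).
#' @slot pmf cached probability mass over lmin:lmax (sums to 1).
#' @seealso [fragLenDist()], [fragPmf()], [fragSurvival()]
#' @export
setClass("FragLenDist",
    representation(kind = "character", L = "numeric", S = "numeric",
                   lmin = "integer", lmax = "integer", pmf = "numeric"))

setValidity("FragLenDist", function(object) {
    if (!object@kind %in% c("gaussian", "delta"))
        return("kind must be 'gaussian' or 'delta'")
    if (object@lmin < 1L) return("lmin must be >= 1")
    if (object@lmin > object@lmax) return("lmin must be <= lmax")
    if (length(object@pmf) != object@lmax - object@lmin + 1L)
        return("pmf length must be lmax - lmin + 1")
    if (abs(sum(object@pmf) - 1) > 1e-9)
        return("pmf must sum to 1 within 1e-9")
    if (object@kind == "delta" &&
        (round(object@L) < object@lmin || round(object@L) > object@lmax))
        return("delta distribution requires lmin <= round(L) <= lmax")
    TRUE
})

#' Enrichment coefficient table
#'
#' Pulldown enrichment coefficients \eqn{C_n = E(n)/E(0)}: how much more
#' likely a fragment carrying n accessible methylated CpGs is to be pulled
#' down, sequenced and aligned than a fragment with none.  Counts above the
#' cap reuse the cap coefficient.  \code{sss} carries the subsample
#' (by-chromosome) standard deviation of each coefficient as a fraction of
#' its value, where estimated.
#'
#' @slot coefs numeric of length cap+1, the coefficients for n = 0..cap;
#'   the first entry (C(0)) is exactly 1.
#' @slot sss subsample SD as a fraction of C(n) (NA where not estimated).
#' @slot cap maximum n with its own coefficient (default 7).
#' @seealso [defaultCnTable()], [cnLookup()], [cnFromCounts()]
#' @export
setClass("CnTable",
    representation(coefs = "numeric", sss = "numeric", cap = "integer"))

setValidity("CnTable", function(object) {
    if (length(object@coefs) != object@cap + 1L)
        return("C must have cap + 1 entries")
    if (length(object@sss) != length(object@coefs))
        return("sss must align with C")
    if (is.na(object@coefs[1L]) || object@coefs[1L] != 1)
        return("C(0) must be exactly 1")
    if (any(!is.na(object@coefs) & object@coefs < 0))
        return("coefficients must be non-negative")
    TRUE
})

#' Model configuration
#'
#' Bundles everything the expected-pulldown scan needs: the fragment-length
#' distribution, the enrichment coefficients, the minimum CpG separation of
#' the steric-exclusion rule, a depth prefactor, and the window-aggregation
#' mode ("start-in-window" sums expected alignments starting in the window;
#' "overlap" sums expected alignments whose fixed-length fragment overlaps
#' the window).
#'
#' @slot dist a \linkS4class{FragLenDist}.
#' @slot cn a \linkS4class{CnTable}.
#' @slot minSep minimum separation (bp) between simultaneously bound CpGs.
#' @slot prefactor overall depth normalization (> 0).
#' @slot mode "start-in-window" or "overlap".
#' @slot lAvg fixed fragment length for overlap mode (bp).
#' @slot clipEdges whether fragments running past a chromosome end
#'   contribute with the accessible count of the clipped intersection
#'   (default) or are dropped.
#' @seealso [modelConfig()], [windowLambda()]
#' @export
setClass("ModelConfig",
    representation(dist = "FragLenDist", cn = "CnTable", minSep = "integer",
                   prefactor = "numeric", mode = "character",
                   lAvg = "integer", clipEdges = "logical"))

setValidity("ModelConfig", function(object) {
    if (object@minSep < 0L) return("minSep must be >= 0")
    if (!is.finite(object@prefactor) || object@prefactor <= 0)
        return("prefactor must be > 0")
    if (!object@mode %in% c("start-in-window", "overlap"))
        return("mode must be 'start-in-window' or 'overlap'")
    if (object@mode == "overlap" &&
        (is.na(object@lAvg) || object@lAvg < 1L))
        return("overlap mode requires lAvg >= 1")
    TRUE
})

#' Fragment counts by accessible-CpG number
#'
#' Per-group (typically per-chromosome) counts of fragments carrying
#' n = 0..cap accessible CpGs; counts above the cap are pooled into the cap
#' bin.  Produced by [classifyFragmentsByNCpG()] and consumed by the
#' enrichment-coefficient estimators.
#'
#' @slot counts integer matrix, groups x (cap+1) with columns "0".."cap".
#' @slot cap the pooling cap.
#' @slot library label of the source library.
#' @export
setClass("NCpGCountTable",
    representation(counts = "matrix", cap = "integer", library = "character"))

setValidity("NCpGCountTable", function(object) {
    if (ncol(object@counts) != object@cap + 1L)
        return("counts must have cap + 1 columns")
    if (any(object@counts < 0)) return("counts must be >= 0")
    TRUE
})

#' Single-CpG positional profile
#'
#' For alignments extended to a fixed-length genomic segment from their 5'
#' end, counts of segments containing exactly one CpG, binned by the 1-based
#' position t of that CpG's C relative to the segment 5' end.  The decay of
#' the pulldown/input ratio of two such profiles along t traces the
#' fragment-length survival function.
#'
#' @slot count integer vector indexed by t = 1..lExt (only t >= tMin is
#'   populated).
#' @slot tMin smallest admissible t (closer CpGs are discarded to avoid
#'   edge effects).
#' @slot lExt segment extension length (bp).
#' @slot nReads number of input alignments.
#' @slot excluded named integer: alignments discarded by reason
#'   (offChromosome, noCpG, multiCpG, belowTMin).
#' @seealso [singleCpGProfile()], [fitFragLen()]
#' @export
setClass("SingleCpGProfile",
    representation(count = "integer", tMin = "integer", lExt = "integer",
                   nReads = "integer", excluded = "integer"))

setValidity("SingleCpGProfile", function(object) {
    if (any(object@count < 0)) return("counts must be >= 0")
    if (length(object@count) != object@lExt)
        return("count must have one bin per segment position")
    if (sum(object@count) + sum(object@excluded) != object@nReads)
        return("qualifying + excluded must equal the input read count")
    TRUE
})

#' Fragment-length fit result
#'
#' Least-squares fit of the single-CpG efficiency-ratio profile to
#' \eqn{R_0 + (R_1 - R_0) P(l \ge t + 1)}, where P is the survival of a
#' truncated discrete Gaussian fragment-length distribution.  R0 and R1 are
#' the pulldown efficiencies of 0- and 1-CpG fragments within the profiled
#' pool.
#'
#' @slot R0,R1 efficiency ratios for 0- and 1-CpG fragments.
#' @slot L,S fitted mean and SD of the fragment length (bp).
#' @slot residualNorm square root of the residual sum of squares.
#' @slot converged whether the optimizer reported convergence.
#' @slot identifiable FALSE when the profile is flat and (L, S) carry no
#'   information.
#' @slot model "survival" or "printed-erf".
#' @seealso [fitFragLen()]
#' @export
setClass("FragLenFit",
    representation(R0 = "numeric", R1 = "numeric", L = "numeric",
                   S = "numeric", residualNorm = "numeric",
                   converged = "logical", identifiable = "logical",
                   model = "character"))

setValidity("FragLenFit", function(object) {
    if (isTRUE(object@converged) && !is.finite(object@residualNorm))
        return("a converged fit must have a finite residual norm")
    if (object@identifiable && !is.na(object@S) && object@S <= 0)
        return("S must be > 0")
    TRUE
})

#' ROC curve
#'
#' Operating points obtained by sweeping a descending cutoff over the
#' distinct prediction scores (ties grouped into one step), with the
#' trapezoidal area under the curve.
#'
#' @slot fpr,tpr coordinates from (0, 0) to (1, 1), non-decreasing.
#' @slot cutoffs score threshold attached to each point (Inf for (0, 0)):
#'   windows with score >= cutoff are called methylated.
#' @slot auc trapezoidal area under the curve.
#' @seealso [rocAuc()], [youdenPoint()]
#' @export
setClass("ROCCurve",
    representation(fpr = "numeric", tpr = "numeric", cutoffs = "numeric",
                   auc = "numeric"))

setValidity("ROCCurve", function(object) {
    n <- length(object@fpr)
    if (length(object@tpr) != n || length(object@cutoffs) != n)
        return("fpr, tpr and cutoffs must have equal length")
    if (any(diff(object@fpr) < -1e-12) || any(diff(object@tpr) < -1e-12))
        return("curve points must be monotone non-decreasing")
    if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
    TRUE
})
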