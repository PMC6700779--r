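#' Construct a fragment-length distribution
#'
#' @param kind "gaussian" (Normal density at integer lengths, renormalized
#'   over the truncation range) or "delta" (all mass at \code{round(L)}).
#' @param L mean fragment length (bp).  Default 100.7, the fit obtained for
#'   a MethylMiner MBD2 pulldown library.
#' @param S standard deviation (bp); ignored for "delta".
#' @param lmin,lmax truncation range (bp).
#' @return a \linkS4class{FragLenDist}.
#' @examples
#' d <- fragLenDist()
#' sum(fragPmf(d))        # 1
#' fragSurvival(d, 3L)    # 1 at lmin
#' @export
fragLenDist <- function(kind = c("gaussian", "delta"), L = 100.7, S = 12.98,
                        lmin = 3L, lmax = 200L) {
    kind <- match.arg(kind)
    lmin <- as.integer(lmin); lmax <- as.integer(lmax)
    ls <- lmin:lmax
    if (kind == "gaussian") {
        if (!is.finite(S) || S <= 0) stop("gaussian kind requires S > 0")
        w <- dnorm(ls, mean = L, sd = S)
        if (sum(w) <= 0)
            stop("no probability mass on [lmin, lmax]; check L and S")
        pmf <- w / sum(w)
    } else {
        S <- 0
        pmf <- as.numeric(ls == round(L))
    }
    new("FragLenDist", kind = kind, L = L, S = S, lmin = lmin, lmax = lmax,
        pmf = pmf)
}

setMethod("show", "FragLenDist", function(object) {
    if (object@kind == "gaussian")
        cat(sprintf("FragLenDist: truncated discrete Gaussian L=%g S=%g on [%d, %d]\n",
                    object@L, object@S, object@lmin, object@lmax))
    else
        cat(sprintf("FragLenDist: delta at %d bp on [%d, %d]\n",
                    as.integer(round(object@L)), object@lmin, object@lmax))
})

#' Fragment-length probability mass
#'
#' P(l) for integer lengths; 0 outside \code{[lmin, lmax]}.  With
#' \code{lengths = NULL} the full mass vector over lmin:lmax is returned
#' (named by length).
#'
#' @param dist a \linkS4class{FragLenDist}.
#' @param lengths integer lengths, or NULL for the full vector.
#' @return numeric probabilities.
#' @export
fragPmf <- function(dist, lengths = NULL) {
    stopifnot(is(dist, "FragLenDist"))
    if (is.null(lengths))
        return(stats::setNames(dist@pmf, dist@lmin:dist@lmax))
    out <- numeric(length(lengths))
    ok <- lengths >= dist@lmin & lengths <= dist@lmax & lengths == round(lengths)
    out[ok] <- dist@pmf[lengths[ok] - dist@lmin + 1L]
    out
}

#' Fragment-length survival function
#'
#' P(l >= t), the exact tail sum of the probability mass: 1 at or below
#' lmin, 0 above lmax, non-increasing in t.
#'
#' @param dist a \linkS4class{FragLenDist}.
#' @param t integer length threshold(s).
#' @return numeric probabilities.
#' @export
fragSurvival <- function(dist, t) {
    stopifnot(is(dist, "FragLenDist"))
    tail <- rev(cumsum(rev(dist@pmf)))      # tail[k] = P(l >= lmin + k - 1)
    out <- numeric(length(t))
    out[t <= dist@lmin] <- 1
    mid <- t > dist@lmin & t <= dist@lmax
    out[mid] <- tail[t[mid] - dist@lmin + 1L]
    out
}

#' Positional profile of single-CpG segments
#'
#' Replaces every alignment by the \code{lExt}-long genomic segment starting
#' at its 5' end and extending in read orientation (minus-strand reads
#' extend leftward from their rightmost base).  Segments running off the
#' chromosome are discarded.  A segment qualifies if it contains exactly one
#' CpG -- both C and G inside the segment -- whose position t (1-based from
#' the segment 5' end, on the read strand) is at least \code{tMin}.
#' Qualifying segments are counted by t.
#'
#' @param aln a \linkS4class{GRanges} of stranded alignments.
#' @param index a \linkS4class{CpGIndex} of the same genome.
#' @param lExt segment extension length (bp); chosen larger than any
#'   plausible fragment (default 250).
#' @param tMin smallest admissible CpG position (default 11; closer CpGs
#'   are discarded to avoid alignment edge effects).
#' @return a \linkS4class{SingleCpGProfile}.
#' @export
singleCpGProfile <- function(aln, index, lExt = 250L, tMin = 11L) {
    stopifnot(is(aln, "GRanges"), is(index, "CpGIndex"))
    lExt <- as.integer(lExt); tMin <- as.integer(tMin)
    if (!(lExt >= tMin && tMin >= 1L))
        stop("need lExt >= tMin >= 1")
    count <- integer(lExt)
    excl <- c(offChromosome = 0L, noCpG = 0L, multiCpG = 0L, belowTMin = 0L)
    for (chr in unique(as.character(seqnames(aln)))) {
        if (!chr %in% seqlevels(index))
            stop("alignments on unindexed chromosome: ", chr)
        len <- seqlengths(index)[[chr]]
        cpg <- cpgPositions(index, chr)
        sub <- aln[as.character(seqnames(aln)) == chr]
        plus <- as.character(strand(sub)) == "+"
        s5 <- ifelse(plus, start(sub), end(sub))
        off <- ifelse(plus, s5 + lExt - 1L > len, s5 - lExt + 1L < 1L)
        excl["offChromosome"] <- excl["offChromosome"] + sum(off)
        s5 <- s5[!off]; plus <- plus[!off]
        if (!length(s5)) next
        # CpGs with C and G inside the segment, position measured 5'->3'
        hi <- ifelse(plus, findInterval(s5 + lExt - 2L, cpg),
                           findInterval(s5 - 1L, cpg))
        lo <- ifelse(plus, findInterval(s5 - 1L, cpg),
                           findInterval(s5 - lExt, cpg))
        k <- hi - lo
        excl["noCpG"] <- excl["noCpG"] + sum(k == 0L)
        excl["multiCpG"] <- excl["multiCpG"] + sum(k > 1L)
        one <- k == 1L
        tpos <- integer(sum(one))
        cpos <- cpg[hi[one]]
        tpos <- ifelse(plus[one], cpos - s5[one] + 1L, s5[one] - cpos)
        near <- tpos < tMin
        excl["belowTMin"] <- excl["belowTMin"] + sum(near)
        tpos <- tpos[!near]
        if (length(tpos))
            count <- count + tabulate(tpos, nbins = lExt)
    }
    new("SingleCpGProfile", count = count, tMin = tMin, lExt = lExt,
        nReads = length(aln), excluded = excl)
}

#' @describeIn singleCpGProfile fraction of qualifying segments per t.
#' @param profile a \linkS4class{SingleCpGProfile}.
#' @export
profileFraction <- function(profile) {
    stopifnot(is(profile, "SingleCpGProfile"))
    tot <- sum(profile@count)
    f <- if (tot > 0) profile@count / tot else rep(NA_real_, profile@lExt)
    stats::setNames(f, seq_len(profile@lExt))
}

setMethod("show", "SingleCpGProfile", function(object) {
    cat(sprintf("SingleCpGProfile: %d qualifying segments (of %d reads), t in [%d, %d]\n",
                sum(object@count), object@nReads, object@tMin, object@lExt))
    cat("  excluded:", paste(names(object@excluded), object@excluded,
                             sep = "=", collapse = ", "), "\n")
})

#' Per-position pulldown/input efficiency ratio
#'
#' Ratio of the pulldown and input single-CpG profile fractions at each
#' admissible t.  Positions where the input fraction is zero are flagged
#' undefined and excluded from fitting.
#'
#' @param pulldown,input \linkS4class{SingleCpGProfile}s built with the same
#'   \code{lExt} and \code{tMin}.
#' @return a data.frame with columns t, countPulldown, countInput,
#'   fracPulldown, fracInput, ratio, defined.
#' @export
efficiencyRatioProfile <- function(pulldown, input) {
    stopifnot(is(pulldown, "SingleCpGProfile"), is(input, "SingleCpGProfile"))
    if (pulldown@lExt != input@lExt || pulldown@tMin != input@tMin)
        stop("profiles were built with different lExt/tMin")
    if (sum(pulldown@count) == 0 && sum(input@count) == 0)
        stop("both profiles are empty")
    tt <- pulldown@tMin:pulldown@lExt
    fp <- profileFraction(pulldown)[tt]
    fq <- profileFraction(input)[tt]
    defined <- !is.na(fq) & fq > 0
    ratio <- ifelse(defined, fp / fq, NA_real_)
    data.frame(t = tt, countPulldown = pulldown@count[tt],
               countInput = input@count[tt], fracPulldown = fp,
               fracInput = fq, ratio = ratio, defined = defined,
               row.names = NULL)
}

#' Fit the fragment-length distribution to an efficiency-ratio profile
#'
#' Least-squares fit of \eqn{R_0 + (R_1 - R_0) P(l \ge t + 1)} to the
#' single-CpG efficiency ratio, where P is the survival function of a
#' truncated discrete Gaussian on \code{[lmin, lmax]} with mean L and SD S.
#' \code{model = "printed-erf"} instead uses the error-function expression
#' \eqn{Erf((t + 1 - L)/(S\sqrt 2)) - Erf((1 - L)/(S\sqrt 2))} in place of
#' the survival term, for comparison only: that expression increases with t
#' and is not a survival function, so the default fits the true tail sum.
#'
#' @param ratio a data.frame from [efficiencyRatioProfile()] (columns t,
#'   ratio, defined), or a numeric ratio vector accompanied by \code{t}.
#' @param t positions when \code{ratio} is a bare vector.
#' @param init initial guess, named (R0, R1, L, S).
#' @param lmin,lmax truncation range of the fitted distribution; lmax
#'   defaults to the profile extension length.
#' @param model "survival" (default) or "printed-erf".
#' @return a \linkS4class{FragLenFit}.
#' @export
fitFragLen <- function(ratio, t = NULL,
                       init = c(R0 = 1.0, R1 = 1.0, L = 200, S = 50),
                       lmin = 3L, lmax = 250L,
                       model = c("survival", "printed-erf")) {
    model <- match.arg(model)
    if (is.data.frame(ratio)) {
        keep <- ratio$defined & is.finite(ratio$ratio)
        t <- ratio$t[keep]
        y <- ratio$ratio[keep]
    } else {
        if (is.null(t)) stop("t must accompany a bare ratio vector")
        keep <- is.finite(ratio)
        y <- ratio[keep]; t <- t[keep]
    }
    if (length(y) < 8L)
        stop("need at least 8 defined ratio points, got ", length(y))
    if (diff(range(y)) < 1e-12) {
        return(new("FragLenFit", R0 = mean(y), R1 = mean(y), L = NA_real_,
                   S = NA_real_, residualNorm = 0, converged = FALSE,
                   identifiable = FALSE, model = model))
    }
    ls <- as.integer(lmin):as.integer(lmax)
    survFun <- if (model == "survival") {
        function(t, L, S) {
            w <- dnorm(ls, L, S)
            sw <- sum(w)
            if (!is.finite(sw) || sw <= 0) return(rep(NaN, length(t)))
            tail <- rev(cumsum(rev(w / sw)))
            i <- pmin(pmax(t + 1L - ls[1L] + 1L, 1L), length(ls))
            out <- tail[i]
            out[t + 1L <= ls[1L]] <- 1
            out[t + 1L > ls[length(ls)]] <- 0
            out
        }
    } else {
        erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
        function(t, L, S) erf((t + 1 - L) / (S * sqrt(2))) -
                          erf((1 - L) / (S * sqrt(2)))
    }
    dat <- data.frame(t = t, y = y)
    fit <- tryCatch(
        nlsLM(y ~ R0 + (R1 - R0) * survFun(t, L, S), data = dat,
              start = as.list(init),
              lower = c(R0 = 0, R1 = 0, L = lmin, S = 0.5),
              upper = c(R0 = Inf, R1 = Inf, L = lmax, S = Inf),
              control = nls.lm.control(maxiter = 200)),
        error = function(e) e)
    if (inherits(fit, "error")) {
        warning("fragment-length fit failed to converge: ",
                conditionMessage(fit))
        return(new("FragLenFit", R0 = NA_real_, R1 = NA_real_, L = NA_real_,
                   S = NA_real_, residualNorm = Inf, converged = FALSE,
                   identifiable = TRUE, model = model))
    }
    cf <- coef(fit)
    conv <- isTRUE(fit$convInfo$isConv)
    if (!conv)
        warning("optimizer did not report convergence; inspect the fit")
    new("FragLenFit", R0 = unname(cf["R0"]), R1 = unname(cf["R1"]),
        L = unname(cf["L"]), S = unname(cf["S"]),
        residualNorm = sqrt(sum(resid(fit)^2)), converged = conv,
        identifiable = TRUE, model = model)
}

setMethod("show", "FragLenFit", function(object) {
    cat(sprintf("FragLenFit (%s): R0=%.4g R1=%.4g L=%.4g S=%.4g\n",
                object@model, object@R0, object@R1, object@L, object@S))
    cat(sprintf("  residual norm %.4g; converged: %s%s\n",
                object@residualNorm, object@converged,
                if (!object@identifiable) "; (L, S) unidentifiable" else ""))
})

#' @describeIn fitFragLen serialize a fit as JSON.
#' @param fit a \linkS4class{FragLenFit}.
#' @param path output path.
#' @export
writeFragLenFit <- function(fit, path) {
    stopifnot(is(fit, "FragLenFit"))
    write_json(list(R0 = fit@R0, R1 = fit@R1, L = fit@L, S = fit@S,
                    residual_norm = fit@residualNorm,
                    converged = fit@converged,
                    identifiable = fit@identifiable, model = fit@model),
               path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @describeIn efficiencyRatioProfile write a ratio profile as TSV.
#' @param x the data.frame returned by efficiencyRatioProfile.
#' @param path output path.
#' @export
writeRatioProfile <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
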