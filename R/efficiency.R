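#' Published enrichment coefficients
#'
#' The default enrichment coefficient table for a MethylMiner MBD2 pulldown:
#' C(n) for n = 0..7 accessible methylated CpGs, with subsample
#' (by-chromosome) standard deviations as a fraction of each value.
#' C(7) is retained at 259.7 despite its large subsample SD (81%): fragments
#' with 7+ well-separated CpGs are rare, but their efficiency is measurably
#' above C(6).
#'
#' @return a \linkS4class{CnTable}.
#' @examples
#' cnLookup(defaultCnTable(), c(0, 1, 12))  # 1, 1.489, 259.7
#' @export
defaultCnTable <- function() {
    new("CnTable",
        coefs = c(1, 1.489, 5.468, 32.31, 124.7, 207.3, 233.2, 259.7),
        sss = c(NA, 0.017, 0.023, 0.022, 0.033, 0.048, 0.19, 0.81),
        cap = 7L)
}

#' Construct an enrichment coefficient table
#'
#' @param C coefficients for n = 0..cap; C[1] must be exactly 1.
#' @param sss optional subsample SDs as a fraction of each C(n).
#' @param cap the lookup cap (counts above it reuse C(cap)).
#' @return a \linkS4class{CnTable}.
#' @export
cnTable <- function(C, sss = rep(NA_real_, length(C)),
                    cap = length(C) - 1L) {
    new("CnTable", coefs = as.numeric(C), sss = as.numeric(sss),
        cap = as.integer(cap))
}

#' @describeIn cnTable coefficient lookup with the cap rule: n > cap
#'   returns C(cap).
#' @param x a \linkS4class{CnTable}.
#' @param n accessible-CpG counts (vectorized).
#' @export
cnLookup <- function(x, n) {
    stopifnot(is(x, "CnTable"))
    if (any(n < 0)) stop("n must be >= 0")
    x@coefs[pmin(n, x@cap) + 1L]
}

setMethod("show", "CnTable", function(object) {
    cat("CnTable (cap", object@cap, ")\n")
    m <- rbind(C = signif(object@coefs, 4),
               `s_ss%` = round(100 * object@sss, 1))
    colnames(m) <- paste0("n=", 0:object@cap)
    print(m)
})

#' Classify fragments by accessible-CpG count
#'
#' Extends every alignment to \code{fragmentLength} bp from its 5' end in
#' read orientation (single-end reads do not reveal the true fragment
#' length, so each is approximated by one fixed length), counts the
#' accessible CpGs on the extended interval (both C and G inside, greedy
#' minimum-separation rule), caps the count, and tabulates fragments by
#' group.  Fragments extending past a chromosome end are discarded and
#' their number reported.
#'
#' @param aln a \linkS4class{GRanges} of stranded alignments.
#' @param index a \linkS4class{CpGIndex}.
#' @param fragmentLength assumed fragment length (bp).
#' @param minSep minimum separation (bp) for simultaneous binding.
#' @param cap pooling cap for the count bins.
#' @param groups factor of subsample groups, one per alignment; defaults to
#'   the chromosome of each alignment.
#' @return an \linkS4class{NCpGCountTable}.
#' @export
classifyFragmentsByNCpG <- function(aln, index, fragmentLength,
                                    minSep = 3L, cap = 7L, groups = NULL) {
    stopifnot(is(aln, "GRanges"), is(index, "CpGIndex"))
    fragmentLength <- as.integer(fragmentLength)
    if (fragmentLength < 1L) stop("fragmentLength must be >= 1")
    if (is.null(groups))
        groups <- as.character(seqnames(aln))
    groups <- as.factor(groups)
    plus <- as.character(strand(aln)) == "+"
    s <- ifelse(plus, start(aln), end(aln) - fragmentLength + 1L)
    e <- s + fragmentLength - 1L
    len <- seqlengths(index)[as.character(seqnames(aln))]
    keep <- s >= 1L & e <= len
    if (any(!keep))
        message(sum(!keep), " fragment(s) extending past a chromosome end ",
                "discarded")
    n <- integer(sum(keep))
    chromv <- as.character(seqnames(aln))[keep]
    sk <- s[keep]; ek <- e[keep]
    for (chr in unique(chromv)) {
        i <- chromv == chr
        n[i] <- cpp_fragment_ncpg(sk[i], ek[i], cpgPositions(index, chr),
                                  as.integer(minSep))
    }
    ncap <- factor(pmin(n, cap), levels = 0:cap)
    counts <- table(droplevels(groups[keep]), ncap)
    m <- matrix(as.integer(counts), nrow = nrow(counts), ncol = cap + 1L,
                dimnames = list(rownames(counts), as.character(0:cap)))
    lab <- metadata(aln)$library
    new("NCpGCountTable", counts = m, cap = as.integer(cap),
        library = if (is.null(lab)) NA_character_ else lab)
}

setMethod("show", "NCpGCountTable", function(object) {
    cat(sprintf("NCpGCountTable: %d fragments, %d group(s), library '%s'\n",
                sum(object@counts), nrow(object@counts), object@library))
    print(colSums(object@counts))
})

#' @describeIn classifyFragmentsByNCpG the counts matrix (groups x n).
#' @param x an \linkS4class{NCpGCountTable}.
#' @export
ncpgCounts <- function(x) {
    stopifnot(is(x, "NCpGCountTable"))
    x@counts
}

#' @describeIn classifyFragmentsByNCpG write counts as a long TSV
#'   (group, n, count, library).
#' @param path output path.
#' @export
writeNCpGCounts <- function(x, path) {
    stopifnot(is(x, "NCpGCountTable"))
    df <- data.frame(group = rep(rownames(x@counts), ncol(x@counts)),
                     n = rep(0:x@cap, each = nrow(x@counts)),
                     count = as.vector(x@counts), library = x@library)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.poolCounts <- function(x) colSums(x@counts)

#' Enrichment coefficients from paired count tables
#'
#' Pools groups, computes the pulldown efficiency E(n) as the ratio of the
#' pulldown and input fractions of fragments with n accessible CpGs, and
#' scales to C(n) = E(n)/E(0).  Bins with zero pooled input count yield an
#' undefined coefficient (NA) and are reported.
#'
#' @param pulldown,input \linkS4class{NCpGCountTable}s with equal caps
#'   (pulldown = SssI-treated, captured library; input = SssI-treated,
#'   sequenced without capture).
#' @return a \linkS4class{CnTable} (sss slot unset; see [subsampleSd()]).
#' @export
cnFromCounts <- function(pulldown, input) {
    stopifnot(is(pulldown, "NCpGCountTable"), is(input, "NCpGCountTable"))
    if (pulldown@cap != input@cap)
        stop("count tables have different caps")
    cp <- .poolCounts(pulldown); ci <- .poolCounts(input)
    if (sum(cp) == 0 || sum(ci) == 0)
        stop("a count table is empty")
    if (cp[1L] == 0 || ci[1L] == 0)
        stop("the n = 0 bin is empty after pooling; C(n) is undefined")
    fp <- cp / sum(cp); fi <- ci / sum(ci)
    E <- ifelse(fi > 0, fp / fi, NA_real_)
    if (anyNA(E))
        message("undefined C(n) for n = ",
                paste(which(is.na(E)) - 1L, collapse = ", "),
                " (zero input count)")
    C <- E / E[1L]
    C[1L] <- 1
    cnTable(C, cap = pulldown@cap)
}

#' Subsample standard deviation of enrichment coefficients
#'
#' Computes C_n separately on each subsample group (typically each
#' chromosome), averages them to C_n*, and reports the fluctuation
#' \eqn{\sqrt{mean_g (C_n(g) - C_n^*)^2}} as a fraction of the pooled
#' headline C(n).  Groups where C_n(g) is undefined for a given n are
#' excluded from that n's statistic and counted.
#'
#' @param pulldown,input \linkS4class{NCpGCountTable}s sharing group names.
#' @return a list: \code{sss} (fraction of pooled C(n)), \code{sd}
#'   (absolute), \code{cstar} (group-averaged coefficients),
#'   \code{perGroup} (matrix of per-group C_n), \code{nGroups} (usable
#'   groups per n), \code{pooled} (the pooled \linkS4class{CnTable}).
#' @export
subsampleSd <- function(pulldown, input) {
    stopifnot(is(pulldown, "NCpGCountTable"), is(input, "NCpGCountTable"))
    grp <- intersect(rownames(pulldown@counts), rownames(input@counts))
    if (length(grp) < 2L)
        stop("need at least 2 shared subsample groups, got ", length(grp))
    cap <- pulldown@cap
    perGroup <- matrix(NA_real_, length(grp), cap + 1L,
                       dimnames = list(grp, as.character(0:cap)))
    for (g in grp) {
        cp <- pulldown@counts[g, ]; ci <- input@counts[g, ]
        if (sum(cp) == 0 || sum(ci) == 0 || cp[1L] == 0 || ci[1L] == 0)
            next
        fp <- cp / sum(cp); fi <- ci / sum(ci)
        E <- ifelse(fi > 0 & fp >= 0, fp / fi, NA_real_)
        perGroup[g, ] <- E / E[1L]
    }
    pooled <- cnFromCounts(pulldown, input)
    cstar <- colMeans(perGroup, na.rm = TRUE)
    nGroups <- colSums(!is.na(perGroup))
    sdv <- sqrt(colMeans(sweep(perGroup, 2L, cstar)^2, na.rm = TRUE))
    sdv[nGroups < 2L] <- NA_real_
    sss <- sdv / pooled@coefs
    list(sss = sss, sd = sdv, cstar = cstar, perGroup = perGroup,
         nGroups = nGroups, pooled = pooled)
}

#' One-call enrichment coefficient estimate
#'
#' Convenience wrapper: pooled coefficients from [cnFromCounts()] with the
#' subsample SDs of [subsampleSd()] filled in (when at least two groups are
#' available).
#'
#' @inheritParams subsampleSd
#' @return a \linkS4class{CnTable}.
#' @export
estimateCnTable <- function(pulldown, input) {
    pooled <- cnFromCounts(pulldown, input)
    nshared <- length(intersect(rownames(pulldown@counts),
                                rownames(input@counts)))
    if (nshared >= 2L)
        pooled@sss <- unname(subsampleSd(pulldown, input)$sss)
    pooled
}

#' @describeIn cnFromCounts serialize a coefficient table as JSON with a
#'   provenance block.
#' @param x a \linkS4class{CnTable}.
#' @param path output path.
#' @param provenance named list recorded alongside the values.
#' @export
writeCnTable <- function(x, path, provenance = list()) {
    stopifnot(is(x, "CnTable"))
    write_json(list(C = x@coefs, s_ss = x@sss, cap = x@cap,
                    provenance = provenance),
               path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
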