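# Independent oracles used across the suite.  These deliberately avoid the
# package's C++ paths: plain R loops and exhaustive enumeration only.

# maximum subset of sorted positions such that every consecutive selected
# pair satisfies (c_i + 1) + minSep < c_j, by exhaustive search (k <= ~15)
oracleMaxSubset <- function(pos, minSep = 3L) {
    k <- length(pos)
    if (k == 0L) return(0L)
    best <- 0L
    for (mask in 0:(2^k - 1L)) {
        sel <- pos[bitwAnd(bitwShiftR(mask, 0:(k - 1L)), 1L) == 1L]
        if (length(sel) <= best) next
        if (length(sel) < 2L || all((sel[-length(sel)] + 1L) + minSep <
                                    sel[-1L]))
            best <- length(sel)
    }
    best
}

# plain-R greedy accessible count (independent of the C++ implementation)
rGreedy <- function(pos, minSep = 3L) {
    n <- 0L; last <- -Inf
    for (p in pos) {
        if (n == 0L || (last + 1L) + minSep < p) {
            n <- n + 1L
            last <- p
        }
    }
    n
}

# brute-force expected pulldown at position x: direct enumeration over
# (length, strand) with R greedy counts.  cpg: sorted 1-based C positions;
# cn: numeric coefficients C(0..cap); pmf indexed lmin..lmax.
oracleLambdaAt <- function(x, cpg, chromLen, lmin, lmax, pmf, cn,
                           minSep = 3L, prefactor = 1, clipEdges = TRUE) {
    cap <- length(cn) - 1L
    tot <- 0
    for (l in lmin:lmax) {
        wF <- pmf[l - lmin + 1L]
        wR <- wF
        if (!clipEdges) {
            if (x + l - 1L > chromLen) wF <- 0
            if (x - l + 1L < 1L) wR <- 0
        }
        nF <- rGreedy(cpg[cpg >= x & cpg <= x + l - 2L], minSep)
        nR <- rGreedy(cpg[cpg >= x - l + 1L & cpg <= x - 1L], minSep)
        tot <- tot + wF * cn[min(nF, cap) + 1L] + wR * cn[min(nR, cap) + 1L]
    }
    prefactor * tot
}

# AUC as the normalized Mann-Whitney U statistic with half credit for ties
oracleAUC <- function(score, positive) {
    sp <- score[positive]
    sn <- score[!positive]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# random DNA string (no structure guarantees)
randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# convenience: CpGIndex straight from named character sequences
indexFromSeq <- function(...) {
    indexCpGs(Biostrings::DNAStringSet(c(...)))
}

# width-1 GRanges of per-CpG counts (m, r must be set via mcols: the name
# "r" would partially match GRanges()'s "ranges" argument)
methGR <- function(chrom, pos, m, r) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    S4Vectors::mcols(gr)$m <- as.integer(m)
    S4Vectors::mcols(gr)$r <- as.integer(r)
    gr
}
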