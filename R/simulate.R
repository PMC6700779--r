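#' Random genome with planted CpGs
#'
#' Generates an i.i.d. background sequence, scrubs accidental CG
#' dinucleotides, and plants CG dinucleotides at positions drawn with
#' geometric inter-CpG gaps (minimum 2 bp so planted sites never overlap),
#' giving the requested expected CpG rate.  All CpGs in the result are
#' planted, so their positions follow a known point process.
#'
#' @param length genome length in bp (>= 2).
#' @param cpgRate expected CpGs per bp, in (0, 0.5]; 0 gives a CpG-free
#'   genome.
#' @param seed RNG seed (mandatory; the function calls \code{set.seed}).
#' @param chromName name of the single simulated chromosome.
#' @return a list with \code{genome} (\linkS4class{DNAStringSet}) and
#'   \code{index} (\linkS4class{CpGIndex}).
#' @export
randomGenome <- function(length, cpgRate, seed, chromName = "sim1") {
    if (length < 2L) stop("length must be >= 2")
    if (cpgRate < 0 || cpgRate > 0.5)
        stop("infeasible cpgRate ", cpgRate, "; must be in [0, 0.5]")
    set.seed(seed)
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    hit <- which(b[-length] == "C" & b[-1L] == "G")
    if (base::length(hit))
        b[hit + 1L] <- "A"       # removes the CG; cannot create a new one
    if (cpgRate > 0) {
        p <- cpgRate / (1 - cpgRate)     # gap = 2 + Geom(p), mean 1/rate
        nMax <- ceiling(length * cpgRate * 1.3) + 30L
        gaps <- 2L + rgeom(nMax, p)
        pos <- cumsum(gaps)
        pos <- pos[pos <= length - 1L]
        b[pos] <- "C"
        b[pos + 1L] <- "G"
    }
    genome <- DNAStringSet(stats::setNames(paste(b, collapse = ""),
                                           chromName))
    list(genome = genome, index = indexCpGs(genome))
}

#' Methylomes over a CpG index
#'
#' A methylome assigns a methylation level in [0, 1] to every indexed CpG,
#' as a named list of numeric vectors aligned with [cpgPositions()].
#' \code{sssiMethylome} emulates SssI treatment (every CpG fully
#' methylated); \code{blockMethylome} draws one level per genomic block,
#' giving a bimodal, regionally coherent methylome.
#'
#' @param index a \linkS4class{CpGIndex}.
#' @return a named list of per-CpG methylation levels.
#' @export
sssiMethylome <- function(index) {
    stopifnot(is(index, "CpGIndex"))
    lapply(cpgPositions(index), function(p) rep(1, length(p)))
}

#' @describeIn sssiMethylome block-constant bimodal methylome.
#' @param blockSize block width in bp.
#' @param levels the per-block levels to draw from.
#' @param seed RNG seed (the function calls \code{set.seed}).
#' @export
blockMethylome <- function(index, blockSize = 1000L, levels = c(0.05, 0.95),
                           seed) {
    stopifnot(is(index, "CpGIndex"))
    set.seed(seed)
    out <- list()
    for (chr in seqlevels(index)) {
        pos <- cpgPositions(index, chr)
        nBlocks <- ceiling(seqlengths(index)[[chr]] / blockSize)
        lv <- sample(levels, nBlocks, replace = TRUE)
        out[[chr]] <- lv[(pos - 1L) %/% as.integer(blockSize) + 1L]
    }
    out
}

# draw candidate fragments: chrom by length, l by pmf, strand fair,
# start uniform over positions where the fragment fits
.drawFragments <- function(index, n, dist) {
    sl <- seqlengths(index)
    chrom <- if (length(sl) == 1L) rep(names(sl), n)
             else sample(names(sl), n, replace = TRUE, prob = sl)
    ls <- dist@lmin:dist@lmax
    l <- if (dist@kind == "delta") rep(as.integer(round(dist@L)), n)
         else sample(ls, n, replace = TRUE, prob = dist@pmf)
    maxStart <- sl[chrom] - l + 1L
    ok <- maxStart >= 1L
    start <- integer(n)
    start[ok] <- 1L + floor(runif(sum(ok)) * maxStart[ok])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    list(chrom = chrom, start = as.integer(start),
         end = as.integer(start + l - 1L), strand = strand, ok = ok)
}

.fragmentsToGRanges <- function(f, keep, label) {
    gr <- GRanges(f$chrom[keep], IRanges(f$start[keep], f$end[keep]),
                  strand = f$strand[keep])
    metadata(gr)$library <- label
    gr
}

#' Simulate input-control reads
#'
#' Fragments drawn uniformly over the genome (5' ends uniform, strand fair,
#' lengths from the fragment-length distribution) and emitted as alignment
#' intervals: the sequencing of SssI-treated DNA without any capture step.
#'
#' @param index a \linkS4class{CpGIndex} (provides chromosome lengths).
#' @param n number of fragments.
#' @param dist a \linkS4class{FragLenDist}.
#' @param seed RNG seed (the function calls \code{set.seed}).
#' @param label library label.
#' @return a \linkS4class{GRanges} of stranded fragment intervals.
#' @export
simulateInputReads <- function(index, n, dist = fragLenDist(), seed,
                               label = "input-control") {
    stopifnot(is(index, "CpGIndex"), is(dist, "FragLenDist"))
    set.seed(seed)
    if (n == 0L) {
        gr <- GRanges()
        metadata(gr)$library <- label
        return(gr)
    }
    f <- .drawFragments(index, n, dist)
    .fragmentsToGRanges(f, f$ok, label)
}

#' Simulate pulldown reads under the enrichment model
#'
#' Candidate fragments are drawn as in [simulateInputReads()]; each CpG on
#' a candidate is methylated with its methylome probability; the fragment's
#' accessible count n of methylated CpGs is computed under the
#' steric-exclusion rule; and the fragment is retained with probability
#' C(min(n, cap))/C(cap) -- rejection sampling normalized by the cap
#' coefficient so acceptance probabilities stay at or below 1.  Candidates
#' are drawn until \code{n} fragments are retained.
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param methylome per-CpG methylation levels (see [sssiMethylome()]).
#' @param n number of retained fragments.
#' @param dist a \linkS4class{FragLenDist}.
#' @param cn a \linkS4class{CnTable}.
#' @param minSep minimum separation (bp) of the accessibility rule.
#' @param seed RNG seed (the function calls \code{set.seed}).
#' @param label library label.
#' @param maxCandidates abort threshold on the total candidates drawn.
#' @return a \linkS4class{GRanges} of retained stranded fragment intervals.
#' @export
simulatePulldownReads <- function(index, methylome, n, dist = fragLenDist(),
                                  cn = defaultCnTable(), minSep = 3L,
                                  seed, label = "pulldown",
                                  maxCandidates = 5e8) {
    stopifnot(is(index, "CpGIndex"), is(dist, "FragLenDist"),
              is(cn, "CnTable"))
    set.seed(seed)
    if (n == 0L) {
        gr <- GRanges()
        metadata(gr)$library <- label
        return(gr)
    }
    chroms <- seqlevels(index)
    if (!all(chroms %in% names(methylome)))
        stop("methylome does not cover all indexed chromosomes")
    kept <- vector("list", 64L)
    nKept <- 0L; batches <- 0L; drawn <- 0
    accEst <- 0.05
    while (nKept < n) {
        batchN <- min(max(ceiling((n - nKept) / accEst * 1.2), 1e4), 4e6)
        drawn <- drawn + batchN
        if (drawn > maxCandidates)
            stop("candidate budget exhausted; acceptance rate ~",
                 signif(accEst, 2))
        f <- .drawFragments(index, batchN, dist)
        acc <- logical(batchN)
        for (chr in chroms) {
            i <- f$ok & f$chrom == chr
            if (!any(i)) next
            acc[i] <- cpp_pulldown_accept(f$start[i], f$end[i],
                                          cpgPositions(index, chr),
                                          methylome[[chr]], cn@coefs,
                                          as.integer(minSep))
        }
        acc <- acc & f$ok
        accEst <- max(sum(acc) / batchN, 1e-4)
        batches <- batches + 1L
        gr <- .fragmentsToGRanges(f, acc, label)
        kept[[batches]] <- gr
        nKept <- nKept + length(gr)
    }
    out <- suppressWarnings(do.call(c, kept[seq_len(batches)]))
    out <- out[seq_len(n)]
    metadata(out)$library <- label
    out
}

#' Simulate per-CpG bisulfite counts
#'
#' Per CpG j, total coverage r_j ~ Poisson(coverage) and methylated count
#' m_j ~ Binomial(r_j, mu_j): the count structure of a bisulfite coverage
#' table over a known methylome.
#'
#' @param index a \linkS4class{CpGIndex}.
#' @param methylome per-CpG methylation levels.
#' @param coverage target mean coverage (>= 0).
#' @param seed RNG seed (the function calls \code{set.seed}).
#' @return a width-1 \linkS4class{GRanges} with columns \code{m}, \code{r}.
#' @export
simulateRrbsCounts <- function(index, methylome, coverage, seed) {
    stopifnot(is(index, "CpGIndex"), coverage >= 0)
    set.seed(seed)
    grs <- lapply(seqlevels(index), function(chr) {
        pos <- cpgPositions(index, chr)
        r <- rpois(length(pos), coverage)
        m <- rbinom(length(pos), r, methylome[[chr]])
        gr <- GRanges(chr, IRanges(pos, width = 1L))
        mcols(gr)$m <- m
        mcols(gr)$r <- r
        gr
    })
    out <- suppressWarnings(do.call(c, grs))
    seqlengths(out) <- seqlengths(index)[seqlevels(out)]
    out
}

#' Write a self-consistent simulation fixture bundle
#'
#' Generates a named simulation scenario and writes it to disk in standard
#' formats (FASTA genome, BED6 alignments, 4-column bisulfite count table,
#' JSON truth parameters), so the whole estimation pipeline can be
#' exercised through its file interfaces.  Scenarios:
#' \describe{
#'   \item{sssi-recovery}{1 Mb genome (CpG rate 0.01), 10^6 input and 10^6
#'     pulldown fragments of fixed length 100 bp under the published
#'     enrichment coefficients, SssI (fully methylated) methylome.  Tests
#'     recovery of C_n.  A fixed length is used so the estimator's
#'     fixed-fragment-length approximation is exact and the enrichment
#'     estimate is isolated from length-approximation error.}
#'   \item{fraglen-recovery}{1 Mb genome (CpG rate 0.004), 10^5 input and
#'     10^5 pulldown fragments with Gaussian lengths (L = 100, S = 13).
#'     Tests recovery of (L, S) from single-CpG profiles.}
#'   \item{bimodal-methylome}{200 kb genome (CpG rate 0.01), block-bimodal
#'     methylome (1 kb blocks at levels 0.05/0.95), 2 x 10^5
#'     sample-of-interest pulldown fragments, bisulfite counts at mean
#'     coverage 20.  Feeds the end-to-end evaluation smoke test.}
#' }
#' All randomness flows from \code{seed}; the same (scenario, seed) yields
#' a byte-identical bundle.
#'
#' @param scenario one of "sssi-recovery", "fraglen-recovery",
#'   "bimodal-methylome".
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the written paths plus the in-memory
#'   objects (genome, index, alignments, truth).
#' @export
makeFixtureBundle <- function(scenario, seed, dir) {
    scenario <- match.arg(scenario, c("sssi-recovery", "fraglen-recovery",
                                      "bimodal-methylome"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(dir, f)
    writeBed <- function(gr, path) {
        if (length(gr)) {
            mcols(gr)$name <- sprintf("r%d", seq_along(gr))
            mcols(gr)$score <- 0L
        }
        rtracklayer::export(gr, path, format = "BED")
    }
    out <- list(dir = dir, scenario = scenario, seed = seed)
    if (scenario == "sssi-recovery") {
        sim <- randomGenome(1e6, 0.01, seed)
        dist <- fragLenDist("delta", L = 100)
        cn <- defaultCnTable()
        input <- simulateInputReads(sim$index, 1e6, dist, seed = seed + 1L)
        pull <- simulatePulldownReads(sim$index, sssiMethylome(sim$index),
                                      1e6, dist, cn, minSep = 3L,
                                      seed = seed + 2L)
        truth <- list(scenario = scenario, seed = seed,
                      cn = cn@coefs, cap = cn@cap, min_sep = 3,
                      fragment_length = 100, dist = "delta")
        writeBed(input, pth("input.bed"))
        writeBed(pull, pth("pulldown.bed"))
        out$alignments <- list(input = input, pulldown = pull)
    } else if (scenario == "fraglen-recovery") {
        sim <- randomGenome(1e6, 0.004, seed)
        dist <- fragLenDist("gaussian", L = 100, S = 13)
        cn <- defaultCnTable()
        input <- simulateInputReads(sim$index, 1e5, dist, seed = seed + 1L)
        pull <- simulatePulldownReads(sim$index, sssiMethylome(sim$index),
                                      1e5, dist, cn, minSep = 3L,
                                      seed = seed + 2L)
        truth <- list(scenario = scenario, seed = seed, L = 100, S = 13,
                      lmin = dist@lmin, lmax = dist@lmax, min_sep = 3)
        writeBed(input, pth("input.bed"))
        writeBed(pull, pth("pulldown.bed"))
        out$alignments <- list(input = input, pulldown = pull)
    } else {
        sim <- randomGenome(2e5, 0.01, seed)
        meth <- blockMethylome(sim$index, 1000L, c(0.05, 0.95),
                               seed = seed + 1L)
        dist <- fragLenDist()
        cn <- defaultCnTable()
        pull <- simulatePulldownReads(sim$index, meth, 2e5, dist, cn,
                                      minSep = 3L, seed = seed + 2L,
                                      label = "sample-of-interest")
        rrbs <- simulateRrbsCounts(sim$index, meth, 20, seed = seed + 3L)
        truth <- list(scenario = scenario, seed = seed, block_size = 1000,
                      levels = c(0.05, 0.95), rrbs_coverage = 20,
                      n_fragments = 2e5)
        writeBed(pull, pth("sample.bed"))
        write.table(data.frame(chrom = as.character(seqnames(rrbs)),
                               pos = start(rrbs), m = mcols(rrbs)$m,
                               r = mcols(rrbs)$r),
                    pth("rrbs.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        out$alignments <- list(sample = pull)
        out$rrbs <- rrbs
        out$methylome <- meth
    }
    writeXStringSet(sim$genome, pth("genome.fa"))
    write_json(truth, pth("truth.json"), auto_unbox = TRUE, digits = NA,
               pretty = TRUE)
    out$genome <- sim$genome
    out$index <- sim$index
    out$truth <- truth
    out$files <- list.files(dir, full.names = TRUE)
    invisible(out)
}
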