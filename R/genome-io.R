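#' Load a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into a \linkS4class{DNAStringSet}.
#' Record names are trimmed to the first whitespace-delimited word and must
#' be unique; record order is preserved.  Bases are stored in the DNA
#' alphabet (lowercase input is normalized to uppercase; IUPAC ambiguity
#' codes such as N are kept and never form part of a CG dinucleotide).
#'
#' @param path path to a FASTA file.
#' @return a named \linkS4class{DNAStringSet}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtN"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(path) {
    g <- readDNAStringSet(path)
    if (length(g) == 0L)
        stop("no sequences found in ", path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g)))
        stop("duplicate sequence names in ", path, ": ",
             paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
    g
}

#' Index CpG dinucleotides
#'
#' Scans a genome for CG dinucleotides and records the 1-based position of
#' each C.  The CpG is identified with the position of its cytosine;
#' ambiguous bases break the dinucleotide, so e.g. "CNG" contains no CpG.
#'
#' @param genome a named \linkS4class{DNAStringSet}.
#' @return a \linkS4class{CpGIndex}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "ACGCGT"))
#' cpgPositions(indexCpGs(g), "c1")  # 2, 4
#' @export
indexCpGs <- function(genome) {
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
    m <- vmatchPattern("CG", genome, fixed = TRUE)
    pos <- IntegerList(lapply(m, start))
    names(pos) <- names(genome)
    new("CpGIndex", positions = pos,
        seqlengths = stats::setNames(width(genome), names(genome)))
}

#' @describeIn indexCpGs CpG positions, for one chromosome (integer vector)
#'   or all (IntegerList).
#' @param index a \linkS4class{CpGIndex}.
#' @param chrom optional chromosome name.
#' @export
cpgPositions <- function(index, chrom = NULL) {
    stopifnot(is(index, "CpGIndex"))
    if (is.null(chrom))
        return(index@positions)
    if (!chrom %in% names(index@positions))
        stop("unknown chromosome: ", chrom)
    index@positions[[chrom]]
}

#' @export
setMethod("seqlengths", "CpGIndex", function(x) x@seqlengths)

#' @export
setMethod("seqlevels", "CpGIndex", function(x) names(x@seqlengths))

setMethod("show", "CpGIndex", function(object) {
    cat("CpGIndex on", length(object@seqlengths), "sequence(s),",
        sum(lengths(object@positions)), "CpGs\n")
    for (chr in utils::head(names(object@seqlengths), 5L))
        cat(sprintf("  %s: %d bp, %d CpGs\n", chr,
                    object@seqlengths[[chr]],
                    length(object@positions[[chr]])))
    if (length(object@seqlengths) > 5L) cat("  ...\n")
})

#' Tile a genome into fixed-width windows
#'
#' Builds the grid of non-overlapping fixed-width windows covering every
#' chromosome.  The trailing window of a chromosome may be narrower; it is
#' kept by default (it can still hold CpGs) and can be dropped with
#' \code{keepPartial = FALSE}.
#'
#' @param x a \linkS4class{DNAStringSet}, a \linkS4class{CpGIndex}, or a
#'   named integer vector of chromosome lengths.
#' @param width window width in bp (>= 1).
#' @param keepPartial keep the trailing partial window?
#' @return a \linkS4class{GRanges} with seqlengths set, in genomic order.
#' @examples
#' tileWindows(c(c1 = 250L), 100L)
#' @export
tileWindows <- function(x, width, keepPartial = TRUE) {
    if (is(x, "DNAStringSet"))
        sl <- stats::setNames(Biostrings::width(x), names(x))
    else if (is(x, "CpGIndex"))
        sl <- seqlengths(x)
    else
        sl <- x
    if (!is.numeric(width) || length(width) != 1L || width < 1)
        stop("width must be a single value >= 1")
    grid <- tileGenome(sl, tilewidth = as.integer(width),
                       cut.last.tile.in.chrom = TRUE)
    if (!keepPartial)
        grid <- grid[width(grid) == as.integer(width)]
    grid
}

#' Load a per-base mappability track
#'
#' Imports a bedGraph/wig mappability track (e.g. an ENCODE k-mer alignability
#' track).  Scores must lie in [0, 1]; bases absent from the track score 0.
#'
#' @param path path to a bedGraph or wig file.
#' @return a \linkS4class{GRanges} with a \code{score} column.
#' @export
loadMappability <- function(path) {
    gr <- rtracklayer::import(path)
    if (is.null(gr$score))
        stop("mappability track has no score column: ", path)
    if (any(gr$score < 0 | gr$score > 1))
        stop("mappability scores outside [0, 1] in ", path)
    gr
}

#' Fraction of fully mappable bases per window
#'
#' For each window, the fraction of its bases carrying a mappability score
#' of exactly 1.  Scores are rounded to 6 decimals before the equality test
#' because track files store rounded floats; bases without track data count
#' as unmappable.
#'
#' @param track a \linkS4class{GRanges} with \code{score} in [0, 1].
#' @param grid a window grid from [tileWindows()].
#' @return numeric vector in [0, 1], one value per window.
#' @export
windowMappableFraction <- function(track, grid) {
    out <- numeric(length(grid))
    ones <- track[round(track$score, 6) == 1]
    sl <- seqlengths(grid)
    for (chr in seqlevels(grid)) {
        wi <- which(as.character(seqnames(grid)) == chr)
        if (!length(wi)) next
        sub <- ones[as.character(seqnames(ones)) == chr]
        cov <- coverage(ranges(sub), width = sl[[chr]])
        v <- Views(cov, start(grid)[wi], end(grid)[wi])
        out[wi] <- viewSums(v) / width(grid)[wi]
    }
    pmin(out, 1)
}

#' Load single-end alignments
#'
#' Reads alignment intervals from BED6 (via rtracklayer) or BAM (via
#' Rsamtools; unmapped and secondary records are skipped and their count
#' reported).  Every record must carry a strand: the 5' end of the read
#' determines how fragments are reconstructed downstream.
#'
#' @param path path to a .bed or .bam file.
#' @param format "bed" or "bam"; guessed from the extension by default.
#' @param label library label stored in \code{metadata(x)$library}.
#' @return a \linkS4class{GRanges} of alignment intervals with strand.
#' @export
loadAlignments <- function(path, format = NULL,
                           label = sub("\\.[^.]*$", "", basename(path))) {
    if (is.null(format))
        format <- tolower(file_ext(path))
    gr <- switch(format,
        bed = {
            if (file.info(path)$size == 0)
                GRanges()
            else
                tryCatch(rtracklayer::import(path, format = "BED"),
                         error = function(e)
                             stop("malformed BED file ", path, ": ",
                                  conditionMessage(e), call. = FALSE))
        },
        bam = .loadBam(path),
        stop("unsupported alignment format: ", format)
    )
    bad <- which(as.character(strand(gr)) == "*")
    if (length(bad)) {
        nm <- if (!is.null(gr$name)) gr$name[bad[1L]] else
            sprintf("%s:%d-%d", seqnames(gr)[bad[1L]],
                    start(gr)[bad[1L]], end(gr)[bad[1L]])
        stop(length(bad), " record(s) without strand (first: ", nm,
             "); strand is required")
    }
    metadata(gr)$library <- label
    gr
}

.loadBam <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("reading BAM requires the Rsamtools package")
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("rname", "pos", "qwidth", "strand"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    total <- Rsamtools::countBam(path)$records
    kept <- length(b$pos)
    if (total > kept)
        message(total - kept, " unmapped/secondary record(s) skipped in ",
                basename(path))
    GRanges(b$rname, IRanges(b$pos, width = b$qwidth), strand = b$strand)
}

#' Load per-CpG bisulfite counts
#'
#' Reads a per-CpG methylation count table: either the 4-column layout
#' (chrom, 1-based position, methylated count, total count) or the 6-column
#' Bismark coverage dialect (chrom, start, end, percent, count methylated,
#' count unmethylated), for which m = methylated and r = methylated +
#' unmethylated.  When a \linkS4class{CpGIndex} is supplied, records on the
#' G strand (position = C position + 1 of an indexed CpG) are merged into
#' the C-strand record by summing counts; positions matching neither strand
#' of an indexed CpG are kept standalone with a warning.
#'
#' @param path path to the count table (TSV, no header).
#' @param index optional \linkS4class{CpGIndex} used for strand merging.
#' @return a width-1 \linkS4class{GRanges} at C positions with integer
#'   columns \code{m} (methylated reads) and \code{r} (total reads).
#' @export
loadCpGMethCounts <- function(path, index = NULL) {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(tab) == 4L) {
        df <- data.frame(chrom = as.character(tab[[1L]]), pos = tab[[2L]],
                         m = tab[[3L]], r = tab[[4L]])
    } else if (ncol(tab) == 6L) {
        df <- data.frame(chrom = as.character(tab[[1L]]), pos = tab[[2L]],
                         m = tab[[5L]], r = tab[[5L]] + tab[[6L]])
    } else {
        stop("expected 4 or 6 tab-separated columns in ", path)
    }
    bad <- which(df$m > df$r)
    if (length(bad))
        stop("methylated count exceeds total at ", df$chrom[bad[1L]], ":",
             df$pos[bad[1L]])
    if (!is.null(index)) {
        stopifnot(is(index, "CpGIndex"))
        shifted <- logical(nrow(df))
        for (chr in unique(df$chrom)) {
            if (!chr %in% seqlevels(index)) next
            cpg <- cpgPositions(index, chr)
            i <- which(df$chrom == chr)
            isC <- df$pos[i] %in% cpg
            isG <- !isC & (df$pos[i] - 1L) %in% cpg
            df$pos[i[isG]] <- df$pos[i[isG]] - 1L
            shifted[i] <- isC | isG
        }
        if (any(!shifted))
            warning(sum(!shifted),
                    " record(s) at positions not matching an indexed CpG ",
                    "were kept unmerged")
    }
    agg <- stats::aggregate(cbind(m, r) ~ chrom + pos, data = df, FUN = sum)
    agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
    gr <- GRanges(agg$chrom, IRanges(agg$pos, width = 1L))
    mcols(gr)$m <- as.integer(agg$m)
    mcols(gr)$r <- as.integer(agg$r)
    gr
}
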