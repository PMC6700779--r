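test_that("pmf honors delta and normalization contracts", {
    d <- fragLenDist("delta", L = 300, lmin = 3L, lmax = 400L)
    expect_equal(fragPmf(d, 300), 1)
    expect_equal(fragPmf(d, 299), 0)
    for (L in c(50, 100.7, 180)) {
        for (S in c(5, 12.98, 40)) {
            g <- fragLenDist("gaussian", L = L, S = S)
            expect_equal(sum(fragPmf(g)), 1, tolerance = 1e-9)
        }
    }
    g <- fragLenDist("gaussian", L = 100.7, S = 12.98)
    # truncation cancels in density ratios
    expect_equal(fragPmf(g, 101) / fragPmf(g, 150),
                 dnorm(101, 100.7, 12.98) / dnorm(150, 100.7, 12.98))
})

test_that("survival is the exact tail sum", {
    d <- fragLenDist("delta", L = 300, lmin = 3L, lmax = 400L)
    expect_equal(fragSurvival(d, 300), 1)
    expect_equal(fragSurvival(d, 301), 0)
    g <- fragLenDist("gaussian", L = 100.7, S = 12.98)
    expect_equal(fragSurvival(g, 3L), 1)
    ts <- 1:210
    brute <- vapply(ts, function(t) sum(fragPmf(g, t:200)), numeric(1))
    expect_equal(fragSurvival(g, ts), brute, tolerance = 1e-12)
    sv <- fragSurvival(g, 3:201)
    expect_true(all(diff(sv) <= 0))
    expect_equal(sv[-length(sv)] - sv[-1L], fragPmf(g, 3:200))
})

test_that("singleCpGProfile places and filters CpGs as specified", {
    # 19 A's, CG, then padding: + read at 1-based start 1 sees the C at t=20
    s <- paste0(strrep("A", 19), "CG", strrep("A", 279))
    idx <- indexFromSeq(c1 = s)
    plus <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 36), strand = "+")
    p <- singleCpGProfile(plus, idx, lExt = 250L, tMin = 11L)
    expect_identical(p@count[20L], 1L)
    expect_identical(sum(p@count), 1L)
    # a second CpG inside the segment excludes it
    s2 <- paste0(strrep("A", 19), "CG", strrep("A", 50), "CG",
                 strrep("A", 229))
    idx2 <- indexFromSeq(c1 = s2)
    p2 <- singleCpGProfile(plus, idx2)
    expect_identical(sum(p2@count), 0L)
    expect_identical(unname(p2@excluded["multiCpG"]), 1L)
    # CpG below tMin excluded
    s3 <- paste0("AAAA", "CG", strrep("A", 294))
    p3 <- singleCpGProfile(plus, indexFromSeq(c1 = s3))
    expect_identical(sum(p3@count), 0L)
    expect_identical(unname(p3@excluded["belowTMin"]), 1L)
})

test_that("minus-strand segments extend leftward and measure t from the 5' end", {
    # genome of 300 bp with a single CpG at C position 101
    s <- paste0(strrep("A", 100), "CG", strrep("A", 198))
    idx <- indexFromSeq(c1 = s)
    # minus read with rightmost base 290: segment [41, 290];
    # read-strand C of the CpG is the complement of G at 102 -> t = 290-101 = 189
    minus <- GenomicRanges::GRanges("c1", IRanges::IRanges(271, 290),
                                    strand = "-")
    p <- singleCpGProfile(minus, idx)
    expect_identical(p@count[189L], 1L)
    # segment running off the 5' start of the chromosome is discarded
    minus2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 120),
                                     strand = "-")
    p2 <- singleCpGProfile(minus2, idx)
    expect_identical(unname(p2@excluded["offChromosome"]), 1L)
    # read conservation: qualifying + excluded = input
    both <- c(minus, minus2)
    p3 <- singleCpGProfile(both, idx)
    expect_identical(sum(p3@count) + sum(p3@excluded), 2L)
})

test_that("efficiencyRatioProfile flags undefined bins", {
    s <- paste0(strrep("A", 19), "CG", strrep("A", 279))
    idx <- indexFromSeq(c1 = s)
    plus <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 36), strand = "+")
    p <- singleCpGProfile(plus, idx)
    r <- efficiencyRatioProfile(p, p)
    expect_equal(r$ratio[r$defined], 1)       # identical profiles
    expect_true(all(is.na(r$ratio[!r$defined])))
    q <- singleCpGProfile(plus[0], idx)
    expect_error(efficiencyRatioProfile(q, q), "empty")
})

test_that("fitFragLen recovers known parameters from a noiseless ratio", {
    tt <- 11:250
    d <- fragLenDist("gaussian", L = 100, S = 13, lmin = 3L, lmax = 250L)
    y <- 0.9 + (1.2 - 0.9) * fragSurvival(d, tt + 1L)
    fit <- fitFragLen(y, t = tt)
    expect_true(fit@converged)
    expect_lt(abs(fit@L - 100), 0.5)
    expect_lt(abs(fit@S - 13), 0.5)
    expect_lt(abs(fit@R0 - 0.9), 0.01)
    expect_lt(abs(fit@R1 - 1.2), 0.01)
})

test_that("a flat ratio is flagged unidentifiable", {
    fit <- fitFragLen(rep(1, 100), t = 11:110)
    expect_false(fit@converged)
    expect_false(fit@identifiable)
    expect_equal(fit@R0, 1)
    expect_equal(fit@R1, 1)
})

test_that("fitFragLen tolerates multiplicative noise across seeds", {
    tt <- 11:250
    d <- fragLenDist("gaussian", L = 100, S = 13, lmin = 3L, lmax = 250L)
    mu <- 0.9 + (1.2 - 0.9) * fragSurvival(d, tt + 1L)
    dL <- dS <- numeric(20)
    for (i in 1:20) {
        set.seed(1000 + i)
        y <- mu * exp(rnorm(length(tt), sd = 0.01))
        fit <- fitFragLen(y, t = tt)
        dL[i] <- abs(fit@L - 100)
        dS[i] <- abs(fit@S - 13)
    }
    expect_true(all(dL < 2))
    expect_true(all(dS < 3))
    expect_lt(median(dL), 1)
})

test_that("the printed-erf variant is available but distinct", {
    tt <- 11:250
    d <- fragLenDist("gaussian", L = 100, S = 13, lmin = 3L, lmax = 250L)
    y <- 0.9 + (1.2 - 0.9) * fragSurvival(d, tt + 1L)
    fit <- fitFragLen(y, t = tt, model = "printed-erf")
    expect_identical(fit@model, "printed-erf")
    # the printed expression increases with t, so it cannot track the
    # decaying ratio the way the survival model does
    fitS <- fitFragLen(y, t = tt)
    expect_gt(fit@residualNorm, fitS@residualNorm)
})
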