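test_that("accessibleCount follows the greedy separation rule", {
    expect_identical(accessibleCount(integer(0)), 0L)
    expect_identical(accessibleCount(c(10, 15)), 2L)   # (10+1)+3 < 15
    expect_identical(accessibleCount(c(10, 14)), 1L)   # 14 is not < 14
    # bind 10, skip 14, bind 15, skip 19, bind 20 ((15+1)+3 = 19 < 20)
    expect_identical(accessibleCount(c(10, 14, 15, 19, 20)), 3L)
    expect_error(accessibleCount(c(5, 5)), "increasing")
})

test_that("greedy equals exhaustive max-subset search and is monotone", {
    set.seed(99)
    for (rep in 1:200) {
        k <- sample(0:10, 1)
        pos <- sort(sample(1:60, k))
        minSep <- sample(2:3, 1)
        expect_identical(accessibleCount(pos, minSep),
                         oracleMaxSubset(pos, minSep))
        # insertion monotonicity
        if (length(pos) < 10L) {
            extra <- sample(setdiff(1:60, pos), 1)
            expect_gte(accessibleCount(sort(c(pos, extra)), minSep),
                       accessibleCount(pos, minSep))
        }
    }
})

test_that("fragmentNCpG requires both C and G on the fragment", {
    idx <- indexFromSeq(c1 = strrep("A", 100))
    expect_identical(fragmentNCpG(idx, "c1", 10L, 20L), 0L)
    # CpG with C at the last fragment base (G outside) is not counted
    s <- paste0(strrep("A", 9), "CG", strrep("A", 89))   # C at 10, G at 11
    idx2 <- indexFromSeq(c1 = s)
    expect_identical(fragmentNCpG(idx2, "c1", 1L, 10L), 0L)
    expect_identical(fragmentNCpG(idx2, "c1", 1L, 11L), 1L)
    # 10 well-separated CpGs: uncapped count returned
    s10 <- paste(rep(c("CG", "AAAA"), 10), collapse = "")
    idx10 <- indexFromSeq(c1 = s10)
    expect_identical(fragmentNCpG(idx10, "c1", 1L, 60L), 10L)
})

test_that("lambdaAt matches hand-computed cases", {
    idx0 <- indexFromSeq(c1 = strrep("A", 200))
    cfg <- modelConfig(dist = fragLenDist("delta", L = 5, lmin = 3L,
                                          lmax = 10L))
    expect_equal(lambdaAt(idx0, "c1", c(1, 100, 200), cfg), rep(2, 3))
    # single CpG inside both fragments at x: 2 * C(1)
    s <- paste0(strrep("A", 99), "CG", strrep("A", 99))
    idx1 <- indexFromSeq(c1 = s)
    cfg50 <- modelConfig(dist = fragLenDist("delta", L = 50, lmin = 3L,
                                            lmax = 60L))
    expect_equal(lambdaAt(idx1, "c1", 120, cfg50), 1 + 1.489)
    expect_equal(lambdaAt(idx1, "c1", 80, cfg50), 1.489 + 1)
})

test_that("the streamed track equals per-position evaluation", {
    sim <- randomGenome(3000L, 0.02, seed = 5)
    for (cfg in list(modelConfig(),
                     modelConfig(minSep = 2L),
                     modelConfig(dist = fragLenDist("delta", L = 101)),
                     modelConfig(clipEdges = FALSE))) {
        tr <- lambdaTrack(sim$index, cfg)
        expect_equal(as.numeric(tr$sim1),
                     round(lambdaAt(sim$index, "sim1", 1:3000, cfg), 9))
    }
})

test_that("windowLambda floors the exact window sums", {
    idx0 <- indexFromSeq(c1 = strrep("A", 200))
    cfg <- modelConfig(dist = fragLenDist("delta", L = 5, lmin = 3L,
                                          lmax = 10L))
    grid <- tileWindows(c(c1 = 200L), 50L)
    expect_identical(windowValues(windowLambda(idx0, grid, cfg)),
                     rep(100L, 4L))
    # floor bound: sum of counts within #windows of the track total
    sim <- randomGenome(5000L, 0.02, seed = 31)
    g2 <- tileWindows(c(sim1 = 5000L), 100L)
    wc <- windowLambda(sim$index, g2)
    tot <- sum(as.numeric(lambdaTrack(sim$index)$sim1))
    expect_lte(sum(windowValues(wc)), tot)
    expect_lt(tot, sum(windowValues(wc)) + length(g2))
})

test_that("prefactor scales pre-floor sums exactly and preserves ranking", {
    sim <- randomGenome(5000L, 0.02, seed = 13)
    grid <- tileWindows(c(sim1 = 5000L), 100L)
    base <- lambdaTrack(sim$index, modelConfig())
    up <- lambdaTrack(sim$index, modelConfig(prefactor = 10))
    expect_equal(as.numeric(up$sim1), 10 * as.numeric(base$sim1),
                 tolerance = 1e-8)
    y1 <- windowValues(windowLambda(sim$index, grid, modelConfig()))
    y10 <- windowValues(windowLambda(sim$index, grid,
                                     modelConfig(prefactor = 10)))
    y01 <- windowValues(windowLambda(sim$index, grid,
                                     modelConfig(prefactor = 0.1)))
    expect_gte(cor(y1, y10, method = "spearman"), 0.999)
    expect_gte(cor(y1, y01, method = "spearman"), 0.999)
})

test_that("overlap aggregation reduces to start-in-window at length 1", {
    sim <- randomGenome(2000L, 0.02, seed = 17)
    grid <- tileWindows(c(sim1 = 2000L), 100L)
    d1 <- fragLenDist("delta", L = 1, lmin = 1L, lmax = 5L)
    cfgO <- modelConfig(dist = d1, mode = "overlap", lAvg = 1L)
    cfgS <- modelConfig(dist = d1)
    expect_identical(windowValues(windowLambdaOverlap(sim$index, grid, cfgO)),
                     windowValues(windowLambda(sim$index, grid, cfgS)))
    expect_error(windowLambdaOverlap(sim$index, grid, cfgS), "overlap")
})

test_that("overlap aggregation equals explicit fragment enumeration", {
    sim <- randomGenome(300L, 0.03, seed = 23)
    cpg <- cpgPositions(sim$index, "sim1")
    lavg <- 100L
    cfg <- modelConfig(dist = fragLenDist("delta", L = lavg, lmin = 3L,
                                          lmax = 200L),
                       mode = "overlap", lAvg = lavg)
    grid <- tileWindows(c(sim1 = 300L), 100L)
    got <- windowValues(windowLambdaOverlap(sim$index, grid, cfg))
    cn <- defaultCnTable()@coefs
    expected <- integer(length(grid))
    for (w in seq_along(grid)) {
        ws <- start(grid)[w]; we <- end(grid)[w]
        tot <- 0
        for (x in 1:300) {
            nF <- rGreedy(cpg[cpg >= x & cpg <= x + lavg - 2L], 3L)
            nR <- rGreedy(cpg[cpg >= x - lavg + 1L & cpg <= x - 1L], 3L)
            # forward fragment [x, x+lavg-1], reverse [x-lavg+1, x]
            if (x <= we && x + lavg - 1L >= ws)
                tot <- tot + cn[min(nF, 7L) + 1L]
            if (x >= ws && x - lavg + 1L <= we)
                tot <- tot + cn[min(nR, 7L) + 1L]
        }
        expected[w] <- floor(round(tot, 9))
    }
    expect_equal(got, expected, ignore_attr = TRUE)
})

test_that("overlap counts over a CpG-free interior window have closed form", {
    idx0 <- indexFromSeq(c1 = strrep("A", 1000))
    lavg <- 50L
    cfg <- modelConfig(dist = fragLenDist("delta", L = lavg, lmin = 3L,
                                          lmax = 100L),
                       mode = "overlap", lAvg = lavg)
    grid <- tileWindows(c(c1 = 1000L), 100L)
    got <- windowValues(windowLambdaOverlap(idx0, grid, cfg))
    # interior window of width w: (w + lavg - 1) starts per strand, C(0)=1
    expect_identical(got[5L], as.integer((100L + lavg - 1L) * 2L))
})

test_that("bedGraph export merges constant runs and round-trips", {
    sim <- randomGenome(2000L, 0.02, seed = 41)
    tr <- lambdaTrack(sim$index)
    bg <- withr::local_tempfile(fileext = ".bedGraph")
    exportLambdaBedGraph(tr, bg)
    back <- rtracklayer::import(bg)
    # re-expanded per-base values equal the track
    v <- rep(back$score, width(back))
    expect_equal(v, as.numeric(tr$sim1), tolerance = 1e-6)
    # run-length merging: number of records equals number of runs
    expect_identical(length(back), length(S4Vectors::runValue(tr$sim1)))
    # empty chromosome emits nothing
    idx0 <- indexFromSeq(c1 = strrep("A", 100))
    tr0 <- lambdaTrack(idx0)
    exportLambdaBedGraph(tr0, bg)
    expect_identical(length(rtracklayer::import(bg)), 1L)  # one constant run
})
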