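test_that("windowMethylation implements the read-weighted mean", {
    idx <- indexFromSeq(c1 = paste0("ACGACG", strrep("A", 194)))
    grid <- tileWindows(c(c1 = 200L), 100L)
    counts <- methGR("c1", c(2, 5), c(3, 7), c(5, 10))
    wm <- windowMethylation(counts, grid)
    expect_equal(S4Vectors::mcols(wm)$mu[1L], 10 / 15)
    expect_identical(S4Vectors::mcols(wm)$coverage[1L], 15L)
    expect_identical(as.character(S4Vectors::mcols(wm)$label),
                     c("methylated", "undefined"))
    # m = r everywhere -> mu = 1; mu = 0.5 is unmethylated (boundary)
    c2 <- methGR("c1", 2, 4, 4)
    expect_equal(S4Vectors::mcols(windowMethylation(c2, grid))$mu[1L], 1)
    c3 <- methGR("c1", 2, 2, 4)
    expect_identical(
        as.character(S4Vectors::mcols(windowMethylation(c3, grid))$label[1L]),
        "unmethylated")
})

test_that("selectEvalWindows applies inclusive thresholds", {
    grid <- tileWindows(c(c1 = 300L), 100L)
    wm <- grid
    S4Vectors::mcols(wm)$coverage <- c(9L, 10L, 33L)
    S4Vectors::mcols(wm)$mu <- c(0.5, 0.5, 0.5)
    keep <- suppressMessages(selectEvalWindows(wm, c(1, 0.75, 0.74)))
    expect_identical(as.logical(keep), c(FALSE, TRUE, FALSE))
    expect_identical(unname(attr(keep, "excluded")), c(1L, 1L))
    # WGBS-style variant
    keep33 <- suppressMessages(selectEvalWindows(wm, NULL, minCov = 33L))
    expect_identical(as.logical(keep33), c(FALSE, FALSE, TRUE))
})

test_that("rocAuc handles separation, ties and pair counting", {
    expect_equal(rocAuc(c(.9, .8, .2, .1), c(TRUE, TRUE, FALSE, FALSE))@auc,
                 1)
    expect_equal(rocAuc(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))@auc, 0.5)
    expect_equal(rocAuc(c(.9, .4, .6, .1),
                        c(TRUE, FALSE, TRUE, FALSE))@auc, 1)
    expect_equal(rocAuc(c(.9, .6, .4, .1),
                        c(TRUE, FALSE, TRUE, FALSE))@auc, 0.75)
    expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "unmethylated")
    # curve endpoints and monotonicity
    roc <- rocAuc(runif(50), rep(c(TRUE, FALSE), 25))
    expect_equal(c(roc@fpr[1L], roc@tpr[1L]), c(0, 0))
    expect_equal(c(roc@fpr[length(roc@fpr)], roc@tpr[length(roc@tpr)]),
                 c(1, 1))
})

test_that("rocAuc equals the Mann-Whitney statistic on random instances", {
    set.seed(101)
    for (i in 1:60) {
        n <- sample(4:200, 1)
        score <- sample(round(runif(n), sample(c(1, 3), 1)))  # forces ties
        lab <- runif(n) < 0.5
        if (!any(lab) || all(lab)) next
        expect_equal(rocAuc(score, lab)@auc, oracleAUC(score, lab))
    }
})

test_that("AUC is invariant under strictly increasing transforms", {
    set.seed(7)
    score <- runif(100)
    lab <- runif(100) < 0.4
    a1 <- rocAuc(score, lab)@auc
    expect_equal(rocAuc(qlogis(score / 2 + 0.25), lab)@auc, a1)
    expect_equal(rocAuc(rank(score), lab)@auc, a1)
})

test_that("youdenPoint equals an exhaustive scan and breaks ties low", {
    roc <- rocAuc(c(.9, .8, .2, .1), c(TRUE, TRUE, FALSE, FALSE))
    yp <- youdenPoint(roc)
    expect_equal(c(yp$tpr, yp$fpr), c(1, 0))
    # diagonal curve: distance 0, first point by the tie rule
    rocD <- rocAuc(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
    ypD <- youdenPoint(rocD)
    expect_equal(ypD$distance, 0)
    expect_equal(ypD$fpr, 0)
    set.seed(3)
    roc2 <- rocAuc(runif(40), runif(40) < 0.5)
    yp2 <- youdenPoint(roc2)
    d <- (roc2@tpr - roc2@fpr) / sqrt(2)
    expect_equal(yp2$distance, max(d))
})

test_that("regimeSummary matches hand enumeration", {
    mu <-  c(0.05, 0.08, 0.10, 0.50, 0.90, 0.95, 1.00, 0.02, 0.91, 0.30)
    pred <- c(0.60, 0.05, 0.05, 0.40, 0.95, 0.40, 0.92, 0.02, 0.10, 0.80)
    s <- regimeSummary(pred, mu)
    # low regime: mu <= 0.10 -> indices 1,2,3,8; pred > 0.5 only for #1
    expect_identical(s$low$n, 4L)
    expect_equal(s$low$miscategorized, 1 / 4)
    expect_equal(s$low$retained, 3 / 4)
    # high regime: mu >= 0.90 -> indices 5,6,7,9; pred <= 0.5 for #6 and #9
    expect_identical(s$high$n, 4L)
    expect_equal(s$high$miscategorized, 2 / 4)
    expect_equal(s$high$retained, 2 / 4)
    # perfect predictions -> no miscategorization
    p0 <- regimeSummary(mu, mu)
    expect_equal(p0$low$miscategorized, 0)
    expect_equal(p0$high$miscategorized, 0)
})

test_that("lambdaCutoffSweep recomputes AUC on thresholded subsets", {
    set.seed(11)
    n <- 200L
    ylam <- sample(0:50, n, replace = TRUE)
    lab <- runif(n) < 0.5
    pred <- ifelse(lab, runif(n, 0.4, 1), runif(n, 0, 0.6))
    sw <- lambdaCutoffSweep(ylam, list(a = pred), lab, step = 5)
    expect_identical(nrow(sw), 20L)
    expect_equal(sw$auc[sw$percentile == 0], rocAuc(pred, lab)@auc)
    for (p in c(25, 60, 95)) {
        cut <- sort(ylam)[ceiling(p / 100 * n)]
        keep <- ylam >= cut
        expect_equal(sw$auc[sw$percentile == p],
                     rocAuc(pred[keep], lab[keep])@auc)
    }
    # constant coverage: every cutoff keeps everything
    swc <- lambdaCutoffSweep(rep(5, n), list(a = pred), lab)
    expect_true(all(swc$n == n))
    expect_equal(unique(swc$auc), rocAuc(pred, lab)@auc)
})

test_that("cpgDensityWindow counts CpGs in the flanked window", {
    s <- paste0(strrep("A", 48), "CG", strrep("A", 100), "CG",
                strrep("A", 148))
    idx <- indexFromSeq(c1 = s)          # C positions 49 and 151
    grid <- tileWindows(c(c1 = 300L), 100L)
    expect_identical(cpgDensityWindow(idx, grid, 0L), c(1L, 1L, 0L))
    # CpG 50 bp left of window 2 counted with context 101
    expect_identical(cpgDensityWindow(idx, grid, 101L), c(2L, 2L, 1L))
    # brute force on a random toy
    sim <- randomGenome(2000L, 0.03, seed = 8)
    g2 <- tileWindows(c(sim1 = 2000L), 100L)
    cpg <- cpgPositions(sim$index, "sim1")
    for (ctx in c(0L, 37L, 101L)) {
        got <- cpgDensityWindow(sim$index, g2, ctx)
        exp <- vapply(seq_along(g2), function(w)
            sum(cpg >= max(start(g2)[w] - ctx, 1L) &
                cpg <= min(end(g2)[w] + ctx, 2000L)), integer(1))
        expect_identical(got, exp)
    }
})

test_that("the caller-input table round-trips", {
    sim <- randomGenome(500L, 0.02, seed = 4)
    grid <- tileWindows(c(sim1 = 500L), 100L)
    yS <- c(5L, 0L, 2L, 9L, 1L)
    yL <- windowLambda(sim$index, grid)
    dens <- cpgDensityWindow(sim$index, grid, 101L)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    exportBaymethTable(tsv, grid, yS, yL, dens, rep(1, 5))
    back <- readBaymethTable(tsv)
    expect_identical(nrow(back), 5L)
    expect_identical(back$y_sample, yS)
    expect_identical(back$y_control, windowValues(yL))
    expect_identical(back$cpg_density, dens)
    expect_identical(back$start, start(grid))
    expect_error(exportBaymethTable(tsv, grid, yS, NULL), "control")
})

test_that("external score tables align to the grid", {
    grid <- tileWindows(c(c1 = 300L), 100L)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("chrom\tstart\tend\tscore", "c1\t101\t200\t0.7"), tsv)
    sc <- readWindowScores(tsv, grid)
    expect_equal(sc, c(NA, 0.7, NA))
})
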