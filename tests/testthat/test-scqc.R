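test_that("library-size outliers fail QC at median - 3 scaled MADs", {
    libs <- c(1, 8, 9, 10, 11, 12) * 1e4
    counts <- rbind(matrix(0L, 3, 6), as.integer(libs))
    rownames(counts) <- c("g1", "g2", "g3", "g4")
    colnames(counts) <- sprintf("c%d", 1:6)
    qc <- suppressWarnings(qcFilterCells(counts, nmads = 3))
    ## median 9.5e4, scaled MAD ~2.2239e4 -> only the 1e4 cell fails
    expect_identical(qc$failLowLibsize, c(TRUE, rep(FALSE, 5)))
    expect_identical(qc$pass, c(FALSE, rep(TRUE, 5)))
    expect_match(qc$failReasons[1], "low_libsize")
})

test_that("identical samples degenerate the MAD to the median with a
           warning, and all pass", {
    counts <- matrix(5L, 10, 6,
                     dimnames = list(sprintf("g%d", 1:10),
                                     sprintf("c%d", 1:6)))
    w <- capture_warnings(qc <- qcFilterCells(counts))
    expect_true(any(grepl("MAD is 0", w)))
    expect_true(all(qc$pass))
})

test_that("high spike-in fractions fail QC above median + 3 MADs", {
    set.seed(2)
    counts <- matrix(rpois(20 * 10, 50), 20, 10,
                     dimnames = list(c(sprintf("g%d", 1:19), "ERCC-1"),
                                     sprintf("c%d", 1:10)))
    counts["ERCC-1", ] <- as.integer(round(colSums(counts[1:19, ]) * 0.01))
    counts["ERCC-1", 10] <- as.integer(round(
        sum(counts[1:19, 10]) * 0.9 / 0.1))       # ~90% spike-in cell
    qc <- suppressWarnings(qcFilterCells(counts, erccPattern = "^ERCC-"))
    expect_identical(which(qc$failHighErcc), 10L)
})

test_that("qcFilterCells matches a brute-force reimplementation on random
           matrices", {
    set.seed(77)
    for (i in 1:25) {
        n <- 20L
        counts <- matrix(rpois(50 * n, lambda = sample(1:80, 1)), 50, n)
        rownames(counts) <- c(sprintf("g%d", 1:45), sprintf("ERCC-%d", 1:5))
        colnames(counts) <- sprintf("c%d", seq_len(n))
        ## perturb some cells to create outliers
        counts[, 1] <- counts[, 1] %/% 20L
        got <- suppressWarnings(qcFilterCells(counts))
        expect_identical(got$pass, unname(bruteQcPass(counts)))
    }
})

test_that("qcFilterCells agrees with scater's outlier calls", {
    skip_if_not_installed("scater")
    set.seed(5)
    counts <- matrix(rpois(50 * 16, 40), 50, 16,
                     dimnames = list(sprintf("g%d", 1:50),
                                     sprintf("c%d", 1:16)))
    counts[, 2] <- counts[, 2] %/% 30L
    qc <- suppressWarnings(qcFilterCells(counts))
    libs <- colSums(counts)
    sc <- scater::isOutlier(libs, nmads = 3, type = "lower")
    expect_identical(qc$failLowLibsize, unname(as.logical(sc)))
})

test_that("gene filtering applies the 0.1-mean rule and exclusion lists", {
    counts <- rbind(
        lowish = c(0L, 0L, 1L),                  # mean 1/3 -> kept
        matrix(5L, 2, 3, dimnames = list(c("keep1", "mt-co1"), NULL)))
    colnames(counts) <- sprintf("c%d", 1:3)
    expect_setequal(rownames(filterGenes(counts)),
                    c("lowish", "keep1", "mt-co1"))
    expect_setequal(rownames(filterGenes(counts,
                                         exclude = list(mito = "mt-co1"))),
                    c("lowish", "keep1"))
    expect_warning(filterGenes(counts, exclude = "nosuchgene"),
                   "unknown genes")

    ## mean 1/12 < 0.1 -> dropped
    c12 <- matrix(0L, 2, 12, dimnames = list(c("sparse", "dense"), NULL))
    c12["sparse", 1] <- 1L
    c12["dense", ] <- 3L
    colnames(c12) <- sprintf("c%d", 1:12)
    expect_identical(rownames(filterGenes(c12)), "dense")

    ## brute-force equivalence on random matrices
    set.seed(123)
    for (i in 1:10) {
        m <- matrix(rpois(50 * 20, 0.15), 50, 20,
                    dimnames = list(sprintf("g%d", 1:50),
                                    sprintf("c%d", 1:20)))
        excl <- sample(rownames(m), 4)
        keepBrute <- rowMeans(m) >= 0.1 & !(rownames(m) %in% excl)
        expect_identical(rownames(filterGenes(m, exclude = excl)),
                         rownames(m)[keepBrute])
    }
})

test_that("FPKM transform follows its formula and matches edgeR", {
    counts <- matrix(c(100L, 999900L, 50L, 1999950L), 2, 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
    cm <- countMatrix(counts, c(1000, 500))
    f <- SummarizedExperiment::assay(computeFpkm(cm), "fpkm")
    expect_equal(f["a", "s1"], 100)     # 100 / (1e6/1e6) / (1000/1e3)
    expect_equal(f["a", "s2"], 25)      # 50 / 2 / 1
    expect_equal(f["b", "s2"] * 0 + f["a", "s2"] * 0, 0)

    skip_if_not_installed("edgeR")
    set.seed(8)
    counts <- matrix(rpois(40, 60), 8, 5,
                     dimnames = list(sprintf("g%d", 1:8),
                                     sprintf("s%d", 1:5)))
    lens <- sample(200:3000, 8)
    cm <- countMatrix(counts, lens)
    ours <- SummarizedExperiment::assay(computeFpkm(cm), "fpkm")
    ref <- edgeR::rpkm(edgeR::DGEList(counts = counts),
                       gene.length = lens, normalized.lib.sizes = FALSE)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("FPKM is invariant in proportion under per-sample count scaling", {
    set.seed(10)
    counts <- matrix(rpois(30, 40), 6, 5,
                     dimnames = list(sprintf("g%d", 1:6),
                                     sprintf("s%d", 1:5)))
    lens <- sample(300:2000, 6)
    f1 <- SummarizedExperiment::assay(
        computeFpkm(countMatrix(counts, lens)), "fpkm")
    f2 <- SummarizedExperiment::assay(
        computeFpkm(countMatrix(counts * 7L, lens)), "fpkm")
    expect_equal(f1, f2)
    expect_error(computeFpkm(countMatrix(cbind(counts, z = 0L),
                                         lens)), "zero library")
})

test_that("marker combinations label cells and fractions sum to one", {
    fp <- cbind(c1 = c(5, 0, 2), c2 = c(1, 1, 1), c3 = c(0, 0, 0),
                c4 = c(0, 3, 0))
    rownames(fp) <- c("tcf21", "tbx18", "wt1b")
    got <- classifyMarkerCombinations(fp, c("tcf21", "tbx18", "wt1b"))
    expect_identical(got$calls$label,
                     c("tcf21+wt1b", "tcf21+tbx18+wt1b", "none", "tbx18"))
    expect_equal(sum(got$fractions$fraction), 1)

    ## 40/100 triple-positive cells -> triple fraction 0.40
    set.seed(3)
    n <- 100L
    triple <- seq_len(40L)
    fp2 <- matrix(0, 3, n, dimnames = list(c("tcf21", "tbx18", "wt1b"),
                                           sprintf("c%d", 1:n)))
    fp2[, triple] <- 1
    fp2["tcf21", 41:100] <- 1
    got2 <- classifyMarkerCombinations(fp2, c("tcf21", "tbx18", "wt1b"))
    fr <- got2$fractions
    expect_equal(fr$fraction[fr$combination == "tcf21+tbx18+wt1b"], 0.40)
    expect_equal(fr$fraction[fr$combination == "tcf21"], 0.60)

    ## positivity threshold is strict
    got3 <- classifyMarkerCombinations(fp, c("tcf21", "tbx18", "wt1b"),
                                       threshold = 2)
    expect_identical(got3$calls$label[1], "tcf21")

    expect_error(classifyMarkerCombinations(fp, "nope"), "absent")
    expect_warning(classifyMarkerCombinations(
        fp, "tcf21", groups = factor(rep("a", 4), levels = c("a", "b"))),
        "zero cells")
})
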