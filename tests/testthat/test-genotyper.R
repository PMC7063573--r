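chromT <- local({
    set.seed(42)
    randomChrom(2000)
})
genomeT <- Biostrings::DNAStringSet(c(chrT = chromT))
siteT <- data.frame(name = "sgT", chrom = "chrT", cut_pos = 1000L,
                    window = 15L, stringsAsFactors = FALSE)

refSlice <- function(s, e) substr(chromT, s, e)

test_that("extractSiteReads requires the footprint to cover the window", {
    reads <- rbind(
        makeRead("in", "chrT", 900, "150M", refSlice(900, 1049)),
        makeRead("short", "chrT", 900, "100M", refSlice(900, 999)),
        ## spans the window via a deletion inside it
        makeRead("delspan", "chrT", 960,
                 paste0("35M", 20, "D", "45M"),
                 paste0(refSlice(960, 994), refSlice(1015, 1059))),
        makeRead("supp", "chrT", 900, "150M", refSlice(900, 1049),
                 flag = 2048L, isSupplementary = TRUE))
    got <- extractSiteReads(reads, siteT)
    expect_setequal(got$queryName, c("in", "delspan"))
})

test_that("callReadAllele classifies match, indel, substitution, compound", {
    ## perfect match
    r <- makeRead("m", "chrT", 950, "100M", refSlice(950, 1049))
    expect_identical(callReadAllele(r, genomeT, siteT)$call, "match")

    ## 38-bp insertion at the cut
    ins <- randomChrom(38)
    r <- makeRead("i38", "chrT", 950,
                  "51M38I49M",
                  paste0(refSlice(950, 1000), ins, refSlice(1001, 1049)))
    got <- callReadAllele(r, genomeT, siteT)
    expect_identical(got$call, "indel")
    expect_identical(got$allele, sprintf("I:1000:%s", ins))

    ## 7-bp deletion plus 1-bp substitution: one compound indel event
    subPos <- 995L
    refB <- substr(chromT, subPos, subPos)
    altB <- setdiff(c("A", "C", "G", "T"), refB)[1]
    seqStr <- paste0(refSlice(950, 1049), "")
    q <- paste0(refSlice(950, subPos - 1), altB,
                refSlice(subPos + 1, 1000), refSlice(1008, 1056))
    r <- makeRead("cmp", "chrT", 950, "51M7D49M", q)
    got <- callReadAllele(r, genomeT, siteT)
    expect_identical(got$call, "indel")
    expect_identical(got$allele,
                     sprintf("S:%d:%s>%s;D:1001-1007", subPos, refB, altB))

    ## spliced across the window: excluded from calling
    r <- makeRead("spl", "chrT", 950, "40M100N40M",
                  paste0(refSlice(950, 989), refSlice(1090, 1129)))
    expect_identical(callReadAllele(r, genomeT, siteT)$call, "spliced")
})

test_that("callReadAllele equals the base-by-base projection oracle on
           random CIGAR fixtures", {
    set.seed(99)
    chrom <- randomChrom(3000)
    gnm <- Biostrings::DNAStringSet(c(chrT = chrom))
    mismatches <- 0L
    for (i in 1:300) {
        rd <- randomAlignedRead(chrom, sprintf("r%d", i))
        fp <- rd$pos + rd$refWidth - 1L
        if (fp - rd$pos < 40L) next
        cut <- sample((rd$pos + 12L):(fp - 12L), 1L)
        st <- data.frame(name = "s", chrom = "chrT", cut_pos = cut,
                         window = 10L, stringsAsFactors = FALSE)
        if (rd$pos > cut - 10L || fp < cut + 10L) next
        a <- callReadAllele(rd, gnm, st)
        b <- oracleCallAllele(rd, chrom, cut, 10L)
        if (!identical(a$call, b$call) || !identical(a$allele, b$allele))
            mismatches <- mismatches + 1L
    }
    expect_identical(mismatches, 0L)
})

test_that("genotypeSample counts support, handles coverage, is monotone in
           minSupport", {
    mkDel <- function(q) makeRead(q, "chrT", 950, "51M5D49M",
                                  paste0(refSlice(950, 1000),
                                         refSlice(1006, 1054)))
    mkWt <- function(q) makeRead(q, "chrT", 950, "100M",
                                 refSlice(950, 1049))
    reads <- rbind(do.call(rbind, lapply(sprintf("d%d", 1:6), mkDel)),
                   do.call(rbind, lapply(sprintf("w%d", 1:4), mkWt)))
    gt <- genotypeSample(reads, genomeT, siteT)
    expect_identical(unname(gt$status["sgT"]), "edited")
    expect_identical(gt$events$support, 6L)
    expect_identical(gt$events$spanning, 10L)

    ## all-match sample
    gtWt <- genotypeSample(do.call(rbind, lapply(sprintf("w%d", 1:10),
                                                 mkWt)), genomeT, siteT)
    expect_identical(unname(gtWt$status["sgT"]), "unedited")

    ## no coverage at one site, coverage at another
    site2 <- data.frame(name = "sg2", chrom = "chrT", cut_pos = 200L,
                        window = 15L, stringsAsFactors = FALSE)
    gt2 <- genotypeSample(reads, genomeT, rbind(siteT, site2))
    expect_identical(unname(gt2$status["sg2"]), "no_coverage")
    expect_identical(unname(gt2$status["sgT"]), "edited")

    ## raising minSupport never increases edited calls
    nEdited <- vapply(1:8, function(ms) {
        sum(genotypeSample(reads, genomeT, siteT,
                           minSupport = ms)$status == "edited")
    }, integer(1))
    expect_true(all(diff(nEdited) <= 0L))
    expect_identical(unname(
        genotypeSample(reads, genomeT, siteT, minSupport = 7L)$status),
        "unedited")
})

test_that("detectLargeDeletion finds split alignments flanking two distant
           cuts", {
    siteA <- data.frame(name = "sgA", chrom = "chr11",
                        cut_pos = 35307703L, window = 15L,
                        stringsAsFactors = FALSE)
    siteB <- data.frame(name = "sgB", chrom = "chr11",
                        cut_pos = 35213000L, window = 15L,
                        stringsAsFactors = FALSE)
    ## block ending 20 bp before the lower cut, supplementary block
    ## starting 20 bp after the higher cut
    mk <- function(q) rbind(
        makeRead(q, "chr11", 35212940L, "40M35S", strrep("A", 75)),
        makeRead(q, "chr11", 35307723L, "40S35M", strrep("A", 75),
                 flag = 2048L, isSupplementary = TRUE))
    reads <- rbind(mk("q1"), mk("q2"))
    ev <- detectLargeDeletion(reads, siteA, siteB, minSupport = 2L)
    expect_identical(ev$category, "large_deletion")
    expect_identical(ev$support, 2L)
    expect_gt(ev$refEnd - ev$refStart + 1L, 10000L)
    ## deleted span ~94.7 kb: breakpoints just outside the aligned blocks
    expect_identical(ev$refStart, 35212980L)
    expect_identical(ev$refEnd, 35307722L)

    ## an ordinary 2 kb spliced read is not a large deletion
    spl <- makeRead("s1", "chr11", 35212950L, "40M2000N35M",
                    strrep("A", 75))
    expect_null(detectLargeDeletion(spl, siteA, siteB))
    expect_null(detectLargeDeletion(reads[0, ], siteA, siteB))
})

test_that("summarizeCohort excludes no-coverage samples from denominators", {
    mkGt <- function(id, status) list(sampleId = id,
                                      status = c(sgT = status),
                                      events = data.frame())
    gts <- c(lapply(sprintf("e%d", 1:7), mkGt, status = "edited"),
             lapply(sprintf("u%d", 1:7), mkGt, status = "unedited"),
             lapply(sprintf("n%d", 1:3), mkGt, status = "no_coverage"))
    cs <- summarizeCohort(gts)
    expect_identical(cs$overall$nAnalyzed, 14L)
    expect_identical(cs$overall$editedFraction, 0.5)
    expect_identical(cs$perSite$nNoCoverage, 3L)

    csz <- summarizeCohort(lapply(sprintf("u%d", 1:10), mkGt,
                                  status = "unedited"))
    expect_identical(csz$overall$editedFraction, 0)
    expect_warning(summarizeCohort(lapply("n1", mkGt,
                                          status = "no_coverage")),
                   "coverage")
})

test_that("genotyping recovers simulated truth exactly without errors", {
    toy <- toyRefFixture()
    semSites <- toy$sites[toy$sites$chrom == "chrS", ]
    cfg <- simConfig(seed = 21, nSamples = 40, depthMrna = 10,
                     depthAmplicon = 15, editedFraction = 0.5,
                     seqErrorRate = 0)
    sim <- simulateReads(cfg, toy$genome, toy$models, semSites)
    gts <- lapply(sim$sampleIds, function(s)
        genotypeSample(sim$reads[sim$reads$sampleId == s, ], toy$genome,
                       semSites))
    st <- do.call(rbind, lapply(gts, `[[`, "status"))
    trm <- matrix(sim$truth$editing$edited, nrow = 40, byrow = TRUE,
                  dimnames = list(sim$sampleIds, semSites$name))
    covered <- st != "no_coverage"
    expect_identical(sum(covered & ((st == "edited") != trm)), 0L)
})
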