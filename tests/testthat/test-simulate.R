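test_that("identical configurations give byte-identical SAM and manifest", {
    toy <- toyRefFixture()
    cfg <- simConfig(seed = 5, nSamples = 3, depthMrna = 8,
                     depthAmplicon = 6, editedFraction = 0.5,
                     seqErrorRate = 0.01)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateReads(cfg, toy$genome, toy$models, toy$sites, outDir = d1)
    simulateReads(cfg, toy$genome, toy$models, toy$sites, outDir = d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
})

test_that("unedited simulations match the reference at every guide window", {
    toy <- toyRefFixture()
    cfg <- simConfig(seed = 6, nSamples = 4, depthMrna = 10,
                     depthAmplicon = 10, editedFraction = 0,
                     seqErrorRate = 0)
    sim <- simulateReads(cfg, toy$genome, toy$models, toy$sites)
    expect_false(any(sim$truth$editing$edited))
    for (k in seq_len(nrow(toy$sites))) {
        st <- toy$sites[k, ]
        span <- extractSiteReads(sim$reads, st)
        chrom <- as.character(toy$genome[[st$chrom]])
        for (j in seq_len(nrow(span))) {
            got <- oracleCallAllele(span[j, ], chrom, st$cut_pos,
                                    st$window)
            expect_true(got$call %in% c("match", "spliced"))
        }
    }
})

test_that("reads carry the truth allele exactly when the sample is edited", {
    toy <- toyRefFixture()
    cfg <- simConfig(seed = 8, nSamples = 12, depthMrna = 10,
                     depthAmplicon = 10, editedFraction = 0.6,
                     seqErrorRate = 0)
    sim <- simulateReads(cfg, toy$genome, toy$models, toy$sites)
    tr <- sim$truth$editing
    for (k in seq_len(nrow(toy$sites))) {
        st <- toy$sites[k, ]
        chrom <- as.character(toy$genome[[st$chrom]])
        for (sid in sim$sampleIds) {
            span <- extractSiteReads(
                sim$reads[sim$reads$sampleId == sid, ], st)
            if (nrow(span) == 0L) next
            calls <- vapply(seq_len(nrow(span)), function(j)
                oracleCallAllele(span[j, ], chrom, st$cut_pos,
                                 st$window)$call, character(1))
            callable <- calls[calls != "spliced"]
            isEd <- tr$edited[tr$sampleId == sid & tr$site == st$name]
            if (isEd) expect_true(all(callable != "match"))
            else expect_true(all(callable == "match"))
        }
    }
})

test_that("junction gaps reproduce the exon structure or the configured
           skip (independent CIGAR walk)", {
    toy <- toyRefFixture()
    cxc <- toy$models$cxcX
    cfg <- simConfig(seed = 14, nSamples = 4, depthMrna = 150,
                     depthAmplicon = 0, editedFraction = 0,
                     aberrantSpliceRatio = 0.5, erccFraction = 0)
    sim <- simulateReads(cfg, toy$genome["chrC"], toy$models["cxcX"],
                         toy$sites[0, ])
    ## allowed gaps: exon1->exon2, exon2->exon3 (canonical), exon1->exon3
    allowed <- c("1500 2001", "2118 3001", "1500 3001")
    seen <- character(0)
    for (i in seq_len(nrow(sim$reads))) {
        r <- sim$reads$pos[i]
        for (seg in oracleParseCigar(sim$reads$cigar[i])) {
            if (seg$op %in% c("M", "D")) r <- r + seg$len
            else if (seg$op == "N") {
                key <- paste(r - 1L, r + seg$len)
                expect_true(key %in% allowed)
                seen <- c(seen, key)
                r <- r + seg$len
            }
        }
    }
    expect_setequal(unique(seen), allowed)
})

test_that("aberrant_splice_ratio 1 makes every exon-1 junction read skip
           into exon 3", {
    toy <- toyRefFixture()
    cfg <- simConfig(seed = 15, nSamples = 2, depthMrna = 200,
                     depthAmplicon = 0, editedFraction = 0,
                     aberrantSpliceRatio = 1, erccFraction = 0)
    sim <- simulateReads(cfg, toy$genome["chrC"], toy$models["cxcX"],
                         toy$sites[0, ])
    jx <- extractJunctions(sim$reads, toy$models$cxcX)
    expect_identical(jx$donorEnd, 1500L)
    expect_identical(jx$acceptorStart, 3001L)
})

test_that("the truth manifest has one row per sample and site and
           round-trips losslessly", {
    toy <- toyRefFixture()
    d <- withr::local_tempdir()
    cfg <- simConfig(seed = 4, nSamples = 5, depthMrna = 4,
                     depthAmplicon = 4, editedFraction = 0.5)
    sim <- simulateReads(cfg, toy$genome, toy$models, toy$sites,
                         outDir = d)
    expect_identical(nrow(sim$truth$editing), 5L * nrow(toy$sites))
    back <- readTruthManifest(d)
    expect_equal(back$editing, sim$truth$editing,
                 ignore_attr = TRUE)
    expect_equal(back$expression, sim$truth$expression,
                 ignore_attr = TRUE)

    ## empty simulation: header-only manifest
    cfg0 <- simConfig(seed = 4, nSamples = 0)
    sim0 <- simulateReads(cfg0, toy$genome, toy$models, toy$sites,
                          outDir = d)
    expect_identical(nrow(sim0$truth$editing), 0L)
    expect_identical(length(readLines(file.path(d, "truth_editing.tsv"))),
                     1L)
})

test_that("configuration validation rejects out-of-range and oversized
           alleles", {
    toy <- toyRefFixture()
    expect_error(simConfig(seqErrorRate = 0.2), "seqErrorRate")
    expect_error(simConfig(editedFraction = 1.5), "editedFraction")
    expect_error(simConfig(erccFraction = 1), "erccFraction")
    cfg <- simConfig(seed = 1, nSamples = 1,
                     alleleSpec = list(cxcX_sg1 = list(type = "insertion",
                                                       len = 80L)))
    expect_error(simulateReads(cfg, toy$genome, toy$models, toy$sites),
                 "allele longer than read length")
})

test_that("per-site edited fractions drive independent site draws", {
    toy <- toyRefFixture()
    cxcSites <- toy$sites[toy$sites$chrom == "chrC", ]
    cfg <- simConfig(seed = 30, nSamples = 150, depthMrna = 0,
                     depthAmplicon = 2, erccFraction = 0,
                     editedFraction = c(cxcX_sg1 = 0.1, cxcX_sg3 = 0.9))
    sim <- simulateReads(cfg, toy$genome, toy$models["cxcX"], cxcSites)
    tr <- sim$truth$editing
    f1 <- mean(tr$edited[tr$site == "cxcX_sg1"])
    f3 <- mean(tr$edited[tr$site == "cxcX_sg3"])
    expect_lt(abs(f1 - 0.1), 0.08)
    expect_lt(abs(f3 - 0.9), 0.08)
})
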