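test_that("toy cxcX wildtype and splice forms match the designed lengths", {
    toy <- toyRefFixture()
    cxc <- toy$models$cxcX
    expect_identical(transcriptLength(cxc), 1342L)
    cds <- buildCds(cxc, toy$genome)
    expect_identical(nchar(cds), 300L)                # 99 codons + stop
    rep <- translateOrf(spliceTranscript(cxc, toy$genome), cxc)
    expect_identical(rep$proteinLengthAA, 99L)
    expect_identical(rep$relativeLength, 1)
    expect_false(rep$frameshift)
    expect_false(rep$prematureStop)

    skip2 <- applySpliceVariant(cxc, toy$genome, 2L)
    expect_identical(nchar(skip2$transcript), 1224L)
    skip0 <- applySpliceVariant(cxc, toy$genome, integer(0))
    expect_identical(nchar(skip0$transcript), 1342L)
    expect_identical(skip0$transcript, spliceTranscript(cxc, toy$genome))
    expect_error(applySpliceVariant(cxc, toy$genome, 1:3), "every exon")
})

test_that("edits project into the transcript with correct frame tracking", {
    toy <- toyRefFixture()
    cxc <- toy$models$cxcX
    wt <- spliceTranscript(cxc, toy$genome)
    ## 15-bp in-frame deletion at the start of the coding sequence
    ## (CDS transcript 450..749; genomic exon 1 is 1001..1500)
    ## tx 450 is the A of the start codon (genomic 1450); delete just after
    del15 <- list(category = "indel", refStart = 1453L, refEnd = 1467L,
                  alt = "")
    v <- applyEdit(cxc, toy$genome, del15)
    expect_identical(nchar(v$transcript), 1342L - 15L)
    expect_identical(v$netCodingIndel, -15L)
    rep <- translateOrf(v, cxc)
    expect_identical(rep$proteinLengthAA, 94L)
    expect_false(rep$frameshift)
    expect_false(rep$prematureStop)
    expect_equal(rep$relativeLength, 94 / 99)

    ## 38-bp exonic insertion: frameshift (38 mod 3 = 2)
    ins38 <- list(category = "indel", refStart = 1470L, refEnd = 1470L,
                  alt = randomChrom(38))
    v <- applyEdit(cxc, toy$genome, ins38)
    expect_identical(nchar(v$transcript), 1342L + 38L)
    rep <- translateOrf(v, cxc)
    expect_true(rep$frameshift)
    expect_lt(rep$relativeLength, 1)

    ## 1-base substitution: length unchanged
    sub1 <- list(category = "substitution", refStart = 1470L,
                 refEnd = 1470L, alt = "A")
    expect_identical(nchar(applyEdit(cxc, toy$genome, sub1)$transcript),
                     1342L)

    ## intronic event is a no-op with warning
    intronic <- list(category = "indel", refStart = 1700L, refEnd = 1705L,
                     alt = "")
    expect_warning(v <- applyEdit(cxc, toy$genome, intronic), "intronic")
    expect_identical(v$transcript, wt)

    ## exon boundaries outside the chromosome: validation error
    bad <- geneModel("bad", "chrC", "+", 5990, 6050, 1, 12)
    expect_error(spliceTranscript(bad, toy$genome), "outside")
})

test_that("minus-strand transcripts are reverse-complemented", {
    set.seed(7)
    chrom <- randomChrom(500)
    gnm <- Biostrings::DNAStringSet(c(chrM = chrom))
    m <- geneModel("neg", "chrM", "-", 101, 300, 11, 190)
    tx <- spliceTranscript(m, gnm)
    expect_identical(tx, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(chrom, 101, 300)))))
})

test_that("skipping the start-codon exon falls back to a downstream ATG", {
    set.seed(11)
    ## 2-exon gene whose start codon sits in exon 1
    fix <- singleExonGene(nCodon = 60L, utr5 = 12L, utr3 = 30L)
    ## rebuild as two exons: split the single exon into [s, s+49], [s+80, e]
    ex <- exonRanges(fix$model)
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    chrom <- as.character(fix$genome[[1]])
    ## move the second part 30 bp downstream by inserting an intron copy
    chrom2 <- paste0(substr(chrom, 1, s + 49), randomChrom(30),
                     substr(chrom, s + 50, nchar(chrom)))
    m2 <- geneModel("twoEx", "chrR", "+", c(s, s + 80), c(s + 49, e + 30),
                    cdsStart = cdsStart(fix$model),
                    cdsEnd = cdsEnd(fix$model))
    gnm2 <- Biostrings::DNAStringSet(c(chrR = chrom2))
    expect_identical(spliceTranscript(m2, gnm2),
                     spliceTranscript(fix$model, fix$genome))
    v <- applySpliceVariant(m2, gnm2, 1L)
    rep <- translateOrf(v, m2)
    expect_true(grepl("alternative_start", rep$flags) ||
                    grepl("no_start", rep$flags))
})

test_that("random in-frame stop-free indels scale the protein exactly", {
    set.seed(31)
    for (i in 1:40) {
        fix <- singleExonGene(nCodon = sample(40:90, 1L))
        m <- fix$model
        wtAA <- (cdsEnd(m) - cdsStart(m) + 1L) %/% 3L - 1L
        exStart <- IRanges::start(exonRanges(m))
        ## whole-codon deletion inside the CDS (never touching start/stop)
        kCodons <- sample(1:5, 1L)
        cFrom <- sample(2:(wtAA - kCodons), 1L)    # codon index
        txStart <- cdsStart(m) + 3L * (cFrom - 1L)
        gStart <- exStart + txStart - 1L
        ev <- list(category = "indel", refStart = gStart,
                   refEnd = gStart + 3L * kCodons - 1L, alt = "")
        rep <- translateOrf(applyEdit(m, fix$genome, ev), m)
        expect_false(rep$frameshift)
        expect_identical(rep$proteinLengthAA, wtAA - kCodons)
        expect_equal(rep$relativeLength, (wtAA - kCodons) / wtAA)
    }
})

test_that("frameshifting indels terminate where a brute-force codon scan
           says they do", {
    set.seed(53)
    for (i in 1:250) {
        fix <- singleExonGene(nCodon = sample(30:80, 1L))
        m <- fix$model
        exStart <- IRanges::start(exonRanges(m))
        txLen <- transcriptLength(m)
        insLen <- sample(c(1L, 2L, 4L, 5L, 7L, 38L), 1L)
        del <- stats::runif(1) < 0.5
        tpos <- sample((cdsStart(m) + 3L):(cdsEnd(m) - 10L), 1L)
        gpos <- exStart + tpos - 1L
        if (del) {
            dl <- sample(c(1L, 2L, 4L, 5L, 7L), 1L)
            ev <- list(category = "indel", refStart = gpos,
                       refEnd = gpos + dl - 1L, alt = "")
            net <- -dl
        } else {
            ev <- list(category = "indel", refStart = gpos, refEnd = gpos,
                       alt = randomChrom(insLen))
            net <- insLen
        }
        v <- applyEdit(m, fix$genome, ev)
        rep <- translateOrf(v, m)
        expect_identical(rep$frameshift, net %% 3L != 0L)
        ## oracle: brute codon scan of the edited transcript
        br <- bruteTranslateScan(v$transcript, v$cdsStart)
        expect_identical(rep$proteinLengthAA, br$aa)
        if (!br$stopFound) expect_match(rep$flags, "ran_off_end")
    }
})

test_that("applying an edit then translating equals direct translation of a
           hand-built sequence", {
    toy <- toyRefFixture()
    cxc <- toy$models$cxcX
    wt <- spliceTranscript(cxc, toy$genome)
    ## hand-construct the 15-bp deletion: tx positions 453..467 removed
    ev <- list(category = "indel", refStart = 1453L, refEnd = 1467L,
               alt = "")
    v <- applyEdit(cxc, toy$genome, ev)
    hand <- paste0(substr(wt, 1, 452), substr(wt, 468, nchar(wt)))
    expect_identical(v$transcript, hand)
    expect_identical(translateOrf(v, cxc)$proteinLengthAA,
                     bruteTranslateScan(hand, 450L)$aa)
})
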