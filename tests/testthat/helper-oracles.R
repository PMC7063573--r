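## Shared fixtures and independent oracles used across the suite.

randomChrom <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Minimal read-row constructor matching readAlignments() columns.
makeRead <- function(qname, chrom, pos, cigar, seq, sampleId = "s1",
                     flag = 0L, isDuplicate = FALSE,
                     isSupplementary = FALSE) {
    data.frame(queryName = qname, sampleId = sampleId, chrom = chrom,
               pos = as.integer(pos), cigar = cigar, seq = seq,
               flag = as.integer(flag), isDuplicate = isDuplicate,
               isSupplementary = isSupplementary,
               refWidth = cigarRefWidth(cigar), stringsAsFactors = FALSE)
}

## ---- allele-calling oracle ------------------------------------------------
## Character-by-character CIGAR scan building an explicit base-by-base
## reference projection of the read; independent of cigarWalk().

oracleParseCigar <- function(cigar) {
    out <- list()
    num <- ""
    for (i in seq_len(nchar(cigar))) {
        ch <- substr(cigar, i, i)
        if (ch >= "0" && ch <= "9") {
            num <- paste0(num, ch)
        } else {
            out[[length(out) + 1L]] <- list(op = ch, len = as.integer(num))
            num <- ""
        }
    }
    out
}

oracleCallAllele <- function(read, chromSeq, cut, w) {
    lo <- cut - w
    hi <- cut + w
    r <- read$pos
    q <- 1L
    mism <- list()       # refpos -> c(ref, alt)
    comps <- character(0)
    compPos <- integer(0)
    hasIndel <- FALSE
    spliced <- FALSE
    blockId <- 0L
    for (seg in oracleParseCigar(read$cigar)) {
        if (seg$op %in% c("M", "=", "X")) {
            blockId <- blockId + 1L
            for (k in seq_len(seg$len)) {
                rp <- r + k - 1L
                if (rp >= lo && rp <= hi) {
                    rb <- substr(chromSeq, rp, rp)
                    qb <- substr(read$seq, q + k - 1L, q + k - 1L)
                    if (rb != qb) mism[[as.character(rp)]] <- c(rb, qb,
                                                               blockId)
                }
            }
            r <- r + seg$len
            q <- q + seg$len
        } else if (seg$op == "D") {
            if (r + seg$len - 1L >= lo && r <= hi) {
                hasIndel <- TRUE
                comps <- c(comps, sprintf("D:%d-%d", r, r + seg$len - 1L))
                compPos <- c(compPos, r)
            }
            r <- r + seg$len
        } else if (seg$op == "I") {
            if (r - 1L >= lo - 1L && r - 1L <= hi) {
                hasIndel <- TRUE
                comps <- c(comps, sprintf("I:%d:%s", r - 1L,
                                          substr(read$seq, q,
                                                 q + seg$len - 1L)))
                compPos <- c(compPos, r - 1L)
            }
            q <- q + seg$len
        } else if (seg$op == "N") {
            if (r + seg$len - 1L >= lo && r <= hi) spliced <- TRUE
            r <- r + seg$len
        } else if (seg$op == "S") {
            q <- q + seg$len
        }
    }
    if (spliced) return(list(call = "spliced", allele = ""))
    ## merge adjacent mismatch positions into substitution runs
    if (length(mism)) {
        mp <- sort(as.integer(names(mism)))
        blk <- vapply(mp, function(p) mism[[as.character(p)]][3L],
                      character(1))
        brk <- c(TRUE, diff(mp) != 1L | blk[-1L] != blk[-length(blk)])
        runStart <- mp[brk]
        runEnd <- mp[c(brk[-1L], TRUE)]
        for (i in seq_along(runStart)) {
            ps <- seq(runStart[i], runEnd[i])
            refs <- paste(vapply(ps, function(p)
                mism[[as.character(p)]][1L], character(1)), collapse = "")
            alts <- paste(vapply(ps, function(p)
                mism[[as.character(p)]][2L], character(1)), collapse = "")
            comps <- c(comps, sprintf("S:%d:%s>%s", runStart[i], refs, alts))
            compPos <- c(compPos, runStart[i])
        }
    }
    if (!length(comps)) return(list(call = "match", allele = ""))
    o <- order(compPos, comps)
    list(call = if (hasIndel) "indel" else "substitution",
         allele = paste(comps[o], collapse = ";"))
}

## Random aligned read over a chromosome: alternating M segments joined by
## I/D/N connectors, optional soft clips, ~5% M-base mismatches.
randomAlignedRead <- function(chromSeq, qname = "r1") {
    L <- nchar(chromSeq)
    pos <- sample(200:(L - 600), 1L)
    nConn <- sample(0:3, 1L)
    ops <- character(0)
    seqStr <- ""
    r <- pos
    if (runif(1) < 0.3) {
        sl <- sample(1:5, 1L)
        ops <- c(ops, paste0(sl, "S"))
        seqStr <- paste0(seqStr, randomChrom(sl))
    }
    addM <- function() {
        ml <- sample(10:40, 1L)
        bases <- strsplit(substr(chromSeq, r, r + ml - 1L), "")[[1L]]
        flip <- runif(ml) < 0.05
        bases[flip] <- vapply(bases[flip], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        ops <<- c(ops, paste0(ml, "M"))
        seqStr <<- paste0(seqStr, paste(bases, collapse = ""))
        r <<- r + ml
    }
    addM()
    for (i in seq_len(nConn)) {
        conn <- sample(c("I", "D", "N"), 1L)
        if (conn == "I") {
            il <- sample(1:6, 1L)
            ops <- c(ops, paste0(il, "I"))
            seqStr <- paste0(seqStr, randomChrom(il))
        } else if (conn == "D") {
            dl <- sample(1:6, 1L)
            ops <- c(ops, paste0(dl, "D"))
            r <- r + dl
        } else {
            nl <- sample(30:150, 1L)
            ops <- c(ops, paste0(nl, "N"))
            r <- r + nl
        }
        addM()
    }
    if (runif(1) < 0.3) {
        sl <- sample(1:5, 1L)
        ops <- c(ops, paste0(sl, "S"))
        seqStr <- paste0(seqStr, randomChrom(sl))
    }
    makeRead(qname, "chrT", pos, paste(ops, collapse = ""), seqStr)
}

## ---- ORF oracle -----------------------------------------------------------
## Brute-force codon scan from a fixed start position.
bruteTranslateScan <- function(tx, start) {
    stops <- c("TAA", "TAG", "TGA")
    aa <- 0L
    p <- start
    stopFound <- FALSE
    while (p + 2L <= nchar(tx)) {
        if (substr(tx, p, p + 2L) %in% stops) {
            stopFound <- TRUE
            break
        }
        aa <- aa + 1L
        p <- p + 3L
    }
    list(aa = aa, stopFound = stopFound)
}

## Single-exon test gene with a stop-free CDS of `nCodon` codons + stop.
singleExonGene <- function(nCodon = 60L, utr5 = 30L, utr3 = 40L,
                           gid = "rndX") {
    b <- c("A", "C", "G", "T")
    all3 <- apply(expand.grid(b, b, b), 1L, paste, collapse = "")
    safe <- setdiff(all3, c("TAA", "TAG", "TGA"))
    cds <- paste(c("ATG", sample(safe, nCodon - 1L, replace = TRUE), "TAA"),
                 collapse = "")
    chromSeq <- paste0(randomChrom(100L + utr5), cds, randomChrom(utr3))
    exonStart <- 101L
    exonEnd <- 100L + utr5 + nchar(cds) + utr3
    model <- geneModel(gid, "chrR", "+", exonStart, exonEnd,
                       cdsStart = utr5 + 1L,
                       cdsEnd = utr5 + nchar(cds))
    genome <- Biostrings::DNAStringSet(c(chrR = chromSeq))
    list(model = model, genome = genome, cds = cds)
}

## ---- QC oracle ------------------------------------------------------------
bruteQcPass <- function(counts, erccPattern = "^ERCC-", nmads = 3) {
    ercc <- grepl(erccPattern, rownames(counts))
    lib <- colSums(counts)
    ng <- colSums(counts > 0)
    ef <- if (any(ercc)) colSums(counts[ercc, , drop = FALSE]) /
        pmax(lib, 1) else rep(0, ncol(counts))
    th <- function(x) stats::median(x) -
        nmads * stats::mad(x, constant = 1.4826)
    thHi <- function(x) stats::median(x) +
        nmads * stats::mad(x, constant = 1.4826)
    !(lib < th(lib) | ng < th(ng) | ef > thHi(ef))
}

## ---- shared toy reference (built once per test run) -----------------------
toyRefFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- makeToyReference(seed = 1L)
        cache
    }
})
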