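#' Simulation configuration
#'
#' Defines the conditions of a synthetic TARGET-seq-like experiment:
#' per-sample spliced mRNA reads plus genomic-amplicon reads over guide-site
#' regions, with programmable editing alleles, aberrant splicing, sequencing
#' error, library-size variation and spike-in fractions. A given
#' configuration (including its seed) fixes the output byte-for-byte.
#'
#' @param seed integer RNG seed; fixes the full output.
#' @param nSamples number of samples (cells/larvae).
#' @param depthMrna expected spliced mRNA reads per gene per sample
#'   (scalar, or one value per sample).
#' @param depthAmplicon expected genomic-amplicon reads per guide site per
#'   sample (scalar or per-sample).
#' @param editedFraction either a single number -- the per-sample
#'   probability of carrying an edit, with the edited site chosen uniformly
#'   among the simulated sites ("both sgRNAs contributing") -- or a named
#'   per-site vector of independent per-site editing probabilities (the
#'   bulk mosaic setting).
#' @param alleleSpec named list (by site name) of allele descriptions:
#'   \code{list(type = "deletion"|"insertion"|"substitution", len = n)} or
#'   \code{list(type = "large_deletion", partner = "<site name>")}.
#'   Unlisted sites default to \code{deletion(5)}.
#' @param aberrantSpliceRatio molecular fraction of exon-skipping
#'   transcripts, in \code{[0, 1]}, for genes named in \code{skipSpec}.
#' @param skipSpec named list (by gene id) of exon indices skipped by the
#'   aberrant splice form.
#' @param seqErrorRate per-base substitution error rate in \code{[0, 0.05]};
#'   errors never fall on allele positions, inserted bases, or (for edited
#'   reads) inside the guide window.
#' @param librarySizeLogSD sd of the log-normal per-sample library-size
#'   factor (meanlog 0).
#' @param erccFraction expected fraction of the mRNA library drawn from
#'   spike-in genes, in \code{[0, 1)}.
#' @param readLength read length in bp (75, the platform's read length).
#' @param forcedEdited optional logical matrix (nSamples x sites, column
#'   names = site names) that fixes the editing truth instead of random
#'   draws.
#' @return a validated configuration list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nSamples = 200L, depthMrna = 20,
                      depthAmplicon = 30, editedFraction = 0.5,
                      alleleSpec = NULL, aberrantSpliceRatio = 0.2,
                      skipSpec = list(cxcX = 2L, semX = 2L:3L),
                      seqErrorRate = 0, librarySizeLogSD = 0.3,
                      erccFraction = 0.05, readLength = 75L,
                      forcedEdited = NULL) {
    stopifnot(nSamples >= 0L, readLength >= 30L)
    if (any(editedFraction < 0 | editedFraction > 1))
        stop("editedFraction must be in [0, 1]")
    if (aberrantSpliceRatio < 0 || aberrantSpliceRatio > 1)
        stop("aberrantSpliceRatio must be in [0, 1]")
    if (seqErrorRate < 0 || seqErrorRate > 0.05)
        stop("seqErrorRate must be in [0, 0.05]")
    if (erccFraction < 0 || erccFraction >= 1)
        stop("erccFraction must be in [0, 1)")
    if (librarySizeLogSD < 0) stop("librarySizeLogSD must be >= 0")
    structure(list(seed = as.integer(seed), nSamples = as.integer(nSamples),
                   depthMrna = depthMrna, depthAmplicon = depthAmplicon,
                   editedFraction = editedFraction, alleleSpec = alleleSpec,
                   aberrantSpliceRatio = aberrantSpliceRatio,
                   skipSpec = skipSpec, seqErrorRate = seqErrorRate,
                   librarySizeLogSD = librarySizeLogSD,
                   erccFraction = erccFraction,
                   readLength = as.integer(readLength),
                   forcedEdited = forcedEdited),
              class = "SimConfig")
}

codonAlphabet <- function() {
    b <- c("A", "C", "G", "T")
    all3 <- apply(expand.grid(b, b, b), 1L, paste, collapse = "")
    setdiff(all3, c("TAA", "TAG", "TGA"))
}

## Implant a stop-free CDS (ATG ... TAA) into a chromosome at the genomic
## positions of the model's CDS transcript interval.
implantCds <- function(chromSeq, model) {
    nCodon <- (cdsEnd(model) - cdsStart(model) + 1L) %/% 3L
    codons <- c("ATG", sample(codonAlphabet(), nCodon - 2L, replace = TRUE),
                "TAA")
    cdsSeq <- strsplit(paste(codons, collapse = ""), "")[[1L]]
    gpos <- transcriptToGenomic(model, seq(cdsStart(model), cdsEnd(model)))
    chars <- strsplit(chromSeq, "")[[1L]]
    if (geneStrand(model) == "-")
        cdsSeq <- rev(unname(compBase[cdsSeq]))
    chars[sort(gpos)] <- if (geneStrand(model) == "-") cdsSeq else
        cdsSeq[order(order(gpos))]
    paste(chars, collapse = "")
}

#' Build the packaged toy reference
#'
#' Emits a small genome with (i) gene \code{semX}: 10 exons on a ~18 kb
#' chromosome, coding for 791 aa, with guide sites in exons 2 and 10 more
#' than 10 kb apart; (ii) gene \code{cxcX}: 3 exons with exon 2 exactly
#' 118 bp, a 1342 bp spliced transcript (1224 bp without exon 2) and a CDS
#' encoding a 99 aa protein, with guide sites in exon 1 (near the start of
#' the coding sequence) and exon 3; and (iii) eight single-exon ERCC-like
#' spike genes.
#'
#' @param seed RNG seed for the background sequence and CDS codons.
#' @return a list with \code{genome} (DNAStringSet), \code{models} (named
#'   list of \code{GeneModel}s) and \code{sites} (guide-site data.frame).
#' @export
makeToyReference <- function(seed = 1L) {
    set.seed(seed)
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    ## semX: 10 exons, CDS 2376 nt = 791 aa + stop
    semStarts <- c(1001L, 2801L, 4501L, 6251L, 7991L, 9751L, 11501L,
                   13231L, 14981L, 16701L)
    semWidths <- c(300L, 200L, 250L, 240L, 260L, 250L, 230L, 250L, 220L,
                   400L)
    semEnds <- semStarts + semWidths - 1L
    semX <- geneModel("semX", "chrS", "+", semStarts, semEnds,
                      cdsStart = 101L, cdsEnd = 2476L)
    chrS <- rand(18000L)
    chrS <- implantCds(chrS, semX)
    ## cxcX: exons 500/118/724 -> 1342 nt spliced, 1224 nt without exon 2;
    ## CDS 300 nt = 99 aa + stop starting inside exon 1
    cxcX <- geneModel("cxcX", "chrC", "+",
                      c(1001L, 2001L, 3001L), c(1500L, 2118L, 3724L),
                      cdsStart = 450L, cdsEnd = 749L)
    chrC <- rand(6000L)
    chrC <- implantCds(chrC, cxcX)
    ## spike-in genes, single exon, 60 aa toy ORFs
    nErcc <- 8L
    chrE <- rand(8100L)
    models <- list(semX = semX, cxcX = cxcX)
    for (i in seq_len(nErcc)) {
        gid <- sprintf("ERCC-%04d", i)
        m <- geneModel(gid, "chrE", "+", (i - 1L) * 1000L + 101L,
                       (i - 1L) * 1000L + 700L, cdsStart = 51L,
                       cdsEnd = 233L)
        chrE <- implantCds(chrE, m)
        models[[gid]] <- m
    }
    genome <- Biostrings::DNAStringSet(c(chrS = chrS, chrC = chrC,
                                         chrE = chrE))
    sites <- data.frame(
        name = c("semX_sg1", "semX_sg10", "cxcX_sg1", "cxcX_sg3"),
        chrom = c("chrS", "chrS", "chrC", "chrC"),
        cut_pos = c(2900L, 16800L, 1470L, 3082L),
        window = 15L, stringsAsFactors = FALSE)
    list(genome = genome, models = models, sites = sites)
}

defaultAlleleSpec <- list(
    semX_sg1 = list(type = "deletion", len = 7L),
    semX_sg10 = list(type = "insertion", len = 4L),
    cxcX_sg1 = list(type = "deletion", len = 15L),
    cxcX_sg3 = list(type = "substitution", len = 2L))

## ---- haplotype block maps -------------------------------------------------

## Blocks: data.frame(type "M"/"I", gstart, gend, bases). Gaps between M
## blocks become N (intron) unless fully inside a recorded deletion span.
exonBlockMap <- function(model, skip = integer(0)) {
    ex <- exonRanges(model)
    idx <- exonIndex(model)
    keep <- !(idx %in% skip)
    data.frame(type = "M", gstart = IRanges::start(ex)[keep],
               gend = IRanges::end(ex)[keep], bases = "",
               stringsAsFactors = FALSE)
}

ampliconBlockMap <- function(cut, chromLen, pad = 150L) {
    data.frame(type = "M", gstart = max(1L, cut - pad),
               gend = min(chromLen, cut + pad), bases = "",
               stringsAsFactors = FALSE)
}

## Apply a small allele (deletion/insertion/substitution at `cut`) to a
## block map. Returns list(blocks, delSpans, subs).
applyAlleleToBlocks <- function(blocks, allele, cut) {
    delSpans <- matrix(integer(0), ncol = 2L)
    subs <- list(pos = integer(0), base = character(0))
    if (is.null(allele)) {
        return(list(blocks = blocks, delSpans = delSpans, subs = subs))
    }
    type <- allele$type
    if (type == "deletion") {
        s <- cut
        e <- cut + allele$len - 1L
        out <- list()
        for (i in seq_len(nrow(blocks))) {
            b <- blocks[i, ]
            if (b$type != "M" || b$gend < s || b$gstart > e) {
                out[[length(out) + 1L]] <- b
                next
            }
            if (b$gstart < s)
                out[[length(out) + 1L]] <-
                    data.frame(type = "M", gstart = b$gstart, gend = s - 1L,
                               bases = "", stringsAsFactors = FALSE)
            if (b$gend > e)
                out[[length(out) + 1L]] <-
                    data.frame(type = "M", gstart = e + 1L, gend = b$gend,
                               bases = "", stringsAsFactors = FALSE)
        }
        blocks <- do.call(rbind, out)
        delSpans <- rbind(delSpans, c(s, e))
    } else if (type == "insertion") {
        out <- list()
        for (i in seq_len(nrow(blocks))) {
            b <- blocks[i, ]
            if (b$type == "M" && cut >= b$gstart && cut < b$gend) {
                out[[length(out) + 1L]] <-
                    data.frame(type = "M", gstart = b$gstart, gend = cut,
                               bases = "", stringsAsFactors = FALSE)
                out[[length(out) + 1L]] <-
                    data.frame(type = "I", gstart = NA_integer_,
                               gend = NA_integer_, bases = allele$bases,
                               stringsAsFactors = FALSE)
                out[[length(out) + 1L]] <-
                    data.frame(type = "M", gstart = cut + 1L, gend = b$gend,
                               bases = "", stringsAsFactors = FALSE)
            } else {
                out[[length(out) + 1L]] <- b
            }
        }
        blocks <- do.call(rbind, out)
    } else if (type == "substitution") {
        subs <- list(pos = seq(cut, cut + allele$len - 1L),
                     base = strsplit(allele$bases, "")[[1L]])
    } else {
        stop("unsupported allele type for block map: ", type)
    }
    list(blocks = blocks, delSpans = delSpans, subs = subs)
}

## Expand a block map into per-transcript-position arrays.
txIndexFromBlocks <- function(bmap, chromSeq) {
    chars <- character(0)
    op <- character(0)
    gp <- integer(0)
    blocks <- bmap$blocks
    for (i in seq_len(nrow(blocks))) {
        b <- blocks[i, ]
        if (b$type == "M") {
            seg <- strsplit(substring(chromSeq, b$gstart, b$gend), "")[[1L]]
            pos <- seq(b$gstart, b$gend)
            hit <- match(bmap$subs$pos, pos)
            ok <- !is.na(hit)
            if (any(ok)) seg[hit[ok]] <- bmap$subs$base[ok]
            chars <- c(chars, seg)
            op <- c(op, rep("M", length(seg)))
            gp <- c(gp, pos)
        } else {
            seg <- strsplit(b$bases, "")[[1L]]
            chars <- c(chars, seg)
            op <- c(op, rep("I", length(seg)))
            gp <- c(gp, rep(NA_integer_, length(seg)))
        }
    }
    list(chars = chars, op = op, gp = gp, n = length(chars),
         delSpans = bmap$delSpans)
}

gapIsDeletion <- function(lo, hi, delSpans) {
    if (nrow(delSpans) == 0L) return(FALSE)
    any(delSpans[, 1L] <= lo & delSpans[, 2L] >= hi)
}

## Build pos/cigar/seq for the read covering transcript slice [s, s+len-1].
## Returns NULL when the slice does not start and end on M positions.
emitRead <- function(idx, s, len) {
    e <- s + len - 1L
    if (e > idx$n || idx$op[s] != "M" || idx$op[e] != "M") return(NULL)
    op <- idx$op[s:e]
    gp <- idx$gp[s:e]
    pieces <- character(0)
    gaps <- NULL
    lastG <- NA_integer_
    i <- 1L
    n <- len
    while (i <= n) {
        if (op[i] == "I") {
            j <- i
            while (j < n && op[j + 1L] == "I") j <- j + 1L
            pieces <- c(pieces, paste0(j - i + 1L, "I"))
            i <- j + 1L
            next
        }
        j <- i
        while (j < n && op[j + 1L] == "M" && gp[j + 1L] == gp[j] + 1L)
            j <- j + 1L
        if (!is.na(lastG)) {
            gapLen <- gp[i] - lastG - 1L
            if (gapLen > 0L) {
                gapIsDel <- gapIsDeletion(lastG + 1L, gp[i] - 1L,
                                          idx$delSpans)
                pieces <- c(pieces, paste0(gapLen,
                                           if (gapIsDel) "D" else "N"))
                if (!gapIsDel)
                    gaps <- rbind(gaps, c(lastG, gp[i]))
            }
        }
        pieces <- c(pieces, paste0(j - i + 1L, "M"))
        lastG <- gp[j]
        i <- j + 1L
    }
    list(pos = gp[which(op == "M")[1L]],
         cigar = paste(pieces, collapse = ""),
         seq = paste(idx$chars[s:e], collapse = ""),
         gaps = gaps)                    # N gaps as (donorEnd, acceptorStart)
}

injectErrors <- function(seqStr, rate, protect = logical(nchar(seqStr))) {
    if (rate <= 0) return(seqStr)
    chars <- strsplit(seqStr, "")[[1L]]
    hit <- which(stats::runif(length(chars)) < rate & !protect)
    for (i in hit) {
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
}

## ---- main generator -------------------------------------------------------

#' Simulate per-sample aligned reads with known ground truth
#'
#' For every sample, emits spliced mRNA reads for each gene
#' (junction-spanning reads carry \code{N} CIGAR ops; reads are sampled
#' length-proportionally from the configured mix of full-length and
#' exon-skipping transcripts), genomic-amplicon reads over each guide site
#' (contiguous, no \code{N} ops), and spike-in reads. Samples drawn as
#' edited carry their site's configured allele in both amplicon and mRNA
#' reads overlapping the site; large-deletion alleles are emitted as split
#' primary/supplementary alignment pairs flanking the two cuts (and
#' suppress the gene's mRNA for that sample). Base errors are substitutions
#' only and never coincide with allele positions. The truth manifest
#' records every draw.
#'
#' @param config a \code{\link{simConfig}}.
#' @param ref,models,sites a reference as returned by
#'   \code{\link{makeToyReference}} (genome, gene models, guide-site table;
#'   sites may be a subset).
#' @param outDir optional directory; when given, writes
#'   \code{reference.fa}, \code{annotation.gff3}, \code{sites.tsv}, one
#'   coordinate-sorted SAM per sample and the truth manifest, all
#'   byte-deterministically.
#' @return a list with \code{reads} (data.frame of all emitted reads),
#'   \code{truth} (list: \code{editing} data.frame of nSamples x nSites
#'   rows; \code{expression} data.frame of per-sample per-gene read
#'   bookkeeping) and \code{sampleIds}.
#' @export
simulateReads <- function(config, ref, models, sites, outDir = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$nSamples
    readLen <- config$readLength
    sampleIds <- sprintf("cell%03d", seq_len(n))
    chromStr <- lapply(as.character(ref), identity)
    depthM <- rep_len(config$depthMrna, n)
    depthA <- rep_len(config$depthAmplicon, n)
    perSiteEF <- length(config$editedFraction) > 1L ||
        !is.null(names(config$editedFraction))
    if (perSiteEF && !all(sites$name %in% names(config$editedFraction)))
        stop("per-site editedFraction must name every simulated site")
    alleleSpec <- config$alleleSpec
    if (is.null(alleleSpec)) alleleSpec <- defaultAlleleSpec
    for (s in sites$name) {
        if (is.null(alleleSpec[[s]]))
            alleleSpec[[s]] <- list(type = "deletion", len = 5L)
    }
    validateAlleles(alleleSpec, sites, readLen)
    geneIds <- names(models)
    mainGenes <- geneIds[!grepl("^ERCC-", geneIds)]
    erccGenes <- setdiff(geneIds, mainGenes)
    f <- config$erccFraction
    erccPerGene <- if (length(erccGenes)) {
        f / (1 - f) * length(mainGenes) / length(erccGenes)
    } else 0
    siteGene <- siteToGene(sites, models)
    ## canonical junctions per gene (generator bookkeeping)
    canonicalKeys <- lapply(models, function(m) {
        ex <- exonRanges(m)
        k <- length(ex)
        if (k < 2L) return(character(0))
        paste(IRanges::end(ex)[-k], IRanges::start(ex)[-1L])
    })
    txCache <- list()                    # wildtype/skip maps are shared
    allReads <- list()
    editingRows <- list()
    exprRows <- list()
    readCounter <- 0L
    for (si in seq_len(n)) {
        sid <- sampleIds[si]
        libF <- if (config$librarySizeLogSD > 0)
            stats::rlnorm(1L, 0, config$librarySizeLogSD) else 1
        ## ---- editing truth ----
        edited <- drawEditing(config, sites, si, perSiteEF)
        alleles <- list()
        ldPairs <- list()
        for (k in which(edited)) {
            sn <- sites$name[k]
            spec <- alleleSpec[[sn]]
            if (spec$type == "large_deletion") {
                partner <- spec$partner
                edited[match(partner, sites$name)] <- TRUE
                key <- paste(sort(c(sn, partner)), collapse = "+")
                ldPairs[[key]] <- sort(c(sites$cut_pos[k],
                                         sites$cut_pos[match(partner,
                                                             sites$name)]))
                alleles[[sn]] <- spec
                alleles[[partner]] <- spec
            } else if (is.null(alleles[[sn]])) {
                alleles[[sn]] <- instantiateAllele(
                    spec, chromStr[[sites$chrom[k]]], sites$cut_pos[k])
            }
        }
        for (k in seq_len(nrow(sites))) {
            sn <- sites$name[k]
            a <- alleles[[sn]]
            editingRows[[length(editingRows) + 1L]] <- data.frame(
                sampleId = sid, site = sn, edited = edited[k],
                category = if (!edited[k]) "" else
                    if (a$type == "large_deletion") "large_deletion" else
                    if (a$type == "substitution") "substitution" else "indel",
                alleleType = if (edited[k]) a$type else "",
                alleleLen = if (edited[k] && !is.null(a$len)) a$len else 0L,
                alleleBases = if (edited[k] && !is.null(a$bases)) a$bases
                    else "", stringsAsFactors = FALSE)
        }
        ## genes silenced by a large deletion in this sample
        ldGenes <- unique(unlist(lapply(names(ldPairs), function(key) {
            unname(siteGene[strsplit(key, "+", fixed = TRUE)[[1L]]])
        })))
        sampleReads <- list()
        ## ---- mRNA + spike reads ----
        for (g in geneIds) {
            model <- models[[g]]
            depth <- if (g %in% erccGenes) depthM[si] * erccPerGene
                     else depthM[si]
            nr <- stats::rpois(1L, depth * libF)
            aberrant <- 0L
            junctionReads <- 0L
            aberrantReads <- 0L
            if (!is.na(match(g, ldGenes))) nr <- 0L
            if (nr > 0L) {
                res <- emitMrnaReads(model, g, nr, config, sites, alleles,
                                     chromStr, txCache, canonicalKeys[[g]],
                                     readLen, sid, readCounter)
                txCache <- res$txCache
                readCounter <- res$readCounter
                sampleReads <- c(sampleReads, res$reads)
                junctionReads <- res$junctionReads
                aberrantReads <- res$aberrantReads
                nr <- res$nEmitted
            }
            exprRows[[length(exprRows) + 1L]] <- data.frame(
                sampleId = sid, gene = g, mrnaReads = nr,
                junctionReads = junctionReads,
                aberrantJunctionReads = aberrantReads,
                stringsAsFactors = FALSE)
        }
        ## ---- amplicon reads ----
        emittedLd <- character(0)
        for (k in seq_len(nrow(sites))) {
            sn <- sites$name[k]
            a <- alleles[[sn]]
            na <- stats::rpois(1L, depthA[si])
            if (na == 0L) next
            if (!is.null(a) && a$type == "large_deletion") {
                key <- names(ldPairs)[vapply(names(ldPairs), function(kk) {
                    sn %in% strsplit(kk, "+", fixed = TRUE)[[1L]]
                }, logical(1))][1L]
                if (key %in% emittedLd) next
                emittedLd <- c(emittedLd, key)
                cuts <- ldPairs[[key]]
                for (r in seq_len(na)) {
                    readCounter <- readCounter + 1L
                    qn <- sprintf("%s_ld%06d", sid, readCounter)
                    aLen <- sample(25:45, 1L)
                    bLen <- readLen - aLen
                    ch <- sites$chrom[k]
                    seqStr <- paste0(
                        substring(chromStr[[ch]], cuts[1L] - aLen + 1L,
                                  cuts[1L]),
                        substring(chromStr[[ch]], cuts[2L] + 1L,
                                  cuts[2L] + bLen))
                    sampleReads[[length(sampleReads) + 1L]] <- data.frame(
                        queryName = qn, sampleId = sid, chrom = ch,
                        pos = cuts[1L] - aLen + 1L,
                        cigar = sprintf("%dM%dS", aLen, bLen), seq = seqStr,
                        flag = 0L, isDuplicate = FALSE,
                        isSupplementary = FALSE, stringsAsFactors = FALSE)
                    sampleReads[[length(sampleReads) + 1L]] <- data.frame(
                        queryName = qn, sampleId = sid, chrom = ch,
                        pos = cuts[2L] + 1L,
                        cigar = sprintf("%dS%dM", aLen, bLen), seq = seqStr,
                        flag = 2048L, isDuplicate = FALSE,
                        isSupplementary = TRUE, stringsAsFactors = FALSE)
                }
                next
            }
            res <- emitAmpliconReads(sites[k, ], a, na, config, chromStr,
                                     readLen, sid, readCounter)
            readCounter <- res$readCounter
            sampleReads <- c(sampleReads, res$reads)
        }
        allReads[[si]] <- if (length(sampleReads))
            do.call(rbind, sampleReads) else emptyReads()[, 1:9]
    }
    reads <- do.call(rbind, c(allReads, list(emptyReads()[, 1:9])))
    rownames(reads) <- NULL
    if (nrow(reads)) {
        reads$refWidth <- vapply(reads$cigar, cigarRefWidth, integer(1),
                                 USE.NAMES = FALSE)
    } else {
        reads$refWidth <- integer(0)
    }
    truth <- list(
        editing = if (length(editingRows)) do.call(rbind, editingRows) else
            data.frame(),
        expression = if (length(exprRows)) do.call(rbind, exprRows) else
            data.frame())
    out <- list(reads = reads, truth = truth, sampleIds = sampleIds)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeGenome(ref, file.path(outDir, "reference.fa"))
        writeGeneModels(models, file.path(outDir, "annotation.gff3"))
        writeGuideSites(sites, file.path(outDir, "sites.tsv"))
        for (sid in sampleIds) {
            writeSam(reads[reads$sampleId == sid, , drop = FALSE], ref,
                     file.path(outDir, paste0(sid, ".sam")))
        }
        writeTruthManifest(truth, outDir)
        out$dir <- outDir
    }
    out
}

siteToGene <- function(sites, models) {
    setNames(vapply(seq_len(nrow(sites)), function(k) {
        for (g in names(models)) {
            m <- models[[g]]
            ex <- exonRanges(m)
            if (geneChrom(m) == sites$chrom[k] &&
                any(sites$cut_pos[k] >= IRanges::start(ex) &
                    sites$cut_pos[k] <= IRanges::end(ex))) return(g)
        }
        NA_character_
    }, character(1)), sites$name)
}

drawEditing <- function(config, sites, si, perSiteEF) {
    if (!is.null(config$forcedEdited)) {
        fe <- config$forcedEdited
        return(as.logical(fe[si, sites$name]))
    }
    if (perSiteEF) {
        ef <- config$editedFraction[sites$name]
        stats::runif(nrow(sites)) < ef
    } else {
        edited <- rep(FALSE, nrow(sites))
        if (stats::runif(1L) < config$editedFraction) {
            edited[sample.int(nrow(sites), 1L)] <- TRUE
        }
        edited
    }
}

instantiateAllele <- function(spec, chromSeq, cut) {
    a <- spec
    if (spec$type == "insertion") {
        a$bases <- paste(sample(c("A", "C", "G", "T"), spec$len,
                                replace = TRUE), collapse = "")
    } else if (spec$type == "substitution") {
        a$bases <- substitutionBases(chromSeq, cut, spec$len)
    } else {
        a$bases <- ""
    }
    a
}

validateAlleles <- function(alleleSpec, sites, readLen) {
    for (k in seq_len(nrow(sites))) {
        spec <- alleleSpec[[sites$name[k]]]
        w <- sites$window[k]
        if (spec$type == "large_deletion") {
            if (is.null(spec$partner) || !spec$partner %in% sites$name)
                stop("large_deletion allele needs a partner site")
            next
        }
        if (spec$len >= readLen)
            stop("allele longer than read length at site ", sites$name[k])
        if (spec$type == "insertion" && spec$len > readLen - 2L * w - 2L)
            stop("insertion too long to leave window-covering reads at ",
                 sites$name[k])
        if (spec$type == "deletion" && spec$len > w)
            stop("deletion longer than the calling window at ",
                 sites$name[k])
        if (spec$type == "substitution" && spec$len > w + 1L)
            stop("substitution longer than the calling window at ",
                 sites$name[k])
    }
    invisible(TRUE)
}

## substitution bases differing from the reference at [cut, cut+len-1]
substitutionBases <- function(chromSeq, cut, len) {
    refB <- strsplit(substring(chromSeq, cut, cut + len - 1L), "")[[1L]]
    paste(vapply(refB, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1)), collapse = "")
}

emitMrnaReads <- function(model, g, nr, config, sites, alleles, chromStr,
                          txCache, canonicalKey, readLen, sid,
                          readCounter) {
    ch <- geneChrom(model)
    skip <- config$skipSpec[[g]]
    hasSkip <- !is.null(skip) && config$aberrantSpliceRatio > 0
    ## site alleles on this gene's chromosome, applied to mRNA
    geneAlleles <- list()
    for (k in seq_len(nrow(sites))) {
        a <- alleles[[sites$name[k]]]
        if (is.null(a) || sites$chrom[k] != ch) next
        if (a$type == "large_deletion") next
        geneAlleles[[sites$name[k]]] <- list(allele = a,
                                             cut = sites$cut_pos[k])
    }
    buildIdx <- function(skipExons) {
        bmap <- list(blocks = exonBlockMap(model, skipExons),
                     delSpans = matrix(integer(0), ncol = 2L),
                     subs = list(pos = integer(0), base = character(0)))
        for (ga in geneAlleles) {
            res <- applyAlleleToBlocks(bmap$blocks, ga$allele, ga$cut)
            bmap$blocks <- res$blocks
            bmap$delSpans <- rbind(bmap$delSpans, res$delSpans)
            bmap$subs <- list(pos = c(bmap$subs$pos, res$subs$pos),
                              base = c(bmap$subs$base, res$subs$base))
        }
        txIndexFromBlocks(bmap, chromStr[[ch]])
    }
    cacheKey <- function(skipExons) {
        paste0(g, "|", paste(skipExons, collapse = ","), "|",
               paste(vapply(geneAlleles, function(ga)
                   paste0(ga$cut, ga$allele$type, ga$allele$len,
                          ga$allele$bases), character(1)), collapse = ";"))
    }
    getIdx <- function(skipExons) {
        key <- cacheKey(skipExons)
        if (is.null(txCache[[key]])) txCache[[key]] <<- buildIdx(skipExons)
        txCache[[key]]
    }
    idxFull <- getIdx(integer(0))
    idxSkip <- if (hasSkip) getIdx(skip) else NULL
    ## length-proportional isoform sampling
    sFull <- max(0L, idxFull$n - readLen + 1L)
    sSkip <- if (hasSkip) max(0L, idxSkip$n - readLen + 1L) else 0L
    r <- if (hasSkip) config$aberrantSpliceRatio else 0
    pSkip <- if (hasSkip && (r * sSkip + (1 - r) * sFull) > 0)
        r * sSkip / (r * sSkip + (1 - r) * sFull) else 0
    ## protected positions for error injection (allele windows)
    protectG <- unlist(lapply(geneAlleles, function(ga) {
        seq(ga$cut - 20L, ga$cut + 20L)
    }))
    qn <- pos <- cig <- sq <- character(0)
    posv <- integer(0)
    junctionReads <- 0L
    aberrantReads <- 0L
    nEmitted <- 0L
    for (rIdx in seq_len(nr)) {
        useSkip <- hasSkip && stats::runif(1L) < pSkip
        idx <- if (useSkip) idxSkip else idxFull
        nStarts <- idx$n - readLen + 1L
        if (nStarts < 1L) next
        rec <- NULL
        for (att in 1:20) {                 # resample starts landing on I/gap
            s <- sample.int(nStarts, 1L)
            rec <- emitRead(idx, s, readLen)
            if (!is.null(rec)) break
        }
        if (is.null(rec)) next
        readCounter <- readCounter + 1L
        seqStr <- rec$seq
        if (config$seqErrorRate > 0) {
            e <- s + readLen - 1L
            protect <- idx$op[s:e] == "I" |
                (!is.na(idx$gp[s:e]) & idx$gp[s:e] %in% protectG)
            seqStr <- injectErrors(seqStr, config$seqErrorRate, protect)
        }
        qn <- c(qn, sprintf("%s_m%06d", sid, readCounter))
        posv <- c(posv, rec$pos)
        cig <- c(cig, rec$cigar)
        sq <- c(sq, seqStr)
        nEmitted <- nEmitted + 1L
        if (!is.null(rec$gaps)) {
            junctionReads <- junctionReads + 1L
            keys <- paste(rec$gaps[, 1L], rec$gaps[, 2L])
            if (any(!keys %in% canonicalKey))
                aberrantReads <- aberrantReads + 1L
        }
    }
    reads <- if (length(qn)) list(data.frame(
        queryName = qn, sampleId = sid, chrom = ch, pos = posv,
        cigar = cig, seq = sq, flag = 0L, isDuplicate = FALSE,
        isSupplementary = FALSE, stringsAsFactors = FALSE)) else list()
    list(reads = reads, txCache = txCache, readCounter = readCounter,
         junctionReads = junctionReads, aberrantReads = aberrantReads,
         nEmitted = nEmitted)
}

emitAmpliconReads <- function(site, allele, na, config, chromStr, readLen,
                              sid, readCounter) {
    ch <- site$chrom
    cut <- site$cut_pos
    w <- site$window
    chromLen <- nchar(chromStr[[ch]])
    bmap0 <- list(blocks = ampliconBlockMap(cut, chromLen),
                  delSpans = matrix(integer(0), ncol = 2L),
                  subs = list(pos = integer(0), base = character(0)))
    if (!is.null(allele)) {
        res <- applyAlleleToBlocks(bmap0$blocks, allele, cut)
        bmap0$blocks <- res$blocks
        bmap0$delSpans <- res$delSpans
        bmap0$subs <- res$subs
    }
    idx <- txIndexFromBlocks(bmap0, chromStr[[ch]])
    tLow <- which(!is.na(idx$gp) & idx$gp == cut - w)
    tHigh <- which(!is.na(idx$gp) & idx$gp == cut + w)
    if (length(tLow) != 1L || length(tHigh) != 1L)
        stop("internal: window boundary missing from amplicon map")
    sMin <- max(1L, tHigh - readLen + 1L)
    sMax <- min(tLow, idx$n - readLen + 1L)
    if (sMin > sMax) stop("allele too long for window-covering reads")
    starts <- sMin:sMax
    ok <- idx$op[starts] == "M" & idx$op[starts + readLen - 1L] == "M"
    starts <- starts[ok]
    protect <- !is.na(idx$gp) & idx$gp >= cut - w - 5L & idx$gp <= cut + w + 5L
    qn <- cig <- sq <- character(0)
    posv <- integer(0)
    for (r in seq_len(na)) {
        s <- starts[sample.int(length(starts), 1L)]
        rec <- emitRead(idx, s, readLen)
        readCounter <- readCounter + 1L
        seqStr <- rec$seq
        if (config$seqErrorRate > 0) {
            e <- s + readLen - 1L
            pr <- if (!is.null(allele)) (idx$op[s:e] == "I") | protect[s:e]
                  else rep(FALSE, readLen)
            seqStr <- injectErrors(seqStr, config$seqErrorRate, pr)
        }
        qn <- c(qn, sprintf("%s_a%06d", sid, readCounter))
        posv <- c(posv, rec$pos)
        cig <- c(cig, rec$cigar)
        sq <- c(sq, seqStr)
    }
    reads <- if (length(qn)) list(data.frame(
        queryName = qn, sampleId = sid, chrom = ch, pos = posv,
        cigar = cig, seq = sq, flag = 0L, isDuplicate = FALSE,
        isSupplementary = FALSE, stringsAsFactors = FALSE)) else list()
    list(reads = reads, readCounter = readCounter)
}

#' Write / read the ground-truth manifest
#'
#' The editing manifest holds one row per sample x site (lossless TSV);
#' the expression bookkeeping is written alongside.
#'
#' @param truth the \code{truth} element of a \code{\link{simulateReads}}
#'   result.
#' @param dir output directory.
#' @return the manifest path (write) or the truth list (read).
#' @export
writeTruthManifest <- function(truth, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, "truth_editing.tsv")
    utils::write.table(truth$editing, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth$expression,
                       file.path(dir, "truth_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(p)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(dir) {
    ed <- utils::read.delim(file.path(dir, "truth_editing.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(sampleId = "character",
                                           site = "character",
                                           edited = "logical",
                                           category = "character",
                                           alleleType = "character",
                                           alleleLen = "integer",
                                           alleleBases = "character"))
    ed[is.na(ed)] <- ""
    ex <- utils::read.delim(file.path(dir, "truth_expression.tsv"),
                            stringsAsFactors = FALSE)
    list(editing = ed, expression = ex)
}
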