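## Per-read splice gaps: one row per N op of every read overlapping the gene.
readGaps <- function(reads, model) {
    rr <- reads[reads$chrom == geneChrom(model) & !reads$isSupplementary, ,
                drop = FALSE]
    ex <- exonRanges(model)
    gLo <- min(IRanges::start(ex))
    gHi <- max(IRanges::end(ex))
    out <- list()
    hasN <- grepl("N", rr$cigar, fixed = TRUE)
    for (j in which(hasN)) {
        walk <- cigarWalk(rr$pos[j], rr$cigar[j])
        ns <- which(walk$op == "N")
        for (i in ns) {
            donorEnd <- walk$refStart[i] - 1L
            acceptorStart <- walk$refEnd[i] + 1L
            if (acceptorStart < gLo || donorEnd > gHi) next   # off the gene
            out[[length(out) + 1L]] <- data.frame(
                readIndex = j, sampleId = rr$sampleId[j],
                chrom = rr$chrom[j], donorEnd = donorEnd,
                acceptorStart = acceptorStart, stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) {
        return(data.frame(readIndex = integer(0), sampleId = character(0),
                          chrom = character(0), donorEnd = integer(0),
                          acceptorStart = integer(0),
                          stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
}

#' Extract splice junctions supported by spliced alignments
#'
#' Every \code{N} CIGAR op overlapping the gene yields one junction keyed by
#' (\code{donorEnd}, \code{acceptorStart}): the last exonic base before the
#' gap and the first exonic base after it (1-based). Read support is
#' aggregated across reads; a read with several \code{N} ops contributes one
#' count per gap.
#'
#' @param reads a reads data.frame (see \code{\link{readAlignments}}).
#' @param model the gene's \code{\linkS4class{GeneModel}}.
#' @return a data.frame with columns \code{chrom}, \code{donorEnd},
#'   \code{acceptorStart}, \code{readCount}, sorted by coordinates.
#' @export
extractJunctions <- function(reads, model) {
    gaps <- readGaps(reads, model)
    if (nrow(gaps) == 0L) {
        return(data.frame(chrom = character(0), donorEnd = integer(0),
                          acceptorStart = integer(0), readCount = integer(0),
                          stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(list(readCount = rep(1L, nrow(gaps))),
                            by = gaps[c("chrom", "donorEnd",
                                        "acceptorStart")], FUN = sum)
    agg <- agg[order(agg$donorEnd, agg$acceptorStart), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

#' Flag junctions as canonical or aberrant
#'
#' A junction is canonical iff its (donor, acceptor) pair equals the
#' boundary of two genomically consecutive annotated exons (exact matching;
#' \code{tolerance} bp of slack may be allowed but defaults to 0).
#' Everything else -- multi-exon skips and cryptic intronic donors or
#' acceptors -- is aberrant.
#'
#' @param junctions a junction data.frame from
#'   \code{\link{extractJunctions}}.
#' @param model the gene's \code{\linkS4class{GeneModel}}.
#' @param tolerance matching slack in bp (default 0, exact).
#' @return \code{junctions} with an added logical column \code{canonical}.
#' @export
classifyJunctions <- function(junctions, model, tolerance = 0L) {
    ex <- exonRanges(model)
    n <- length(ex)
    if (n >= 2L) {
        dEnds <- IRanges::end(ex)[-n]
        aStarts <- IRanges::start(ex)[-1L]
    } else {
        dEnds <- integer(0)
        aStarts <- integer(0)
    }
    canonical <- vapply(seq_len(nrow(junctions)), function(i) {
        any(abs(junctions$donorEnd[i] - dEnds) <= tolerance &
            abs(junctions$acceptorStart[i] - aStarts) <= tolerance)
    }, logical(1))
    junctions$canonical <- canonical
    junctions
}

#' Aberrant-splicing fraction of a gene
#'
#' Two modes mirroring the two normalisations used for knockout libraries:
#' \describe{
#'   \item{\code{all_junctions}}{total = all junction-gap counts of the
#'     gene; aberrant = counts at non-canonical junctions.}
#'   \item{\code{from_exon}}{per-read: total = reads having a gap whose
#'     donor is exon \code{fromExon}'s end; aberrant = those whose acceptor
#'     is not the next exon's start (each read counts once).}
#' }
#'
#' @param reads a reads data.frame.
#' @param model the gene's \code{\linkS4class{GeneModel}}.
#' @param mode \code{"all_junctions"} or \code{"from_exon"}.
#' @param fromExon donor exon index (transcript order) for
#'   \code{"from_exon"} mode.
#' @param tolerance junction-matching slack in bp.
#' @return a one-row data.frame: \code{geneId}, \code{mode},
#'   \code{totalReads}, \code{aberrantReads}, \code{fraction} (\code{NA}
#'   with a warning when \code{totalReads} is 0).
#' @export
aberrantFraction <- function(reads, model,
                             mode = c("all_junctions", "from_exon"),
                             fromExon = NULL, tolerance = 0L) {
    mode <- match.arg(mode)
    if (mode == "all_junctions") {
        jx <- classifyJunctions(extractJunctions(reads, model), model,
                                tolerance = tolerance)
        total <- sum(jx$readCount)
        aberrant <- sum(jx$readCount[!jx$canonical])
        modeLabel <- "all_junctions"
    } else {
        if (is.null(fromExon)) stop("from_exon mode needs fromExon")
        ex <- exonRanges(model)
        idx <- exonIndex(model)
        gRow <- which(idx == fromExon)
        if (length(gRow) != 1L) stop("no exon with index ", fromExon)
        nxtRow <- which(idx == fromExon + 1L)
        if (length(nxtRow) != 1L)
            stop("exon ", fromExon, " has no downstream exon")
        ## genomic donor/acceptor of the canonical exon k -> k+1 junction
        if (geneStrand(model) == "+") {
            donor <- IRanges::end(ex)[gRow]
            acceptor <- IRanges::start(ex)[nxtRow]
        } else {
            donor <- IRanges::end(ex)[nxtRow]
            acceptor <- IRanges::start(ex)[gRow]
        }
        gaps <- readGaps(reads, model)
        if (geneStrand(model) == "+") {
            fromK <- gaps[abs(gaps$donorEnd - donor) <= tolerance, ,
                          drop = FALSE]
            okAcc <- abs(fromK$acceptorStart - acceptor) <= tolerance
        } else {
            ## on the - strand, "splicing from exon k" leaves exon k's
            ## genomic start and lands on exon k+1's genomic end
            fromK <- gaps[abs(gaps$acceptorStart - acceptor) <= tolerance, ,
                          drop = FALSE]
            okAcc <- abs(fromK$donorEnd - donor) <= tolerance
        }
        byRead <- split(okAcc, fromK$readIndex)
        total <- length(byRead)
        aberrant <- sum(!vapply(byRead, all, logical(1)))
        modeLabel <- sprintf("from_exon(%d)", fromExon)
    }
    if (total == 0L) {
        warning("no splicing reads for ", geneId(model), " in mode ",
                modeLabel)
        frac <- NA_real_
    } else {
        frac <- aberrant / total
    }
    data.frame(geneId = geneId(model), mode = modeLabel,
               totalReads = as.integer(total),
               aberrantReads = as.integer(aberrant), fraction = frac,
               stringsAsFactors = FALSE)
}

#' Samples with spliced reads at multiple junctions
#'
#' Identifies the samples whose reads support at least \code{minJunctions}
#' distinct splice junctions of the gene with at least \code{minReads} reads
#' each -- the inclusion rule used before computing per-sample aberrant
#' splicing fractions.
#'
#' @param reads a reads data.frame carrying \code{sampleId}.
#' @param model the gene's \code{\linkS4class{GeneModel}}.
#' @param minReads minimum reads per junction.
#' @param minJunctions minimum number of distinct junctions.
#' @return a character vector of sample ids.
#' @export
multiJunctionSamples <- function(reads, model, minReads = 1L,
                                 minJunctions = 2L) {
    gaps <- readGaps(reads, model)
    if (nrow(gaps) == 0L) return(character(0))
    key <- paste(gaps$donorEnd, gaps$acceptorStart)
    bySample <- split(key, gaps$sampleId)
    ok <- vapply(bySample, function(k) {
        sum(table(k) >= minReads) >= minJunctions
    }, logical(1))
    names(bySample)[ok]
}
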