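## M-op blocks of every read: data.frame(readIndex, chrom, start, end).
## Junction (N) and deletion (D) segments are not overlap evidence.
readMBlocks <- function(reads) {
    out <- vector("list", nrow(reads))
    for (j in seq_len(nrow(reads))) {
        walk <- cigarWalk(reads$pos[j], reads$cigar[j])
        m <- walk[walk$op %in% c("M", "=", "X"), , drop = FALSE]
        out[[j]] <- data.frame(readIndex = j, chrom = reads$chrom[j],
                               start = m$refStart, end = m$refEnd,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(data.frame(readIndex = integer(0),
                                          chrom = character(0),
                                          start = integer(0),
                                          end = integer(0)))))
}

#' Count reads over a gene with masked exons
#'
#' A read is counted iff at least one of its aligned (\code{M}) bases
#' overlaps a retained (non-masked) exon; overlap confined to masked exons
#' or introns contributes nothing. With an empty mask this is plain
#' union-exon counting. Supplementary records are not counted.
#'
#' @param reads a reads data.frame (one sample, or any pool).
#' @param model the gene's \code{\linkS4class{GeneModel}}.
#' @param maskedExons integer vector of exon indices (transcript order) to
#'   mask; must be a subset of the gene's exons.
#' @return the integer read count.
#' @export
countReadsMasked <- function(reads, model, maskedExons = integer(0)) {
    idx <- exonIndex(model)
    maskedExons <- as.integer(maskedExons)
    if (length(maskedExons) && !all(maskedExons %in% idx))
        stop("maskedExons refers to exon indices not present in ",
             geneId(model))
    keepRows <- !(idx %in% maskedExons)
    if (!any(keepRows)) return(0L)
    ex <- exonRanges(model)[keepRows]
    rr <- reads[reads$chrom == geneChrom(model) & !reads$isSupplementary, ,
                drop = FALSE]
    if (nrow(rr) == 0L) return(0L)
    blocks <- readMBlocks(rr)
    hits <- IRanges::findOverlaps(
        IRanges::IRanges(blocks$start, blocks$end), ex, minoverlap = 1L)
    length(unique(blocks$readIndex[S4Vectors::queryHits(hits)]))
}

#' Library-size normalisation (counts per million)
#'
#' @param geneCount raw read count(s).
#' @param librarySize per-sample total counted reads (> 0).
#' @param scale scaling constant (default 1e6, i.e. CPM).
#' @return normalised value(s).
#' @export
libsizeNormalize <- function(geneCount, librarySize, scale = 1e6) {
    if (any(librarySize <= 0)) stop("librarySize must be > 0")
    geneCount / librarySize * scale
}

#' Splicing-weighted effective transcript length
#'
#' Mixes the exon-skipped and full-length transcript lengths by the aberrant
#' splicing ratio \code{r}: \code{r * lenSkip + (1 - r) * lenFull}. At
#' \code{r = 0} this is the wildtype length, at \code{r = 1} the skipped
#' length, and it decreases monotonically in between.
#'
#' @param lenFull full (wildtype) transcript length in bp.
#' @param lenSkip exon-skipped transcript length in bp
#'   (\code{0 < lenSkip < lenFull}).
#' @param r aberrant splicing ratio in \code{[0, 1]} (vectorised).
#' @return effective length(s) in bp.
#' @export
effectiveLength <- function(lenFull, lenSkip, r) {
    if (!(lenSkip > 0 && lenSkip < lenFull))
        stop("need 0 < lenSkip < lenFull")
    if (any(r < 0 | r > 1)) stop("aberrant splicing ratio must be in [0, 1]")
    r * lenSkip + (1 - r) * lenFull
}

#' FPKM from a count, a library size, and an effective length
#'
#' \code{count / (librarySize / 1e6) / (effectiveLengthBp / 1e3)}.
#'
#' @param geneCount raw read count(s).
#' @param librarySize per-sample library size (> 0).
#' @param effectiveLengthBp effective transcript length in bp (> 0).
#' @return FPKM value(s).
#' @export
fpkmManual <- function(geneCount, librarySize, effectiveLengthBp) {
    if (any(librarySize <= 0)) stop("librarySize must be > 0")
    if (any(effectiveLengthBp <= 0)) stop("effectiveLengthBp must be > 0")
    geneCount / (librarySize / 1e6) / (effectiveLengthBp / 1e3)
}

#' Build a gene-by-sample count matrix from reads
#'
#' Union-exon counting of every gene model over every sample present in
#' \code{reads}; the per-sample library size is the column sum (total
#' counted reads over the full, unmasked annotation).
#'
#' @param reads a reads data.frame carrying \code{sampleId}.
#' @param models a named list of \code{GeneModel}s.
#' @return a \code{\link[SummarizedExperiment]{SummarizedExperiment}} with
#'   assay \code{counts}, \code{rowData$geneLengthBp} (union exon length)
#'   and \code{colData$librarySize}.
#' @export
countMatrixFromReads <- function(reads, models) {
    samples <- sort(unique(reads$sampleId))
    counts <- matrix(0L, nrow = length(models), ncol = length(samples),
                     dimnames = list(names(models), samples))
    for (s in samples) {
        rs <- reads[reads$sampleId == s, , drop = FALSE]
        for (g in names(models)) {
            counts[g, s] <- countReadsMasked(rs, models[[g]])
        }
    }
    lens <- vapply(models, function(m) sum(IRanges::width(exonRanges(m))),
                   integer(1))
    countMatrix(counts, geneLengthBp = lens)
}

#' Construct a count-matrix container
#'
#' @param counts a non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param geneLengthBp per-gene (effective or union-exon) length in bp.
#' @return a \code{SummarizedExperiment} with \code{colData$librarySize}
#'   set to the column sums.
#' @export
countMatrix <- function(counts, geneLengthBp) {
    if (any(counts < 0)) stop("counts must be non-negative")
    if (length(geneLengthBp) != nrow(counts))
        stop("geneLengthBp must have one entry per gene")
    if (any(geneLengthBp <= 0)) stop("geneLengthBp must be > 0")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(geneLengthBp = as.numeric(geneLengthBp),
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(librarySize = colSums(counts),
                                       row.names = colnames(counts)))
}
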