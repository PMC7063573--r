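#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

#' GeneModel: single-transcript exon/CDS structure of a gene
#'
#' One transcript per gene: an ordered set of non-overlapping exons on one
#' chromosome plus the coding region given in transcript-relative, 1-based
#' inclusive coordinates. Exons are stored in genomic order; transcript order
#' (the exon index) runs with the genome on the \code{+} strand and against it
#' on the \code{-} strand.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons an \code{\link[IRanges]{IRanges}} of exon intervals
#'   (genomic, 1-based inclusive), sorted and disjoint.
#' @slot cdsStart,cdsEnd transcript-relative 1-based positions of the first
#'   and last coding base (the stop codon's last base is \code{cdsEnd}).
#' @export
setClass("GeneModel",
    slots = c(geneId = "character", chrom = "character", strand = "character",
              exons = "IRanges", cdsStart = "integer", cdsEnd = "integer"))

setValidity("GeneModel", function(object) {
    msg <- character(0)
    ex <- object@exons
    if (length(object@geneId) != 1L || !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(ex) == 0L)
        msg <- c(msg, "at least one exon is required")
    if (length(ex) > 1L) {
        s <- IRanges::start(ex)
        e <- IRanges::end(ex)
        if (is.unsorted(s, strictly = TRUE) ||
            any(e[-length(ex)] >= s[-1L]))
            msg <- c(msg, "exons must be sorted and non-overlapping")
    }
    txLen <- sum(IRanges::width(ex))
    if (!(object@cdsStart >= 1L && object@cdsStart < object@cdsEnd &&
          object@cdsEnd <= txLen))
        msg <- c(msg, "need 1 <= cdsStart < cdsEnd <= spliced length")
    if ((object@cdsEnd - object@cdsStart + 1L) %% 3L != 0L)
        msg <- c(msg, "CDS length must be a multiple of 3")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exonStarts,exonEnds genomic 1-based inclusive exon coordinates
#'   (will be sorted genomically).
#' @param cdsStart,cdsEnd transcript-relative CDS coordinates (1-based,
#'   inclusive of the stop codon).
#' @return a validated \code{\linkS4class{GeneModel}}.
#' @examples
#' gm <- geneModel("cxcX", "chrC", "+",
#'                 exonStarts = c(1001, 2001, 3001),
#'                 exonEnds   = c(1500, 2118, 3724),
#'                 cdsStart = 450, cdsEnd = 749)
#' transcriptLength(gm)
#' @export
geneModel <- function(geneId, chrom, strand, exonStarts, exonEnds,
                      cdsStart, cdsEnd) {
    o <- order(exonStarts)
    new("GeneModel", geneId = as.character(geneId),
        chrom = as.character(chrom), strand = as.character(strand),
        exons = IRanges::IRanges(start = as.integer(exonStarts[o]),
                                 end = as.integer(exonEnds[o])),
        cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd))
}

#' @rdname geneModel
#' @param object,x a \code{GeneModel}.
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname geneModel
#' @export
setMethod("geneId", "GeneModel", function(object) object@geneId)

#' @rdname geneModel
#' @export
setGeneric("geneChrom", function(object) standardGeneric("geneChrom"))
#' @rdname geneModel
#' @export
setMethod("geneChrom", "GeneModel", function(object) object@chrom)

#' @rdname geneModel
#' @export
setGeneric("geneStrand", function(object) standardGeneric("geneStrand"))
#' @rdname geneModel
#' @export
setMethod("geneStrand", "GeneModel", function(object) object@strand)

#' @rdname geneModel
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @rdname geneModel
#' @export
setMethod("exonRanges", "GeneModel", function(object) object@exons)

#' @rdname geneModel
#' @export
setGeneric("cdsStart", function(object) standardGeneric("cdsStart"))
#' @rdname geneModel
#' @export
setMethod("cdsStart", "GeneModel", function(object) object@cdsStart)

#' @rdname geneModel
#' @export
setGeneric("cdsEnd", function(object) standardGeneric("cdsEnd"))
#' @rdname geneModel
#' @export
setMethod("cdsEnd", "GeneModel", function(object) object@cdsEnd)

#' @rdname geneModel
#' @export
setGeneric("transcriptLength",
           function(object) standardGeneric("transcriptLength"))
#' @rdname geneModel
#' @export
setMethod("transcriptLength", "GeneModel",
          function(object) sum(IRanges::width(object@exons)))

#' Exon indices in transcript order
#'
#' Returns, for each exon in genomic order, its 1-based transcript-order
#' index: on the \code{+} strand exon 1 is the genomically first exon; on the
#' \code{-} strand exon 1 is the genomically last exon.
#'
#' @param object a \code{GeneModel}.
#' @return an integer vector parallel to \code{exonRanges(object)}.
#' @export
setGeneric("exonIndex", function(object) standardGeneric("exonIndex"))
#' @rdname exonIndex
#' @export
setMethod("exonIndex", "GeneModel", function(object) {
    n <- length(object@exons)
    if (object@strand == "+") seq_len(n) else rev(seq_len(n))
})

setMethod("show", "GeneModel", function(object) {
    cat("GeneModel ", object@geneId, " (", object@chrom, object@strand,
        "): ", length(object@exons), " exon(s), spliced length ",
        transcriptLength(object), " nt, CDS ", object@cdsStart, "-",
        object@cdsEnd, " (", (object@cdsEnd - object@cdsStart + 1L) %/% 3L - 1L,
        " aa + stop)\n", sep = "")
})

## Genomic -> transcript coordinate projection for exonic positions.
## Returns NA for intronic/off-gene positions. Vectorised over gpos.
genomicToTranscript <- function(model, gpos) {
    ex <- model@exons
    s <- IRanges::start(ex)
    e <- IRanges::end(ex)
    w <- IRanges::width(ex)
    idx <- exonIndex(model)
    ## cumulative transcript offset preceding each exon, in transcript order
    offs <- integer(length(ex))
    ord <- order(idx)
    offs[ord] <- cumsum(c(0L, w[ord]))[seq_along(ex)]
    vapply(as.integer(gpos), function(g) {
        i <- which(g >= s & g <= e)
        if (length(i) != 1L) return(NA_integer_)
        if (model@strand == "+") offs[i] + (g - s[i] + 1L)
        else offs[i] + (e[i] - g + 1L)
    }, integer(1))
}

## Transcript -> genomic projection (inverse of genomicToTranscript).
transcriptToGenomic <- function(model, tpos) {
    ex <- model@exons
    s <- IRanges::start(ex)
    e <- IRanges::end(ex)
    w <- IRanges::width(ex)
    idx <- exonIndex(model)
    offs <- integer(length(ex))
    ord <- order(idx)
    offs[ord] <- cumsum(c(0L, w[ord]))[seq_along(ex)]
    vapply(as.integer(tpos), function(t) {
        i <- which(t > offs & t <= offs + w)
        if (length(i) != 1L) return(NA_integer_)
        if (model@strand == "+") s[i] + (t - offs[i] - 1L)
        else e[i] - (t - offs[i] - 1L)
    }, integer(1))
}
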