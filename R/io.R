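#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into a named
#' \code{\link[Biostrings]{DNAStringSet}}, upper-casing the sequence.
#' Chromosome names must be unique and sequences may only contain
#' \code{A C G T N}.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet} (one element per chromosome).
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
    if (length(x) == 0L)
        stop("FASTA format error in '", path, "': no records")
    ## drop description after first whitespace, as aligners do
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate chromosome names in '", path, "'")
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    bad <- grepl("[^ACGTN]", as.character(x))
    if (any(bad))
        stop("FASTA sequence with letters outside {A,C,G,T,N}: ",
             paste(names(x)[bad], collapse = ", "))
    if (sum(Biostrings::width(x)) == 0L)
        stop("FASTA format error in '", path, "': total length 0")
    x
}

#' Write a genome to FASTA
#'
#' @param genome a named \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
    invisible(path)
}

#' Read gene models from a GFF3-style annotation
#'
#' Expects \code{exon} and \code{CDS} feature rows carrying a \code{gene_id}
#' attribute (exon rows also an \code{exon_number}). Exons are grouped per
#' gene and sorted genomically; the exon index follows transcript order
#' (reverse genomic order on the \code{-} strand). CDS rows are genomic and
#' are projected onto the spliced transcript to obtain the
#' transcript-relative \code{cdsStart}/\code{cdsEnd} of the returned
#' \code{\linkS4class{GeneModel}}s. One transcript per gene.
#'
#' @param path path to the annotation file.
#' @return a named list of \code{GeneModel} objects.
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$gene_id)) stop("annotation lacks gene_id attributes: ", path)
    keep <- mc$type %in% c("exon", "CDS")
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    models <- list()
    for (gid in unique(mc$gene_id)) {
        sel <- mc$gene_id == gid
        sub <- gr[sel]
        subType <- S4Vectors::mcols(sub)$type
        ex <- sub[subType == "exon"]
        cds <- sub[subType == "CDS"]
        if (length(ex) == 0L) stop("gene ", gid, " has no exon rows")
        if (length(cds) == 0L) stop("gene ", gid, " has no CDS rows")
        strand <- as.character(GenomicRanges::strand(ex))[1L]
        if (!strand %in% c("+", "-"))
            stop("gene ", gid, " has no usable strand")
        es <- GenomicRanges::start(ex)
        ee <- GenomicRanges::end(ex)
        o <- order(es)
        es <- es[o]; ee <- ee[o]
        if (length(es) > 1L && any(ee[-length(ee)] >= es[-1L]))
            stop("overlapping exons within gene ", gid)
        ## temporary model with a placeholder CDS to reuse the projection
        tmp <- geneModel(gid, as.character(GenomicRanges::seqnames(ex))[1L],
                         strand, es, ee, 1L, 3L + 3L)
        gLo <- min(GenomicRanges::start(cds))
        gHi <- max(GenomicRanges::end(cds))
        tLo <- genomicToTranscript(tmp, if (strand == "+") gLo else gHi)
        tHi <- genomicToTranscript(tmp, if (strand == "+") gHi else gLo)
        if (is.na(tLo) || is.na(tHi))
            stop("CDS of gene ", gid, " does not map onto its exons")
        models[[gid]] <- geneModel(gid, tmp@chrom, strand, es, ee, tLo, tHi)
    }
    models
}

#' Write gene models to a GFF3-style annotation
#'
#' Emits one \code{exon} row per exon (with \code{exon_number} in transcript
#' order) and one \code{CDS} row per exon portion overlapping the coding
#' region; the inverse of \code{\link{readGeneModels}}.
#'
#' @param models a list of \code{GeneModel} objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    lines <- c("##gff-version 3")
    for (m in models) {
        ex <- exonRanges(m)
        idx <- exonIndex(m)
        for (i in seq_along(ex)) {
            lines <- c(lines, paste(geneChrom(m), "editscope", "exon",
                IRanges::start(ex)[i], IRanges::end(ex)[i], ".", geneStrand(m),
                ".", sprintf("gene_id=%s;exon_number=%d", geneId(m), idx[i]),
                sep = "\t"))
        }
        ## genomic CDS span per exon: project CDS transcript interval back
        tpos <- seq(cdsStart(m), cdsEnd(m))
        gpos <- transcriptToGenomic(m, tpos)
        for (i in seq_along(ex)) {
            inEx <- gpos[gpos >= IRanges::start(ex)[i] &
                         gpos <= IRanges::end(ex)[i]]
            if (length(inEx) == 0L) next
            lines <- c(lines, paste(geneChrom(m), "editscope", "CDS",
                min(inEx), max(inEx), ".", geneStrand(m), "0",
                sprintf("gene_id=%s", geneId(m)), sep = "\t"))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read aligned reads from plain-text SAM
#'
#' Parses one or more SAM files into a single data frame of mapped reads.
#' Unmapped records are skipped; duplicate-flagged records are dropped when
#' \code{dropDuplicates} is \code{TRUE}. Each mapped record is checked for
#' consistency between its CIGAR's query-consuming length and its sequence
#' length. Multiple files given together are merged (e.g. a re-sequenced
#' sample's two runs).
#'
#' @param paths character vector of SAM file paths.
#' @param sampleId sample identifier attached to every read; defaults to the
#'   file name without extension (per file).
#' @param dropDuplicates drop records with the 0x400 duplicate flag.
#' @return a data.frame with columns \code{queryName}, \code{sampleId},
#'   \code{chrom}, \code{pos}, \code{cigar}, \code{seq}, \code{flag},
#'   \code{isDuplicate}, \code{isSupplementary}, \code{refWidth}.
#' @export
readAlignments <- function(paths, sampleId = NULL, dropDuplicates = TRUE) {
    out <- vector("list", length(paths))
    for (k in seq_along(paths)) {
        path <- paths[k]
        if (!file.exists(path)) stop("no such file: ", path)
        lines <- readLines(path)
        lines <- lines[!startsWith(lines, "@")]
        sid <- if (is.null(sampleId)) sub("\\.[^.]*$", "", basename(path))
               else sampleId
        if (length(lines) == 0L) {
            out[[k]] <- emptyReads()
            next
        }
        f <- strsplit(lines, "\t", fixed = TRUE)
        nf <- lengths(f)
        if (any(nf < 11L))
            stop("SAM record with fewer than 11 fields in '", path,
                 "' (line ", which(nf < 11L)[1L], ")")
        getf <- function(i) vapply(f, `[[`, character(1), i)
        flag <- as.integer(getf(2L))
        df <- data.frame(
            queryName = getf(1L), sampleId = sid, chrom = getf(3L),
            pos = as.integer(getf(4L)), cigar = getf(6L), seq = getf(10L),
            flag = flag,
            isDuplicate = bitwAnd(flag, 1024L) > 0L,
            isSupplementary = bitwAnd(flag, 2048L) > 0L,
            stringsAsFactors = FALSE)
        mapped <- bitwAnd(flag, 4L) == 0L & df$chrom != "*" & df$cigar != "*"
        df <- df[mapped, , drop = FALSE]
        qw <- vapply(df$cigar, cigarQueryWidth, integer(1), USE.NAMES = FALSE)
        hasSeq <- df$seq != "*"
        bad <- hasSeq & qw != nchar(df$seq)
        if (any(bad))
            stop("CIGAR/sequence length mismatch for read ",
                 df$queryName[bad][1L], " in '", path, "'")
        df$refWidth <- vapply(df$cigar, cigarRefWidth, integer(1),
                              USE.NAMES = FALSE)
        out[[k]] <- df
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    if (dropDuplicates) reads <- reads[!reads$isDuplicate, , drop = FALSE]
    reads
}

emptyReads <- function() {
    data.frame(queryName = character(0), sampleId = character(0),
               chrom = character(0), pos = integer(0), cigar = character(0),
               seq = character(0), flag = integer(0),
               isDuplicate = logical(0), isSupplementary = logical(0),
               refWidth = integer(0), stringsAsFactors = FALSE)
}

#' Write reads to plain-text SAM
#'
#' Records are coordinate-sorted; the header carries \code{@SQ} lines from
#' the supplied genome. Output is byte-deterministic for a given input.
#'
#' @param reads a reads data.frame (see \code{\link{readAlignments}}).
#' @param genome a named \code{DNAStringSet} supplying chromosome lengths.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(reads, genome, path) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     Biostrings::width(genome)))
    o <- order(match(reads$chrom, names(genome)), reads$pos, reads$queryName,
               reads$isSupplementary)
    reads <- reads[o, , drop = FALSE]
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                   reads$queryName, reads$flag, reads$chrom, reads$pos,
                   reads$cigar, reads$seq)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read or write a guide-site table
#'
#' Tab-delimited with header columns \code{name}, \code{chrom},
#' \code{cut_pos} (1-based genomic cut position), \code{window} (half-width
#' in bp of the calling window around the cut).
#'
#' @param path file path.
#' @return \code{readGuideSites}: a data.frame of guide sites.
#' @export
readGuideSites <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "chrom", "cut_pos", "window")
    if (!all(need %in% names(df)))
        stop("guide-site table must have columns: ",
             paste(need, collapse = ", "))
    if (any(df$window < 0L)) stop("guide-site window must be >= 0")
    if (any(df$cut_pos < 1L)) stop("guide-site cut_pos must be >= 1")
    df
}

#' @rdname readGuideSites
#' @param sites a guide-site data.frame.
#' @export
writeGuideSites <- function(sites, path) {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
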