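#' Spliced transcript and coding sequence of a gene model
#'
#' \code{spliceTranscript} concatenates the exon sequences in transcript
#' order (reverse-complementing on the \code{-} strand);
#' \code{buildCds} additionally trims to the coding region
#' \code{[cdsStart, cdsEnd]}. A CDS that does not begin with \code{ATG}
#' triggers a warning only, since edited models may legitimately lose the
#' start codon.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param genome a named \code{DNAStringSet} containing the model's
#'   chromosome.
#' @return a character string of nucleotides.
#' @export
spliceTranscript <- function(model, genome) {
    chrom <- geneChrom(model)
    if (!chrom %in% names(genome))
        stop("chromosome ", chrom, " not in genome")
    chromSeq <- as.character(genome[[chrom]])
    ex <- exonRanges(model)
    if (max(IRanges::end(ex)) > nchar(chromSeq) || min(IRanges::start(ex)) < 1L)
        stop("exon boundaries of ", geneId(model),
             " fall outside chromosome ", chrom)
    parts <- substring(chromSeq, IRanges::start(ex), IRanges::end(ex))
    tx <- paste(parts, collapse = "")
    if (geneStrand(model) == "-") tx <- revComp(tx)
    tx
}

#' @rdname spliceTranscript
#' @export
buildCds <- function(model, genome) {
    tx <- spliceTranscript(model, genome)
    cds <- substring(tx, cdsStart(model), cdsEnd(model))
    if (substring(cds, 1L, 3L) != "ATG")
        warning("CDS of ", geneId(model), " does not start with ATG")
    cds
}

revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

compBase <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Apply an editing event to a gene's transcript
#'
#' Projects a genomic editing event into transcript coordinates and applies
#' it: insertions add their bases, deletions remove the intersection of the
#' reference span with the exons, substitutions replace bases in place, and
#' large deletions remove all exonic sequence inside their span. An event
#' lying entirely in intronic sequence is a no-op with a warning. The
#' position of the (wildtype) start codon is tracked through the edit, as is
#' the net inserted-minus-deleted base count inside the coding region.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param genome a named \code{DNAStringSet}.
#' @param event a list with \code{category} (\code{"indel"},
#'   \code{"substitution"} or \code{"large_deletion"}), \code{refStart},
#'   \code{refEnd} (genomic 1-based span; for a pure insertion
#'   \code{refEnd = refStart} and the bases are inserted after
#'   \code{refStart}), and \code{alt} (inserted/replacement bases on the
#'   forward genomic strand, \code{""} for deletions). An insertion is an
#'   event with \code{alt != ""} and \code{refEnd == refStart}; otherwise
#'   \code{alt == ""} means deletion and \code{nchar(alt) ==} span width
#'   means substitution.
#' @return a transcript-variant list with elements \code{geneId},
#'   \code{transcript}, \code{cdsStart} (projected start-codon position),
#'   \code{netCodingIndel} and \code{variant} (description string), suitable
#'   for \code{\link{translateOrf}}.
#' @export
applyEdit <- function(model, genome, event) {
    tx <- spliceTranscript(model, genome)
    L <- nchar(tx)
    isSubstitution <- identical(event$category, "substitution")
    isInsertion <- !isSubstitution && nzchar(event$alt) &&
        event$refEnd == event$refStart
    gspan <- seq(event$refStart, event$refEnd)
    tspan <- genomicToTranscript(model, gspan)
    if (isInsertion) {
        tIns <- tspan[1L]
        if (is.na(tIns)) {
            warning("event for ", geneId(model),
                    " lies entirely in intronic sequence; no-op")
            return(wildtypeVariant(model, tx,
                                   variant = describeEvent(event)))
        }
        insBases <- toupper(event$alt)
        if (geneStrand(model) == "+") {
            edit <- list(insertAfter = tIns, bases = insBases)
        } else {
            edit <- list(insertAfter = tIns - 1L, bases = revComp(insBases))
        }
        del <- integer(0)
        subs <- NULL
    } else if (isSubstitution) {
        if (nchar(event$alt) != length(gspan))
            stop("substitution alt length must equal its reference span")
        keep <- !is.na(tspan)
        if (!any(keep)) {
            warning("event for ", geneId(model),
                    " lies entirely in intronic sequence; no-op")
            return(wildtypeVariant(model, tx, variant = describeEvent(event)))
        }
        altBases <- strsplit(toupper(event$alt), "")[[1L]][keep]
        if (geneStrand(model) == "-") altBases <- unname(compBase[altBases])
        subs <- list(tpos = tspan[keep], base = altBases)
        del <- integer(0)
        edit <- NULL
    } else {
        del <- tspan[!is.na(tspan)]
        if (length(del) == 0L) {
            warning("event for ", geneId(model),
                    " lies entirely in intronic sequence; no-op")
            return(wildtypeVariant(model, tx, variant = describeEvent(event)))
        }
        subs <- NULL
        edit <- NULL
    }
    rebuildVariant(model, tx, del = del, ins = edit, subs = subs,
                   variant = describeEvent(event))
}

describeEvent <- function(event) {
    if (identical(event$category, "substitution"))
        sprintf("sub%d@%d", nchar(event$alt), event$refStart)
    else if (nzchar(event$alt) && event$refEnd == event$refStart)
        sprintf("ins%d@%d", nchar(event$alt), event$refStart)
    else if (nzchar(event$alt))
        sprintf("sub%d@%d", nchar(event$alt), event$refStart)
    else sprintf("del%d@%d", event$refEnd - event$refStart + 1L,
                 event$refStart)
}

wildtypeVariant <- function(model, tx, variant = "wildtype") {
    list(geneId = geneId(model), transcript = tx, cdsStart = cdsStart(model),
         netCodingIndel = 0L, variant = variant)
}

## Core rebuild: delete transcript positions `del`, apply substitutions,
## optionally insert bases after transcript position `ins$insertAfter`
## (0 = before the first base). Tracks the start-codon position and the net
## indel length inside the wildtype CDS.
rebuildVariant <- function(model, tx, del = integer(0), ins = NULL,
                           subs = NULL, variant = "variant") {
    L <- nchar(tx)
    cs <- cdsStart(model)
    ce <- cdsEnd(model)
    chars <- strsplit(tx, "")[[1L]]
    if (!is.null(subs)) chars[subs$tpos] <- subs$base
    keep <- rep(TRUE, L)
    keep[del] <- FALSE
    pieces <- ifelse(keep, chars, "")
    insertAfter <- rep("", L + 1L)            # slot k+1 = after position k
    if (!is.null(ins)) insertAfter[ins$insertAfter + 1L] <- ins$bases
    ## emitted sequence: insertAfter(0), base1, insertAfter(1), base2, ...
    emitted <- character(2L * L + 1L)
    emitted[1L] <- insertAfter[1L]
    emitted[seq(2L, 2L * L, by = 2L)] <- pieces
    emitted[seq(3L, 2L * L + 1L, by = 2L)] <- insertAfter[-1L]
    newTx <- paste(emitted, collapse = "")
    ## projected start codon: emitted index of the first kept base at or
    ## after the wildtype cdsStart
    lens <- nchar(emitted)
    cum <- cumsum(lens)
    firstKept <- which(keep & seq_len(L) >= cs)
    if (length(firstKept) == 0L) {
        newCs <- NA_integer_
    } else {
        slot <- 2L * firstKept[1L]            # emitted slot of that base
        newCs <- cum[slot]                    # its 1-based position in newTx
    }
    insLen <- if (is.null(ins)) 0L else nchar(ins$bases)
    insCoding <- if (!is.null(ins) && ins$insertAfter >= cs &&
                     ins$insertAfter < ce) insLen else 0L
    delCoding <- sum(del >= cs & del <= ce)
    list(geneId = geneId(model), transcript = newTx, cdsStart = newCs,
         netCodingIndel = as.integer(insCoding - delCoding),
         variant = variant)
}

#' Apply an exon-skipping splice variant
#'
#' Removes the named exons (by transcript-order exon index) from the spliced
#' transcript, e.g. \code{skipExons = 2} produces the exon-1-into-exon-3
#' splice form.
#'
#' @param model a \code{\linkS4class{GeneModel}}.
#' @param genome a named \code{DNAStringSet}.
#' @param skipExons integer vector of exon indices (transcript order) to
#'   remove; must leave at least one exon.
#' @return a transcript-variant list as in \code{\link{applyEdit}}.
#' @export
applySpliceVariant <- function(model, genome, skipExons = integer(0)) {
    tx <- spliceTranscript(model, genome)
    idx <- exonIndex(model)
    n <- length(idx)
    skipExons <- as.integer(skipExons)
    if (length(skipExons) && !all(skipExons %in% idx))
        stop("skipExons refers to exon indices not present in ",
             geneId(model))
    if (length(unique(skipExons)) >= n)
        stop("cannot skip every exon of ", geneId(model))
    if (length(skipExons) == 0L)
        return(wildtypeVariant(model, tx))
    w <- IRanges::width(exonRanges(model))
    ord <- order(idx)                          # genomic rows in tx order
    wTx <- w[ord]                              # widths in transcript order
    offs <- cumsum(c(0L, wTx))
    del <- unlist(lapply(sort(unique(skipExons)), function(k) {
        seq(offs[k] + 1L, offs[k + 1L])
    }))
    rebuildVariant(model, tx, del = del,
                   variant = paste0("skip_exon_",
                                    paste(sort(unique(skipExons)),
                                          collapse = "+")))
}

stopCodons <- c("TAA", "TAG", "TGA")

#' Translate a (possibly edited) transcript and report ORF consequences
#'
#' Translation starts at the wildtype start-codon position projected through
#' the edit. If the start codon was destroyed (by an edit or an exon-1
#' skip), the next downstream \code{ATG} is used and the report flagged
#' \code{alternative_start}. Translation proceeds to the first in-frame stop
#' (\code{TAA}/\code{TAG}/\code{TGA}); the protein length excludes the stop.
#' A frameshift is a net coding indel not divisible by 3; a premature stop
#' is a termination earlier than expected from the wildtype protein length
#' and the net in-frame indel. Absent any in-frame stop the report carries
#' the flag \code{ran_off_end}.
#'
#' @param x a transcript-variant list from \code{\link{applyEdit}} /
#'   \code{\link{applySpliceVariant}}, or a plain transcript string (then
#'   taken as an unedited transcript of \code{model}).
#' @param model the wildtype \code{\linkS4class{GeneModel}} (source of the
#'   wildtype protein length used for \code{relativeLength}).
#' @return a one-row data.frame: \code{geneId}, \code{variant},
#'   \code{proteinLengthAA}, \code{wtLengthAA}, \code{relativeLength},
#'   \code{frameshift}, \code{prematureStop}, \code{flags}.
#' @export
translateOrf <- function(x, model) {
    if (is.character(x)) {
        x <- list(geneId = geneId(model), transcript = x,
                  cdsStart = cdsStart(model), netCodingIndel = 0L,
                  variant = "wildtype")
    }
    tx <- toupper(x$transcript)
    if (!nzchar(tx)) stop("empty transcript")
    wtAA <- (cdsEnd(model) - cdsStart(model) + 1L) %/% 3L - 1L
    flags <- character(0)
    start <- x$cdsStart
    if (is.na(start) || substring(tx, start, start + 2L) != "ATG") {
        from <- if (is.na(start)) 1L else start
        hit <- regexpr("ATG", substring(tx, from), fixed = TRUE)
        if (hit == -1L) {
            return(orfReport(x, 0L, wtAA,
                             frameshift = (x$netCodingIndel %% 3L) != 0L,
                             prematureStop = TRUE, flags = "no_start"))
        }
        start <- from + as.integer(hit) - 1L
        flags <- c(flags, "alternative_start")
    }
    aa <- 0L
    stopFound <- FALSE
    p <- start
    L <- nchar(tx)
    while (p + 2L <= L) {
        codon <- substring(tx, p, p + 2L)
        if (codon %in% stopCodons) {
            stopFound <- TRUE
            break
        }
        aa <- aa + 1L
        p <- p + 3L
    }
    if (!stopFound) flags <- c(flags, "ran_off_end")
    frameshift <- (x$netCodingIndel %% 3L) != 0L
    if (frameshift) {
        premature <- stopFound
    } else {
        expectedAA <- wtAA + x$netCodingIndel %/% 3L
        premature <- stopFound && aa < expectedAA
    }
    orfReport(x, aa, wtAA, frameshift, premature, flags)
}

orfReport <- function(x, aa, wtAA, frameshift, prematureStop, flags) {
    data.frame(geneId = x$geneId, variant = x$variant,
               proteinLengthAA = as.integer(aa), wtLengthAA = as.integer(wtAA),
               relativeLength = aa / wtAA, frameshift = frameshift,
               prematureStop = prematureStop,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
}
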