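#' Extract reads spanning a guide target site
#'
#' Returns the reads whose reference-consuming footprint (CIGAR M/D/N ops)
#' fully covers the calling window \code{[cut_pos - window, cut_pos +
#' window]}. A read whose deletion (\code{D}) op crosses the window still
#' covers it; supplementary alignment blocks are excluded (they are handled
#' by \code{\link{detectLargeDeletion}}).
#'
#' @param reads a reads data.frame (see \code{\link{readAlignments}}).
#' @param site a one-row guide-site data.frame (columns \code{name},
#'   \code{chrom}, \code{cut_pos}, \code{window}).
#' @param window optional half-width override (bp).
#' @return the spanning subset of \code{reads}.
#' @export
extractSiteReads <- function(reads, site, window = NULL) {
    w <- if (is.null(window)) site$window else window
    lo <- site$cut_pos - w
    hi <- site$cut_pos + w
    if (is.null(reads$refWidth)) {
        reads$refWidth <- vapply(reads$cigar, cigarRefWidth, integer(1),
                                 USE.NAMES = FALSE)
    }
    keep <- reads$chrom == site$chrom & !reads$isSupplementary &
        reads$pos <= lo & (reads$pos + reads$refWidth - 1L) >= hi
    reads[keep, , drop = FALSE]
}

#' Call the editing allele carried by one read at a guide site
#'
#' Walks the read's CIGAR across the calling window and compares it with the
#' reference: insertion/deletion ops intersecting the window yield an indel
#' call; aligned bases differing from the reference yield substitutions;
#' a read matching the reference over the whole window is a \code{match}.
#' A read spliced (\code{N}) across the window carries no sequence evidence
#' at the site and is returned as \code{spliced}. A read with both an indel
#' and substitutions is categorised \code{indel} (compound allele), the
#' allele string listing every component.
#'
#' @param read a one-row reads data.frame.
#' @param genome a named \code{DNAStringSet} (or a named list of plain
#'   chromosome strings, as cached by \code{\link{genotypeSample}}).
#' @param site a one-row guide-site data.frame.
#' @param window optional half-width override (bp).
#' @return a list with \code{call} (\code{"match"}, \code{"indel"},
#'   \code{"substitution"} or \code{"spliced"}) and \code{allele}
#'   (a canonical event-string, \code{""} for match/spliced).
#' @export
callReadAllele <- function(read, genome, site, window = NULL) {
    w <- if (is.null(window)) site$window else window
    lo <- site$cut_pos - w
    hi <- site$cut_pos + w
    chromSeq <- if (is.character(genome[[site$chrom]])) genome[[site$chrom]]
                else as.character(genome[[site$chrom]])
    walk <- cigarWalk(read$pos, read$cigar)
    inWin <- walk$refEnd >= lo & walk$refStart <= hi
    if (any(walk$op == "N" & inWin)) {
        return(list(call = "spliced", allele = "",
                    reason = "spliced over site"))
    }
    ev <- character(0)
    pos <- integer(0)
    hasIndel <- FALSE
    hasSub <- FALSE
    for (i in seq_len(nrow(walk))) {
        op <- walk$op[i]
        if (op == "D" && inWin[i]) {
            hasIndel <- TRUE
            ev <- c(ev, sprintf("D:%d-%d", walk$refStart[i], walk$refEnd[i]))
            pos <- c(pos, walk$refStart[i])
        } else if (op == "I" &&
                   walk$refStart[i] >= lo && walk$refStart[i] <= hi + 1L) {
            ## inserted between refStart-1 and refStart
            hasIndel <- TRUE
            ins <- substring(read$seq, walk$qStart[i], walk$qEnd[i])
            ev <- c(ev, sprintf("I:%d:%s", walk$refStart[i] - 1L, ins))
            pos <- c(pos, walk$refStart[i] - 1L)
        } else if (op %in% c("M", "=", "X") && inWin[i]) {
            os <- max(walk$refStart[i], lo)
            oe <- min(walk$refEnd[i], hi)
            refBit <- substring(chromSeq, os, oe)
            qs <- walk$qStart[i] + (os - walk$refStart[i])
            qBit <- substring(read$seq, qs, qs + (oe - os))
            mism <- which(strsplit(refBit, "")[[1L]] != strsplit(qBit, "")[[1L]])
            if (length(mism)) {
                hasSub <- TRUE
                ## merge adjacent mismatches into runs
                runs <- split(mism, cumsum(c(1L, diff(mism) != 1L)))
                for (r in runs) {
                    ev <- c(ev, sprintf("S:%d:%s>%s", os + r[1L] - 1L,
                                        substring(refBit, r[1L], r[length(r)]),
                                        substring(qBit, r[1L], r[length(r)])))
                    pos <- c(pos, os + r[1L] - 1L)
                }
            }
        }
    }
    if (!length(ev)) return(list(call = "match", allele = ""))
    o <- order(pos, ev)
    list(call = if (hasIndel) "indel" else "substitution",
         allele = paste(ev[o], collapse = ";"))
}

#' Detect a large deletion between two guide sites
#'
#' Looks for read pairs or split (supplementary) alignments of one query
#' whose aligned blocks flank both cut positions with the intervening
#' reference (> 10 kb) absent from the alignment. The flanking blocks must
#' end/start within \code{flank} bp outside the cuts (or \code{window} bp
#' inside).
#'
#' @param sampleReads all reads of one sample (including supplementary
#'   records).
#' @param siteA,siteB one-row guide-site data.frames on the same chromosome,
#'   more than 10 kb apart.
#' @param minSupport minimum number of supporting queries.
#' @param flank how far outside a cut a flanking block may end/start (bp).
#' @return \code{NULL}, or a one-row data.frame describing the
#'   \code{large_deletion} event (\code{refStart}, \code{refEnd},
#'   \code{support}, \code{sites}).
#' @export
detectLargeDeletion <- function(sampleReads, siteA, siteB, minSupport = 1L,
                                flank = 200L) {
    if (siteA$chrom != siteB$chrom)
        stop("sites must be on the same chromosome")
    cutLo <- min(siteA$cut_pos, siteB$cut_pos)
    cutHi <- max(siteA$cut_pos, siteB$cut_pos)
    if (cutHi - cutLo <= 10000L)
        stop("sites must be separated by > 10 kb")
    wLo <- if (siteA$cut_pos == cutLo) siteA$window else siteB$window
    wHi <- if (siteA$cut_pos == cutHi) siteA$window else siteB$window
    rr <- sampleReads[sampleReads$chrom == siteA$chrom, , drop = FALSE]
    if (nrow(rr) == 0L) return(NULL)
    if (is.null(rr$refWidth)) {
        rr$refWidth <- vapply(rr$cigar, cigarRefWidth, integer(1),
                              USE.NAMES = FALSE)
    }
    ends <- rr$pos + rr$refWidth - 1L
    supportsLeft <- ends >= cutLo - flank & ends <= cutLo + wLo
    supportsRight <- rr$pos >= cutHi - wHi & rr$pos <= cutHi + flank
    qn <- rr$queryName
    supQ <- character(0)
    bounds <- NULL
    for (q in unique(qn[supportsLeft])) {
        i <- qn == q
        if (!any(supportsRight & i)) next
        e1 <- max(ends[i & supportsLeft])
        s2 <- min(rr$pos[i & supportsRight])
        if (s2 - e1 - 1L > 10000L) {
            supQ <- c(supQ, q)
            bounds <- rbind(bounds, c(e1 + 1L, s2 - 1L))
        }
    }
    if (length(supQ) < minSupport) return(NULL)
    ## consensus span: the most common breakpoint pair
    key <- paste(bounds[, 1L], bounds[, 2L])
    top <- names(sort(table(key), decreasing = TRUE))[1L]
    bp <- as.integer(strsplit(top, " ")[[1L]])
    data.frame(category = "large_deletion", refStart = bp[1L],
               refEnd = bp[2L], alt = "", support = length(supQ),
               sites = paste(sort(c(siteA$name, siteB$name)), collapse = "+"),
               stringsAsFactors = FALSE)
}

#' Genotype one sample at a set of guide sites
#'
#' Per site: \code{no_coverage} if no read spans the calling window;
#' \code{edited} if at least \code{minSupport} reads carry one identical
#' non-reference allele (identical allele strings aggregate into one event;
#' distinct alleles within a sample are all reported, reflecting mosaic
#' somatic editing); otherwise \code{unedited}. Pairs of sites on one
#' chromosome more than 10 kb apart are additionally screened for large
#' deletions, which mark both involved sites edited.
#'
#' @param reads all reads of one sample.
#' @param genome a named \code{DNAStringSet}.
#' @param sites a guide-site data.frame.
#' @param minSupport minimum reads supporting one allele to call edited.
#' @param maxErrorFrac support fractions at or below this are attributed to
#'   sequencing/amplification error and do not call an edit (default 0:
#'   any deviant read sequence counts, matching visual-inspection calling;
#'   raise under non-zero sequencing error).
#' @param window optional half-width override applied to every site.
#' @return a list with \code{sampleId}, \code{status} (named character
#'   vector per site), and \code{events} (data.frame: one row per distinct
#'   allele with \code{site}, \code{category}, \code{allele},
#'   \code{support}, \code{spanning}, plus any large-deletion events).
#' @export
genotypeSample <- function(reads, genome, sites, minSupport = 1L,
                           maxErrorFrac = 0, window = NULL) {
    sampleId <- if (nrow(reads)) reads$sampleId[1L] else NA_character_
    chromCache <- list()
    for (ch in unique(sites$chrom)) {
        if (ch %in% names(genome))
            chromCache[[ch]] <- as.character(genome[[ch]])
    }
    status <- setNames(rep("no_coverage", nrow(sites)), sites$name)
    events <- list()
    for (i in seq_len(nrow(sites))) {
        site <- sites[i, , drop = FALSE]
        span <- extractSiteReads(reads, site, window = window)
        if (nrow(span) == 0L) next
        calls <- lapply(seq_len(nrow(span)), function(j) {
            callReadAllele(span[j, , drop = FALSE], chromCache, site,
                           window = window)
        })
        callType <- vapply(calls, `[[`, character(1), "call")
        callable <- callType != "spliced"
        nSpan <- sum(callable)
        if (nSpan == 0L) next                 # only spliced evidence: no call
        alleles <- vapply(calls, `[[`, character(1), "allele")[callable]
        types <- callType[callable]
        nonMatch <- alleles[types != "match"]
        edited <- FALSE
        if (length(nonMatch)) {
            tab <- table(nonMatch)
            for (a in names(tab)) {
                cat_ <- types[match(a, alleles)]
                events[[length(events) + 1L]] <- data.frame(
                    site = site$name, category = cat_, allele = a,
                    support = as.integer(tab[[a]]), spanning = nSpan,
                    stringsAsFactors = FALSE)
                if (tab[[a]] >= minSupport &&
                    tab[[a]] > maxErrorFrac * nSpan) edited <- TRUE
            }
        }
        status[site$name] <- if (edited) "edited" else "unedited"
    }
    ## large-deletion screen across qualifying site pairs
    if (nrow(sites) >= 2L) {
        for (i in seq_len(nrow(sites) - 1L)) {
            for (j in seq(i + 1L, nrow(sites))) {
                a <- sites[i, , drop = FALSE]
                b <- sites[j, , drop = FALSE]
                if (a$chrom != b$chrom) next
                if (abs(a$cut_pos - b$cut_pos) <= 10000L) next
                ld <- detectLargeDeletion(reads, a, b,
                                          minSupport = minSupport)
                if (is.null(ld)) next
                events[[length(events) + 1L]] <- data.frame(
                    site = ld$sites, category = "large_deletion",
                    allele = sprintf("LD:%d-%d", ld$refStart, ld$refEnd),
                    support = ld$support, spanning = ld$support,
                    stringsAsFactors = FALSE)
                status[a$name] <- "edited"
                status[b$name] <- "edited"
            }
        }
    }
    ev <- if (length(events)) do.call(rbind, events) else
        data.frame(site = character(0), category = character(0),
                   allele = character(0), support = integer(0),
                   spanning = integer(0), stringsAsFactors = FALSE)
    if (nrow(ev)) ev <- cbind(sampleId = sampleId, ev)
    list(sampleId = sampleId, status = status, events = ev)
}

#' Summarise per-sample genotypes over a cohort
#'
#' Edited fractions are computed among covered samples only:
#' \code{no_coverage} calls are excluded from every denominator. The overall
#' fraction counts a sample as analysed if it has coverage at one or more
#' sites and as edited if it is edited at one or more sites.
#'
#' @param genotypes a list of \code{\link{genotypeSample}} results.
#' @return a list with \code{perSite} (data.frame: site, nEdited,
#'   nUnedited, nNoCoverage, editedFraction) and \code{overall} (one-row
#'   data.frame: nAnalyzed, nEdited, editedFraction).
#' @export
summarizeCohort <- function(genotypes) {
    statuses <- do.call(rbind, lapply(genotypes, `[[`, "status"))
    siteNames <- colnames(statuses)
    perSite <- do.call(rbind, lapply(siteNames, function(s) {
        st <- statuses[, s]
        data.frame(site = s, nEdited = sum(st == "edited"),
                   nUnedited = sum(st == "unedited"),
                   nNoCoverage = sum(st == "no_coverage"),
                   editedFraction =
                       sum(st == "edited") /
                       max(1L, sum(st != "no_coverage")) *
                       ifelse(sum(st != "no_coverage") == 0L, NA, 1),
                   stringsAsFactors = FALSE)
    }))
    covered <- rowSums(statuses != "no_coverage") > 0L
    if (!any(covered)) {
        warning("every sample lacks coverage at every site")
        return(list(perSite = perSite[0L, ],
                    overall = data.frame(nAnalyzed = 0L, nEdited = 0L,
                                         editedFraction = NA_real_)))
    }
    edited <- rowSums(statuses == "edited") > 0L
    overall <- data.frame(nAnalyzed = sum(covered),
                          nEdited = sum(edited & covered),
                          editedFraction = sum(edited & covered) /
                              sum(covered))
    list(perSite = perSite, overall = overall)
}

#' Read-level edited fraction at one guide site
#'
#' The fraction of callable spanning reads (pooled over the supplied reads,
#' e.g. one bulk library) whose allele call differs from the reference --
#' the per-site edited-read fraction reported for bulk RNA-seq of mosaic
#' knockout animals.
#'
#' @param reads a reads data.frame.
#' @param genome a named \code{DNAStringSet}.
#' @param site a one-row guide-site data.frame.
#' @param window optional half-width override (bp).
#' @return a one-row data.frame: \code{site}, \code{spanning},
#'   \code{edited}, \code{fraction} (\code{NA} when nothing spans).
#' @export
siteEditedReadFraction <- function(reads, genome, site, window = NULL) {
    span <- extractSiteReads(reads, site, window = window)
    chromCache <- list()
    chromCache[[site$chrom]] <- as.character(genome[[site$chrom]])
    if (nrow(span) == 0L) {
        return(data.frame(site = site$name, spanning = 0L, edited = 0L,
                          fraction = NA_real_, stringsAsFactors = FALSE))
    }
    callType <- vapply(seq_len(nrow(span)), function(j) {
        callReadAllele(span[j, , drop = FALSE], chromCache, site,
                       window = window)$call
    }, character(1))
    callable <- callType != "spliced"
    n <- sum(callable)
    e <- sum(callType[callable] != "match")
    data.frame(site = site$name, spanning = n, edited = e,
               fraction = if (n) e / n else NA_real_,
               stringsAsFactors = FALSE)
}
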