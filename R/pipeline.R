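#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-sided p-value:
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' When both groups have zero variance the statistic degenerates; it is
#' computed as defined, with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2 with finite values.
#' @return a one-row data.frame of class \code{GroupComparison}:
#'   \code{meanA}, \code{meanB}, \code{tStatistic}, \code{welchDf},
#'   \code{pValue} (two-sided).
#' @examples
#' welchT(c(10, 10, 10), c(20, 20, 21))
#' @export
welchT <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (!all(is.finite(c(a, b)))) stop("non-finite values in input")
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    se2 <- va + vb
    if (se2 == 0) {
        warning("both groups have zero variance; t statistic degenerates")
        t <- (mean(a) - mean(b)) / sqrt(se2)   # 0/0 -> NaN, d/0 -> +-Inf
        df <- NaN
        p <- if (is.nan(t)) NaN else 0
    } else {
        t <- (mean(a) - mean(b)) / sqrt(se2)
        df <- se2^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
        p <- 2 * stats::pt(-abs(t), df)
    }
    out <- data.frame(meanA = mean(a), meanB = mean(b), tStatistic = t,
                      welchDf = df, pValue = p)
    class(out) <- c("GroupComparison", class(out))
    out
}

#' Validate a pipeline run configuration
#'
#' A flat list of paths and stage parameters; every referenced path must
#' exist at validation time and parameters must lie in their documented
#' ranges. When \code{simulate} is \code{TRUE} the input paths are produced
#' by the generator and need not pre-exist.
#'
#' @param outDir output directory (created on run).
#' @param simulate generate the inputs with \code{\link{simulateReads}}.
#' @param referencePath,annotationPath,sitesPath,alignmentPaths input files
#'   (required unless \code{simulate}).
#' @param simConfig a \code{\link{simConfig}} (when \code{simulate}).
#' @param window,minSupport,maxErrorFrac genotyping parameters.
#' @param nmads QC threshold width.
#' @param spliceMode \code{"all_junctions"} or \code{"from_exon"}.
#' @param fromExon donor exon for \code{"from_exon"} mode.
#' @param maskedExons named list: gene id -> exon indices masked during
#'   counting (genomic-amplicon exons).
#' @param skipIsoform named list: gene id -> exon index whose skip form
#'   defines the effective-length mixture (FPKM is refused for masked genes
#'   without one).
#' @param seed RNG seed for the run.
#' @return the validated configuration, class \code{RunConfig}.
#' @export
runConfig <- function(outDir, simulate = TRUE, referencePath = NULL,
                      annotationPath = NULL, sitesPath = NULL,
                      alignmentPaths = NULL, simConfig = NULL,
                      window = NULL, minSupport = 1L, maxErrorFrac = 0,
                      nmads = 3, spliceMode = "from_exon", fromExon = 1L,
                      maskedExons = list(semX = c(2L, 10L)),
                      skipIsoform = list(cxcX = 2L), seed = 1L) {
    if (!simulate) {
        for (p in c(referencePath, annotationPath, sitesPath,
                    alignmentPaths)) {
            if (is.null(p) || !file.exists(p))
                stop("missing input path: ",
                     if (is.null(p)) "(unset)" else p)
        }
    }
    if (!spliceMode %in% c("all_junctions", "from_exon"))
        stop("spliceMode must be 'all_junctions' or 'from_exon'")
    if (minSupport < 1L) stop("minSupport must be >= 1")
    if (maxErrorFrac < 0 || maxErrorFrac >= 1)
        stop("maxErrorFrac must be in [0, 1)")
    if (nmads <= 0) stop("nmads must be > 0")
    structure(list(outDir = outDir, simulate = simulate,
                   referencePath = referencePath,
                   annotationPath = annotationPath, sitesPath = sitesPath,
                   alignmentPaths = alignmentPaths, simConfig = simConfig,
                   window = window, minSupport = as.integer(minSupport),
                   maxErrorFrac = maxErrorFrac, nmads = nmads,
                   spliceMode = spliceMode, fromExon = as.integer(fromExon),
                   maskedExons = maskedExons, skipIsoform = skipIsoform,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

logMsg <- function(level, ...) {
    message("[", level, "] ", ...)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional) -> QC -> genotype -> ORF ->
#' splice -> quantify -> compare, writing one TSV per stage into
#' \code{config$outDir}, plus a structured log line per stage on standard
#' error. Outputs are byte-deterministic for a given configuration
#' (timestamps live only in the log). Any stage failure aborts with a
#' stage-named error; earlier outputs are retained.
#'
#' @param config a validated \code{\link{runConfig}}.
#' @return (invisibly) a list with the key result tables and the paths of
#'   every written file.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    stage <- function(name, expr) {
        logMsg("info", "stage ", name, " (seed ", config$seed, ")")
        tryCatch(expr, error = function(e) {
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }
    ## ---- inputs ----
    if (config$simulate) {
        sc <- config$simConfig
        if (is.null(sc)) sc <- simConfig(seed = config$seed)
        dat <- stage("simulate", {
            toy <- makeToyReference(seed = config$seed)
            sim <- simulateReads(sc, toy$genome, toy$models, toy$sites,
                                 outDir = file.path(config$outDir, "sim"))
            list(genome = toy$genome, models = toy$models,
                 sites = toy$sites, reads = sim$reads, truth = sim$truth)
        })
    } else {
        dat <- stage("load", {
            genome <- readGenome(config$referencePath)
            models <- readGeneModels(config$annotationPath)
            sites <- readGuideSites(config$sitesPath)
            reads <- readAlignments(config$alignmentPaths)
            list(genome = genome, models = models, sites = sites,
                 reads = reads, truth = NULL)
        })
    }
    genome <- dat$genome
    models <- dat$models
    sites <- dat$sites
    reads <- dat$reads
    samples <- sort(unique(reads$sampleId))
    ## ---- counts + QC ----
    qc <- stage("qc", {
        cm <- countMatrixFromReads(reads, models)
        rep <- qcFilterCells(cm, nmads = config$nmads)
        paths$counts <- writeTsv(
            data.frame(gene = rownames(cm),
                       SummarizedExperiment::assay(cm, "counts"),
                       check.names = FALSE),
            file.path(config$outDir, "counts.tsv"))
        paths$qc <- writeTsv(rep, file.path(config$outDir, "qc.tsv"))
        list(cm = cm, report = rep)
    })
    ## ---- genotyping ----
    geno <- stage("genotype", {
        gts <- lapply(samples, function(s) {
            genotypeSample(reads[reads$sampleId == s, , drop = FALSE],
                           genome, sites, minSupport = config$minSupport,
                           maxErrorFrac = config$maxErrorFrac,
                           window = config$window)
        })
        events <- do.call(rbind, c(lapply(gts, `[[`, "events"),
                                   list(data.frame())))
        statuses <- do.call(rbind, lapply(gts, function(g) {
            data.frame(sampleId = g$sampleId, t(g$status),
                       check.names = FALSE, stringsAsFactors = FALSE)
        }))
        cohort <- summarizeCohort(gts)
        paths$events <- writeTsv(events,
                                  file.path(config$outDir, "events.tsv"))
        paths$genotypes <- writeTsv(statuses,
                                     file.path(config$outDir,
                                               "genotypes.tsv"))
        paths$cohort <- writeTsv(cbind(cohort$perSite),
                                  file.path(config$outDir,
                                            "cohort_per_site.tsv"))
        paths$cohortOverall <- writeTsv(cohort$overall,
                                         file.path(config$outDir,
                                                   "cohort_overall.tsv"))
        list(genotypes = gts, events = events, cohort = cohort)
    })
    ## ---- ORF consequences (one report per distinct small allele) ----
    orf <- stage("orf", {
        ev <- geno$events
        reports <- list()
        if (nrow(ev)) {
            ev <- ev[ev$category != "large_deletion", , drop = FALSE]
            uniq <- unique(ev[, c("site", "allele", "category")])
            for (i in seq_len(nrow(uniq))) {
                siteRow <- sites[sites$name == uniq$site[i], , drop = FALSE]
                g <- names(models)[vapply(models, function(m) {
                    geneChrom(m) == siteRow$chrom &&
                        any(siteRow$cut_pos >=
                                IRanges::start(exonRanges(m)) &
                            siteRow$cut_pos <= IRanges::end(exonRanges(m)))
                }, logical(1))][1L]
                if (is.na(g)) next
                event <- alleleStringToEvent(uniq$allele[i])
                if (is.null(event)) next
                var <- applyEdit(models[[g]], genome, event)
                rep <- translateOrf(var, models[[g]])
                rep$site <- uniq$site[i]
                rep$allele <- uniq$allele[i]
                reports[[length(reports) + 1L]] <- rep
            }
        }
        reports <- if (length(reports)) do.call(rbind, reports) else
            data.frame()
        paths$orf <- writeTsv(reports, file.path(config$outDir, "orf.tsv"))
        reports
    })
    ## ---- splicing ----
    splice <- stage("splice", {
        rows <- list()
        for (g in names(config$skipIsoform)) {
            model <- models[[g]]
            for (s in samples) {
                rs <- reads[reads$sampleId == s, , drop = FALSE]
                for (mode in unique(c(config$spliceMode,
                                      "all_junctions"))) {
                    sm <- suppressWarnings(aberrantFraction(
                        rs, model, mode = mode,
                        fromExon = config$fromExon))
                    sm$sampleId <- s
                    rows[[length(rows) + 1L]] <- sm
                }
            }
        }
        out <- if (length(rows)) do.call(rbind, rows) else data.frame()
        paths$splice <- writeTsv(out,
                                  file.path(config$outDir, "splice.tsv"))
        out
    })
    ## ---- quantification ----
    quant <- stage("quantify", {
        libSize <- SummarizedExperiment::colData(qc$cm)$librarySize
        names(libSize) <- colnames(qc$cm)
        rows <- list()
        for (g in names(models)) {
            model <- models[[g]]
            mask <- config$maskedExons[[g]]
            if (is.null(mask)) mask <- integer(0)
            skipEx <- config$skipIsoform[[g]]
            lenFull <- transcriptLength(model)
            for (s in samples) {
                rs <- reads[reads$sampleId == s, , drop = FALSE]
                cnt <- countReadsMasked(rs, model, maskedExons = mask)
                cpm <- if (libSize[s] > 0)
                    libsizeNormalize(cnt, libSize[s]) else NA_real_
                effLen <- NA_real_
                fpkm <- NA_real_
                if (!is.null(skipEx) && libSize[s] > 0) {
                    sm <- splice[splice$sampleId == s &
                                 splice$geneId == g &
                                 splice$mode != "all_junctions", ,
                                 drop = FALSE]
                    rA <- if (nrow(sm) && !is.na(sm$fraction[1L]))
                        sm$fraction[1L] else NA_real_
                    if (!is.na(rA)) {
                        w <- IRanges::width(exonRanges(model))
                        lenSkip <- lenFull -
                            sum(w[exonIndex(model) %in% skipEx])
                        effLen <- effectiveLength(lenFull, lenSkip, rA)
                        fpkm <- fpkmManual(cnt, libSize[s], effLen)
                    }
                } else if (length(mask) == 0L && libSize[s] > 0) {
                    effLen <- lenFull
                    fpkm <- fpkmManual(cnt, libSize[s], effLen)
                }
                ## masked genes without a declared skip isoform: FPKM
                ## refused (effective length not reliably computable)
                rows[[length(rows) + 1L]] <- data.frame(
                    sampleId = s, gene = g, rawCount = cnt, cpm = cpm,
                    effectiveLength = effLen, fpkm = fpkm,
                    stringsAsFactors = FALSE)
            }
        }
        out <- do.call(rbind, rows)
        paths$quant <- writeTsv(out,
                                 file.path(config$outDir,
                                           "quantification.tsv"))
        out
    })
    ## ---- group comparison: edited vs unedited samples ----
    compare <- stage("compare", {
        statuses <- do.call(rbind, lapply(geno$genotypes, function(g) {
            data.frame(sampleId = g$sampleId,
                       edited = any(g$status == "edited"),
                       covered = any(g$status != "no_coverage"),
                       stringsAsFactors = FALSE)
        }))
        rows <- list()
        for (g in names(models)) {
            q <- quant[quant$gene == g, , drop = FALSE]
            m <- merge(q, statuses, by = "sampleId")
            a <- m$cpm[m$edited & m$covered & is.finite(m$cpm)]
            b <- m$cpm[!m$edited & m$covered & is.finite(m$cpm)]
            if (length(a) >= 2L && length(b) >= 2L &&
                (stats::var(a) + stats::var(b)) > 0) {
                w <- welchT(a, b)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene = g, nEdited = length(a), nUnedited = length(b),
                    w, stringsAsFactors = FALSE)
            }
        }
        out <- if (length(rows)) do.call(rbind, rows) else data.frame()
        paths$compare <- writeTsv(out,
                                   file.path(config$outDir,
                                             "comparisons.tsv"))
        out
    })
    logMsg("info", "pipeline complete: ", config$outDir)
    invisible(list(qc = qc$report, events = geno$events,
                   cohort = geno$cohort, orf = orf, splice = splice,
                   quantification = quant, comparisons = compare,
                   truth = dat$truth, paths = paths))
}

## Parse a genotyper allele string back into an editing event (first
## component wins for compound alleles' span bookkeeping; all components
## are applied for indel+substitution compounds via sequential events).
alleleStringToEvent <- function(allele) {
    parts <- strsplit(allele, ";", fixed = TRUE)[[1L]]
    if (!length(parts)) return(NULL)
    ## apply the first indel component, or the first substitution
    for (p in parts) {
        if (startsWith(p, "D:")) {
            span <- as.integer(strsplit(sub("^D:", "", p), "-")[[1L]])
            return(list(category = "indel", refStart = span[1L],
                        refEnd = span[2L], alt = ""))
        }
        if (startsWith(p, "I:")) {
            bits <- strsplit(sub("^I:", "", p), ":", fixed = TRUE)[[1L]]
            return(list(category = "indel",
                        refStart = as.integer(bits[1L]),
                        refEnd = as.integer(bits[1L]), alt = bits[2L]))
        }
    }
    p <- parts[1L]
    if (startsWith(p, "S:")) {
        bits <- strsplit(sub("^S:", "", p), ":", fixed = TRUE)[[1L]]
        refAlt <- strsplit(bits[2L], ">", fixed = TRUE)[[1L]]
        s <- as.integer(bits[1L])
        return(list(category = "substitution", refStart = s,
                    refEnd = s + nchar(refAlt[2L]) - 1L, alt = refAlt[2L]))
    }
    NULL
}
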