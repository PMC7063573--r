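#' MAD-based single-cell quality-control filtering
#'
#' A library fails \code{low_libsize} if its size is more than \code{nmads}
#' median absolute deviations below the median library size of the whole
#' dataset; \code{low_genes} if its number of detected genes (count > 0) is
#' more than \code{nmads} MADs below the median; and \code{high_ercc} if its
#' spike-in count fraction is more than \code{nmads} MADs above the median.
#' The MAD uses the 1.4826 normal-consistency scaling and is computed on raw
#' values. When a MAD is 0 the threshold degenerates to the median; a
#' warning is emitted and the rule applied as stated (strict inequality, so
#' ties with the median pass).
#'
#' @param object a count \code{SummarizedExperiment} (see
#'   \code{\link{countMatrix}}) or a plain counts matrix.
#' @param erccPattern regular expression identifying spike-in feature names
#'   (default \code{"^ERCC-"}).
#' @param nmads number of MADs (default 3).
#' @param madConstant MAD scale factor (default \code{1.4826}).
#' @return a data.frame per sample: \code{sampleId}, \code{librarySize},
#'   \code{nGenesDetected}, \code{erccFraction}, the three logical
#'   \code{fail*} columns, \code{failReasons} (comma-separated) and
#'   \code{pass}.
#' @export
qcFilterCells <- function(object, erccPattern = "^ERCC-", nmads = 3,
                          madConstant = 1.4826) {
    counts <- if (methods::is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "counts") else object
    if (ncol(counts) < 4L)
        stop("MAD-based QC needs at least 4 samples")
    ercc <- grepl(erccPattern, rownames(counts))
    libSize <- colSums(counts)
    nGenes <- colSums(counts > 0)
    erccFrac <- if (any(ercc)) {
        colSums(counts[ercc, , drop = FALSE]) / pmax(libSize, 1)
    } else rep(0, ncol(counts))
    lowCut <- function(x) {
        m <- stats::mad(x, constant = madConstant)
        if (m == 0) warning("MAD is 0; threshold degenerates to the median")
        stats::median(x) - nmads * m
    }
    highCut <- function(x) {
        m <- stats::mad(x, constant = madConstant)
        if (m == 0) warning("MAD is 0; threshold degenerates to the median")
        stats::median(x) + nmads * m
    }
    failLib <- libSize < lowCut(libSize)
    failGenes <- nGenes < lowCut(nGenes)
    failErcc <- erccFrac > highCut(erccFrac)
    reasons <- vapply(seq_len(ncol(counts)), function(i) {
        paste(c(if (failLib[i]) "low_libsize",
                if (failGenes[i]) "low_genes",
                if (failErcc[i]) "high_ercc"), collapse = ",")
    }, character(1))
    data.frame(sampleId = colnames(counts), librarySize = unname(libSize),
               nGenesDetected = unname(nGenes),
               erccFraction = unname(erccFrac),
               failLowLibsize = unname(failLib),
               failLowGenes = unname(failGenes),
               failHighErcc = unname(failErcc),
               failReasons = reasons, pass = !nzchar(reasons),
               stringsAsFactors = FALSE)
}

#' Filter genes by mean expression and exclusion lists
#'
#' Keeps genes whose mean count across all cells is at least \code{minMean}
#' and that are not named in any exclusion list (e.g. mitochondrial genes,
#' cell-cycle-annotated genes, or user-supplied lists). Exclusion-list
#' entries naming unknown genes raise a warning, not an error.
#'
#' @param object a count \code{SummarizedExperiment} or counts matrix.
#' @param minMean minimum mean count (default 0.1).
#' @param exclude character vector (or list of vectors) of gene ids to drop
#'   regardless of expression.
#' @return the filtered object (same class as the input).
#' @export
filterGenes <- function(object, minMean = 0.1, exclude = character(0)) {
    counts <- if (methods::is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "counts") else object
    exclude <- unique(unlist(exclude, use.names = FALSE))
    unknown <- setdiff(exclude, rownames(counts))
    if (length(unknown))
        warning("exclusion list names unknown genes: ",
                paste(unknown, collapse = ", "))
    keep <- rowMeans(counts) >= minMean & !(rownames(counts) %in% exclude)
    if (methods::is(object, "SummarizedExperiment")) object[keep, ]
    else object[keep, , drop = FALSE]
}

#' FPKM transformation of a count matrix
#'
#' \code{fpkm(g, s) = counts(g, s) / (librarySize(s) / 1e6) /
#' (geneLengthBp(g) / 1e3)}. Library sizes are taken from the container's
#' \code{colData} (fixed at construction, so subsetting genes does not
#' silently change the denominator).
#'
#' @param object a count \code{SummarizedExperiment} with
#'   \code{rowData$geneLengthBp} and \code{colData$librarySize}.
#' @param log2Offset pseudocount recorded for log display (metadata only,
#'   never applied to the stored values).
#' @return the object with an added \code{fpkm} assay.
#' @export
computeFpkm <- function(object, log2Offset = 1) {
    counts <- SummarizedExperiment::assay(object, "counts")
    libSize <- SummarizedExperiment::colData(object)$librarySize
    lens <- SummarizedExperiment::rowData(object)$geneLengthBp
    if (is.null(libSize) || is.null(lens))
        stop("object must carry colData$librarySize and rowData$geneLengthBp")
    if (any(libSize <= 0))
        stop("zero library size for sample(s): ",
             paste(colnames(counts)[libSize <= 0], collapse = ", "))
    fpkm <- sweep(sweep(counts, 2L, libSize / 1e6, "/"), 1L, lens / 1e3, "/")
    SummarizedExperiment::assay(object, "fpkm") <- fpkm
    S4Vectors::metadata(object)$log2Offset <- log2Offset
    object
}

#' Classify cells by marker co-expression combinations
#'
#' A marker is called positive in a cell iff its FPKM exceeds
#' \code{threshold}. Each cell is labelled with the set of positive markers
#' (e.g. \code{"tcf21+wt1b"}) or \code{"none"}; per group, the fraction of
#' cells carrying each combination is reported (fractions over all
#' combinations including \code{"none"} sum to 1).
#'
#' @param object a \code{SummarizedExperiment} with an \code{fpkm} assay
#'   (see \code{\link{computeFpkm}}) or a plain FPKM matrix.
#' @param markers character vector of marker gene ids (order fixes the
#'   label order).
#' @param threshold positivity cut on FPKM (default 0: any detected
#'   expression).
#' @param groups optional per-cell group labels (cluster/region), recycled
#'   to one group \code{"all"} when absent. Groups with zero cells are
#'   omitted with a warning.
#' @return a list with \code{calls} (per cell: logical state per marker and
#'   \code{label}) and \code{fractions} (per group x combination:
#'   \code{n}, \code{fraction}).
#' @export
classifyMarkerCombinations <- function(object, markers, threshold = 0,
                                       groups = NULL) {
    fpkm <- if (methods::is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "fpkm") else object
    if (!all(markers %in% rownames(fpkm)))
        stop("markers absent from the matrix: ",
             paste(setdiff(markers, rownames(fpkm)), collapse = ", "))
    pos <- t(fpkm[markers, , drop = FALSE] > threshold)
    label <- apply(pos, 1L, function(p) {
        if (!any(p)) "none" else paste(markers[p], collapse = "+")
    })
    calls <- data.frame(sampleId = colnames(fpkm), pos, label = label,
                        stringsAsFactors = FALSE, row.names = NULL)
    names(calls)[seq_along(markers) + 1L] <- markers
    if (is.null(groups)) groups <- rep("all", ncol(fpkm))
    if (is.factor(groups)) {
        empty <- setdiff(levels(groups), unique(as.character(groups)))
        if (length(empty))
            warning("group(s) with zero cells omitted: ",
                    paste(empty, collapse = ", "))
        groups <- as.character(groups)
    }
    combos <- c(unlist(lapply(seq_along(markers), function(k) {
        apply(utils::combn(markers, k), 2L, paste, collapse = "+")
    })), "none")
    fractions <- do.call(rbind, lapply(unique(groups), function(g) {
        lab <- label[groups == g]
        n <- vapply(combos, function(cb) sum(lab == cb), integer(1))
        data.frame(group = g, combination = combos, n = n,
                   fraction = n / length(lab), stringsAsFactors = FALSE,
                   row.names = NULL)
    }))
    list(calls = calls, fractions = fractions)
}
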