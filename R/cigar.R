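#' Parse a CIGAR string
#'
#' Splits a SAM CIGAR string into its operations and lengths. Operations are
#' restricted to the SAM alphabet \code{M I D N S H P = X}.
#'
#' @param cigar a single CIGAR string, e.g. \code{"30M2I38M"}.
#' @return a \code{data.frame} with columns \code{op} and \code{len}, one row
#'   per operation, in read order. \code{"*"} yields zero rows.
#' @examples
#' parseCigar("30M2I38M")
#' @export
parseCigar <- function(cigar) {
    stopifnot(is.character(cigar), length(cigar) == 1L)
    if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
        return(data.frame(op = character(0), len = integer(0)))
    }
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
    if (length(lens) != length(ops) ||
        paste0(lens, ops, collapse = "") != cigar) {
        stop("malformed CIGAR string: ", cigar)
    }
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

#' Query and reference widths of a CIGAR
#'
#' \code{cigarQueryWidth} counts query-consuming bases (\code{M I S = X});
#' \code{cigarRefWidth} counts reference-consuming bases (\code{M D N = X}).
#' Hard clips (\code{H}) consume neither.
#'
#' @param cigar a single CIGAR string.
#' @return an integer.
#' @export
cigarQueryWidth <- function(cigar) {
    cw <- parseCigar(cigar)
    sum(cw$len[cw$op %in% c("M", "I", "S", "=", "X")])
}

#' @rdname cigarQueryWidth
#' @export
cigarRefWidth <- function(cigar) {
    cw <- parseCigar(cigar)
    sum(cw$len[cw$op %in% c("M", "D", "N", "=", "X")])
}

#' Walk a CIGAR over reference and query coordinates
#'
#' Expands a CIGAR into per-operation 1-based inclusive reference and query
#' intervals, starting from the read's leftmost aligned reference position.
#' Non-consuming operations get an empty interval (\code{end = start - 1}).
#'
#' @param pos 1-based leftmost aligned reference position of the read.
#' @param cigar the read's CIGAR string.
#' @return a \code{data.frame} with columns \code{op}, \code{len},
#'   \code{refStart}, \code{refEnd}, \code{qStart}, \code{qEnd}.
#' @export
cigarWalk <- function(pos, cigar) {
    cw <- parseCigar(cigar)
    n <- nrow(cw)
    refStart <- refEnd <- qStart <- qEnd <- integer(n)
    r <- as.integer(pos)
    q <- 1L
    for (i in seq_len(n)) {
        op <- cw$op[i]
        len <- cw$len[i]
        cr <- op %in% c("M", "D", "N", "=", "X")
        cq <- op %in% c("M", "I", "S", "=", "X")
        refStart[i] <- r
        refEnd[i] <- if (cr) r + len - 1L else r - 1L
        qStart[i] <- q
        qEnd[i] <- if (cq) q + len - 1L else q - 1L
        if (cr) r <- r + len
        if (cq) q <- q + len
    }
    cbind(cw, data.frame(refStart = refStart, refEnd = refEnd,
                         qStart = qStart, qEnd = qEnd))
}

## Reference footprint [start, end] of an aligned read (M/D/N/=/X consume).
readFootprint <- function(pos, cigar) {
    c(as.integer(pos), as.integer(pos) + cigarRefWidth(cigar) - 1L)
}
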