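# Accessors, subsetting and show methods.

#' @rdname UTRSet-class
#' @export
setMethod("geneIds", "UTRSet", function(x) x@geneId)

#' @rdname UTRSet-class
#' @export
setMethod("accessions", "UTRSet", function(x) x@accession)

#' @rdname UTRSet-class
#' @export
setMethod("utrLength", "UTRSet", function(x)
    setNames(width(x@seq), x@accession))

#' @rdname UTRSet-class
#' @export
setMethod("utrSeqs", "UTRSet", function(x)
    setNames(x@seq, x@accession))

#' @rdname UTRSet-class
#' @export
setMethod("utrRanges", "UTRSet", function(x)
    setNames(x@ranges, x@accession))

#' @rdname UTRSet-class
#' @export
setMethod("length", "UTRSet", function(x) length(x@accession))

#' @rdname UTRSet-class
#' @param i index: integer, logical, or accession character
#' @param j,...,drop ignored
#' @export
setMethod("[", "UTRSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i))
        i <- match(i, x@accession)
    if (anyNA(i))
        stop("unknown accession in subset")
    new("UTRSet",
        geneId = x@geneId[i], accession = x@accession[i],
        ranges = x@ranges[i], seq = x@seq[i])
})

setMethod("show", "UTRSet", function(object) {
    cat("UTRSet with", length(object), "UTR model(s),",
        length(unique(object@geneId)), "gene(s)\n")
    if (length(object) > 0L)
        cat("  length range:", min(width(object@seq)), "-",
            max(width(object@seq)), "nt\n")
})

#' @rdname ConservationTrack-class
#' @param object,x a ConservationTrack
#' @export
setMethod("show", "ConservationTrack", function(object) {
    cat("ConservationTrack:", length(object@gr), "scored interval(s) on",
        length(unique(as.character(seqnames(object@gr)))), "chromosome(s);",
        sum(width(object@gr)), "covered base(s)\n")
})

#' @rdname PositionalProfile-class
#' @param object a PositionalProfile
#' @export
setMethod("show", "PositionalProfile", function(object) {
    nb <- length(object@binEdges) - 1L
    cat("PositionalProfile anchored at '", object@anchor, "': ", nb,
        " bin(s) spanning [", object@binEdges[1L], ", ",
        object@binEdges[nb + 1L], "), ", object@nGenes, " gene(s)\n",
        sep = "")
    cat("  conserved sites:", sum(object@countsConserved),
        " non-conserved:", sum(object@countsNonconserved), "\n")
})

#' @rdname PositionalProfile-class
#' @export
setMethod("binEdges", "PositionalProfile", function(x) x@binEdges)

#' @rdname PositionalProfile-class
#' @return \code{siteCounts}: data.frame with bin edges and per-bin conserved /
#'   non-conserved counts and contributing-gene counts.
#' @export
setMethod("siteCounts", "PositionalProfile", function(x) {
    nb <- length(x@binEdges) - 1L
    data.frame(
        bin_start = x@binEdges[-(nb + 1L)],
        bin_end = x@binEdges[-1L],
        count_conserved = x@countsConserved,
        count_nonconserved = x@countsNonconserved,
        genes_per_bin = x@genesPerBin
    )
})

#' @rdname PermTestResult-class
#' @export
setMethod("pValues", "PermTestResult", function(x)
    setNames(x@pValues, .binLabels(x@binEdges)))

#' @rdname PermTestResult-class
#' @export
setMethod("observedStat", "PermTestResult", function(x)
    setNames(x@observed, .binLabels(x@binEdges)))

#' @rdname PermTestResult-class
#' @export
setMethod("nullStats", "PermTestResult", function(x) x@nullStats)

#' @rdname PermTestResult-class
#' @export
setMethod("binEdges", "PermTestResult", function(x) x@binEdges)

setMethod("show", "PermTestResult", function(object) {
    cat("PermTestResult ('", object@test, "'): ", object@nIter,
        " iterations, seed ", object@seed, "\n", sep = "")
    sig <- sum(object@pValues < 0.05)
    cat("  ", length(object@pValues), " bin(s); ", sig,
        " with one-sided p < 0.05\n", sep = "")
})

.binLabels <- function(edges) {
    nb <- length(edges) - 1L
    sprintf("[%d,%d)", edges[-(nb + 1L)], edges[-1L])
}

#' Tabular view of a permutation test result
#'
#' @param x a PermTestResult
#' @return data.frame with bin edges, observed statistic, null mean/sd and
#'   one-sided p-value per bin.
#' @export
permTestTable <- function(x) {
    stopifnot(is(x, "PermTestResult"))
    nb <- length(x@binEdges) - 1L
    data.frame(
        bin_start = x@binEdges[-(nb + 1L)],
        bin_end = x@binEdges[-1L],
        observed = x@observed,
        null_mean = colMeans(x@nullStats),
        null_sd = apply(x@nullStats, 2L, stats::sd),
        p_value = x@pValues
    )
}
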