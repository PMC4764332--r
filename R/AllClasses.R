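#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import Biostrings
NULL

#' UTRSet: a collection of 3'UTR models
#'
#' One element per transcript accession: an ordered set of genomic intervals
#' on a single chromosome/strand plus the spliced UTR sequence in transcript
#' sense orientation (5' to 3').  UTR-relative coordinates used throughout the
#' package are 0-based: position 0 is the 5'-most transcript-sense base of the
#' UTR.  Genomic coordinates follow the GRanges convention (1-based, closed).
#'
#' @slot geneId character vector of gene identifiers (one per element).
#' @slot accession character vector of transcript accessions (unique).
#' @slot ranges \code{GRangesList}; each element's ranges are stored in
#'   transcript-sense 5' to 3' order, all on one chromosome and strand.
#' @slot seq \code{DNAStringSet} of spliced UTR sequences, sense orientation.
#'
#' @seealso [readUtrModels()], [genomicToUtr()], [utrToGenomic()]
#' @export
setClass("UTRSet",
    representation(
        geneId = "character",
        accession = "character",
        ranges = "GRangesList",
        seq = "DNAStringSet"
    )
)

setValidity("UTRSet", function(object) {
    n <- length(object@accession)
    if (length(object@geneId) != n || length(object@ranges) != n ||
        length(object@seq) != n)
        return("geneId, accession, ranges and seq must have equal length")
    if (anyDuplicated(object@accession))
        return("accessions must be unique")
    if (n == 0L)
        return(TRUE)
    rw <- sum(width(object@ranges))
    sw <- width(object@seq)
    if (!all(rw == sw))
        return("sum of interval widths must equal sequence length")
    nstr <- elementNROWS(unique(strand(object@ranges)))
    nchr <- elementNROWS(unique(seqnames(object@ranges)))
    if (any(nstr != 1L) || any(nchr != 1L))
        return("each UTR model must lie on a single chromosome and strand")
    TRUE
})

#' ConservationTrack: a sparse per-base conservation score track
#'
#' Wraps a set of scored genomic intervals (e.g. read from bedGraph).
#' Positions not covered by any interval are *missing*: queries return
#' \code{NA}, never a silent 0.
#'
#' @slot gr disjoint \code{GRanges} with a numeric \code{score} column.
#' @seealso [readConservationTrack()], [trackScores()], [conservationProfile()]
#' @export
setClass("ConservationTrack", representation(gr = "GRanges"))

setValidity("ConservationTrack", function(object) {
    if (is.null(object@gr$score) || !is.numeric(object@gr$score))
        return("track requires a numeric 'score' metadata column")
    if (!isDisjoint(object@gr))
        return("track intervals must be disjoint")
    TRUE
})

#' PositionalProfile: binned site counts around an anchor
#'
#' Counts of conserved and non-conserved seed-match sites in fixed-width bins
#' of UTR-relative distance from a per-gene anchor (the 5'-most APA site, or
#' the full-length UTR end).  Negative distances are 5' (upstream) of the
#' anchor; a site at distance 0 belongs to the first downstream bin.
#'
#' @slot anchor "apa" or "utr_end".
#' @slot binEdges integer vector of length nbins+1 (contiguous, equal width).
#' @slot countsConserved,countsNonconserved integer per-bin site counts.
#' @slot nGenes number of genes contributing to the profile.
#' @slot genesPerBin number of genes whose UTR sequence fully covers each bin.
#' @seealso [profileSites()]
#' @export
setClass("PositionalProfile",
    representation(
        anchor = "character",
        binEdges = "integer",
        countsConserved = "integer",
        countsNonconserved = "integer",
        nGenes = "integer",
        genesPerBin = "integer"
    )
)

setValidity("PositionalProfile", function(object) {
    nb <- length(object@binEdges) - 1L
    if (nb < 1L)
        return("need at least one bin")
    w <- diff(object@binEdges)
    if (any(w <= 0L) || length(unique(w)) != 1L)
        return("bins must be contiguous with equal positive width")
    if (length(object@countsConserved) != nb ||
        length(object@countsNonconserved) != nb ||
        length(object@genesPerBin) != nb)
        return("per-bin slots must have length nbins")
    if (any(object@countsConserved < 0L) || any(object@countsNonconserved < 0L))
        return("counts must be non-negative")
    TRUE
})

#' PermTestResult: a positional randomization/permutation test result
#'
#' Shared container for the randomized-APA null, the two-set partition test
#' and the cluster-versus-all test.  Holds the observed per-bin statistic, the
#' stored null ensemble, and +1-corrected one-sided p-values
#' \code{(1 + #\{null >= observed\}) / (1 + nIter)}.
#'
#' @slot test one of "randomized_apa", "two_set_partition", "cluster_vs_all".
#' @slot binEdges integer vector of bin edges (distance from anchor).
#' @slot observed numeric observed per-bin statistic.
#' @slot nullStats numeric matrix, nIter rows x nbins columns.
#' @slot pValues numeric per-bin one-sided p-values in (0, 1].
#' @slot nIter number of randomization iterations.
#' @slot seed integer seed used for the ensemble.
#' @slot info list of test-specific details (group sizes, gene counts).
#' @seealso [randomizedApaNull()], [twoSetPartitionTest()], [clusterVsAllTest()]
#' @export
setClass("PermTestResult",
    representation(
        test = "character",
        binEdges = "integer",
        observed = "numeric",
        nullStats = "matrix",
        pValues = "numeric",
        nIter = "integer",
        seed = "integer",
        info = "list"
    )
)

setValidity("PermTestResult", function(object) {
    nb <- length(object@binEdges) - 1L
    if (length(object@observed) != nb || length(object@pValues) != nb)
        return("observed and pValues must have length nbins")
    if (ncol(object@nullStats) != nb)
        return("nullStats must have nbins columns")
    if (nrow(object@nullStats) != object@nIter)
        return("nullStats must have nIter rows")
    if (any(object@pValues <= 0) || any(object@pValues > 1))
        return("pValues must lie in (0, 1]")
    TRUE
})
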