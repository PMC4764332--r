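# Codon-usage vectors and codon-usage based gene-set expansion.

.senseCodons <- function() {
    all <- mkAllStrings(c("A", "C", "G", "T"), 3L)
    setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Codon-usage vector of a coding sequence
#'
#' Counts the 61 sense codons of an in-frame CDS and normalizes to relative
#' frequencies.  A terminal stop codon is trimmed; an internal stop codon or
#' a length not divisible by 3 is an error.
#'
#' @param cds a DNAString or character coding sequence
#' @return named numeric vector of 61 sense-codon frequencies (sums to 1),
#'   with attribute \code{n_codons}
#' @export
codonUsage <- function(cds) {
    if (!is(cds, "DNAString"))
        cds <- DNAString(toupper(as.character(cds)))
    stops <- c("TAA", "TAG", "TGA")
    if (length(cds) %% 3L != 0L)
        stop("CDS length (", length(cds), ") is not divisible by 3")
    if (length(cds) >= 3L &&
        as.character(subseq(cds, length(cds) - 2L, length(cds))) %in% stops)
        cds <- subseq(cds, 1L, length(cds) - 3L)
    if (length(cds) == 0L)
        stop("CDS has no sense codons")
    counts <- trinucleotideFrequency(cds, step = 3L)
    if (any(counts[stops] > 0L))
        stop("internal stop codon in CDS")
    sense <- .senseCodons()
    f <- counts[sense]
    n <- sum(f)
    if (n < 1L)
        stop("CDS has no sense codons")
    out <- f / n
    attr(out, "n_codons") <- as.integer(n)
    out
}

#' Codon-usage matrix for a set of coding sequences
#'
#' @param cds a named DNAStringSet (or FASTA path) of in-frame CDSs
#' @return numeric matrix, one row per gene, 61 sense-codon columns
#' @export
codonUsageMatrix <- function(cds) {
    if (is.character(cds) && length(cds) == 1L && file.exists(cds))
        cds <- readDNAStringSet(cds)
    if (is.null(names(cds)))
        stop("CDS sequences must be named by gene id")
    names(cds) <- sub("\\s.*$", "", names(cds))
    sense <- .senseCodons()
    m <- matrix(0, nrow = length(cds), ncol = length(sense),
                dimnames = list(names(cds), sense))
    for (i in seq_along(cds))
        m[i, ] <- codonUsage(cds[[i]])
    m
}

#' Expand a seed gene set by codon-usage correlation
#'
#' The seed set's centroid is the arithmetic mean of its members' codon-usage
#' vectors; a gene joins the expanded set iff the Pearson correlation between
#' its vector and the centroid is at least \code{threshold}.  Seed genes are
#' always retained.
#'
#' @param seedGenes character vector of seed gene ids (>= 2, all present in
#'   \code{usage})
#' @param usage codon-usage matrix from [codonUsageMatrix()]
#' @param threshold Pearson correlation threshold in (0, 1)
#' @return character vector of expanded gene ids, with attribute
#'   \code{correlations} (named numeric, all genes vs the centroid)
#' @export
expandGeneSet <- function(seedGenes, usage, threshold) {
    stopifnot(threshold > 0, threshold < 1)
    if (length(seedGenes) < 2L)
        stop("seed set must contain at least 2 genes")
    if (!all(seedGenes %in% rownames(usage)))
        stop("seed gene(s) missing from the usage matrix: ",
             paste(setdiff(seedGenes, rownames(usage)), collapse = ", "))
    centroid <- colMeans(usage[seedGenes, , drop = FALSE])
    r <- as.vector(stats::cor(t(usage), centroid))
    names(r) <- rownames(usage)
    out <- union(seedGenes, rownames(usage)[r >= threshold])
    attr(out, "correlations") <- r
    out
}

#' Expand two competing seed sets by codon-usage correlation
#'
#' Both sets are expanded as in [expandGeneSet()]; a non-seed gene qualifying
#' for both is assigned to the set with the higher correlation (exact ties
#' are excluded from both).  Seed genes always stay in their own set.
#'
#' @param seedA,seedB disjoint character vectors of seed gene ids
#' @inheritParams expandGeneSet
#' @return list with elements \code{A} and \code{B}: expanded gene id vectors
#' @export
expandCompetingSets <- function(seedA, seedB, usage, threshold) {
    if (length(intersect(seedA, seedB)))
        stop("seed sets must be disjoint")
    eA <- expandGeneSet(seedA, usage, threshold)
    eB <- expandGeneSet(seedB, usage, threshold)
    rA <- attr(eA, "correlations")
    rB <- attr(eB, "correlations")
    both <- setdiff(intersect(eA, eB), c(seedA, seedB))
    dropA <- both[rB[both] > rA[both] | rA[both] == rB[both]]
    dropB <- both[rA[both] > rB[both] | rA[both] == rB[both]]
    list(A = setdiff(as.vector(eA), dropA),
         B = setdiff(as.vector(eB), dropB))
}

#' Load externally defined gene sets
#'
#' @param path two-column TSV (set name, gene id), no header required; a
#'   header line "name\\tgene_id" is tolerated
#' @return named list of character vectors (duplicates removed), with
#'   attribute \code{provenance = "external"}
#' @export
loadGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L)
        stop("empty gene-set file: ", path)
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 2L))
        stop("gene-set file must have two tab-separated columns")
    df <- data.frame(name = vapply(parts, `[`, "", 1L),
                     gene = vapply(parts, `[`, "", 2L))
    df <- df[!(df$name == "name" & df$gene == "gene_id"), ]
    sets <- lapply(split(df$gene, df$name), function(g) sort(unique(g)))
    attr(sets, "provenance") <- "external"
    sets
}

#' Write gene sets as a two-column TSV
#' @param sets named list of character vectors
#' @param path output path
#' @return invisibly, the path
#' @export
writeGeneSets <- function(sets, path) {
    df <- data.frame(
        name = rep(names(sets), lengths(sets)),
        gene_id = unlist(sets, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
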