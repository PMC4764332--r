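# Readers/writers for the external formats and the shared coordinate
# conventions.  Genomic coordinates are GRanges-style (1-based, closed);
# BED/bedGraph conversion is left to rtracklayer.  UTR-relative coordinates
# are 0-based: position 0 is the 5'-most transcript-sense base.

.pkgComment <- function(params = character()) {
    ver <- tryCatch(as.character(utils::packageVersion("apaMiR")),
                    error = function(e) "dev")
    paste0("# apaMiR ", ver,
           if (length(params)) paste0("; ", paste(params, collapse = "; ")))
}

#' Write a TSV with a commented provenance header
#'
#' @param df data.frame to write
#' @param path output path
#' @param params character vector of "name=value" strings recorded in the
#'   comment line
#' @return invisibly, the path
#' @export
writeTsv <- function(df, path, params = character()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.pkgComment(params), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a TSV written by [writeTsv()] (comment lines ignored)
#' @param path input path
#' @return data.frame
#' @export
readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      quote = "", stringsAsFactors = FALSE)
}

.checkBed6 <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    for (i in which(keep)) {
        f <- strsplit(lines[i], "\t| +")[[1]]
        if (length(f) < 6L)
            stop("malformed BED line ", i, " in '", path,
                 "': expected >= 6 fields, got ", length(f))
        if (is.na(suppressWarnings(as.integer(f[2L]))) ||
            is.na(suppressWarnings(as.integer(f[3L]))))
            stop("malformed BED line ", i, " in '", path,
                 "': non-numeric coordinates")
        if (!f[6L] %in% c("+", "-"))
            stop("malformed BED line ", i, " in '", path,
                 "': unknown strand symbol '", f[6L], "'")
    }
    sum(keep)
}

#' Read aligned 3'-end read positions from BED6
#'
#' Each record marks the last templated base before the poly(A) tail of one
#' read; the BED name column carries the sample label.  The cleavage
#' coordinate is strand-aware: the 3'-most base of the interval in transcript
#' sense (interval end for plus-strand records, interval start for minus).
#'
#' @param path BED6 file
#' @return width-1 \code{GRanges} located at the cleavage coordinate, with a
#'   \code{sample} metadata column
#' @export
readReadEnds <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    n <- .checkBed6(path)
    if (n == 0L)
        return(GRanges(sample = character(0)))
    gr <- rtracklayer::import(path, format = "BED")
    if (any(is.na(gr$name)) || any(!nzchar(gr$name)))
        stop("read-end BED requires a non-empty sample label in the name column")
    pos <- ifelse(as.character(strand(gr)) == "+", end(gr), start(gr))
    out <- GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = strand(gr))
    out$sample <- gr$name
    out
}

#' Write 3'-end read positions to BED6
#'
#' @param ends width-1 GRanges with a \code{sample} column (as returned by
#'   [readReadEnds()])
#' @param path output BED path
#' @return invisibly, the path
#' @export
writeReadEnds <- function(ends, path) {
    stopifnot(is(ends, "GRanges"), !is.null(ends$sample))
    out <- granges(ends)
    out$name <- ends$sample
    out$score <- rep(0L, length(out))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

.readGenome <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        names(genome) <- sub("\\s.*$", "", names(genome))
        return(genome)
    }
    if (!file.exists(genome))
        stop("no such FASTA: ", genome)
    g <- readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

.utrAnnotationRanges <- function(annotation) {
    ## -> named GRangesList keyed by "gene|accession", genomic order
    if (is(annotation, "GRangesList"))
        return(annotation)
    ext <- tolower(tools::file_ext(annotation))
    if (ext %in% c("gff", "gff3", "gtf")) {
        gr <- rtracklayer::import(annotation)
        gid <- gr$gene_id
        acc <- gr$transcript_id
        if (is.null(gid) || is.null(acc))
            stop("GFF UTR annotation requires gene_id and transcript_id attributes")
        key <- paste0(gid, "|", acc)
        return(splitAsList(granges(gr), key))
    }
    gr <- rtracklayer::import(annotation, format = "BED")
    if (length(gr) == 0L)
        return(GRangesList())
    if (is.null(gr$name))
        stop("BED UTR annotation requires a name column (gene|accession)")
    if (!is.null(gr$blocks)) {
        grl <- rtracklayer::blocks(gr)      # BED12 -> per-record exon blocks
        names(grl) <- gr$name
        unl <- unlist(grl, use.names = FALSE)
        strand(unl) <- rep(as.character(strand(gr)), elementNROWS(grl))
        return(relist(unl, grl))
    }
    splitAsList(granges(gr), gr$name)
}

.senseOrder <- function(gr) {
    minus <- as.character(strand(gr)[1L]) == "-"
    gr[order(start(gr), decreasing = minus)]
}

#' Read 3'UTR models and extract their spliced sequences
#'
#' Accepts BED6 (one interval per record, grouped by name), BED12 (blocks are
#' exons) or GFF3 (records carrying \code{gene_id}/\code{transcript_id});
#' the BED name column is "gene_id|accession" (a bare gene id is used for
#' both).  Sequences are extracted strand-aware from the genome FASTA:
#' minus-strand UTRs are reverse-complemented so the stored sequence reads
#' 5' to 3' in transcript sense.
#'
#' @param annotation annotation path (BED/GFF) or a named GRangesList
#' @param genome genome FASTA path or a DNAStringSet
#' @return a [UTRSet-class]
#' @export
readUtrModels <- function(annotation, genome) {
    grl <- .utrAnnotationRanges(annotation)
    genome <- .readGenome(genome)
    if (length(grl) == 0L)
        return(new("UTRSet", geneId = character(0), accession = character(0),
                   ranges = GRangesList(), seq = DNAStringSet()))
    key <- names(grl)
    gene <- sub("\\|.*$", "", key)
    acc <- ifelse(grepl("\\|", key), sub("^[^|]*\\|", "", key), key)
    if (anyDuplicated(acc)) {
        dup <- acc[duplicated(acc)][1L]
        stop("duplicated transcript accession in UTR annotation: ", dup)
    }
    ranges <- vector("list", length(grl))
    seqs <- vector("list", length(grl))
    for (i in seq_along(grl)) {
        gr <- .senseOrder(grl[[i]])
        chrom <- as.character(seqnames(gr)[1L])
        if (!chrom %in% names(genome))
            stop("chromosome '", chrom, "' of UTR '", acc[i],
                 "' absent from genome FASTA")
        if (max(end(gr)) > length(genome[[chrom]]))
            stop("UTR '", acc[i], "' extends beyond the end of contig '",
                 chrom, "'")
        pieces <- lapply(seq_along(gr), function(j)
            subseq(genome[[chrom]], start(gr)[j], end(gr)[j]))
        s <- do.call(xscat, pieces)
        if (as.character(strand(gr)[1L]) == "-")
            s <- reverseComplement(s)
        ranges[[i]] <- gr
        seqs[[i]] <- s
    }
    new("UTRSet",
        geneId = unname(gene), accession = unname(acc),
        ranges = GRangesList(ranges),
        seq = if (length(seqs)) DNAStringSet(seqs) else DNAStringSet())
}

#' Write UTR models as BED12
#'
#' @param utrs a UTRSet
#' @param path output BED path
#' @return invisibly, the path
#' @export
writeUtrModels <- function(utrs, path) {
    grl <- utrs@ranges
    if (length(utrs) == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    names(grl) <- paste0(utrs@geneId, "|", utrs@accession)
    ## rtracklayer requires genomic order within BED12 blocks
    grl <- endoapply(grl, function(gr) gr[order(start(gr))])
    rtracklayer::export(grl, path, format = "BED")
    invisible(path)
}

.utrIndex <- function(utrs, accession) {
    i <- match(accession, utrs@accession)
    if (anyNA(i))
        stop("unknown accession(s): ",
             paste(unique(accession[is.na(i)]), collapse = ", "))
    i
}

#' Map genomic positions to UTR-relative positions
#'
#' UTR position 0 is the 5'-most transcript-sense base of the UTR; positions
#' strictly increase 5' to 3'.  Genomic positions outside the UTR intervals
#' map to \code{NA} (sentinel, not an error).
#'
#' @param utrs a UTRSet
#' @param accession transcript accession (length 1 or length(pos))
#' @param pos genomic position(s), 1-based
#' @return integer vector of 0-based UTR positions, NA outside the UTR
#' @export
genomicToUtr <- function(utrs, accession, pos) {
    accession <- rep_len(accession, length(pos))
    out <- rep(NA_integer_, length(pos))
    for (acc in unique(accession)) {
        idx <- which(accession == acc)
        gr <- utrs@ranges[[.utrIndex(utrs, acc)]]
        gr <- .senseOrder(gr)
        cum <- c(0L, cumsum(width(gr)))
        minus <- as.character(strand(gr)[1L]) == "-"
        for (j in seq_along(gr)) {
            g <- pos[idx]
            inside <- !is.na(g) & g >= start(gr)[j] & g <= end(gr)[j]
            if (!any(inside)) next
            off <- if (minus) end(gr)[j] - g[inside] else g[inside] - start(gr)[j]
            out[idx[inside]] <- cum[j] + as.integer(off)
        }
    }
    out
}

#' Map UTR-relative positions back to genomic positions
#'
#' Inverse of [genomicToUtr()] over the UTR bases.
#'
#' @param utrs a UTRSet
#' @param accession transcript accession (length 1 or length(pos))
#' @param pos 0-based UTR position(s)
#' @return integer vector of 1-based genomic positions; NA for positions
#'   outside \code{[0, utrLength)}
#' @export
utrToGenomic <- function(utrs, accession, pos) {
    accession <- rep_len(accession, length(pos))
    out <- rep(NA_integer_, length(pos))
    for (acc in unique(accession)) {
        idx <- which(accession == acc)
        gr <- .senseOrder(utrs@ranges[[.utrIndex(utrs, acc)]])
        cum <- c(0L, cumsum(width(gr)))
        minus <- as.character(strand(gr)[1L]) == "-"
        p <- pos[idx]
        j <- findInterval(p, cum, rightmost.closed = FALSE)
        ok <- !is.na(p) & p >= 0L & p < cum[length(cum)]
        within <- p[ok] - cum[j[ok]]
        out[idx[ok]] <- as.integer(
            if (minus) end(gr)[j[ok]] - within else start(gr)[j[ok]] + within)
    }
    out
}

#' Read a miRNA seed table
#'
#' TSV with columns \code{family_id}, \code{site7} (the 7-nt DNA seed match,
#' i.e. the reverse complement of miRNA bases 2-8) and \code{conserved_family}
#' (logical or 0/1).
#'
#' @param path TSV path
#' @return data.frame(family_id, site7, conserved_family)
#' @export
readSeedTable <- function(path) {
    df <- readTsv(path)
    need <- c("family_id", "site7", "conserved_family")
    if (!all(need %in% names(df)))
        stop("seed table requires columns: ", paste(need, collapse = ", "))
    df$site7 <- toupper(df$site7)
    if (any(nchar(df$site7) != 7L) || any(grepl("[^ACGT]", df$site7)))
        stop("site7 must be 7-nt over the DNA alphabet {A,C,G,T}")
    df$conserved_family <- as.logical(df$conserved_family)
    df[need]
}

#' Read a per-site table (conserved-site list or score table)
#'
#' TSV keyed by \code{gene_id}, \code{utr_start} (0-based UTR position of the
#' 7-mer's 5' end) and \code{family_id}, with an optional \code{score} column.
#'
#' @param path TSV path
#' @return data.frame
#' @export
readSiteTable <- function(path) {
    df <- readTsv(path)
    need <- c("gene_id", "utr_start", "family_id")
    if (!all(need %in% names(df)))
        stop("site table requires columns: ", paste(need, collapse = ", "))
    df$utr_start <- as.integer(df$utr_start)
    df
}

#' Construct a ConservationTrack from scored intervals
#' @param gr GRanges with a numeric \code{score} column
#' @return a [ConservationTrack-class]
#' @export
conservationTrack <- function(gr) new("ConservationTrack", gr = gr)

#' Read a per-base conservation track (bedGraph / wiggle)
#'
#' @param path bedGraph (.bedgraph/.bg) or wiggle (.wig) file
#' @return a [ConservationTrack-class]; positions not covered in the file are
#'   missing and query as NA
#' @export
readConservationTrack <- function(path) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("wig", "wiggle")) "WIG" else "bedGraph"
    conservationTrack(rtracklayer::import(path, format = fmt))
}

#' Write a ConservationTrack as bedGraph
#' @param track a ConservationTrack
#' @param path output path
#' @return invisibly, the path
#' @export
writeConservationTrack <- function(track, path) {
    rtracklayer::export(track@gr, path, format = "bedGraph")
    invisible(path)
}

#' Query per-base conservation scores
#'
#' @param track a ConservationTrack
#' @param chrom chromosome name (length 1 or length(pos))
#' @param pos 1-based genomic positions
#' @return numeric scores; NA where the track has no coverage (never a
#'   silent 0)
#' @export
trackScores <- function(track, chrom, pos) {
    chrom <- rep_len(chrom, length(pos))
    out <- rep(NA_real_, length(pos))
    ok <- !is.na(pos) & pos >= 1L &
        chrom %in% seqlevels(track@gr)
    if (!any(ok))
        return(out)
    q <- GRanges(chrom[ok], IRanges(pos[ok], width = 1L),
                 seqinfo = seqinfo(track@gr))
    hits <- findOverlaps(q, track@gr, ignore.strand = TRUE)
    out[which(ok)[queryHits(hits)]] <- track@gr$score[subjectHits(hits)]
    out
}

#' Keep the longest UTR model per gene
#'
#' When a gene has several transcript accessions, downstream gene-level calls
#' use its longest UTR.
#'
#' @param utrs a UTRSet
#' @return a UTRSet with one model per gene
#' @export
selectLongestUtr <- function(utrs) {
    if (length(utrs) == 0L)
        return(utrs)
    len <- width(utrs@seq)
    ord <- order(utrs@geneId, -len, utrs@accession)
    keep <- ord[!duplicated(utrs@geneId[ord])]
    utrs[sort(keep)]
}
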