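# Readers and summaries for deposited cleavage-site result tables (the
# RUN_S / RUN_E / RUN_MAX / InternalPrim_FLAG schema used both by
# writeCleavageSites() and by published 3'seq supplementary tables).

#' Read a deposited cleavage-site result table
#'
#' Expects a TSV (or CSV) with at least the columns \code{RUN_S},
#' \code{RUN_E}, \code{RUN_MAX} and \code{InternalPrim_FLAG}; extra columns
#' are kept.  The flag column may be logical, 0/1 or a non-empty marker
#' string.
#'
#' @param path table path
#' @return data.frame
#' @export
readCleavageSiteTable <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            comment.char = "#", quote = "\"",
                            stringsAsFactors = FALSE)
    need <- c("RUN_S", "RUN_E", "RUN_MAX", "InternalPrim_FLAG")
    if (!all(need %in% names(df)))
        stop("cleavage-site table requires columns: ",
             paste(need, collapse = ", "))
    f <- df$InternalPrim_FLAG
    df$InternalPrim_FLAG <- if (is.logical(f)) f
        else if (is.numeric(f)) f != 0
        else !is.na(f) & nzchar(trimws(as.character(f)))
    df
}

#' Summarize a deposited cleavage-site table
#'
#' Row counts and run-length statistics used for sanity checks against
#' published values: total rows, internal-priming-flagged rows, retained
#' rows, and the median run length under both length conventions (half-open
#' span \code{RUN_E - RUN_S} and closed span \code{RUN_E - RUN_S + 1}).
#'
#' @param df data.frame from [readCleavageSiteTable()]
#' @return list of summary statistics
#' @export
summarizeCleavageSiteTable <- function(df) {
    list(
        n_sites = nrow(df),
        n_flagged = sum(df$InternalPrim_FLAG),
        n_retained = sum(!df$InternalPrim_FLAG),
        median_run_span = stats::median(df$RUN_E - df$RUN_S),
        median_run_span_closed = stats::median(df$RUN_E - df$RUN_S + 1)
    )
}
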