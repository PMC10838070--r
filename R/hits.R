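#' Hit tables: the top BLAST hits of each query
#'
#' A hit table is a data.frame with one row per (query, subject) alignment
#' and the six canonical BLAST tabular columns plus the backend output
#' position:
#' `query_id`, `subject_id`, `pident` (percent identical positions),
#' `align_length` (bp), `evalue`, `bitscore`, `input_rank`.
#'
#' Within each query, hits follow the canonical order
#' (bitscore descending, `input_rank` ascending) — a total, stable order, so
#' repeated runs give byte-identical tables. The bit score ranks hits within
#' a query; it is not comparable across queries.
#'
#' @name hit_table
NULL

hit_cols <- function() {
  c("query_id", "subject_id", "pident", "align_length",
    "evalue", "bitscore", "input_rank")
}

#' Validate and canonically sort a hit table (internal)
#' @noRd
as_hit_table <- function(df, line_offset = 0L) {
  missing_cols <- setdiff(hit_cols(), names(df))
  if (length(missing_cols) > 0L) {
    stop("hit table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(df$pident < 0 | df$pident > 100 | df$align_length < 1 | df$evalue < 0)
  if (length(bad) > 0L) {
    stop("invalid hit record at line ", bad[1L] + line_offset,
         " (need 0 <= pident <= 100, align_length >= 1, evalue >= 0)")
  }
  df <- df[order(df$query_id, -df$bitscore, df$input_rank), , drop = FALSE]
  rownames(df) <- NULL
  df[, hit_cols()]
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the six-column tabular format produced by
#' `blastn -outfmt "6 qseqid sseqid pident length evalue bitscore"`; extra
#' trailing columns are tolerated and ignored. The file's row order within a
#' query is preserved as `input_rank` (the BLAST output order), after which
#' hits are canonically sorted and truncated to `max_hits`.
#'
#' @param path Tab-separated file, no header. An empty file yields an empty
#'   table (a valid outcome: BLAST found no match).
#' @param max_hits Keep at most this many hits per query (default 10).
#' @return A hit table (see [hit_table]).
#' @export
parse_blast_tabular <- function(path, max_hits = 10L) {
  if (!file.exists(path)) stop("cannot read blast tabular file: ", path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), align_length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      input_rank = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 6L) stop("blast tabular file must have >= 6 columns")
  df <- data.frame(query_id = raw[[1L]], subject_id = raw[[2L]],
                   pident = suppressWarnings(as.numeric(raw[[3L]])),
                   align_length = suppressWarnings(as.integer(raw[[4L]])),
                   evalue = suppressWarnings(as.numeric(raw[[5L]])),
                   bitscore = suppressWarnings(as.numeric(raw[[6L]])),
                   stringsAsFactors = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0L) stop("malformed blast tabular row at line ", bad[1L])
  df$input_rank <- stats::ave(seq_len(nrow(df)), df$query_id,
                              FUN = seq_along)
  top_hits(as_hit_table(df), max_hits)
}

#' Write a hit table in BLAST tabular format
#'
#' Emits the six canonical columns tab-separated without a header, in
#' canonical order, so `parse_blast_tabular()` round-trips the table.
#'
#' @param hits A hit table.
#' @param path Output path.
#' @export
write_blast_tabular <- function(hits, path) {
  hits <- as_hit_table(hits)
  utils::write.table(hits[, c("query_id", "subject_id", "pident",
                              "align_length", "evalue", "bitscore")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep the n best hits of each query
#'
#' Truncates each query's hit list to its `n` best records under the
#' canonical order (bitscore descending, backend output order for ties).
#'
#' @param hits A hit table.
#' @param n Hits to keep per query (default 10, as in "the 10 top hits").
#' @return The truncated hit table.
#' @export
top_hits <- function(hits, n = 10L) {
  stopifnot(n >= 1L)
  hits <- as_hit_table(hits)
  keep <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                     FUN = seq_along) <= n
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
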