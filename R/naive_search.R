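#' Built-in pairwise local-alignment search backend
#'
#' A self-contained substitute for an external BLAST run: every query is
#' locally aligned (Smith-Waterman with affine gaps, via
#' [Biostrings::pairwiseAlignment()]) against every reference sequence, and
#' the hits are reported with the same six fields as BLAST tabular output.
#' Scoring uses blastn-like constants: match +2, mismatch -3, gap open -5,
#' gap extend -2. The raw score S is converted to a bit score as
#' `(lambda * S - ln K) / ln 2` with `lambda = 0.625`, `K = 0.41`, and the
#' E-value as `m * n * 2^(-bitscore)` with m = query length and n = total
#' reference length. These constants are fixed conventions of this backend,
#' not a calibration against NCBI BLAST: downstream assignment logic depends
#' only on hit ordering, percent identity and alignment length, which behave
#' like their BLAST counterparts. `pident` is the percentage of identical
#' positions over the alignment length (gap columns included). Ties in bit
#' score are ordered by reference load order, which becomes `input_rank`.
#'
#' @param queries,reference [ref_db] objects (non-empty).
#' @param max_hits Hits kept per query (default 10).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring constants.
#' @param lambda,K Bit-score conversion constants.
#' @return A hit table (see [hit_table]).
#' @export
naive_search <- function(queries, reference, max_hits = 10L,
                         match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2,
                         lambda = 0.625, K = 0.41) {
  stopifnot(inherits(queries, "ref_db"), inherits(reference, "ref_db"))
  if (nrow(queries$records) == 0L || nrow(reference$records) == 0L) {
    stop("naive_search needs non-empty query and reference databases")
  }
  ref_seqs <- Biostrings::DNAStringSet(reference$records$sequence)
  names(ref_seqs) <- reference$records$seq_id
  n_total <- sum(Biostrings::width(ref_seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  out <- vector("list", nrow(queries$records))
  for (i in seq_len(nrow(queries$records))) {
    q <- queries$records[i, ]
    aln <- Biostrings::pairwiseAlignment(ref_seqs,
                                         Biostrings::DNAString(q$sequence),
                                         type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = gap_open,
                                         gapExtension = gap_extend)
    raw_score <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    nmatch <- Biostrings::nmatch(aln)
    bitscore <- (lambda * raw_score - log(K)) / log(2)
    hits <- data.frame(query_id = q$seq_id,
                       subject_id = reference$records$seq_id,
                       pident = round(100 * nmatch / alen, 3L),
                       align_length = alen,
                       evalue = nchar(q$sequence) * n_total * 2^(-bitscore),
                       bitscore = round(bitscore, 4L),
                       stringsAsFactors = FALSE)
    # empty local alignments (no positive-scoring region) are not hits
    hits <- hits[alen >= 1L, , drop = FALSE]
    if (nrow(hits) == 0L) {
      out[i] <- list(NULL)
      next
    }
    # reference load order is the backend output order for tied bit scores
    hits <- hits[order(-hits$bitscore, seq_len(nrow(hits))), , drop = FALSE]
    hits <- hits[seq_len(min(max_hits, nrow(hits))), , drop = FALSE]
    hits$input_rank <- seq_len(nrow(hits))
    out[[i]] <- hits
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), align_length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      input_rank = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  as_hit_table(res)
}
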