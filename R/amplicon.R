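#' Extract the primer-amplified region from a reference sequence
#'
#' Locates the best forward-primer site and the best reverse-primer site
#' downstream of it (the reverse primer is given 5'->3' on the reverse
#' strand and is reverse-complemented before matching), each allowing up to
#' `max_mismatch` mismatches. IUPAC degeneracy is honoured on the primer
#' side only: an `R` in the primer matches `A` or `G` in the sequence, but
#' an `N` in the sequence does not match everything. The best site is the
#' one with the fewest mismatches; ties are broken towards the leftmost
#' position for the forward primer and the rightmost for the reverse, so the
#' widest amplicon wins. When either site is absent the sequence is lost
#' from the restricted database, mirroring the sequence attrition seen when
#' full-length references only partially cover the amplified region or carry
#' too many substitutions in a primer site.
#'
#' @param record One-row data.frame (a `ref_db` record) or a list with at
#'   least `seq_id` and `sequence`.
#' @param fwd_primer,rev_primer IUPAC primer strings; `rev_primer` is
#'   reverse-complemented internally.
#' @param max_mismatch Maximum mismatches tolerated per site (default 2).
#' @param include_primers Keep the primer-binding sites in the output
#'   (default `FALSE`: the amplicon is the inter-primer insert).
#' @return The record with `sequence` replaced by the amplicon (and the same
#'   `source_accession`, linking it to its full-length parent), or `NULL`
#'   when either primer site is not found.
#' @export
extract_amplicon <- function(record, fwd_primer, rev_primer,
                             max_mismatch = 2L, include_primers = FALSE) {
  seq <- toupper(record$sequence)
  subject <- Biostrings::DNAString(seq)
  fwd <- Biostrings::DNAString(toupper(fwd_primer))
  rev <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev_primer)))

  fwd_site <- best_primer_site(fwd, subject, max_mismatch, prefer = "left")
  if (is.null(fwd_site)) return(NULL)
  # reverse site must start after the forward site ends
  rev_site <- best_primer_site(rev, subject, max_mismatch, prefer = "right",
                               min_start = fwd_site$end + 1L)
  if (is.null(rev_site)) return(NULL)

  from <- if (include_primers) fwd_site$start else fwd_site$end + 1L
  to <- if (include_primers) rev_site$end else rev_site$start - 1L
  if (to < from) return(NULL)  # zero-length insert: nothing amplified
  out <- record
  out$sequence <- substr(seq, from, to)
  out
}

#' Find the lowest-mismatch match of a primer in a subject (internal)
#'
#' Scans mismatch budgets 0..max_mismatch and returns the first budget with
#' hits; `fixed = "subject"` makes IUPAC codes degenerate on the primer side
#' only.
#'
#' @noRd
best_primer_site <- function(primer, subject, max_mismatch, prefer, min_start = 1L) {
  for (mm in 0:max_mismatch) {
    m <- Biostrings::matchPattern(primer, subject, max.mismatch = mm,
                                  fixed = "subject")
    st <- Biostrings::start(m)
    en <- Biostrings::end(m)
    ok <- st >= min_start
    if (any(ok)) {
      idx <- if (prefer == "left") which(ok)[1L] else rev(which(ok))[1L]
      return(list(start = st[idx], end = en[idx], mismatches = mm))
    }
  }
  NULL
}

#' Restrict a whole database to a primer-amplified region
#'
#' Applies [extract_amplicon()] to every record; records without both primer
#' sites are dropped (their count is reported). The result carries
#' `region = "restricted"` and each survivor keeps its `source_accession`,
#' which is what ties a restricted sequence back to its full-length parent
#' in restricted-vs-general cross-validation.
#'
#' @param db A [ref_db].
#' @inheritParams extract_amplicon
#' @return A [ref_db] with `region = "restricted"`.
#' @export
restrict_database <- function(db, fwd_primer, rev_primer,
                              max_mismatch = 2L, include_primers = FALSE) {
  stopifnot(inherits(db, "ref_db"))
  recs <- db$records
  kept <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    kept[[i]] <- extract_amplicon(recs[i, , drop = FALSE], fwd_primer, rev_primer,
                                  max_mismatch = max_mismatch,
                                  include_primers = include_primers)
  }
  n_lost <- sum(vapply(kept, is.null, logical(1L)))
  if (n_lost > 0L) {
    message(n_lost, " record(s) lost during primer restriction")
  }
  kept <- do.call(rbind, kept[!vapply(kept, is.null, logical(1L))])
  if (is.null(kept) || nrow(kept) == 0L) stop("no record retained both primer sites")
  rownames(kept) <- NULL
  out <- db
  out$records <- kept
  out$region <- "restricted"
  out
}
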