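#' Taxonomic assignment from the top BLAST hits
#'
#' Four strategies turn a query's top hits (default the 10 best by bit
#' score) into a predicted taxon at each of family, genus and species rank:
#'
#' * **TopHit** — the lineage of the single hit with the best bit score
#'   (what BLAST itself reports when keeping one match); ties broken by
#'   backend output order.
#' * **TopHitPlus** — as TopHit, but bit-score ties are broken by the taxon
#'   with the highest consensus score among the tied hits.
#' * **TopN** — at each rank independently, the taxon with the highest
#'   consensus score among all considered hits; the species chosen can
#'   therefore belong to a different genus than the genus chosen.
#' * **TopNPlus** — hits failing predefined requirements (alignment length,
#'   E-value, per-rank identity floor, identity distance to the best hit)
#'   are discarded first; the consensus winner is then taken among the
#'   survivors, and a rank with no surviving hit gets no taxon at all.
#'
#' Every assignment carries two diagnostic scores: the **consensus score**
#' (percentage of considered hits matching the assigned taxon at that rank)
#' and the **identity score** (the `pident` of the best-bit-score hit among
#' those matching the taxon — not necessarily the maximum `pident`, because
#' the bit score penalises short alignments).
#'
#' Hits whose lineage is `"unknown"` at a rank count in the consensus
#' denominator but can never be assigned: "unknown" is not a taxon.
#'
#' @name assignment
NULL

#' Consensus scores of the taxa among a query's hits
#'
#' The consensus score of a taxon is the percentage of the considered hits
#' whose subject carries that taxon at the given rank. With 10 hits mapping
#' to two *Brassica napus*, six *Brassica nigra* and two *Sinapis alba*, the
#' consensus is 60% for *Brassica nigra* at species rank, 80% for *Brassica*
#' at genus rank and 100% for *Brassicaceae* at family rank.
#'
#' @param hits Hit table rows of a single query.
#' @param taxmap A [ref_db] or a data.frame with `seq_id` plus rank columns
#'   resolving every `subject_id`.
#' @param rank One of `"family"`, `"genus"`, `"species"` (any of
#'   [tax_ranks()] is accepted).
#' @return Named numeric vector of percentages, one entry per taxon seen at
#'   the rank (hits with `"unknown"` at the rank contribute to the
#'   denominator but get no entry). Entries sum to 100 when no hit is
#'   rank-unknown.
#' @export
consensus_scores <- function(hits, taxmap, rank) {
  taxa <- subject_taxa(hits, taxmap, rank)
  n <- length(taxa)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(taxa[taxa != UNKNOWN])
  out <- 100 * as.numeric(tab) / n
  stats::setNames(out, names(tab))
}

#' Identity score attributed to a taxon
#'
#' Returns the `pident` of the maximum-bit-score hit among the hits matching
#' `taxon` at `rank` (ties broken by backend output order). This is not
#' necessarily the maximum identity among those hits: a 98% identity over a
#' 400 bp alignment outranks a 100% identity over 50 bp by bit score, and 98
#' is then the identity attributed to the taxon.
#'
#' @inheritParams consensus_scores
#' @param taxon Taxon name; at least one hit must match it at `rank`.
#' @return The attributed identity (percentage).
#' @export
identity_for_taxon <- function(hits, taxmap, rank, taxon) {
  taxa <- subject_taxa(hits, taxmap, rank)
  sel <- which(taxa == taxon)
  if (length(sel) == 0L) stop("no hit matches taxon '", taxon, "' at rank ", rank)
  sub <- hits[sel, , drop = FALSE]
  best <- order(-sub$bitscore, sub$input_rank)[1L]
  sub$pident[best]
}

#' Resolve hit subjects to taxa at a rank (internal)
#' @noRd
subject_taxa <- function(hits, taxmap, rank) {
  if (!rank %in% tax_ranks()) stop("unknown rank: ", rank)
  if (inherits(taxmap, "ref_db")) taxmap <- taxmap$records
  m <- match(hits$subject_id, taxmap$seq_id)
  if (anyNA(m)) {
    stop("subject_id not found in taxonomy map: ",
         hits$subject_id[which(is.na(m))[1L]])
  }
  taxmap[[rank]][m]
}

#' One unassigned result row (internal)
#' @noRd
empty_assignment <- function(query_id, method) {
  row <- data.frame(query_id = query_id, method = method,
                    stringsAsFactors = FALSE)
  for (rk in eval_ranks()) {
    row[[rk]] <- NA_character_
    row[[paste0(rk, "_identity")]] <- NA_real_
    row[[paste0(rk, "_consensus")]] <- NA_real_
  }
  row
}

#' Fill one rank of a result row (internal); taxon may be NA
#' @noRd
set_rank <- function(row, rank, taxon, identity, consensus) {
  row[[rank]] <- taxon
  row[[paste0(rank, "_identity")]] <- identity
  row[[paste0(rank, "_consensus")]] <- consensus
  row
}

#' @rdname assignment
#' @inheritParams consensus_scores
#' @param query_id Used to label the result when `hits` is empty; defaults
#'   to the hits' query.
#' @return A one-row data.frame: `query_id`, `method`, then
#'   `<rank>`, `<rank>_identity`, `<rank>_consensus` for family, genus,
#'   species. `NA` in the taxon column means no taxon was attributed.
#' @export
assign_tophit <- function(hits, taxmap, query_id = NULL) {
  qid <- query_label(hits, query_id)
  row <- empty_assignment(qid, "TopHit")
  if (nrow(hits) == 0L) return(row)
  best <- hits[order(-hits$bitscore, hits$input_rank)[1L], , drop = FALSE]
  for (rk in eval_ranks()) {
    taxon <- subject_taxa(best, taxmap, rk)
    if (taxon == UNKNOWN) next
    cons <- consensus_scores(hits, taxmap, rk)
    row <- set_rank(row, rk, taxon,
                    identity_for_taxon(hits, taxmap, rk, taxon),
                    unname(cons[taxon]))
  }
  row
}

#' @rdname assignment
#' @export
assign_tophitplus <- function(hits, taxmap, query_id = NULL) {
  qid <- query_label(hits, query_id)
  row <- empty_assignment(qid, "TopHitPlus")
  if (nrow(hits) == 0L) return(row)
  tied <- hits[hits$bitscore == max(hits$bitscore), , drop = FALSE]
  for (rk in eval_ranks()) {
    cand <- unique(subject_taxa(tied, taxmap, rk))
    cand <- cand[cand != UNKNOWN]
    if (length(cand) == 0L) next
    cons <- consensus_scores(hits, taxmap, rk)
    cand_cons <- cons[cand]
    # highest consensus among the tied taxa; residual ties alphabetical
    winners <- cand[cand_cons == max(cand_cons)]
    taxon <- sort(winners)[1L]
    row <- set_rank(row, rk, taxon,
                    identity_for_taxon(hits, taxmap, rk, taxon),
                    unname(cons[taxon]))
  }
  row
}

#' @rdname assignment
#' @export
assign_topn <- function(hits, taxmap, query_id = NULL) {
  qid <- query_label(hits, query_id)
  row <- empty_assignment(qid, "TopN")
  if (nrow(hits) == 0L) return(row)
  for (rk in eval_ranks()) {
    res <- consensus_winner(hits, taxmap, rk)
    if (is.null(res)) next
    row <- set_rank(row, rk, res$taxon, res$identity, res$consensus)
  }
  row
}

#' Argmax of the consensus table at a rank, ties by identity then name
#' (internal). Returns NULL when no taxon is known at the rank.
#' @noRd
consensus_winner <- function(hits, taxmap, rank) {
  cons <- consensus_scores(hits, taxmap, rank)
  if (length(cons) == 0L) return(NULL)
  best <- names(cons)[cons == max(cons)]
  if (length(best) > 1L) {
    ids <- vapply(best, function(tx) identity_for_taxon(hits, taxmap, rank, tx),
                  numeric(1L))
    best <- best[ids == max(ids)]
    best <- sort(best)
  }
  taxon <- best[1L]
  list(taxon = taxon,
       identity = identity_for_taxon(hits, taxmap, rank, taxon),
       consensus = unname(cons[taxon]))
}

#' TopNPlus filtering thresholds
#'
#' Defaults follow the published requirements: discard hits with alignment
#' length < 100 bp or E-value > 1e-10; require an identity of at least 97%
#' at species, 90% at genus and 80% at family rank; and discard hits whose
#' identity is 1 (species), 10 (genus) or 20 (family) or more percentage
#' points below the best hit's identity (the comparison is strict: the
#' difference must be `< window`).
#'
#' @param min_length Minimum alignment length (bp).
#' @param max_evalue Maximum E-value.
#' @param identity_floor Named vector of per-rank identity floors (%),
#'   compared with `>=`.
#' @param identity_window Named vector of per-rank identity windows
#'   (percentage points below the best hit, strict `<`).
#' @param window_reference `"prefilter"` (default): the best hit anchoring
#'   the identity window is the max-bit-score hit among the original top
#'   hits; `"postfilter"`: among the hits surviving the length/E-value/floor
#'   filters at that rank.
#' @return A list of thresholds for [assign_topnplus()].
#' @export
topnplus_params <- function(min_length = 100,
                            max_evalue = 1e-10,
                            identity_floor = c(family = 80, genus = 90, species = 97),
                            identity_window = c(family = 20, genus = 10, species = 1),
                            window_reference = c("prefilter", "postfilter")) {
  stopifnot(all(eval_ranks() %in% names(identity_floor)),
            all(eval_ranks() %in% names(identity_window)))
  list(min_length = min_length, max_evalue = max_evalue,
       identity_floor = identity_floor, identity_window = identity_window,
       window_reference = match.arg(window_reference))
}

#' @rdname assignment
#' @param params Thresholds from [topnplus_params()].
#' @export
assign_topnplus <- function(hits, taxmap, params = topnplus_params(),
                            query_id = NULL) {
  qid <- query_label(hits, query_id)
  row <- empty_assignment(qid, "TopNPlus")
  if (nrow(hits) == 0L) return(row)
  base_keep <- hits$align_length >= params$min_length &
    hits$evalue <= params$max_evalue
  best_pident_pre <- {
    b <- order(-hits$bitscore, hits$input_rank)[1L]
    hits$pident[b]
  }
  for (rk in eval_ranks()) {
    keep <- base_keep & hits$pident >= params$identity_floor[[rk]]
    if (params$window_reference == "prefilter") {
      anchor <- best_pident_pre
    } else {
      sub0 <- hits[keep, , drop = FALSE]
      if (nrow(sub0) == 0L) next
      anchor <- sub0$pident[order(-sub0$bitscore, sub0$input_rank)[1L]]
    }
    keep <- keep & (anchor - hits$pident) < params$identity_window[[rk]]
    survivors <- hits[keep, , drop = FALSE]
    if (nrow(survivors) == 0L) next
    res <- consensus_winner(survivors, taxmap, rk)
    if (is.null(res)) next
    row <- set_rank(row, rk, res$taxon, res$identity, res$consensus)
  }
  row
}

#' @noRd
query_label <- function(hits, query_id) {
  if (!is.null(query_id)) return(query_id)
  if (nrow(hits) > 0L) return(hits$query_id[1L])
  NA_character_
}

#' Run assignment methods over a whole hit table
#'
#' Applies the requested methods to every query in `hits` and binds the
#' one-row results. Queries listed in `query_ids` but absent from the hit
#' table (BLAST found no match) yield unassigned rows, so the output is
#' complete: one row per query and method.
#'
#' @param hits A hit table covering one or more queries.
#' @param taxmap A [ref_db] or data.frame resolving all `subject_id`s.
#' @param methods Subset of `c("TopHit", "TopHitPlus", "TopN", "TopNPlus")`.
#' @param params Thresholds for TopNPlus ([topnplus_params()]).
#' @param query_ids Optional full set of queries (defaults to those present
#'   in `hits`).
#' @return Data.frame, one row per query x method, in the column layout of
#'   [assign_tophit()].
#' @export
assign_hits <- function(hits, taxmap,
                        methods = c("TopHit", "TopHitPlus", "TopN", "TopNPlus"),
                        params = topnplus_params(),
                        query_ids = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(query_ids)) query_ids <- unique(hits$query_id)
  fns <- list(TopHit = assign_tophit,
              TopHitPlus = assign_tophitplus,
              TopN = assign_topn,
              TopNPlus = function(h, tm, query_id) {
                assign_topnplus(h, tm, params, query_id = query_id)
              })
  split_idx <- split(seq_len(nrow(hits)), hits$query_id)
  out <- vector("list", length(query_ids) * length(methods))
  k <- 0L
  for (qid in query_ids) {
    qhits <- hits[split_idx[[qid]] %||% integer(), , drop = FALSE]
    for (m in methods) {
      k <- k + 1L
      out[[k]] <- fns[[m]](qhits, taxmap, query_id = qid)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an assignment table
#'
#' Tab-separated with header, `NA` for unassigned ranks.
#'
#' @param assignments Output of [assign_hits()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
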