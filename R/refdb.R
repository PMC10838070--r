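#' Reference databases of barcode sequences
#'
#' A `ref_db` bundles a table of records (sequence + lineage + origin flag)
#' with three pieces of provenance: a free-text `label` (typically the
#' barcode name), a `scope` (`"world"` or `"local"`) and a `region`
#' (`"general"` for full-length sequences or `"restricted"` for
#' primer-trimmed amplicons). Records keep load order; `seq_id` is unique.
#' Identical sequences carrying different taxonomies (dereplication "unique
#' mode" upstream) are simply distinct records here.
#'
#' @param records Data.frame with columns `seq_id`, `sequence`, the seven
#'   rank columns of [tax_ranks()], and optionally `origin`
#'   (`"local"`/`"foreign"`, default `"foreign"`) and `source_accession`
#'   (identifier shared between a restricted sequence and its full-length
#'   parent; defaults to `seq_id`).
#' @param label Free-text database label.
#' @param scope `"world"` or `"local"`.
#' @param region `"general"` or `"restricted"`.
#' @return An object of class `ref_db`.
#' @export
ref_db <- function(records, label = "refdb", scope = "world", region = "general") {
  scope <- match.arg(scope, c("world", "local"))
  region <- match.arg(region, c("general", "restricted"))
  stopifnot(is.data.frame(records))
  needed <- c("seq_id", "sequence", tax_ranks())
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$seq_id)) {
    stop("duplicate seq_id in reference database")
  }
  records$sequence <- toupper(records$sequence)
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", records$sequence)
  if (any(bad)) {
    stop(sum(bad), " sequence(s) contain non-IUPAC characters (first: ",
         records$seq_id[which(bad)[1L]], ")")
  }
  if (any(nchar(records$sequence) < 1L)) stop("zero-length sequence in database")
  if (is.null(records$origin)) records$origin <- "foreign"
  if (is.null(records$source_accession)) records$source_accession <- records$seq_id
  if (!all(records$origin %in% c("local", "foreign"))) {
    stop("origin must be 'local' or 'foreign'")
  }
  rownames(records) <- NULL
  structure(list(records = records, label = label, scope = scope, region = region),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  r <- x$records
  cat(sprintf("<ref_db '%s'> %d records | scope=%s region=%s | %d species, %d genera, %d families | %d local\n",
              x$label, nrow(r), x$scope, x$region,
              length(unique(r$species)), length(unique(r$genus)),
              length(unique(r$family)), sum(r$origin == "local")))
  invisible(x)
}

#' @export
length.ref_db <- function(x) nrow(x$records)

#' Read a reference database from FASTA + taxonomy table
#'
#' Joins a FASTA file (IDs = first whitespace-delimited token of each header;
#' wrapped sequences accepted) with a two-column taxonomy table
#' ([read_taxonomy()]). FASTA entries without a taxonomy row are dropped with
#' a message reporting the count. Origin defaults to `"foreign"` until
#' [label_origin()] is applied.
#'
#' @param fasta_path,taxonomy_path File paths.
#' @inheritParams ref_db
#' @return A [ref_db] object.
#' @export
read_reference <- function(fasta_path, taxonomy_path,
                           label = "refdb", scope = "world", region = "general") {
  if (!file.exists(fasta_path)) stop("cannot read FASTA: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1L), 1L)
  tax <- read_taxonomy(taxonomy_path)
  keep <- ids %in% tax$seq_id
  if (sum(keep) == 0L) stop("no FASTA entry has a matching taxonomy row")
  if (any(!keep)) {
    message(sum(!keep), " FASTA entr(ies) without taxonomy dropped")
  }
  ids <- ids[keep]
  seqs <- seqs[keep]
  m <- match(ids, tax$seq_id)
  records <- data.frame(seq_id = ids,
                        sequence = as.character(seqs),
                        tax[m, tax_ranks(), drop = FALSE],
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  check_genus_consistency(records)
  ref_db(records, label = label, scope = scope, region = region)
}

#' Write a reference database to FASTA + taxonomy table
#'
#' Writers emit records in stored (load) order so outputs are deterministic.
#'
#' @param db A [ref_db].
#' @param fasta_path,taxonomy_path Output paths.
#' @export
write_reference <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "ref_db"))
  seqs <- Biostrings::DNAStringSet(db$records$sequence)
  names(seqs) <- db$records$seq_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  write_taxonomy(data.frame(seq_id = db$records$seq_id,
                            lineage = lineage_string(db$records)),
                 taxonomy_path)
  invisible(db)
}

#' Flag records as local or foreign species
#'
#' Classifies every record by whether its species name belongs to the study
#' area's flora. The split drives both target selection (all local targets
#' are kept, foreign ones subsampled) and the Local DB subset.
#'
#' @param db A [ref_db].
#' @param local_species Character vector of species binomials present in the
#'   study area. May be empty (everything foreign).
#' @return The database with `origin` set per record.
#' @export
label_origin <- function(db, local_species) {
  stopifnot(inherits(db, "ref_db"), is.character(local_species))
  db$records$origin <- ifelse(db$records$species %in% local_species,
                              "local", "foreign")
  message(sum(db$records$origin == "local"), " local / ",
          sum(db$records$origin == "foreign"), " foreign records")
  db
}

#' Subset a database to the local flora (Local DB)
#'
#' @param db A [ref_db] with origins labelled.
#' @return A [ref_db] with only `origin == "local"` records and
#'   `scope = "local"`.
#' @export
subset_local <- function(db) {
  stopifnot(inherits(db, "ref_db"))
  keep <- db$records$origin == "local"
  if (!any(keep)) stop("no local records: did you run label_origin()?")
  out <- db
  out$records <- db$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$scope <- "local"
  out
}

#' Select cross-validation target sequences
#'
#' Targets are the sequences whose taxonomy we pretend not to know: all
#' records of local species plus a seeded random sample of a fraction
#' (default 10%) of the foreign records, minus every record whose species
#' name is a hybrid ([is_hybrid()]) or an imprecise identification
#' ([is_imprecise()]).
#'
#' @param db A [ref_db] with origins labelled.
#' @param foreign_fraction Fraction of foreign records sampled (default 0.1).
#' @param seed Integer seed; the sample is deterministic given the seed.
#' @return Character vector of target `seq_id`s (database order).
#' @export
select_targets <- function(db, foreign_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(db, "ref_db"),
            foreign_fraction >= 0, foreign_fraction <= 1)
  r <- db$records
  excluded <- is_hybrid(r$species) | is_imprecise(r$species)
  loc <- r$seq_id[r$origin == "local" & !excluded]
  foreign_ids <- r$seq_id[r$origin == "foreign" & !excluded]
  n_take <- round(foreign_fraction * length(foreign_ids))
  sampled <- if (n_take > 0L) {
    local_seed(seed)
    sample(foreign_ids, n_take)
  } else character()
  ids <- union(loc, sampled)
  r$seq_id[r$seq_id %in% ids]
}

#' Subset a database by record IDs (internal)
#' @noRd
subset_records <- function(db, ids, keep = TRUE) {
  out <- db
  sel <- db$records$seq_id %in% ids
  if (!keep) sel <- !sel
  out$records <- db$records[sel, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Read / write a local-species list
#'
#' Plain text, one species binomial per line.
#'
#' @param path File path.
#' @export
read_species_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[x != ""]
}

#' @rdname read_species_list
#' @param species Character vector of binomials.
#' @export
write_species_list <- function(species, path) {
  writeLines(species, path)
  invisible(path)
}
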