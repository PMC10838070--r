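#' Cross-validation configuration
#'
#' Bundles the choices that define one cross-validation run.
#'
#' * `cv_mode` — `"kfold"` removes each fold's sequences from the reference
#'   before searching (how well does the database identify a sequence it
#'   does not contain?); `"leaked"` searches against the full database (can
#'   the exact sequence be retrieved when present?).
#' * `region_design` — `"general"` (full-length vs full-length),
#'   `"restricted"` (amplicon vs amplicon) or `"restricted_general"`
#'   (amplicon queries vs full-length reference; each fold's full-length
#'   parents, matched by `source_accession`, are removed first).
#' * `db_scope` — `"world"` uses the whole database as reference;
#'   `"local"` drops foreign-species records from the reference first.
#'
#' @param cv_mode `"kfold"` or `"leaked"`.
#' @param k Number of folds (default 10; ignored for leaked CV).
#' @param region_design See above.
#' @param db_scope `"world"` or `"local"`.
#' @param foreign_fraction Fraction of foreign records used as targets
#'   (default 0.1; all local records are always targets).
#' @param seed Integer seed controlling target sampling and fold assignment.
#' @param max_hits Top hits kept per query (default 10).
#' @param methods Assignment methods to run.
#' @param stratify_by Optional rank name; folds are then drawn within each
#'   taxon of that rank instead of fully at random.
#' @param params TopNPlus thresholds ([topnplus_params()]).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(cv_mode = c("kfold", "leaked"),
                      k = 10L,
                      region_design = c("general", "restricted", "restricted_general"),
                      db_scope = c("world", "local"),
                      foreign_fraction = 0.1,
                      seed = 1L,
                      max_hits = 10L,
                      methods = c("TopHit", "TopHitPlus", "TopN", "TopNPlus"),
                      stratify_by = NULL,
                      params = topnplus_params()) {
  cv_mode <- match.arg(cv_mode)
  region_design <- match.arg(region_design)
  db_scope <- match.arg(db_scope)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(k >= 2L, foreign_fraction >= 0, foreign_fraction <= 1, max_hits >= 1L)
  structure(list(cv_mode = cv_mode, k = as.integer(k),
                 region_design = region_design, db_scope = db_scope,
                 foreign_fraction = foreign_fraction, seed = as.integer(seed),
                 max_hits = as.integer(max_hits), methods = methods,
                 stratify_by = stratify_by, params = params),
            class = "cv_config")
}

#' Split target sequences into k folds
#'
#' A seeded uniform random permutation is cut into `k` folds whose sizes
#' differ by at most one. With `stratify_by`, the split is done within each
#' taxon of that rank (the default is the plain random split).
#'
#' @param target_ids Character vector of query IDs.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param strata Optional character vector (same length as `target_ids`) of
#'   group labels for stratified splitting.
#' @return Named integer vector: fold index (1..k) per target.
#' @export
make_folds <- function(target_ids, k = 10L, seed = 1L, strata = NULL) {
  stopifnot(k >= 2L)
  n <- length(target_ids)
  if (n < k) stop("fewer targets (", n, ") than folds (", k, ")")
  local_seed(seed)
  if (is.null(strata)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(strata) == n)
    fold <- integer(n)
    for (g in unique(strata)) {
      idx <- which(strata == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  stats::setNames(fold, target_ids)
}

#' Build the reference database for one fold
#'
#' * leaked CV: the reference is the full (scoped) database, fold ignored.
#' * k-fold, general or restricted design: the fold's own records are
#'   removed from the reference.
#' * k-fold, restricted-general design: the reference is the full-length
#'   (general) database minus every record whose `source_accession` is
#'   shared with a fold member — the restricted query's full-length parent
#'   must not be present.
#'
#' @param db The reference [ref_db] (for `restricted_general`, the general
#'   database).
#' @param fold_ids `seq_id`s of the fold's queries.
#' @param cv_mode `"kfold"` or `"leaked"`.
#' @param region_design As in [cv_config()].
#' @param query_db For `restricted_general`: the restricted [ref_db] the
#'   fold IDs refer to (source of their `source_accession`).
#' @return A [ref_db].
#' @export
build_fold_reference <- function(db, fold_ids, cv_mode = "kfold",
                                 region_design = "general",
                                 query_db = NULL) {
  stopifnot(inherits(db, "ref_db"))
  if (cv_mode == "leaked") return(db)
  if (region_design == "restricted_general") {
    if (is.null(query_db)) stop("restricted_general needs the restricted query_db")
    qrec <- query_db$records
    acc <- qrec$source_accession[qrec$seq_id %in% fold_ids]
    out <- db
    out$records <- db$records[!db$records$source_accession %in% acc, , drop = FALSE]
  } else {
    out <- subset_records(db, fold_ids, keep = FALSE)
  }
  rownames(out$records) <- NULL
  if (nrow(out$records) == 0L) stop("fold reference is empty")
  out
}

#' Run a cross-validation experiment
#'
#' End-to-end driver: selects targets ([select_targets()]), assigns folds
#' ([make_folds()]; leaked CV uses a single pass with the full reference),
#' builds each fold's reference ([build_fold_reference()], honouring
#' `db_scope` — a Local DB drops foreign records before anything else),
#' searches each fold's queries with `backend`, truncates to
#' `config$max_hits`, runs the configured assignment methods and scores each
#' prediction against the query's true lineage. Input databases are never
#' modified.
#'
#' Leaked CV with a local-scope reference silently degenerates for foreign
#' queries (their records are not in the reference at all, so nothing is
#' "leaked"); a warning is emitted rather than an error since the design is
#' occasionally useful as a contrast.
#'
#' @param db A [ref_db] with origins labelled; the source of both queries
#'   and reference (for `region_design = "restricted_general"` this is the
#'   restricted database).
#' @param config A [cv_config()].
#' @param backend Function `(queries_db, reference_db, max_hits)` returning
#'   a hit table; default [naive_search()]. Use a wrapper around
#'   [parse_blast_tabular()] to plug in real BLAST output.
#' @param general_db Full-length [ref_db], required for
#'   `region_design = "restricted_general"`.
#' @param targets Optional pre-selected target IDs (defaults to
#'   [select_targets()] under `config`).
#' @return Data.frame of class `cv_result`: one row per target x method with
#'   `query_id`, `fold`, `origin`, `method`, true taxa
#'   (`true_family`, `true_genus`, `true_species`), predicted taxa and
#'   scores (layout of [assign_hits()]) and per-rank logical
#'   `correct_family`, `correct_genus`, `correct_species` (unassigned =
#'   `FALSE`; the taxon column's `NA` is the no-identification marker).
#' @export
run_cv <- function(db, config = cv_config(), backend = naive_search,
                   general_db = NULL, targets = NULL) {
  stopifnot(inherits(db, "ref_db"), inherits(config, "cv_config"))
  if (config$region_design == "restricted_general" && is.null(general_db)) {
    stop("region_design 'restricted_general' requires general_db")
  }
  if (is.null(targets)) {
    targets <- select_targets(db, config$foreign_fraction, config$seed)
  }
  if (length(targets) == 0L) stop("no target sequences selected")
  trec <- db$records[match(targets, db$records$seq_id), , drop = FALSE]

  ref_base <- if (config$region_design == "restricted_general") general_db else db
  if (config$db_scope == "local") ref_base <- subset_local(ref_base)
  if (config$cv_mode == "leaked" && config$db_scope == "local" &&
      any(trec$origin == "foreign")) {
    warning("leaked CV against a Local DB: foreign queries are absent from ",
            "the reference, so their results behave like k-fold CV")
  }

  if (config$cv_mode == "leaked") {
    folds <- stats::setNames(rep(1L, length(targets)), targets)
  } else {
    strata <- if (!is.null(config$stratify_by)) {
      taxon_at(trec, config$stratify_by)
    } else {
      NULL
    }
    folds <- make_folds(targets, config$k, config$seed, strata = strata)
  }

  out <- vector("list", length(unique(folds)))
  for (f in sort(unique(folds))) {
    fold_ids <- names(folds)[folds == f]
    reference <- build_fold_reference(ref_base, fold_ids,
                                      cv_mode = config$cv_mode,
                                      region_design = config$region_design,
                                      query_db = db)
    queries <- subset_records(db, fold_ids)
    hits <- tryCatch(
      top_hits(backend(queries, reference, config$max_hits), config$max_hits),
      error = function(e) {
        stop("search backend failed on fold ", f, " (", length(fold_ids),
             " queries): ", conditionMessage(e))
      })
    asg <- assign_hits(hits, reference, methods = config$methods,
                       params = config$params, query_ids = fold_ids)
    asg$fold <- f
    out[[f]] <- asg
  }
  res <- do.call(rbind, out)
  m <- match(res$query_id, db$records$seq_id)
  res$origin <- db$records$origin[m]
  for (rk in eval_ranks()) {
    res[[paste0("true_", rk)]] <- db$records[[rk]][m]
    res[[paste0("correct_", rk)]] <-
      !is.na(res[[rk]]) & res[[rk]] == res[[paste0("true_", rk)]]
  }
  first <- c("query_id", "fold", "origin", "method",
             paste0("true_", eval_ranks()))
  res <- res[, c(first, setdiff(names(res), first))]
  res <- res[order(res$method, res$fold, res$query_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cv_result", class(res))
  res
}
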