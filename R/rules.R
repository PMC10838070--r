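#' Declarative discard rules for unreliable assignments
#'
#' A filter rule is a boolean expression over the two per-rank scores
#' `identity` and `consensus`, written in a small grammar: the comparators
#' `<`, `<=`, `>`, `>=`, `==`, the logical operators `&` (and), `|` (or),
#' `!` (not), parentheses, and numeric literals. The expression states the
#' *discard* condition: assignments for which it evaluates `TRUE` are
#' dropped.
#'
#' A rule set is an ordered cascade of up to two stages at one rank:
#' stage 1 applies the Local-DB rule to the Local-DB assignments; queries
#' whose assignment is discarded there (or that were never assigned) fall
#' through to stage 2, where the World-DB rule is applied to the World-DB
#' assignments. Queries failing both stages end up unassigned. Single-stage
#' sets (e.g. the genus rules, which use World-DB results only) simply omit
#' a stage.
#'
#' @param expr Discard condition as a character string, e.g.
#'   `"consensus < 40 & identity < 98.5"`.
#' @return `filter_rule`: the parsed rule (class `filter_rule`).
#' @export
#' @examples
#' r <- filter_rule("consensus < 40 & identity < 98.5")
#' rule_discards(r, identity = c(99, 97), consensus = c(50, 30))
filter_rule <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  e <- str2lang(expr)
  check_rule_ast(e)
  structure(list(expr = e, text = expr), class = "filter_rule")
}

#' @noRd
check_rule_ast <- function(e) {
  allowed_ops <- c("<", "<=", ">", ">=", "==", "&", "|", "!", "(")
  if (is.numeric(e) || is.integer(e)) return(invisible(TRUE))
  if (is.name(e)) {
    if (!as.character(e) %in% c("identity", "consensus")) {
      stop("rule may only reference 'identity' and 'consensus', not '",
           as.character(e), "'")
    }
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% allowed_ops) {
      stop("operator '", op, "' is not part of the rule grammar")
    }
    for (i in seq_along(e)[-1L]) check_rule_ast(e[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported element in rule expression")
}

#' @rdname filter_rule
#' @param rule A `filter_rule`.
#' @param identity,consensus Numeric score vectors (percentages).
#' @return `rule_discards`: logical vector, `TRUE` where the assignment is
#'   discarded; `NA` scores propagate to `NA`.
#' @export
rule_discards <- function(rule, identity, consensus) {
  stopifnot(inherits(rule, "filter_rule"))
  eval(rule$expr, list(identity = identity, consensus = consensus),
       baseenv())
}

#' @export
print.filter_rule <- function(x, ...) {
  cat("<filter_rule> discard if:", x$text, "\n")
  invisible(x)
}

#' Build a two-stage (Local-then-World) rule set
#'
#' @param rank Rank the rules apply to.
#' @param local Discard expression for the Local-DB stage (string or
#'   `filter_rule`), or `NULL` to skip the stage.
#' @param world Discard expression for the World-DB stage, or `NULL`.
#' @param label Free-text label.
#' @return A list of class `rule_set`.
#' @export
rule_set <- function(rank, local = NULL, world = NULL, label = "") {
  stopifnot(rank %in% eval_ranks())
  as_rule <- function(x) {
    if (is.null(x) || inherits(x, "filter_rule")) x else filter_rule(x)
  }
  if (is.null(local) && is.null(world)) stop("rule set needs at least one stage")
  structure(list(rank = rank, local = as_rule(local), world = as_rule(world),
                 label = label),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set '%s' rank=%s>\n", x$label, x$rank))
  if (!is.null(x$local)) cat("  local: discard if", x$local$text, "\n")
  if (!is.null(x$world)) cat("  world: discard if", x$world$text, "\n")
  invisible(x)
}

#' The shipped default rule sets
#'
#' Threshold rules derived from classification trees and GLM fits on large
#' ITS2 and rbcL cross-validation runs, encoded verbatim:
#'
#' * genus (ITS2): discard if `consensus < 40 & identity < 98.5`
#'   (World DB only);
#' * genus (rbcL): discard if `consensus < 40 & identity < 99.7`
#'   (World DB only);
#' * species (ITS2): Local DB, discard if `identity < 99`; then World DB,
#'   discard if `(consensus < 40 & identity < 99.9) | consensus < 20`;
#' * species (rbcL): Local DB, discard if
#'   `identity < 99.7 | (identity <= 100 & consensus < 50)`; then World DB,
#'   discard if `consensus < 30 | (consensus < 60 & identity < 100)`.
#'
#' Two ambiguities in the printed rules are configurable. The rbcL local
#' clause `identity <= 100` is vacuously true (identity never exceeds 100),
#' so the clause reduces to `consensus < 50`; `rbcl_local_identity =
#' "lt_100"` selects the alternative strict reading `identity < 100`. The
#' genus rules join their two clauses with "and" as printed;
#' `genus_operator = "or"` selects the more aggressive disjunctive variant.
#'
#' @param genus_operator `"and"` (as printed) or `"or"`.
#' @param rbcl_local_identity `"le_100"` (as printed; vacuous) or
#'   `"lt_100"`.
#' @return Named list of [rule_set] objects: `its2_genus`, `rbcl_genus`,
#'   `its2_species`, `rbcl_species`.
#' @export
default_rule_sets <- function(genus_operator = c("and", "or"),
                              rbcl_local_identity = c("le_100", "lt_100")) {
  genus_operator <- match.arg(genus_operator)
  rbcl_local_identity <- match.arg(rbcl_local_identity)
  gop <- if (genus_operator == "and") "&" else "|"
  rbcl_id <- if (rbcl_local_identity == "le_100") "identity <= 100" else "identity < 100"
  list(
    its2_genus = rule_set("genus",
                          world = paste("consensus < 40", gop, "identity < 98.5"),
                          label = "ITS2 genus"),
    rbcl_genus = rule_set("genus",
                          world = paste("consensus < 40", gop, "identity < 99.7"),
                          label = "rbcL genus"),
    its2_species = rule_set("species",
                            local = "identity < 99",
                            world = "(consensus < 40 & identity < 99.9) | consensus < 20",
                            label = "ITS2 species"),
    rbcl_species = rule_set("species",
                            local = paste0("identity < 99.7 | (", rbcl_id,
                                           " & consensus < 50)"),
                            world = "consensus < 30 | (consensus < 60 & identity < 100)",
                            label = "rbcL species")
  )
}

#' Apply a rule cascade to cross-validation assignments
#'
#' Stage 1 evaluates the Local-DB discard rule on `local_rows`; queries
#' whose assignment survives keep it (stage `"local"`). Queries whose
#' assignment was *discarded* fall through to the World-DB rule on
#' `world_rows`; survivors there keep the world assignment (stage
#' `"world"`). Queries failing both stages are unassigned (stage
#' `"none"`), and a query that carried no assignment at a stage passes
#' through as unassigned rather than falling through. Since rules only ever
#' discard, filtering can convert wrong assignments to no-identification
#' but never mint new wrong ones when the stages agree on the predicted
#' taxon.
#'
#' @param local_rows,world_rows `cv_result` rows of a single method, from
#'   runs against the Local and World databases; keyed by `query_id` on the
#'   same query set. Either may be `NULL` when the rule set omits that
#'   stage.
#' @param rules A [rule_set].
#' @return Data.frame with one row per query: `query_id`, the true taxon,
#'   predicted `taxon`, `identity`, `consensus`, `stage`
#'   (`"local"`/`"world"`/`"none"`) and `correct`.
#' @export
apply_rules <- function(local_rows = NULL, world_rows = NULL, rules) {
  stopifnot(inherits(rules, "rule_set"))
  rk <- rules$rank
  if (!is.null(rules$local) && is.null(local_rows)) {
    stop("rule set has a Local-DB stage but local_rows is NULL")
  }
  if (!is.null(rules$world) && is.null(world_rows)) {
    stop("rule set has a World-DB stage but world_rows is NULL")
  }
  base <- if (!is.null(local_rows)) local_rows else world_rows
  check_single_method(base)
  qids <- base$query_id
  out <- data.frame(query_id = qids,
                    true_taxon = base[[paste0("true_", rk)]],
                    taxon = NA_character_, identity = NA_real_,
                    consensus = NA_real_, stage = "none",
                    stringsAsFactors = FALSE)
  # pending: still eligible for the next stage. A query that was never
  # assigned at a stage passes through unassigned; only assignments that the
  # stage actively discarded fall through to the next stage.
  pending <- rep(TRUE, length(qids))

  stage_apply <- function(rows, rule, stage_name) {
    check_single_method(rows)
    m <- match(out$query_id, rows$query_id)
    if (anyNA(m)) stop("query sets differ between stages")
    taxon <- rows[[rk]][m]
    idn <- rows[[paste0(rk, "_identity")]][m]
    cons <- rows[[paste0(rk, "_consensus")]][m]
    assigned <- !is.na(taxon)
    discard <- rep(TRUE, length(taxon))
    discard[assigned] <- rule_discards(rule, idn[assigned], cons[assigned])
    take <- pending & assigned & !discard
    out$taxon[take] <<- taxon[take]
    out$identity[take] <<- idn[take]
    out$consensus[take] <<- cons[take]
    out$stage[take] <<- stage_name
    # exhausted: unassigned input at this stage (nothing to pass on)
    pending <<- pending & assigned & discard
    invisible(NULL)
  }
  if (!is.null(rules$local)) stage_apply(local_rows, rules$local, "local")
  if (!is.null(rules$world) && any(pending)) {
    stage_apply(world_rows, rules$world, "world")
  }
  out$correct <- !is.na(out$taxon) & out$taxon == out$true_taxon
  out
}

#' @noRd
check_single_method <- function(rows) {
  if (!is.null(rows$method) && length(unique(rows$method)) > 1L) {
    stop("rows mix several assignment methods")
  }
  invisible(TRUE)
}

#' Correct / wrong / no-identification shares before and after filtering
#'
#' Summarises the effect of a discard cascade: the three shares sum to 100
#' per table, and for the filtered table the residual error among the
#' assignments that were kept (`wrong / (wrong + correct)`) is reported —
#' e.g. shares of 68% correct and 17% wrong give 17/(17+68) = 20% of the
#' kept assignments still incorrect.
#'
#' @param before A `cv_result` of a single method (raw assignments) with a
#'   `correct_<rank>` column, or the output of [apply_rules()].
#' @param after Output of [apply_rules()] on the same query set (or any
#'   table in the same layout).
#' @param rank Evaluated rank (used for `cv_result` inputs).
#' @return List with `before` and `after` rows (`pct_correct`, `pct_wrong`,
#'   `pct_no_id`) and `error_among_assigned` (%) of the after table (`NA`
#'   when nothing remains assigned).
#' @export
summarize_filtering <- function(before, after, rank) {
  shares <- function(x) {
    if (!is.null(x$stage)) {           # apply_rules output
      assigned <- !is.na(x$taxon)
      correct <- x$correct
      qid <- x$query_id
    } else {                           # cv_result rows
      check_single_method(x)
      assigned <- !is.na(x[[rank]])
      correct <- x[[paste0("correct_", rank)]]
      qid <- x$query_id
    }
    n <- length(assigned)
    list(qid = qid,
         pct_correct = 100 * sum(assigned & correct) / n,
         pct_wrong = 100 * sum(assigned & !correct) / n,
         pct_no_id = 100 * sum(!assigned) / n)
  }
  b <- shares(before)
  a <- shares(after)
  if (!setequal(b$qid, a$qid)) stop("before/after query sets differ")
  denom <- a$pct_correct + a$pct_wrong
  list(before = b[c("pct_correct", "pct_wrong", "pct_no_id")],
       after = a[c("pct_correct", "pct_wrong", "pct_no_id")],
       error_among_assigned = if (denom > 0) 100 * a$pct_wrong / denom else NA_real_)
}
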