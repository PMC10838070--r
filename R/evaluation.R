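#' Multi-class prediction quality at one rank
#'
#' Computes the standard quality metrics of a cross-validation result at a
#' given rank. A query with no predicted taxon counts as not successfully
#' predicted, so
#' `accuracy = n_correct / n_total * 100` with
#' `n_correct + n_wrong + n_unassigned = n_total`.
#'
#' Per class (taxon) `c`: precision `P = TP/(TP+FP)`, recall
#' `R = TP/(TP+FN)`, F-score `F = 2PR/(P+R)` (`NA` when `P+R = 0`), where a
#' true-`c` query left unassigned is a false negative of `c`. Micro-averaged
#' metrics pool TP/FP/FN over all classes: micro-precision is computed over
#' the assigned queries, micro-recall over all queries; when every query is
#' assigned, accuracy = micro-P = micro-R = micro-F ("micro F1").
#'
#' @param rows A `cv_result` (or compatible data.frame) containing a single
#'   method; mixing methods is an error (`evaluate` would silently pool
#'   them).
#' @param rank `"family"`, `"genus"` or `"species"`.
#' @return A list of class `tax_metrics`: `rank`, `n_total`, `n_correct`,
#'   `n_wrong`, `n_unassigned`, `accuracy`, `micro_precision`,
#'   `micro_recall`, `micro_f`, and `per_class` (data.frame with `taxon`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`).
#' @export
evaluate <- function(rows, rank) {
  stopifnot(rank %in% eval_ranks(), nrow(rows) > 0L)
  if (length(unique(rows$method)) > 1L) {
    stop("rows mix several methods; evaluate one method at a time")
  }
  truth <- rows[[paste0("true_", rank)]]
  pred <- rows[[rank]]
  n_total <- length(truth)
  assigned <- !is.na(pred)
  correct <- assigned & pred == truth
  n_correct <- sum(correct)
  n_wrong <- sum(assigned & !correct)
  n_unassigned <- sum(!assigned)

  classes <- sort(unique(c(truth, pred[assigned])))
  tp <- vapply(classes, function(cl) sum(assigned & pred == cl & truth == cl),
               numeric(1L))
  fp <- vapply(classes, function(cl) sum(assigned & pred == cl & truth != cl),
               numeric(1L))
  fn <- vapply(classes, function(cl) sum(truth == cl & (!assigned | pred != cl)),
               numeric(1L))
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
              2 * prec * rec / (prec + rec), NA_real_)
  per_class <- data.frame(taxon = classes, tp = tp, fp = fp, fn = fn,
                          precision = prec, recall = rec, f_score = f,
                          row.names = NULL, stringsAsFactors = FALSE)

  micro_p <- if (sum(assigned) > 0L) n_correct / sum(assigned) else NA_real_
  micro_r <- n_correct / n_total
  micro_f <- if (!is.na(micro_p) && (micro_p + micro_r) > 0) {
    2 * micro_p * micro_r / (micro_p + micro_r)
  } else {
    NA_real_
  }
  structure(list(rank = rank, n_total = n_total, n_correct = n_correct,
                 n_wrong = n_wrong, n_unassigned = n_unassigned,
                 accuracy = 100 * n_correct / n_total,
                 micro_precision = 100 * micro_p,
                 micro_recall = 100 * micro_r,
                 micro_f = 100 * micro_f,
                 per_class = per_class),
            class = "tax_metrics")
}

#' @export
print.tax_metrics <- function(x, ...) {
  cat(sprintf("<tax_metrics rank=%s> n=%d | correct %d (%.1f%%) | wrong %d | no-ID %d\n",
              x$rank, x$n_total, x$n_correct, x$accuracy, x$n_wrong,
              x$n_unassigned))
  cat(sprintf("  micro P/R/F: %.1f / %.1f / %.1f (%% over %d classes)\n",
              x$micro_precision, x$micro_recall, x$micro_f,
              nrow(x$per_class)))
  invisible(x)
}

#' Model the probability that an assignment is correct (binomial GLM)
#'
#' Fits `correct ~ identity * consensus` (logit link, maximum likelihood via
#' IRLS) on the assigned rows of a cross-validation result at one rank. The
#' fitted surface is the basis for reading off how the probability of a
#' correct identification grows with the two scores; whether that growth is
#' monotone over the observed score range is checked and reported, not
#' enforced.
#'
#' Unassigned rows carry no scores and are excluded: the model describes the
#' correctness of assignments that were actually made.
#'
#' @param rows A `cv_result` (single method).
#' @param rank Evaluated rank.
#' @param interaction Include the identity x consensus term (default
#'   `TRUE`); `FALSE` gives the additive fit used for univariate reading.
#' @param epsilon,maxit IRLS convergence tolerance on deviance and iteration
#'   cap.
#' @return A list of class `correctness_glm`: `coefficients`, `std_errors`,
#'   `converged`, `separation` (fitted probabilities numerically at 0/1 or
#'   a degenerate all-correct/all-wrong response), `monotone` (named logical
#'   for the two scores), `n`, `rank`, and the underlying `fit`
#'   ([stats::glm] object).
#' @export
fit_correctness_glm <- function(rows, rank, interaction = TRUE,
                                epsilon = 1e-8, maxit = 100L) {
  stopifnot(rank %in% eval_ranks())
  d <- data.frame(correct = rows[[paste0("correct_", rank)]],
                  identity = rows[[paste0(rank, "_identity")]],
                  consensus = rows[[paste0(rank, "_consensus")]])
  d <- d[!is.na(d$identity) & !is.na(d$consensus), , drop = FALSE]
  if (nrow(d) < 4L) stop("too few assigned rows to fit a GLM")
  if (stats::var(d$identity) == 0) stop("identity is constant: degenerate design")
  if (stats::var(d$consensus) == 0) stop("consensus is constant: degenerate design")
  form <- if (interaction) {
    correct ~ identity * consensus
  } else {
    correct ~ identity + consensus
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(),
               data = d, control = stats::glm.control(epsilon = epsilon,
                                                      maxit = maxit)))
  p <- stats::fitted(fit)
  eps <- 1e-8
  separation <- all(d$correct) || !any(d$correct) ||
    all(p > 1 - eps | p < eps)
  # monotonicity of the fitted probability in each score, other score at its
  # median, over the observed range
  mono <- vapply(c("identity", "consensus"), function(v) {
    grid <- data.frame(identity = stats::median(d$identity),
                       consensus = stats::median(d$consensus))
    grid <- grid[rep(1L, 25L), , drop = FALSE]
    grid[[v]] <- seq(min(d[[v]]), max(d[[v]]), length.out = 25L)
    pr <- stats::predict(fit, newdata = grid, type = "response")
    all(diff(pr) >= -1e-10)
  }, logical(1L))
  structure(list(coefficients = stats::coef(fit),
                 std_errors = summary(fit)$coefficients[, "Std. Error"],
                 converged = fit$converged,
                 separation = separation,
                 monotone = mono,
                 n = nrow(d), rank = rank, fit = fit),
            class = "correctness_glm")
}

#' @export
print.correctness_glm <- function(x, ...) {
  cat(sprintf("<correctness_glm rank=%s> n=%d converged=%s separation=%s\n",
              x$rank, x$n, x$converged, x$separation))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tree hyperparameters
#'
#' @param min_split Minimum rows in a node before a split is attempted.
#' @param min_bucket Minimum rows in a leaf.
#' @param max_depth Maximum tree depth.
#' @param cp Minimum complexity (relative impurity decrease) for a split
#'   during growing; kept small so pruning, not growing, does the model
#'   selection.
#' @param xval Folds of the internal cross-validation used for pruning.
#' @param seed Seed for the internal cross-validation.
#' @return A list for [fit_threshold_tree()].
#' @export
tree_params <- function(min_split = 20L, min_bucket = 7L, max_depth = 5L,
                        cp = 1e-4, xval = 10L, seed = 1L) {
  list(min_split = as.integer(min_split), min_bucket = as.integer(min_bucket),
       max_depth = as.integer(max_depth), cp = cp, xval = as.integer(xval),
       seed = as.integer(seed))
}

#' Threshold discovery with a Gini classification tree
#'
#' Fits a binary classification tree (Gini impurity, axis-aligned splits on
#' the identity and consensus scores, response = correct/incorrect
#' assignment) and prunes it with the one-standard-error rule: among the
#' cost-complexity subtrees, pick the smallest one whose cross-validated
#' error is within one standard error of the minimum. The split thresholds
#' of the pruned tree are the natural candidates for "discard below this
#' score" filtering rules.
#'
#' The tree machinery is [rpart::rpart()] (Gini splits, cost-complexity
#' path, seeded internal CV); this function adds the 1-SE subtree selection
#' and a flat export of the split structure.
#'
#' @inheritParams fit_correctness_glm
#' @param params Hyperparameters from [tree_params()].
#' @return A list of class `threshold_tree`: `tree` (pruned rpart object),
#'   `splits` (data.frame `variable`, `threshold`, `node`), `cptable`,
#'   `cp_chosen`, `n`, `rank`. An all-one-class response yields a valid
#'   single-leaf tree.
#' @export
fit_threshold_tree <- function(rows, rank, params = tree_params()) {
  stopifnot(rank %in% eval_ranks())
  d <- data.frame(correct = factor(rows[[paste0("correct_", rank)]],
                                   levels = c(FALSE, TRUE),
                                   labels = c("wrong", "correct")),
                  identity = rows[[paste0(rank, "_identity")]],
                  consensus = rows[[paste0(rank, "_consensus")]])
  d <- d[!is.na(d$identity) & !is.na(d$consensus), , drop = FALSE]
  if (nrow(d) < params$min_split) {
    stop("too few assigned rows (", nrow(d), ") for min_split = ",
         params$min_split)
  }
  local_seed(params$seed)
  fit <- rpart::rpart(correct ~ identity + consensus, data = d,
                      method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        minsplit = params$min_split,
                        minbucket = params$min_bucket,
                        maxdepth = params$max_depth,
                        cp = params$cp,
                        xval = params$xval))
  cpt <- fit$cptable
  if (nrow(cpt) > 1L && "xerror" %in% colnames(cpt)) {
    i_min <- which.min(cpt[, "xerror"])
    thresh <- cpt[i_min, "xerror"] + cpt[i_min, "xstd"]
    # smallest subtree within 1 SE; earlier rows have fewer splits
    i_sel <- which(cpt[, "xerror"] <= thresh)[1L]
    cp_chosen <- cpt[i_sel, "CP"]
    pruned <- rpart::prune(fit, cp = cp_chosen * 1.0000001)
  } else {
    cp_chosen <- if (nrow(cpt) > 0L) cpt[1L, "CP"] else NA_real_
    pruned <- fit
  }
  splits <- extract_splits(pruned)
  structure(list(tree = pruned, splits = splits, cptable = cpt,
                 cp_chosen = cp_chosen, n = nrow(d), rank = rank),
            class = "threshold_tree")
}

#' @noRd
extract_splits <- function(fit) {
  fr <- fit$frame
  sp <- fit$splits
  internal <- fr$var != "<leaf>"
  if (!any(internal)) {
    return(data.frame(variable = character(), threshold = numeric(),
                      node = integer(), stringsAsFactors = FALSE))
  }
  # primary split of each internal node, in node order
  nsub <- fr$ncompete + fr$nsurrogate + 1L
  first <- cumsum(c(1L, (nsub * internal)[-length(internal)]))
  idx <- first[internal]
  data.frame(variable = as.character(fr$var[internal]),
             threshold = sp[idx, "index"],
             node = as.integer(rownames(fr)[internal]),
             stringsAsFactors = FALSE)
}

#' Root split of a fitted threshold tree
#'
#' @param x A `threshold_tree`.
#' @return List with `variable` and `threshold`, or `NULL` for a
#'   single-leaf tree.
#' @export
root_split <- function(x) {
  stopifnot(inherits(x, "threshold_tree"))
  if (nrow(x$splits) == 0L) return(NULL)
  i <- which(x$splits$node == 1L)
  list(variable = x$splits$variable[i], threshold = x$splits$threshold[i])
}

#' @export
print.threshold_tree <- function(x, ...) {
  cat(sprintf("<threshold_tree rank=%s> n=%d, %d split(s), cp=%.4g\n",
              x$rank, x$n, nrow(x$splits), x$cp_chosen))
  if (nrow(x$splits) > 0L) {
    print(x$splits, row.names = FALSE)
  }
  invisible(x)
}
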