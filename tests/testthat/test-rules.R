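test_that("the rule grammar accepts score expressions and nothing else", {
  r <- filter_rule("consensus < 40 & identity < 98.5")
  expect_identical(rule_discards(r, identity = c(99, 97, 97),
                                 consensus = c(30, 50, 30)),
                   c(FALSE, FALSE, TRUE))
  expect_error(filter_rule("system('rm -rf /')"), "grammar")
  expect_error(filter_rule("pident < 99"), "identity")
  expect_error(filter_rule("identity %in% 1"), "grammar")
})

test_that("genus rule: conjunction as printed, boolean evaluation by hand", {
  rs <- default_rule_sets()
  its2_g <- rs$its2_genus
  expect_null(its2_g$local)  # genus rules use World DB results only
  # consensus 50, identity 97: conjunction fails (consensus >= 40) -> kept
  expect_false(rule_discards(its2_g$world, identity = 97, consensus = 50))
  expect_true(rule_discards(its2_g$world, identity = 97, consensus = 30))
  expect_false(rule_discards(its2_g$world, identity = 99, consensus = 30))
  # rbcL variant differs only in the identity cut
  expect_true(rule_discards(rs$rbcl_genus$world, identity = 99.5, consensus = 30))
  # OR variant is stricter
  rs_or <- default_rule_sets(genus_operator = "or")
  expect_true(rule_discards(rs_or$its2_genus$world, identity = 97, consensus = 50))
})

test_that("ITS2 species cascade: local stage, then world, else unassigned", {
  rs <- default_rule_sets()$its2_species
  world <- make_cv_rows(true_species = c("S a", "S a", "S a"),
                        pred_species = c("S a", "S b", "S a"),
                        identity = c(100, 100, 99.95),
                        consensus = c(10, 80, 50))
  local <- make_cv_rows(true_species = c("S a", "S a", "S a"),
                        pred_species = c("S a", "S a", "S b"),
                        identity = c(99.5, 98, 98.5),
                        consensus = c(90, 90, 90))
  out <- apply_rules(local, world, rs)
  # q1: local identity 99.5 >= 99 -> kept at stage 1
  expect_identical(out$stage[1], "local")
  expect_identical(out$taxon[1], "S a")
  # q2: local 98 discarded; world identity 100 consensus 80 -> kept at stage 2
  expect_identical(out$stage[2], "world")
  expect_identical(out$taxon[2], "S b")
  # q3: local 98.5 discarded; world consensus 50 identity 99.95:
  #     (consensus<40 & identity<99.9) FALSE, consensus<20 FALSE -> kept
  expect_identical(out$stage[3], "world")

  # two-stage discard by hand: local identity 98, world identity 100 but
  # consensus 10 (< 20) -> unassigned
  world2 <- world; world2$species_consensus[1] <- 10
  local2 <- local; local2$species_identity[1] <- 98
  out2 <- apply_rules(local2, world2, rs)
  expect_identical(out2$stage[1], "none")
  expect_true(is.na(out2$taxon[1]))
})

test_that("the verbatim rbcL local rule reduces to its consensus clause", {
  rs <- default_rule_sets()$rbcl_species
  # identity <= 100 is vacuous: consensus < 50 alone decides
  expect_true(rule_discards(rs$local, identity = 100, consensus = 40))
  expect_false(rule_discards(rs$local, identity = 100, consensus = 60))
  expect_true(rule_discards(rs$local, identity = 99.5, consensus = 90))
  # alternative strict reading spares identity-100 hits from the clause
  alt <- default_rule_sets(rbcl_local_identity = "lt_100")$rbcl_species
  expect_false(rule_discards(alt$local, identity = 100, consensus = 40))
})

test_that("filtering is monotone: never more wrong, never fewer unassigned", {
  withr::local_seed(303)
  for (rs in default_rule_sets()[c("its2_species", "rbcl_species")]) {
    n <- 120
    truth <- sample(paste0("S", 1:6), n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.55, truth,
                   sample(paste0("S", 1:6), n, TRUE))
    pred[stats::runif(n) < 0.08] <- NA
    # same predictions in both stages, independently drawn scores
    mk <- function() {
      make_cv_rows(truth, pred,
                   identity = round(stats::runif(n, 95, 100), 2),
                   consensus = round(stats::runif(n, 0, 100)))
    }
    local <- mk(); world <- mk()
    out <- apply_rules(local, world, rs)
    before <- evaluate(local, "species")
    wrong_after <- sum(!is.na(out$taxon) & !out$correct)
    expect_lte(wrong_after, before$n_wrong)
    expect_gte(sum(is.na(out$taxon)), before$n_unassigned)
    # both stages actually used
    expect_setequal(intersect(c("local", "world"), out$stage),
                    c("local", "world"))
  }
})

test_that("mismatched query sets and missing stages are errors", {
  # identities below the local cut force the cascade into stage 2
  rows <- make_cv_rows(c("S a", "S b"), c("S a", "S b"), identity = 97)
  rs <- default_rule_sets()$its2_species
  expect_error(apply_rules(rows, rows[1, ], rs), "query sets")
  expect_error(apply_rules(NULL, rows, rs), "local_rows")
})

test_that("filtering summaries reproduce the error-among-assigned arithmetic", {
  # after-table shares: 68% correct, 17% wrong, 15% no-ID
  truth <- rep("S a", 100)
  pred_before <- c(rep("S a", 70), rep("S b", 30))
  pred_after <- c(rep("S a", 68), rep(NA, 2), rep("S b", 17), rep(NA, 13))
  before <- make_cv_rows(truth, pred_before)
  after <- make_cv_rows(truth, pred_after)
  s <- summarize_filtering(before, after, "species")
  expect_equal(s$after$pct_correct, 68)
  expect_equal(s$after$pct_wrong, 17)
  expect_equal(s$after$pct_no_id, 15)
  expect_equal(s$after$pct_correct + s$after$pct_wrong + s$after$pct_no_id, 100)
  expect_equal(s$error_among_assigned, 100 * 17 / (17 + 68))

  # discard nothing -> before == after; discard everything -> all no-ID
  same <- summarize_filtering(before, before, "species")
  expect_equal(same$before, same$after)
  none <- make_cv_rows(truth, rep(NA_character_, 100))
  all_gone <- summarize_filtering(before, none, "species")
  expect_equal(all_gone$after$pct_no_id, 100)
  expect_true(is.na(all_gone$error_among_assigned))
})
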