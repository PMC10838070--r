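test_that("consensus scores reproduce the Brassica worked example", {
  hits <- brassica_hits()
  tm <- brassica_taxmap()
  sp <- consensus_scores(hits, tm, "species")
  expect_equal(sp[["Brassica nigra"]], 60)
  expect_equal(sp[["Brassica napus"]], 20)
  expect_equal(sp[["Sinapis alba"]], 20)
  ge <- consensus_scores(hits, tm, "genus")
  expect_equal(ge[["Brassica"]], 80)
  expect_equal(ge[["Sinapis"]], 20)
  fa <- consensus_scores(hits, tm, "family")
  expect_equal(fa[["Brassicaceae"]], 100)
})

test_that("consensus denominator counts all considered hits; unknowns excluded as taxa", {
  tm <- make_taxmap(paste0("s", 1:4),
                    c("Gen1 a", "Gen1 a", "Gen1 b", "unknown"))
  tm$species[4] <- "unknown"; tm$genus[4] <- "unknown"; tm$family[4] <- "unknown"
  hits <- make_hits(paste0("s", 1:4), pident = 99, bitscore = c(90, 80, 70, 60))
  cs <- consensus_scores(hits, tm, "species")
  expect_equal(cs[["Gen1 a"]], 50)         # 2 of 4 considered hits
  expect_false("unknown" %in% names(cs))
  expect_equal(sum(cs), 75)                # <= 100 with a rank-unknown hit
  # fewer than 10 hits, unanimous -> consensus 100, not capped by a fixed 10
  h3 <- make_hits(paste0("s", 1:3), pident = 99, bitscore = c(90, 80, 70))
  expect_equal(consensus_scores(h3, tm, "genus")[["Gen1"]], 100)
  # unresolvable subject errors
  hx <- make_hits("nope", 99, 50)
  expect_error(consensus_scores(hx, tm, "species"), "not found")
})

test_that("identity attribution follows the max bit score, not max identity", {
  tm <- make_taxmap(c("long", "short"), rep("Gen1 a", 2))
  hits <- make_hits(c("long", "short"), pident = c(98, 100),
                    bitscore = c(350, 60), align_length = c(400L, 50L))
  expect_equal(identity_for_taxon(hits, tm, "species", "Gen1 a"), 98)
  # single matching hit
  h1 <- make_hits("long", 99.4, 200)
  expect_equal(identity_for_taxon(h1, tm, "species", "Gen1 a"), 99.4)
  # equal bit scores: the earlier backend-output hit wins
  h2 <- make_hits(c("long", "short"), pident = c(97, 99), bitscore = c(100, 100))
  expect_equal(identity_for_taxon(h2, tm, "species", "Gen1 a"), 97)
  expect_error(identity_for_taxon(hits, tm, "species", "Gen1 zz"), "no hit")
})

test_that("TopHit takes the best-bit-score lineage at every rank", {
  hits <- brassica_hits(bitscores = seq(110, 101))  # s1 (B. napus) best
  tm <- brassica_taxmap()
  r <- assign_tophit(hits, tm)
  expect_identical(r$species, "Brassica napus")
  expect_identical(r$genus, "Brassica")
  expect_identical(r$family, "Brassicaceae")
  expect_equal(r$species_consensus, 20)
  expect_equal(r$genus_consensus, 80)

  # tie at the best bit score: input rank 1 wins
  h <- make_hits(c("a", "b"), pident = c(99, 98), bitscore = c(100, 100))
  tm2 <- make_taxmap(c("a", "b"), c("Gen1 a", "Gen2 b"))
  expect_identical(assign_tophit(h, tm2)$species, "Gen1 a")

  # empty hit list: unassigned everywhere
  r0 <- assign_tophit(hits[0, ], tm, query_id = "qq")
  expect_identical(r0$query_id, "qq")
  expect_true(is.na(r0$species) && is.na(r0$genus) && is.na(r0$family))
  expect_true(is.na(r0$species_identity) && is.na(r0$species_consensus))
})

test_that("TopHitPlus breaks bit-score ties by consensus, then alphabetically", {
  # tied best hits: species A and B; A has 4 of 10 hits, B has 1
  sp <- c("Gen1 A", "Gen2 B", rep("Gen1 A", 3), rep("Gen3 C", 5))
  tm <- make_taxmap(paste0("s", 1:10), sp)
  hits <- make_hits(paste0("s", 1:10), pident = 99,
                    bitscore = c(120, 120, rep(100, 8)))
  r <- assign_tophitplus(hits, tm)
  expect_identical(r$species, "Gen1 A")
  expect_equal(r$species_consensus, 40)

  # no tie: identical to TopHit at every rank
  hits2 <- make_hits(paste0("s", 1:10), pident = 99, bitscore = seq(120, 111))
  a <- assign_tophit(hits2, tm)
  b <- assign_tophitplus(hits2, tm)
  expect_identical(a[, setdiff(names(a), "method")],
                   b[, setdiff(names(b), "method")])

  # equal consensus among tied taxa: alphabetically first
  sp3 <- c("Gen1 zeta", "Gen1 alpha", "Gen1 zeta", "Gen1 alpha")
  tm3 <- make_taxmap(paste0("s", 1:4), sp3)
  h3 <- make_hits(paste0("s", 1:4), pident = 99,
                  bitscore = c(120, 120, 90, 90))
  expect_identical(assign_tophitplus(h3, tm3)$species, "Gen1 alpha")
})

test_that("TopN picks the per-rank consensus winner, ranks independently", {
  hits <- brassica_hits()
  tm <- brassica_taxmap()
  r <- assign_topn(hits, tm)
  expect_identical(r$species, "Brassica nigra")
  expect_equal(r$species_consensus, 60)
  expect_identical(r$genus, "Brassica")
  expect_equal(r$genus_consensus, 80)
  expect_identical(r$family, "Brassicaceae")
  expect_equal(r$family_consensus, 100)

  # cross-rank inconsistency: species from one genus, genus from another.
  # 5 hits species A (genus G1), 3 + 2 hits species B, C (both genus G2):
  # species -> A (50%), genus -> tie G1/G2 at 50 broken by identity -> G2.
  sp <- c(rep("G1 A", 5), rep("G2 B", 3), rep("G2 C", 2))
  tm2 <- make_taxmap(paste0("s", 1:10), sp)
  hits2 <- make_hits(paste0("s", 1:10),
                     pident = c(rep(95, 5), rep(99, 5)),
                     bitscore = c(rep(100, 5), rep(90, 5)))
  r2 <- assign_topn(hits2, tm2)
  expect_identical(r2$species, "G1 A")
  expect_identical(r2$genus, "G2")   # identity tie-break: 99 > 95

  # single hit: its full lineage, consensus 100
  h1 <- make_hits("s1", 98.2, 140)
  r1 <- assign_topn(h1, tm2)
  expect_identical(r1$species, "G1 A")
  expect_equal(r1$species_consensus, 100)
})

test_that("TopNPlus applies the four filters and can leave ranks unassigned", {
  # all hits clean and unanimous -> assigned with consensus 100
  tm <- make_taxmap(paste0("s", 1:10), rep("Gen1 a", 10))
  clean <- make_hits(paste0("s", 1:10), pident = 99.5, bitscore = seq(120, 111),
                     align_length = 350L, evalue = 0)
  r <- assign_topnplus(clean, tm)
  expect_identical(r$species, "Gen1 a")
  expect_equal(r$species_consensus, 100)

  # identity floor: pident 95 fails species (97) but passes genus (90)
  mid <- make_hits(paste0("s", 1:10), pident = 95, bitscore = seq(120, 111),
                   align_length = 350L, evalue = 0)
  r2 <- assign_topnplus(mid, tm)
  expect_true(is.na(r2$species))
  expect_true(is.na(r2$species_identity) && is.na(r2$species_consensus))
  expect_identical(r2$genus, "Gen1")
  expect_identical(r2$family, "Genaceae")

  # alignment length and E-value screens
  short <- make_hits(paste0("s", 1:2), pident = 99.5, bitscore = c(120, 110),
                     align_length = c(99L, 350L), evalue = c(0, 1e-5))
  expect_true(is.na(assign_topnplus(short, tm)$species))

  # identity window at species rank, applied by hand:
  # best hit 100; 99.5 (same species) within 1%, 98.7 (other species) excluded
  sp <- c("Gen1 a", "Gen1 a", "Gen2 b")
  tm3 <- make_taxmap(paste0("s", 1:3), sp)
  h3 <- make_hits(paste0("s", 1:3), pident = c(100, 99.5, 98.7),
                  bitscore = c(130, 120, 110), align_length = 350L, evalue = 0)
  r3 <- assign_topnplus(h3, tm3)
  expect_identical(r3$species, "Gen1 a")
  expect_equal(r3$species_consensus, 100)  # 2 of the 2 surviving hits
  # at genus rank the 10%-window keeps all three hits
  expect_equal(r3$genus_consensus, 100 * 2 / 3)
})

test_that("assignment invariants hold over random hit tables", {
  withr::local_seed(71)
  for (i in 1:200) {
    case <- random_hit_case(n_hits = sample(3:10, 1), tie_prone = (i %% 2 == 0))
    for (rk in eval_ranks()) {
      cs <- consensus_scores(case$hits, case$taxmap, rk)
      expect_lte(sum(cs), 100 + 1e-9)
      expect_equal(sum(cs), 100)  # no unknowns in this generator
    }
    for (fn in list(assign_tophit, assign_tophitplus, assign_topn)) {
      r <- fn(case$hits, case$taxmap)
      for (rk in eval_ranks()) {
        taxon <- r[[rk]]
        idn <- r[[paste0(rk, "_identity")]]
        # attributed identity is the pident of some hit matching the taxon
        sel <- case$taxmap[[rk]][match(case$hits$subject_id,
                                       case$taxmap$seq_id)] == taxon
        expect_true(idn %in% case$hits$pident[sel])
      }
    }
  }
})

test_that("assign_hits is complete over queries, including no-match queries", {
  case <- {
    withr::local_seed(5)
    random_hit_case(10)
  }
  out <- assign_hits(case$hits, case$taxmap,
                     query_ids = c("q1", "q_missing"))
  expect_identical(nrow(out), 8L)  # 2 queries x 4 methods
  miss <- out[out$query_id == "q_missing", ]
  expect_true(all(is.na(miss$species)))
})
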