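test_that("FASTA + taxonomy join keeps matched records and reports drops", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "db.fasta")
  tx <- file.path(dir, "db.tsv")
  writeLines(c(">a extra header words", "ACGTACGT", ">b", "GGGG", "CCCC",
               ">c", "TTTT"), fa)
  write_taxonomy(data.frame(seq_id = c("a", "b", "c"),
                            lineage = rep("k;p;c;o;f;Gen;Gen sp1", 3)), tx)
  db <- read_reference(fa, tx)
  expect_s3_class(db, "ref_db")
  expect_identical(db$records$seq_id, c("a", "b", "c"))
  expect_identical(db$records$sequence[2], "GGGGCCCC")  # wrapped FASTA

  # one FASTA entry without taxonomy is dropped with a message
  write_taxonomy(data.frame(seq_id = c("a", "c"),
                            lineage = rep("k;p;c;o;f;Gen;Gen sp1", 2)), tx)
  expect_message(db2 <- read_reference(fa, tx), "1 FASTA")
  expect_identical(db2$records$seq_id, c("a", "c"))

  write_taxonomy(data.frame(seq_id = "zz", lineage = "k;;;;;;"), tx)
  expect_error(read_reference(fa, tx), "no FASTA entry")
})

test_that("write_reference / read_reference round-trips a database", {
  db <- tiny_db(n_species = 3, copies = 2)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "out.fasta")
  tx <- file.path(dir, "out.tsv")
  write_reference(db, fa, tx)
  back <- read_reference(fa, tx)
  expect_identical(back$records[, c("seq_id", "sequence", tax_ranks())],
                   db$records[, c("seq_id", "sequence", tax_ranks())])
})

test_that("ref_db enforces its invariants", {
  rec <- tiny_db()$records
  rec2 <- rec
  rec2$seq_id[2] <- rec2$seq_id[1]
  expect_error(ref_db(rec2), "duplicate seq_id")
  rec3 <- rec
  rec3$sequence[1] <- "ACGTZZ"
  expect_error(ref_db(rec3), "non-IUPAC")
  # lower case is normalised, IUPAC ambiguity codes pass
  rec4 <- rec
  rec4$sequence[1] <- "acgtrykn"
  expect_identical(ref_db(rec4)$records$sequence[1], "ACGTRYKN")
})

test_that("origin labelling and the Local DB subset conserve records", {
  db <- tiny_db(n_species = 5, copies = 2)
  expect_message(db <- label_origin(db, c("Gen1 alpha", "Gen3 alpha")),
                 "4 local / 6 foreign")
  expect_identical(sum(db$records$origin == "local"), 4L)

  loc <- subset_local(db)
  expect_identical(loc$scope, "local")
  expect_identical(nrow(loc$records), 4L)
  # conservation: local + foreign = world
  expect_identical(nrow(loc$records) + sum(db$records$origin == "foreign"),
                   nrow(db$records))
  expect_setequal(c(loc$records$seq_id,
                    db$records$seq_id[db$records$origin == "foreign"]),
                  db$records$seq_id)

  all_foreign <- suppressMessages(label_origin(db, character()))
  expect_true(all(all_foreign$records$origin == "foreign"))
  expect_error(subset_local(all_foreign), "no local records")

  all_local <- suppressMessages(
    label_origin(db, unique(db$records$species)))
  expect_true(all(all_local$records$origin == "local"))
})

test_that("target selection keeps locals, samples foreigners, excludes bad names", {
  # 2 local species (4 records) + 10 foreign records, fraction 0.5 -> 4 + 5
  db <- tiny_db(n_species = 7, copies = 2)
  db <- suppressMessages(label_origin(db, c("Gen1 alpha", "Gen2 alpha")))
  t1 <- select_targets(db, foreign_fraction = 0.5, seed = 9)
  expect_length(t1, 4L + 5L)
  expect_true(all(db$records$seq_id[db$records$origin == "local"] %in% t1))
  # determinism
  expect_identical(select_targets(db, 0.5, seed = 9), t1)
  expect_false(identical(select_targets(db, 0.5, seed = 10), t1))

  # brute-force exclusion oracle: flag hybrids/imprecise by hand
  rec <- db$records
  rec$species[rec$genus == "Gen1"] <- "Gen1 x alpha"     # hybrid, local
  rec$species[rec$genus == "Gen3"] <- "Gen3 sp."         # imprecise, foreign
  db2 <- ref_db(rec)
  db2 <- suppressMessages(label_origin(db2, c("Gen1 x alpha", "Gen2 alpha")))
  t2 <- select_targets(db2, foreign_fraction = 0, seed = 1)
  manual <- rec$seq_id[rec$origin == "local" &
                         !is_hybrid(rec$species) & !is_imprecise(rec$species)]
  expect_identical(t2, manual)   # only the non-excluded local records
  expect_identical(t2, rec$seq_id[rec$genus == "Gen2"])
})

test_that("amplicon extraction finds primer sites within the mismatch budget", {
  fwd <- "ACGTACGTAC"
  rev <- "TTGCATGCAT"            # given 5'->3' on the reverse strand
  rev_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev)))
  set.seed(5)
  insert <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  rec <- data.frame(seq_id = "x", sequence = paste0(fwd, insert, rev_site),
                    stringsAsFactors = FALSE)

  amp <- extract_amplicon(rec, fwd, rev, max_mismatch = 0)
  expect_identical(amp$sequence, insert)          # primers excluded
  amp_in <- extract_amplicon(rec, fwd, rev, max_mismatch = 0,
                             include_primers = TRUE)
  expect_identical(amp_in$sequence, rec$sequence) # inclusive dialect

  # missing reverse site -> none
  rec2 <- rec
  rec2$sequence <- paste0(fwd, insert)
  expect_null(extract_amplicon(rec2, fwd, rev, max_mismatch = 0))

  # 2 mismatches in the forward site: budget 1 fails, budget 2 succeeds
  fwd_mut <- fwd
  substr(fwd_mut, 1, 1) <- "G"
  substr(fwd_mut, 5, 5) <- "C"
  rec3 <- rec
  rec3$sequence <- paste0(fwd_mut, insert, rev_site)
  expect_null(extract_amplicon(rec3, fwd, rev, max_mismatch = 1))
  amp3 <- extract_amplicon(rec3, fwd, rev, max_mismatch = 2)
  expect_identical(amp3$sequence, insert)

  # IUPAC degeneracy honoured on the primer side
  amp4 <- extract_amplicon(rec, "ACGTRCGTAC", rev, max_mismatch = 0)
  expect_identical(amp4$sequence, insert)

  # the amplicon is always an exact substring of the input
  expect_true(grepl(amp$sequence, rec$sequence, fixed = TRUE))
})

test_that("restrict_database trims all records and flags the region", {
  cfg <- sim_config(n_families = 2, genera_per_family = 1,
                    species_per_genus = 2, records_per_species = 2,
                    sequence_length = 150,
                    primers = list(fwd = "ACGTACGTACGTACGTACGT",
                                   rev = "TGCATGCATGCATGCATGCA"),
                    seed = 3)
  sim <- simulate_database(cfg)
  res <- restrict_database(sim$db, cfg$primers$fwd, cfg$primers$rev,
                           max_mismatch = 1)
  expect_identical(res$region, "restricted")
  expect_identical(nrow(res$records), nrow(sim$db$records))
  expect_true(all(nchar(res$records$sequence) == 150))
  expect_identical(res$records$source_accession, sim$db$records$seq_id)
})
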