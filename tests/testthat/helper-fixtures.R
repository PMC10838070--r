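# Fixtures are built in code; no data files.

# The classic worked example: 10 hits whose subjects map to
# 2x Brassica napus, 6x Brassica nigra, 2x Sinapis alba.
brassica_taxmap <- function() {
  species <- c(rep("Brassica napus", 2), rep("Brassica nigra", 6),
               rep("Sinapis alba", 2))
  genus <- vapply(strsplit(species, " "), `[`, character(1), 1)
  data.frame(seq_id = paste0("s", 1:10),
             kingdom = "Viridiplantae", phylum = "Streptophyta",
             class = "Magnoliopsida", order = "Brassicales",
             family = "Brassicaceae", genus = genus, species = species,
             stringsAsFactors = FALSE)
}

brassica_hits <- function(bitscores = seq(110, 101)) {
  data.frame(query_id = "q1", subject_id = paste0("s", 1:10),
             pident = c(99, 98.5, rep(99.5, 6), 97, 96.5),
             align_length = 350L, evalue = 1e-50, bitscore = bitscores,
             input_rank = 1:10, stringsAsFactors = FALSE)
}

# Minimal hit constructor for hand-built cases.
make_hits <- function(subject_id, pident, bitscore,
                      align_length = 300L, evalue = 1e-30,
                      query_id = "q1") {
  data.frame(query_id = query_id, subject_id = subject_id,
             pident = pident, align_length = align_length,
             evalue = evalue, bitscore = bitscore,
             input_rank = seq_along(subject_id), stringsAsFactors = FALSE)
}

# Taxonomy map from explicit species names (family/genus derived).
make_taxmap <- function(seq_id, species,
                        genus = vapply(strsplit(species, " "), `[`, character(1), 1),
                        family = paste0(substr(genus, 1, 3), "aceae")) {
  data.frame(seq_id = seq_id, kingdom = "k", phylum = "p", class = "c",
             order = "o", family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

# Random hit table + taxonomy for property tests. Bit scores are drawn from
# a coarse grid so ties (including tied best hits) occur regularly.
random_hit_case <- function(n_hits = 10, tie_prone = FALSE) {
  n_species <- sample(2:5, 1)
  species <- paste0("Gen", sample(1:3, n_species, replace = TRUE),
                    " sp", seq_len(n_species))
  sid <- paste0("r", seq_len(n_hits))
  sp <- sample(species, n_hits, replace = TRUE)
  bs_pool <- if (tie_prone) seq(90, 100, by = 5) else seq(50, 150, by = 1)
  hits <- make_hits(sid,
                    pident = round(stats::runif(n_hits, 80, 100), 1),
                    bitscore = sample(bs_pool, n_hits, replace = TRUE))
  list(hits = hits, taxmap = make_taxmap(sid, sp))
}

# A tiny reference database of mutually dissimilar sequences: every species
# gets `copies` identical records built from an independent random sequence.
tiny_db <- function(n_species = 4, copies = 2, len = 120, seed = 42) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    data.frame(seq_id = sprintf("sp%d_r%d", i, seq_len(copies)),
               sequence = s, kingdom = "k", phylum = "p", class = "c",
               order = "o", family = sprintf("Fam%d", (i + 1) %/% 2),
               genus = sprintf("Gen%d", i), species = sprintf("Gen%d alpha", i),
               stringsAsFactors = FALSE)
  }))
  ref_db(recs)
}

# Assignment-shaped rows for evaluation/rules tests.
make_cv_rows <- function(true_species, pred_species,
                         identity = rep(99, length(true_species)),
                         consensus = rep(80, length(true_species)),
                         method = "TopHit") {
  n <- length(true_species)
  data.frame(query_id = paste0("q", seq_len(n)), fold = 1L, origin = "local",
             method = method,
             true_family = "F", true_genus = "G", true_species = true_species,
             family = "F", family_identity = identity, family_consensus = consensus,
             genus = "G", genus_identity = identity, genus_consensus = consensus,
             species = pred_species,
             species_identity = ifelse(is.na(pred_species), NA_real_, identity),
             species_consensus = ifelse(is.na(pred_species), NA_real_, consensus),
             correct_family = TRUE, correct_genus = TRUE,
             correct_species = !is.na(pred_species) & pred_species == true_species,
             stringsAsFactors = FALSE)
}
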