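#' Configuration for the hierarchical database simulator
#'
#' The simulator emulates the structure of a curated barcode reference
#' database: families containing genera containing species, each species
#' represented by several near-identical records. Sequences evolve down a
#' star tree at each level: a random root sequence is mutated at rate
#' `d_family` to give each family's consensus, then `d_genus` per genus,
#' `d_species` per species, and finally `d_within` per individual record.
#' Substitutions are i.i.d. per site to one of the three other bases
#' (Jukes-Cantor-like); optional indels add alignment-length variation.
#'
#' Defaults give a "well-separated" database: divergences ordered
#' `d_within < d_species < d_genus <= d_family`, several records per
#' species, half the species local. These are meant as a realistic
#' small-scale stand-in for a regional barcode database (intraspecific
#' variation well below interspecific divergence, congeners clearly closer
#' than confamilials).
#'
#' @param n_families,genera_per_family,species_per_genus Integers defining
#'   the taxonomy.
#' @param records_per_species Integer, or length-2 range sampled uniformly
#'   per species.
#' @param sequence_length Barcode length in bp (default 300, the order of a
#'   typical ITS2/rbcL amplicon).
#' @param d_family,d_genus,d_species,d_within Expected per-site substitution
#'   proportions on the root-to-record path (each in \[0, 0.75\]).
#' @param indel_rate Expected per-site indel rate at the record level
#'   (default 0: equal-length records).
#' @param fraction_local Fraction of species marked as local flora.
#' @param fraction_hybrid,fraction_imprecise Fractions of species given
#'   hybrid (`"Gen1_1 x species2"`) or imprecise (`"Gen1_1 cf. species2"`)
#'   name forms, to exercise target exclusion.
#' @param primers Optional list `list(fwd =, rev =)` of IUPAC primer
#'   strings; records are then built as
#'   `pad + fwd_site + barcode + rev_site + pad` so that primer restriction
#'   can be tested.
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 4L, genera_per_family = 3L,
                       species_per_genus = 3L, records_per_species = 3L,
                       sequence_length = 300L,
                       d_family = 0.20, d_genus = 0.10,
                       d_species = 0.05, d_within = 0.005,
                       indel_rate = 0,
                       fraction_local = 0.5,
                       fraction_hybrid = 0, fraction_imprecise = 0,
                       primers = NULL, seed = 1L) {
  dv <- c(d_family = d_family, d_genus = d_genus,
          d_species = d_species, d_within = d_within)
  if (any(dv < 0 | dv > 0.75)) stop("divergences must lie in [0, 0.75]")
  stopifnot(n_families >= 1L, genera_per_family >= 1L, species_per_genus >= 1L,
            length(records_per_species) %in% 1:2,
            all(records_per_species >= 1L),
            sequence_length >= 10L,
            fraction_local >= 0, fraction_local <= 1,
            indel_rate >= 0, indel_rate < 1)
  structure(list(n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 records_per_species = as.integer(records_per_species),
                 sequence_length = as.integer(sequence_length),
                 d_family = d_family, d_genus = d_genus,
                 d_species = d_species, d_within = d_within,
                 indel_rate = indel_rate,
                 fraction_local = fraction_local,
                 fraction_hybrid = fraction_hybrid,
                 fraction_imprecise = fraction_imprecise,
                 primers = primers, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' @noRd
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- stats::runif(length(x)) < rate
  n <- sum(hit)
  if (n == 0L) return(x)
  # substitute with one of the three other bases, uniformly
  shift <- sample.int(3L, n, replace = TRUE)
  cur <- match(x[hit], BASES)
  x[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  x
}

#' @noRd
apply_indels <- function(x, rate) {
  if (rate <= 0) return(x)
  u <- stats::runif(length(x))
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  out <- as.list(x)
  out[del] <- list(character(0))
  if (any(ins)) {
    ins_base <- sample(BASES, sum(ins), replace = TRUE)
    out[ins] <- Map(c, x[ins], ins_base)
  }
  unlist(out, use.names = FALSE)
}

#' Simulate a reference database
#'
#' Generates a [ref_db] under a [sim_config()], together with the local
#' species list and a manifest recording the configuration. Taxon names are
#' deterministic (`"Fam03"`, `"Gen03_2"`, `"Gen03_2 species5"`); record IDs
#' are `<Genus>_<speciesIndex>_r<replicate>`. Lineages are fully populated
#' (a fixed kingdom/phylum/class and one order per family).
#'
#' @param config A [sim_config()].
#' @return List with elements `db` ([ref_db]), `local_species` (character),
#'   and `manifest` (list: config echo plus record/species counts).
#' @export
simulate_database <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed)
  L <- config$sequence_length
  root <- sample(BASES, L, replace = TRUE)

  recs <- list()
  species_names <- character()
  for (fi in seq_len(config$n_families)) {
    fam_name <- sprintf("Fam%02d", fi)
    ord_name <- sprintf("Ord%02d", fi)
    fam_seq <- mutate_seq(root, config$d_family)
    for (gi in seq_len(config$genera_per_family)) {
      gen_name <- sprintf("Gen%02d_%d", fi, gi)
      gen_seq <- mutate_seq(fam_seq, config$d_genus)
      for (si in seq_len(config$species_per_genus)) {
        sp_name <- sprintf("%s species%d", gen_name, si)
        sp_seq <- mutate_seq(gen_seq, config$d_species)
        species_names <- c(species_names, sp_name)
        n_rec <- if (length(config$records_per_species) == 2L) {
          sample(config$records_per_species[1L]:config$records_per_species[2L], 1L)
        } else {
          config$records_per_species
        }
        for (ri in seq_len(n_rec)) {
          rec_seq <- mutate_seq(sp_seq, config$d_within)
          rec_seq <- apply_indels(rec_seq, config$indel_rate)
          recs[[length(recs) + 1L]] <- data.frame(
            seq_id = sprintf("%s_%d_r%d", gen_name, si, ri),
            sequence = paste(rec_seq, collapse = ""),
            kingdom = "Viridiplantae", phylum = "Streptophyta",
            class = "Magnoliopsida", order = ord_name,
            family = fam_name, genus = gen_name, species = sp_name,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, recs)

  n_sp <- length(species_names)
  # rename a slice of species to hybrid / imprecise forms
  reshuffle <- sample(n_sp)
  n_hyb <- round(config$fraction_hybrid * n_sp)
  n_imp <- round(config$fraction_imprecise * n_sp)
  rename <- function(records, old, new) {
    records$species[records$species == old] <- new
    records
  }
  renamed <- species_names
  if (n_hyb > 0L) {
    for (i in reshuffle[seq_len(n_hyb)]) {
      toks <- strsplit(species_names[i], " ")[[1L]]
      new <- paste(toks[1L], "x", toks[2L])
      records <- rename(records, species_names[i], new)
      renamed[i] <- new
    }
  }
  if (n_imp > 0L) {
    for (i in reshuffle[n_hyb + seq_len(n_imp)]) {
      toks <- strsplit(species_names[i], " ")[[1L]]
      # "cf." keeps the name unique per species while flagging imprecision
      new <- paste(toks[1L], "cf.", toks[2L])
      records <- rename(records, species_names[i], new)
      renamed[i] <- new
    }
  }

  n_local <- round(config$fraction_local * n_sp)
  local_species <- sort(renamed[sample(n_sp, n_local)])

  if (!is.null(config$primers)) {
    fwd <- toupper(config$primers$fwd)
    rev_site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(config$primers$rev))))
    pads <- replicate(nrow(records) * 2L,
                      paste(sample(BASES, 20L, replace = TRUE), collapse = ""))
    records$sequence <- paste0(pads[seq_len(nrow(records))], fwd,
                               records$sequence, rev_site,
                               pads[nrow(records) + seq_len(nrow(records))])
  }

  db <- ref_db(records, label = sprintf("sim-seed%d", config$seed))
  db <- suppressMessages(label_origin(db, local_species))
  manifest <- list(config = unclass(config),
                   n_records = nrow(records),
                   n_species = n_sp,
                   n_local_species = n_local)
  list(db = db, local_species = local_species, manifest = manifest)
}

#' Write a simulated database to disk
#'
#' Emits FASTA + taxonomy TSV + local species list + a JSON manifest, all
#' deterministic given the simulation seed.
#'
#' @param sim Output of [simulate_database()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"simdb"`).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "simdb") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(sim$db,
                  file.path(dir, paste0(prefix, ".fasta")),
                  file.path(dir, paste0(prefix, "_taxonomy.tsv")))
  write_species_list(sim$local_species,
                     file.path(dir, paste0(prefix, "_local_species.txt")))
  jsonlite::write_json(sim$manifest,
                       file.path(dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Named benchmark presets with known qualitative behaviour
#'
#' Each preset is a database engineered so that a known qualitative result
#' must hold, making whole-pipeline properties testable without external
#' data:
#'
#' * `"well-separated"` — clear divergence hierarchy, 3 records per
#'   species: k-fold species accuracy is high, and leaked CV can only be
#'   better.
#' * `"singleton-species"` — every species has exactly one record: k-fold
#'   species accuracy is 0 (the true label is never in the fold reference)
#'   while genus accuracy stays positive via congeners.
#' * `"low-interspecific-divergence"` — species nearly identical within a
#'   genus, no intraspecific variation: best-bit-score ties across species
#'   are frequent, which is where TopHitPlus improves on TopHit.
#' * `"foreign-vs-local"` — half the species foreign: searching foreign
#'   queries against the Local DB cannot recover their species (0%
#'   accuracy).
#'
#' @param presets Subset of the preset names.
#' @param seed Integer seed forwarded to the simulator.
#' @return Named list; each element has `db`, `local_species`, `manifest`
#'   and `expectation` (text).
#' @export
make_benchmark_suite <- function(presets = c("well-separated",
                                             "singleton-species",
                                             "low-interspecific-divergence",
                                             "foreign-vs-local"),
                                 seed = 1L) {
  presets <- match.arg(presets, several.ok = TRUE)
  build <- function(cfg, expectation) {
    sim <- simulate_database(cfg)
    sim$expectation <- expectation
    sim
  }
  out <- list()
  if ("well-separated" %in% presets) {
    out[["well-separated"]] <- build(
      sim_config(n_families = 4L, genera_per_family = 2L,
                 species_per_genus = 2L, records_per_species = 3L,
                 d_family = 0.20, d_genus = 0.10, d_species = 0.05,
                 d_within = 0.005, seed = seed),
      "high k-fold species accuracy; leaked CV >= k-fold CV at every rank")
  }
  if ("singleton-species" %in% presets) {
    out[["singleton-species"]] <- build(
      sim_config(n_families = 3L, genera_per_family = 2L,
                 species_per_genus = 3L, records_per_species = 1L,
                 d_family = 0.20, d_genus = 0.10, d_species = 0.05,
                 d_within = 0, seed = seed),
      "k-fold species accuracy 0 (true label absent); genus accuracy > 0")
  }
  if ("low-interspecific-divergence" %in% presets) {
    out[["low-interspecific-divergence"]] <- build(
      sim_config(n_families = 2L, genera_per_family = 2L,
                 species_per_genus = 4L, records_per_species = 2L,
                 d_family = 0.20, d_genus = 0.10, d_species = 0.002,
                 d_within = 0, seed = seed),
      "frequent best-bit-score ties across species: TopHitPlus can beat TopHit")
  }
  if ("foreign-vs-local" %in% presets) {
    out[["foreign-vs-local"]] <- build(
      sim_config(n_families = 4L, genera_per_family = 2L,
                 species_per_genus = 2L, records_per_species = 3L,
                 d_family = 0.20, d_genus = 0.10, d_species = 0.05,
                 d_within = 0.005, fraction_local = 0.5, seed = seed),
      "foreign queries against the Local DB: species accuracy exactly 0")
  }
  out
}
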