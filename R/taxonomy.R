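#' Ranked taxonomy: lineages, rank access, and name screening
#'
#' A lineage is stored as a named character vector over the seven Linnaean
#' ranks (kingdom, phylum, class, order, family, genus, species). Ranks that
#' are not known carry the literal string `"unknown"`, never `NA`, so that
#' downstream tabulations treat "no label" as its own category.
#'
#' @name taxonomy
NULL

#' The fixed rank vocabulary
#'
#' @return Character vector of the seven rank names, from kingdom to species.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Ranks at which assignments are scored
#'
#' Assignment and evaluation operate on family, genus and species; the four
#' higher ranks are carried through for completeness but not scored.
#'
#' @return Character vector `c("family", "genus", "species")`.
#' @export
eval_ranks <- function() {
  c("family", "genus", "species")
}

UNKNOWN <- "unknown"

#' Parse a semicolon-delimited lineage string
#'
#' Accepts the QIIME2-style taxonomy dialect: up to seven fields separated by
#' `";"`, optional `x__` rank prefixes (e.g. `g__Salix`), optional surrounding
#' whitespace. Short strings are right-padded with `"unknown"`; empty fields
#' become `"unknown"`.
#'
#' @param x Character vector of lineage strings.
#' @return For a single string, a named character vector of length 7 (names
#'   [tax_ranks()]); for a vector, a data.frame with one column per rank and
#'   one row per input.
#' @export
#' @examples
#' parse_lineage("Viridiplantae;Streptophyta;Magnoliopsida;Brassicales;Brassicaceae;Brassica;Brassica nigra")
#' parse_lineage("k__Viridiplantae;p__Streptophyta;c__X;o__Y;f__Salicaceae;g__Salix;s__Salix alba")
parse_lineage <- function(x) {
  stopifnot(is.character(x))
  rk <- tax_ranks()
  parse1 <- function(s) {
    fields <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (length(fields) > 7L) {
      stop("lineage string has ", length(fields), " fields (max 7): ", s)
    }
    fields <- trimws(fields)
    fields <- sub("^[a-zA-Z]__", "", fields)
    fields <- trimws(fields)
    fields[fields == ""] <- UNKNOWN
    out <- c(fields, rep(UNKNOWN, 7L - length(fields)))
    names(out) <- rk
    out
  }
  if (length(x) == 1L) {
    return(parse1(x))
  }
  mat <- t(vapply(x, parse1, character(7L)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  names(df) <- rk
  df
}

#' Serialise a lineage back to a semicolon-delimited string
#'
#' Inverse of [parse_lineage()]: `"unknown"` slots become empty fields, so a
#' parse/serialise round trip is the identity on the parsed representation.
#'
#' @param lineage Named character vector as returned by [parse_lineage()], or
#'   a data.frame of rank columns.
#' @return Character vector of lineage strings.
#' @export
lineage_string <- function(lineage) {
  rk <- tax_ranks()
  if (is.data.frame(lineage)) {
    mat <- as.matrix(lineage[, rk, drop = FALSE])
    mat[mat == UNKNOWN] <- ""
    return(apply(mat, 1L, paste, collapse = ";"))
  }
  fields <- unname(lineage[rk])
  fields[fields == UNKNOWN] <- ""
  paste(fields, collapse = ";")
}

#' Extract the taxon name at a given rank
#'
#' @param lineage Named character vector (one lineage) or data.frame of rank
#'   columns (many).
#' @param rank One of [tax_ranks()].
#' @return Taxon name(s); `"unknown"` where no label is stored.
#' @export
#' @examples
#' lin <- parse_lineage("Viridiplantae;;;;Brassicaceae;Brassica;Brassica nigra")
#' taxon_at(lin, "genus")
taxon_at <- function(lineage, rank) {
  if (!rank %in% tax_ranks()) {
    stop("unknown rank: ", rank)
  }
  if (is.data.frame(lineage)) {
    return(lineage[[rank]])
  }
  unname(lineage[[rank]])
}

#' Detect hybrid species names
#'
#' A name is treated as a hybrid when it contains the multiplication sign
#' (U+00D7), a standalone token `x` between two name tokens, or the token
#' `hybrid` (case-insensitive). Hybrid taxa are excluded
#' from cross-validation targets because their labels are not comparable to a
#' single parental lineage.
#'
#' @param species_name Character vector of species names.
#' @param patterns Optional extra regular expressions (case-insensitive); any
#'   match also flags the name. What counts as a "doubtful" name is
#'   community-dependent, so the rule is extensible.
#' @return Logical vector.
#' @export
#' @examples
#' is_hybrid(c("Salix \u00d7 sepulcralis", "Populus x canadensis", "Brassica nigra"))
is_hybrid <- function(species_name, patterns = character()) {
  stopifnot(is.character(species_name))
  vapply(species_name, function(nm) {
    if (is.na(nm)) return(FALSE)
    if (grepl("\u00d7", nm, fixed = TRUE)) return(TRUE)
    toks <- strsplit(trimws(nm), "\\s+")[[1]]
    n <- length(toks)
    if (n >= 3L && any(tolower(toks[2:(n - 1L)]) == "x")) return(TRUE)
    if (any(tolower(toks) == "hybrid")) return(TRUE)
    for (p in patterns) {
      if (grepl(p, nm, ignore.case = TRUE)) return(TRUE)
    }
    FALSE
  }, logical(1L), USE.NAMES = FALSE)
}

#' Detect imprecise species identifications
#'
#' A name is imprecise when it does not resolve to a species-level binomial:
#' the literal `"unknown"`, a bare genus (single token), or an epithet slot
#' occupied by one of `sp.`, `sp`, `spp.`, `spp`, `cf.`, `aff.`
#' (case-insensitive). Such records cannot be scored at species rank and are
#' excluded from cross-validation targets.
#'
#' @inheritParams is_hybrid
#' @param epithet_tokens Tokens that mark an unresolved epithet; override to
#'   tighten or extend the screen.
#' @return Logical vector.
#' @export
#' @examples
#' is_imprecise(c("Salix sp.", "Rosa cf. canina", "Salix alba"))
is_imprecise <- function(species_name,
                         epithet_tokens = c("sp.", "sp", "spp.", "spp", "cf.", "aff.")) {
  stopifnot(is.character(species_name))
  toks_low <- tolower(epithet_tokens)
  vapply(species_name, function(nm) {
    if (is.na(nm) || trimws(nm) == "" || trimws(nm) == UNKNOWN) return(TRUE)
    toks <- strsplit(trimws(nm), "\\s+")[[1]]
    if (length(toks) < 2L) return(TRUE)
    any(tolower(toks[-1L]) %in% toks_low)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Check genus/binomial agreement in a lineage table
#'
#' For every row where both genus and species are known, the first token of
#' the species binomial should equal the genus label. Violations are reported
#' (returned and warned about), never silently repaired: the per-rank labels
#' of the source database are authoritative.
#'
#' @param lineages Data.frame of rank columns (from [parse_lineage()]).
#' @param warn Emit a warning when violations exist (default `TRUE`).
#' @return Integer vector of offending row indices (invisibly).
#' @export
check_genus_consistency <- function(lineages, warn = TRUE) {
  g <- lineages$genus
  s <- lineages$species
  known <- g != UNKNOWN & s != UNKNOWN
  first_tok <- vapply(strsplit(s, "\\s+"), `[`, character(1L), 1L)
  bad <- which(known & first_tok != g)
  if (warn && length(bad) > 0L) {
    warning(length(bad), " lineage(s) where the species binomial does not start ",
            "with the genus label (rows ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "", ")")
  }
  invisible(bad)
}

#' Read / write a two-column taxonomy table
#'
#' Tab-separated, column 1 = sequence ID, column 2 = semicolon-delimited
#' lineage (QIIME2 feature-taxonomy dialect). A header line is detected and
#' skipped when the second field of the first row does not parse as a
#' lineage-like string containing no header keywords.
#'
#' @param path File path.
#' @return `read_taxonomy`: data.frame with columns `seq_id`, `lineage`
#'   (string) plus the seven parsed rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("cannot read taxonomy table: ", path)
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("taxonomy table must have 2 tab-separated columns")
  raw <- raw[, 1:2]
  names(raw) <- c("seq_id", "lineage")
  # tolerate a QIIME2-style header row
  if (nrow(raw) > 0L &&
      tolower(raw$seq_id[1L]) %in% c("feature id", "feature-id", "featureid",
                                     "seq_id", "id", "#otu id")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  ranks <- parse_lineage(raw$lineage)
  if (is.null(dim(ranks))) ranks <- as.data.frame(as.list(ranks), stringsAsFactors = FALSE)
  out <- cbind(raw, ranks)
  rownames(out) <- NULL
  out
}

#' @rdname read_taxonomy
#' @param tax Data.frame with `seq_id` and either a `lineage` column or the
#'   seven rank columns.
#' @export
write_taxonomy <- function(tax, path) {
  lin <- if ("lineage" %in% names(tax)) tax$lineage else lineage_string(tax)
  utils::write.table(data.frame(tax$seq_id, lin),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
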