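# Protein registry: sequence input, per-protein metadata, digestion scenarios.

#' Bundled registry of dietary and gut endogenous proteins
#'
#' Metadata for the 26 gut endogenous and 7 dietary proteins studied:
#' UniProt accession, name, origin (`dietary` / `endogenous`), secretion
#' sites within the gastrointestinal tract, applicable digestion scenarios
#' and expected mature-chain length (signal peptide excluded; initiator
#' methionine retained where the deposited chain keeps it, e.g. actin and
#' myosin).
#'
#' Most rows derive their scenarios from origin and secretion sites via
#' [scenarios_for()]; a few gut hormones secreted around the
#' gastro-duodenal junction (and mucin-5AC) carry explicit scenario
#' assignments, recorded in the `scenarios` list-column.
#'
#' @param path Optional path to a user registry TSV (columns `accession`,
#'   `name`, `origin`, `secretion_sites` (semicolon-separated), optional
#'   `scenarios` (semicolon-separated), `chain_length`) overriding the
#'   bundled one.
#' @return A tibble with one row per protein: `accession`, `name`,
#'   `origin`, `secretion_sites` (list-column), `scenarios` (list-column),
#'   `chain_length`.
#' @export
#' @examples
#' bundled_registry()
bundled_registry <- function(path = NULL) {
  path <- path %||% pkg_extdata("protein_registry.tsv")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character(),
                                                 chain_length = readr::col_integer()))
  required <- c("accession", "name", "origin", "secretion_sites", "chain_length")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Registry file lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"scenarios" %in% names(raw)) raw$scenarios <- NA_character_
  reg <- raw |>
    mutate(
      secretion_sites = map(.data$secretion_sites, split_semis),
      scenarios = map(.data$scenarios, split_semis)
    )
  bad_origin <- setdiff(unique(reg$origin), c("dietary", "endogenous"))
  if (length(bad_origin) > 0L) {
    abort(sprintf("Unknown origin value(s): %s", paste(bad_origin, collapse = ", ")))
  }
  bad_sites <- setdiff(unique(unlist(reg$secretion_sites)), SECRETION_SITES)
  if (length(bad_sites) > 0L) {
    abort(sprintf("Unknown secretion site(s): %s", paste(bad_sites, collapse = ", ")))
  }
  # Default scenario assignment where no explicit override is recorded.
  reg <- reg |>
    mutate(scenarios = pmap(
      list(.data$scenarios, .data$origin, .data$secretion_sites),
      function(sc, origin, sites) if (length(sc) > 0L) sc else scenarios_for(origin, sites)
    ))
  reg
}

#' Look up one accession in a registry
#'
#' @param accession Single accession string.
#' @param registry Registry tibble, by default [bundled_registry()].
#' @return The matching one-row tibble; unknown accessions are an error,
#'   never a silent default.
#' @export
#' @examples
#' registry_lookup("P02666")
registry_lookup <- function(accession, registry = bundled_registry()) {
  hit <- registry[registry$accession == accession, , drop = FALSE]
  if (nrow(hit) == 0L) {
    abort(sprintf("Accession '%s' not found in the registry.", accession))
  }
  hit
}

#' Digestion scenarios applicable to a protein
#'
#' Scenario assignment follows where the protein enters the gut:
#' dietary proteins and endogenous proteins secreted in the mouth or
#' stomach undergo gastric digestion (pepsin) followed by combined gastric
#' plus small-intestinal digestion (pepsin, trypsin, chymotrypsin);
#' endogenous proteins secreted into the small intestine, duodenum or from
#' the pancreas undergo small-intestinal digestion only (trypsin,
#' chymotrypsin).  Proteins secreted at both levels (e.g. serum albumin)
#' get all three scenarios.
#'
#' This is the pure default rule; the bundled registry additionally
#' carries explicit per-protein scenario assignments for a few hormones
#' whose descriptive secretion sites do not determine the scenario set.
#'
#' @param origin `"dietary"` or `"endogenous"`.
#' @param secretion_sites Character vector of sites (empty for dietary
#'   proteins); see [bundled_registry()].
#' @return Character vector of scenario labels, a subset of
#'   `c("gastric", "gastric_plus_small_intestinal", "small_intestinal_only")`.
#' @export
#' @examples
#' scenarios_for("dietary", character(0))
#' scenarios_for("endogenous", c("stomach", "small_intestine"))
scenarios_for <- function(origin, secretion_sites) {
  origin <- match.arg(origin, c("dietary", "endogenous"))
  if (origin == "dietary") {
    if (length(secretion_sites) > 0L) {
      abort("Dietary proteins must have empty secretion sites.")
    }
    return(SCENARIO_LABELS[1:2])
  }
  if (length(secretion_sites) == 0L) {
    abort("Endogenous proteins must have at least one secretion site.")
  }
  bad <- setdiff(secretion_sites, SECRETION_SITES)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown secretion site(s): %s", paste(bad, collapse = ", ")))
  }
  out <- character(0)
  if (any(secretion_sites %in% c("mouth", "stomach"))) {
    out <- c(out, SCENARIO_LABELS[1:2])
  }
  if (any(secretion_sites %in% c("small_intestine", "pancreas", "duodenum"))) {
    out <- c(out, SCENARIO_LABELS[3])
  }
  if (length(out) == 0L) {
    abort(sprintf(
      "Secretion site(s) %s map to no digestion scenario.",
      paste(secretion_sites, collapse = ", ")
    ))
  }
  out
}

#' Enzymes applied under a digestion scenario
#'
#' @param label Scenario label.
#' @param pepsin Pepsin specificity variant (`"pepsin_ph1.3"`, the fasted
#'   gastric default, or `"pepsin_ph_gt2"`).
#' @param chymotrypsin Chymotrypsin variant (`"chymotrypsin_high"`, the
#'   default, or `"chymotrypsin_low"`).
#' @return Character vector of enzyme rule-set names.
#' @export
#' @examples
#' scenario_enzymes("gastric_plus_small_intestinal")
scenario_enzymes <- function(label,
                             pepsin = "pepsin_ph1.3",
                             chymotrypsin = "chymotrypsin_high") {
  label <- match.arg(label, SCENARIO_LABELS)
  pepsin <- match.arg(pepsin, c("pepsin_ph1.3", "pepsin_ph_gt2"))
  chymotrypsin <- match.arg(chymotrypsin, c("chymotrypsin_high", "chymotrypsin_low"))
  switch(label,
    gastric = pepsin,
    gastric_plus_small_intestinal = c(pepsin, "trypsin", chymotrypsin),
    small_intestinal_only = c("trypsin", chymotrypsin)
  )
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard one-letter
#' codes; metadata (name, origin, secretion sites, scenarios) is resolved
#' from the registry when the header's accession is known, and left `NA`
#' (with empty site/scenario sets) otherwise.  Headers of the UniProt form
#' `sp|P02666|CASB_BOVIN ...` are parsed for the middle accession; plain
#' headers use their first whitespace-delimited token.
#'
#' A sequence whose length disagrees with the registry's expected mature
#' chain length triggers a warning (never silent truncation): bundled
#' lengths exclude the signal peptide, so a mismatch usually means a
#' precursor rather than mature chain was supplied.
#'
#' @param path FASTA file (multi-record; wrapped or unwrapped lines).
#' @param registry Registry tibble used to resolve metadata.
#' @param accept_ambiguous Accept B/Z/X/U residues as inert? Default `FALSE`.
#' @return A tibble of protein records in file order: `accession`, `name`,
#'   `origin`, `secretion_sites`, `scenarios`, `sequence`, `chain_length`.
#' @export
read_fasta <- function(path, registry = bundled_registry(), accept_ambiguous = FALSE) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  # Read as raw strings so that alphabet violations surface through our own
  # validation (naming record and position) rather than the parser's.
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Could not parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' contains no records.", path))
  headers <- names(set)
  ids <- map_chr(headers, function(h) {
    tok <- strsplit(str_trim(h), "\\s+")[[1L]][1L]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L && parts[1L] %in% c("sp", "tr")) parts[2L] else tok
  })
  seqs <- str_to_upper(as.character(set))
  walk(seq_along(seqs), function(i) validate_sequence(seqs[i], ids[i], accept_ambiguous))

  recs <- tibble(
    accession = ids,
    sequence = unname(seqs),
    chain_length = nchar(seqs)
  ) |>
    left_join(
      registry |>
        select("accession", "name", "origin", "secretion_sites", "scenarios",
               expected_chain_length = "chain_length"),
      by = "accession"
    ) |>
    mutate(
      secretion_sites = map(.data$secretion_sites, function(x) x %||% character(0)),
      scenarios = map(.data$scenarios, function(x) x %||% character(0))
    )
  mismatch <- recs |>
    filter(!is.na(.data$expected_chain_length),
           .data$chain_length != .data$expected_chain_length)
  if (nrow(mismatch) > 0L) {
    warn(sprintf(
      "Chain length differs from the registry's expected mature length for: %s",
      paste(sprintf("%s (%d != %d)", mismatch$accession, mismatch$chain_length,
                    mismatch$expected_chain_length), collapse = "; ")
    ))
  }
  recs |> select(-"expected_chain_length")
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `accession` and `sequence` columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
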