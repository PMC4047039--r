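# Simulated enzymatic digestion of a protein chain.

#' Cleavage sites of one enzyme on a protein chain
#'
#' Evaluates every peptide bond of the chain against a declarative rule
#' table.  Bond `i` sits between residues `i` and `i + 1` (1-based); the
#' returned indices mean "cut after position i".  A window offset that
#' falls outside the chain makes that condition evaluate false for every
#' rule kind, so truncated context can neither permit nor block a cut.
#'
#' @param sequence Residue string over the 20 standard codes.
#' @param enzyme An `enzyme_ruleset` or a built-in rule-set name
#'   (aliases `"pepsin"` and `"chymotrypsin"` resolve to the defaults).
#' @param rulesets Named list of rule sets used to resolve names.
#' @return Sorted integer vector of bond indices (possibly empty).
#' @export
#' @examples
#' cleavage_sites("AAKAA", "trypsin")
#' cleavage_sites("AAKPAA", "trypsin")  # K-P bond resists cleavage
cleavage_sites <- function(sequence, enzyme, rulesets = builtin_rulesets()) {
  enzyme <- resolve_enzyme(enzyme, rulesets)
  n <- nchar(sequence)
  if (n < 2L) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bonds <- seq_len(n - 1L)

  rule_fires <- function(rule) {
    ok <- rep(TRUE, n - 1L)
    for (off_name in names(rule$conditions)) {
      off <- as.integer(off_name)
      pos <- if (off < 0L) bonds + off + 1L else bonds + off
      inside <- pos >= 1L & pos <= n
      hit <- rep(FALSE, n - 1L)
      hit[inside] <- chars[pos[inside]] %in% rule$conditions[[off_name]]
      ok <- ok & hit
    }
    ok
  }

  kinds <- vapply(enzyme$rules, `[[`, "", "kind")
  fires <- matrix(
    vapply(enzyme$rules, rule_fires, logical(n - 1L)),
    nrow = n - 1L
  )
  permits <- fires[, kinds %in% c("permit", "exception_permit"), drop = FALSE]
  blocks <- fires[, kinds == "exception_block", drop = FALSE]
  cut <- rowSums(permits) > 0L & rowSums(blocks) == 0L
  bonds[cut]
}

#' Digest a protein chain under a digestion scenario
#'
#' The cut set is the union, over the scenario's enzymes, of
#' [cleavage_sites()] computed on the intact chain (not sequential
#' re-digestion, so the result is independent of enzyme order and
#' re-digesting a fragment produces no new cuts).  Fragments are the
#' maximal runs between consecutive cuts, N- to C-terminal; digestion is
#' exhaustive, with no missed-cleavage model.
#'
#' @param sequence Residue string.
#' @param enzymes Character vector of rule-set names, a scenario label
#'   (`"gastric"`, `"gastric_plus_small_intestinal"` or
#'   `"small_intestinal_only"`), or a list of `enzyme_ruleset`s.
#' @param rulesets Named list of rule sets used to resolve names.
#' @return A tibble of fragments: `fragment`, `start`, `end` (1-based,
#'   inclusive).  Concatenating `fragment` reproduces `sequence` exactly.
#' @export
#' @examples
#' digest("AAKAAFAA", "gastric_plus_small_intestinal")
digest <- function(sequence, enzymes, rulesets = builtin_rulesets()) {
  if (is.character(enzymes) && length(enzymes) == 1L && enzymes %in% SCENARIO_LABELS) {
    enzymes <- scenario_enzymes(enzymes)
  }
  if (!is.list(enzymes)) enzymes <- as.list(enzymes)
  cuts <- sort(unique(unlist(
    map(enzymes, function(e) cleavage_sites(sequence, e, rulesets))
  )))
  n <- nchar(sequence)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  tibble(
    fragment = substring(sequence, starts, ends),
    start = as.integer(starts),
    end = as.integer(ends)
  )
}

#' Digest a table of proteins under one scenario
#'
#' @param proteins Tibble with `accession`, `sequence` columns (e.g. from
#'   [read_fasta()] or [generate_study()]).
#' @param scenario Scenario label.
#' @param pepsin,chymotrypsin Specificity variants, see [scenario_enzymes()].
#' @param rulesets Named list of rule sets.
#' @return Tibble: `accession`, `scenario`, `fragment`, `start`, `end`.
#' @export
digest_proteins <- function(proteins, scenario,
                            pepsin = "pepsin_ph1.3",
                            chymotrypsin = "chymotrypsin_high",
                            rulesets = builtin_rulesets()) {
  enzymes <- scenario_enzymes(scenario, pepsin = pepsin, chymotrypsin = chymotrypsin)
  map_dfr(seq_len(nrow(proteins)), function(i) {
    digest(proteins$sequence[i], enzymes, rulesets) |>
      mutate(accession = proteins$accession[i], scenario = scenario, .before = 1L)
  })
}
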