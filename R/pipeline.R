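# End-to-end orchestration: FASTA + peptide db (+ registry, diet) ->
# intact and post-digestion profiles, released-peptide listings and the
# daily-quantity report, with TSV/JSON twins on disk.

#' Run the full bioactive-peptide profiling pipeline
#'
#' For every input protein: the intact occurrence profile (counts, A_O, Y
#' per activity category), and per applicable digestion scenario the
#' post-digestion profile (counts, A_D) and the released-peptide listing.
#' Inputs are validated before any computation; every stage failure aborts
#' with a stage-named message.
#'
#' @param fasta Path to a protein FASTA file, or a protein tibble as
#'   returned by [read_fasta()] / [generate_study()].
#' @param peptide_db Path to a peptide database TSV, or a `peptide_db`.
#' @param registry Registry tibble (default [bundled_registry()]).
#' @param counting Per-category digest counting mode, `"unique"` or
#'   `"occurrence"` (see [profile_digest()]).
#' @param pepsin,chymotrypsin Enzyme specificity variants.
#' @param default_scenarios Scenarios applied to proteins whose accession
#'   is not in the registry (default: the dietary pair).
#' @param out_dir Optional output directory; writes `intact_profile.tsv`,
#'   `digest_profile.tsv`, `released_peptides.tsv`, a JSON twin
#'   `report.json` and a `run_log.txt` (version, config hash, db size;
#'   timestamps are confined to the log).
#' @param quiet Suppress progress messages? Default `TRUE`.
#' @return Invisibly, a list: `proteins`, `db`, `intact` (an
#'   `intact_profile`), `digest` (per-category counts across scenarios),
#'   `released`, `totals` (per protein x scenario with `total_released`
#'   and `freq_AD`), and `config`.
#' @export
run_profile <- function(fasta, peptide_db,
                        registry = bundled_registry(),
                        counting = c("unique", "occurrence"),
                        pepsin = "pepsin_ph1.3",
                        chymotrypsin = "chymotrypsin_high",
                        default_scenarios = SCENARIO_LABELS[1:2],
                        out_dir = NULL,
                        quiet = TRUE) {
  counting <- match.arg(counting)
  # --- validation stage -----------------------------------------------
  if (is.character(fasta) && !file.exists(fasta)) {
    abort(sprintf("validation: FASTA file not found: %s", fasta))
  }
  if (is.character(peptide_db) && !file.exists(peptide_db)) {
    abort(sprintf("validation: peptide database file not found: %s", peptide_db))
  }

  proteins <- if (is.character(fasta)) {
    read_fasta(fasta, registry = registry)
  } else {
    as_tibble(fasta)
  }
  if (!all(c("accession", "sequence") %in% names(proteins))) {
    abort("validation: proteins need `accession` and `sequence` columns.")
  }
  if (!"scenarios" %in% names(proteins)) {
    proteins$scenarios <- rep(list(character(0)), nrow(proteins))
  }
  proteins$scenarios <- map(proteins$scenarios, function(sc) {
    if (length(sc) == 0L) default_scenarios else sc
  })
  db <- if (is.character(peptide_db)) load_peptide_db(peptide_db, quiet = quiet) else peptide_db
  if (!inherits(db, "peptide_db")) abort("validation: `peptide_db` is not a peptide database.")

  # --- intact scan stage ----------------------------------------------
  intact <- tryCatch(scan_intact(proteins, db),
                     error = function(e) abort(sprintf("intact-scan: %s", conditionMessage(e))))

  # --- digestion stage ------------------------------------------------
  labels <- intersect(SCENARIO_LABELS, unique(unlist(proteins$scenarios)))
  per_scenario <- map(labels, function(lab) {
    idx <- map_lgl(proteins$scenarios, function(sc) lab %in% sc)
    tryCatch(
      profile_digest(proteins[idx, , drop = FALSE], db, lab, counting = counting,
                     pepsin = pepsin, chymotrypsin = chymotrypsin),
      error = function(e) abort(sprintf("digestion (%s): %s", lab, conditionMessage(e)))
    )
  })
  digest_counts <- map_dfr(per_scenario, as_tibble)
  released <- map_dfr(per_scenario, function(x) attr(x, "released"))
  totals <- map_dfr(per_scenario, function(x) attr(x, "totals"))

  config <- list(
    counting = counting, pepsin = pepsin, chymotrypsin = chymotrypsin,
    n_proteins = nrow(proteins), db_entries = nrow(db)
  )
  bundle <- list(proteins = proteins, db = db, intact = intact,
                 digest = digest_counts, released = released, totals = totals,
                 config = config)

  # --- report stage ---------------------------------------------------
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(as_tibble(intact), file.path(out_dir, "intact_profile.tsv"), progress = FALSE)
    readr::write_tsv(digest_counts, file.path(out_dir, "digest_profile.tsv"), progress = FALSE)
    readr::write_tsv(released, file.path(out_dir, "released_peptides.tsv"), progress = FALSE)
    readr::write_tsv(totals, file.path(out_dir, "digest_totals.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(intact = as_tibble(intact), intact_totals = glance(intact),
           digest = digest_counts, released = released, totals = totals,
           config = config),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(c(
      sprintf("peptigest %s", as.character(utils::packageVersion("peptigest"))),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      sprintf("config hash: %s", rlang::hash(config)),
      sprintf("proteins: %d; peptide db entries: %d", nrow(proteins), nrow(db))
    ), file.path(out_dir, "run_log.txt"))
  }
  if (!quiet) inform(sprintf("Profiled %d proteins under %d scenario(s).",
                             nrow(proteins), length(labels)))
  invisible(bundle)
}

#' Daily-quantity report from a profile bundle
#'
#' Converts per-molecule released-peptide counts (gastric plus
#' small-intestinal digestion) into mg bioactive peptide per g protein
#' for each diet member, averages members within a food item, and totals
#' mg/day over the model diet.  Optionally adds the endogenous-protein
#' estimate.
#'
#' @param bundle A profile bundle from [run_profile()], or a totals tibble
#'   with `accession`, `scenario`, `total_released`.
#' @param diet Diet tibble (`item`, `grams`, `members` list-column of
#'   accessions), by default [default_diet()].
#' @param sequences Named character vector (or tibble with `accession`,
#'   `sequence`) supplying the member protein sequences for molar masses;
#'   defaults to the bundle's proteins.
#' @param reference_mass Assumed released-peptide mass
#'   ([reference_peptide_mass()] by default).
#' @param endogenous_grams Endogenous protein secreted per day (g); the
#'   endogenous total is reported only when `endogenous_mg_per_g` is
#'   given.
#' @param endogenous_mg_per_g Mean mg/g over the representative
#'   endogenous proteins, or `NULL` to skip the endogenous estimate.
#' @return List: `items` (a `quantity_estimate` with per-item mg/g and
#'   mg/day), `dietary_total_mg_per_day`, and
#'   `endogenous_total_mg_per_day` (`NA` unless requested).
#' @export
run_quantity <- function(bundle, diet = default_diet(), sequences = NULL,
                         reference_mass = reference_peptide_mass(),
                         endogenous_grams = 48,
                         endogenous_mg_per_g = NULL) {
  totals <- if (is.data.frame(bundle)) bundle else bundle$totals
  if (is.null(sequences) && !is.data.frame(bundle)) {
    sequences <- stats::setNames(bundle$proteins$sequence, bundle$proteins$accession)
  }
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$accession)
  }
  needed <- c("accession", "scenario", "total_released")
  if (!all(needed %in% names(totals))) {
    abort("`bundle` must provide totals with accession, scenario and total_released.")
  }
  gsi <- totals |> filter(.data$scenario == "gastric_plus_small_intestinal")

  member_mg <- function(acc) {
    row <- gsi |> filter(.data$accession == acc)
    if (nrow(row) == 0L) {
      abort(sprintf(
        "Diet member '%s' has no gastric_plus_small_intestinal digest totals in the bundle.", acc
      ))
    }
    if (is.null(sequences) || !acc %in% names(sequences)) {
      abort(sprintf("No sequence available for diet member '%s'.", acc))
    }
    mg_per_g(row$total_released[1L], protein_molar_mass(sequences[[acc]]),
             reference_mass = reference_mass, round = FALSE)
  }

  items <- diet |>
    mutate(mg_per_g = map_dbl(.data$members, function(m) {
      round_half_up(mean(vapply(m, member_mg, numeric(1L))))
    })) |>
    select("item", "grams", "mg_per_g")
  est <- daily_total(items)
  list(
    items = est,
    dietary_total_mg_per_day = attr(est, "total_mg_per_day"),
    endogenous_total_mg_per_day = if (is.null(endogenous_mg_per_g)) NA_real_ else
      endogenous_daily(endogenous_mg_per_g, endogenous_grams)
  )
}
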