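# Synthetic study generator: proteins with planted reference peptides and
# known ground truth, so every pipeline stage is testable without any
# external download.
#
# Construction guarantees:
#   * background residues come from an inert alphabet (A/G/S/T/V) that no
#     scenario enzyme cleaves and that excludes proline;
#   * a releasable plant is preceded by an inert run plus a cleavable
#     linker residue (K for tryptic scenarios, F otherwise) and ends in a
#     cleavable residue, so both boundary bonds cut and, having no internal
#     cleavage site, the peptide is released exactly;
#   * a non-releasable plant is preceded by inert residues only, so its
#     left boundary can never be cut and full-length matching fails.
# Collisions (a planted peptide recurring by chance, or a background
# fragment matching the database) are detected post hoc and trigger
# regeneration with a derived sub-seed.

SYN_BACKGROUND <- c("A", "G", "S", "T", "V")

# P1 residues that any enzyme of the scenario can cleave after.
scenario_p1_residues <- function(scenario, rulesets = builtin_rulesets()) {
  enzymes <- scenario_enzymes(scenario)
  sort(unique(unlist(map(enzymes, function(nm) {
    rs <- rulesets[[nm]]
    unlist(map(keep(rs$rules, function(r) r$kind == "permit"),
               function(r) r$conditions[["-1"]]))
  }))))
}

syn_linker <- function(scenario) {
  if ("trypsin" %in% scenario_enzymes(scenario)) "K" else "F"
}

# Alphabet safe for the *interior* of planted peptides under a scenario.
syn_internal_alphabet <- function(scenario) {
  setdiff(AA_STANDARD, c(scenario_p1_residues(scenario), "P", SYN_BACKGROUND))
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483629) + 1L
}

# Can this peptide be released exactly under the scenario?  Probed in a
# minimal inert context; a releasable flag on a peptide that fails this
# (e.g. one harbouring an internal cleavage site) is a generation error.
peptide_releasable <- function(peptide, scenario, rulesets = builtin_rulesets()) {
  probe <- paste0("GG", syn_linker(scenario), peptide, "AGG")
  frags <- digest(probe, scenario, rulesets)
  any(frags$fragment == peptide & frags$start == 4L)
}

#' Generate one synthetic protein with planted peptides
#'
#' Embeds each planted peptide into an inert background so that peptides
#' flagged releasable are released exactly (and only they are) when the
#' protein is digested under `scenario`, while every plant -- releasable
#' or not -- is found by [scan_intact()] at exactly its manifest
#' positions.
#'
#' @param planted Tibble with columns `peptide` and `releasable`
#'   (logical).
#' @param length Target chain length in residues; must leave room for the
#'   plants plus flanks.
#' @param seed Integer seed; the same seed reproduces the record
#'   byte-for-byte.
#' @param scenario Digestion scenario the releasability refers to.
#' @param db Optional `peptide_db` screened against for spurious digest
#'   matches in the background (collision triggers regeneration).
#' @param accession Identifier for the generated record.
#' @param rulesets Enzyme rule sets.
#' @param max_tries Background resampling attempts before giving up.
#' @return List with `record` (one-row protein tibble) and `manifest`
#'   (tibble `accession`, `peptide`, `start`, `end`, `releasable`).
#' @export
generate_protein <- function(planted, length = 80L, seed = 1L,
                             scenario = "small_intestinal_only",
                             db = NULL, accession = "SYN1",
                             rulesets = builtin_rulesets(),
                             max_tries = 25L) {
  scenario <- match.arg(scenario, SCENARIO_LABELS)
  planted <- as_tibble(planted)
  stopifnot(all(c("peptide", "releasable") %in% names(planted)))
  planted$peptide <- str_to_upper(planted$peptide)
  walk(planted$peptide, validate_sequence)

  # Releasability is a property of the peptide itself; fail fast.
  for (i in seq_len(nrow(planted))) {
    if (planted$releasable[i] && !peptide_releasable(planted$peptide[i], scenario, rulesets)) {
      abort(sprintf(
        "Peptide '%s' cannot be released intact under scenario '%s' (internal cleavage site or uncleavable boundary) yet is flagged releasable.",
        planted$peptide[i], scenario
      ))
    }
  }

  k <- nrow(planted)
  linker <- syn_linker(scenario)
  needed <- sum(nchar(planted$peptide)) + sum(planted$releasable) + 3L * (k + 1L)
  if (length < needed) {
    abort(sprintf("Target length %d too short; need at least %d residues.", length, needed))
  }

  for (attempt in seq_len(max_tries)) {
    set.seed(derive_seed(seed, attempt - 1L))
    bg_total <- length - sum(nchar(planted$peptide)) - sum(planted$releasable)
    # Split the background across the k+1 gaps, each at least 3 residues.
    gaps <- rep(3L, k + 1L)
    extra <- bg_total - sum(gaps)
    if (extra > 0L) {
      add <- table(factor(sample.int(k + 1L, extra, replace = TRUE), levels = seq_len(k + 1L)))
      gaps <- gaps + as.integer(add)
    }
    bg_seg <- map_chr(gaps, function(g) {
      paste0(sample(SYN_BACKGROUND, g, replace = TRUE), collapse = "")
    })

    chain <- ""
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      chain <- paste0(chain, bg_seg[i])
      if (planted$releasable[i]) chain <- paste0(chain, linker)
      start <- nchar(chain) + 1L
      chain <- paste0(chain, planted$peptide[i])
      rows[[i]] <- tibble(
        accession = accession,
        peptide = planted$peptide[i],
        start = start,
        end = nchar(chain),
        releasable = planted$releasable[i]
      )
    }
    chain <- paste0(chain, bg_seg[k + 1L])
    manifest <- bind_rows(rows)
    if (k == 0L) {
      manifest <- tibble(accession = character(0), peptide = character(0),
                         start = integer(0), end = integer(0), releasable = logical(0))
    }

    ok <- syn_check(chain, manifest, scenario, db, rulesets)
    if (ok) {
      record <- tibble(
        accession = accession,
        name = paste("Synthetic protein", accession),
        origin = "endogenous",
        secretion_sites = list("small_intestine"),
        scenarios = list(scenario),
        sequence = chain,
        chain_length = nchar(chain)
      )
      return(list(record = record, manifest = manifest))
    }
    inform(sprintf("generate_protein: collision on attempt %d for %s; resampling background.",
                   attempt, accession))
  }
  abort(sprintf("Could not embed plants without collisions after %d attempts.", max_tries))
}

# Post-hoc ground-truth verification for one assembled chain.
syn_check <- function(chain, manifest, scenario, db, rulesets) {
  # Every plant occurs exactly at its manifest positions (intact-scan truth).
  for (pep in unique(manifest$peptide)) {
    expected <- sort(manifest$start[manifest$peptide == pep])
    if (!identical(sort(find_occurrences(chain, pep)), as.integer(expected))) return(FALSE)
  }
  frags <- digest(chain, scenario, rulesets)
  rel <- manifest[manifest$releasable, , drop = FALSE]
  # Recall: every releasable plant is an exact fragment at its position.
  for (i in seq_len(nrow(rel))) {
    hit <- frags$fragment == rel$peptide[i] & frags$start == rel$start[i]
    if (!any(hit)) return(FALSE)
  }
  # Precision: no digest fragment outside the releasable manifest matches
  # the database (or the planted set when no db is supplied).
  screen <- unique(c(if (!is.null(db)) db$sequence, manifest$peptide))
  outside <- vapply(seq_len(nrow(frags)), function(i) {
    !any(rel$peptide == frags$fragment[i] & rel$start == frags$start[i])
  }, logical(1L))
  if (any(frags$fragment[outside] %in% screen)) return(FALSE)
  TRUE
}

#' Generate a complete synthetic study
#'
#' Builds a reference peptide database (peptides 2-9 residues long, the
#' observed length range of released bioactive peptides, each carrying
#' one or two activity categories), plants a fraction of them into
#' synthetic proteins with known releasability, and returns the study
#' with its ground-truth manifest.  All randomness flows from the single
#' master seed through a fixed splitting scheme, so regeneration from
#' `(seed, parameters)` is byte-identical.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param db_size Number of database peptides.
#' @param plant_rate Probability that a database peptide is planted into
#'   some protein.
#' @param seed Master integer seed.
#' @param scenario Digestion scenario used for releasability.
#' @param releasable_rate Probability that a planted peptide is embedded
#'   releasably (default 0.8; the rest are embedded unreleasably).
#' @param protein_length Target residues per protein (grown if the plants
#'   need more room).
#' @param dir Optional directory: writes `proteins.fasta`, `peptides.tsv`
#'   and `manifest.json` there.
#' @return A `synthetic_study` list: `proteins` (tibble), `db`
#'   (`peptide_db`), `manifest` (tibble), `scenario`, `seed`, `params`.
#' @export
#' @examples
#' study <- generate_study(n_proteins = 3, db_size = 10, plant_rate = 0.5, seed = 7)
#' study$manifest
generate_study <- function(n_proteins, db_size, plant_rate, seed,
                           scenario = "small_intestinal_only",
                           releasable_rate = 0.8,
                           protein_length = 120L,
                           dir = NULL) {
  if (n_proteins < 1L || db_size < 1L) abort("`n_proteins` and `db_size` must be positive.")
  if (plant_rate < 0 || plant_rate > 1) abort("`plant_rate` must be in [0, 1].")
  scenario <- match.arg(scenario, SCENARIO_LABELS)

  set.seed(derive_seed(seed, 0L))
  internal <- syn_internal_alphabet(scenario)
  terminal <- intersect(c("K", "R", "F", "L"), scenario_p1_residues(scenario))

  peptides <- character(0)
  tries <- 0L
  while (length(peptides) < db_size) {
    tries <- tries + 1L
    if (tries > db_size * 200L) abort("Could not generate a substring-free peptide database.")
    len <- sample(2:9, 1L)
    pep <- paste0(
      paste0(sample(internal, len - 1L, replace = TRUE), collapse = ""),
      sample(terminal, 1L)
    )
    # Keep the database substring-free so occurrence ground truth is exact.
    if (pep %in% peptides) next
    if (any(vapply(peptides, function(q) grepl(q, pep, fixed = TRUE) ||
                                          grepl(pep, q, fixed = TRUE), logical(1L)))) next
    peptides <- c(peptides, pep)
  }
  activities <- map(seq_len(db_size), function(i) {
    as.character(sort(sample.int(10L, sample(1:2, 1L))))
  })
  db <- new_peptide_db(tibble(
    sequence = peptides,
    activities = activities,
    source_id = "synthetic"
  ) |> arrange(.data$sequence))

  planted_mask <- stats::runif(db_size) < plant_rate
  planted_peps <- peptides[planted_mask]
  releasable <- stats::runif(length(planted_peps)) < releasable_rate
  host <- if (length(planted_peps) > 0L) {
    sample.int(n_proteins, length(planted_peps), replace = TRUE)
  } else integer(0)
  protein_seeds <- sample.int(100000000L, n_proteins)

  records <- vector("list", n_proteins)
  manifests <- vector("list", n_proteins)
  for (p in seq_len(n_proteins)) {
    sel <- which(host == p)
    plant_tbl <- tibble(peptide = planted_peps[sel], releasable = releasable[sel])
    need <- sum(nchar(plant_tbl$peptide)) + nrow(plant_tbl) + 3L * (nrow(plant_tbl) + 1L)
    gp <- generate_protein(
      plant_tbl,
      length = max(protein_length, need + 10L),
      seed = protein_seeds[p],
      scenario = scenario,
      db = db,
      accession = sprintf("SYN%03d", p)
    )
    records[[p]] <- gp$record
    manifests[[p]] <- gp$manifest
  }

  study <- structure(list(
    proteins = bind_rows(records),
    db = db,
    manifest = bind_rows(manifests),
    scenario = scenario,
    seed = seed,
    params = list(n_proteins = n_proteins, db_size = db_size,
                  plant_rate = plant_rate, releasable_rate = releasable_rate,
                  protein_length = protein_length)
  ), class = "synthetic_study")

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(study$proteins, file.path(dir, "proteins.fasta"))
    write_peptide_db(study$db, file.path(dir, "peptides.tsv"))
    jsonlite::write_json(
      list(
        seed = seed, scenario = scenario, params = study$params,
        manifest = study$manifest
      ),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  study
}

#' Recall and precision of the pipeline on a synthetic study
#'
#' Digests every study protein under the study scenario, matches the
#' fragments against the study database and compares the released set
#' with the ground-truth manifest.  By construction both recall (every
#' releasable plant recovered) and precision (no match outside the
#' manifest) are 1 for a successfully generated study.
#'
#' @param study A `synthetic_study`.
#' @return Tibble with `recall`, `precision`, `n_releasable`, `n_matched`.
#' @export
evaluate_study <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  rel <- study$manifest[study$manifest$releasable, , drop = FALSE]
  found <- 0L
  matched_total <- 0L
  spurious <- 0L
  for (p in seq_len(nrow(study$proteins))) {
    acc <- study$proteins$accession[p]
    frags <- digest(study$proteins$sequence[p], study$scenario)
    prof <- match_digest(frags, study$db)
    hits <- attr(prof, "matches")
    matched_total <- matched_total + nrow(hits)
    here <- rel[rel$accession == acc, , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      if (any(hits$fragment == here$peptide[i] & hits$start == here$start[i])) {
        found <- found + 1L
      }
    }
    in_manifest <- vapply(seq_len(nrow(hits)), function(i) {
      any(here$peptide == hits$fragment[i] & here$start == hits$start[i])
    }, logical(1L))
    spurious <- spurious + sum(!in_manifest)
  }
  tibble(
    recall = if (nrow(rel) > 0L) found / nrow(rel) else NA_real_,
    precision = if (matched_total > 0L) (matched_total - spurious) / matched_total else NA_real_,
    n_releasable = nrow(rel),
    n_matched = matched_total
  )
}
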