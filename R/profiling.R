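# Occurrence and release statistics: A_O, Y, A_D.
#
# A_O: per-residue frequency of bioactive-fragment occurrences in the
#      intact chain, 1000 * count / N, rounded to integer.
# Y:   relative frequency (%) of one activity category among all
#      bioactive-fragment occurrences, 100 * count_j / total, rounded.
# A_D: per-residue frequency of bioactive peptides released by digestion,
#      same formula as A_O with the released count.
# The x1000 / x100 scalings and half-up rounding are fixed by the printed
# count/frequency pairs they must reproduce (e.g. 1000 * 2250 / 5159 = 436).

#' Start positions of a peptide within a sequence
#'
#' Counts every start position at which `peptide` occurs as a contiguous
#' substring; overlapping occurrences at distinct starts count separately.
#'
#' @param sequence Protein sequence.
#' @param peptide Peptide sequence (matching is case-insensitive).
#' @return Integer vector of 1-based start positions.
#' @export
#' @examples
#' find_occurrences("AAAA", "AA")
find_occurrences <- function(sequence, peptide) {
  sequence <- str_to_upper(sequence)
  peptide <- str_to_upper(peptide)
  n <- nchar(sequence)
  k <- nchar(peptide)
  if (k < 1L || k > n) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(sequence, starts, starts + k - 1L) == peptide]
}

#' Per-residue bioactive-fragment frequency (A statistic)
#'
#' `round_half_up(1000 * count / chain_length)`.  Used both for the intact
#' chain (A_O, with an occurrence count) and after digestion (A_D, with a
#' released-peptide count).
#'
#' @param count Non-negative integer count (occurrences or released
#'   peptides per protein molecule).
#' @param chain_length Number of residues in the mature chain (>= 1).
#' @return Integer frequency (per 1000 residues).
#' @export
#' @examples
#' freq_A(127, 209)
freq_A <- function(count, chain_length) {
  if (any(chain_length < 1L)) abort("`chain_length` must be >= 1.")
  if (any(count < 0L)) abort("`count` must be non-negative.")
  as.integer(round_half_up(1000 * count / chain_length))
}

#' Relative frequency of one activity category (Y statistic, %)
#'
#' `round_half_up(100 * count_j / total)` where `total` is the number of
#' bioactive-fragment occurrences across all activity categories.
#'
#' @param count_j Occurrence count for the category of interest.
#' @param total Total occurrence count over all categories (>= 1).
#' @return Integer percentage.
#' @export
#' @examples
#' rel_freq_Y(1680, 2250)
rel_freq_Y <- function(count_j, total) {
  if (any(total < 1L)) {
    abort("`total` must be >= 1; Y is undefined for a protein with no bioactive fragments.")
  }
  as.integer(round_half_up(100 * count_j / total))
}

#' Scan intact proteins for bioactive peptide occurrences
#'
#' For each database peptide, every start position at which it occurs as a
#' contiguous substring of the intact chain is counted (overlaps included).
#' A peptide carrying k activities contributes its occurrences to all k
#' category counts; the per-protein total sums over all categories, so the
#' Y percentages over all categories add to ~100 up to rounding.
#'
#' @param proteins Tibble with `accession`, `sequence` (and optionally
#'   `chain_length`) columns.
#' @param db A `peptide_db`.
#' @return An `intact_profile`: a tibble with one row per protein x
#'   category present in the database (`accession`, `chain_length`,
#'   `category`, `count`, `freq_A`, `rel_Y`), with a per-protein summary
#'   (`total_count`, `overall_freq_A`) available via [glance()] or
#'   `attr(x, "totals")`.
#' @export
scan_intact <- function(proteins, db) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 1L)
  categories <- sort(unique(unlist(db$activities)))
  dbl <- db_long(db)
  per_protein <- map_dfr(seq_len(nrow(proteins)), function(i) {
    seqc <- proteins$sequence[i]
    occ <- map_int(db$sequence, function(p) length(find_occurrences(seqc, p)))
    counts <- tibble(sequence = db$sequence, occ = occ) |>
      inner_join(dbl, by = "sequence") |>
      group_by(category = .data$activity) |>
      summarise(count = sum(.data$occ), .groups = "drop")
    tibble(
      accession = proteins$accession[i],
      chain_length = nchar(seqc),
      category = categories
    ) |>
      left_join(counts, by = "category") |>
      mutate(count = ifelse(is.na(.data$count), 0L, as.integer(.data$count)))
  })
  totals <- per_protein |>
    group_by(.data$accession, .data$chain_length) |>
    summarise(total_count = sum(.data$count), .groups = "drop") |>
    mutate(overall_freq_A = ifelse(
      .data$total_count > 0L, freq_A(.data$total_count, .data$chain_length), 0L
    ))
  out <- per_protein |>
    left_join(totals |> select("accession", "total_count"), by = "accession") |>
    mutate(
      freq_A = freq_A(.data$count, .data$chain_length),
      rel_Y = ifelse(.data$total_count > 0L,
                     as.integer(round_half_up(100 * .data$count / .data$total_count)),
                     NA_integer_)
    ) |>
    select("accession", "chain_length", "category", "count", "freq_A", "rel_Y")
  structure(out,
            totals = totals,
            class = c("intact_profile", class(tibble())))
}

#' Match digest fragments against the peptide database
#'
#' Release semantics: a fragment matches a database peptide iff their
#' sequences are identical over the full fragment length -- a bioactive
#' sequence still buried inside a longer fragment does not count after
#' digestion.  Counts are reported per category in two modes: `unique`
#' (distinct matched fragment sequences) and `occurrence` (fragment
#' instances).  The total released count is the number of distinct
#' matched sequences, counted once regardless of multiplicity or
#' multi-activity.
#'
#' @param fragments Tibble of digest fragments with a `fragment` column
#'   (plus `start`/`end`/`accession`/`scenario` carried through if
#'   present), e.g. from [digest()] or [digest_proteins()].
#' @param db A `peptide_db`.
#' @return A `digest_profile`: tibble of per-category counts (`category`,
#'   `n_unique`, `n_occurrence`), with attributes `matches` (the matched
#'   fragments with their activities) and `total_released`; [glance()]
#'   returns the totals.
#' @export
#' @examples
#' frags <- tibble::tibble(fragment = c("AAK", "HL", "HL"))
#' match_digest(frags, fixture_peptide_db())
match_digest <- function(fragments, db) {
  stopifnot(is.data.frame(fragments), "fragment" %in% names(fragments))
  frag <- fragments |>
    mutate(sequence = str_to_upper(.data$fragment))
  matches <- frag |>
    inner_join(
      tibble(sequence = db$sequence, activities = db$activities),
      by = "sequence"
    ) |>
    select(-"sequence")
  matched_long <- matches |>
    select(fragment_up = "fragment", activities = "activities") |>
    mutate(fragment_up = str_to_upper(.data$fragment_up)) |>
    tidyr::unnest("activities") |>
    rename(category = "activities")
  counts <- if (nrow(matched_long) == 0L) {
    tibble(category = character(0), n_unique = integer(0), n_occurrence = integer(0))
  } else {
    matched_long |>
      group_by(.data$category) |>
      summarise(
        n_unique = n_distinct(.data$fragment_up),
        n_occurrence = n(),
        .groups = "drop"
      ) |>
      arrange(.data$category)
  }
  total_released <- n_distinct(str_to_upper(matches$fragment))
  structure(counts,
            matches = matches,
            total_released = total_released,
            class = c("digest_profile", class(tibble())))
}

#' Released peptides of a digest, with their activities
#'
#' @param profile A `digest_profile` from [match_digest()].
#' @return Tibble of distinct released peptides: `peptide`, `activities`
#'   (semicolon-collapsed codes), `n_copies` (fragment instances).
#' @export
released_peptides <- function(profile) {
  matches <- attr(profile, "matches")
  if (is.null(matches) || nrow(matches) == 0L) {
    return(tibble(peptide = character(0), activities = character(0),
                  n_copies = integer(0)))
  }
  matches |>
    mutate(peptide = str_to_upper(.data$fragment)) |>
    group_by(.data$peptide) |>
    summarise(
      activities = paste(sort(unique(unlist(.data$activities))), collapse = ";"),
      n_copies = n(),
      .groups = "drop"
    )
}

#' Full digestion profile of proteins under one scenario
#'
#' Digests each protein, matches fragments for full-length equality
#' against the database and reports per-category counts plus the
#' per-protein released total and its A_D frequency.
#'
#' @inheritParams digest_proteins
#' @param db A `peptide_db`.
#' @param counting Per-category counting mode reported in the `count`
#'   column: `"unique"` (default; distinct released sequences per
#'   category) or `"occurrence"` (fragment instances).
#' @return Tibble: `accession`, `scenario`, `category`, `count`, with
#'   attributes `released` (per-protein released-peptide listing) and
#'   `totals` (`accession`, `scenario`, `chain_length`, `total_released`,
#'   `freq_AD`); [glance()] returns the totals.
#' @export
profile_digest <- function(proteins, db, scenario,
                           counting = c("unique", "occurrence"),
                           pepsin = "pepsin_ph1.3",
                           chymotrypsin = "chymotrypsin_high",
                           rulesets = builtin_rulesets()) {
  counting <- match.arg(counting)
  rows <- map(seq_len(nrow(proteins)), function(i) {
    frags <- digest(proteins$sequence[i],
                    scenario_enzymes(scenario, pepsin = pepsin, chymotrypsin = chymotrypsin),
                    rulesets)
    prof <- match_digest(frags, db)
    rel <- released_peptides(prof)
    counts <- as_tibble(prof) |>
      mutate(count = if (counting == "unique") .data$n_unique else .data$n_occurrence) |>
      select("category", "count")
    n_chain <- nchar(proteins$sequence[i])
    list(
      counts = counts |>
        mutate(accession = proteins$accession[i], scenario = scenario, .before = 1L),
      released = rel |>
        mutate(accession = proteins$accession[i], scenario = scenario, .before = 1L),
      totals = tibble(
        accession = proteins$accession[i],
        scenario = scenario,
        chain_length = n_chain,
        total_released = attr(prof, "total_released"),
        freq_AD = freq_A(attr(prof, "total_released"), n_chain)
      )
    )
  })
  out <- map_dfr(rows, `[[`, "counts")
  structure(out,
            released = map_dfr(rows, `[[`, "released"),
            totals = map_dfr(rows, `[[`, "totals"),
            counting = counting,
            class = c("scenario_profile", class(tibble())))
}
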