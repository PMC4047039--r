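# Reference database of known bioactive peptides and activity categories.
#
# A peptide database is a tibble of class "peptide_db" with one row per
# distinct sequence: `sequence`, `activities` (list-column of category
# codes) and `source_id`.  Category codes are the characters "1".."10"
# for the ten tabulated categories; any other label is carried through
# verbatim as an OTHER category (the source database distinguishes ~48
# activities, only ten of which are profiled here).

#' The ten tabulated bioactivity categories
#'
#' @return Tibble with `code` ("1".."10") and `description`.
#' @export
#' @examples
#' activity_categories()
activity_categories <- function() {
  tibble(
    code = as.character(1:10),
    description = c(
      "antiamnestic",
      "ACE-inhibitor",
      "antithrombotic",
      "stimulating (glucose uptake, vasoactive substance release)",
      "regulating (ion flow, stomach mucosal membrane activity, phosphoinositol mechanism)",
      "antioxidative",
      "bacterial permease ligand",
      "inhibitor (DPP-IV, dipeptidyl-aminopeptidase IV, dipeptidyl carboxypeptidase, CaMPDE, neuropeptide)",
      "hypotensive",
      "activating ubiquitin mediated proteolysis"
    )
  )
}

# Bundled free-text label -> category code map; lookup is case-insensitive,
# unmatched labels pass through case-preserved as OTHER categories.
activity_label_map <- function() {
  readr::read_tsv(pkg_extdata("activity_labels.tsv"), show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

map_activity_labels <- function(labels, label_map = activity_label_map()) {
  idx <- match(tolower(labels), tolower(label_map$label))
  codes <- ifelse(is.na(idx), labels, label_map$code[idx])
  # A label already given as a bare code stays that code.
  unique(codes)
}

new_peptide_db <- function(entries) {
  class(entries) <- c("peptide_db", class(tibble()))
  entries
}

#' Load a bioactive-peptide reference table
#'
#' Reads a TSV with columns `sequence`, `activities` (semicolon-separated
#' activity labels) and optional `source_id`.  Sequences are uppercased
#' (matching is case-insensitive); duplicate sequences are merged with the
#' union of their activities; labels are mapped to category codes 1-10
#' where recognised and kept verbatim as OTHER categories otherwise.
#'
#' @param path TSV file path.
#' @param quiet Suppress the load log message? Default `FALSE`.
#' @return A `peptide_db` tibble: `sequence`, `activities` (list-column of
#'   codes), `source_id`.
#' @export
load_peptide_db <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("Peptide database file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sequence", "activities") %in% names(raw))) {
    abort(sprintf(
      "Peptide database '%s' must have columns 'sequence' and 'activities' (found: %s).",
      path, paste(names(raw), collapse = ", ")
    ))
  }
  if (!"source_id" %in% names(raw)) raw$source_id <- NA_character_
  raw$sequence <- str_to_upper(str_trim(raw$sequence))
  walk(seq_len(nrow(raw)), function(i) {
    validate_sequence(raw$sequence[i], id = sprintf("row %d", i))
    if (nchar(raw$sequence[i]) < 2L) {
      abort(sprintf(
        "Row %d: peptide '%s' is shorter than 2 residues.", i, raw$sequence[i]
      ))
    }
  })
  label_map <- activity_label_map()
  db <- raw |>
    mutate(activities = map(.data$activities, function(x) {
      labels <- split_semis(x)
      if (length(labels) == 0L) {
        abort("Every peptide needs at least one activity label.")
      }
      map_activity_labels(labels, label_map)
    })) |>
    group_by(.data$sequence) |>
    summarise(
      activities = list(unique(unlist(.data$activities))),
      source_id = paste(unique(stats::na.omit(.data$source_id)), collapse = ";"),
      .groups = "drop"
    ) |>
    mutate(source_id = ifelse(nzchar(.data$source_id), .data$source_id, NA_character_))
  db <- new_peptide_db(db)
  if (!quiet) {
    inform(sprintf(
      "Loaded peptide database: %d entries, %d activity categories.",
      nrow(db), length(unique(unlist(db$activities)))
    ))
  }
  db
}

#' Write a peptide database to TSV
#'
#' Round-trips through [load_peptide_db()] to an equal database (category
#' codes are written as-is and survive the label mapping unchanged).
#'
#' @param db A `peptide_db`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_peptide_db <- function(db, path) {
  out <- tibble(
    sequence = db$sequence,
    activities = map_chr(db$activities, paste0, collapse = ";"),
    source_id = db$source_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Bundled fixture database of released bioactive peptides
#'
#' A small curated reference set: the peptides reported released from
#' serum albumin, somatostatin, beta-casein and ovalbumin across the three
#' digestion scenarios (ACE-inhibitory, stimulating, antioxidative,
#' inhibitor and hypotensive categories), plus the antihypertensive
#' lactotripeptides VPP and IPP.  It is explicitly not a full reference
#' snapshot: reproducing complete per-protein profile counts requires the
#' user to supply a full database export via [load_peptide_db()].
#'
#' @return A `peptide_db` tibble.
#' @export
#' @examples
#' db <- fixture_peptide_db()
#' db[db$sequence == "HL", ]
fixture_peptide_db <- function() {
  load_peptide_db(pkg_extdata("bioactive_peptides_fixture.tsv"), quiet = TRUE)
}

#' Query database entries carrying a given activity
#'
#' @param db A `peptide_db`.
#' @param code Category code ("1".."10" or an OTHER label).
#' @return The matching rows of `db`.
#' @export
peptides_with_activity <- function(db, code) {
  db[map_lgl_activities(db$activities, code), , drop = FALSE]
}

map_lgl_activities <- function(activities, code) {
  vapply(activities, function(a) code %in% a, logical(1L))
}

# Long (sequence, activity) view used by the profiling joins.
db_long <- function(db) {
  tibble(sequence = db$sequence, activity = db$activities) |>
    tidyr::unnest("activity")
}
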