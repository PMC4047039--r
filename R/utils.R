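# Shared constants and small numeric helpers.

# The 20 standard one-letter amino acid codes; ambiguity codes are opt-in
# (accepted as never-cleavable, never-matching residues).
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_AMBIGUOUS <- c("B", "Z", "X", "U")

SECRETION_SITES <- c(
  "mouth", "stomach", "small_intestine", "pancreas",
  "duodenum", "colon", "plasma"
)

SCENARIO_LABELS <- c("gastric", "gastric_plus_small_intestinal", "small_intestinal_only")

#' Round half away from zero
#'
#' Rounding used for all reported frequencies and quantities.  For the
#' non-negative counts and frequencies handled here this is plain half-up
#' rounding, i.e. 0.5 rounds to 1 (unlike [base::round()]'s banker's rounding).
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Numeric vector of rounded values.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Validate a protein or peptide sequence
#'
#' Checks that a sequence uses only the 20 standard uppercase one-letter
#' codes (optionally also the ambiguity codes B, Z, X, U).  On failure the
#' error names the offending record and position.
#'
#' @param sequence A single character string.
#' @param id Record identifier used in error messages.
#' @param accept_ambiguous Accept B/Z/X/U as inert residues? Default `FALSE`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_sequence <- function(sequence, id = "<sequence>", accept_ambiguous = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single character string.")
  }
  if (!nzchar(sequence)) {
    abort(sprintf("Record '%s' has an empty sequence.", id))
  }
  allowed <- AA_STANDARD
  if (accept_ambiguous) allowed <- c(allowed, AA_AMBIGUOUS)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Record '%s': invalid residue '%s' at position %d.",
      id, chars[bad[1L]], bad[1L]
    ))
  }
  invisible(TRUE)
}

# Split a semicolon-separated field into a trimmed character vector.
split_semis <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- str_trim(strsplit(x, ";", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

# system.file wrapper that fails loudly if a bundled data file is missing.
pkg_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "peptigest")
  if (!nzchar(path)) {
    abort(sprintf("Bundled data file not found: %s", file.path(...)))
  }
  path
}
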