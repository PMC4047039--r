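# Independent brute-force oracles used by the property tests.  These are
# deliberately written as naive position-by-position loops, sharing no
# code with the vectorised implementations they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Naive substring occurrence counter.
oracle_count <- function(sequence, peptide) {
  n <- nchar(sequence)
  k <- nchar(peptide)
  if (k > n) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (substr(sequence, i, i + k - 1L) == peptide) hits <- hits + 1L
  }
  hits
}

# Naive per-bond rule evaluator operating on one bond at a time.
oracle_bond_cleaves <- function(chars, i, ruleset) {
  eval_rule <- function(rule) {
    for (off_name in names(rule$conditions)) {
      off <- as.integer(off_name)
      pos <- if (off < 0) i + off + 1L else i + off
      if (pos < 1L || pos > length(chars)) return(FALSE)
      if (!(chars[pos] %in% rule$conditions[[off_name]])) return(FALSE)
    }
    TRUE
  }
  permitted <- FALSE
  blocked <- FALSE
  for (rule in ruleset$rules) {
    if (rule$kind %in% c("permit", "exception_permit") && eval_rule(rule)) permitted <- TRUE
    if (rule$kind == "exception_block" && eval_rule(rule)) blocked <- TRUE
  }
  permitted && !blocked
}

oracle_cleavage_sites <- function(sequence, ruleset) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  which(vapply(seq_len(n - 1L), function(i) oracle_bond_cleaves(chars, i, ruleset),
               logical(1)))
}

# Internal cut positions implied by a fragment tiling.
frags_cuts <- function(frags) frags$end[-nrow(frags)]

random_sequence <- function(n, alphabet = AA20) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
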