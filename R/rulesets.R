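# Declarative cleavage-specificity rule tables.
#
# A rule set is a list with a name and an ordered list of rules.  Each rule
# has kind "permit", "exception_permit" or "exception_block" and a set of
# conditions mapping window offsets (-4..+4 relative to the candidate bond;
# -1 = P1, +1 = P1', -2 = P2, ...) to allowed residue sets.  A bond cleaves
# iff (any permit fires OR any exception_permit fires) AND no
# exception_block fires; a rule fires when ALL its conditions hold.

RULE_KINDS <- c("permit", "exception_permit", "exception_block")

new_ruleset <- function(name, rules) {
  structure(list(name = name, rules = rules), class = "enzyme_ruleset")
}

#' @export
print.enzyme_ruleset <- function(x, ...) {
  kinds <- vapply(x$rules, `[[`, "", "kind")
  cat(sprintf(
    "<enzyme_ruleset> %s: %d permit, %d exception_permit, %d exception_block\n",
    x$name, sum(kinds == "permit"), sum(kinds == "exception_permit"),
    sum(kinds == "exception_block")
  ))
  invisible(x)
}

validate_ruleset <- function(rs, source = "<ruleset>") {
  if (!is.list(rs$rules) || length(rs$rules) == 0L) {
    abort(sprintf("%s: rule set must contain at least one rule.", source))
  }
  for (i in seq_along(rs$rules)) {
    rule <- rs$rules[[i]]
    if (is.null(rule$kind) || !rule$kind %in% RULE_KINDS) {
      abort(sprintf("%s: rule %d has invalid kind '%s'.", source, i, rule$kind %||% "<missing>"))
    }
    conds <- rule$conditions
    if (is.null(conds) || length(conds) == 0L) {
      abort(sprintf("%s: rule %d has no conditions.", source, i))
    }
    offsets <- suppressWarnings(as.integer(names(conds)))
    if (anyNA(offsets) || any(offsets == 0L) || any(abs(offsets) > 4L)) {
      abort(sprintf(
        "%s: rule %d has an invalid window offset (allowed: -4..-1, +1..+4).",
        source, i
      ))
    }
    for (j in seq_along(conds)) {
      residues <- conds[[j]]
      if (length(residues) == 0L || any(!residues %in% AA_STANDARD)) {
        abort(sprintf(
          "%s: rule %d, offset %s: residue set must be a non-empty subset of the 20 standard codes.",
          source, i, names(conds)[j]
        ))
      }
    }
  }
  if (!any(vapply(rs$rules, `[[`, "", "kind") == "permit")) {
    abort(sprintf("%s: rule set needs at least one permit rule.", source))
  }
  invisible(rs)
}

#' Read an enzyme rule set from a YAML file
#'
#' The file carries a `name` and a list of `rules`, each with a `kind`
#' (`permit`, `exception_permit`, `exception_block`) and `conditions`
#' mapping quoted window offsets (`"-1"` = P1, `"+1"` = P1', ...) to
#' strings of allowed residues.
#'
#' @param path YAML file path.
#' @return An `enzyme_ruleset` object.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) abort(sprintf("Rule file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name) || is.null(raw$rules)) {
    abort(sprintf("Rule file '%s' must have 'name' and 'rules' fields.", path))
  }
  rules <- map(raw$rules, function(rule) {
    conds <- map(rule$conditions, function(set) {
      strsplit(as.character(set), "", fixed = TRUE)[[1L]]
    })
    list(kind = rule$kind %||% NA_character_, conditions = conds)
  })
  rs <- new_ruleset(raw$name, rules)
  validate_ruleset(rs, source = basename(path))
  rs
}

#' Write an enzyme rule set to YAML
#'
#' Inverse of [read_ruleset()]; a written file reloads to a rule set with
#' identical cleavage behaviour.
#'
#' @param ruleset An `enzyme_ruleset`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_ruleset <- function(ruleset, path) {
  out <- list(
    name = ruleset$name,
    rules = map(ruleset$rules, function(rule) {
      list(
        kind = rule$kind,
        conditions = map(rule$conditions, paste0, collapse = "")
      )
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Built-in protease specificity tables
#'
#' Loads the five bundled Keil-style rule tables: `trypsin`,
#' `chymotrypsin_high` (the default chymotrypsin), `chymotrypsin_low`,
#' `pepsin_ph1.3` (the default pepsin, fasted gastric pH) and
#' `pepsin_ph_gt2`.  Tables live as YAML data files under
#' `inst/extdata/enzymes/` and can be overridden via [read_ruleset()].
#'
#' @return Named list of `enzyme_ruleset` objects.
#' @export
#' @examples
#' names(builtin_rulesets())
builtin_rulesets <- function() {
  dir <- pkg_extdata("enzymes")
  files <- sort(list.files(dir, pattern = "\\.yml$", full.names = TRUE))
  sets <- map(files, read_ruleset)
  stats::setNames(sets, map_chr(sets, `[[`, "name"))
}

# Resolve an enzyme given as a name (with "pepsin"/"chymotrypsin" aliases),
# a ruleset object, or a list element.
resolve_enzyme <- function(enzyme, rulesets = builtin_rulesets()) {
  if (inherits(enzyme, "enzyme_ruleset")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1L) {
    key <- switch(enzyme,
      pepsin = "pepsin_ph1.3",
      chymotrypsin = "chymotrypsin_high",
      enzyme
    )
    if (!key %in% names(rulesets)) {
      abort(sprintf("Unknown enzyme rule set '%s'.", enzyme))
    }
    return(rulesets[[key]])
  }
  abort("`enzyme` must be an enzyme_ruleset or a rule-set name.")
}
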