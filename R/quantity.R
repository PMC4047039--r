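# Daily-quantity model: per-molecule released counts -> mg bioactive
# peptide per g protein and per day under a model diet.

AA_WATER_MASS <- 18.02

#' Average residue masses of the 20 standard amino acids
#'
#' Average (not monoisotopic) residue masses in Da, i.e. the free amino
#' acid minus one water.  Add one water (18.02 Da) for a whole chain.
#'
#' @return Named numeric vector (one-letter codes).
#' @export
amino_acid_masses <- function() {
  c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
}

#' Molar mass of a protein or peptide chain
#'
#' Sum of average residue masses plus one water.
#'
#' @param sequence Residue string over the 20 standard codes.
#' @param masses Residue mass table, by default [amino_acid_masses()].
#' @return Mass in Da.
#' @export
#' @examples
#' protein_molar_mass("GG")
protein_molar_mass <- function(sequence, masses = amino_acid_masses()) {
  validate_sequence(sequence, id = "<molar mass input>")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(masses[chars]) + AA_WATER_MASS
}

#' Reference mass of an average released peptide
#'
#' The quantity model assumes the typical released bioactive peptide is a
#' short oligomer of compositionally average residues (a dipeptide by
#' default, since most released bioactives are dipeptides):
#' `length * mean(residue masses) + water`, ~255.8 Da for the dipeptide.
#'
#' @param length Reference peptide length in residues (default 2).
#' @param masses Residue mass table.
#' @return Mass in Da.
#' @export
#' @examples
#' reference_peptide_mass()
reference_peptide_mass <- function(length = 2L, masses = amino_acid_masses()) {
  if (length < 1L) abort("Reference peptide length must be >= 1.")
  length * mean(masses) + AA_WATER_MASS
}

#' Milligrams of bioactive peptide released per gram of protein
#'
#' One mole of protein releases `n_released` moles of (reference-mass)
#' bioactive peptide, so per gram of protein:
#' `n_released * reference_mass / molar_mass * 1000` mg/g, rounded to
#' integer for reporting.
#'
#' @param n_released Bioactive peptides released per protein molecule
#'   (total released count after gastric plus small-intestinal digestion).
#' @param molar_mass Protein molar mass in Da (> 0).
#' @param reference_mass Assumed mass of one released peptide, by default
#'   the average dipeptide of [reference_peptide_mass()].
#' @param round Round to integer (reporting convention)? Default `TRUE`.
#' @return mg bioactive peptide per g protein.
#' @export
#' @examples
#' mg_per_g(8, 23583)
mg_per_g <- function(n_released, molar_mass,
                     reference_mass = reference_peptide_mass(),
                     round = TRUE) {
  if (any(molar_mass <= 0)) abort("`molar_mass` must be positive.")
  if (any(n_released < 0)) abort("`n_released` must be non-negative.")
  out <- n_released * reference_mass / molar_mass * 1000
  if (round) round_half_up(out) else out
}

#' Model diet composition
#'
#' The theoretical ~40 g protein/day adult diet used by the quantity
#' model: dairy, wheat, soya, chicken egg and chicken meat products
#' contribute 4, 14, 3, 6 and 13 g protein/day respectively, each food
#' represented by its evaluated member protein(s).  Multi-protein items
#' (wheat = gliadin + glutenin; chicken meat = actin + myosin) use the
#' unweighted mean of the member proteins' mg/g.
#'
#' @return Tibble: `item`, `grams` (protein per day), `members`
#'   (list-column of accessions).
#' @export
default_diet <- function() {
  tibble(
    item = c("Dairy", "Wheat products", "Soya products",
             "Chicken egg products", "Chicken meat"),
    grams = c(4, 14, 3, 6, 13),
    members = list("P02666", c("P02863", "P10385"), "P04347",
                   "P01012", c("P60706", "P13538"))
  )
}

#' Daily bioactive peptide quantity from per-item mg/g values
#'
#' Per item, mg/day = grams of protein/day x mg bioactive peptide per g
#' protein; the estimate totals the items.  Linear in grams and
#' permutation-invariant over items.
#'
#' @param items Tibble with columns `item` (or `name`), `grams` and
#'   `mg_per_g`.
#' @return A `quantity_estimate` tibble (`item`, `grams`, `mg_per_g`,
#'   `mg_per_day`) whose `total_mg_per_day` attribute (also via
#'   [glance()]) holds the summed daily quantity.
#' @export
#' @examples
#' daily_total(tibble::tibble(
#'   item = c("Dairy", "Wheat products", "Soya products",
#'            "Chicken egg products", "Chicken meat"),
#'   grams = c(4, 14, 3, 6, 13),
#'   mg_per_g = c(87, 14, 69, 54, 59)
#' ))
daily_total <- function(items) {
  if (!is.data.frame(items)) abort("`items` must be a data frame.")
  if ("name" %in% names(items) && !"item" %in% names(items)) {
    items <- items |> rename(item = "name")
  }
  needed <- c("item", "grams", "mg_per_g")
  missing <- setdiff(needed, names(items))
  if (length(missing) > 0L) {
    abort(sprintf("`items` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(items) > 0L && any(items$grams < 0)) abort("`grams` must be non-negative.")
  out <- items |>
    select("item", "grams", "mg_per_g") |>
    mutate(mg_per_day = .data$grams * .data$mg_per_g)
  structure(out,
            total_mg_per_day = sum(out$mg_per_day),
            class = c("quantity_estimate", class(tibble())))
}

#' Daily quantity from gut endogenous protein
#'
#' Endogenous secretion is modelled as a single pool: grams of endogenous
#' protein entering the gut per day times the mean mg/g over the
#' representative endogenous proteins.  The default daily supply of 48 g
#' reflects reported gut endogenous protein-nitrogen flows (excluding
#' microbial protein and sloughed epithelial cells).
#'
#' @param mg_per_g_mean Mean mg bioactive peptide per g endogenous protein.
#' @param grams Endogenous protein secreted per day (g).
#' @return mg bioactive peptide per day.
#' @export
endogenous_daily <- function(mg_per_g_mean, grams = 48) {
  if (grams < 0) abort("`grams` must be non-negative.")
  grams * mg_per_g_mean
}
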