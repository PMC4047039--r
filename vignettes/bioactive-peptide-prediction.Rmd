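---
title: "Predicting bioactive peptide release from gastrointestinal digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bioactive peptide release from gastrointestinal digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptigest)
library(dplyr)
```

## The scientific question

Dietary proteins are a known source of latent bioactive peptides: short
sequences (dipeptides up to ~40-mers) that act as ACE inhibitors,
antioxidants, DPP-IV inhibitors and so on once proteolysis frees them
from the parent chain.  Gut *endogenous* proteins — mucins, serum
albumin, digestive enzymes, gut hormones — are secreted into the same
lumen in quantities that match or exceed dietary protein, and most of
them are digested and reabsorbed.  peptigest implements an in silico
pipeline for asking whether these proteins, too, are a source of
bioactive peptides: simulate gastric and small-intestinal proteolysis
from primary sequence and protease specificity alone, match the
resulting fragments against a reference database of known bioactive
peptides, and summarise the result with the standard frequency
statistics of the bioinformatic bioactive-peptide literature.

The pipeline makes no claim about efficacy, absorption or kinetics; it
predicts which known bioactive sequences are present and which could be
liberated by the major gastrointestinal proteases.

## The model

**Digestion scenarios.**  Where a protein enters the gut decides which
proteases see it:

* `gastric` — pepsin only (proteins entering via mouth or stomach,
  sampled before intestinal digestion, and all dietary proteins);
* `gastric_plus_small_intestinal` — pepsin, then trypsin and
  chymotrypsin (the full upper-tract transit);
* `small_intestinal_only` — trypsin and chymotrypsin (proteins secreted
  into the duodenum, from the pancreas, or into the small intestine,
  which never meet pepsin).

The bundled registry records origin, secretion sites and expected mature
chain length for the 26 endogenous and 7 dietary proteins studied.
Scenario assignment is a pure function of origin and secretion site
(`scenarios_for()`), except for three proteins (mucin-5AC, promotilin,
secretin) whose descriptive secretion sites straddle the
gastro-duodenal boundary; these carry explicit scenario assignments in
the registry matching the scenario sets they were actually profiled
under.

**Cleavage rules.**  Protease specificity is declarative: each enzyme is
an ordered table of rules over a local sequence window (offsets −4..+4
around the candidate bond; −1 is P1, +1 is P1′).  A rule is a `permit`,
an `exception_permit`, or an `exception_block`; a bond is cut iff some
permit or exception permit fires and no block fires, and a condition
whose window offset falls outside the chain is false for every rule
kind, so truncated termini can neither permit nor block a cut.  The
bundled tables are:

* **trypsin** — cuts after K/R unless P1′ = P, with the classical
  restoring pairs (W at P2 for K–P; M at P2 for R–P) and the
  non-cleaving triples (CKD, DKD, CKH, CKY, CRK, RRH, RRR);
* **chymotrypsin** — high-specificity variant (default): aromatic P1
  (F/Y/W), P1′ ≠ P, with W–M and W–P resistant; a low-specificity
  variant adds L/M/H at P1 with its own resistant pairs;
* **pepsin** — pH 1.3 variant (default, fasted gastric pH): F/L at P1,
  disfavoured by proline at P1′ or P2; a pH > 2 variant broadens P1 to
  F/L/W/Y.

The pepsin and chymotrypsin tables are deliberately compact stand-ins
for the full Keil statistical matrices, which the primary literature
cites but does not print.  They live as YAML data files, so a fuller
transcription can be dropped in without code changes.  One known
consequence of the compact tables: no bundled enzyme can cut an X–P
bond (only trypsin's exception permits can, in W/M contexts), so
proline-flanked reference peptides such as PLP can never be released
under the defaults even though tools built on the full matrices report
them.  Sensitivity to the variant choice is one flag away
(`pepsin = "pepsin_ph_gt2"`, `chymotrypsin = "chymotrypsin_low"`).

**Multi-enzyme digestion** takes the union of per-enzyme cut sets
computed on the intact chain, not sequential re-digestion.  This makes
digestion order-independent, exhaustive (no missed-cleavage model) and
monotone: every gastric cut is also a cut of the gastric + small
intestinal scenario.  Fragments tile the chain exactly.

**Matching and statistics.**  Against a reference database two
different match semantics apply, and the distinction matters:

* *intact scan* — a database peptide counts at every start position
  where it occurs as a substring of the intact chain (overlaps
  included); a peptide with k activities contributes its occurrences to
  all k category counts, and the per-protein total sums over all
  categories;
* *digest matching* — a fragment matches only by full-length equality
  (release semantics); a bioactive sequence still buried inside a
  longer fragment is not released.

The reported statistics are integer-rounded (half away from zero):

* `A_O = 1000 * a_O / N` — occurrences per 1000 residues of intact
  chain (per category, and overall);
* `Y_j = 100 * a_Oj / a_O` — percentage share of category j among all
  occurrences;
* `A_D = 1000 * a_D / N` — distinct released bioactive peptides per
  1000 residues after digestion.

The ×1000 and ×100 scalings are fixed by the published count/frequency
pairs these formulas must reproduce (e.g. 1000 × 2250 / 5159 = 436 for
mucin-2's overall A_O, 100 × 1680 / 2250 = 75 for its ACE share).  For
per-category digest counts both a `unique` (distinct released
sequences; the default) and an `occurrence` (fragment instances) mode
are exposed, because multi-copy release makes the published totals
ambiguous between the two; the released *total* always counts distinct
sequences once.

**Quantity model.**  Per-molecule released counts convert to mass per
gram of protein by a mole ratio: one mole of protein yields
`n_released` moles of released peptide, each assumed to weigh as much
as an average-composition dipeptide (2 × mean residue mass + water ≈
255.8 Da — most released bioactives are dipeptides), giving
`mg/g = n * 255.8 / M * 1000`.  With mature bovine β-casein
(M ≈ 23,583 Da) and 8 released peptides per molecule this reproduces
the published 87 mg/g, which is the one independently checkable row.
Daily quantities multiply mg/g by the grams of protein each food item
contributes under a model ~40 g-protein/day diet (dairy 4 g, wheat
14 g, soya 3 g, egg 6 g, chicken meat 13 g); multi-protein items use
the unweighted mean of their members' mg/g.  The endogenous pool is
modelled as a single flux, defaulting to 48 g protein/day (the value
implied by the published mean 56 mg/g and its daily total), excluding
microbial protein and sloughed epithelial cells.

## A small worked run

```{r example}
bc <- read_fasta(system.file("extdata", "P02666_beta_casein_mature.fasta",
                             package = "peptigest"))
bundle <- run_profile(bc, fixture_peptide_db())
filter(bundle$released, scenario == "gastric_plus_small_intestinal")
bundle$totals
```

The fixture database bundled with the package is the small published
released-peptide reference set (44 peptides), not a full reference
snapshot; absolute per-protein counts against it are therefore much
smaller than counts against a complete database, and the package makes
no claim to reproduce full-database profile counts unless the user
supplies such an export via `load_peptide_db()`.

Note also the VPP/IPP check: both lactotripeptides occur in the intact
β-casein chain, and neither is released by the simulated digestion —
consistent with their known release by fermentation rather than
gastrointestinal proteolysis.

```{r vpp}
length(find_occurrences(bc$sequence, "VPP"))
"VPP" %in% bundle$released$peptide
```

## The synthetic-data generator

Real inputs (a proteome and a reference database snapshot) are large
and external, so the package ships a generator that builds studies with
*known* ground truth.  `generate_study()` creates a substring-free
database of 2–9-residue peptides (the observed length range of released
bioactives) and plants a configurable fraction of them into synthetic
proteins:

* background residues come from an inert alphabet (A/G/S/T/V) that no
  bundled enzyme cleaves;
* a releasable plant is preceded by a cleavable linker (K for tryptic
  scenarios) and ends in a cleavable residue, with no internal cut
  site, so it is released exactly;
* a non-releasable plant is preceded by inert residues only, so its
  left boundary can never be cut;
* collisions (a plant recurring by chance, a background fragment
  matching the database) are detected post hoc and the background is
  resampled from a derived sub-seed.

All randomness flows from one master seed through a fixed splitting
scheme, so regeneration is byte-identical.  By construction the full
pipeline achieves recall and precision 1.0 on planted releasable
peptides — which validates the plumbing, not the biology.  The
generator deliberately does not emulate realistic proteome composition,
real reference-database content, or partial digestion; passing its
tests shows the engine implements its stated rules exactly, and says
nothing about how well the rule tables approximate in vivo proteolysis.

```{r synth}
study <- generate_study(n_proteins = 5, db_size = 20, plant_rate = 0.5, seed = 7)
evaluate_study(study)
```

## Numerical and design choices

* **Rounding** is half away from zero everywhere a reported integer is
  produced; none of the published checks falls on an exact .5.
* **Ambiguity codes** (B/Z/X/U) are rejected by default and accepted as
  never-cleavable, never-matching residues under
  `accept_ambiguous = TRUE`; the intended inputs are curated mature
  chains.
* **Mature chains**: registry lengths exclude signal peptides, and a
  supplied sequence whose length disagrees with the registry triggers a
  warning, never silent truncation.  Initiator methionine is kept when
  the deposited chain keeps it.
* **Degenerate inputs**: an empty cut set returns the whole chain as
  one fragment; database peptides longer than the protein simply never
  match; Y is undefined (an error) for a protein with zero occurrences.
* **Problem sizes in the test suite** — 8,000 exhaustive tripeptides
  against a brute-force rule evaluator, 1,000 fuzzed digestion and
  substring cases, synthetic studies of ~5 proteins × 20 peptides —
  were chosen as the smallest sizes that exercise every rule branch
  and window edge exhaustively.

## Limitations

* The pepsin/chymotrypsin tables are compact stand-ins (see above);
  results depending on X–P cleavage or on Keil's positional
  preferences beyond P2/P1/P1′ will differ from tools carrying the
  full matrices.
* No kinetics, cleavage probabilities, pH continuum, exopeptidase
  (brush-border) trimming, tertiary-structure or food-matrix effects:
  digestion is an all-or-nothing rule evaluation on primary sequence.
* The bundled fixture database is a 44-peptide reference subset;
  absolute profile counts are only meaningful relative to the database
  supplied.
* Bioactivity is taken from the reference database's annotations;
  nothing here validates potency, stability or absorption.
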