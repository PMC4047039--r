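test_that("bundled registry carries all 33 proteins with their mature chain lengths", {
  reg <- bundled_registry()
  expect_equal(nrow(reg), 33L)
  expect_setequal(reg$origin, c("dietary", "endogenous"))
  expect_equal(sum(reg$origin == "dietary"), 7L)
  expect_equal(sum(reg$origin == "endogenous"), 26L)

  alb <- registry_lookup("P02768", reg)
  expect_match(alb$name, "albumin", ignore.case = TRUE)
  expect_equal(alb$origin, "endogenous")
  expect_setequal(alb$secretion_sites[[1]], c("stomach", "small_intestine"))
  expect_equal(alb$chain_length, 591L)
  expect_setequal(alb$scenarios[[1]],
                  c("gastric", "gastric_plus_small_intestinal", "small_intestinal_only"))

  expect_equal(registry_lookup("Q02817", reg)$chain_length, 5159L)
  bcas <- registry_lookup("P02666", reg)
  expect_equal(bcas$origin, "dietary")
  expect_equal(bcas$chain_length, 209L)
  expect_length(bcas$secretion_sites[[1]], 0L)

  expect_error(registry_lookup("NOPE42", reg), "not found")
})

test_that("dietary records have no sites and endogenous records have at least one", {
  reg <- bundled_registry()
  for (i in seq_len(nrow(reg))) {
    if (reg$origin[i] == "dietary") {
      expect_length(reg$secretion_sites[[i]], 0L)
    } else {
      expect_gt(length(reg$secretion_sites[[i]]), 0L)
    }
  }
})

test_that("scenario assignment follows origin and secretion site", {
  expect_equal(scenarios_for("dietary", character(0)),
               c("gastric", "gastric_plus_small_intestinal"))
  expect_equal(scenarios_for("endogenous", "pancreas"), "small_intestinal_only")
  expect_equal(scenarios_for("endogenous", "mouth"),
               c("gastric", "gastric_plus_small_intestinal"))
  expect_setequal(scenarios_for("endogenous", c("stomach", "small_intestine")),
                  c("gastric", "gastric_plus_small_intestinal", "small_intestinal_only"))
  expect_error(scenarios_for("endogenous", character(0)), "at least one")
  expect_error(scenarios_for("dietary", "stomach"), "empty")
  # pure in its two arguments
  expect_identical(scenarios_for("endogenous", c("colon", "duodenum")),
                   scenarios_for("endogenous", c("colon", "duodenum")))
})

test_that("registry scenario assignment matches the scenarios each protein was profiled under", {
  reg <- bundled_registry()
  sc <- function(acc) registry_lookup(acc, reg)$scenarios[[1]]
  expect_equal(sc("P07477"), "small_intestinal_only")              # trypsin, pancreas
  expect_setequal(sc("P01350"), c("gastric", "gastric_plus_small_intestinal",
                                  "small_intestinal_only"))        # gastrin
  expect_setequal(sc("P12872"), c("gastric", "gastric_plus_small_intestinal",
                                  "small_intestinal_only"))        # promotilin
  expect_setequal(sc("P98088"), c("gastric", "gastric_plus_small_intestinal")) # mucin-5AC
  expect_equal(sc("P06307"), "small_intestinal_only")              # cholecystokinin
})

test_that("read_fasta parses records in order, uppercases and validates", {
  p <- write_temp_fasta(c(">X", "PEPTIDE"))
  rec <- read_fasta(p)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$sequence, "PEPTIDE")
  expect_equal(rec$chain_length, 7L)

  p2 <- write_temp_fasta(c(">first one", "peptide", ">second", "AAAK", "GGG"))
  recs <- read_fasta(p2)
  expect_equal(recs$accession, c("first", "second"))
  expect_equal(recs$sequence, c("PEPTIDE", "AAAKGGG"))  # wrapped lines joined

  bad <- write_temp_fasta(c(">bad", "PEP1TIDE"))
  expect_error(read_fasta(bad), "bad.*position 4")
  star <- write_temp_fasta(c(">star", "PEPTIDE*"))
  expect_error(read_fasta(star), "position 8")

  empty <- write_temp_fasta(character(0))
  expect_error(read_fasta(empty), "no records|parse")
})

test_that("read_fasta resolves registry metadata from UniProt-style headers", {
  p <- write_temp_fasta(c(">sp|P02666|CASB_BOVIN Beta-casein", "MKVVL"))
  expect_warning(rec <- read_fasta(p), "Chain length differs")
  expect_equal(rec$accession, "P02666")
  expect_equal(rec$origin, "dietary")

  mature <- read_fasta(system.file("extdata", "P02666_beta_casein_mature.fasta",
                                   package = "peptigest"))
  expect_equal(mature$chain_length, 209L)  # matches the registry, no warning
  expect_equal(mature$scenarios[[1]], c("gastric", "gastric_plus_small_intestinal"))
})

test_that("ambiguity codes are rejected by default and inert when opted in", {
  p <- write_temp_fasta(c(">amb", "PEPXTIDE"))
  expect_error(read_fasta(p), "position 4")
  rec <- read_fasta(p, accept_ambiguous = TRUE)
  expect_equal(rec$chain_length, 8L)
})
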