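test_that("built-in rule tables load with the expected structure", {
  sets <- builtin_rulesets()
  expect_setequal(names(sets), c("trypsin", "chymotrypsin_high", "chymotrypsin_low",
                                 "pepsin_ph1.3", "pepsin_ph_gt2"))
  kinds <- vapply(sets$trypsin$rules, `[[`, "", "kind")
  expect_equal(sum(kinds == "permit"), 1L)
  expect_equal(sum(kinds == "exception_permit"), 2L)
  expect_equal(sum(kinds == "exception_block"), 7L)
  # aliases resolve to the default variants
  expect_equal(cleavage_sites("AAFAA", "chymotrypsin"),
               cleavage_sites("AAFAA", sets$chymotrypsin_high))
  expect_equal(cleavage_sites("ALAAA", "pepsin"),
               cleavage_sites("ALAAA", sets$`pepsin_ph1.3`))
})

test_that("cleavage rules reproduce the documented specificity cases", {
  cases <- list(
    list("AAKAA", "trypsin", 3L),           # K at P1, benign P1'
    list("AAKPAA", "trypsin", integer(0)),  # proline at P1' resists
    list("AWKPAA", "trypsin", 3L),          # W at P2 restores the K-P cut
    list("AARAA", "trypsin", 3L),
    list("AAFAA", "chymotrypsin_high", 3L),
    list("AAWMA", "chymotrypsin_high", integer(0)),  # W-M resists
    list("AAFPA", "chymotrypsin_high", integer(0)),
    list("AALAA", "chymotrypsin_high", integer(0)),  # L needs low specificity
    list("AALAA", "chymotrypsin_low", 3L),
    list("AALAA", "pepsin_ph1.3", 3L),
    list("AAFAA", "pepsin_ph1.3", 3L),
    list("APFAA", "pepsin_ph1.3", integer(0)),       # P at P2 resists
    list("AAYAA", "pepsin_ph1.3", integer(0)),
    list("AAYAA", "pepsin_ph_gt2", 3L),
    list("KA", "trypsin", 1L)                        # truncated P2 context still permits
  )
  for (case in cases) {
    expect_equal(cleavage_sites(case[[1]], case[[2]]), case[[3]],
                 info = paste(case[[1]], case[[2]]))
  }
  expect_equal(cleavage_sites("", "trypsin"), integer(0))
})

test_that("digestion tiles the chain and honours the scenario enzyme sets", {
  frags <- digest("PEPTIDE", "small_intestinal_only")
  expect_equal(nrow(frags), 1L)
  expect_equal(frags$fragment, "PEPTIDE")
  expect_equal(c(frags$start, frags$end), c(1L, 7L))

  frags2 <- digest("AAKAAFAA", "gastric_plus_small_intestinal")
  expect_equal(frags2$fragment, c("AAK", "AAF", "AA"))
  expect_equal(frags2$start, c(1L, 4L, 7L))
  expect_equal(frags2$end, c(3L, 6L, 8L))

  expect_equal(scenario_enzymes("gastric"), "pepsin_ph1.3")
  expect_setequal(scenario_enzymes("gastric_plus_small_intestinal"),
                  c("pepsin_ph1.3", "trypsin", "chymotrypsin_high"))
  expect_setequal(scenario_enzymes("small_intestinal_only"),
                  c("trypsin", "chymotrypsin_high"))
  expect_setequal(scenario_enzymes("small_intestinal_only", chymotrypsin = "chymotrypsin_low"),
                  c("trypsin", "chymotrypsin_low"))
})

test_that("digestion conserves the chain and larger scenarios refine smaller ones", {
  set.seed(421)
  sets <- builtin_rulesets()
  for (rep in 1:200) {
    seqc <- random_sequence(sample(5:80, 1))
    frags <- digest(seqc, "gastric_plus_small_intestinal", sets)
    expect_identical(paste0(frags$fragment, collapse = ""), seqc)
    expect_identical(frags$end - frags$start + 1L, nchar(frags$fragment))

    gastric_cuts <- frags_cuts(digest(seqc, "gastric", sets))
    gsi_cuts <- frags_cuts(digest(seqc, "gastric_plus_small_intestinal", sets))
    expect_true(all(gastric_cuts %in% gsi_cuts))
  }
})

test_that("the vectorised bond evaluator agrees with a brute-force oracle on all tripeptides", {
  sets <- builtin_rulesets()
  tri <- expand.grid(a = AA20, b = AA20, c = AA20, stringsAsFactors = FALSE)
  seqs <- paste0(tri$a, tri$b, tri$c)
  expect_length(seqs, 8000L)
  for (enzyme in c("trypsin", "chymotrypsin_high", "pepsin_ph1.3")) {
    rs <- sets[[enzyme]]
    got <- lapply(seqs, cleavage_sites, enzyme = rs)
    want <- lapply(seqs, oracle_cleavage_sites, ruleset = rs)
    expect_identical(got, want, info = enzyme)
  }
})

test_that("rule sets round-trip through serialization with identical behaviour", {
  sets <- builtin_rulesets()
  path <- withr::local_tempfile(fileext = ".yml")
  write_ruleset(sets$trypsin, path)
  reloaded <- read_ruleset(path)
  set.seed(99)
  for (i in 1:300) {
    s <- random_sequence(10)
    expect_identical(cleavage_sites(s, reloaded), cleavage_sites(s, sets$trypsin))
  }
})

test_that("malformed rule files fail with the offending rule named", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "name: broken",
    "rules:",
    "- kind: permit",
    "  conditions:",
    '    "-1": "KR"',
    "- kind: permit",
    "  conditions:",
    '    "0": "AA"'
  ), path)
  expect_error(read_ruleset(path), "rule 2")

  writeLines(c(
    "name: broken2",
    "rules:",
    "- kind: sometimes",
    "  conditions:",
    '    "-1": "KR"'
  ), path)
  expect_error(read_ruleset(path), "rule 1.*kind")
})
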