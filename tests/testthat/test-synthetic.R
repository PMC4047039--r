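test_that("releasable plants are recovered exactly by digestion", {
  gp <- generate_protein(
    tibble::tibble(peptide = "VPK", releasable = TRUE),
    length = 40, seed = 3, scenario = "small_intestinal_only"
  )
  frags <- digest(gp$record$sequence, "small_intestinal_only")
  m <- gp$manifest
  expect_true(any(frags$fragment == "VPK" & frags$start == m$start[1]))
  expect_equal(substr(gp$record$sequence, m$start[1], m$end[1]), "VPK")
})

test_that("non-releasable plants are visible intact but never released", {
  gp <- generate_protein(
    tibble::tibble(peptide = c("DIK", "ENQR"), releasable = c(TRUE, FALSE)),
    length = 60, seed = 12, scenario = "small_intestinal_only"
  )
  chain <- gp$record$sequence
  m <- gp$manifest
  for (i in seq_len(nrow(m))) {
    expect_equal(find_occurrences(chain, m$peptide[i]), m$start[i])
  }
  frags <- digest(chain, "small_intestinal_only")
  expect_true("DIK" %in% frags$fragment)
  expect_false("ENQR" %in% frags$fragment)
})

test_that("peptides that cannot be released intact are rejected as releasable plants", {
  # no cleavable C-terminal residue under trypsin/chymotrypsin
  expect_error(
    generate_protein(tibble::tibble(peptide = "HL", releasable = TRUE),
                     length = 40, seed = 1, scenario = "small_intestinal_only"),
    "cannot be released"
  )
  # internal tryptic site
  expect_error(
    generate_protein(tibble::tibble(peptide = "AKAR", releasable = TRUE),
                     length = 40, seed = 1, scenario = "small_intestinal_only"),
    "cannot be released"
  )
  # but the same peptides are fine as non-releasable plants
  gp <- generate_protein(tibble::tibble(peptide = "HL", releasable = FALSE),
                         length = 40, seed = 1, scenario = "small_intestinal_only")
  expect_equal(nrow(gp$manifest), 1L)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_protein(tibble::tibble(peptide = "VPK", releasable = TRUE),
                        length = 50, seed = 42)
  b <- generate_protein(tibble::tibble(peptide = "VPK", releasable = TRUE),
                        length = 50, seed = 42)
  expect_identical(a, b)
  c <- generate_protein(tibble::tibble(peptide = "VPK", releasable = TRUE),
                        length = 50, seed = 43)
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("synthetic studies regenerate byte-identically and carry valid manifests", {
  s1 <- generate_study(n_proteins = 4, db_size = 15, plant_rate = 0.6, seed = 7)
  s2 <- generate_study(n_proteins = 4, db_size = 15, plant_rate = 0.6, seed = 7)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(3, 12, 0.5, seed = 11, dir = d1)
  generate_study(3, 12, 0.5, seed = 11, dir = d2)
  for (f in c("proteins.fasta", "peptides.tsv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }

  # manifest positions are consistent with the sequences
  m <- s1$manifest
  for (i in seq_len(nrow(m))) {
    chain <- s1$proteins$sequence[s1$proteins$accession == m$accession[i]]
    expect_equal(substr(chain, m$start[i], m$end[i]), m$peptide[i])
  }
  expect_true(all(nchar(s1$db$sequence) >= 2 & nchar(s1$db$sequence) <= 9))
})

test_that("the pipeline recovers planted ground truth with perfect recall and precision", {
  study <- generate_study(n_proteins = 5, db_size = 20, plant_rate = 0.5, seed = 7)
  expect_gt(sum(study$manifest$releasable), 0L)
  metrics <- evaluate_study(study)
  expect_equal(metrics$recall, 1)
  expect_equal(metrics$precision, 1)
})

test_that("a zero plant rate yields no digest matches at all", {
  study <- generate_study(n_proteins = 3, db_size = 10, plant_rate = 0, seed = 5)
  expect_equal(nrow(study$manifest), 0L)
  for (i in seq_len(nrow(study$proteins))) {
    frags <- digest(study$proteins$sequence[i], study$scenario)
    prof <- match_digest(frags, study$db)
    expect_equal(glance(prof)$total_released, 0L)
  }
})

test_that("every planted peptide is found by the intact scan at its manifest positions", {
  study <- generate_study(n_proteins = 4, db_size = 15, plant_rate = 0.7, seed = 19)
  prof <- scan_intact(study$proteins, study$db)
  m <- study$manifest
  planted_counts <- table(paste(m$accession, m$peptide))
  for (p in seq_len(nrow(study$proteins))) {
    acc <- study$proteins$accession[p]
    chain <- study$proteins$sequence[p]
    for (pep in study$db$sequence) {
      expected <- sort(m$start[m$accession == acc & m$peptide == pep])
      expect_identical(find_occurrences(chain, pep), as.integer(expected),
                       info = paste(acc, pep))
    }
  }
})
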