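test_that("generated elements satisfy the structural contract", {
  p <- academ_profile("AcademH_fungal")
  el <- make_element(p, seed = 101)
  s <- el$sequence
  expect_equal(nchar(s), p$element_length)
  expect_true(substr(s, 1, 1) %in% c("C", "T"))
  expect_true(substr(s, nchar(s), nchar(s)) %in% c("G", "A"))
  # prefix equals reverse complement of suffix over the TIR
  tl <- p$tir_length
  expect_identical(substr(s, 1, tl),
                   dna_revcomp(substr(s, nchar(s) - tl + 1, nchar(s))))
  # cassettes embedded between the TIRs without overlap
  expect_equal(nrow(el$orfs), 2L)
  expect_true(all(el$orfs$start0 >= tl & el$orfs$end0 <= nchar(s) - tl))
  o <- el$orfs[order(el$orfs$start0), ]
  expect_true(all(o$start0[-1] >= o$end0[-nrow(o)]))
})

test_that("element generation is deterministic and profile-faithful", {
  p <- academ_profile("AcademHP")
  expect_identical(make_element(p, seed = 7)$sequence,
                   make_element(p, seed = 7)$sequence)
  expect_false(identical(make_element(p, seed = 7)$sequence,
                         make_element(p, seed = 8)$sequence))
  # fungal profile only ever plants 9-bp duplications
  g <- plant_insertions(random_genome(60000, seed = 1),
                        academ_profile("AcademH_fungal"), 5, seed = 2)
  expect_true(all(g$truth$tsd_len == 9L))
})

test_that("a zero-TIR profile yields only chance-level terminal self-complementarity", {
  p <- lineage_profile("tirless", "nonautonomous", tsd_lengths = 9L,
                       tir_length = 0L, element_length = 400L)
  hits <- vapply(1:40, function(i)
    detect_tir(make_element(p, seed = 1000 + i)$sequence)$length, integer(1))
  expect_true(mean(hits == 0L) >= 0.95)
})

test_that("oversized cassettes trigger an explicit sizing error", {
  expect_error(
    make_element(lineage_profile(
      "tiny", "AcademH_fungal", tsd_lengths = 9L, tir_length = 20L,
      element_length = 900L,
      cassettes = list(list(kind = "transposase", strand = "+"),
                       list(kind = "helicase", strand = "-"))), seed = 1),
    "too small")
})

test_that("profile invariants are validated", {
  expect_error(lineage_profile("x", "AcademH_fungal", tsd_lengths = 13L,
                               tir_length = 10L, element_length = 500L),
               "\\[0, 12\\]")
  expect_error(lineage_profile("x", "AcademH_fungal", tsd_lengths = 9L,
                               tir_length = 300L, element_length = 500L),
               "tir_length")
  expect_error(lineage_profile("x", "AcademH_fungal", tsd_lengths = 9L,
                               tir_length = 10L, element_length = 60L),
               "element_length")
  expect_error(lineage_profile("x", "AcademH_fungal", tsd_lengths = 9L,
                               tir_length = 10L, element_length = 500L,
                               divergence = 1.5), "divergence")
})

test_that("planting n = 0 returns the background unchanged", {
  bg <- random_genome(5000, seed = 3)
  g <- plant_insertions(bg, academ_profile("Academ_nonautonomous"), 0)
  expect_identical(g$contigs, bg)
  expect_equal(nrow(g$truth), 0L)
})

test_that("insertion length bookkeeping is exact", {
  bg <- random_genome(30000, seed = 4)
  p <- academ_profile("Academ_nonautonomous")  # 600 bp, 9-bp TSD
  g <- plant_insertions(bg, p, 1, seed = 5)
  expect_equal(nchar(g$contigs), nchar(bg) + 600L + 9L,
               ignore_attr = TRUE)
  tr <- g$truth
  expect_equal(tr$end0 - tr$start0, 600L)
})

test_that("TSD copies flank every insertion and excision restores the ancestor", {
  p <- lineage_profile("mini", "nonautonomous", tsd_lengths = c(9L, 10L),
                       tir_length = 15L, element_length = 300L)
  total <- 0L
  for (seed in c(11, 12, 13)) {
    g <- plant_insertions(random_genome(80000, seed = seed), p, 35,
                          seed = seed + 100, margin = 300L)
    tr <- g$truth
    total <- total + nrow(tr)
    for (i in seq_len(nrow(tr))) {
      s <- g$contigs[[tr$contig[i]]]
      expect_identical(substr(s, tr$start0[i] - tr$tsd_len[i] + 1,
                              tr$start0[i]),
                       substr(s, tr$end0[i] + 1, tr$end0[i] + tr$tsd_len[i]))
    }
    expect_identical(restore_ancestral(g), g$ancestral)
  }
  expect_gte(total, 100L)
})

test_that("divergence and truncation touch element copies only", {
  p <- academ_profile("Academ_nonautonomous", divergence = 0.1,
                      truncation_prob = 0.5)
  g <- plant_insertions(random_genome(50000, seed = 21), p, 10, seed = 22)
  tr <- g$truth
  expect_true(any(tr$n_substitutions > 0L))
  expect_true(any(tr$truncated))
  # flanks and TSDs are never mutated: excision still restores the ancestor
  expect_identical(restore_ancestral(g), g$ancestral)
})

test_that("planting errors on impossible requests", {
  expect_error(plant_insertions(c(c1 = ""), academ_profile("AcademH_fungal"),
                                1), "zero-length")
  expect_error(plant_insertions(random_genome(3000, seed = 1),
                                academ_profile("AcademH_fungal"), 50),
               "too small")
})

test_that("planting is byte-identical for identical seeds", {
  p <- academ_profile("AcademH_animal", divergence = 0.05)
  bg <- random_genome(50000, seed = 31)
  g1 <- plant_insertions(bg, p, 5, seed = 32)
  g2 <- plant_insertions(bg, p, 5, seed = 32)
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$truth, g2$truth)
})

test_that("fixtures round-trip through FASTA/TSV/GFF3", {
  g <- plant_insertions(random_genome(40000, seed = 41),
                        academ_profile("AcademH_fungal"), 3, seed = 42)
  d <- withr::local_tempdir()
  paths <- write_fixtures(g, d)
  g2 <- read_fixtures(d)
  expect_identical(g2$contigs, g$contigs)
  expect_identical(g2$ancestral, g$ancestral)
  expect_identical(g2$truth, g$truth[, names(g2$truth)])
  # GFF3 is valid 1-based inclusive by an independent parser
  gr <- rtracklayer::import(paths[["gff"]])
  expect_equal(BiocGenerics::start(gr), g$truth$start0 + 1L)
  expect_equal(BiocGenerics::end(gr), g$truth$end0)
  expect_equal(as.character(gr$family), g$truth$family)
})

test_that("an empty genome writes valid empty fixtures", {
  g <- structure(list(contigs = character(0),
                      truth = plant_insertions(random_genome(5000, seed = 1),
                                               academ_profile("AcademH_fungal"),
                                               0)$truth,
                      ancestral = character(0), elements = list(),
                      seed = 1L), class = "synthetic_genome")
  d <- withr::local_tempdir()
  paths <- write_fixtures(g, d)
  expect_true(file.exists(paths[["contigs"]]))
  tt <- readLines(paths[["truth"]])
  expect_length(tt, 1L)  # header only
  expect_match(readLines(paths[["gff"]])[1], "##gff-version 3", fixed = TRUE)
})

test_that("non-autonomous templates inherit autonomous termini", {
  profs <- list(academ_profile("AcademH_fungal"),
                academ_profile("Academ_nonautonomous"))
  g <- plant_insertions(random_genome(60000, seed = 51), profs, c(2, 2),
                        seed = 52)
  auto <- g$elements[["AcademH_fungal"]]$sequence
  na <- g$elements[["Academ_nonautonomous"]]$sequence
  expect_identical(substr(na, 1, 100), substr(auto, 1, 100))
  expect_identical(substr(na, nchar(na) - 99, nchar(na)),
                   substr(auto, nchar(auto) - 99, nchar(auto)))
})
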