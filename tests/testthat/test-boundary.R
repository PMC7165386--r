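test_that("call_tsd finds planted duplications and rejects their absence", {
  tsd <- "GTTCAAGGT"
  left <- paste0("ACACGTGTTAAC", tsd)
  right <- paste0(tsd, "CCTGATTGACAA")
  r <- call_tsd(left, right)
  expect_equal(r$length, 9L)
  expect_identical(r$left_seq, tsd)
  expect_true(r$exact)
  # flanks sharing no junction k-mer
  r0 <- call_tsd("AAAAAAAAAAAA", "CCCCCCCCCCCC")
  expect_equal(r0$length, 0L)
  # short flanks lower kmax with a warning flag
  rs <- call_tsd("ACGTA", "ACGTAGGG")
  expect_true(rs$warning)
  r1 <- call_tsd("", "ACGT")
  expect_equal(r1$length, 0L)
  expect_true(r1$warning)
})

test_that("call_tsd equals the brute-force oracle on 1000 random flank pairs", {
  set.seed(201)
  for (i in 1:1000) {
    left <- random_dna(sample(12:25, 1))
    right <- random_dna(sample(12:25, 1))
    # occasionally plant a real duplication
    if (i %% 5 == 0) {
      k <- sample(2:12, 1)
      tsd <- random_dna(k)
      left <- paste0(left, tsd)
      right <- paste0(tsd, right)
    }
    expect_identical(call_tsd(left, right)$length, oracle_tsd(left, right))
  }
})

test_that("detect_tir reports planted TIR lengths exactly, including extremes", {
  el_long <- make_element(academ_profile("AcademH-1_LoTr"), seed = 211)
  r <- detect_tir(el_long$sequence)
  expect_equal(r$length, 526L)
  expect_equal(r$mismatches, 0L)
  el_short <- make_element(academ_profile("AcademH-2_PSt"), seed = 212)
  expect_equal(detect_tir(el_short$sequence, min_len = 8L)$length, 8L)
  el_cvi <- make_element(academ_profile("AcademH-16_CVi"), seed = 213)
  expect_equal(detect_tir(el_cvi$sequence)$length, 575L)
  # internal divergence is tolerated up to the identity threshold
  s <- el_long$sequence
  v <- strsplit(s, "")[[1]]
  set.seed(214)
  for (i in sample(20:500, 15)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  r2 <- detect_tir(paste(v, collapse = ""))
  expect_gte(r2$length, 500L)
  expect_gte(r2$identity, 0.8)
  expect_equal(r2$identity, (r2$length - r2$mismatches) / r2$length)
})

test_that("detect_tir is symmetric under reverse complement and null on random sequence", {
  set.seed(221)
  for (i in 1:20) {
    el <- make_element(academ_profile("AcademH_fungal"))
    expect_equal(detect_tir(dna_revcomp(el$sequence))$length,
                 detect_tir(el$sequence)$length)
  }
  fp <- vapply(1:1000, function(i) detect_tir(random_dna(600))$length > 0L,
               logical(1))
  expect_gte(mean(!fp), 0.99)
})

test_that("terminal motif check follows the pyrimidine/purine rule", {
  expect_equal(terminal_motif_check("CAAATG"),
               list(terminal_5_ok = TRUE, terminal_3_ok = TRUE))
  expect_equal(terminal_motif_check("GAAATC"),
               list(terminal_5_ok = FALSE, terminal_3_ok = FALSE))
  for (nm in c("AcademH_fungal", "AcademH_animal", "AcademHP",
               "AcademX_animal", "AcademX_red_alga")) {
    tm <- terminal_motif_check(make_element(academ_profile(nm), seed = 5)$sequence)
    expect_true(tm$terminal_5_ok && tm$terminal_3_ok)
  }
})

test_that("the single-copy acceptance rule applies strict inequalities", {
  fake <- function(tir, tsd, source = "single_copy", nsup = 1L) {
    structure(list(contig = "c", start = 0L, end = 100L, strand = "+",
                   tsd = list(length = tsd), tir = list(length = tir),
                   terminal_5_ok = TRUE, terminal_3_ok = TRUE,
                   source = source, n_tsd_support = nsup,
                   accepted_full_length = FALSE),
              class = "element_annotation")
  }
  expect_true(accept_element(fake(11L, 9L)))   # > 10-bp TIR, > 8-bp TSD
  expect_false(accept_element(fake(10L, 9L)))  # TIR exactly 10: rejected
  expect_false(accept_element(fake(11L, 8L)))  # TSD exactly 8: rejected
  # multicopy rule: TSD >= 3 with >= 2 member support
  expect_true(accept_element(fake(0L, 3L, "multicopy", 2L)))
  expect_false(accept_element(fake(0L, 2L, "multicopy", 2L)))
  expect_false(accept_element(fake(0L, 9L, "multicopy", 1L)))
  # monotonicity: increasing TIR or TSD never flips accepted -> rejected
  for (source in c("single_copy", "multicopy")) {
    prev <- FALSE
    for (tir in c(5L, 10L, 11L, 40L)) {
      prev_tsd <- FALSE
      for (tsd in 0:12) {
        a <- accept_element(fake(tir, tsd, source, 2L))
        expect_false(prev_tsd && !a)
        prev_tsd <- a
      }
    }
    for (tsd in c(2L, 8L, 9L, 12L)) {
      prev_tir <- FALSE
      for (tir in 0:40) {
        a <- accept_element(fake(tir, tsd, source, 2L))
        expect_false(prev_tir && !a)
        prev_tir <- a
      }
    }
  }
})

test_that("annotation at truth spans recovers planted TSD and TIR exactly", {
  total <- 0L
  for (seed in c(231, 232)) {
    g <- plant_insertions(random_genome(220000, seed = seed),
                          academ_profile("AcademH_fungal"), 25,
                          seed = seed + 1)
    tr <- g$truth
    total <- total + nrow(tr)
    for (i in seq_len(nrow(tr))) {
      ann <- annotate_element(g$contigs, tr$contig[i], tr$start0[i],
                              tr$end0[i], strand = tr$strand[i],
                              source = "multicopy", n_tsd_support = 2L)
      expect_equal(ann$tsd$length, tr$tsd_len[i])
      expect_equal(ann$tir$length, tr$tir_len[i])
      expect_true(ann$terminal_5_ok && ann$terminal_3_ok)
      expect_true(ann$accepted_full_length)
    }
  }
  expect_gte(total, 50L)
})

test_that("boundary refinement restores shifted candidates and is idempotent", {
  g <- plant_insertions(random_genome(40000, seed = 241),
                        academ_profile("AcademH_fungal"), 1, seed = 242)
  tr <- g$truth[1, ]
  # shifted +7 bp on both ends is restored to truth exactly
  ann <- refine_boundaries(g$contigs, tr$contig, tr$start0 + 7L,
                           tr$end0 + 7L, strand = tr$strand)
  expect_equal(ann$start, tr$start0)
  expect_equal(ann$end, tr$end0)
  expect_equal(ann$tsd$length, tr$tsd_len)
  # already-optimal candidates are unchanged
  ann2 <- refine_boundaries(g$contigs, tr$contig, ann$start, ann$end,
                            strand = tr$strand)
  expect_equal(ann2$start, ann$start)
  expect_equal(ann2$end, ann$end)
})

test_that("equal-score boundary pairs resolve to the leftmost", {
  # two insertion-like layouts where a duplicated 4-mer appears twice:
  # D E D E D with element between; shifting by the period gives the same
  # TSD length, so the leftmost pair must win
  set.seed(251)
  d <- "ACGT"
  core <- paste0(strrep("T", 30), "C", random_dna(58), "G", strrep("A", 30))
  s <- paste0(random_dna(60), d, d, core, d, d, random_dna(60))
  g <- c(c1 = s)
  start0 <- 68L  # after flank + two TSD copies: element begins here
  end0 <- start0 + nchar(core)
  ann <- refine_boundaries(g, "c1", start0, end0, search_radius = 10L)
  alt <- refine_boundaries(g, "c1", start0 + 4L, end0 + 4L,
                           search_radius = 10L)
  expect_equal(ann$tsd$length, alt$tsd$length)
  expect_equal(ann$start, alt$start)  # same (leftmost) pair from both starts
})
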