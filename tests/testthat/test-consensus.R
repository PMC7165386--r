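# build a scan -> cluster -> consensus chain on a small planted genome
local_family <- function(profile, n, bg_len = 80000L, seed = 301) {
  g <- plant_insertions(random_genome(bg_len, seed = seed), profile, n,
                        seed = seed + 1L)
  h <- scan_genome(g$contigs, g$elements[[1]]$sequence,
                   query_id = profile$name)
  seqs <- vapply(seq_len(nrow(h)), function(i)
    extract_with_flanks(g$contigs, h[i, ], 0L)$seq, character(1))
  cl <- cluster_hits(h, seqs)
  list(genome = g, hits = h, clusters = cl)
}

test_that("identical copies form one cluster; unrelated elements form two", {
  profs <- list(academ_profile("AcademH_fungal"),
                academ_profile("AcademX_animal"))
  g <- plant_insertions(random_genome(90000, seed = 311), profs, c(4, 4),
                        seed = 312)
  hits <- rbind(
    scan_genome(g$contigs, g$elements[[1]]$sequence, query_id = "qH"),
    scan_genome(g$contigs, g$elements[[2]]$sequence, query_id = "qX"))
  class(hits) <- c("seq_hits", "data.frame")
  seqs <- vapply(seq_len(nrow(hits)), function(i)
    extract_with_flanks(g$contigs, hits[i, ], 0L)$seq, character(1))
  cl <- cluster_hits(hits, seqs)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, function(x) nrow(x$members), integer(1)),
                  c(4L, 4L))
  expect_length(cluster_hits(hits[0, ], character(0)), 0L)
})

test_that("clustering equals all-pairs alignment components on small inputs", {
  set.seed(321)
  fams <- replicate(3, random_dna(300))
  seqs <- unlist(lapply(fams, function(f)
    replicate(4, mutate_seq(f, 0.03))))
  n <- length(seqs)
  hits <- make_hits(strand = "+",
                    tstart = seq(0L, by = 400L, length.out = n),
                    tend = seq(300L, by = 400L, length.out = n),
                    qstart = 0L, qend = 300L)
  cl <- cluster_hits(hits, seqs)
  got <- partition_signature(lapply(cl, function(x)
    match(paste(x$members$contig, x$members$tstart),
          paste(hits$contig, hits$tstart))), n)
  # oracle: all-pairs global alignment identity/coverage, then union-find
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[i]), Biostrings::DNAString(seqs[j]),
      type = "local", substitutionMatrix = sm,
      gapOpening = 5, gapExtension = 2)
    idt <- Biostrings::nmatch(al) /
      (Biostrings::nmatch(al) + Biostrings::nmismatch(al))
    cov <- Biostrings::nchar(al) / min(nchar(seqs[i]), nchar(seqs[j]))
    if (idt >= 0.8 && cov >= 0.5) edges <- rbind(edges, c(i, j))
  }
  expect_equal(got, oracle_components(n, edges))
})

test_that("consensus of identical copies equals the planted element over its span", {
  fam <- local_family(academ_profile("AcademH_fungal"), 6, seed = 331)
  expect_length(fam$clusters, 1L)
  cons <- build_consensus(fam$clusters[[1]], fam$genome$contigs,
                          flank = 500L, top_n = 10L)
  sp <- cons$element_span
  expect_identical(substr(cons$sequence, sp[1], sp[2] - 1L),
                   fam$genome$elements[[1]]$sequence)
  expect_equal(length(cons$column_support), nchar(cons$sequence))
  # element columns carry full support
  expect_true(all(cons$column_support[sp[1]:(sp[2] - 1L)] == 6L))
  # top_n = 1 reduces the consensus to the representative's extraction
  c1 <- build_consensus(fam$clusters[[1]], fam$genome$contigs,
                        flank = 500L, top_n = 1L)
  rep_hit <- fam$clusters[[1]]$members[fam$clusters[[1]]$representative, ]
  rep_seq <- extract_with_flanks(fam$genome$contigs, rep_hit, 500L)$seq
  expect_identical(c1$sequence, rep_seq)
  expect_true(c1$low_support)
})

test_that("per-column consensus at divergence 0.1 follows the member majority", {
  set.seed(341)
  anc <- make_element(academ_profile("Academ_nonautonomous"))$sequence
  L <- nchar(anc)
  n <- 10L
  copies <- vapply(1:n, function(i) mutate_seq(anc, 0.1), character(1))
  # place copies at known offsets separated by one base
  starts <- 200L + (0:(n - 1L)) * (L + 1L)
  hits <- make_hits(strand = "+", tstart = starts, tend = starts + L,
                    qstart = 0L, qend = L)
  gen <- c(c1 = paste0(random_dna(200), paste(copies, collapse = "T")))
  cluster <- structure(list(cluster_id = "fam", members = hits,
                            sequences = copies, representative = 1L),
                       class = "hit_cluster")
  cons <- build_consensus(cluster, gen, flank = 0L, top_n = 10L)
  expect_equal(nchar(cons$sequence), L)
  cm <- strsplit(cons$sequence, "")[[1]]
  am <- strsplit(anc, "")[[1]]
  Mm <- do.call(rbind, strsplit(copies, ""))
  retained <- colSums(Mm == matrix(am, n, L, byrow = TRUE))
  # wherever a strict majority of members retain the ancestral base,
  # the consensus equals it
  expect_true(all(cm[retained > n / 2] == am[retained > n / 2]))
  # overall consensus-ancestor mismatch rate is consistent with the
  # per-column binomial (majority loss is rare at divergence 0.1)
  expect_lt(mean(cm != am), 0.01)
})

test_that("TSD refinement confirms flush boundaries in one iteration and is idempotent", {
  fam <- local_family(academ_profile("AcademH_fungal"), 6, seed = 351)
  cons <- build_consensus(fam$clusters[[1]], fam$genome$contigs)
  r1 <- refine_until_tsd(cons, fam$genome$contigs)
  expect_equal(r1$boundary_status, "tsd_confirmed")
  expect_equal(r1$iterations, 1L)
  expect_identical(r1$sequence, fam$genome$elements[[1]]$sequence)
  r2 <- refine_until_tsd(r1, fam$genome$contigs)
  expect_identical(r2, r1)
})

test_that("over-extended candidate boundaries are trimmed back to truth", {
  fam <- local_family(academ_profile("AcademH_fungal"), 6, seed = 361)
  cons <- build_consensus(fam$clusters[[1]], fam$genome$contigs)
  cons$element_span <- c(cons$element_span[1] - 30L,
                         cons$element_span[2] + 30L)
  r <- refine_until_tsd(cons, fam$genome$contigs)
  expect_equal(r$boundary_status, "tsd_confirmed")
  expect_identical(r$sequence, fam$genome$elements[[1]]$sequence)
  # confirmed member annotations carry the planted TSD
  expect_true(all(vapply(r$insertions, function(a) a$tsd$length,
                         integer(1)) == 9L))
})

test_that("members without planted TSDs stay unconfirmed", {
  p <- lineage_profile("noTSD", "nonautonomous", tsd_lengths = 0L,
                       tir_length = 20L, element_length = 600L)
  fam <- local_family(p, 5, bg_len = 60000L, seed = 371)
  cons <- build_consensus(fam$clusters[[1]], fam$genome$contigs)
  r <- refine_until_tsd(cons, fam$genome$contigs)
  expect_equal(r$boundary_status, "unconfirmed")
})

test_that("consensus construction is deterministic", {
  fam <- local_family(academ_profile("AcademH_animal"), 5, seed = 381)
  c1 <- build_consensus(fam$clusters[[1]], fam$genome$contigs)
  c2 <- build_consensus(fam$clusters[[1]], fam$genome$contigs)
  expect_identical(c1$sequence, c2$sequence)
  expect_identical(c1$column_support, c2$column_support)
})
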