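## pairwise similarity of two member sequences using the package scanner:
## identity and coverage of the shorter sequence by merged hits
.pair_similarity <- function(a, b, params = scan_params(min_hit_len = 30L)) {
  if (nchar(a) <= nchar(b)) { q <- a; s <- b } else { q <- b; s <- a }
  h <- scan_genome(c(s = s), q, params)
  if (!nrow(h)) return(list(identity = 0, coverage = 0))
  h <- merge_hits(h, max_gap = 100L)
  ## union of covered query intervals
  iv <- h[order(h$qstart), c("qstart", "qend"), drop = FALSE]
  cov <- 0L; cur_s <- iv$qstart[1]; cur_e <- iv$qend[1]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv$qstart[i] <= cur_e) cur_e <- max(cur_e, iv$qend[i])
    else { cov <- cov + cur_e - cur_s; cur_s <- iv$qstart[i]; cur_e <- iv$qend[i] }
  }
  cov <- cov + cur_e - cur_s
  list(identity = sum(h$identity * h$length) / sum(h$length),
       coverage = cov / nchar(q))
}

#' Cluster hits into families by single linkage
#'
#' Builds the graph whose edges join hit sequences with pairwise identity at
#' least `id_thresh` over at least `cov_thresh` of the shorter sequence, and
#' returns its connected components (single-linkage clusters), emulating the
#' all-against-all clustering used to group homologous repeat copies.
#' Cluster ids are deterministic, ordered by the smallest member coordinate.
#'
#' @param hits hit table from [scan_genome()]/[merge_hits()].
#' @param member_sequences character vector, one (oriented) sequence per hit.
#' @param id_thresh minimum pairwise identity.
#' @param cov_thresh minimum coverage of the shorter sequence.
#' @param params scanner parameters used for the pairwise comparisons.
#' @return list of `hit_cluster` objects: list with `cluster_id`, `members`
#'   (hit rows), `sequences`, `representative` (index within the cluster:
#'   longest member, ties by identity then leftmost).
#' @export
cluster_hits <- function(hits, member_sequences, id_thresh = 0.8,
                         cov_thresh = 0.5,
                         params = scan_params(min_hit_len = 30L)) {
  n <- nrow(hits)
  stopifnot(length(member_sequences) == n)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (find(i) == find(j)) next
    sim <- .pair_similarity(member_sequences[i], member_sequences[j], params)
    if (sim$identity >= id_thresh && sim$coverage >= cov_thresh)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  ## order clusters by smallest member coordinate
  first <- vapply(groups, function(ix) {
    h <- hits[ix, , drop = FALSE]
    o <- order(h$contig, h$tstart)[1]
    paste(h$contig[o], formatC(h$tstart[o], width = 12, flag = "0"))
  }, character(1))
  groups <- groups[order(first)]
  lapply(seq_along(groups), function(ci) {
    ix <- groups[[ci]]
    h <- hits[ix, , drop = FALSE]
    len <- h$tend - h$tstart
    o <- order(-len, -h$identity, h$tstart)[1]
    structure(list(cluster_id = sprintf("%s_c%02d", h$query_id[1], ci),
                   members = h, sequences = member_sequences[ix],
                   representative = o),
              class = "hit_cluster")
  })
}

#' @export
print.hit_cluster <- function(x, ...) {
  cat(sprintf("<hit_cluster> %s: %d member(s), representative #%d\n",
              x$cluster_id, nrow(x$members), x$representative))
  invisible(x)
}

## map one member onto the anchor by global pairwise alignment;
## returns list(chars = member char per anchor position, mempos = 1-based
## member index per anchor position, NA at deletions)
.map_member <- function(anchor, mem) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(mem),
    subject = Biostrings::DNAString(anchor),
    type = "global", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 1)
  pc <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- sc != "-"
  mem_idx <- cumsum(pc != "-")
  chars <- pc[keep]
  mempos <- ifelse(pc[keep] == "-", NA_integer_, mem_idx[keep])
  list(chars = chars, mempos = mempos)
}

#' Build a family consensus from clustered hits
#'
#' Extracts the `top_n` highest-scoring members with `flank` bp of flanking
#' sequence on both sides (minus-strand members reverse-complemented into a
#' common orientation), star-aligns them onto the representative, and takes
#' the per-column majority base (ties broken alphabetically; columns with a
#' majority of gaps are dropped). When all extractions have equal length and
#' high stacked identity the star alignment reduces to direct column
#' stacking; otherwise pairwise global alignments against the representative
#' are used.
#'
#' @param cluster a `hit_cluster`.
#' @param genome named character vector of contigs.
#' @param flank flanking sequence length (bp) on each side.
#' @param top_n number of members used.
#' @return object of class `consensus_element`: list with `family`,
#'   `sequence`, `column_support`, `n_members_used`, `iterations`,
#'   `boundary_status`, per-member coordinate maps and the initial
#'   `element_span` (1-based half-open columns of the representative hit).
#' @export
build_consensus <- function(cluster, genome, flank = 1000L, top_n = 10L) {
  stopifnot(inherits(cluster, "hit_cluster"))
  contigs <- .as_contigs(genome)
  h <- cluster$members
  n_all <- nrow(h)
  ord <- order(-h$score, h$contig, h$tstart)
  use <- ord[seq_len(min(top_n, n_all))]
  if (!(cluster$representative %in% use)) use[length(use)] <- cluster$representative
  anchor_i <- which(use == cluster$representative)[1]
  if (is.na(anchor_i)) anchor_i <- 1L
  exts <- lapply(use, function(i) extract_with_flanks(contigs, h[i, ], flank))
  seqs <- vapply(exts, `[[`, character(1), "seq")
  anchor <- seqs[anchor_i]
  L <- nchar(anchor)
  nm <- length(seqs)

  M <- matrix("-", nrow = nm, ncol = L)
  mempos <- matrix(NA_integer_, nrow = nm, ncol = L)
  same_len <- all(nchar(seqs) == L)
  for (i in seq_len(nm)) {
    if (i == anchor_i) {
      M[i, ] <- strsplit(anchor, "")[[1]]
      mempos[i, ] <- seq_len(L)
      next
    }
    stacked <- FALSE
    if (same_len) {
      ch <- strsplit(seqs[i], "")[[1]]
      idt <- mean(ch == strsplit(anchor, "")[[1]])
      if (idt >= 0.5) {
        M[i, ] <- ch
        mempos[i, ] <- seq_len(L)
        stacked <- TRUE
      }
    }
    if (!stacked) {
      mp <- .map_member(anchor, seqs[i])
      M[i, ] <- mp$chars
      mempos[i, ] <- mp$mempos
    }
  }

  cnt <- vapply(c(.BASES, "-"), function(b) colSums(M == b),
                numeric(L))          # L x 5
  gap_major <- cnt[, 5] > nm / 2
  base_idx <- max.col(cnt[, 1:4, drop = FALSE], ties.method = "first")
  cons_chars <- .BASES[base_idx]
  support <- cnt[cbind(seq_len(L), base_idx)]

  keep <- !gap_major
  ## genomic coordinate maps (0-based) per member, per kept column
  maps <- lapply(seq_len(nm), function(i) {
    e <- exts[[i]]
    g <- if (e$strand == "+") e$ext_start + mempos[i, ] - 1L
         else e$ext_end - mempos[i, ]
    g[keep]
  })
  rep_off <- exts[[anchor_i]]$offset
  rep_len <- exts[[anchor_i]]$hit_len
  colmap <- cumsum(keep)             # old col -> new col index
  cs <- colmap[rep_off + 1L]
  ce <- colmap[rep_off + rep_len] + 1L

  structure(list(
    family = cluster$cluster_id,
    sequence = paste(cons_chars[keep], collapse = ""),
    column_support = as.integer(support[keep]),
    n_members_used = nm, iterations = 1L,
    boundary_status = "unconfirmed",
    low_support = nm < 2L,
    members = h[use, , drop = FALSE],
    maps = maps,
    strands = vapply(exts, `[[`, character(1), "strand"),
    contigs_of = vapply(exts, `[[`, character(1), "contig"),
    element_span = c(cs, ce),
    insertions = NULL), class = "consensus_element")
}

#' @export
print.consensus_element <- function(x, ...) {
  cat(sprintf("<consensus_element> %s: %d bp, %d member(s), %s (%d iteration(s))\n",
              x$family, nchar(x$sequence), x$n_members_used,
              x$boundary_status, x$iterations))
  invisible(x)
}

.trim_consensus <- function(cons, cs, ce) {
  idx <- cs:(ce - 1L)
  cons$sequence <- paste(strsplit(cons$sequence, "")[[1]][idx], collapse = "")
  cons$column_support <- cons$column_support[idx]
  cons$maps <- lapply(cons$maps, function(g) g[idx])
  cons$element_span <- c(1L, length(idx) + 1L)
  cons
}

## member columns [cs, ce) -> genomic 0-based half-open span
.member_span <- function(gpos, strand, cs, ce) {
  a <- gpos[cs]; b <- gpos[ce - 1L]
  if (is.na(a) || is.na(b)) return(NULL)
  if (strand == "+") c(a, b + 1L) else c(b, a + 1L)
}

## For one member, the largest exact TSD length for every candidate
## (start-column, end-column) pair, decoupled per axis. Returns a matrix
## (length(s_cols) x length(e_cols)) of k values (0 = none).
.member_tsd_matrix <- function(ctg, gpos, strand, s_cols, e_cols,
                               kmin = 2L, kmax = 12L) {
  n <- nchar(ctg)
  if (strand == "+") {
    a <- gpos[s_cols]                 # 0-based element start per s_col
    b <- gpos[e_cols - 1L] + 1L       # 0-based element end per e_col
  } else {
    a <- gpos[e_cols - 1L]            # genomic start depends on e_col
    b <- gpos[s_cols] + 1L            # genomic end depends on s_col
  }
  ok_a <- !is.na(a) & a >= kmax & a <= n
  ok_b <- !is.na(b) & b >= 0L & b + kmax <= n
  if (!any(ok_a) || !any(ok_b)) return(NULL)
  maxk <- matrix(0L, length(s_cols), length(e_cols))
  for (k in kmin:kmax) {
    lk <- rep(NA_character_, length(a))
    rk <- rep(NA_character_, length(b))
    lk[ok_a] <- substring(ctg, a[ok_a] - k + 1L, a[ok_a])
    rk[ok_b] <- substring(ctg, b[ok_b] + 1L, b[ok_b] + k)
    eq <- if (strand == "+") outer(lk, rk, "==") else t(outer(lk, rk, "=="))
    eq[is.na(eq)] <- FALSE
    maxk[eq] <- k
  }
  maxk
}

## TSD sequence of one member at a confirmed (cs, ce) column pair, reported
## in element orientation so that plus- and minus-strand members of an
## element-internal repeat artifact yield the identical string
.member_tsd_seq <- function(ctg, gpos, strand, cs, ce, k) {
  sp <- .member_span(gpos, strand, cs, ce)
  if (is.null(sp)) return(NA_character_)
  if (strand == "+") substring(ctg, sp[1] - k + 1L, sp[1])
  else dna_revcomp(substring(ctg, sp[2] + 1L, sp[2] + k))
}

#' Refine a consensus until TSDs confirm its boundaries
#'
#' Re-checks the member copies for flanking target site duplications at
#' every boundary pair within `search_radius` of the current candidate
#' boundaries (widening the window on later iterations), and accepts the
#' pair supported by the most member insertions (ties: longer TSD, then
#' leftmost) once at least `min_support` members show TSDs at the same
#' consensus positions. Because a true TSD is duplicated host sequence, its
#' sequence differs between insertion sites; candidate boundaries whose
#' supporting "TSDs" are identical in every member are element-internal
#' repeat artifacts and are rejected. The confirmed repeat unit excludes the
#' TSD copies. An unconfirmed status is a valid outcome (e.g. families that
#' do not generate duplications).
#'
#' @param cons a `consensus_element` built from at least 2 members
#'   (single-copy elements go through the single-copy rule of
#'   [refine_boundaries()]/[accept_element()] instead).
#' @param genome named character vector of contigs.
#' @param max_iter maximum refinement iterations.
#' @param search_radius boundary search radius (bp) in iteration 1; widened
#'   to `2 * search_radius` (capped) on later iterations.
#' @param min_support members required to agree on TSD-flanked boundaries.
#' @param kmin,kmax TSD length range searched.
#' @param sig_level chance-support bound: a boundary pair is confirmed only
#'   when the binomial probability of its member support arising from random
#'   k-mer coincidences, multiplied by the number of pairs examined, is
#'   below this level (short TSDs therefore need more supporting copies
#'   than long ones).
#' @return the refined `consensus_element`; when confirmed, `insertions`
#'   holds one `element_annotation` per member at the confirmed boundaries.
#' @export
refine_until_tsd <- function(cons, genome, max_iter = 5L,
                             search_radius = 50L, min_support = 2L,
                             kmin = 2L, kmax = 12L, sig_level = 0.01) {
  stopifnot(inherits(cons, "consensus_element"))
  if (cons$boundary_status == "tsd_confirmed") return(cons)
  if (cons$n_members_used < 2L) {
    warning("consensus built from a single member; TSD confirmation needs >= 2")
    return(cons)
  }
  contigs <- .as_contigs(genome)
  cand <- cons$element_span
  L <- nchar(cons$sequence)
  nm <- cons$n_members_used
  prev_radius <- 0L
  for (it in seq_len(max_iter)) {
    radius <- min(search_radius * it, 2L * search_radius)
    if (radius == prev_radius) break   # window cannot grow further
    prev_radius <- radius
    s_cols <- max(1L, cand[1] - radius):min(L, cand[1] + radius)
    e_cols <- max(2L, cand[2] - radius):min(L + 1L, cand[2] + radius)
    mats <- lapply(seq_len(nm), function(m)
      .member_tsd_matrix(contigs[[cons$contigs_of[m]]], cons$maps[[m]],
                         cons$strands[m], s_cols, e_cols, kmin, kmax))
    valid <- !vapply(mats, is.null, logical(1))
    if (!any(valid)) next
    support <- Reduce(`+`, lapply(mats[valid], function(mk) (mk > 0L) * 1L))
    ksum <- Reduce(`+`, lapply(mats[valid], function(mk) mk))
    ## minimum span length guard
    span_ok <- outer(s_cols, e_cols, function(a, b) b - a >= 50L)
    support[!span_ok] <- 0L
    if (max(support) < min_support) next
    ord <- order(-support, -ksum, rep(s_cols, length(e_cols)),
                 rep(e_cols, each = length(s_cols)))
    ord <- ord[support[ord] >= min_support]
    ord <- utils::head(ord, 2000L)
    for (o in ord) {
      si <- (o - 1L) %% length(s_cols) + 1L
      ei <- (o - 1L) %/% length(s_cols) + 1L
      cs <- s_cols[si]; ce <- e_cols[ei]
      sup_m <- which(valid)[vapply(mats[valid],
                                   function(mk) mk[si, ei] > 0L, logical(1))]
      ## independent support only: overlapping extractions of adjacent
      ## copies can map several members onto the same genomic span
      span_key <- vapply(sup_m, function(m) {
        sp <- .member_span(cons$maps[[m]], cons$strands[m], cs, ce)
        if (is.null(sp)) NA_character_
        else paste(cons$contigs_of[m], sp[1], sp[2])
      }, character(1))
      sup_m <- sup_m[!is.na(span_key) & !duplicated(span_key)]
      if (length(sup_m) < min_support) next
      tsds <- vapply(sup_m, function(m)
        .member_tsd_seq(contigs[[cons$contigs_of[m]]], cons$maps[[m]],
                        cons$strands[m], cs, ce,
                        mats[[m]][si, ei]), character(1))
      tsds <- tsds[!is.na(tsds)]
      if (length(tsds) >= 2L && length(unique(tsds)) == 1L)
        next   # identical in all members: element-internal repeat, not a TSD
      nsup <- length(sup_m)
      ## chance-support guard: P(a random flank pair shows a >= k-mer exact
      ## duplication) ~ (4/3) * 4^-k; Bonferroni over the examined window
      ks <- vapply(sup_m, function(m) mats[[m]][si, ei], integer(1))
      p_ch <- (4 / 3) * 4^(-min(ks))
      bound <- choose(nm, nsup) * p_ch^nsup *
        length(s_cols) * length(e_cols)
      if (bound > sig_level) next
      cons <- .trim_consensus(cons, cs, ce)
      cons$boundary_status <- "tsd_confirmed"
      cons$iterations <- it
      seen <- character(0)
      cons$insertions <- lapply(seq_len(nm), function(m) {
        sp <- .member_span(cons$maps[[m]], cons$strands[m], 1L,
                           nchar(cons$sequence) + 1L)
        if (is.null(sp)) return(NULL)
        key <- paste(cons$contigs_of[m], sp[1], sp[2])
        if (key %in% seen) return(NULL)
        seen <<- c(seen, key)
        annotate_element(contigs, cons$contigs_of[m], sp[1], sp[2],
                         strand = cons$strands[m], source = "multicopy",
                         n_tsd_support = nsup)
      })
      cons$insertions <- Filter(Negate(is.null), cons$insertions)
      return(cons)
    }
  }
  cons <- .trim_consensus(cons, cand[1], cand[2])
  cons$boundary_status <- "unconfirmed"
  cons$iterations <- min(it, max_iter)
  cons$insertions <- list()
  cons
}
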