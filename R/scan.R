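#' Scanner parameters
#'
#' Parameters of the seeded, x-drop-extended local alignment scanner. The
#' upstream search tool used for repeat discovery does not publish its
#' internal parameters; these defaults are this package's documented
#' surrogate values, not claims about that tool.
#'
#' @param word_size exact seed length in bp (>= 4).
#' @param xdrop score drop-off terminating ungapped extension.
#' @param min_identity minimum hit identity in `(0,1]`.
#' @param min_hit_len minimum reported hit length in bp.
#' @param match,mismatch match/mismatch scores.
#' @return an object of class `scan_params`.
#' @export
scan_params <- function(word_size = 12L, xdrop = 20L, min_identity = 0.7,
                        min_hit_len = 50L, match = 1L, mismatch = -1L) {
  word_size <- as.integer(word_size)
  if (word_size < 4L) stop("word_size must be >= 4")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must lie in (0, 1]")
  if (match <= 0 || mismatch >= 0) stop("match > 0 and mismatch < 0 required")
  structure(list(word_size = word_size, xdrop = as.integer(xdrop),
                 min_identity = min_identity,
                 min_hit_len = as.integer(min_hit_len),
                 match = as.integer(match), mismatch = as.integer(mismatch)),
            class = "scan_params")
}

## rolling k-mer codes (base-4, numeric to allow w up to 26)
.kmer_codes <- function(v, w) {
  n <- length(v)
  if (n < w) return(numeric(0))
  m <- n - w + 1L
  code <- numeric(m)
  for (j in seq_len(w)) code <- code * 4 + v[j:(j + m - 1L)]
  code
}

## chunked ungapped x-drop extension along one diagonal.
## gv, qv: encoded sequences; t0, q0: first positions compared (1-based);
## dirn: +1 (rightward) or -1 (leftward).
.extend_xdrop <- function(gv, qv, t0, q0, dirn, p, chunk = 64L) {
  best_len <- 0L; best_score <- 0L; best_nm <- 0L
  score <- 0L; nm <- 0L; len <- 0L
  ng <- length(gv); nq <- length(qv)
  repeat {
    remaining <- if (dirn > 0L) min(ng - t0 - len + 1L, nq - q0 - len + 1L)
                 else min(t0 - len, q0 - len)
    if (remaining <= 0L) break
    k <- min(chunk, remaining)
    idx <- len:(len + k - 1L)
    m <- gv[t0 + dirn * idx] == qv[q0 + dirn * idx]
    sc <- score + cumsum(ifelse(m, p$match, p$mismatch))
    nmc <- nm + cumsum(m)
    ## running (prefix) best, seeded with the best from earlier chunks
    rb <- pmax(cummax(sc), best_score)
    drop <- which(rb - sc > p$xdrop)
    lim <- if (length(drop)) drop[1L] else k
    better <- which(sc[seq_len(lim)] > best_score)
    if (length(better)) {
      bi <- better[which.max(sc[better])]
      best_score <- sc[bi]; best_len <- len + bi; best_nm <- nmc[bi]
    }
    score <- sc[lim]; nm <- nmc[lim]; len <- len + lim
    if (length(drop)) break
  }
  list(len = best_len, score = best_score, nmatch = best_nm)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), contig = character(0),
             strand = character(0), qstart = integer(0), qend = integer(0),
             tstart = integer(0), tend = integer(0), length = integer(0),
             identity = numeric(0), score = integer(0),
             stringsAsFactors = FALSE)
}

## scan one oriented query against one contig (forward strand only);
## returns 0-based half-open coordinates on both axes
.scan_one <- function(subject, query, p) {
  gv <- .enc_dna(subject); qv <- .enc_dna(query)
  w <- p$word_size
  if (length(gv) < w || length(qv) < w) return(.empty_hits()[, 4:10])
  gs <- .kmer_codes(gv, w)
  qs <- .kmer_codes(qv, w)
  o <- order(qs)
  qsort <- qs[o]
  hi <- findInterval(gs, qsort)
  lo <- findInterval(gs - 0.5, qsort)
  cnt <- hi - lo
  keep <- which(cnt > 0L)
  if (!length(keep)) return(.empty_hits()[, 4:10])
  tpos <- rep.int(keep, cnt[keep])
  qidx <- sequence(cnt[keep]) + rep.int(lo[keep], cnt[keep])
  qpos <- o[qidx]
  dg <- tpos - qpos
  od <- order(dg, tpos)
  dgo <- dg[od]; tpo <- tpos[od]
  gap <- max(4L * w, 64L)
  nseed <- length(od)
  newrun <- c(TRUE, dgo[-1L] != dgo[-nseed] | tpo[-1L] - tpo[-nseed] > gap)
  rs <- which(newrun)
  re <- c(rs[-1L] - 1L, nseed)

  out <- vector("list", length(rs))
  nout <- 0L
  prev_diag <- NA_integer_; cov_end <- -1L
  for (r in seq_along(rs)) {
    d <- dgo[rs[r]]
    t1 <- tpo[rs[r]]; t2 <- tpo[re[r]]
    if (!is.na(prev_diag) && d == prev_diag) {
      if (t1 <= cov_end) next  # already covered by an extension on this diagonal
    } else {
      cov_end <- -1L
    }
    prev_diag <- d
    q1 <- t1 - d; q2 <- t2 - d
    core_m <- gv[t1:(t2 + w - 1L)] == qv[q1:(q2 + w - 1L)]
    core_nm <- sum(core_m)
    core_len <- t2 + w - t1
    le <- .extend_xdrop(gv, qv, t1 - 1L, q1 - 1L, -1L, p)
    rext <- .extend_xdrop(gv, qv, t2 + w, q2 + w, +1L, p)
    len <- core_len + le$len + rext$len
    nmatch <- core_nm + le$nmatch + rext$nmatch
    cov_end <- max(cov_end, t2 + w - 1L + rext$len)
    if (len < p$min_hit_len) next
    identity <- nmatch / len
    if (identity < p$min_identity) next
    nout <- nout + 1L
    out[[nout]] <- c(qstart = q1 - le$len - 1L,
                     qend = q2 + w - 1L + rext$len,
                     tstart = t1 - le$len - 1L,
                     tend = t2 + w - 1L + rext$len,
                     length = len, nmatch = nmatch)
  }
  if (!nout) return(.empty_hits()[, 4:10])
  m <- do.call(rbind, out[seq_len(nout)])
  df <- as.data.frame(m)
  df$identity <- df$nmatch / df$length
  df$score <- p$match * df$nmatch + p$mismatch * (df$length - df$nmatch)
  df$nmatch <- NULL
  df
}

#' Scan a genome for copies of a query element
#'
#' Finds local, ungapped seeded matches of the query on both strands of every
#' contig. Minus-strand hits report forward-strand target coordinates with
#' `strand == "-"`. Overlapping hits are deduplicated by (contig, strand,
#' span) with best score winning; hits wholly contained (on both axes) inside
#' a higher-scoring hit are dropped, which also removes the palindromic
#' self-matches produced by long terminal inverted repeats.
#'
#' @param genome named character vector of contigs (or DNAStringSet/path).
#' @param query DNA string (a reported element or consensus sequence).
#' @param params a [scan_params()].
#' @param query_id identifier recorded in the hit table.
#' @return data.frame of hits with 0-based half-open `qstart`/`qend` (query)
#'   and `tstart`/`tend` (forward target strand), `identity` and `score`.
#' @export
scan_genome <- function(genome, query, params = scan_params(),
                        query_id = "query") {
  stopifnot(inherits(params, "scan_params"))
  contigs <- .as_contigs(genome)
  query <- toupper(query)
  if (!length(contigs) || !nzchar(query)) return(.empty_hits())
  if (nchar(query) < params$word_size)
    stop("query shorter than word_size")
  qf <- query
  qr <- dna_revcomp(qf)
  Q <- nchar(qf)
  res <- list()
  for (ct in names(contigs)) {
    for (st in c("+", "-")) {
      h <- .scan_one(contigs[[ct]], if (st == "+") qf else qr, params)
      if (!nrow(h)) next
      if (st == "-") {
        tmp <- h$qstart
        h$qstart <- Q - h$qend
        h$qend <- Q - tmp
      }
      h$contig <- ct
      h$strand <- st
      h$query_id <- query_id
      res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) return(.empty_hits())
  df <- do.call(rbind, res)
  df <- df[, c("query_id", "contig", "strand", "qstart", "qend",
               "tstart", "tend", "length", "identity", "score")]
  ## exact-span dedup
  key <- paste(df$contig, df$strand, df$tstart, df$tend, df$qstart, df$qend)
  df <- df[!duplicated(key), , drop = FALSE]
  ## containment dedup (strand-agnostic within contig)
  df <- df[order(-df$score, df$tstart), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    contained <- df$contig[prior] == df$contig[i] &
      df$tstart[prior] <= df$tstart[i] & df$tend[prior] >= df$tend[i] &
      df$score[prior] >= df$score[i] &
      !(df$tstart[prior] == df$tstart[i] & df$tend[prior] == df$tend[i] &
          df$strand[prior] == df$strand[i])
    if (any(contained)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$tstart, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seq_hits", "data.frame")
  df
}

#' Chain collinear hit fragments
#'
#' Fragmented copies (interrupted by divergence or deletions) produce several
#' collinear hits; this chains hits on the same contig and strand whose
#' target and query gaps are both at most `max_gap`, by dynamic programming
#' maximizing total covered length. Identity is recomputed over covered
#' positions.
#'
#' @param hits a hit table from [scan_genome()].
#' @param max_gap maximum gap (bp) on both target and query axes.
#' @return chained hit table of the same shape.
#' @export
merge_hits <- function(hits, max_gap = 50L) {
  if (!nrow(hits)) return(hits)
  groups <- split(seq_len(nrow(hits)),
                  paste(hits$query_id, hits$contig, hits$strand))
  res <- list()
  for (idx in groups) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$tstart), , drop = FALSE]
    n <- nrow(h)
    minus <- h$strand[1] == "-"
    best <- h$length; prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        tgap <- h$tstart[i] - h$tend[j]
        qgap <- if (minus) h$qstart[j] - h$qend[i] else h$qstart[i] - h$qend[j]
        if (tgap >= 0L && tgap <= max_gap && qgap >= 0L && qgap <= max_gap &&
            best[j] + h$length[i] > best[i]) {
          best[i] <- best[j] + h$length[i]
          prev[i] <- j
        }
      }
    }
    used <- rep(FALSE, n)
    repeat {
      cand <- which(!used)
      if (!length(cand)) break
      i <- cand[which.max(best[cand])]
      chain <- integer(0)
      while (i != 0L && !used[i]) {
        chain <- c(i, chain)
        used[i] <- TRUE
        i <- prev[i]
      }
      ch <- h[chain, , drop = FALSE]
      covered <- sum(ch$length)
      nmatch <- sum(ch$identity * ch$length)
      res[[length(res) + 1L]] <- data.frame(
        query_id = ch$query_id[1], contig = ch$contig[1],
        strand = ch$strand[1], qstart = min(ch$qstart), qend = max(ch$qend),
        tstart = min(ch$tstart), tend = max(ch$tend),
        length = covered, identity = nmatch / covered,
        score = sum(ch$score), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, res)
  df <- df[order(df$contig, df$tstart, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seq_hits", "data.frame")
  df
}

#' Extract a hit with flanking sequence
#'
#' Returns the target region `[tstart - flank, tend + flank)` clipped at
#' contig edges. Minus-strand hits are reverse-complemented so the element
#' reads in query orientation; the returned offsets locate the hit inside
#' the extracted sequence.
#'
#' @param genome named character vector of contigs.
#' @param hit one row of a hit table.
#' @param flank flank length in bp.
#' @return list with `seq`, `offset` (0-based start of the hit within `seq`),
#'   `hit_len`, `ext_start`/`ext_end` (0-based half-open genomic span of the
#'   extraction), `strand`, `contig`, `clipped_left`, `clipped_right`.
#' @export
extract_with_flanks <- function(genome, hit, flank = 1000L) {
  contigs <- .as_contigs(genome)
  s <- contigs[[hit$contig]]
  stopifnot(!is.null(s), hit$tstart >= 0L, hit$tend <= nchar(s))
  ext_s <- max(0L, hit$tstart - flank)
  ext_e <- min(nchar(s), hit$tend + flank)
  seqn <- .sub0(s, ext_s, ext_e)
  left <- hit$tstart - ext_s
  right <- ext_e - hit$tend
  offset <- left
  if (hit$strand == "-") {
    seqn <- dna_revcomp(seqn)
    offset <- right
  }
  list(seq = seqn, offset = offset, hit_len = hit$tend - hit$tstart,
       ext_start = ext_s, ext_end = ext_e, strand = hit$strand,
       contig = hit$contig,
       clipped_left = (hit$tstart - flank) < 0L,
       clipped_right = (hit$tend + flank) > nchar(s))
}

#' Write a hit table to TSV
#'
#' @param hits hit table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
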