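#' Call a target site duplication from element flanks
#'
#' Returns the largest k in `[kmin, kmax]` for which the last k bases of the
#' left flank exactly equal the first k bases of the right flank, the
#' footprint left by target-site duplication on integration. Length 0 means
#' no duplication was found. Matching is exact: the figures supporting the
#' 9/10-bp (AcademH) and 3/4-bp (AcademX) duplication lengths show identical
#' copies on both sides.
#'
#' @param left_flank,right_flank DNA strings immediately left and right of
#'   the element.
#' @param kmin,kmax smallest/largest duplication length searched.
#' @return object of class `tsd_call`: list with `length`, `left_seq`,
#'   `right_seq`, `exact`, `warning` (TRUE when a flank was shorter than
#'   `kmax`).
#' @export
call_tsd <- function(left_flank, right_flank, kmin = 2L, kmax = 12L) {
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  warn <- FALSE
  kcap <- min(kmax, nl, nr)
  if (kcap < kmax) warn <- TRUE
  if (kcap >= kmin) {
    for (k in kcap:kmin) {
      l <- substr(left_flank, nl - k + 1L, nl)
      r <- substr(right_flank, 1L, k)
      if (l == r) {
        return(structure(list(length = k, left_seq = l, right_seq = r,
                              exact = TRUE, warning = warn),
                         class = "tsd_call"))
      }
    }
  }
  structure(list(length = 0L, left_seq = "", right_seq = "", exact = FALSE,
                 warning = warn), class = "tsd_call")
}

#' Detect a terminal inverted repeat
#'
#' Compares the element prefix against the reverse complement of its suffix,
#' ungapped from the termini inward, and reports the maximal-scoring span
#' under +1/mismatch-penalty scoring where the penalty is
#' `min_identity/(1 - min_identity)` (so the score is non-negative exactly
#' when identity is at least `min_identity`). The reported span always starts
#' and ends on a match and must reach `min_len` and `min_identity`;
#' otherwise length 0 is returned. Academ TIRs span 8 bp (e.g.
#' AcademH-2_PSt) to 575 bp (AcademH-16_CVi).
#'
#' @param element DNA string of the candidate element.
#' @param min_len minimum reportable TIR length (bp).
#' @param max_scan maximum terminal span examined (bp).
#' @param min_identity minimum identity of the reported span.
#' @param xdrop score drop-off terminating the inward scan.
#' @return object of class `tir_call`: list with `length`, `mismatches`,
#'   `identity`.
#' @export
detect_tir <- function(element, min_len = 8L, max_scan = 1000L,
                       min_identity = 0.8, xdrop = 20) {
  L <- nchar(element)
  out0 <- structure(list(length = 0L, mismatches = 0L, identity = NA_real_),
                    class = "tir_call")
  w <- min(L %/% 2L, max_scan)
  if (w < 1L || L < 2L * min_len) return(out0)
  pv <- .enc_dna(substr(element, 1L, w))
  sv <- .enc_dna(substr(element, L - w + 1L, L))
  m <- pv == (3L - rev(sv))   # complement in 0..3 coding is 3 - code
  if (!m[1]) return(out0)
  penalty <- min_identity / (1 - min_identity)
  sc <- cumsum(ifelse(m, 1, -penalty))
  best <- cummax(sc)
  stop_at <- which(best - sc > xdrop)
  lim <- if (length(stop_at)) stop_at[1] else w
  k <- which.max(sc[seq_len(lim)])
  nm <- sum(m[seq_len(k)])
  identity <- nm / k
  if (k < min_len || identity < min_identity) return(out0)
  structure(list(length = as.integer(k), mismatches = as.integer(k - nm),
                 identity = identity), class = "tir_call")
}

#' Check the terminal base composition of an element
#'
#' Almost all Academ families start with a pyrimidine (C or T) at the 5'
#' terminus and end with a purine (G or A) at the 3' terminus.
#'
#' @param element DNA string.
#' @return list with logical `terminal_5_ok` and `terminal_3_ok`.
#' @export
terminal_motif_check <- function(element) {
  stopifnot(nzchar(element))
  list(terminal_5_ok = substr(element, 1L, 1L) %in% c("C", "T"),
       terminal_3_ok = substr(element, nchar(element), nchar(element)) %in%
         c("G", "A"))
}

#' Annotate one candidate element span
#'
#' Computes the TSD call (from the immediately adjacent flanks), TIR call,
#' terminal-motif flags and the acceptance flag for a genomic span.
#'
#' @param genome named character vector of contigs.
#' @param contig contig name.
#' @param start0,end0 0-based half-open span of the element.
#' @param strand `"+"` or `"-"` (the element is examined in its own
#'   orientation; TSDs are called on the forward strand).
#' @param source `"multicopy"` or `"single_copy"` (selects the acceptance
#'   rule, see [accept_element()]).
#' @param n_tsd_support number of family members supporting the same TSD
#'   boundaries (multicopy evidence).
#' @param kmax,min_tir_len,max_scan,min_tir_identity caller parameters.
#' @return object of class `element_annotation`.
#' @export
annotate_element <- function(genome, contig, start0, end0, strand = "+",
                             source = c("multicopy", "single_copy"),
                             n_tsd_support = 1L, kmax = 12L,
                             min_tir_len = 8L, max_scan = 1000L,
                             min_tir_identity = 0.8) {
  source <- match.arg(source)
  contigs <- .as_contigs(genome)
  s <- contigs[[contig]]
  stopifnot(!is.null(s), start0 >= 0L, end0 <= nchar(s), start0 < end0)
  left <- .sub0(s, max(0L, start0 - kmax), start0)
  right <- .sub0(s, end0, min(nchar(s), end0 + kmax))
  tsd <- call_tsd(left, right, kmax = kmax)
  el <- .sub0(s, start0, end0)
  if (strand == "-") el <- dna_revcomp(el)
  tir <- detect_tir(el, min_len = min_tir_len, max_scan = max_scan,
                    min_identity = min_tir_identity)
  tm <- terminal_motif_check(el)
  ann <- structure(list(contig = contig, start = start0, end = end0,
                        strand = strand, tsd = tsd, tir = tir,
                        terminal_5_ok = tm$terminal_5_ok,
                        terminal_3_ok = tm$terminal_3_ok,
                        source = source,
                        n_tsd_support = as.integer(n_tsd_support),
                        accepted_full_length = FALSE),
                   class = "element_annotation")
  ann$accepted_full_length <- accept_element(ann)
  ann
}

#' @export
print.element_annotation <- function(x, ...) {
  cat(sprintf("<element_annotation> %s:%d-%d(%s) TSD %d bp, TIR %d bp, 5'%s 3'%s, %s, %s\n",
              x$contig, x$start, x$end, x$strand, x$tsd$length, x$tir$length,
              if (x$terminal_5_ok) "ok" else "no",
              if (x$terminal_3_ok) "ok" else "no", x$source,
              if (x$accepted_full_length) "accepted" else "not accepted"))
  invisible(x)
}

#' Full-length acceptance rule
#'
#' Single-copy candidates are accepted as full-length Academ transposons iff
#' the TIR is longer than 10 bp and an adjacent TSD longer than 8 bp is
#' present (both strict inequalities), the rule applied to single-copy
#' AcademH candidates within 10,000-bp flanking windows. Multicopy elements
#' are accepted when a TSD of at least 3 bp is supported by at least two
#' independent member insertions at the same boundaries.
#'
#' @param annotation an `element_annotation`.
#' @param flank_window window (bp) within which flanks were drawn; flanks
#'   used by [annotate_element()] are immediately adjacent, hence always
#'   within the window.
#' @return logical acceptance flag.
#' @export
accept_element <- function(annotation, flank_window = 10000L) {
  stopifnot(inherits(annotation, "element_annotation"))
  if (annotation$source == "single_copy") {
    annotation$tir$length > 10L && annotation$tsd$length > 8L
  } else {
    annotation$tsd$length >= 3L && annotation$n_tsd_support >= 2L
  }
}

#' Refine element boundaries around a candidate span
#'
#' Evaluates boundary pairs within `search_radius` of the candidate start
#' and end. Because an accepted element requires TSDs immediately adjacent
#' to its terminal inverted repeats, candidate pairs whose element shows a
#' TIR (length at least `min_tir_len`) are preferred; among them the pair
#' maximizing, lexicographically, (1) TSD length, (2) TIR length,
#' (3) terminal-motif flags, (4) leftmost start then end wins. When no
#' boundary pair in the window shows a TIR the same ordering is applied
#' without the TIR requirement (elements without TIRs remain annotatable),
#' and when no pair shows a TSD at all, ranking falls back to TIR length,
#' motif flags and leftmost position. TIR length is ranked on a capped
#' terminal window (`tir_rank_cap`); the winner is re-annotated with the
#' full-depth TIR scan.
#'
#' @param genome named character vector of contigs.
#' @param contig,start0,end0,strand candidate span (0-based half-open).
#' @param search_radius radius (bp) searched around each boundary.
#' @param source,n_tsd_support passed to [annotate_element()].
#' @param kmax maximum TSD length searched.
#' @param min_tir_len minimum span counting as a TIR-bearing boundary.
#' @param tir_rank_cap terminal window used while ranking candidate pairs.
#' @return the refined `element_annotation`.
#' @export
refine_boundaries <- function(genome, contig, start0, end0, strand = "+",
                              search_radius = 50L,
                              source = "multicopy", n_tsd_support = 1L,
                              kmax = 12L, min_tir_len = 8L,
                              tir_rank_cap = 200L) {
  contigs <- .as_contigs(genome)
  s <- contigs[[contig]]
  stopifnot(!is.null(s))
  n <- nchar(s)
  ss <- max(kmax, start0 - search_radius):min(n - 1L, start0 + search_radius)
  ee <- max(1L, end0 - search_radius):min(n - kmax, end0 + search_radius)
  ee <- ee[ee > min(ss) + 10L]
  stopifnot(length(ss) > 0L, length(ee) > 0L)

  eval_pairs <- function(pairs) {
    tirlen <- integer(nrow(pairs))
    flags <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      el <- .sub0(s, pairs$start0[i], pairs$end0[i])
      if (strand == "-") el <- dna_revcomp(el)
      tc <- detect_tir(el, min_len = min_tir_len, max_scan = tir_rank_cap)
      tirlen[i] <- tc$length
      tm <- terminal_motif_check(el)
      flags[i] <- tm$terminal_5_ok + tm$terminal_3_ok
    }
    cbind(pairs, tir = tirlen, flags = flags)
  }
  pick <- function(pe) {
    pe[order(-pe$tir, -pe$flags, pe$start0, pe$end0)[1], , drop = FALSE]
  }

  fallback <- NULL   # best TSD-bearing pair without a TIR, largest k first
  for (k in kmax:2L) {
    lefts <- substring(s, ss - k + 1L, ss)
    rights <- substring(s, ee + 1L, ee + k)
    eqm <- outer(lefts, rights, "==") & outer(ss, ee, function(a, b) b > a + 10L)
    if (!any(eqm)) next
    idx <- which(eqm, arr.ind = TRUE)
    pe <- eval_pairs(data.frame(start0 = ss[idx[, 1]], end0 = ee[idx[, 2]]))
    with_tir <- pe[pe$tir >= min_tir_len, , drop = FALSE]
    if (nrow(with_tir)) {
      w <- pick(with_tir)
      return(annotate_element(genome, contig, w$start0, w$end0,
                              strand = strand, source = source,
                              n_tsd_support = n_tsd_support, kmax = kmax,
                              min_tir_len = min_tir_len))
    }
    if (is.null(fallback)) fallback <- pick(pe)
  }
  if (!is.null(fallback)) {
    return(annotate_element(genome, contig, fallback$start0, fallback$end0,
                            strand = strand, source = source,
                            n_tsd_support = n_tsd_support, kmax = kmax,
                            min_tir_len = min_tir_len))
  }
  ## no TSD anywhere in the window: rank all pairs by TIR, flags, leftmost
  pairs <- expand.grid(start0 = ss, end0 = ee)
  pairs <- pairs[pairs$end0 > pairs$start0 + 10L, , drop = FALSE]
  w <- pick(eval_pairs(pairs))
  annotate_element(genome, contig, w$start0, w$end0, strand = strand,
                   source = source, n_tsd_support = n_tsd_support,
                   kmax = kmax, min_tir_len = min_tir_len)
}
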