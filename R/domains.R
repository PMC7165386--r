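## all matches of a PCRE pattern; data.frame(start, end) 1-based inclusive
.regex_hits <- function(protein, pattern) {
  m <- gregexpr(pattern, protein, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Scan a transposase for the Academ DDE catalytic triad
#'
#' Searches for a first catalytic D and a second catalytic D separated by
#' 138-192 residues (the unusually long D-D spacing of Academ transposases),
#' a `[GAEQ]xxH` motif starting within 20 residues downstream of the second
#' D, and a catalytic E 150-350 residues downstream of the second D (leaving
#' room for the alpha-helical insertion domain). Among candidate D pairs the
#' one with spacing closest to 165 wins; ties go to the leftmost pair.
#' Positions are 1-based residue indices.
#'
#' @param protein amino-acid string (>= 250 residues for a meaningful scan).
#' @return `NULL` when absent, else object of class `dde_triad`: list with
#'   `d1_pos`, `d2_pos`, `e_pos`, `d1_d2_spacing`, `post_d2_motif`.
#' @export
scan_dde_triad <- function(protein) {
  n <- nchar(protein)
  if (n < 250L) return(NULL)
  v <- strsplit(protein, "")[[1]]
  dpos <- which(v == "D")
  epos <- which(v == "E")
  if (length(dpos) < 2L || !length(epos)) return(NULL)
  best <- NULL
  for (i in dpos) {
    js <- dpos[dpos - i >= 138L & dpos - i <= 192L]
    for (j in js) {
      seg <- substr(protein, j + 1L, min(j + 23L, n))
      mm <- regexpr("[GAEQ].{2}H", seg, perl = TRUE)
      if (mm[1] == -1L || mm[1] > 20L) next
      e <- epos[epos >= j + 150L & epos <= j + 350L]
      if (!length(e)) next
      cand <- list(d1_pos = i, d2_pos = j, e_pos = e[1],
                   d1_d2_spacing = j - i,
                   post_d2_motif = substr(seg, mm[1], mm[1] + 3L))
      if (is.null(best) ||
          abs(cand$d1_d2_spacing - 165L) < abs(best$d1_d2_spacing - 165L))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "dde_triad")
}

#' Scan a protein for superfamily 2 helicase motifs
#'
#' Reports an SF2 helicase hit iff the canonical motifs occur in order with
#' plausible spacing: Walker A (`[AG]xxxxGK[TS]`), motif II (`DExH`/`DExD`)
#' and a motif VI-like `QxxGRxxR`, each motif starting at least 10 residues
#' after the previous one and the full span at most 500 residues. The
#' patterns are this package's documented surrogate for the conserved
#' catalytic, nucleic-acid-binding and ATP-binding motifs of the
#' RecQ-related helicases encoded by AcademH.
#'
#' @param protein amino-acid string.
#' @return data.frame of domain hits (possibly empty): `kind`, `start`,
#'   `end` (1-based residue span), `evidence`.
#' @export
scan_helicase <- function(protein) {
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(protein) < 200L) return(empty)
  wa <- .regex_hits(protein, academ_motifs$walker_a)
  m2 <- .regex_hits(protein, academ_motifs$helicase_ii)
  m6 <- .regex_hits(protein, academ_motifs$helicase_vi)
  if (!nrow(wa) || !nrow(m2) || !nrow(m6)) return(empty)
  for (a in seq_len(nrow(wa))) for (b in seq_len(nrow(m2))) {
    if (m2$start[b] < wa$start[a] + 10L) next
    for (d in seq_len(nrow(m6))) {
      if (m6$start[d] < m2$start[b] + 10L) next
      if (m6$end[d] - wa$start[a] > 500L) next
      ev <- sprintf("WalkerA@%d;II@%d;VI@%d", wa$start[a], m2$start[b],
                    m6$start[d])
      return(data.frame(kind = "helicase_SF2", start = wa$start[a],
                        end = m6$end[d], evidence = ev,
                        stringsAsFactors = FALSE))
    }
  }
  empty
}

#' Count PHD fingers (Cys4-His-Cys3) in a protein
#'
#' Counts non-overlapping, leftmost matches of the Cys4-His-Cys3 pattern
#' (one histidine sandwiched by four and three cysteines) characteristic of
#' the PHD fingers inserted between the second D and the last E of AcademHP
#' transposases. Spacer bounds are a documented design decision.
#'
#' @param protein amino-acid string.
#' @return list with `count` and `hits` (data.frame `kind`, `start`, `end`,
#'   `evidence`).
#' @export
scan_phd <- function(protein) {
  h <- .regex_hits(protein, academ_motifs$phd)
  hits <- if (nrow(h)) data.frame(kind = "PHD_finger", start = h$start,
                                  end = h$end,
                                  evidence = substring(protein, h$start, h$end),
                                  stringsAsFactors = FALSE)
          else data.frame(kind = character(0), start = integer(0),
                          end = integer(0), evidence = character(0),
                          stringsAsFactors = FALSE)
  list(count = nrow(h), hits = hits)
}

#' Scan for CCHH zinc fingers
#'
#' Matches `C-x(2,6)-C-x(8,20)-H-x(2,6)-H`. When a DDE triad is supplied,
#' hits positioned between the second D and the catalytic E are flagged as
#' the diagnostic inter-catalytic finger carried by animal AcademH
#' transposases.
#'
#' @param protein amino-acid string.
#' @param triad optional `dde_triad` for the same protein.
#' @return data.frame `kind`, `start`, `end`, `evidence`,
#'   `inter_catalytic`.
#' @export
scan_cchh <- function(protein, triad = NULL) {
  h <- .regex_hits(protein, academ_motifs$cchh)
  if (!nrow(h)) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), evidence = character(0),
                      inter_catalytic = logical(0), stringsAsFactors = FALSE))
  }
  flag <- rep(FALSE, nrow(h))
  if (!is.null(triad))
    flag <- h$start > triad$d2_pos & h$end < triad$e_pos
  data.frame(kind = "CCHH_znf", start = h$start, end = h$end,
             evidence = substring(protein, h$start, h$end),
             inter_catalytic = flag, stringsAsFactors = FALSE)
}

## XPG nuclease / Cys8 zinc finger placeholder scanners (documented patterns)
.scan_xpg <- function(protein) {
  n1 <- .regex_hits(protein, academ_motifs$xpg_n)
  n2 <- .regex_hits(protein, academ_motifs$xpg_i)
  if (!nrow(n1) || !nrow(n2)) return(NULL)
  ok <- which(outer(n1$end, n2$start, `<`), arr.ind = TRUE)
  if (!nrow(ok)) return(NULL)
  a <- ok[1, 1]; b <- ok[1, 2]
  list(start = n1$start[a], end = n2$end[b],
       evidence = sprintf("XPG-N@%d;XPG-I@%d", n1$start[a], n2$start[b]))
}

.scan_cys8 <- function(protein) {
  h <- .regex_hits(protein, academ_motifs$cys8)
  if (!nrow(h)) return(NULL)
  list(start = h$start[1], end = h$end[1],
       evidence = substring(protein, h$start[1], h$end[1]))
}

#' Scan the ORFs of an element for diagnostic domains
#'
#' Runs all domain scanners on each ORF protein and collects the hits.
#'
#' @param orfs data.frame from [find_orfs()].
#' @return data.frame with `orf_index`, `kind`, `start`, `end`, `evidence`,
#'   plus a `phd_count` attribute-free column for PHD hits.
#' @export
scan_domains <- function(orfs) {
  rows <- list()
  add <- function(oi, kind, start, end, evidence) {
    rows[[length(rows) + 1L]] <<- data.frame(
      orf_index = oi, kind = kind, start = start, end = end,
      evidence = evidence, stringsAsFactors = FALSE)
  }
  for (oi in seq_len(nrow(orfs))) {
    prot <- orfs$protein[oi]
    triad <- scan_dde_triad(prot)
    if (!is.null(triad)) {
      add(oi, "transposase_core", triad$d1_pos, triad$e_pos,
          sprintf("DDE:%d,%d,%d;%s", triad$d1_pos, triad$d2_pos,
                  triad$e_pos, triad$post_d2_motif))
      phd <- scan_phd(prot)
      if (phd$count > 0L) for (r in seq_len(phd$count))
        add(oi, "PHD_finger", phd$hits$start[r], phd$hits$end[r],
            phd$hits$evidence[r])
      cchh <- scan_cchh(prot, triad)
      if (nrow(cchh)) for (r in seq_len(nrow(cchh)))
        add(oi, "CCHH_znf", cchh$start[r], cchh$end[r],
            sprintf("%s%s", cchh$evidence[r],
                    if (cchh$inter_catalytic[r]) ";inter_catalytic" else ""))
      xpg <- .scan_xpg(prot)
      if (!is.null(xpg)) add(oi, "XPG_nuclease", xpg$start, xpg$end,
                             xpg$evidence)
      c8 <- .scan_cys8(prot)
      if (!is.null(c8)) add(oi, "Cys8_znf", c8$start, c8$end, c8$evidence)
    }
    hel <- scan_helicase(prot)
    if (nrow(hel)) add(oi, "helicase_SF2", hel$start, hel$end, hel$evidence)
  }
  if (!length(rows)) {
    return(data.frame(orf_index = integer(0), kind = character(0),
                      start = integer(0), end = integer(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Call the coding architecture of an element
#'
#' Decision rules: `two_orf_opposite_helicase` when one ORF carries a
#' transposase core and a different, non-overlapping ORF on the opposite
#' strand carries SF2 helicase motifs (the AcademH layout: two proteins
#' encoded in opposite directions without overlapping);
#' `single_orf_xpg` when a single ORF carries both the transposase core and
#' XPG-nuclease evidence (the AcademX layout); `no_coding` when no ORF has
#' transposase or helicase evidence; `other` otherwise, including the
#' conflicting case where both helicase and XPG evidence are present.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param domain_hits data.frame from [scan_domains()].
#' @return object of class `architecture_call`: list with `kind`,
#'   `orf_indices`, `notes`.
#' @export
call_architecture <- function(orfs, domain_hits) {
  mk <- function(kind, idx = integer(0), notes = "") {
    structure(list(kind = kind, orf_indices = idx, notes = notes),
              class = "architecture_call")
  }
  if (!nrow(domain_hits)) return(mk("no_coding"))
  tr <- unique(domain_hits$orf_index[domain_hits$kind == "transposase_core"])
  hel <- unique(domain_hits$orf_index[domain_hits$kind == "helicase_SF2"])
  xpg <- unique(domain_hits$orf_index[domain_hits$kind == "XPG_nuclease"])
  if (length(hel) && length(xpg))
    return(mk("other", sort(unique(c(tr, hel, xpg))),
              "conflicting evidence: helicase and XPG both present"))
  for (ti in tr) for (hi in hel) {
    if (ti == hi) next
    if (orfs$strand[ti] == orfs$strand[hi]) next
    overlap <- orfs$start0[ti] < orfs$end0[hi] &&
      orfs$start0[hi] < orfs$end0[ti]
    if (!overlap) return(mk("two_orf_opposite_helicase", c(ti, hi)))
  }
  for (ti in tr) if (ti %in% xpg) return(mk("single_orf_xpg", ti))
  if (!length(tr) && !length(hel)) return(mk("no_coding"))
  mk("other", sort(unique(c(tr, hel, xpg))),
     "evidence present but no lineage-defining layout")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(sprintf("<architecture_call> %s (ORFs: %s)%s\n", x$kind,
              if (length(x$orf_indices)) paste(x$orf_indices, collapse = ",")
              else "none",
              if (nzchar(x$notes)) paste0(" - ", x$notes) else ""))
  invisible(x)
}
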