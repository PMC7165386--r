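## Diagnostic protein motif patterns (PCRE) used by the domain scanners and,
## symmetrically, by the synthetic cassette templates. The SF2 helicase,
## PHD and CCHH patterns are canonical field patterns; the XPG and Cys8
## patterns are documented placeholders (no residue-level description of
## those domains is available), used consistently by generator and scanner.
academ_motifs <- list(
  walker_a    = "[AG].{4}GK[TS]",
  helicase_ii = "DE.[HD]",
  helicase_vi = "Q.{2}GR.{2}R",
  gaeq_h      = "[GAEQ].{2}H",
  phd         = "C.{1,6}?C.{8,30}?C.{1,6}?C.{1,6}?H.{1,6}?C.{8,30}?C.{1,6}?C",
  cchh        = "C.{2,6}?C.{8,20}?H.{2,6}?H",
  xpg_n       = "G[IV]DA[LIVMF]",
  xpg_i       = "E[AV]D[LIVMF]{2}E",
  cys8        = "C.{2,4}?C.{6,20}?C.{2,4}?C.{4,20}?C.{2,4}?C.{6,20}?C.{2,4}?C"
)

## Background alphabet for synthetic protein spacers: excludes C, D, E, G, H
## so that no diagnostic motif can arise outside the planted positions.
.AA_BG <- c("A", "F", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T",
            "V", "W", "Y")

.aa_bg <- function(n) {
  if (n < 0) stop("synthetic protein template does not fit: negative spacer")
  if (n == 0) return("")
  paste(sample(.AA_BG, n, replace = TRUE), collapse = "")
}

## One Cys4-His-Cys3 PHD finger (34 aa) with background spacers
.phd_finger <- function() {
  paste0("C", .aa_bg(2), "C", .aa_bg(8), "C", .aa_bg(2), "C", .aa_bg(2),
         "H", .aa_bg(2), "C", .aa_bg(8), "C", .aa_bg(2), "C")
}

## One CCHH zinc finger (19 aa)
.cchh_finger <- function() {
  paste0("C", .aa_bg(2), "C", .aa_bg(10), "H", .aa_bg(3), "H")
}

## Eight-cysteine zinc finger placeholder (38 aa)
.cys8_finger <- function() {
  paste0("C", .aa_bg(2), "C", .aa_bg(8), "C", .aa_bg(2), "C", .aa_bg(6),
         "C", .aa_bg(2), "C", .aa_bg(8), "C", .aa_bg(2), "C")
}

#' Synthetic Academ transposase protein template
#'
#' Builds an artificial transposase amino-acid sequence carrying the
#' diagnostic features of Academ transposases: a DDE catalytic triad with
#' the first and second aspartates 165 residues apart, a GxxH motif 5
#' residues after the second D, the catalytic glutamate 220 residues after
#' the second D, and optional zinc-finger insertions between the second D
#' and the E (PHD fingers for AcademHP, a CCHH finger for animal AcademH).
#' AcademX-style templates add XPG-nuclease and Cys8 zinc-finger placeholder
#' motifs downstream of the catalytic E. Spacer residues are drawn from an
#' alphabet free of C/D/E/G/H so planted motifs are the only motif matches.
#'
#' @param phd number of PHD fingers to embed (0, 1 or 2).
#' @param cchh embed one CCHH zinc finger between D2 and E.
#' @param xpg append XPG nuclease and Cys8 zinc-finger placeholder motifs.
#' @return character protein sequence; attributes `d1`, `d2`, `e` give the
#'   1-based positions of the catalytic residues.
#' @export
transposase_template <- function(phd = 0L, cchh = FALSE, xpg = FALSE) {
  stopifnot(phd %in% 0:2, !(phd > 0 && cchh))
  pre <- .aa_bg(50)                       # D1 at 51
  mid <- .aa_bg(164)                      # D2 at 216
  post_d2 <- paste0(.aa_bg(4), "G", .aa_bg(2), "H")  # GxxH at D2+5..D2+8
  zone_len <- 211                          # D2+9 .. D2+219; E at D2+220
  fingers <- ""
  if (phd >= 1L) {
    fingers <- .phd_finger()
    if (phd == 2L) fingers <- paste0(fingers, .aa_bg(10), .phd_finger())
  } else if (cchh) {
    fingers <- .cchh_finger()
  }
  pre_f <- .aa_bg(21)
  fill <- zone_len - 21L - nchar(fingers)
  zone <- paste0(pre_f, fingers, .aa_bg(fill))
  prot <- paste0(pre, "D", mid, "D", post_d2, zone, "E")
  if (xpg) {
    prot <- paste0(prot, .aa_bg(30), "GIDAL", .aa_bg(25), "EADLLE",
                   .aa_bg(20), .cys8_finger())
  }
  target <- if (xpg) 560L else 480L
  prot <- paste0(prot, .aa_bg(target - nchar(prot)))
  attr(prot, "d1") <- 51L
  attr(prot, "d2") <- 216L
  attr(prot, "e") <- 436L
  prot
}

#' Synthetic SF2 helicase protein template
#'
#' Artificial helicase amino-acid sequence with the three ordered motifs the
#' scanner requires: Walker A (`AQTGSGKT`), motif II (`DEAH`) and motif VI
#' (`QAAGRAAR`), on a background alphabet free of C/D/E/G/H.
#'
#' @return character protein sequence of 420 residues.
#' @export
helicase_template <- function() {
  paste0(.aa_bg(59), "AQTGSGKT",     # Walker A at 60
         .aa_bg(92), "DEAH",         # motif II at 160
         .aa_bg(156), "QAAGRAAR",    # motif VI at 320
         .aa_bg(93))                 # total 420
}

## codon table (no stops) for reverse translation
.CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
})

#' Reverse-translate a protein into DNA
#'
#' Synonymous codons are sampled uniformly with the session RNG.
#'
#' @param protein amino-acid string (no stops).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(.CODONS))
  if (length(bad)) stop("cannot reverse-translate residues: ",
                        paste(bad, collapse = ","))
  paste(vapply(aa, function(a) {
    cs <- .CODONS[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}
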