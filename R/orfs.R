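#' Find open reading frames in all six frames
#'
#' Reports every maximal stop-to-stop ORF of at least `min_aa` residues
#' (standard genetic code, stop-terminated, no start-codon requirement —
#' an intron-naive surrogate for gene prediction on repeat consensus
#' sequences). Minus-strand ORFs carry forward-strand coordinates and
#' `strand == "-"`. The ORF span includes the terminating stop codon, so
#' `end - start` is `3 * (protein length + 1)`.
#'
#' @param element DNA string.
#' @param min_aa minimum protein length in residues.
#' @return data.frame with `start0`, `end0` (0-based half-open on the
#'   element), `strand`, `frame` (0..2 within the strand) and `protein`.
#' @export
find_orfs <- function(element, min_aa = 100L) {
  L <- nchar(element)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") element else dna_revcomp(element)
    for (f in 0:2) {
      naa <- (L - f) %/% 3L
      if (naa < min_aa + 1L) next
      dna <- Biostrings::DNAString(substr(s, f + 1L, f + 3L * naa))
      aa <- as.character(suppressWarnings(Biostrings::translate(
        dna, if.fuzzy.codon = "X", no.init.codon = TRUE)))
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
      for (i in seq_len(length(stops) - 1L)) {
        a <- stops[i] + 1L      # first residue of segment (1-based aa index)
        b <- stops[i + 1L] - 1L # last residue before the stop
        plen <- b - a + 1L
        if (plen < min_aa) next
        prot <- substr(aa, a, b)
        ## nt span on strand s, including the trailing stop codon
        s0 <- f + 3L * (a - 1L)
        e0 <- f + 3L * (b + 1L)
        if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        out[[length(out) + 1L]] <- data.frame(
          start0 = s0, end0 = e0, strand = strand, frame = f,
          protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start0, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
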