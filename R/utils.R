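#' @keywords internal
"_PACKAGE"

.BASES <- c("A", "C", "G", "T")

## DNA string -> integer codes 0..3 (A,C,G,T). Assumes uppercase ACGT.
.enc_dna <- function(x) {
  v <- utf8ToInt(x)
  out <- integer(length(v))
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

.dec_dna <- function(v) {
  paste(.BASES[v + 1L], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement without reversal
.dna_comp <- function(x) chartr("ACGT", "TGCA", x)

## substring with 0-based half-open coordinates
.sub0 <- function(s, start0, end0) substr(s, start0 + 1L, end0)

#' Random DNA sequence
#'
#' @param n length in bp.
#' @param gc GC content in `[0,1]`; 0.5 gives i.i.d. uniform bases.
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

## modal value of an integer vector; ties -> smallest
.modal <- function(x) {
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

## coerce genome input (named character vector, DNAStringSet, FASTA path)
## to a named character vector of contigs
.as_contigs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "XStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.list(genome) && !is.null(genome$contigs)) return(.as_contigs(genome$contigs))
  stopifnot(is.character(genome))
  if (length(genome) && is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  toupper(genome)
}

.write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

## simple GFF3 writer: df with seqid, start0, end0, strand, type, attrs (character)
.write_gff3 <- function(df, path, source = "academscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     df$seqid, source, df$type,
                     df$start0 + 1L, df$end0, df$strand, df$attrs)
    writeLines(lines, con)
  }
  invisible(path)
}
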