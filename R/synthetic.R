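#' Random background genome
#'
#' Generates i.i.d. random contigs (optionally GC-biased) to serve as the
#' neutral background into which synthetic elements are planted.
#'
#' @param lengths integer vector of contig lengths (bp).
#' @param gc GC content in `[0,1]`.
#' @param seed optional integer seed.
#' @return named character vector of contigs.
#' @export
random_genome <- function(lengths, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(lengths, random_dna, character(1), gc = gc)
  names(out) <- paste0("contig", seq_along(out))
  out
}

#' Generate one synthetic Academ-like element
#'
#' Builds a full-length element according to a lineage profile: terminal
#' inverted repeats of the requested length (the prefix equals the reverse
#' complement of the suffix), a pyrimidine 5' terminus and purine 3'
#' terminus, and the profile's coding cassettes (reverse-translated protein
#' templates bracketed by stop codons) embedded between the TIRs without
#' overlap. Three bases immediately interior to each TIR are set
#' non-complementary so the planted TIR length is also the detected one.
#'
#' @param profile a [lineage_profile()].
#' @param seed optional integer seed.
#' @return an object of class `academ_element`: list with `sequence`,
#'   `orfs` (data.frame of planted ORFs, 0-based half-open element
#'   coordinates), `proteins`, `tir_length`, `family`.
#' @export
make_element <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "lineage_profile"))
  if (!is.null(seed)) set.seed(seed)
  L <- profile$element_length
  Tt <- profile$tir_length
  Li <- L - 2L * Tt

  ## cassette DNA blocks
  cas <- profile$cassettes
  proteins <- list()
  cas_dna <- character(0)
  cas_meta <- list()
  for (cs in cas) {
    prot <- switch(cs$kind,
      transposase = transposase_template(phd = cs$phd %||% 0L,
                                         cchh = isTRUE(cs$cchh),
                                         xpg = isTRUE(cs$xpg)),
      helicase = helicase_template(),
      stop("unknown cassette kind: ", cs$kind))
    dna <- paste0("TAA", reverse_translate(as.character(prot)), "TAA")
    if (cs$strand == "-") dna <- dna_revcomp(dna)
    proteins[[length(proteins) + 1L]] <- prot
    cas_dna <- c(cas_dna, dna)
    cas_meta[[length(cas_meta) + 1L]] <-
      list(kind = cs$kind, strand = cs$strand, plen = nchar(prot))
  }
  tot_cas <- sum(nchar(cas_dna))
  nsp <- length(cas_dna) + 1L
  sp_total <- Li - tot_cas
  if (length(cas_dna) && sp_total < 8L * nsp)
    stop("element_length too small for the profile's cassettes (need >= ",
         2L * Tt + tot_cas + 8L * nsp, " bp)")

  sp <- rep(sp_total %/% nsp, nsp)
  sp[1] <- sp[1] + sp_total %% nsp
  pieces <- character(0)
  orfs <- list()
  off <- Tt  # 0-based offset within element
  for (i in seq_along(cas_dna)) {
    pieces <- c(pieces, random_dna(sp[i]))
    off <- off + sp[i]
    clen <- nchar(cas_dna[i])
    m <- cas_meta[[i]]
    span <- if (m$strand == "+") c(off + 3L, off + clen - 0L - 3L + 3L)
            else c(off, off + clen - 3L)
    orfs[[i]] <- data.frame(kind = m$kind, strand = m$strand,
                            start0 = span[1], end0 = span[2],
                            protein_len = m$plen, stringsAsFactors = FALSE)
    pieces <- c(pieces, cas_dna[i])
    off <- off + clen
  }
  pieces <- c(pieces, random_dna(sp[nsp]))
  interior <- paste(pieces, collapse = "")
  stopifnot(nchar(interior) == Li)

  iv <- strsplit(interior, "")[[1]]
  if (Tt > 0L) {
    ltir <- strsplit(random_dna(Tt), "")[[1]]
    ltir[1] <- sample(profile$terminal_5, 1L)
    ## TIR guard: 3 interior bases on each side must not extend the TIR
    for (i in 1:3) {
      if (iv[i] == .dna_comp(iv[Li + 1L - i]))
        iv[i] <- setdiff(.BASES, .dna_comp(iv[Li + 1L - i]))[1L]
    }
    ltir_s <- paste(ltir, collapse = "")
    seqn <- paste0(ltir_s, paste(iv, collapse = ""), dna_revcomp(ltir_s))
  } else {
    if (!(iv[1] %in% profile$terminal_5)) iv[1] <- sample(profile$terminal_5, 1L)
    if (!(iv[Li] %in% profile$terminal_3)) iv[Li] <- sample(profile$terminal_3, 1L)
    seqn <- paste(iv, collapse = "")
  }
  stopifnot(nchar(seqn) == L)
  structure(list(sequence = seqn, family = profile$name,
                 tir_length = Tt, profile = profile,
                 orfs = if (length(orfs)) do.call(rbind, orfs) else
                   data.frame(kind = character(0), strand = character(0),
                              start0 = integer(0), end0 = integer(0),
                              protein_len = integer(0)),
                 proteins = proteins),
            class = "academ_element")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a non-autonomous element from an autonomous parent
#'
#' Non-autonomous Academ copies share their terminal regions with an
#' autonomous family while lacking coding capacity. This replaces the
#' terminal blocks of a (shorter) element with the parent's termini and
#' fills the interior with random sequence.
#'
#' @param parent an `academ_element` (the autonomous family template).
#' @param profile the non-autonomous [lineage_profile()] (gives length,
#'   TSD lengths, name).
#' @param terminal_block length (bp) of each terminus copied from the parent.
#' @return an `academ_element` with the parent's TIR length.
#' @export
derive_nonautonomous <- function(parent, profile, terminal_block = 100L) {
  stopifnot(inherits(parent, "academ_element"),
            inherits(profile, "lineage_profile"))
  L <- profile$element_length
  pl <- nchar(parent$sequence)
  tb <- min(terminal_block, L %/% 2L, pl %/% 2L)
  seqn <- paste0(substr(parent$sequence, 1L, tb),
                 random_dna(L - 2L * tb),
                 substr(parent$sequence, pl - tb + 1L, pl))
  structure(list(sequence = seqn, family = profile$name,
                 tir_length = min(parent$tir_length, tb),
                 profile = profile,
                 orfs = data.frame(kind = character(0), strand = character(0),
                                   start0 = integer(0), end0 = integer(0),
                                   protein_len = integer(0)),
                 proteins = list()),
            class = "academ_element")
}

#' @export
print.academ_element <- function(x, ...) {
  cat(sprintf("<academ_element> %s: %d bp, TIR %d bp, %d cassette ORF(s)\n",
              x$family, nchar(x$sequence), x$tir_length, nrow(x$orfs)))
  invisible(x)
}

## per-site substitutions; returns list(seq, n)
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(list(seq = s, n = 0L))
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  for (i in idx) v[i] <- sample(setdiff(.BASES, v[i]), 1L)
  list(seq = paste(v, collapse = ""), n = length(idx))
}

#' Plant synthetic insertions into a background genome
#'
#' Each insertion duplicates a k-bp target site (k sampled from the
#' profile's TSD lengths) so that identical copies flank the element on both
#' sides, emulating the integration footprint of Academ transposons.
#' Divergence and truncation are applied to element copies only; flanks and
#' TSDs are never mutated, so planted parameters are exactly recoverable at
#' the default settings. Insertions never overlap or nest.
#'
#' @param background named character vector of contigs (or DNAStringSet or
#'   FASTA path).
#' @param profile a [lineage_profile()] or list of profiles (one family each).
#' @param n number of insertions per profile (recycled).
#' @param seed optional integer seed.
#' @param margin minimum distance of any insertion point from contig ends.
#' @param min_gap minimum ancestral distance between insertion points.
#' @return an object of class `synthetic_genome`: list with `contigs`,
#'   `truth` (data.frame, 0-based half-open spans in the modified contigs),
#'   `ancestral`, `elements` (named list of `academ_element` templates) and
#'   `seed`.
#' @export
plant_insertions <- function(background, profile, n, seed = NULL,
                             margin = 1200L, min_gap = 30L) {
  if (!is.null(seed)) set.seed(seed)
  contigs <- .as_contigs(background)
  if (length(contigs) && any(nchar(contigs) == 0L))
    stop("zero-length background contig")
  profiles <- if (inherits(profile, "lineage_profile")) list(profile) else profile
  stopifnot(all(vapply(profiles, inherits, logical(1), "lineage_profile")))
  n <- rep_len(as.integer(n), length(profiles))
  ntot <- sum(n)

  elements <- lapply(profiles, make_element)
  names(elements) <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(names(elements)))
    stop("profiles must have distinct names")
  ## non-autonomous families inherit the termini of the first autonomous
  ## family planted in the same genome (they are recognized by terminal
  ## homology, so independent termini would be unrecoverable by design)
  auto_i <- which(vapply(profiles, function(p) p$lineage != "nonautonomous",
                         logical(1)))
  if (length(auto_i)) {
    for (i in which(vapply(profiles, function(p)
      p$lineage == "nonautonomous", logical(1)))) {
      elements[[i]] <- derive_nonautonomous(elements[[auto_i[1]]],
                                            profiles[[i]])
    }
  }

  truth <- data.frame(contig = character(0), pre_insertion_point = integer(0),
                      start0 = integer(0), end0 = integer(0),
                      strand = character(0), family = character(0),
                      tsd_len = integer(0), tir_len = integer(0),
                      truncated = logical(0), n_substitutions = integer(0),
                      stringsAsFactors = FALSE)
  if (ntot == 0L) {
    return(structure(list(contigs = contigs, truth = truth,
                          ancestral = contigs, elements = elements,
                          seed = seed), class = "synthetic_genome"))
  }
  if (!length(contigs)) stop("empty background genome")

  usable <- pmax(0L, nchar(contigs) - 2L * margin)
  if (sum(usable) < ntot * (min_gap + 1L))
    stop("background too small for ", ntot, " insertions")

  ## assign insertions to contigs, then sample well-separated points
  fam_of <- rep(seq_along(profiles), n)
  ctg_of <- sample(seq_along(contigs), ntot, replace = TRUE,
                   prob = usable / sum(usable))
  pts <- integer(ntot)
  for (ci in unique(ctg_of)) {
    sel <- which(ctg_of == ci)
    lo <- margin; hi <- nchar(contigs[ci]) - margin
    ok <- FALSE
    for (try in 1:200) {
      p <- sort(sample(seq.int(lo, hi), length(sel)))
      if (length(p) < 2L || all(diff(p) >= min_gap)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", length(sel),
                  " non-overlapping insertions on ", names(contigs)[ci])
    pts[sel] <- p
  }

  ord <- order(ctg_of, pts)
  fam_of <- fam_of[ord]; ctg_of <- ctg_of[ord]; pts <- pts[ord]

  out <- contigs
  rows <- vector("list", ntot)
  for (ci in unique(ctg_of)) {
    anc <- contigs[[ci]]
    sel <- which(ctg_of == ci)
    pieces <- character(0)
    prev <- 0L   # 0-based ancestral position consumed so far
    shift <- 0L
    for (ii in sel) {
      pr <- profiles[[fam_of[ii]]]
      el <- elements[[fam_of[ii]]]
      k <- if (length(pr$tsd_lengths) == 1L) pr$tsd_lengths else
        sample(pr$tsd_lengths, 1L, prob = pr$tsd_weights)
      strand <- sample(c("+", "-"), 1L)
      cp <- el$sequence
      mut <- .mutate_seq(cp, pr$divergence)
      cp <- mut$seq
      truncated <- FALSE
      if (stats::runif(1) < pr$truncation_prob) {
        truncated <- TRUE
        cut <- as.integer(round(stats::runif(1, 0.1, 0.5) * nchar(cp)))
        cp <- if (sample(c(TRUE, FALSE), 1L)) .sub0(cp, cut, nchar(cp))
              else .sub0(cp, 0L, nchar(cp) - cut)
      }
      if (strand == "-") cp <- dna_revcomp(cp)
      p <- pts[ii]
      pieces <- c(pieces, .sub0(anc, prev, p + k), cp)
      start0 <- p + k + shift
      rows[[ii]] <- data.frame(contig = names(contigs)[ci],
                               pre_insertion_point = p,
                               start0 = start0, end0 = start0 + nchar(cp),
                               strand = strand, family = el$family,
                               tsd_len = k, tir_len = el$tir_length,
                               truncated = truncated,
                               n_substitutions = mut$n,
                               stringsAsFactors = FALSE)
      shift <- shift + nchar(cp) + k
      prev <- p
    }
    pieces <- c(pieces, .sub0(anc, prev, nchar(anc)))
    out[[ci]] <- paste(pieces, collapse = "")
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$contig, truth$start0), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(contigs = out, truth = truth, ancestral = contigs,
                 elements = elements, seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d contig(s), %d bp total, %d insertion(s), %d famil%s\n",
              length(x$contigs), sum(nchar(x$contigs)), nrow(x$truth),
              length(x$elements), if (length(x$elements) == 1L) "y" else "ies"))
  invisible(x)
}

#' Excise planted insertions to restore the ancestral contigs
#'
#' Removes each truth span together with one flanking TSD copy; at
#' divergence 0 the result equals the retained ancestral sequence exactly.
#'
#' @param genome a `synthetic_genome`.
#' @return named character vector of restored contigs.
#' @export
restore_ancestral <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  out <- genome$contigs
  tr <- genome$truth
  if (!nrow(tr)) return(out)
  for (ci in unique(tr$contig)) {
    rows <- tr[tr$contig == ci, , drop = FALSE]
    rows <- rows[order(rows$start0, decreasing = TRUE), , drop = FALSE]
    s <- out[[ci]]
    for (r in seq_len(nrow(rows))) {
      s <- paste0(.sub0(s, 0L, rows$start0[r]),
                  .sub0(s, rows$end0[r] + rows$tsd_len[r], nchar(s)))
    }
    out[[ci]] <- s
  }
  out
}

#' Write a synthetic genome and its ground truth to disk
#'
#' Emits the contigs as multi-FASTA, the truth table as TSV (0-based
#' half-open coordinates), the truth annotations as GFF3 (1-based inclusive),
#' the family element templates and the ancestral contigs.
#'
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- c(contigs = file.path(dir, "contigs.fa"),
             truth = file.path(dir, "truth.tsv"),
             gff = file.path(dir, "truth.gff3"),
             elements = file.path(dir, "elements.fa"),
             ancestral = file.path(dir, "ancestral.fa"))
  .write_fasta(genome$contigs, paths["contigs"])
  tr <- genome$truth
  utils::write.table(tr[, c("contig", "start0", "end0", "strand", "family",
                            "tsd_len", "tir_len", "truncated")],
                     paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gdf <- data.frame(seqid = character(0), start0 = integer(0),
                    end0 = integer(0), strand = character(0),
                    type = character(0), attrs = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(tr)) {
    gdf <- data.frame(seqid = tr$contig, start0 = tr$start0, end0 = tr$end0,
                      strand = tr$strand, type = "transposable_element",
                      attrs = sprintf(
                        "ID=ins%d;family=%s;tsd_len=%d;tir_len=%d;truncated=%s",
                        seq_len(nrow(tr)), tr$family, tr$tsd_len, tr$tir_len,
                        tolower(tr$truncated)),
                      stringsAsFactors = FALSE)
  }
  .write_gff3(gdf[order(gdf$seqid, gdf$start0), , drop = FALSE], paths["gff"])
  .write_fasta(vapply(genome$elements, `[[`, character(1), "sequence"),
               paths["elements"])
  .write_fasta(genome$ancestral, paths["ancestral"])
  invisible(paths)
}

#' Read back fixtures written by [write_fixtures()]
#'
#' @param dir directory written by [write_fixtures()].
#' @return a `synthetic_genome` (element templates carry sequences only).
#' @export
read_fixtures <- function(dir) {
  contigs <- .as_contigs(file.path(dir, "contigs.fa"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(contig = "character",
                                            family = "character",
                                            strand = "character"))
  els <- .as_contigs(file.path(dir, "elements.fa"))
  ancestral <- .as_contigs(file.path(dir, "ancestral.fa"))
  elements <- lapply(names(els), function(nm)
    structure(list(sequence = els[[nm]], family = nm,
                   tir_length = NA_integer_,
                   orfs = NULL, proteins = NULL), class = "academ_element"))
  names(elements) <- names(els)
  structure(list(contigs = contigs, truth = truth, ancestral = ancestral,
                 elements = elements, seed = NA_integer_),
            class = "synthetic_genome")
}
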