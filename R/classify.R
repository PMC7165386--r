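#' Classify an element into an Academ lineage
#'
#' Combines boundary evidence (TSD length) and coding evidence
#' (architecture, PHD fingers) into a lineage call: AcademH generates
#' relatively long (8-10 bp window; typically 9 or 10 bp) TSDs and encodes a
#' transposase and an SF2 helicase in opposite directions; AcademHP is the
#' AcademH sublineage whose transposase carries one or two PHD fingers;
#' AcademX generates short (3 or 4 bp) TSDs and encodes a single
#' transposase-XPG protein; elements without coding capacity but with
#' terminal homology to a classified autonomous family are non-autonomous.
#' Anything else is unclassified (with partial confidence when exactly one
#' evidence axis matches). The call is total: unclassified is the fallback,
#' never an error.
#'
#' @param annotation an `element_annotation` (or `NULL`; TSD evidence 0).
#' @param architecture an `architecture_call`.
#' @param phd_count number of PHD fingers in the transposase ORF.
#' @param terminal_homology logical; element termini match a classified
#'   autonomous family.
#' @param tsd_window_h,tsd_window_x inclusive TSD windows for the
#'   AcademH and AcademX rules.
#' @return object of class `lineage_call`: list with `lineage`,
#'   `tsd_evidence`, `architecture_evidence`, `phd_count`, `confidence`.
#' @export
classify_element <- function(annotation, architecture, phd_count = 0L,
                             terminal_homology = FALSE,
                             tsd_window_h = c(8L, 10L),
                             tsd_window_x = c(3L, 4L)) {
  stopifnot(inherits(architecture, "architecture_call"))
  tsd <- if (is.null(annotation)) 0L else annotation$tsd$length
  arch <- architecture$kind
  tsd_h <- tsd >= tsd_window_h[1] && tsd <= tsd_window_h[2]
  tsd_x <- tsd >= tsd_window_x[1] && tsd <= tsd_window_x[2]
  mk <- function(lineage, confidence) {
    structure(list(lineage = lineage, tsd_evidence = tsd,
                   architecture_evidence = arch,
                   phd_count = as.integer(phd_count),
                   confidence = confidence), class = "lineage_call")
  }
  if (tsd_h && arch == "two_orf_opposite_helicase")
    return(mk(if (phd_count >= 1L) "AcademHP" else "AcademH", "full"))
  if (tsd_x && arch == "single_orf_xpg")
    return(mk("AcademX", "full"))
  if (arch == "no_coding" && isTRUE(terminal_homology))
    return(mk("Academ_nonautonomous", if (tsd > 0L) "full" else "partial"))
  axes <- (tsd_h || tsd_x) +
    (arch %in% c("two_orf_opposite_helicase", "single_orf_xpg"))
  mk("Academ_unclassified", if (axes == 1L) "partial" else "partial")
}

#' @export
print.lineage_call <- function(x, ...) {
  cat(sprintf("<lineage_call> %s (TSD %d bp, %s, %d PHD finger(s), %s)\n",
              x$lineage, x$tsd_evidence, x$architecture_evidence,
              x$phd_count, x$confidence))
  invisible(x)
}

#' Descriptive statistics of a protein multiple alignment
#'
#' Summarizes a transposase-domain alignment: sequence count, range of
#' ungapped sequence lengths, number of conserved columns at a threshold,
#' and (given the columns of the first and second catalytic D) the range of
#' ungapped D-D spacings across rows.
#'
#' @param alignment an `AAStringSet`, FASTA path, or character vector of
#'   aligned rows (equal lengths; `-` and `.` are gaps).
#' @param conservation_threshold a column is conserved when at least this
#'   fraction of its non-gap residues are identical.
#' @param catalytic_columns optional length-2 integer vector of alignment
#'   columns holding the first and second catalytic D.
#' @return object of class `alignment_stats`: list with `n_seqs`, `min_len`,
#'   `max_len`, `conserved_columns`, `alignment_length`, `dd_spacing_range`.
#' @export
alignment_stats <- function(alignment, conservation_threshold = 0.95,
                            catalytic_columns = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- Biostrings::readAAStringSet(alignment)
  }
  if (methods::is(alignment, "XStringSet")) alignment <- as.character(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  w <- nchar(alignment)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: rows have unequal aligned lengths")
  M <- do.call(rbind, strsplit(toupper(alignment), ""))
  gap <- M == "-" | M == "."
  ungapped <- rowSums(!gap)
  conserved <- 0L
  for (j in seq_len(ncol(M))) {
    res <- M[!gap[, j], j]
    if (!length(res)) next
    if (max(table(res)) / length(res) >= conservation_threshold)
      conserved <- conserved + 1L
  }
  dd <- NULL
  if (!is.null(catalytic_columns)) {
    stopifnot(length(catalytic_columns) == 2L)
    i <- catalytic_columns[1]; j <- catalytic_columns[2]
    sp <- integer(0)
    for (r in seq_len(nrow(M))) {
      if (gap[r, i] || gap[r, j]) next
      u <- cumsum(!gap[r, ])
      sp <- c(sp, u[j] - u[i])
    }
    if (length(sp)) dd <- range(sp)
  }
  structure(list(n_seqs = length(alignment), min_len = min(ungapped),
                 max_len = max(ungapped), conserved_columns = conserved,
                 alignment_length = ncol(M), dd_spacing_range = dd),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("<alignment_stats> %d sequences, %d-%d residues (ungapped), %d/%d conserved columns\n",
              x$n_seqs, x$min_len, x$max_len, x$conserved_columns,
              x$alignment_length))
  if (!is.null(x$dd_spacing_range))
    cat(sprintf("  D-D spacing range: %d-%d residues\n",
                x$dd_spacing_range[1], x$dd_spacing_range[2]))
  invisible(x)
}
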