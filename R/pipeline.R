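#' Pipeline configuration
#'
#' @param scan a [scan_params()].
#' @param flank flanking sequence (bp) used when building consensus.
#' @param top_n members used per consensus.
#' @param id_thresh,cov_thresh clustering thresholds.
#' @param max_gap hit-chaining gap (bp).
#' @param min_aa minimum ORF protein length.
#' @param search_radius boundary refinement radius (bp).
#' @param max_iter maximum TSD-refinement iterations.
#' @param min_tsd_support member insertions required to confirm boundaries.
#' @param flank_window single-copy flank window (bp).
#' @param terminal_len,terminal_min_len terminus length scanned and minimum
#'   match length for non-autonomous terminal homology.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scan = scan_params(), flank = 1000L, top_n = 10L,
                            id_thresh = 0.8, cov_thresh = 0.5,
                            max_gap = 50L, min_aa = 100L,
                            search_radius = 50L, max_iter = 5L,
                            min_tsd_support = 2L, flank_window = 10000L,
                            terminal_len = 100L, terminal_min_len = 50L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.ann_row <- function(ann, family) {
  data.frame(contig = ann$contig, start0 = ann$start, end0 = ann$end,
             strand = ann$strand, family = family,
             tsd_len = ann$tsd$length, tir_len = ann$tir$length,
             terminal_5_ok = ann$terminal_5_ok,
             terminal_3_ok = ann$terminal_3_ok,
             accepted = ann$accepted_full_length, source = ann$source,
             stringsAsFactors = FALSE)
}

## terminal homology of a consensus to any autonomous family consensus
.terminal_homology <- function(seqn, autonomous, cfg) {
  if (!length(autonomous) || nchar(seqn) < 2L * cfg$terminal_min_len)
    return(FALSE)
  tl <- min(cfg$terminal_len, nchar(seqn) %/% 2L)
  p <- scan_params(word_size = cfg$scan$word_size, xdrop = cfg$scan$xdrop,
                   min_identity = 0.8, min_hit_len = cfg$terminal_min_len)
  for (a in autonomous) {
    h5 <- scan_genome(c(ref = a), substr(seqn, 1L, tl), p)
    h3 <- scan_genome(c(ref = a), substr(seqn, nchar(seqn) - tl + 1L,
                                         nchar(seqn)), p)
    if (nrow(h5) && nrow(h3)) return(TRUE)
  }
  FALSE
}

#' Run the full Academ characterization pipeline
#'
#' Executes scan, hit chaining, clustering, consensus building, TSD-driven
#' boundary refinement, per-insertion boundary annotation, ORF and domain
#' scanning, and lineage classification. Deterministic given inputs and
#' configuration (no randomness is used).
#'
#' @param genome named character vector of contigs (or DNAStringSet/path).
#' @param queries named character vector of query element sequences.
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return object of class `academ_report`: list with `families`
#'   (data.frame: family, lineage, tsd_len, tir_len, phd_count, confidence,
#'   n_members, n_accepted, boundary_status, architecture), `insertions`
#'   (per-insertion annotation table), `consensus` (named character vector),
#'   `calls` (list of `lineage_call`), `config`.
#' @export
run_pipeline <- function(genome, queries, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  contigs <- .as_contigs(genome)
  queries <- .as_contigs(queries)
  say <- function(...) if (verbose) message(sprintf(...))

  empty <- structure(list(
    families = data.frame(family = character(0), lineage = character(0),
                          tsd_len = integer(0), tir_len = integer(0),
                          phd_count = integer(0), confidence = character(0),
                          n_members = integer(0), n_accepted = integer(0),
                          boundary_status = character(0),
                          architecture = character(0),
                          stringsAsFactors = FALSE),
    insertions = data.frame(contig = character(0), start0 = integer(0),
                            end0 = integer(0), strand = character(0),
                            family = character(0), tsd_len = integer(0),
                            tir_len = integer(0), terminal_5_ok = logical(0),
                            terminal_3_ok = logical(0), accepted = logical(0),
                            source = character(0), stringsAsFactors = FALSE),
    consensus = character(0), calls = list(), config = config),
    class = "academ_report")

  say("stage scan: %d quer%s vs %d contig(s)", length(queries),
      if (length(queries) == 1L) "y" else "ies", length(contigs))
  hits <- .empty_hits()
  for (nm in names(queries)) {
    h <- scan_genome(contigs, queries[[nm]], config$scan, query_id = nm)
    hits <- rbind(hits, h)
  }
  if (!nrow(hits)) return(empty)
  hits <- merge_hits(hits, config$max_gap)
  ## queries sharing terminal regions (autonomous vs non-autonomous
  ## relatives) produce partial hits at each other's loci; keep only the
  ## best-covering hit per locus
  hits <- hits[order(-(hits$tend - hits$tstart), -hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    contained <- hits$contig[prior] == hits$contig[i] &
      hits$tstart[prior] <= hits$tstart[i] + 10L &
      hits$tend[prior] >= hits$tend[i] - 10L
    if (any(contained)) keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$contig, hits$tstart), , drop = FALSE]
  rownames(hits) <- NULL
  say("stage scan: %d hit(s) after chaining", nrow(hits))

  seqs <- vapply(seq_len(nrow(hits)), function(i)
    extract_with_flanks(contigs, hits[i, ], 0L)$seq, character(1))
  clusters <- cluster_hits(hits, seqs, config$id_thresh, config$cov_thresh)
  say("stage cluster: %d famil%s", length(clusters),
      if (length(clusters) == 1L) "y" else "ies")

  fam_rows <- list(); ins_rows <- list(); cons_seqs <- character(0)
  fam_info <- list()
  for (cl in clusters) {
    nmem <- nrow(cl$members)
    if (nmem >= 2L) {
      cons <- build_consensus(cl, contigs, config$flank, config$top_n)
      cons <- refine_until_tsd(cons, contigs, config$max_iter,
                               config$search_radius, config$min_tsd_support)
      elem_seq <- cons$sequence
      status <- cons$boundary_status
      anns <- cons$insertions %||% list()
      nsup <- if (length(anns)) anns[[1]]$n_tsd_support else 1L
      ## annotate members not used in the consensus at their hit spans
      used_keys <- paste(cons$members$contig, cons$members$tstart)
      extra <- cl$members[!(paste(cl$members$contig, cl$members$tstart) %in%
                              used_keys), , drop = FALSE]
      if (nrow(extra)) {
        for (i in seq_len(nrow(extra))) {
          anns[[length(anns) + 1L]] <- annotate_element(
            contigs, extra$contig[i], extra$tstart[i], extra$tend[i],
            strand = extra$strand[i], source = "multicopy",
            n_tsd_support = nsup)
        }
      }
    } else {
      ann1 <- refine_boundaries(contigs, cl$members$contig[1],
                                cl$members$tstart[1], cl$members$tend[1],
                                strand = cl$members$strand[1],
                                search_radius = config$search_radius,
                                source = "single_copy")
      s <- contigs[[ann1$contig]]
      elem_seq <- .sub0(s, ann1$start, ann1$end)
      if (ann1$strand == "-") elem_seq <- dna_revcomp(elem_seq)
      status <- if (ann1$tsd$length > 0L) "tsd_confirmed" else "unconfirmed"
      anns <- list(ann1)
    }
    say("stage consensus: %s %s (%d bp)", cl$cluster_id, status,
        nchar(elem_seq))

    orfs <- find_orfs(elem_seq, config$min_aa)
    doms <- scan_domains(orfs)
    arch <- call_architecture(orfs, doms)
    tr_orfs <- unique(doms$orf_index[doms$kind == "transposase_core"])
    phd_count <- if (length(tr_orfs))
      max(vapply(tr_orfs, function(oi)
        sum(doms$kind == "PHD_finger" & doms$orf_index == oi), integer(1)))
      else 0L

    acc <- Filter(function(a) a$accepted_full_length, anns)
    fam_tsd <- if (length(acc))
      .modal(vapply(acc, function(a) a$tsd$length, integer(1)))
      else 0L
    fam_tir <- if (length(acc))
      .modal(vapply(acc, function(a) a$tir$length, integer(1)))
      else detect_tir(elem_seq)$length

    fam_info[[cl$cluster_id]] <- list(
      family = cl$cluster_id, elem_seq = elem_seq, status = status,
      arch = arch, phd_count = phd_count, tsd = fam_tsd, tir = fam_tir,
      anns = anns, n_members = nmem,
      n_accepted = length(acc))
  }

  ## lineage calls, with terminal homology against autonomous families
  pre <- lapply(fam_info, function(fi) {
    rep_ann <- if (length(fi$anns)) fi$anns[[1]] else NULL
    acc <- Filter(function(a) a$accepted_full_length, fi$anns)
    if (length(acc)) rep_ann <- acc[[1]]
    classify_element(rep_ann, fi$arch, fi$phd_count)
  })
  autonomous <- vapply(fam_info, `[[`, character(1), "elem_seq")[
    vapply(pre, function(cc) cc$lineage %in% c("AcademH", "AcademHP",
                                               "AcademX"), logical(1))]
  calls <- list()
  for (nm in names(fam_info)) {
    fi <- fam_info[[nm]]
    if (pre[[nm]]$lineage == "Academ_unclassified" &&
        fi$arch$kind == "no_coding") {
      th <- .terminal_homology(fi$elem_seq, autonomous, config)
      rep_ann <- if (length(fi$anns)) fi$anns[[1]] else NULL
      acc <- Filter(function(a) a$accepted_full_length, fi$anns)
      if (length(acc)) rep_ann <- acc[[1]]
      calls[[nm]] <- classify_element(rep_ann, fi$arch, fi$phd_count,
                                      terminal_homology = th)
    } else {
      calls[[nm]] <- pre[[nm]]
    }
    fam_rows[[nm]] <- data.frame(
      family = fi$family, lineage = calls[[nm]]$lineage,
      tsd_len = fi$tsd, tir_len = fi$tir, phd_count = fi$phd_count,
      confidence = calls[[nm]]$confidence, n_members = fi$n_members,
      n_accepted = fi$n_accepted, boundary_status = fi$status,
      architecture = fi$arch$kind, stringsAsFactors = FALSE)
    ins_rows[[nm]] <- do.call(rbind, lapply(fi$anns, .ann_row,
                                            family = fi$family))
    cons_seqs[fi$family] <- fi$elem_seq
  }

  families <- do.call(rbind, fam_rows)
  insertions <- do.call(rbind, ins_rows)
  insertions <- insertions[order(insertions$contig, insertions$start0), ,
                           drop = FALSE]
  rownames(families) <- rownames(insertions) <- NULL
  structure(list(families = families, insertions = insertions,
                 consensus = cons_seqs, calls = calls, config = config),
            class = "academ_report")
}

#' @export
print.academ_report <- function(x, ...) {
  cat(sprintf("<academ_report> %d famil%s, %d insertion(s)\n",
              nrow(x$families), if (nrow(x$families) == 1L) "y" else "ies",
              nrow(x$insertions)))
  if (nrow(x$families)) print(x$families)
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits the lineage table (TSV), the per-insertion table (TSV), insertion
#' features (GFF3, 1-based inclusive) and the family consensus sequences
#' (multi-FASTA). All files round-trip parseably; empty reports produce
#' header-only files.
#'
#' @param report an `academ_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
write_reports <- function(report, out_dir) {
  stopifnot(inherits(report, "academ_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir)
  }
  paths <- c(lineage = file.path(out_dir, "lineage.tsv"),
             insertions = file.path(out_dir, "insertions.tsv"),
             gff = file.path(out_dir, "insertions.gff3"),
             consensus = file.path(out_dir, "consensus.fa"))
  utils::write.table(report$families, paths["lineage"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$insertions, paths["insertions"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ins <- report$insertions
  gdf <- data.frame(seqid = character(0), start0 = integer(0),
                    end0 = integer(0), strand = character(0),
                    type = character(0), attrs = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(ins)) {
    gdf <- data.frame(seqid = ins$contig, start0 = ins$start0,
                      end0 = ins$end0, strand = ins$strand,
                      type = "transposable_element",
                      attrs = sprintf(
                        "ID=el%d;family=%s;tsd_len=%d;tir_len=%d;terminal_motif=%s",
                        seq_len(nrow(ins)), ins$family, ins$tsd_len,
                        ins$tir_len,
                        ifelse(ins$terminal_5_ok & ins$terminal_3_ok, "ok",
                               "violated")),
                      stringsAsFactors = FALSE)
  }
  .write_gff3(gdf, paths["gff"])
  if (length(report$consensus)) .write_fasta(report$consensus,
                                             paths["consensus"])
  else file.create(paths["consensus"])
  invisible(paths)
}
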