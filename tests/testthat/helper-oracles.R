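# Independent oracles used to cross-check the package implementations.

# brute-force largest exact terminal duplication
oracle_tsd <- function(left, right, kmin = 2L, kmax = 12L) {
  best <- 0L
  for (k in kmin:min(kmax, nchar(left), nchar(right))) {
    if (substr(left, nchar(left) - k + 1L, nchar(left)) ==
        substr(right, 1L, k)) best <- k
  }
  best
}

# brute-force six-frame stop-to-stop ORF scan via codon table lookup
oracle_orfs <- function(seqn, min_aa = 100L) {
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqn else dna_revcomp(seqn)
    L <- nchar(s)
    for (f in 0:2) {
      n <- (L - f) %/% 3L
      if (n < 1L) next
      codons <- substring(s, f + 1L + 3L * (0:(n - 1L)), f + 3L * (1:n))
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"
      stops <- c(0L, which(aa == "*"))
      for (i in seq_len(length(stops) - 1L)) {
        a <- stops[i] + 1L; b <- stops[i + 1L] - 1L
        if (b - a + 1L < min_aa) next
        s0 <- f + 3L * (a - 1L); e0 <- f + 3L * (b + 1L)
        if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        out[[length(out) + 1L]] <- data.frame(
          start0 = s0, end0 = e0, strand = strand,
          protein = paste(aa[a:b], collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      strand = character(0), protein = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start0, df$strand), , drop = FALSE]
}

# per-site substitution helper (independent of the generator's internals)
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# connected components from an explicit edge matrix (union-find)
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# canonical partition signature for comparing clusterings
partition_signature <- function(groups_list, n) {
  lab <- integer(n)
  for (i in seq_along(groups_list)) lab[groups_list[[i]]] <- i
  match(lab, unique(lab))
}

modal_int <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])

# small hit table constructor for synthetic fragments
make_hits <- function(..., query_id = "q", contig = "c1") {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$query_id <- query_id
  df$contig <- contig
  if (is.null(df$identity)) df$identity <- 1
  if (is.null(df$length)) df$length <- df$tend - df$tstart
  if (is.null(df$score)) df$score <- df$length
  class(df) <- c("seq_hits", "data.frame")
  df
}
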