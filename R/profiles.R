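#' Generative profile of an Academ lineage
#'
#' A lineage profile bundles the structural parameters that define how
#' synthetic elements of one Academ family are generated: target site
#' duplication (TSD) lengths with sampling weights, terminal inverted repeat
#' (TIR) length, element length, terminal base classes (pyrimidine 5'
#' terminus, purine 3' terminus), the coding cassettes carried between the
#' TIRs, and per-copy divergence/truncation rates.
#'
#' @param name family name.
#' @param lineage one of `"AcademH_fungal"`, `"AcademH_animal"`, `"AcademHP"`,
#'   `"AcademX_animal"`, `"AcademX_red_alga"`, `"nonautonomous"`.
#' @param tsd_lengths integer vector of allowed TSD lengths (bp), each in 0..12.
#' @param tir_length TIR length in bp.
#' @param element_length full element length in bp.
#' @param cassettes list of cassettes, each a list with `kind`
#'   (`"transposase"` or `"helicase"`), `strand` (`"+"`/`"-"`) and for
#'   transposase cassettes optional `phd` (0..2), `cchh`, `xpg` flags.
#' @param tsd_weights sampling weights for `tsd_lengths` (default uniform).
#' @param divergence per-site substitution probability applied to each
#'   planted copy (never to flanks or TSDs).
#' @param truncation_prob probability that a planted copy is truncated.
#' @param terminal_5 allowed 5'-terminal bases (pyrimidines).
#' @param terminal_3 allowed 3'-terminal bases (purines).
#' @return an object of class `lineage_profile`.
#' @export
lineage_profile <- function(name, lineage, tsd_lengths, tir_length,
                            element_length, cassettes = list(),
                            tsd_weights = NULL, divergence = 0,
                            truncation_prob = 0,
                            terminal_5 = c("C", "T"),
                            terminal_3 = c("G", "A")) {
  lineage <- match.arg(lineage, c("AcademH_fungal", "AcademH_animal",
                                  "AcademHP", "AcademX_animal",
                                  "AcademX_red_alga", "nonautonomous"))
  tsd_lengths <- as.integer(tsd_lengths)
  if (any(tsd_lengths < 0 | tsd_lengths > 12))
    stop("tsd_lengths must lie in [0, 12]")
  tir_length <- as.integer(tir_length)
  element_length <- as.integer(element_length)
  if (tir_length < 0 || tir_length > element_length / 2)
    stop("tir_length must satisfy 0 <= tir_length <= element_length/2")
  if (element_length < 2L * tir_length + 50L)
    stop("element_length must be >= 2*tir_length + 50")
  if (divergence < 0 || divergence > 1 || truncation_prob < 0 ||
      truncation_prob > 1)
    stop("divergence and truncation_prob must lie in [0, 1]")
  if (is.null(tsd_weights)) tsd_weights <- rep(1, length(tsd_lengths))
  stopifnot(length(tsd_weights) == length(tsd_lengths), all(tsd_weights >= 0))
  stopifnot(all(terminal_5 %in% c("C", "T")), all(terminal_3 %in% c("G", "A")))
  structure(list(name = name, lineage = lineage, tsd_lengths = tsd_lengths,
                 tsd_weights = tsd_weights, tir_length = tir_length,
                 element_length = element_length, cassettes = cassettes,
                 divergence = divergence, truncation_prob = truncation_prob,
                 terminal_5 = terminal_5, terminal_3 = terminal_3),
            class = "lineage_profile")
}

#' @export
print.lineage_profile <- function(x, ...) {
  cat(sprintf("<lineage_profile> %s (%s)\n", x$name, x$lineage))
  cat(sprintf("  element %d bp, TIR %d bp, TSD {%s} bp\n", x$element_length,
              x$tir_length, paste(x$tsd_lengths, collapse = ",")))
  cat(sprintf("  cassettes: %s\n", if (length(x$cassettes))
    paste(vapply(x$cassettes, function(cs) paste0(cs$kind, "(", cs$strand, ")"),
                 character(1)), collapse = " ") else "none"))
  cat(sprintf("  divergence %.3f, truncation %.2f\n", x$divergence,
              x$truncation_prob))
  invisible(x)
}

.cas_transposase <- function(strand = "+", phd = 0L, cchh = FALSE, xpg = FALSE)
  list(kind = "transposase", strand = strand, phd = phd, cchh = cchh, xpg = xpg)

.cas_helicase <- function(strand = "-") list(kind = "helicase", strand = strand)

#' Built-in Academ lineage profiles
#'
#' Profiles parameterized from the structural characteristics reported for
#' the Academ superfamily: fungal AcademH families generate 9-bp TSDs and
#' animal AcademH families 9- or 10-bp TSDs, with a transposase and an SF2
#' helicase encoded in opposite directions; AcademX families carry a single
#' transposase-XPG ORF and generate 3-bp (animals) or 4-bp (the red alga
#' Chondrus crispus) TSDs; AcademHP is an AcademH sublineage whose
#' transposase carries two PHD fingers. Named-family profiles reproduce
#' reported TIR extremes: `"AcademH-1_LoTr"` (526-bp TIRs),
#' `"AcademH-16_CVi"` (575-bp TIRs) and `"AcademH-2_PSt"` (8-bp TIRs).
#'
#' @param name profile name; one of `"AcademH_fungal"`, `"AcademH_animal"`,
#'   `"AcademHP"`, `"AcademX_animal"`, `"AcademX_red_alga"`,
#'   `"Academ_nonautonomous"`, `"AcademH-1_LoTr"`, `"AcademH-16_CVi"`,
#'   `"AcademH-2_PSt"`.
#' @param divergence,truncation_prob overrides applied to the profile.
#' @return a [lineage_profile()].
#' @export
academ_profile <- function(name = c("AcademH_fungal", "AcademH_animal",
                                    "AcademHP", "AcademX_animal",
                                    "AcademX_red_alga",
                                    "Academ_nonautonomous",
                                    "AcademH-1_LoTr", "AcademH-16_CVi",
                                    "AcademH-2_PSt"),
                           divergence = 0, truncation_prob = 0) {
  name <- match.arg(name)
  p <- switch(name,
    "AcademH_fungal" = lineage_profile(
      name, "AcademH_fungal", tsd_lengths = 9L, tir_length = 20L,
      element_length = 3200L,
      cassettes = list(.cas_transposase("+"), .cas_helicase("-"))),
    "AcademH_animal" = lineage_profile(
      name, "AcademH_animal", tsd_lengths = c(9L, 10L), tir_length = 20L,
      element_length = 3200L,
      cassettes = list(.cas_transposase("+", cchh = TRUE), .cas_helicase("-"))),
    "AcademHP" = lineage_profile(
      name, "AcademHP", tsd_lengths = 9L, tir_length = 20L,
      element_length = 3300L,
      cassettes = list(.cas_transposase("+", phd = 2L), .cas_helicase("-"))),
    "AcademX_animal" = lineage_profile(
      name, "AcademX_animal", tsd_lengths = 3L, tir_length = 15L,
      element_length = 2600L,
      cassettes = list(.cas_transposase("+", xpg = TRUE))),
    "AcademX_red_alga" = lineage_profile(
      name, "AcademX_red_alga", tsd_lengths = 4L, tir_length = 15L,
      element_length = 2600L,
      cassettes = list(.cas_transposase("+", xpg = TRUE))),
    "Academ_nonautonomous" = lineage_profile(
      name, "nonautonomous", tsd_lengths = 9L, tir_length = 20L,
      element_length = 600L, cassettes = list()),
    "AcademH-1_LoTr" = lineage_profile(
      name, "AcademH_fungal", tsd_lengths = 9L, tir_length = 526L,
      element_length = 4200L,
      cassettes = list(.cas_transposase("+"), .cas_helicase("-"))),
    "AcademH-16_CVi" = lineage_profile(
      name, "AcademH_animal", tsd_lengths = c(9L, 10L), tir_length = 575L,
      element_length = 4300L,
      cassettes = list(.cas_transposase("+", cchh = TRUE), .cas_helicase("-"))),
    "AcademH-2_PSt" = lineage_profile(
      name, "AcademH_fungal", tsd_lengths = 9L, tir_length = 8L,
      element_length = 3200L,
      cassettes = list(.cas_transposase("+"), .cas_helicase("-")))
  )
  p$divergence <- divergence
  p$truncation_prob <- truncation_prob
  p
}
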