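# Splice-site dinucleotide compatibility, reading-frame compatibility, and
# in-frame translation with split-codon completion.
#
# Exactly four intron patterns are considered compatible: GT---AG, GC---AG,
# GG---AG and AT---AC. The AT donor pairs only with the AC acceptor.

#' Acceptor dinucleotides compatible with an upstream intron donor
#'
#' The intron in front of a candidate exon keeps the donor of the intron in
#' front of the query exon; its acceptor is the dinucleotide immediately
#' before the candidate. A `GT`, `GC` or `GG` donor requires an `AG`
#' acceptor; an `AT` donor requires `AC`.
#'
#' @param donor 2-nt donor dinucleotide of the intron in front of the query.
#' @return character vector of admissible acceptor dinucleotides; empty for a
#'   non-canonical donor (the query exon is then skipped with a warning).
#' @export
acceptor_targets <- function(donor) {
  if (donor %in% c("GT", "GC", "GG")) return("AG")
  if (donor == "AT") return("AC")
  character(0)
}

#' Donor dinucleotides compatible with a downstream intron acceptor
#'
#' Mirror of [acceptor_targets()]: an `AG` acceptor admits `GT`, `GC` and
#' `GG` donors at the candidate's 3' end; an `AC` acceptor admits only `AT`.
#'
#' @param acceptor 2-nt acceptor dinucleotide of the intron after the query.
#' @return character vector of admissible donor dinucleotides (possibly
#'   empty).
#' @export
donor_targets <- function(acceptor) {
  if (acceptor == "AG") return(c("GT", "GC", "GG"))
  if (acceptor == "AC") return("AT")
  character(0)
}

#' Frame context of a query exon
#'
#' @param query_dna_length exon body length in nucleotides.
#' @param allowed_length_difference maximum length difference between query
#'   and candidate, in amino acids (default 20).
#' @param start_phase,end_phase GFF3-style phases of the query exon.
#' @return list used by [is_frame_compatible()].
#' @export
frame_context <- function(query_dna_length, allowed_length_difference = 20,
                          start_phase = 0L, end_phase = 0L) {
  stopifnot(query_dna_length >= 3, allowed_length_difference >= 0)
  list(query_dna_length = as.integer(query_dna_length),
       allowed_length_difference = allowed_length_difference,
       start_phase = as.integer(start_phase),
       end_phase = as.integer(end_phase))
}

#' Is a candidate length compatible with the query exon's reading frame?
#'
#' Compatible means the DNA length difference is a multiple of three (so
#' split codons in the query remain split codons in the candidate, which
#' inherits the query's start phase) and at most
#' `3 * allowed_length_difference` nucleotides in absolute value.
#'
#' @param ctx a [frame_context()].
#' @param candidate_dna_length candidate body length in nucleotides.
#' @return logical.
#' @export
is_frame_compatible <- function(ctx, candidate_dna_length) {
  d <- candidate_dna_length - ctx$query_dna_length
  d %% 3 == 0 & abs(d) <= 3 * ctx$allowed_length_difference
}

#' Translate an exon body in its reading frame
#'
#' Split codons at the exon edges are completed with nucleotides from the
#' flanking constitutive exons; for a candidate these completions are those
#' of the query exon it would replace, so query and candidate translations
#' are directly comparable.
#'
#' @param dna exon body nucleotide string.
#' @param start_phase GFF3 phase; `upstream_completion` must supply
#'   `(3 - start_phase) %% 3` nucleotides.
#' @param upstream_completion,downstream_completion flanking nucleotides
#'   completing the edge codons (possibly empty).
#' @return amino-acid string (may contain `*`; the caller rejects in-frame
#'   stops), or `NA` if any codon contains `N` (untranslatable).
#' @export
translate_in_frame <- function(dna, start_phase = 0L,
                               upstream_completion = "",
                               downstream_completion = "") {
  if (nchar(upstream_completion) != (3L - start_phase) %% 3L) {
    stop("upstream completion has ", nchar(upstream_completion),
         " nt but start phase ", start_phase, " requires ",
         (3L - start_phase) %% 3L)
  }
  full <- paste0(upstream_completion, dna, downstream_completion)
  if (nchar(full) %% 3L != 0L) {
    stop("completed exon length ", nchar(full), " is not a multiple of 3")
  }
  translate_codons(full)
}

#' Stop and start codon tests
#'
#' @param codon 3-nt string(s).
#' @return logical; `is_stop` is true for `TAG`, `TAA`, `TGA`; `is_start`
#'   for `ATG`.
#' @export
is_stop <- function(codon) codon %in% STOP_CODONS

#' @rdname is_stop
#' @export
is_start <- function(codon) codon == "ATG"
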