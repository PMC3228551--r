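# Candidate-exon enumeration inside a search region.
#
# A candidate interval [s, e) must
#   * start right after an admissible acceptor dinucleotide (or at an ATG
#     for first-exon searches),
#   * end right before an admissible donor dinucleotide (or be followed by a
#     stop codon for last-exon searches),
#   * differ from the query exon body by a multiple of 3 nt, by at most
#     3 * allowed_length_difference nt,
#   * leave min_new_intron_length nt to the boundaries of an intron region
#     on every splice-anchored side, and
#   * contain no N in its body.
# Overlapping dinucleotide occurrences all count as sites.

# 0-based start positions of any of `targets` in `seq` (overlapping kept)
find_motif_positions <- function(seq, targets) {
  if (!length(targets) || nchar(seq) < min(nchar(targets))) return(integer(0))
  pat <- paste0("(?=(", paste(targets, collapse = "|"), "))")
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  sort(as.integer(m) - 1L)
}

#' Candidate start sites in a region
#'
#' Every occurrence of a target acceptor dinucleotide at region-local
#' position `p` yields a candidate start at `p + 2`; starts closer than
#' `min_margin` (or than the dinucleotide itself) to the region's 5'
#' boundary are dropped.
#'
#' @param region_seq nucleotide string of the searchable region.
#' @param targets acceptor dinucleotides, from [acceptor_targets()].
#' @param min_margin minimum length of the implied intron piece between the
#'   region's 5' boundary and the candidate start (nt).
#' @return sorted integer vector of region-local candidate start positions
#'   (0-based).
#' @export
find_acceptor_sites <- function(region_seq, targets, min_margin = 0L) {
  starts <- find_motif_positions(region_seq, targets) + 2L
  starts[starts >= max(min_margin, 2L)]
}

#' Candidate end sites in a region
#'
#' Every occurrence of a target donor dinucleotide at region-local position
#' `p` yields a candidate end at `p`; ends closer than `min_margin` to the
#' region's 3' boundary are dropped.
#'
#' @inheritParams find_acceptor_sites
#' @param targets donor dinucleotides, from [donor_targets()].
#' @return sorted integer vector of region-local candidate end positions.
#' @export
find_donor_sites <- function(region_seq, targets, min_margin = 0L) {
  ends <- find_motif_positions(region_seq, targets)
  ends[nchar(region_seq) - ends >= max(min_margin, 2L)]
}

# start positions of ATG codons; stop-anchored ends (positions followed by
# an in-frame stop codon fitting inside the region)
find_atg_sites <- function(region_seq) find_motif_positions(region_seq, "ATG")
find_stop_anchored_ends <- function(region_seq) {
  p <- find_motif_positions(region_seq, STOP_CODONS)
  p[p + 3L <= nchar(region_seq)]
}

# core pairing of start/end site lists under the frame/length constraints;
# returns a data.frame of region-local (start, end)
pair_sites <- function(starts, ends, query_dna_length,
                       allowed_length_difference) {
  if (!length(starts) || !length(ends)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  maxd <- 3L * allowed_length_difference
  ends <- sort(ends)
  res_s <- integer(0); res_e <- integer(0)
  for (s in starts) {
    lo <- max(s + 3L, s + query_dna_length - maxd)
    hi <- s + query_dna_length + maxd
    sel <- ends[ends >= lo & ends <= hi]
    sel <- sel[(sel - s - query_dna_length) %% 3L == 0L]
    if (length(sel)) {
      res_s <- c(res_s, rep.int(s, length(sel)))
      res_e <- c(res_e, sel)
    }
  }
  out <- data.frame(start = res_s, end = res_e)
  out[order(out$start, out$end), , drop = FALSE]
}

# drop candidates whose body contains N
drop_n_bodies <- function(cand, region_seq) {
  if (!nrow(cand)) return(cand)
  bodies <- substr(rep(region_seq, nrow(cand)), cand$start + 1L, cand$end)
  cand[!grepl("N", bodies, fixed = TRUE), , drop = FALSE]
}

#' Enumerate candidate intervals in one region
#'
#' Low-level enumeration working directly from a region sequence and the
#' splice context of the query exon; [enumerate_candidates()] wraps it with
#' gene-structure bookkeeping.
#'
#' @param region_seq nucleotide string of the region.
#' @param region_start genomic coordinate of the region's first base.
#' @param query_dna_length query exon body length (nt).
#' @param params a [search_params()].
#' @param start_anchor `"acceptor"` or `"atg"`.
#' @param end_anchor `"donor"` or `"stop"`.
#' @param acc_targets,don_targets admissible dinucleotides for
#'   splice-anchored sides.
#' @param intron_region `TRUE` if the region is an intron interior (boundary
#'   margins apply on splice-anchored sides).
#' @return data.frame with genomic `start`, `end` (0-based half-open),
#'   sorted by (start, end).
#' @export
enumerate_in_region <- function(region_seq, region_start, query_dna_length,
                                params,
                                start_anchor = "acceptor",
                                end_anchor = "donor",
                                acc_targets = character(0),
                                don_targets = character(0),
                                intron_region = TRUE) {
  margin <- if (intron_region) params$min_new_intron_length else 0L
  starts <- switch(start_anchor,
    acceptor = find_acceptor_sites(region_seq, acc_targets, margin),
    atg = find_atg_sites(region_seq),
    stop("unknown start anchor: ", start_anchor))
  ends <- switch(end_anchor,
    donor = find_donor_sites(region_seq, don_targets, margin),
    stop = find_stop_anchored_ends(region_seq),
    stop("unknown end anchor: ", end_anchor))
  cand <- pair_sites(starts, ends, query_dna_length,
                     params$allowed_length_difference)
  cand <- drop_n_bodies(cand, region_seq)
  cand$start <- cand$start + region_start
  cand$end <- cand$end + region_start
  cand
}

# anchoring of a query exon given the search parameters; NULL anchors mean
# the exon cannot be searched (logged by the caller)
exon_anchoring <- function(gene, exon_index, params) {
  ex <- gene$exons[exon_index, ]
  n <- nrow(gene$exons)
  start_anchor <- "acceptor"; end_anchor <- "donor"
  acc <- character(0); don <- character(0)
  reason <- NULL

  use_start_codon <- switch(params$search_with_start_codon,
    on = TRUE, off = FALSE, auto = gene$starts_with_met)
  use_stop_codon <- switch(params$search_with_stop_codon,
    on = TRUE, off = FALSE, auto = gene$followed_by_stop)

  if (ex$is_first) {
    if (!use_start_codon) {
      return(list(reason = "first exon without start-codon anchoring"))
    }
    start_anchor <- "atg"
  } else {
    d <- gene$introns$donor[exon_index - 1L]
    acc <- acceptor_targets(d)
    if (!length(acc)) {
      return(list(reason = paste0("non-canonical donor '", d,
                                  "' on upstream intron")))
    }
  }
  if (ex$is_last) {
    if (!use_stop_codon) {
      return(list(reason = "last exon without stop-codon anchoring"))
    }
    end_anchor <- "stop"
  } else {
    a <- gene$introns$acceptor[exon_index]
    don <- donor_targets(a)
    if (!length(don)) {
      return(list(reason = paste0("non-canonical acceptor '", a,
                                  "' on downstream intron")))
    }
  }
  list(start_anchor = start_anchor, end_anchor = end_anchor,
       acc_targets = acc, don_targets = don, reason = NULL)
}

#' Enumerate candidate exons for a query exon in one search region
#'
#' Applies the splice-pattern, frame, length-window, boundary-margin and
#' N-content constraints and returns every admissible interval. Query exons
#' shorter than `min_exon_length` amino acids yield no candidates.
#'
#' @param gene a [gene_structure][derive_gene_structure].
#' @param exon_index 1-based index of the query exon.
#' @param region list with `start`, `end` (genomic, 0-based half-open) and
#'   `role` (one of `upstream_intron`, `downstream_intron`, `other_intron`,
#'   `upstream_region`, `downstream_region`).
#' @param params a [search_params()].
#' @return data.frame with `start`, `end`, `role`, `query_exon`.
#' @export
enumerate_candidates <- function(gene, exon_index, region, params) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      role = character(0), query_exon = integer(0))
  if (gene$exons$aa_length[exon_index] < params$min_exon_length) return(empty)
  anch <- exon_anchoring(gene, exon_index, params)
  if (!is.null(anch$reason)) return(empty)
  region_seq <- subseq0(gene$sequence, region$start, region$end)
  cand <- enumerate_in_region(
    region_seq, region$start,
    gene$exons$end[exon_index] - gene$exons$start[exon_index],
    params,
    start_anchor = anch$start_anchor, end_anchor = anch$end_anchor,
    acc_targets = anch$acc_targets, don_targets = anch$don_targets,
    intron_region = grepl("intron", region$role))
  if (!nrow(cand)) return(empty)
  cand$role <- region$role
  cand$query_exon <- exon_index
  cand
}

#' First- and last-exon candidate enumeration
#'
#' Convenience wrappers over [enumerate_candidates()] for terminal exons:
#' first-exon candidates are anchored at `ATG` start codons, last-exon
#' candidates must be followed by an in-frame stop codon.
#'
#' @inheritParams enumerate_candidates
#' @export
enumerate_first_exon_candidates <- function(gene, region, params) {
  stopifnot(gene$exons$is_first[1L])
  enumerate_candidates(gene, 1L, region, params)
}

#' @rdname enumerate_first_exon_candidates
#' @export
enumerate_last_exon_candidates <- function(gene, region, params) {
  enumerate_candidates(gene, nrow(gene$exons), region, params)
}
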