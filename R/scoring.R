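# Candidate scoring: in-frame translation, Gotoh affine-gap global alignment
# against the query exon with Blosum62, self-score normalization,
# thresholding, and overlap resolution.

#' Alignment parameters
#'
#' Gap model: a run of `L` gap positions costs
#' `gap_open + (L - 1) * gap_extend`, i.e. -10 for the first gap position and
#' -2 for each further one under the defaults. Terminal gaps are penalized
#' like internal gaps (true global alignment).
#'
#' @param substitution_matrix named symmetric integer matrix; defaults to
#'   Blosum62 (as distributed with Biostrings).
#' @param gap_open score of the first position of a gap run (default -10).
#' @param gap_extend score of each further gap position (default -2).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = blosum62(),
                             gap_open = -10, gap_extend = -2) {
  stopifnot(is.matrix(substitution_matrix),
            identical(rownames(substitution_matrix),
                      colnames(substitution_matrix)),
            isTRUE(all.equal(substitution_matrix, t(substitution_matrix))),
            gap_open <= gap_extend, gap_extend <= 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' The Blosum62 substitution matrix
#'
#' @return the Blosum62 matrix distributed with Biostrings (20 amino acids
#'   plus B, Z, X and `*`).
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path path to a matrix file as distributed by NCBI (comment lines
#'   starting with `#`, one header row of residues, one labelled row per
#'   residue).
#' @return named numeric matrix.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}

encode_aa <- function(x, mat) {
  if (nchar(x) == 0L) return(integer(0))
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  i <- match(ch, rownames(mat))
  if (anyNA(i)) {
    xi <- match("X", rownames(mat))
    if (is.na(xi)) stop("residue(s) ", paste(unique(ch[is.na(i)]),
                                             collapse = ""),
                        " absent from substitution matrix (no X row)")
    i[is.na(i)] <- xi
  }
  i
}

#' Gotoh global alignment with affine gap costs
#'
#' Computes the optimal global alignment score of two amino-acid sequences
#' under the gap model of [alignment_params()], plus one optimal traceback.
#' Ties are broken by preferring match/mismatch over a gap in `a` over a gap
#' in `b`.
#'
#' @param a,b amino-acid strings (empty allowed).
#' @param params an [alignment_params()].
#' @return list with `score` and the gapped strings `a` and `b`.
#' @export
#' @examples
#' gotoh_align("MA", "MA")$score  # 5 + 4 on Blosum62
gotoh_align <- function(a, b, params = alignment_params()) {
  S <- params$substitution_matrix
  r <- gotoh_align_cpp(encode_aa(a, S), encode_aa(b, S), S,
                       params$gap_open, params$gap_extend)
  ach <- strsplit(a, "", fixed = TRUE)[[1L]]
  bch <- strsplit(b, "", fixed = TRUE)[[1L]]
  ga <- character(length(r$moves)); gb <- character(length(r$moves))
  i <- 0L; j <- 0L
  for (k in seq_along(r$moves)) {
    mv <- r$moves[k]
    if (mv == 1L) { i <- i + 1L; j <- j + 1L; ga[k] <- ach[i]; gb[k] <- bch[j] }
    else if (mv == 2L) { j <- j + 1L; ga[k] <- "-"; gb[k] <- bch[j] }
    else { i <- i + 1L; ga[k] <- ach[i]; gb[k] <- "-" }
  }
  list(score = r$score,
       a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Relative alignment score of a candidate against its query
#'
#' The raw Gotoh score is divided by the query's self-alignment score, giving
#' a similarity on a scale where identity is 1.0.
#'
#' @param candidate_aa,query_aa amino-acid strings.
#' @param params an [alignment_params()].
#' @return numeric relative score (at most 1 for a diagonal-dominant
#'   matrix).
#' @export
relative_score <- function(candidate_aa, query_aa,
                           params = alignment_params()) {
  self <- gotoh_align(query_aa, query_aa, params)$score
  if (self <= 0) stop("query self-score is not positive; query skipped")
  gotoh_align(candidate_aa, query_aa, params)$score / self
}

#' Translate and score candidate intervals against a query exon
#'
#' Each candidate is translated in the query's reading frame (split codons
#' completed from the query's flanking exons); candidates with an in-frame
#' stop codon, untranslatable codons (N) or more than 50% `X` are rejected
#' before alignment, the rest are scored and marked accepted when their
#' relative score reaches `min_score`.
#'
#' @param gene a [gene_structure][derive_gene_structure].
#' @param exon_index 1-based query exon index.
#' @param candidates data.frame from [enumerate_candidates()].
#' @param params a [search_params()].
#' @return data.frame of scored candidates (`start`, `end`, `role`,
#'   `translation`, `raw_score`, `self_score`, `relative_score`, `accepted`,
#'   `reject_reason`, `aln_query`, `aln_candidate`).
#' @export
score_candidates <- function(gene, exon_index, candidates, params) {
  ap <- params$alignment
  qaa <- exon_translation(gene, exon_index)
  self <- gotoh_align(qaa, qaa, ap)$score
  if (self <= 0) stop("query self-score is not positive; query skipped")
  comp <- exon_completions(gene, exon_index)
  phase <- gene$exons$start_phase[exon_index]

  n <- nrow(candidates)
  out <- candidates
  out$translation <- rep(NA_character_, n)
  out$raw_score <- rep(NA_real_, n)
  out$self_score <- rep(self, n)
  out$relative_score <- rep(NA_real_, n)
  out$accepted <- rep(FALSE, n)
  out$reject_reason <- rep(NA_character_, n)
  out$aln_query <- rep(NA_character_, n)
  out$aln_candidate <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    body <- subseq0(gene$sequence, out$start[k], out$end[k])
    aa <- translate_in_frame(body, phase, comp$up, comp$down)
    if (is.na(aa)) { out$reject_reason[k] <- "untranslatable"; next }
    out$translation[k] <- aa
    if (grepl("*", aa, fixed = TRUE)) {
      out$reject_reason[k] <- "in-frame stop"; next
    }
    nx <- lengths(regmatches(aa, gregexpr("X", aa, fixed = TRUE)))
    if (nx > nchar(aa) / 2) { out$reject_reason[k] <- "excess X"; next }
    al <- gotoh_align(aa, qaa, ap)
    out$raw_score[k] <- al$score
    out$relative_score[k] <- al$score / self
    out$aln_candidate[k] <- al$a
    out$aln_query[k] <- al$b
    if (out$relative_score[k] >= params$min_score - 1e-9) {
      out$accepted[k] <- TRUE
    } else {
      out$reject_reason[k] <- "low score"
    }
  }
  out
}

#' Resolve overlapping accepted candidates
#'
#' Greedy selection ordered by relative score (descending), DNA length
#' (descending), then start (ascending): a candidate is kept iff it shares
#' no genomic base with an already kept one. The output is invariant under
#' permutation of the input rows.
#'
#' @param scored data.frame of accepted candidates of one query exon.
#' @return subset of `scored`, pairwise non-overlapping, sorted by start.
#' @export
resolve_overlaps <- function(scored) {
  acc <- scored[scored$accepted, , drop = FALSE]
  if (nrow(acc) <= 1L) return(acc)
  ord <- order(-acc$relative_score, -(acc$end - acc$start), acc$start)
  acc <- acc[ord, , drop = FALSE]
  keep <- logical(nrow(acc))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(acc))) {
    if (!any(acc$start[i] < ke & acc$end[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, acc$start[i]); ke <- c(ke, acc$end[i])
    }
  }
  out <- acc[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
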