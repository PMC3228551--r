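# Annotation-scale screening: run the search over every multi-exon
# transcript, extract annotation-defined MXE clusters, scan neighbouring
# exons for MXE-like features, and compute agreement statistics.

#' Screen an annotation for mutually exclusive exon candidates
#'
#' Runs [search_transcript()] on every transcript with more than one exon,
#' pools predictions per gene, extracts annotation-defined mutually
#' exclusive clusters, performs the neighbour-exon similarity scan, and
#' assembles a report. The default parameters are the screening settings
#' (length difference 20 aa, minimal score 15%, minimal exon length 15 aa,
#' surrounding introns only, no recursion).
#'
#' @param genome named character vector of sequences (from [read_fasta()])
#'   or a FASTA path.
#' @param annotation list of gene structures (from [read_gff3()]) or a GFF3
#'   path.
#' @param params a [search_params()].
#' @return a `screen_report`: list with `n_genes`, `n_transcripts`,
#'   `n_exons`, `predicted` (counts of exons/clusters/genes by
#'   classification), `table` (per-candidate record table), `annotated`
#'   (annotation-defined clusters), `evaluation` (sensitivity/specificity,
#'   see [evaluate_against_annotation()]), `neighbour` (see
#'   [neighbour_similarity_scan()]), `skipped`.
#' @export
chromosome_screen <- function(genome, annotation,
                              params = search_params()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(annotation)) {
    annotation <- read_gff3(annotation, genome, strict = FALSE)
  }
  multi <- Filter(function(g) nrow(g$exons) > 1L, annotation)
  skipped <- attr(annotation, "log")

  tabs <- list(); results <- list()
  for (g in multi) {
    res <- search_transcript(g, params)
    results[[g$transcript_id]] <- res
    tab <- result_table(res)
    if (nrow(tab)) tabs[[length(tabs) + 1L]] <- tab
  }
  table <- if (length(tabs)) do.call(rbind, tabs) else result_table(
    structure(list(clusters = list(),
                   gene = list(seq_id = "", transcript_id = "",
                               gene_id = "")), class = "search_result"))

  gene_ids <- unique(vapply(annotation, `[[`, character(1), "gene_id"))
  annotated <- list()
  for (gid in gene_ids) {
    txs <- Filter(function(g) g$gene_id == gid, annotation)
    annotated <- c(annotated, annotated_mxe_clusters(txs))
  }
  evaluation <- evaluate_against_annotation(table, annotated)
  neighbour <- neighbour_similarity_scan(multi, params)

  pred_rows <- table[!table$is_query, , drop = FALSE]
  by_class <- function(rows, what) {
    cls <- c("internal_mxe", "multiple_promoter_like",
             "multiple_polyA_like", "group_pattern")
    vapply(cls, function(cc) {
      r <- rows[rows$classification == cc, , drop = FALSE]
      switch(what,
             exons = nrow(r),
             clusters = nrow(unique(r[, c("transcript_id", "cluster_id")])),
             genes = length(unique(r$gene_id)))
    }, integer(1))
  }
  structure(list(
    n_genes = length(gene_ids),
    n_transcripts = length(multi),
    n_exons = sum(vapply(multi, function(g) nrow(g$exons), integer(1))),
    predicted = list(exons = by_class(pred_rows, "exons"),
                     clusters = by_class(pred_rows, "clusters"),
                     genes = by_class(pred_rows, "genes")),
    table = table,
    annotated = annotated,
    evaluation = evaluation,
    neighbour = neighbour,
    skipped = skipped,
    params = params), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("mxescan screen: ", x$n_genes, " gene(s), ", x$n_transcripts,
      " multi-exon transcript(s), ", x$n_exons, " exon(s)\n", sep = "")
  cat("predicted exons by class:\n")
  print(x$predicted$exons)
  cat(sprintf("annotated internal MXE exons: %d\n",
              x$evaluation$n_annotated))
  cat(sprintf("sensitivity %.3f (%d/%d), specificity %.3f (%d/%d)\n",
              x$evaluation$sensitivity, x$evaluation$n_matched,
              x$evaluation$n_annotated, x$evaluation$specificity,
              x$evaluation$n_matched, x$evaluation$n_predicted))
  cat(sprintf("neighbour scan: %d exon(s), %d transcript(s), %d gene(s)\n",
              x$neighbour$n_exons_flagged, x$neighbour$n_transcripts_flagged,
              x$neighbour$n_genes_flagged))
  invisible(x)
}

#' Annotation-defined mutually exclusive exon clusters of one gene
#'
#' A set of exons is a cluster of mutually exclusive spliced exons if each
#' transcript of the gene contains exactly one exon of the set, the set has
#' at least two exons, the exons are neighbouring (no other exon of the gene
#' between them), and the cluster is surrounded by further exons on both
#' sides (`flanked`). Unflanked sets are reported with `terminal_side` set
#' (multiple-promoter / multiple-poly(A) types). Sets in which members come
#' in blocks of two or more exons per transcript are flagged
#' `group_type` (trans-splice-like) instead.
#'
#' @param transcripts list of gene structures of one gene (same normalized
#'   sequence).
#' @return list of clusters: each a list with `gene_id`, `members`
#'   (data.frame of `start`, `end`), `flanked`, `terminal_side`
#'   (`"none"`, `"first"` or `"last"`) and `group_type`.
#' @export
annotated_mxe_clusters <- function(transcripts) {
  if (!length(transcripts)) return(list())
  gid <- transcripts[[1L]]$gene_id
  ex_by_tx <- lapply(transcripts, function(g)
    paste(g$exons$start, g$exons$end, sep = "-"))
  all_keys <- sort(unique(unlist(ex_by_tx)))
  parts <- do.call(rbind, lapply(strsplit(all_keys, "-", fixed = TRUE),
                                 as.integer))
  ex <- data.frame(start = parts[, 1L], end = parts[, 2L], key = all_keys,
                   stringsAsFactors = FALSE)
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(list())

  count_in_window <- function(tx_keys, keys) sum(tx_keys %in% keys)
  clusters <- list()
  covered <- rep(FALSE, n)
  # windows from largest to smallest so that only maximal sets are reported
  for (size in n:2) {
    for (i in seq_len(n - size + 1L)) {
      j <- i + size - 1L
      if (any(covered[i:j])) next
      win <- ex[i:j, , drop = FALSE]
      # members must be pairwise non-overlapping
      if (any(win$start[-1L] < win$end[-size])) next
      counts <- vapply(ex_by_tx, count_in_window, integer(1),
                       keys = win$key)
      group_type <- FALSE
      if (all(counts == 1L)) {
        # each transcript contains exactly one member: true MXE-style set
      } else if (all(counts == counts[1L]) && counts[1L] >= 2L) {
        # members come in equal-sized, pairwise-disjoint blocks of
        # consecutive exons per transcript: trans-splice-like group
        contiguous <- vapply(ex_by_tx, function(keys)
          all(diff(which(keys %in% win$key)) == 1L), logical(1))
        if (!all(contiguous)) next
        blocks <- unique(lapply(ex_by_tx, function(keys)
          sort(intersect(keys, win$key))))
        if (length(blocks) < 2L) next
        if (anyDuplicated(unlist(blocks))) next
        group_type <- TRUE
      } else {
        next                                   # "exactly one" violated
      }
      # neighbouring: no other exon of the gene inside the window span
      span_s <- min(win$start); span_e <- max(win$end)
      others <- ex[-(i:j), , drop = FALSE]
      if (any(others$start < span_e & others$end > span_s)) next
      before <- vapply(seq_along(transcripts), function(t)
        any(transcripts[[t]]$exons$end <= span_s), logical(1))
      after <- vapply(seq_along(transcripts), function(t)
        any(transcripts[[t]]$exons$start >= span_e), logical(1))
      flanked <- all(before) && all(after)
      terminal_side <- if (flanked) "none"
        else if (!any(before)) "first"
        else if (!any(after)) "last"
        else "none"
      if (!flanked && terminal_side == "none") next
      clusters[[length(clusters) + 1L]] <- list(
        gene_id = gid,
        members = win[, c("start", "end")],
        flanked = flanked,
        terminal_side = terminal_side,
        group_type = group_type)
      covered[i:j] <- TRUE
    }
  }
  clusters
}

#' Neighbour-exon similarity scan
#'
#' Compares every pair of adjacent exons in every transcript with respect to
#' the features of mutually exclusive exons: both at least
#' `min_exon_length` amino acids, length difference at most
#' `allowed_length_difference` amino acids with a DNA difference that is a
#' multiple of 3, the same reading frame (equal start phases), and a
#' relative alignment score of at least `min_score` (the upstream exon of
#' the pair is the normalizing query).
#'
#' @param transcripts list of gene structures.
#' @param params a [search_params()].
#' @return list with `pairs` (data.frame of all considered pairs with a
#'   `flagged` column) and the counts `n_exons_flagged`,
#'   `n_transcripts_flagged`, `n_genes_flagged`.
#' @export
neighbour_similarity_scan <- function(transcripts,
                                      params = search_params()) {
  rows <- list()
  for (g in transcripts) {
    ex <- g$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      j <- i + 1L
      long_enough <- ex$aa_length[i] >= params$min_exon_length &&
        ex$aa_length[j] >= params$min_exon_length
      d <- (ex$end[j] - ex$start[j]) - (ex$end[i] - ex$start[i])
      frame_ok <- d %% 3L == 0L &&
        abs(d) <= 3L * params$allowed_length_difference
      same_frame <- ex$start_phase[i] == ex$start_phase[j]
      rel <- NA_real_
      if (long_enough && frame_ok && same_frame) {
        rel <- relative_score(exon_translation(g, j), exon_translation(g, i),
                              params$alignment)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, transcript_id = g$transcript_id,
        exon_i = i, exon_j = j,
        aa_i = ex$aa_length[i], aa_j = ex$aa_length[j],
        long_enough = long_enough, frame_ok = frame_ok,
        same_frame = same_frame, relative_score = rel,
        flagged = isTRUE(long_enough && frame_ok && same_frame &&
                           !is.na(rel) &&
                           rel >= params$min_score - 1e-9),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               exon_i = integer(0), exon_j = integer(0),
               aa_i = integer(0), aa_j = integer(0),
               long_enough = logical(0), frame_ok = logical(0),
               same_frame = logical(0), relative_score = numeric(0),
               flagged = logical(0), stringsAsFactors = FALSE)
  fl <- pairs[pairs$flagged, , drop = FALSE]
  n_exons <- if (nrow(fl)) {
    sum(vapply(split(fl, fl$transcript_id), function(d)
      length(unique(c(d$exon_i, d$exon_j))), integer(1)))
  } else 0L
  list(pairs = pairs,
       n_exons_flagged = n_exons,
       n_transcripts_flagged = length(unique(fl$transcript_id)),
       n_genes_flagged = length(unique(fl$gene_id)))
}

#' Compare predictions with annotation-defined clusters
#'
#' The predicted set P consists of all members (query exons and accepted
#' candidates) of non-trivial internal clusters; the annotated set A of all
#' members of flanked, non-group annotation-defined clusters. Matching is by
#' exact exon borders within the same gene. Sensitivity is |M|/|A| and
#' specificity |M|/|P| with M the matched set; predicted exons overlapping
#' an annotated alternative exon without matching its borders are listed
#' separately.
#'
#' @param predictions a result table ([result_table()] rows, possibly
#'   pooled over transcripts).
#' @param annotated list of clusters from [annotated_mxe_clusters()].
#' @return list with `sensitivity`, `specificity`, `n_matched`,
#'   `n_annotated`, `n_predicted`, `n_overlap_only` and the match table.
#' @export
evaluate_against_annotation <- function(predictions, annotated) {
  ann <- annotated[vapply(annotated, function(a)
    a$flanked && !a$group_type, logical(1))]
  ann_rows <- if (length(ann)) do.call(rbind, lapply(ann, function(a)
    data.frame(gene_id = a$gene_id, start = a$members$start,
               end = a$members$end, stringsAsFactors = FALSE)))
    else data.frame(gene_id = character(0), start = integer(0),
                    end = integer(0))
  ann_rows <- unique(ann_rows)

  pred <- predictions[predictions$classification == "internal_mxe", ,
                      drop = FALSE]
  pred <- unique(pred[, c("gene_id", "start", "end")])
  pred <- pred[order(pred$gene_id, pred$start), , drop = FALSE]
  pkey <- paste(pred$gene_id, pred$start, pred$end)
  akey <- paste(ann_rows$gene_id, ann_rows$start, ann_rows$end)
  matched <- pkey %in% akey
  overlap_only <- vapply(seq_len(nrow(pred)), function(i) {
    if (matched[i]) return(FALSE)
    any(ann_rows$gene_id == pred$gene_id[i] &
          ann_rows$start < pred$end[i] & ann_rows$end > pred$start[i])
  }, logical(1))
  n_matched <- sum(akey %in% pkey)
  list(
    sensitivity = if (nrow(ann_rows)) n_matched / nrow(ann_rows) else NA_real_,
    specificity = if (nrow(pred)) sum(matched) / nrow(pred) else NA_real_,
    n_matched = n_matched,
    n_annotated = nrow(ann_rows),
    n_predicted = nrow(pred),
    n_overlap_only = sum(overlap_only),
    matches = cbind(pred, matched = matched, overlap_only = overlap_only))
}

#' Compare two exon interval sets
#'
#' @param set_a,set_b data.frames with `start`, `end` columns (optionally a
#'   `seqid` column).
#' @return list with `n_a`, `n_b`, `exact` (intervals of `set_a` present in
#'   `set_b`) and `overlap` (intervals of `set_a` overlapping at least one
#'   interval of `set_b` by one or more bases).
#' @export
compare_exon_sets <- function(set_a, set_b) {
  norm <- function(x) {
    x <- as.data.frame(x)
    if (!"seqid" %in% names(x)) x$seqid <- "."
    x[, c("seqid", "start", "end")]
  }
  a <- norm(set_a); b <- norm(set_b)
  akey <- paste(a$seqid, a$start, a$end)
  bkey <- paste(b$seqid, b$start, b$end)
  ov <- vapply(seq_len(nrow(a)), function(i)
    any(b$seqid == a$seqid[i] & b$start < a$end[i] & b$end > a$start[i]),
    logical(1))
  list(n_a = nrow(a), n_b = nrow(b),
       exact = sum(akey %in% bkey), overlap = sum(ov))
}
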