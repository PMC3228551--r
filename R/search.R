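# Per-exon and per-transcript search: region selection, enumeration,
# scoring, overlap resolution, optional recursion, cluster classification,
# and group-pattern (tandem-duplication / trans-splice) detection.

#' Search parameters
#'
#' Every user-tunable knob of the search with its default.
#'
#' @param allowed_length_difference maximum query/candidate length
#'   difference in amino acids (default 20).
#' @param min_score minimal relative alignment score for acceptance
#'   (default 0.15; values above 1 are interpreted as percent).
#' @param min_exon_length minimal query exon length in amino acids;
#'   shorter query exons are not searched (default 15).
#' @param max_recursion_depth number of recursive rounds with found
#'   candidates as queries, 0-3 (default 0 = disabled).
#' @param search_all_introns scan all introns of the gene instead of only
#'   the two surrounding ones (default `FALSE`).
#' @param search_updownstream scan the up-/downstream regions of the gene
#'   (default `FALSE`).
#' @param region_size size of the up-/downstream windows in nt
#'   (default 10000).
#' @param search_with_start_codon `"auto"`, `"on"` or `"off"`: anchor
#'   first-exon candidates at ATG; `"auto"` enables it iff the protein
#'   starts with methionine.
#' @param search_with_stop_codon `"auto"`, `"on"` or `"off"`: require a
#'   stop codon after last-exon candidates; `"auto"` enables it iff the
#'   last exon is followed by a stop codon.
#' @param min_new_intron_length minimal length of the intron pieces implied
#'   by splicing in a candidate (default 4 nt: room for both
#'   dinucleotides).
#' @param group_min_exons minimal number of consecutive query exons whose
#'   candidates must form a parallel ordered group to flag a
#'   tandem-duplication / trans-splice pattern (default 2).
#' @param alignment an [alignment_params()].
#' @param seed integer seed, used only by fixture generation.
#' @return list of class `search_params`.
#' @export
search_params <- function(allowed_length_difference = 20,
                          min_score = 0.15,
                          min_exon_length = 15,
                          max_recursion_depth = 0,
                          search_all_introns = FALSE,
                          search_updownstream = FALSE,
                          region_size = 10000,
                          search_with_start_codon = c("auto", "on", "off"),
                          search_with_stop_codon = c("auto", "on", "off"),
                          min_new_intron_length = 4,
                          group_min_exons = 2,
                          alignment = alignment_params(),
                          seed = 1L) {
  if (is.character(min_score)) {
    min_score <- as.numeric(sub("%", "", min_score, fixed = TRUE)) / 100
  } else if (min_score > 1) {
    min_score <- min_score / 100
  }
  search_with_start_codon <- match.arg(search_with_start_codon)
  search_with_stop_codon <- match.arg(search_with_stop_codon)
  stopifnot(allowed_length_difference >= 0, min_score >= 0,
            min_exon_length >= 0,
            max_recursion_depth >= 0, max_recursion_depth <= 3,
            region_size >= 0, min_new_intron_length >= 0,
            group_min_exons >= 2)
  structure(list(
    allowed_length_difference = allowed_length_difference,
    min_score = min_score,
    min_exon_length = min_exon_length,
    max_recursion_depth = as.integer(max_recursion_depth),
    search_all_introns = isTRUE(search_all_introns),
    search_updownstream = isTRUE(search_updownstream),
    region_size = as.integer(region_size),
    search_with_start_codon = search_with_start_codon,
    search_with_stop_codon = search_with_stop_codon,
    min_new_intron_length = as.integer(min_new_intron_length),
    group_min_exons = as.integer(group_min_exons),
    alignment = alignment,
    seed = as.integer(seed)), class = "search_params")
}

# search regions for one query exon under the scope parameters
regions_for_exon <- function(gene, exon_index, params) {
  ex <- gene$exons[exon_index, ]
  n_introns <- nrow(gene$introns)
  regions <- list()
  add <- function(start, end, role) {
    if (end - start >= 3L) {
      regions[[length(regions) + 1L]] <<- list(start = start, end = end,
                                               role = role)
    }
    invisible(NULL)
  }
  intron_role <- function(i) {
    if (i == exon_index - 1L) "upstream_intron"
    else if (i == exon_index) "downstream_intron"
    else "other_intron"
  }
  if (params$search_all_introns) {
    for (i in seq_len(n_introns)) {
      add(gene$introns$start[i], gene$introns$end[i], intron_role(i))
    }
  } else {
    if (exon_index > 1L) {
      add(gene$introns$start[exon_index - 1L],
          gene$introns$end[exon_index - 1L], "upstream_intron")
    }
    if (exon_index <= n_introns) {
      add(gene$introns$start[exon_index],
          gene$introns$end[exon_index], "downstream_intron")
    }
  }
  if (params$search_updownstream) {
    terminal <- ex$is_first || ex$is_last
    # internal exons reach the flanks only in the gene-duplication /
    # trans-splice screening mode (all introns + flanks)
    if (terminal || params$search_all_introns) {
      L <- nchar(gene$sequence)
      g_start <- gene$exons$start[1L]
      g_end <- gene$exons$end[nrow(gene$exons)]
      if (ex$is_first || params$search_all_introns) {
        add(max(0L, g_start - params$region_size), g_start,
            "upstream_region")
      }
      if (ex$is_last || params$search_all_introns) {
        add(g_end + 3L, min(L, g_end + 3L + params$region_size),
            "downstream_region")
      }
    }
  }
  regions
}

new_cluster <- function(gene, exon_index, members, classification) {
  structure(list(query_exon = exon_index, members = members,
                 classification = classification,
                 recursion_rounds_used = max(members$depth)),
            class = "exon_cluster")
}

query_member_row <- function(gene, exon_index, self_score) {
  ex <- gene$exons[exon_index, ]
  data.frame(start = ex$start, end = ex$end, role = "query",
             query_exon = exon_index,
             translation = exon_translation(gene, exon_index),
             raw_score = self_score, self_score = self_score,
             relative_score = 1.0, accepted = TRUE,
             reject_reason = NA_character_,
             aln_query = NA_character_, aln_candidate = NA_character_,
             is_query = TRUE, depth = 0L,
             matches_annotated = FALSE, stringsAsFactors = FALSE)
}

#' Search one query exon for mutually exclusive candidates
#'
#' Enumerates candidates in the exon's search regions (the two surrounding
#' introns by default), pools them, translates, scores, thresholds and
#' overlap-resolves across the pool, then assembles and classifies the
#' cluster. With `max_recursion_depth > 0` the search is repeated with the
#' found candidates as queries.
#'
#' @param gene a [gene_structure][derive_gene_structure].
#' @param exon_index 1-based query exon index.
#' @param params a [search_params()].
#' @return an `exon_cluster`: list with `query_exon`, `members` (data.frame,
#'   member 1 is the annotated exon), `classification`,
#'   `recursion_rounds_used`; or `NULL` with attribute `"reason"` when the
#'   exon was skipped.
#' @export
search_exon <- function(gene, exon_index, params = search_params()) {
  skip <- function(reason) {
    structure(list(), class = "exon_skip", reason = reason,
              query_exon = exon_index)
  }
  if (gene$exons$aa_length[exon_index] < params$min_exon_length) {
    return(skip(sprintf("query exon of %d aa below minimal exon length %d",
                        gene$exons$aa_length[exon_index],
                        params$min_exon_length)))
  }
  anch <- exon_anchoring(gene, exon_index, params)
  if (!is.null(anch$reason)) return(skip(anch$reason))

  regions <- regions_for_exon(gene, exon_index, params)
  pool <- do.call(rbind, c(
    lapply(regions, function(rg) enumerate_candidates(gene, exon_index, rg,
                                                      params)),
    list(make.row.names = FALSE)))
  if (is.null(pool)) {
    pool <- data.frame(start = integer(0), end = integer(0),
                       role = character(0), query_exon = integer(0))
  }
  scored <- score_candidates(gene, exon_index, pool, params)
  kept <- resolve_overlaps(scored)
  self <- if (nrow(scored)) scored$self_score[1L] else
    gotoh_align(exon_translation(gene, exon_index),
                exon_translation(gene, exon_index), params$alignment)$score
  if (nrow(kept)) {
    kept$is_query <- FALSE
    kept$depth <- 0L
    kept$matches_annotated <- interval_in_set(kept$start, kept$end,
                                              gene$exons$start,
                                              gene$exons$end)
  }
  members <- rbind(query_member_row(gene, exon_index, self), kept)
  members <- members[order(members$start), , drop = FALSE]
  rownames(members) <- NULL
  cl <- new_cluster(gene, exon_index, members,
                    classify_kind(gene$exons$kind[exon_index]))
  if (params$max_recursion_depth > 0L) {
    cl <- recursive_expand(gene, cl, params)
  }
  cl
}

interval_in_set <- function(s, e, set_s, set_e) {
  vapply(seq_along(s), function(i) any(set_s == s[i] & set_e == e[i]),
         logical(1))
}

classify_kind <- function(kind) {
  switch(kind,
         internal = "internal_mxe",
         first = "multiple_promoter_like",
         single = "multiple_promoter_like",
         last = "multiple_polyA_like")
}

#' Classify a cluster by the position of its query exon
#'
#' Internal query exons give `internal_mxe`, first exons
#' `multiple_promoter_like`, last exons `multiple_polyA_like`.
#' [detect_group_pattern()] may override the label with `group_pattern`.
#'
#' @param cluster an `exon_cluster`.
#' @param gene the gene structure it belongs to.
#' @return classification label.
#' @export
classify_cluster <- function(cluster, gene) {
  classify_kind(gene$exons$kind[cluster$query_exon])
}

#' Recursive expansion of a cluster
#'
#' Repeats the search with every found candidate as a query (its own
#' translation, its inherited frame), up to `max_recursion_depth` rounds or
#' until a fixed point. New candidates are deduplicated by exact genomic
#' interval and overlap-resolved against existing members, which always win;
#' previously accepted members are never removed.
#'
#' @param gene a gene structure.
#' @param cluster an `exon_cluster` from the depth-0 search.
#' @param params a [search_params()].
#' @return the expanded `exon_cluster`.
#' @export
recursive_expand <- function(gene, cluster, params) {
  if (params$max_recursion_depth < 1L) return(cluster)
  exon_index <- cluster$query_exon
  anch <- exon_anchoring(gene, exon_index, params)
  if (!is.null(anch$reason)) return(cluster)
  regions <- regions_for_exon(gene, exon_index, params)
  comp <- exon_completions(gene, exon_index)
  phase <- gene$exons$start_phase[exon_index]
  members <- cluster$members
  rounds_used <- 0L

  for (depth in seq_len(params$max_recursion_depth)) {
    # round 1 uses the depth-0 candidates as queries, later rounds the
    # members added in the previous round; re-querying older members cannot
    # add intervals that their own round did not already contribute
    new_queries <- members[members$depth == depth - 1L & !members$is_query, ,
                           drop = FALSE]
    if (!nrow(new_queries)) break
    found <- list()
    for (q in seq_len(nrow(new_queries))) {
      qrow <- new_queries[q, ]
      qaa <- qrow$translation
      qlen <- qrow$end - qrow$start
      qself <- gotoh_align(qaa, qaa, params$alignment)$score
      if (qself <= 0) next
      for (rg in regions) {
        region_seq <- subseq0(gene$sequence, rg$start, rg$end)
        cand <- enumerate_in_region(
          region_seq, rg$start, qlen, params,
          start_anchor = anch$start_anchor, end_anchor = anch$end_anchor,
          acc_targets = anch$acc_targets, don_targets = anch$don_targets,
          intron_region = grepl("intron", rg$role))
        if (!nrow(cand)) next
        cand$role <- rg$role
        cand$query_exon <- exon_index
        for (k in seq_len(nrow(cand))) {
          body <- subseq0(gene$sequence, cand$start[k], cand$end[k])
          aa <- translate_in_frame(body, phase, comp$up, comp$down)
          if (is.na(aa) || grepl("*", aa, fixed = TRUE)) next
          al <- gotoh_align(aa, qaa, params$alignment)
          rel <- al$score / qself
          if (rel < params$min_score - 1e-9) next
          found[[length(found) + 1L]] <- data.frame(
            start = cand$start[k], end = cand$end[k], role = rg$role,
            query_exon = exon_index, translation = aa,
            raw_score = al$score, self_score = qself,
            relative_score = rel, accepted = TRUE,
            reject_reason = NA_character_,
            aln_query = al$b, aln_candidate = al$a,
            is_query = FALSE, depth = depth,
            matches_annotated = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(found)) break
    new <- do.call(rbind, found)
    # dedup by exact interval against existing members and within the batch
    new <- new[!interval_in_set(new$start, new$end,
                                members$start, members$end), , drop = FALSE]
    new <- new[!duplicated(new[, c("start", "end")]), , drop = FALSE]
    # existing members win overlaps
    if (nrow(new)) {
      ov <- vapply(seq_len(nrow(new)), function(i)
        any(new$start[i] < members$end & new$end[i] > members$start),
        logical(1))
      new <- new[!ov, , drop = FALSE]
    }
    new <- resolve_overlaps(new)
    if (!nrow(new)) break
    new$matches_annotated <- interval_in_set(new$start, new$end,
                                             gene$exons$start,
                                             gene$exons$end)
    members <- rbind(members, new)
    members <- members[order(members$start), , drop = FALSE]
    rownames(members) <- NULL
    rounds_used <- depth
  }
  cluster$members <- members
  cluster$recursion_rounds_used <- rounds_used
  cluster
}

#' Search a whole transcript
#'
#' Applies [search_exon()] to every exon of the gene structure. Clusters
#' with candidates are collected; skipped exons and exons without candidates
#' are recorded in the log. When `search_all_introns` is enabled,
#' [detect_group_pattern()] is applied to the result.
#'
#' @param gene a [gene_structure][derive_gene_structure].
#' @param params a [search_params()].
#' @return a `search_result`: list with `gene`, `clusters` (non-trivial
#'   only, ordered by query exon), `params`, `log`.
#' @export
search_transcript <- function(gene, params = search_params()) {
  clusters <- list(); log <- character(0)
  for (i in seq_len(nrow(gene$exons))) {
    cl <- search_exon(gene, i, params)
    if (inherits(cl, "exon_skip")) {
      log <- c(log, sprintf("exon %d skipped: %s", i, attr(cl, "reason")))
    } else if (nrow(cl$members) <= 1L) {
      log <- c(log, sprintf("exon %d: no candidates", i))
    } else {
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  res <- structure(list(gene = gene, clusters = clusters, params = params,
                        log = log), class = "search_result")
  if (params$search_all_introns) res <- detect_group_pattern(res, params)
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat("mxescan search of ", x$gene$transcript_id, ": ",
      length(x$clusters), " cluster(s)\n", sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  exon %d [%s]: %d member(s)\n", cl$query_exon,
                cl$classification, nrow(cl$members)))
  }
  if (length(x$log)) cat("  log:", length(x$log), "entries\n")
  invisible(x)
}

#' Flag tandem-duplication / trans-splice group patterns
#'
#' When candidates of at least `group_min_exons` consecutive query exons
#' form a parallel ordered group — one candidate per query exon, in the same
#' genomic order, consecutive group members at most `region_size` apart and
#' with no annotated exon of the transcript between them — the clusters
#' involved are re-labelled `group_pattern`. Such groups arise from tandemly
#' arrayed gene duplications and from groups of trans-spliced exons, not
#' from true mutually exclusive splicing. Requires a result produced with
#' `search_all_introns`.
#'
#' @param result a [search_result][search_transcript].
#' @param params a [search_params()]; defaults to the result's.
#' @return the result with classifications updated.
#' @export
detect_group_pattern <- function(result, params = result$params) {
  if (!params$search_all_introns || length(result$clusters) < 2L) {
    return(result)
  }
  gene <- result$gene
  q_idx <- vapply(result$clusters, `[[`, integer(1), "query_exon")
  cand <- lapply(result$clusters, function(cl)
    cl$members[!cl$members$is_query, , drop = FALSE])

  # forward/backward chain lengths over links between candidates of
  # consecutive query exons
  fwd <- lapply(cand, function(m) rep(1L, nrow(m)))
  bwd <- lapply(cand, function(m) rep(1L, nrow(m)))
  for (k in seq_along(q_idx)[-1L]) {
    if (q_idx[k] != q_idx[k - 1L] + 1L) next
    up <- cand[[k - 1L]]; dn <- cand[[k]]
    if (!nrow(up) || !nrow(dn)) next
    for (j in seq_len(nrow(dn))) {
      ok <- dn$start[j] >= up$end &
        dn$start[j] - up$end <= params$region_size
      if (any(ok)) {
        blocked <- vapply(which(ok), function(i)
          any(gene$exons$start >= up$end[i] &
                gene$exons$end <= dn$start[j]), logical(1))
        ok[which(ok)] <- !blocked
      }
      if (any(ok)) fwd[[k]][j] <- max(fwd[[k - 1L]][ok]) + 1L
    }
  }
  for (k in rev(seq_along(q_idx))[-1L]) {
    if (q_idx[k + 1L] != q_idx[k] + 1L) next
    up <- cand[[k]]; dn <- cand[[k + 1L]]
    if (!nrow(up) || !nrow(dn)) next
    for (i in seq_len(nrow(up))) {
      ok <- dn$start >= up$end[i] &
        dn$start - up$end[i] <= params$region_size
      if (any(ok)) {
        blocked <- vapply(which(ok), function(j)
          any(gene$exons$start >= up$end[i] &
                gene$exons$end <= dn$start[j]), logical(1))
        ok[which(ok)] <- !blocked
      }
      if (any(ok)) bwd[[k]][i] <- max(bwd[[k + 1L]][ok]) + 1L
    }
  }
  for (k in seq_along(q_idx)) {
    if (!length(fwd[[k]])) next
    if (max(fwd[[k]] + bwd[[k]] - 1L) >= params$group_min_exons) {
      result$clusters[[k]]$classification <- "group_pattern"
    }
  }
  result
}
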