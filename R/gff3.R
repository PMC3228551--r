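# GFF3 input (via rtracklayer) and result writers (GFF3 / YAML / TSV).
#
# GFF3 on disk is 1-based inclusive; everything internal is 0-based
# half-open. Minus-strand transcripts are reverse-complement-normalized at
# load: the stored sequence is the reverse complement of the contig and
# coordinates are flipped (s, e) -> (L - e, L - s), after which all search
# logic is strand-free.

#' Read gene structures from a GFF3 annotation
#'
#' One [gene_structure][derive_gene_structure] is built per mRNA from its CDS
#' features. Phases are recomputed from scratch and checked against the file
#' phases when present; a trailing stop codon included in the last CDS is
#' trimmed (the gene model keeps the stop *after* the last exon).
#'
#' @param path path to a GFF3 file with gene/mRNA/CDS (or transcript)
#'   features.
#' @param seqs named character vector of genomic sequences, as from
#'   [read_fasta()].
#' @param strict if `TRUE`, structural errors abort; otherwise the offending
#'   transcript is skipped and logged (see `attr(, "log")`).
#' @return list of `gene_structure` objects, named by transcript id, with a
#'   character vector attribute `"log"` of per-transcript skip records.
#' @export
read_gff3 <- function(path, seqs, strict = TRUE) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  if (!is.null(df$ID)) df$ID <- as.character(df$ID)

  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in ", path)
  # CDS may point at an mRNA or directly at a gene
  tx_ids <- unique(stats::na.omit(cds$Parent))
  out <- list(); log <- character(0)

  for (tx in tx_ids) {
    rec <- cds[!is.na(cds$Parent) & cds$Parent == tx, , drop = FALSE]
    res <- tryCatch({
      seqid <- unique(rec$seqnames)
      if (length(seqid) != 1L) stop("CDS of ", tx, " on multiple sequences")
      if (!seqid %in% names(seqs)) {
        stop("sequence '", seqid, "' of transcript ", tx, " absent from FASTA")
      }
      strand <- unique(rec$strand)
      if (length(strand) != 1L) stop("CDS of ", tx, " on mixed strands")
      rec <- rec[order(rec$start), , drop = FALSE]
      st0 <- rec$start - 1L; en0 <- rec$end          # to 0-based half-open
      if (any(st0[-1L] < en0[-length(en0)])) {
        stop("overlapping CDS within transcript ", tx)
      }
      seq <- seqs[[seqid]]
      L <- nchar(seq)
      file_phase <- suppressWarnings(as.integer(as.character(rec$phase)))
      if (strand == "-") {
        seq <- revcomp(seq)
        tmp <- st0
        st0 <- rev(L - en0); en0 <- rev(L - tmp)
        file_phase <- rev(file_phase)
      } else if (strand != "+") {
        stop("transcript ", tx, " has no strand")
      }
      gid <- if (nrow(mrna) && tx %in% mrna$ID) {
        p <- mrna$Parent[match(tx, mrna$ID)]
        if (is.na(p)) tx else p
      } else tx
      first_phase <- if (!is.na(file_phase[1L])) file_phase[1L] else 0L
      g <- build_structure_trimming_stop(
        seq, data.frame(start = st0, end = en0),
        seq_id = seqid, transcript_id = tx, gene_id = gid,
        first_phase = first_phase)
      ok <- !is.na(file_phase)
      if (any(ok) && any(g$exons$start_phase[ok] != file_phase[ok])) {
        warning("phase mismatch in transcript ", tx,
                ": recomputed phases differ from file phases", call. = FALSE)
      }
      g
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("transcript ", tx, ": ", conditionMessage(res))
      log <- c(log, paste0(tx, ": ", conditionMessage(res)))
    } else {
      out[[tx]] <- res
    }
  }
  attr(out, "log") <- log
  out
}

# derive a structure; if the CDS translation ends with a stop codon (GFF3
# convention includes it), trim the final 3 nt off the last exon and retry
build_structure_trimming_stop <- function(seq, exons, ...) {
  n <- nrow(exons)
  last_cod <- subseq0(seq, exons$end[n] - 3L, exons$end[n])
  total <- sum(exons$end - exons$start)
  if (total %% 3L == 0L && is_stop(last_cod)) {
    exons$end[n] <- exons$end[n] - 3L
    if (exons$end[n] <= exons$start[n]) stop("last CDS is a bare stop codon")
  }
  derive_gene_structure(seq, exons, ...)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a search result as GFF3
#'
#' Emits the annotated exons of the transcript plus one `exon` feature per
#' accepted candidate, with `cluster_id`, `relative_score` (4 decimals),
#' `recursion_depth` and `classification` attributes. An empty result gives
#' a valid header-only file.
#'
#' @param result a [search_result][search_transcript], or `NULL`/empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(result, path) {
  lines <- "##gff-version 3"
  if (!is.null(result$gene)) {
    g <- result$gene
    ex <- g$exons
    for (i in seq_len(nrow(ex))) {
      cl <- cluster_for_exon(result, i)
      attrs <- c(
        paste0("ID=", gff3_escape(g$transcript_id), ".exon", i),
        "role=query")
      score <- "."
      if (!is.null(cl)) {
        attrs <- c(attrs,
                   paste0("cluster_id=cluster_", cl$query_exon),
                   "relative_score=1.0000",
                   "recursion_depth=0",
                   paste0("classification=", cl$classification))
        score <- "1.0000"
      }
      lines <- c(lines, paste(g$seq_id, "mxescan", "exon",
                              ex$start[i] + 1L, ex$end[i], score, "+",
                              ex$start_phase[i],
                              paste(attrs, collapse = ";"), sep = "\t"))
    }
    k <- 0L
    for (cl in result$clusters) {
      mem <- cl$members[!cl$members$is_query, , drop = FALSE]
      for (j in seq_len(nrow(mem))) {
        k <- k + 1L
        attrs <- c(
          paste0("ID=", gff3_escape(g$transcript_id), ".cand", k),
          "role=candidate",
          paste0("cluster_id=cluster_", cl$query_exon),
          paste0("relative_score=", sprintf("%.4f", mem$relative_score[j])),
          paste0("recursion_depth=", mem$depth[j]),
          paste0("classification=", cl$classification))
        lines <- c(lines, paste(g$seq_id, "mxescan", "exon",
                                mem$start[j] + 1L, mem$end[j],
                                sprintf("%.4f", mem$relative_score[j]), "+",
                                g$exons$start_phase[cl$query_exon],
                                paste(attrs, collapse = ";"), sep = "\t"))
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

cluster_for_exon <- function(result, index) {
  for (cl in result$clusters) if (cl$query_exon == index) return(cl)
  NULL
}

result_to_list <- function(result) {
  g <- result$gene
  list(
    format = "mxescan-result",
    format_version = 1L,
    sequence_id = g$seq_id,
    transcript_id = g$transcript_id,
    gene_id = g$gene_id,
    params = result$params[setdiff(names(result$params), "alignment")],
    clusters = lapply(result$clusters, function(cl) {
      m <- cl$members
      list(
        query_exon = cl$query_exon,
        classification = cl$classification,
        members = lapply(seq_len(nrow(m)), function(i) list(
          start = m$start[i], end = m$end[i],
          is_query = m$is_query[i],
          relative_score = round(m$relative_score[i], 6),
          recursion_depth = m$depth[i],
          translation = m$translation[i])))
    }),
    log = as.list(result$log))
}

#' Write / read a search result as YAML
#'
#' The YAML document is this package's own schema (documented in the return
#' value of `read_result_yaml`): format tag, transcript/gene ids, the scalar
#' search parameters, one entry per cluster with its members, and the
#' per-exon log. A write/read/write cycle is byte-identical on the second
#' pass.
#'
#' @param result a [search_result][search_transcript].
#' @param path output file path.
#' @return `path` (write) or the result list (read).
#' @export
write_result_yaml <- function(result, path) {
  yaml::write_yaml(result_to_list(result), path,
                   precision = 9L, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' @rdname write_result_yaml
#' @export
read_result_yaml <- function(path) yaml::read_yaml(path)

# re-serialize a previously read result list (round-trip support)
write_result_list_yaml <- function(x, path) {
  yaml::write_yaml(x, path, precision = 9L, indent.mapping.sequence = TRUE)
  invisible(path)
}

#' Write a search result as a TSV report
#'
#' One row per cluster member (query exon and accepted candidates).
#'
#' @inheritParams write_result_yaml
#' @export
write_tsv <- function(result, path) {
  tab <- result_table(result)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate a search result
#'
#' @param result a [search_result][search_transcript].
#' @return data.frame with one row per cluster member.
#' @export
result_table <- function(result) {
  rows <- lapply(result$clusters, function(cl) {
    m <- cl$members
    data.frame(
      seq_id = result$gene$seq_id,
      transcript_id = result$gene$transcript_id,
      gene_id = result$gene$gene_id,
      cluster_id = paste0("cluster_", cl$query_exon),
      query_exon = cl$query_exon,
      classification = cl$classification,
      start = m$start, end = m$end,
      dna_length = m$end - m$start,
      is_query = m$is_query,
      relative_score = round(m$relative_score, 6),
      recursion_depth = m$depth,
      translation = m$translation,
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(
      seq_id = character(0), transcript_id = character(0),
      gene_id = character(0), cluster_id = character(0),
      query_exon = integer(0), classification = character(0),
      start = integer(0), end = integer(0), dna_length = integer(0),
      is_query = logical(0), relative_score = numeric(0),
      recursion_depth = integer(0), translation = character(0),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
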