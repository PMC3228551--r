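# Gene model: sequences, exon/intron structures, phases, splice dinucleotides.
#
# Coordinates are 0-based half-open on a forward-normalized genomic axis;
# minus-strand transcripts are reverse-complement-normalized at load so that
# all downstream logic is strand-free. Exon and intron *indices* are 1-based.
#
# Phase convention is GFF3 CDS phase: `start_phase` is the number of
# nucleotides at the 5' end of an exon that complete a codon split with the
# previous exon (i.e. nucleotides to skip to reach the first complete codon);
# `end_phase` is the number of leftover nucleotides after the last complete
# codon, which begin a codon completed by the next exon.

#' Read a FASTA file of genomic sequences
#'
#' Residues are uppercased, `U` is mapped to `T`, and any character outside
#' `A/C/G/T/N` is rejected with an error naming the offending record and
#' position.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return named character vector of uppercase nucleotide strings; names are
#'   the FASTA ids (first whitespace-delimited token of each header).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">chrX", "ACGTACGT"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- chartr("u", "t", tolower(as.character(set)))
  res <- toupper(res)
  bad <- regexpr("[^ACGTN]", res)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1L]
    stop("illegal character '", substr(res[k], bad[k], bad[k]),
         "' in record '", ids[k], "' at position ", bad[k])
  }
  setNames(res, ids)
}

# phase chain for exon lengths: returns data.frame(start_phase, end_phase,
# aa_length). start_phase[1] = first_phase.
exon_phases <- function(lengths, first_phase = 0L) {
  n <- length(lengths)
  sp <- integer(n); ep <- integer(n); aa <- integer(n)
  p <- as.integer(first_phase)
  for (i in seq_len(n)) {
    len <- lengths[i]
    if (len < p) stop("exon ", i, " shorter than its split-codon carry")
    r <- (len - p) %% 3L
    up <- (3L - p) %% 3L
    down <- (3L - r) %% 3L
    sp[i] <- p; ep[i] <- r
    aa[i] <- (up + len + down) %/% 3L
    p <- (3L - r) %% 3L
  }
  data.frame(start_phase = sp, end_phase = ep, aa_length = aa)
}

#' Derive a full gene structure from exon coordinates
#'
#' Populates introns with their splice dinucleotides, per-exon phases and
#' amino-acid lengths, the translated protein, and the terminal-codon flags
#' used to decide start-/stop-codon anchored terminal searches.
#'
#' @param sequence a single genomic nucleotide string (may be named; the name
#'   is used as the sequence id), or a named character vector of length 1.
#' @param exons a data.frame or 2-column matrix of exon `start`/`end`
#'   coordinates, 0-based half-open, sorted, non-overlapping.
#' @param seq_id,transcript_id,gene_id identifiers stored on the structure.
#' @param first_phase GFF3 phase of the first exon (0 for complete CDS).
#' @return an object of class `gene_structure`: a list with elements
#'   `sequence`, `seq_id`, `transcript_id`, `gene_id`, `exons` (data.frame
#'   with `start`, `end`, `index`, `kind`, `is_first`, `is_last`,
#'   `start_phase`, `end_phase`, `aa_length`), `introns` (data.frame with
#'   `start`, `end`, `donor`, `acceptor`, `upstream_exon`,
#'   `downstream_exon`), `protein`, `starts_with_met`, `followed_by_stop`.
#' @export
derive_gene_structure <- function(sequence, exons,
                                  seq_id = NULL, transcript_id = "tx1",
                                  gene_id = transcript_id,
                                  first_phase = 0L) {
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(sequence))) names(sequence)[1L] else "seq"
  }
  sequence <- unname(as.character(sequence)[1L])
  L <- nchar(sequence)
  ex <- as.data.frame(exons)
  if (ncol(ex) < 2L) stop("exons must have start and end columns")
  names(ex)[1:2] <- c("start", "end")
  ex <- ex[, c("start", "end")]
  ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
  n <- nrow(ex)
  if (n == 0L) stop("no exons")
  if (any(ex$end <= ex$start)) stop("exon with end <= start")
  if (any(ex$start < 0L) || any(ex$end > L)) {
    stop("exon outside sequence bounds [0, ", L, ")")
  }
  if (n > 1L) {
    gaps <- ex$start[-1L] - ex$end[-n]
    if (any(gaps <= 0L)) stop("overlapping or unsorted exons")
    if (any(gaps < 4L)) {
      stop("intron shorter than 4 nt between exons ",
           which(gaps < 4L)[1L], " and ", which(gaps < 4L)[1L] + 1L)
    }
  }

  ph <- exon_phases(ex$end - ex$start, first_phase)
  if (ph$end_phase[n] != 0L) {
    stop("coding sequence length is not a multiple of 3 ",
         "(last exon leaves ", ph$end_phase[n], " leftover nt)")
  }

  ex$index <- seq_len(n)
  ex$is_first <- ex$index == 1L
  ex$is_last <- ex$index == n
  ex$kind <- ifelse(ex$is_first & ex$is_last, "single",
             ifelse(ex$is_first, "first",
             ifelse(ex$is_last, "last", "internal")))
  ex <- cbind(ex, ph)

  if (n > 1L) {
    introns <- data.frame(
      start = ex$end[-n], end = ex$start[-1L],
      upstream_exon = seq_len(n - 1L), downstream_exon = seq_len(n - 1L) + 1L)
    introns$donor <- substr(sequence, introns$start + 1L, introns$start + 2L)
    introns$acceptor <- substr(sequence, introns$end - 1L, introns$end)
    introns <- introns[, c("start", "end", "donor", "acceptor",
                           "upstream_exon", "downstream_exon")]
  } else {
    introns <- data.frame(start = integer(0), end = integer(0),
                          donor = character(0), acceptor = character(0),
                          upstream_exon = integer(0),
                          downstream_exon = integer(0))
  }

  cds <- paste(vapply(seq_len(n), function(i)
    subseq0(sequence, ex$start[i], ex$end[i]), character(1)), collapse = "")
  if (first_phase > 0L) cds <- substr(cds, first_phase + 1L, nchar(cds))
  protein <- translate_codons(cds)
  if (is.na(protein)) {
    stop("coding sequence of ", transcript_id,
         " contains N; codons with N are untranslatable")
  }
  if (grepl("*", protein, fixed = TRUE)) {
    stop("in-frame stop codon in coding sequence of ", transcript_id,
         " at protein position ", regexpr("*", protein, fixed = TRUE)[1L])
  }
  after <- subseq0(sequence, ex$end[n], min(L, ex$end[n] + 3L))
  structure(list(
    sequence = sequence, seq_id = seq_id,
    transcript_id = transcript_id, gene_id = gene_id,
    exons = ex, introns = introns, protein = protein,
    starts_with_met = substr(protein, 1L, 1L) == "M",
    followed_by_stop = nchar(after) == 3L && after %in% STOP_CODONS
  ), class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("gene_structure ", x$transcript_id, " (gene ", x$gene_id, ") on ",
      x$seq_id, "\n", sep = "")
  cat("  ", nrow(x$exons), " exon(s), ", nchar(x$protein), " aa",
      if (x$starts_with_met) ", starts with Met" else "",
      if (x$followed_by_stop) ", followed by stop" else "", "\n", sep = "")
  print(x$exons[, c("start", "end", "kind", "start_phase", "end_phase",
                    "aa_length")], row.names = FALSE)
  invisible(x)
}

exon_body <- function(gene, index) {
  subseq0(gene$sequence, gene$exons$start[index], gene$exons$end[index])
}

# nucleotides completing the split codons of exon `index`, taken from the
# flanking exons (identical for the query and every candidate of its cluster)
exon_completions <- function(gene, index) {
  ex <- gene$exons
  p <- ex$start_phase[index]; r <- ex$end_phase[index]
  up <- ""
  if (p > 0L) {
    need <- (3L - p) %% 3L
    prev <- exon_body(gene, index - 1L)
    up <- substr(prev, nchar(prev) - need + 1L, nchar(prev))
  }
  down <- ""
  if (r > 0L) {
    need <- (3L - r) %% 3L
    nxt <- exon_body(gene, index + 1L)
    down <- substr(nxt, 1L, need)
  }
  list(up = up, down = down)
}

# in-frame translation of an annotated exon, split codons completed
exon_translation <- function(gene, index) {
  comp <- exon_completions(gene, index)
  translate_in_frame(exon_body(gene, index),
                     gene$exons$start_phase[index], comp$up, comp$down)
}
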