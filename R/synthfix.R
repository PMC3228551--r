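# Deterministic, seeded generator of synthetic genomes and gene structures
# with planted homologous exon copies, tandem gene arrays and trans-spliced
# exon groups, so that every search stage is testable without external data.
#
# All randomness flows from the explicit seed of the fixture spec; no global
# random state is consumed or left behind.

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAG", "TAA", "TGA"))
})

CODON_AA <- local({
  aa <- vapply(NON_STOP_CODONS, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd))),
    character(1))
  setNames(aa, NON_STOP_CODONS)
})

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_codons <- function(n) {
  if (n <= 0L) return(character(0))
  sample(NON_STOP_CODONS, n, replace = TRUE)
}

split_into_codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# substitute / indel whole codons at the given per-codon rates; split-codon
# carries at the edges are kept verbatim so the frame and the flanking
# translations are preserved; substitutions always change the amino acid
mutate_body <- function(body, start_phase, end_phase,
                        substitution_rate = 0, indel_codon_rate = 0) {
  head_nt <- substr(body, 1L, start_phase)
  tail_nt <- if (end_phase > 0L)
    substr(body, nchar(body) - end_phase + 1L, nchar(body)) else ""
  mid <- substr(body, start_phase + 1L, nchar(body) - end_phase)
  codons <- split_into_codons(mid)
  out <- character(0)
  for (cd in codons) {
    cur <- cd
    if (indel_codon_rate > 0 && runif(1) < indel_codon_rate / 2) {
      cur <- NULL                                    # codon deletion
    }
    if (!is.null(cur) && substitution_rate > 0 &&
        runif(1) < substitution_rate) {
      alt <- NON_STOP_CODONS[CODON_AA != CODON_AA[[cd]]]
      cur <- sample(alt, 1L)
    }
    if (!is.null(cur)) out <- c(out, cur)
    if (indel_codon_rate > 0 && runif(1) < indel_codon_rate / 2) {
      out <- c(out, sample(NON_STOP_CODONS, 1L))     # codon insertion
    }
  }
  if (!length(out)) out <- sample(NON_STOP_CODONS, 1L)
  paste0(head_nt, paste(out, collapse = ""), tail_nt)
}

#' Specification of a synthetic gene fixture
#'
#' @param seed integer seed; identical specs give byte-identical fixtures.
#' @param exon_aa_lengths amino acids encoded per exon (split codons shift
#'   the DNA boundaries, not these totals).
#' @param intron_lengths intron lengths in nt (length one less than the
#'   number of exons; each at least 20).
#' @param implants data.frame with columns `exon_index`, `n_copies`,
#'   `substitution_rate`, `indel_codon_rate` and optionally `intron`
#'   (1-based intron index; default the intron downstream of the exon).
#' @param architecture `"simple"` (other architectures are produced by
#'   [make_tandem_array()] and [make_trans_spliced_fixture()]).
#' @param gc_background GC fraction of intron and flank sequence.
#' @param boundary_shifts per-junction shifts of the exon/intron boundary in
#'   nt (-2..2), producing split codons; default all zero.
#' @param flank_length length of the up-/downstream flanks in nt.
#' @return validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         exon_aa_lengths = c(30L, 40L, 30L),
                         intron_lengths = NULL,
                         implants = NULL,
                         architecture = "simple",
                         gc_background = 0.5,
                         boundary_shifts = NULL,
                         flank_length = 300L) {
  n <- length(exon_aa_lengths)
  if (is.null(intron_lengths)) intron_lengths <- rep(200L, max(n - 1L, 0L))
  if (is.null(boundary_shifts)) boundary_shifts <- rep(0L, max(n - 1L, 0L))
  stopifnot(n >= 1L, all(exon_aa_lengths >= 2L),
            length(intron_lengths) == n - 1L, all(intron_lengths >= 20L),
            length(boundary_shifts) == n - 1L,
            all(abs(boundary_shifts) <= 2L),
            gc_background > 0, gc_background < 1)
  if (!is.null(implants)) {
    implants <- as.data.frame(implants)
    stopifnot(all(c("exon_index", "n_copies", "substitution_rate",
                    "indel_codon_rate") %in% names(implants)),
              all(implants$exon_index >= 1L),
              all(implants$exon_index <= n))
  }
  structure(list(seed = as.integer(seed),
                 exon_aa_lengths = as.integer(exon_aa_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 implants = implants,
                 architecture = architecture,
                 gc_background = gc_background,
                 boundary_shifts = as.integer(boundary_shifts),
                 flank_length = as.integer(flank_length)),
            class = "fixture_spec")
}

# assemble a genome string from exon bodies and intron interiors;
# returns list(sequence, exons data.frame)
assemble_gene <- function(bodies, introns, flank_up, flank_down) {
  n <- length(bodies)
  parts <- character(0)
  starts <- integer(n); ends <- integer(n)
  pos <- nchar(flank_up)
  parts <- flank_up
  for (i in seq_len(n)) {
    starts[i] <- pos
    parts <- c(parts, bodies[i])
    pos <- pos + nchar(bodies[i])
    ends[i] <- pos
    if (i < n) {
      parts <- c(parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  parts <- c(parts, "TAA", flank_down)
  list(sequence = paste(parts, collapse = ""),
       exons = data.frame(start = starts, end = ends))
}

#' Generate a random synthetic gene
#'
#' Builds a genome with one multi-exon gene: canonical `GT...AG` introns, a
#' CDS starting with `ATG`, no internal stop codons, a stop codon (`TAA`)
#' immediately after the last exon, and random flanking sequence. Implants
#' (homologous exon copies at controlled divergence) are applied per the
#' spec, and their true coordinates, translations and relative scores are
#' recorded in the ground-truth table.
#'
#' @param spec a [fixture_spec()].
#' @return list with `sequence` (named character), `gene`
#'   ([gene_structure][derive_gene_structure]) and `truth` (data.frame of
#'   implanted intervals: `exon_index`, `copy`, `start`, `end`,
#'   `substitution_rate`, `indel_codon_rate`, `translation`,
#'   `relative_score`).
#' @export
random_gene <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    n <- length(spec$exon_aa_lengths)
    n_aa <- sum(spec$exon_aa_lengths)
    cds <- paste(c("ATG", random_codons(n_aa - 1L)), collapse = "")
    lens <- 3L * spec$exon_aa_lengths
    if (n > 1L) {
      for (j in seq_len(n - 1L)) {
        s <- spec$boundary_shifts[j]
        lens[j] <- lens[j] + s
        lens[j + 1L] <- lens[j + 1L] - s
      }
    }
    if (any(lens < 3L)) stop("boundary shifts make an exon shorter than 3 nt")
    offs <- cumsum(c(0L, lens))
    bodies <- substring(cds, offs[-length(offs)] + 1L, offs[-1L])
    introns <- vapply(spec$intron_lengths, function(L)
      paste0("GT", random_dna(L - 4L, spec$gc_background), "AG"),
      character(1))
    asm <- assemble_gene(bodies, introns,
                         random_dna(spec$flank_length, spec$gc_background),
                         random_dna(spec$flank_length, spec$gc_background))
    seq <- asm$sequence
    gene <- derive_gene_structure(seq, asm$exons, seq_id = "synth",
                                  transcript_id = "synth.t1",
                                  gene_id = "synth.g1")
    truth <- empty_truth()
    if (!is.null(spec$implants)) {
      for (r in seq_len(nrow(spec$implants))) {
        im <- spec$implants[r, ]
        intron <- if ("intron" %in% names(im) && !is.na(im$intron)) {
          im$intron
        } else {
          # default: the roomier of the exon's flanking introns
          fl <- intersect(c(im$exon_index - 1L, im$exon_index),
                          seq_len(nrow(gene$introns)))
          fl[which.max(gene$introns$end[fl] - gene$introns$start[fl])]
        }
        pl <- place_implants(gene, im$exon_index, im$n_copies,
                             im$substitution_rate, im$indel_codon_rate,
                             intron)
        gene <- pl$gene
        truth <- rbind(truth, pl$truth)
      }
    }
    assert_truth_constraints(gene, truth)
    list(sequence = setNames(gene$sequence, gene$seq_id),
         gene = gene, truth = truth)
  })
}

empty_truth <- function() {
  data.frame(exon_index = integer(0), copy = integer(0),
             start = integer(0), end = integer(0),
             substitution_rate = numeric(0), indel_codon_rate = numeric(0),
             translation = character(0), relative_score = numeric(0),
             stringsAsFactors = FALSE)
}

# place n_copies mutated copies of exon `exon_index` into intron `intron`,
# overwriting intron interior (coordinates of annotated exons unchanged);
# consumes the caller's RNG stream
place_implants <- function(gene, exon_index, n_copies,
                           substitution_rate, indel_codon_rate,
                           intron, min_new_intron_length = 4L) {
  stopifnot(intron >= 1L, intron <= nrow(gene$introns))
  body <- exon_body(gene, exon_index)
  p <- gene$exons$start_phase[exon_index]
  r <- gene$exons$end_phase[exon_index]
  comp <- exon_completions(gene, exon_index)
  qaa <- exon_translation(gene, exon_index)

  # acceptor/donor dinucleotides compatible with the query's splice context
  acc <- if (exon_index > 1L)
    acceptor_targets(gene$introns$donor[exon_index - 1L])[1L] else "AG"
  don <- if (exon_index <= nrow(gene$introns))
    donor_targets(gene$introns$acceptor[exon_index])[1L] else "GT"
  if (is.na(acc) || is.na(don) || !nchar(acc)) {
    stop("query exon has a non-canonical splice context")
  }

  it <- gene$introns[intron, ]
  margin <- max(min_new_intron_length, 4L)
  seq <- gene$sequence
  cursor <- it$start + margin
  truth <- empty_truth()
  for (cp in seq_len(n_copies)) {
    mut <- mutate_body(body, p, r, substitution_rate, indel_codon_rate)
    slot <- nchar(mut) + 4L
    cursor <- cursor + sample.int(6L, 1L) - 1L     # small seeded jitter
    if (cursor + slot > it$end - margin) {
      stop("implant placement infeasible: intron ", intron, " (",
           it$end - it$start, " nt) too short for copy ", cp,
           " of exon ", exon_index)
    }
    chunk <- paste0(acc, mut, don)
    substr(seq, cursor + 1L, cursor + slot) <- chunk
    s <- cursor + 2L; e <- s + nchar(mut)
    aa <- translate_in_frame(mut, p, comp$up, comp$down)
    truth <- rbind(truth, data.frame(
      exon_index = exon_index, copy = cp, start = s, end = e,
      substitution_rate = substitution_rate,
      indel_codon_rate = indel_codon_rate,
      translation = aa,
      relative_score = relative_score(aa, qaa),
      stringsAsFactors = FALSE))
    cursor <- cursor + slot + 8L                   # spacer between copies
  }
  gene2 <- derive_gene_structure(seq, gene$exons[, c("start", "end")],
                                 seq_id = gene$seq_id,
                                 transcript_id = gene$transcript_id,
                                 gene_id = gene$gene_id)
  list(gene = gene2, truth = truth)
}

#' Implant homologous copies of an exon into an intron
#'
#' Copies of the exon body are mutated codon-wise (substitutions always
#' change the amino acid and never create stops; indels operate on whole
#' codons, so frame compatibility is guaranteed by construction), written
#' into the intron interior with splice dinucleotides compatible with the
#' query's flanking introns, and recorded with their true coordinates and
#' relative scores.
#'
#' @param gene a [gene_structure][derive_gene_structure].
#' @param exon_index exon to copy.
#' @param substitution_rate,indel_codon_rate per-codon mutation rates in
#'   `[0, 1]`.
#' @param intron 1-based intron receiving the copies (default: downstream
#'   intron of the exon).
#' @param n_copies number of copies.
#' @param seed integer seed.
#' @return list with the mutated `gene` and the `truth` table (see
#'   [random_gene()]).
#' @export
implant_homolog <- function(gene, exon_index, substitution_rate = 0,
                            indel_codon_rate = 0, intron = NULL,
                            n_copies = 1L, seed = 1L) {
  if (is.null(intron)) intron <- min(exon_index, nrow(gene$introns))
  with_seed(seed,
            place_implants(gene, exon_index, n_copies, substitution_rate,
                           indel_codon_rate, intron))
}

# generation-time assertion: every ground-truth interval satisfies the
# enumeration constraints (dinucleotides, frame, margins, translatability)
assert_truth_constraints <- function(gene, truth,
                                     min_new_intron_length = 4L) {
  for (k in seq_len(nrow(truth))) {
    s <- truth$start[k]; e <- truth$end[k]
    i <- truth$exon_index[k]
    qlen <- gene$exons$end[i] - gene$exons$start[i]
    stopifnot((e - s - qlen) %% 3L == 0L)
    acc <- subseq0(gene$sequence, s - 2L, s)
    don <- subseq0(gene$sequence, e, e + 2L)
    ok_acc <- if (i > 1L)
      acc %in% acceptor_targets(gene$introns$donor[i - 1L]) else TRUE
    ok_don <- if (i <= nrow(gene$introns))
      don %in% donor_targets(gene$introns$acceptor[i]) else TRUE
    stopifnot(ok_acc, ok_don)
    it <- gene$introns[gene$introns$start <= s - 2L &
                         gene$introns$end >= e + 2L, , drop = FALSE]
    stopifnot(nrow(it) == 1L,
              s - it$start >= min_new_intron_length,
              it$end - e >= min_new_intron_length)
  }
  invisible(TRUE)
}

#' Tandem array of duplicated genes
#'
#' Builds a genome containing `n_copies` of one synthetic gene arranged in
#' tandem, downstream copies mutated exon-wise at the given divergence. Only
#' the first copy is annotated; searching it with all introns and the
#' up-/downstream regions enabled reveals the duplicates as a parallel
#' ordered group ([detect_group_pattern()]).
#'
#' @param seed integer seed.
#' @param n_copies number of gene copies (>= 1).
#' @param divergence per-codon substitution rate applied to exons of the
#'   downstream copies.
#' @param spacer_length intergenic spacer in nt.
#' @param exon_aa_lengths,intron_lengths,gc_background gene layout (see
#'   [fixture_spec()]).
#' @return list with `sequence`, `gene` (annotated first copy) and `truth`
#'   (exon coordinates of every copy with `copy` and `exon_index` labels).
#' @export
make_tandem_array <- function(seed = 1L, n_copies = 2L, divergence = 0,
                              spacer_length = 200L,
                              exon_aa_lengths = c(25L, 30L, 25L),
                              intron_lengths = NULL,
                              gc_background = 0.5) {
  n <- length(exon_aa_lengths)
  if (is.null(intron_lengths)) intron_lengths <- rep(60L, n - 1L)
  with_seed(seed, {
    n_aa <- sum(exon_aa_lengths)
    cds <- paste(c("ATG", random_codons(n_aa - 1L)), collapse = "")
    lens <- 3L * exon_aa_lengths
    offs <- cumsum(c(0L, lens))
    bodies <- substring(cds, offs[-length(offs)] + 1L, offs[-1L])
    introns <- vapply(intron_lengths, function(L)
      paste0("GT", random_dna(L - 4L, gc_background), "AG"), character(1))
    flank <- random_dna(300L, gc_background)

    blocks <- list(); truth_rows <- list()
    pos <- nchar(flank)
    parts <- flank
    ann_exons <- NULL
    for (cp in seq_len(n_copies)) {
      b <- bodies
      if (cp > 1L && divergence > 0) {
        b <- vapply(bodies, mutate_body, character(1),
                    start_phase = 0L, end_phase = 0L,
                    substitution_rate = divergence, indel_codon_rate = 0)
        # keep the start codon of the duplicated gene intact
        b[1L] <- paste0("ATG", substr(b[1L], 4L, nchar(b[1L])))
      }
      starts <- integer(n); ends <- integer(n)
      for (i in seq_len(n)) {
        starts[i] <- pos
        parts <- c(parts, b[i]); pos <- pos + nchar(b[i])
        ends[i] <- pos
        if (i < n) { parts <- c(parts, introns[i]); pos <- pos + nchar(introns[i]) }
      }
      parts <- c(parts, "TAA"); pos <- pos + 3L
      if (cp < n_copies) {
        sp <- random_dna(spacer_length, gc_background)
        parts <- c(parts, sp); pos <- pos + nchar(sp)
      }
      if (cp == 1L) ann_exons <- data.frame(start = starts, end = ends)
      truth_rows[[cp]] <- data.frame(copy = cp, exon_index = seq_len(n),
                                     start = starts, end = ends)
    }
    parts <- c(parts, flank)
    seq <- paste(parts, collapse = "")
    gene <- derive_gene_structure(seq, ann_exons, seq_id = "tandem",
                                  transcript_id = "tandem.t1",
                                  gene_id = "tandem.g1")
    list(sequence = setNames(seq, "tandem"), gene = gene,
         truth = do.call(rbind, truth_rows))
  })
}

#' Trans-spliced gene fixture
#'
#' Emulates a gene whose transcripts join a common first exon to one of two
#' parallel groups of homologous 3' exons (one group per isoform). The
#' annotated transcript is isoform A; the isoform-B group lies inside the
#' intron between the common exon and the first A-specific exon, each member
#' framed by splice dinucleotides compatible with isoform A's introns. A
#' surrounding-introns search from isoform A therefore proposes a single
#' misleading mutually exclusive candidate for the first A-specific exon,
#' while an all-introns search reveals the whole parallel group.
#'
#' @param seed integer seed.
#' @param group_aa_lengths amino acids of the isoform-specific exons.
#' @param common_aa length of the shared first exon.
#' @param divergence per-codon substitution rate between the A and B group
#'   members.
#' @param pad intra-intron padding around the hidden group members (nt).
#' @param gc_background GC fraction of non-coding sequence.
#' @return list with `sequence`, `gene` (isoform A) and `truth` (intervals
#'   of the hidden isoform-B exons with the matching A exon index).
#' @export
make_trans_spliced_fixture <- function(seed = 1L,
                                       group_aa_lengths = c(25L, 30L, 25L),
                                       common_aa = 20L,
                                       divergence = 0.05,
                                       pad = 30L,
                                       gc_background = 0.5) {
  k <- length(group_aa_lengths)
  with_seed(seed, {
    total_aa <- common_aa + sum(group_aa_lengths)
    cds <- paste(c("ATG", random_codons(total_aa - 1L)), collapse = "")
    lens <- 3L * c(common_aa, group_aa_lengths)
    offs <- cumsum(c(0L, lens))
    bodies <- substring(cds, offs[-length(offs)] + 1L, offs[-1L])
    a_bodies <- bodies[-1L]
    b_bodies <- vapply(a_bodies, mutate_body, character(1),
                       start_phase = 0L, end_phase = 0L,
                       substitution_rate = divergence, indel_codon_rate = 0)

    # big intron: GT pad [AG b1 GT] pad [AG b2 GT] pad [AG b3 TAA] pad AG;
    # the last group member is an alternative terminal exon and is followed
    # by a stop codon rather than a donor site
    mid <- character(0)
    b_local <- integer(k)   # local offsets of b bodies inside the intron
    cursor <- 2L + pad      # after "GT" + pad
    mid <- c("GT", random_dna(pad, gc_background))
    for (i in seq_len(k)) {
      after <- if (i == k) "TAA" else "GT"
      mid <- c(mid, "AG", b_bodies[i], after)
      b_local[i] <- cursor + 2L
      cursor <- cursor + 2L + nchar(b_bodies[i]) + nchar(after)
      padseq <- random_dna(pad, gc_background)
      mid <- c(mid, padseq)
      cursor <- cursor + pad
    }
    mid <- c(mid, "AG")
    big_intron <- paste(mid, collapse = "")

    small_introns <- vapply(seq_len(k - 1L), function(i)
      paste0("GT", random_dna(40L, gc_background), "AG"), character(1))
    flank <- random_dna(300L, gc_background)

    parts <- flank; pos <- nchar(flank)
    starts <- integer(k + 1L); ends <- integer(k + 1L)
    starts[1L] <- pos
    parts <- c(parts, bodies[1L]); pos <- pos + nchar(bodies[1L])
    ends[1L] <- pos
    big_start <- pos
    parts <- c(parts, big_intron); pos <- pos + nchar(big_intron)
    for (i in seq_len(k)) {
      starts[i + 1L] <- pos
      parts <- c(parts, a_bodies[i]); pos <- pos + nchar(a_bodies[i])
      ends[i + 1L] <- pos
      if (i < k) {
        parts <- c(parts, small_introns[i])
        pos <- pos + nchar(small_introns[i])
      }
    }
    parts <- c(parts, "TAA", flank)
    seq <- paste(parts, collapse = "")
    gene <- derive_gene_structure(seq, data.frame(start = starts, end = ends),
                                  seq_id = "trans",
                                  transcript_id = "trans.tA",
                                  gene_id = "trans.g1")
    truth <- data.frame(
      exon_index = seq_len(k) + 1L,  # matching isoform-A exon
      copy = seq_len(k),
      start = big_start + b_local,
      end = big_start + b_local + nchar(b_bodies),
      substitution_rate = divergence, indel_codon_rate = 0,
      translation = vapply(b_bodies, translate_codons, character(1)),
      relative_score = NA_real_,
      stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      truth$relative_score[i] <- relative_score(
        truth$translation[i], exon_translation(gene, i + 1L))
    }
    list(sequence = setNames(seq, "trans"), gene = gene, truth = truth)
  })
}

#' Write a fixture to FASTA + GFF3 + ground-truth TSV
#'
#' @param fixture list from [random_gene()], [make_tandem_array()] or
#'   [make_trans_spliced_fixture()].
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return named character vector of the written paths.
#' @export
write_fixture <- function(fixture, dir, basename = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(basename, ".fa"))
  gff <- file.path(dir, paste0(basename, ".gff3"))
  tsv <- file.path(dir, paste0(basename, "_truth.tsv"))
  writeLines(c(paste0(">", names(fixture$sequence)[1L]),
               unname(fixture$sequence)), fa)
  g <- fixture$gene
  ex <- g$exons
  lines <- c("##gff-version 3",
             paste(g$seq_id, "mxescan_synth", "gene",
                   ex$start[1L] + 1L, ex$end[nrow(ex)], ".", "+", ".",
                   paste0("ID=", g$gene_id), sep = "\t"),
             paste(g$seq_id, "mxescan_synth", "mRNA",
                   ex$start[1L] + 1L, ex$end[nrow(ex)], ".", "+", ".",
                   paste0("ID=", g$transcript_id, ";Parent=", g$gene_id),
                   sep = "\t"),
             vapply(seq_len(nrow(ex)), function(i)
               paste(g$seq_id, "mxescan_synth", "CDS",
                     ex$start[i] + 1L, ex$end[i], ".", "+",
                     ex$start_phase[i],
                     paste0("ID=", g$transcript_id, ".cds", i,
                            ";Parent=", g$transcript_id), sep = "\t"),
               character(1)))
  writeLines(lines, gff)
  write.table(fixture$truth, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(fasta = fa, gff3 = gff, truth = tsv)
}
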