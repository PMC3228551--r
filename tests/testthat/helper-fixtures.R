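# Deterministic fixture builders shared across the tests.

# a small hand-checkable gene: flank + e1 + i1 + e2 + i2 + e3 + TAA + flank
make_hand_gene <- function() {
  e1 <- "ATGGCTAAATTTGGG"                     # MAKFG
  e2 <- "CCCGATGAAGTTCTTGCTATTCGT"            # PDEVLAIR
  e3 <- "GGTCATATTCTG"                        # GHIL
  i1 <- paste0("GT", strrep("C", 30), "AG")
  i2 <- paste0("GT", strrep("T", 26), "AG")
  flank <- strrep("A", 20)
  seq <- paste0(flank, e1, i1, e2, i2, e3, "TAA", flank)
  s1 <- nchar(flank)
  exons <- data.frame(
    start = c(s1, s1 + nchar(e1) + nchar(i1),
              s1 + nchar(e1) + nchar(i1) + nchar(e2) + nchar(i2)),
    end = c(s1 + nchar(e1),
            s1 + nchar(e1) + nchar(i1) + nchar(e2),
            s1 + nchar(e1) + nchar(i1) + nchar(e2) + nchar(i2) + nchar(e3)))
  derive_gene_structure(seq, exons, seq_id = "hand", transcript_id = "hand.t1")
}

# standard implant fixture used by several suites
make_implant_fixture <- function(seed = 7L, n_copies = 2L,
                                 substitution_rate = 0,
                                 indel_codon_rate = 0) {
  random_gene(fixture_spec(
    seed = seed, exon_aa_lengths = c(30L, 40L, 30L),
    intron_lengths = c(250L + 150L * n_copies, 200L),
    implants = data.frame(exon_index = 2L, n_copies = n_copies,
                          substitution_rate = substitution_rate,
                          indel_codon_rate = indel_codon_rate,
                          intron = 1L)))
}

# gene whose intron 1 carries two planted candidates for exon 2:
#   B = first half of exon 2 + junk   (findable from the query exon A)
#   C = other junk + second half of B (findable only from B)
# used for the recursion-depth tests; the premises (B scores above the
# threshold from A, C below from A but above from B) are asserted by the
# tests themselves
make_recursion_fixture <- function(seed = 101L) {
  with_seed(seed, {
    half <- 30L   # nt per half, multiple of 3
    a_body <- paste(mxescan:::random_codons(20L), collapse = "")
    junk1 <- paste(mxescan:::random_codons(10L), collapse = "")
    junk2 <- paste(mxescan:::random_codons(10L), collapse = "")
    b_body <- paste0(substr(a_body, 1L, half), junk1)
    c_body <- paste0(junk2, substr(b_body, half + 1L, nchar(b_body)))
    e1 <- paste(c("ATG", mxescan:::random_codons(19L)), collapse = "")
    e3 <- paste(mxescan:::random_codons(20L), collapse = "")
    pad <- function(n) mxescan:::random_dna(n)
    i1 <- paste0("GT", pad(20), "AG", b_body, "GT", pad(20),
                 "AG", c_body, "GT", pad(20), "AG")
    i2 <- paste0("GT", pad(40), "AG")
    flank <- pad(80)
    seq <- paste0(flank, e1, i1, a_body, i2, e3, "TAA", flank)
    o <- nchar(flank)
    exons <- data.frame(
      start = c(o, o + nchar(e1) + nchar(i1),
                o + nchar(e1) + nchar(i1) + nchar(a_body) + nchar(i2)),
      end = c(o + nchar(e1), o + nchar(e1) + nchar(i1) + nchar(a_body),
              o + nchar(e1) + nchar(i1) + nchar(a_body) + nchar(i2) +
                nchar(e3)))
    gene <- derive_gene_structure(seq, exons, seq_id = "rec",
                                  transcript_id = "rec.t1")
    b_start <- o + nchar(e1) + 2L + 20L + 2L
    c_start <- b_start + nchar(b_body) + 2L + 20L + 2L
    list(gene = gene,
         a_aa = mxescan:::translate_codons(a_body),
         b_aa = mxescan:::translate_codons(b_body),
         c_aa = mxescan:::translate_codons(c_body),
         b = c(b_start, b_start + nchar(b_body)),
         c = c(c_start, c_start + nchar(c_body)))
  })
}

# write a fixture's gene as a MINUS-strand GFF3 over the reverse-complement
# genome (coordinates flipped), to exercise strand normalization
write_minus_strand_fixture <- function(fixture, dir,
                                       basename = "minus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- fixture$gene
  L <- nchar(g$sequence)
  rcseq <- mxescan:::revcomp(g$sequence)
  fa <- file.path(dir, paste0(basename, ".fa"))
  writeLines(c(paste0(">", g$seq_id), rcseq), fa)
  ex <- g$exons
  # exon [s, e) on the plus strand maps to [L - e, L - s) on the rc genome
  st1 <- L - ex$end + 1L    # 1-based inclusive on the rc genome
  en1 <- L - ex$start
  ord <- order(st1)
  lines <- c("##gff-version 3",
             paste(g$seq_id, "test", "gene", min(st1), max(en1), ".", "-",
                   ".", paste0("ID=", g$gene_id), sep = "\t"),
             paste(g$seq_id, "test", "mRNA", min(st1), max(en1), ".", "-",
                   ".", paste0("ID=", g$transcript_id, ";Parent=", g$gene_id),
                   sep = "\t"),
             vapply(ord, function(i)
               paste(g$seq_id, "test", "CDS", st1[i], en1[i], ".", "-",
                     ex$start_phase[i],
                     paste0("ID=cds", i, ";Parent=", g$transcript_id),
                     sep = "\t"), character(1)))
  gff <- file.path(dir, paste0(basename, ".gff3"))
  writeLines(lines, gff)
  c(fasta = fa, gff3 = gff)
}

member_keys <- function(cluster) {
  m <- cluster$members
  paste(m$start, m$end, sep = "-")
}
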