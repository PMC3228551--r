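# helper: a gene with two transcripts sharing flanking exons and one
# alternative internal exon each (an annotation-level MXE cluster)
make_two_transcript_gene <- function(seed = 51L, divergence = 0.1,
                                     gene_id = "mx.g1") {
  fx <- random_gene(fixture_spec(
    seed = seed, exon_aa_lengths = c(25L, 30L, 25L),
    intron_lengths = c(80L, 500L),
    implants = data.frame(exon_index = 2L, n_copies = 1L,
                          substitution_rate = divergence,
                          indel_codon_rate = 0, intron = 2L)))
  g1 <- fx$gene
  g1$gene_id <- gene_id
  ex2 <- g1$exons[, c("start", "end")]
  ex2$start[2L] <- fx$truth$start[1L]
  ex2$end[2L] <- fx$truth$end[1L]
  g2 <- derive_gene_structure(g1$sequence, ex2, seq_id = g1$seq_id,
                              transcript_id = paste0(g1$transcript_id, "b"),
                              gene_id = gene_id)
  list(t1 = g1, t2 = g2, truth = fx$truth)
}

test_that("annotation-defined MXE clusters satisfy all four criteria", {
  mx <- make_two_transcript_gene()
  cl <- annotated_mxe_clusters(list(mx$t1, mx$t2))
  expect_length(cl, 1L)
  expect_true(cl[[1L]]$flanked)
  expect_false(cl[[1L]]$group_type)
  expect_identical(cl[[1L]]$terminal_side, "none")
  expect_identical(nrow(cl[[1L]]$members), 2L)
  keys <- paste(cl[[1L]]$members$start, cl[[1L]]$members$end)
  expect_true(paste(mx$truth$start, mx$truth$end) %in% keys)
  # invariant under transcript order permutation
  cl2 <- annotated_mxe_clusters(list(mx$t2, mx$t1))
  expect_identical(cl2[[1L]]$members, cl[[1L]]$members)
})

test_that("terminal and degenerate annotation patterns are separated", {
  seq <- paste0(strrep("A", 10),
                "ATGGCTAAATTT", "GT", strrep("C", 16), "AG",
                "ATGGCAAAGTTC", "GT", strrep("T", 16), "AG",
                "GGTCATATTCTGGAAGAG", "TAA", strrep("A", 10))
  o <- 10L
  e1a <- c(o, o + 12L)
  e1b <- c(o + 32L, o + 44L)
  e2 <- c(o + 64L, o + 82L)
  t1 <- derive_gene_structure(seq, data.frame(start = c(e1a[1L], e2[1L]),
                                              end = c(e1a[2L], e2[2L])),
                              transcript_id = "tA", gene_id = "g")
  t2 <- derive_gene_structure(seq, data.frame(start = c(e1b[1L], e2[1L]),
                                              end = c(e1b[2L], e2[2L])),
                              transcript_id = "tB", gene_id = "g")
  cl <- annotated_mxe_clusters(list(t1, t2))
  expect_length(cl, 1L)
  expect_false(cl[[1L]]$flanked)
  expect_identical(cl[[1L]]$terminal_side, "first")

  # T1=(e1,e2), T2=(e1,e2,e3): no cluster, "exactly one" violated
  mx <- make_two_transcript_gene(seed = 52L)
  t_short <- derive_gene_structure(mx$t1$sequence,
                                   mx$t1$exons[c(1L, 3L), c("start", "end")],
                                   transcript_id = "short", gene_id = "mx.g1")
  expect_length(annotated_mxe_clusters(list(t_short, mx$t1)), 0L)
})

test_that("neighbour scan flags only frame-compatible similar pairs", {
  # adjacent identical exons, same phase: flagged
  body <- mxescan:::with_seed(61L,
    paste(mxescan:::random_codons(20L), collapse = ""))
  seq <- paste0(strrep("A", 10), "ATGGCTAAA", "GT", strrep("C", 16), "AG",
                body, "GT", strrep("T", 16), "AG",
                body, "GT", strrep("G", 16), "AG",
                "GGTCATATTCTGGAAGAGTTTAAAGGGCATATTGGGCATATTGGGCAT",
                "TAA", strrep("A", 10))
  o <- 10L
  s1 <- o; e1 <- s1 + 9L
  s2 <- e1 + 20L; e2 <- s2 + 60L
  s3 <- e2 + 20L; e3 <- s3 + 60L
  s4 <- e3 + 20L; e4 <- s4 + 48L
  g <- derive_gene_structure(seq, data.frame(start = c(s1, s2, s3, s4),
                                             end = c(e1, e2, e3, e4)),
                             transcript_id = "nb", gene_id = "nb.g")
  sc <- neighbour_similarity_scan(list(g))
  pr <- sc$pairs
  expect_true(pr$flagged[pr$exon_i == 2L & pr$exon_j == 3L])
  # the 3-aa first exon is below the minimal exon length
  expect_false(pr$flagged[pr$exon_i == 1L])
  expect_false(pr$long_enough[pr$exon_i == 1L])
  expect_identical(sc$n_exons_flagged, 2L)
  expect_identical(sc$n_transcripts_flagged, 1L)

  # a length difference beyond 20 aa is never flagged even if homologous
  long1 <- mxescan:::with_seed(62L,
    paste(mxescan:::random_codons(40L), collapse = ""))
  seqB <- paste0(strrep("A", 10), "ATGGCTAAA", "GT", strrep("C", 16), "AG",
                 long1, "GT", strrep("T", 16), "AG",
                 paste0(long1, strrep("GCT", 26)),
                 "TAA", strrep("A", 10))
  sB1 <- 10L; eB1 <- sB1 + 9L
  sB2 <- eB1 + 20L; eB2 <- sB2 + 120L
  sB3 <- eB2 + 20L; eB3 <- sB3 + 198L
  gB <- derive_gene_structure(seqB, data.frame(start = c(sB1, sB2, sB3),
                                               end = c(eB1, eB2, eB3)),
                              transcript_id = "nb2", gene_id = "nb2.g")
  scB <- neighbour_similarity_scan(list(gB))
  pB <- scB$pairs[scB$pairs$exon_i == 2L, ]
  expect_false(pB$flagged)
  expect_false(pB$frame_ok)   # 26 aa difference exceeds the window
})

test_that("evaluation computes sensitivity and specificity exactly", {
  # predictions identical to annotation: both 1.0
  pred <- data.frame(gene_id = "g", start = c(0L, 50L), end = c(30L, 80L),
                     is_query = c(TRUE, FALSE),
                     classification = "internal_mxe",
                     stringsAsFactors = FALSE)
  ann <- list(list(gene_id = "g",
                   members = data.frame(start = c(0L, 50L),
                                        end = c(30L, 80L)),
                   flanked = TRUE, terminal_side = "none",
                   group_type = FALSE))
  ev <- evaluate_against_annotation(pred, ann)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  # 3 annotated, 2 predicted-and-matched, 4 predicted in total
  pred2 <- data.frame(gene_id = "g",
                      start = c(0L, 50L, 100L, 200L),
                      end = c(30L, 80L, 130L, 230L),
                      is_query = c(TRUE, FALSE, FALSE, FALSE),
                      classification = "internal_mxe",
                      stringsAsFactors = FALSE)
  ann2 <- list(list(gene_id = "g",
                    members = data.frame(start = c(0L, 50L, 300L),
                                         end = c(30L, 80L, 330L)),
                    flanked = TRUE, terminal_side = "none",
                    group_type = FALSE))
  ev2 <- evaluate_against_annotation(pred2, ann2)
  expect_equal(ev2$sensitivity, 2 / 3)
  expect_equal(ev2$specificity, 2 / 4)

  # overlapping-but-not-matching predictions are counted separately
  pred3 <- data.frame(gene_id = "g", start = c(0L, 52L), end = c(30L, 82L),
                      is_query = c(TRUE, FALSE),
                      classification = "internal_mxe",
                      stringsAsFactors = FALSE)
  ev3 <- evaluate_against_annotation(pred3, ann)
  expect_identical(ev3$n_overlap_only, 1L)
  expect_equal(ev3$sensitivity, 1 / 2)
})

test_that("exon-set comparison counts exact and overlap matches", {
  a <- data.frame(start = c(0L, 20L, 50L), end = c(10L, 30L, 60L))
  expect_identical(compare_exon_sets(a, a)[c("exact", "overlap")],
                   list(exact = 3L, overlap = 3L))
  b <- data.frame(start = 5L, end = 15L)
  cmp <- compare_exon_sets(data.frame(start = 0L, end = 10L), b)
  expect_identical(cmp$exact, 0L)
  expect_identical(cmp$overlap, 1L)
  cmp2 <- compare_exon_sets(a, data.frame(start = 100L, end = 110L))
  expect_identical(cmp2$exact, 0L)
  expect_identical(cmp2$overlap, 0L)
})

test_that("the screen pools transcripts and recovers planted ground truth", {
  mx <- make_two_transcript_gene(seed = 53L, divergence = 0.05)
  fx_a <- random_gene(fixture_spec(
    seed = 54L, exon_aa_lengths = c(20L, 30L, 20L),
    intron_lengths = c(400L, 80L),
    implants = data.frame(exon_index = 2L, n_copies = 2L,
                          substitution_rate = 0, indel_codon_rate = 0,
                          intron = 1L)))
  fx_b <- random_gene(fixture_spec(seed = 55L,
                                   exon_aa_lengths = c(20L, 25L, 20L),
                                   intron_lengths = c(90L, 90L)))
  relabel <- function(g, id) { g$gene_id <- id; g }
  seqs <- c(mx = unname(mx$t1$sequence), fa = unname(fx_a$gene$sequence),
            fb = unname(fx_b$gene$sequence))
  genes <- list(mx$t1, mx$t2,
                relabel(fx_a$gene, "ga"), relabel(fx_b$gene, "gb"))
  genes[[1L]]$seq_id <- "mx"; genes[[2L]]$seq_id <- "mx"
  genes[[3L]]$seq_id <- "fa"; genes[[4L]]$seq_id <- "fb"
  rep <- chromosome_screen(seqs, genes)
  expect_identical(rep$n_transcripts, 4L)
  expect_identical(rep$n_exons, 12L)
  # both MXE transcripts find each other's exon; fixture A finds 2 implants
  expect_identical(unname(rep$predicted$exons["internal_mxe"]), 4L)
  expect_identical(unname(rep$predicted$genes["internal_mxe"]), 2L)
  # the annotated cluster is fully recovered
  expect_equal(rep$evaluation$sensitivity, 1.0)
  expect_identical(rep$evaluation$n_annotated, 2L)
  # implants of fixture A are predictions without annotation support
  expect_lt(rep$evaluation$specificity, 1.0)
  expect_identical(rep$evaluation$n_predicted, 5L)
  # counts equal independent recounts from the emitted table
  tab <- rep$table
  expect_identical(unname(rep$predicted$exons["internal_mxe"]),
                   sum(!tab$is_query & tab$classification == "internal_mxe"))
})

test_that("screens of annotations without multi-exon transcripts are empty", {
  g1 <- derive_gene_structure("ATGGCTGAAGGGTAA",
                              data.frame(start = 0L, end = 12L),
                              transcript_id = "solo")
  rep <- chromosome_screen(c(s = "ATGGCTGAAGGGTAA"), list(g1))
  expect_identical(rep$n_transcripts, 0L)
  expect_identical(sum(rep$predicted$exons), 0L)
})
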