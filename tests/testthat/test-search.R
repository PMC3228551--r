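test_that("identity implants are recovered with exact borders and score 1", {
  fx <- make_implant_fixture(seed = 7L, n_copies = 2L)
  res <- search_transcript(fx$gene)
  expect_length(res$clusters, 1L)
  cl <- res$clusters[[1L]]
  expect_identical(cl$query_exon, 2L)
  expect_identical(cl$classification, "internal_mxe")
  m <- cl$members
  expect_identical(nrow(m), 3L)
  expect_true(m$is_query[m$start == fx$gene$exons$start[2L]])
  for (k in seq_len(nrow(fx$truth))) {
    hit <- m[m$start == fx$truth$start[k] & m$end == fx$truth$end[k], ]
    expect_identical(nrow(hit), 1L)
    expect_equal(hit$relative_score, 1.0)
  }
  # cluster members are pairwise non-overlapping
  expect_true(all(m$start[-1L] >= m$end[-nrow(m)]))
})

test_that("genes without homologous exon copies give trivial results", {
  fx <- random_gene(fixture_spec(seed = 19L, intron_lengths = c(120L, 120L)))
  res <- search_transcript(fx$gene)
  # any surviving hit must have passed every filter; verify rather than
  # assume absence
  for (cl in res$clusters) {
    m <- cl$members[!cl$members$is_query, ]
    expect_true(all(m$relative_score >= res$params$min_score - 1e-9))
  }
  g1 <- derive_gene_structure("ATGGCTGAAGGGTAA",
                              data.frame(start = 0L, end = 12L))
  r1 <- search_transcript(g1, search_params(
    search_with_start_codon = "off", search_with_stop_codon = "off"))
  expect_length(r1$clusters, 0L)
})

test_that("search is deterministic", {
  fx <- make_implant_fixture(seed = 23L, substitution_rate = 0.1)
  r1 <- search_transcript(fx$gene)
  r2 <- search_transcript(fx$gene)
  expect_identical(r1$clusters, r2$clusters)
})

test_that("recursion adds divergent members reachable only via candidates", {
  fx <- make_recursion_fixture(seed = 101L)
  p0 <- search_params(allowed_length_difference = 0)
  # fixture premises: B is findable from the query, C only from B
  expect_gte(relative_score(fx$b_aa, fx$a_aa), 0.15)
  expect_lt(relative_score(fx$c_aa, fx$a_aa), 0.15)
  expect_gte(relative_score(fx$c_aa, fx$b_aa), 0.15)

  r0 <- search_transcript(fx$gene, p0)
  k0 <- unlist(lapply(r0$clusters, member_keys))
  expect_true(paste(fx$b[1L], fx$b[2L], sep = "-") %in% k0)
  expect_false(paste(fx$c[1L], fx$c[2L], sep = "-") %in% k0)

  p1 <- search_params(allowed_length_difference = 0, max_recursion_depth = 1)
  r1 <- search_transcript(fx$gene, p1)
  k1 <- unlist(lapply(r1$clusters, member_keys))
  expect_true(paste(fx$c[1L], fx$c[2L], sep = "-") %in% k1)
  cl1 <- r1$clusters[[1L]]
  expect_identical(cl1$recursion_rounds_used, 1L)
  expect_identical(cl1$members$depth[cl1$members$start == fx$c[1L]], 1L)
})

test_that("member sets grow monotonically with recursion depth", {
  fixtures <- list(make_recursion_fixture(101L)$gene,
                   make_implant_fixture(25L, n_copies = 3L,
                                        substitution_rate = 0.2)$gene)
  for (g in fixtures) {
    keys <- lapply(0:2, function(d) {
      res <- search_transcript(g, search_params(max_recursion_depth = d))
      unlist(lapply(res$clusters, member_keys))
    })
    expect_true(all(keys[[1L]] %in% keys[[2L]]))
    expect_true(all(keys[[2L]] %in% keys[[3L]]))
  }
})

test_that("minus-strand presentation yields score-identical clusters", {
  fx <- make_implant_fixture(seed = 29L, substitution_rate = 0.1)
  res_plus <- search_transcript(fx$gene)
  dir <- tempfile()
  paths <- write_minus_strand_fixture(fx, dir)
  g2 <- read_gff3(paths["gff3"], read_fasta(paths["fasta"]))[[1L]]
  res_minus <- search_transcript(g2)
  expect_identical(length(res_plus$clusters), length(res_minus$clusters))
  for (i in seq_along(res_plus$clusters)) {
    a <- res_plus$clusters[[i]]$members
    b <- res_minus$clusters[[i]]$members
    expect_identical(a$start, b$start)
    expect_identical(a$end, b$end)
    expect_equal(a$relative_score, b$relative_score)
  }
})

test_that("swapping an accepted candidate into the structure re-finds the query", {
  fx <- make_implant_fixture(seed = 37L, substitution_rate = 0.1)
  res <- search_transcript(fx$gene)
  cl <- res$clusters[[1L]]
  cand <- cl$members[!cl$members$is_query, ][1L, ]
  ex <- fx$gene$exons[, c("start", "end")]
  ex$start[2L] <- cand$start; ex$end[2L] <- cand$end
  g2 <- derive_gene_structure(fx$gene$sequence, ex,
                              transcript_id = "swapped")
  res2 <- search_transcript(g2)
  m2 <- res2$clusters[[1L]]$members
  back <- m2[m2$start == fx$gene$exons$start[2L] &
               m2$end == fx$gene$exons$end[2L], ]
  expect_identical(nrow(back), 1L)
  # symmetric matrix: score(cand vs query)/self(query) was recorded going
  # out; going back the raw score is identical
  expect_equal(back$raw_score, cand$raw_score)
})

test_that("clusters are classified by query exon position", {
  g <- make_hand_gene()
  cl_int <- mxescan:::new_cluster(g, 2L,
    mxescan:::query_member_row(g, 2L, 10), "x")
  expect_identical(classify_cluster(cl_int, g), "internal_mxe")
  cl_first <- mxescan:::new_cluster(g, 1L,
    mxescan:::query_member_row(g, 1L, 10), "x")
  expect_identical(classify_cluster(cl_first, g), "multiple_promoter_like")
  cl_last <- mxescan:::new_cluster(g, 3L,
    mxescan:::query_member_row(g, 3L, 10), "x")
  expect_identical(classify_cluster(cl_last, g), "multiple_polyA_like")
})

test_that("tandem arrays are flagged as group patterns", {
  tx <- make_tandem_array(seed = 3L, n_copies = 2L, divergence = 0)
  p <- search_params(search_all_introns = TRUE, search_updownstream = TRUE)
  res <- search_transcript(tx$gene, p)
  expect_identical(length(res$clusters), nrow(tx$gene$exons))
  for (cl in res$clusters) {
    expect_identical(cl$classification, "group_pattern")
    # the duplicate of the query exon is among the members, exact borders
    dup <- tx$truth[tx$truth$copy == 2L &
                      tx$truth$exon_index == cl$query_exon, ]
    expect_true(paste(dup$start, dup$end, sep = "-") %in% member_keys(cl))
  }
  # a single copy produces no group pattern
  tx1 <- make_tandem_array(seed = 3L, n_copies = 1L)
  res1 <- search_transcript(tx1$gene, p)
  expect_false(any(vapply(res1$clusters, `[[`, character(1),
                          "classification") == "group_pattern"))
})

test_that("trans-spliced groups are revealed by the all-introns search", {
  ts <- make_trans_spliced_fixture(seed = 5L)
  # surrounding introns only: one misleading internal MXE cluster
  r1 <- search_transcript(ts$gene)
  expect_length(r1$clusters, 1L)
  expect_identical(r1$clusters[[1L]]$query_exon, 2L)
  expect_identical(r1$clusters[[1L]]$classification, "internal_mxe")
  # all introns: the parallel group is found and flagged
  r2 <- search_transcript(ts$gene, search_params(search_all_introns = TRUE))
  flagged <- vapply(r2$clusters, `[[`, character(1), "classification")
  expect_identical(sort(vapply(r2$clusters, `[[`, integer(1), "query_exon")),
                   ts$truth$exon_index)
  expect_true(all(flagged == "group_pattern"))
  for (cl in r2$clusters) {
    hid <- ts$truth[ts$truth$exon_index == cl$query_exon, ]
    expect_true(paste(hid$start, hid$end, sep = "-") %in% member_keys(cl))
  }
})

test_that("group patterns are not flagged for plain MXE clusters", {
  fx <- make_implant_fixture(seed = 7L, n_copies = 2L)
  res <- search_transcript(fx$gene, search_params(search_all_introns = TRUE,
                                                  search_updownstream = TRUE))
  expect_false(any(vapply(res$clusters, `[[`, character(1),
                          "classification") == "group_pattern"))
})
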