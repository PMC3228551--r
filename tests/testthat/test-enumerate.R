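test_that("acceptor and donor site scans keep overlapping occurrences", {
  expect_identical(find_acceptor_sites("GTCCAGTT", "AG"), 6L)
  expect_identical(find_acceptor_sites("AGAGAG", "AG"), c(2L, 4L, 6L))
  expect_identical(find_acceptor_sites("CCCC", "AG"), integer(0))
  expect_identical(find_donor_sites("AAGTAA", c("GT", "GC", "GG")), 2L)
  expect_identical(find_donor_sites("GGGG", c("GT", "GC", "GG")),
                   c(0L, 1L, 2L))
  expect_identical(find_donor_sites("AAAA", c("GT", "GC", "GG")), integer(0))
  # margins push sites away from the region boundaries
  expect_identical(find_acceptor_sites("AGAGAG", "AG", min_margin = 4L),
                   c(4L, 6L))
  expect_identical(find_donor_sites("GGGG", c("GG"), min_margin = 4L),
                   0L)
})

test_that("candidate enumeration applies the splice/frame constraints", {
  intron <- "GTAAACAGATGGCTGAAGTTTTTTTAG"
  p <- search_params(allowed_length_difference = 0, min_exon_length = 1)
  cand <- enumerate_in_region(intron, 0L, 9L, p,
                              acc_targets = acceptor_targets("GT"),
                              don_targets = donor_targets("AG"))
  expect_identical(cand$start, 8L)
  expect_identical(cand$end, 17L)
  expect_identical(substr(intron, 9L, 17L), "ATGGCTGAA")

  # a 12-nt query has no frame-compatible interval here
  cand12 <- enumerate_in_region(intron, 0L, 12L, p,
                                acc_targets = "AG",
                                don_targets = c("GT", "GC", "GG"))
  expect_identical(nrow(cand12), 0L)
})

test_that("queries below the minimal exon length are not searched", {
  fx <- make_implant_fixture(seed = 5L)
  g <- fx$gene
  region <- list(start = g$introns$start[1L], end = g$introns$end[1L],
                 role = "upstream_intron")
  p <- search_params(min_exon_length = 100)   # 40-aa exon is too short now
  expect_identical(nrow(enumerate_candidates(g, 2L, region, p)), 0L)
  cl <- search_exon(g, 2L, p)
  expect_s3_class(cl, "exon_skip")
  expect_match(attr(cl, "reason"), "minimal exon length")
})

test_that("first-exon candidates are anchored at ATG", {
  region_seq <- "CCATGGCTGAAGTCC"
  p <- search_params(allowed_length_difference = 0, min_exon_length = 1)
  cand <- enumerate_in_region(region_seq, 0L, 9L, p,
                              start_anchor = "atg", end_anchor = "donor",
                              don_targets = donor_targets("AG"),
                              intron_region = FALSE)
  expect_identical(cand$start, 2L)
  expect_identical(cand$end, 11L)
  expect_identical(substr(region_seq, 3L, 11L), "ATGGCTGAA")
  # no ATG, no candidates
  none <- enumerate_in_region("CCCCCCGGTTTT", 0L, 9L, p,
                              start_anchor = "atg", end_anchor = "donor",
                              don_targets = "GT", intron_region = FALSE)
  expect_identical(nrow(none), 0L)
})

test_that("last-exon candidates must be followed by a stop codon", {
  region_seq <- "CCAGGCTGAAGAGTAACC"
  p <- search_params(allowed_length_difference = 0, min_exon_length = 1)
  cand <- enumerate_in_region(region_seq, 0L, 9L, p,
                              start_anchor = "acceptor", end_anchor = "stop",
                              acc_targets = acceptor_targets("GT"),
                              intron_region = FALSE)
  expect_identical(cand$start, 4L)
  expect_identical(cand$end, 13L)
  expect_identical(substr(region_seq, 14L, 16L), "TAA")
  # no in-frame stop after any compatible interval
  none <- enumerate_in_region("CCAGGCTGAAGAGCCCCC", 0L, 9L, p,
                              start_anchor = "acceptor", end_anchor = "stop",
                              acc_targets = "AG", intron_region = FALSE)
  expect_identical(nrow(none), 0L)
})

test_that("terminal anchoring follows the start/stop codon modes", {
  fx <- make_implant_fixture(seed = 9L)
  g <- fx$gene
  expect_true(g$starts_with_met && g$followed_by_stop)
  a_auto <- mxescan:::exon_anchoring(g, 1L, search_params())
  expect_identical(a_auto$start_anchor, "atg")
  a_off <- mxescan:::exon_anchoring(g, 1L,
    search_params(search_with_start_codon = "off"))
  expect_match(a_off$reason, "start-codon")
  z_auto <- mxescan:::exon_anchoring(g, nrow(g$exons), search_params())
  expect_identical(z_auto$end_anchor, "stop")
})

test_that("every emitted interval satisfies the printed constraints", {
  p <- search_params()
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(60:800, 1L)
    region_seq <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                               prob = c(.24, .24, .24, .24, .04)),
                        collapse = "")
    qlen <- 3L * sample(15:40, 1L)
    cand <- enumerate_in_region(region_seq, 0L, qlen, p,
                                acc_targets = "AG",
                                don_targets = c("GT", "GC", "GG"))
    if (!nrow(cand)) next
    d <- cand$end - cand$start
    expect_true(all((d - qlen) %% 3L == 0L))
    expect_true(all(abs(d - qlen) <= 3L * p$allowed_length_difference))
    expect_true(all(cand$start >= p$min_new_intron_length))
    expect_true(all(n - cand$end >= p$min_new_intron_length))
    expect_true(all(substring(region_seq, cand$start - 1L,
                              cand$start) == "AG"))
    expect_true(all(substring(region_seq, cand$end + 1L,
                              cand$end + 2L) %in% c("GT", "GC", "GG")))
    expect_false(any(grepl("N", substring(region_seq, cand$start + 1L,
                                          cand$end), fixed = TRUE)))
  }
})

test_that("shrinking the allowed length difference never adds candidates", {
  set.seed(405)
  p20 <- search_params(allowed_length_difference = 20)
  p5 <- search_params(allowed_length_difference = 5)
  p0 <- search_params(allowed_length_difference = 0)
  for (rep in 1:20) {
    region_seq <- mxescan:::with_seed(rep, mxescan:::random_dna(600L))
    qlen <- 3L * sample(15:30, 1L)
    key <- function(p) {
      cand <- enumerate_in_region(region_seq, 0L, qlen, p,
                                  acc_targets = "AG",
                                  don_targets = c("GT", "GC", "GG"))
      paste(cand$start, cand$end)
    }
    k20 <- key(p20); k5 <- key(p5); k0 <- key(p0)
    expect_true(all(k5 %in% k20))
    expect_true(all(k0 %in% k5))
  }
})
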