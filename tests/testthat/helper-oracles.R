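# Independent oracles used by the property and acceptance tests. These are
# deliberately written against the plain constraint statements, not against
# the package internals.

# Brute-force candidate enumeration: scan every dinucleotide index pair of
# the region directly and apply the constraints one by one.
bf_enumerate <- function(region_seq, qlen, ald, margin, acc, don) {
  n <- nchar(region_seq)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < 2L || !length(acc) || !length(don)) return(empty)
  di <- substring(region_seq, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  starts <- which(di %in% acc) - 1L + 2L        # candidate start = pos + 2
  starts <- starts[starts >= max(margin, 2L)]
  ends <- which(di %in% don) - 1L               # candidate end = pos
  ends <- ends[n - ends >= max(margin, 2L)]
  if (!length(starts) || !length(ends)) return(empty)
  g <- expand.grid(start = starts, end = ends)
  d <- g$end - g$start
  g <- g[d >= 3L & (d - qlen) %% 3L == 0L & abs(d - qlen) <= 3L * ald, ,
         drop = FALSE]
  if (nrow(g)) {
    body <- substring(region_seq, g$start + 1L, g$end)
    g <- g[!grepl("N", body, fixed = TRUE), , drop = FALSE]
  }
  g <- g[order(g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Exhaustive global-alignment oracle: enumerate every monotone alignment
# path of shape (n, m), score each path by summing substitution scores over
# its matched positions and charging every maximal gap run
# gap_open + (L - 1) * gap_extend, and take the maximum.
enumerate_paths <- function(n, m) {
  if (n == 0L && m == 0L) return(list(character(0)))
  out <- list()
  if (n > 0L && m > 0L) {
    out <- c(out, lapply(enumerate_paths(n - 1L, m - 1L),
                         function(p) c(p, "M")))
  }
  if (m > 0L) out <- c(out, lapply(enumerate_paths(n, m - 1L),
                                   function(p) c(p, "I")))
  if (n > 0L) out <- c(out, lapply(enumerate_paths(n - 1L, m),
                                   function(p) c(p, "D")))
  out
}

path_gap_cost <- function(path, go, ge) {
  cost <- 0
  run <- ""
  len <- 0L
  for (mv in c(path, "M")) {
    if (mv == run) { len <- len + 1L; next }
    if (run %in% c("I", "D")) cost <- cost + go + (len - 1L) * ge
    run <- if (mv %in% c("I", "D")) mv else ""
    len <- 1L
  }
  cost
}

# matched (i, j) index pairs of a path
path_matches <- function(path) {
  i <- 0L; j <- 0L
  ii <- integer(0); jj <- integer(0)
  for (mv in path) {
    if (mv == "M") { i <- i + 1L; j <- j + 1L; ii <- c(ii, i); jj <- c(jj, j) }
    else if (mv == "I") j <- j + 1L
    else i <- i + 1L
  }
  cbind(ii, jj)
}

oracle_align_score <- function(a, b, S, go = -10, ge = -2) {
  ach <- strsplit(a, "")[[1L]]; bch <- strsplit(b, "")[[1L]]
  best <- -Inf
  for (p in enumerate_paths(length(ach), length(bch))) {
    mm <- path_matches(p)
    sc <- path_gap_cost(p, go, ge)
    if (nrow(mm)) sc <- sc + sum(S[cbind(ach[mm[, 1L]], bch[mm[, 2L]])])
    if (sc > best) best <- sc
  }
  if (length(ach) == 0L && length(bch) == 0L) 0 else best
}
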