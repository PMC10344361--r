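# Shared fixtures and independent oracles, all generated in code.

mk_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")

# deterministic small circular reference used across tests
small_ref <- local({
  set.seed(7001)
  circular_reference(mk_seq(2000), name = "t2k")
})

# reference with exactly one BamHI recognition site at a chosen position
make_site_ref <- function(L, site_pos, seed) {
  set.seed(seed)
  s <- mk_seq(L)
  repeat {
    hits <- find_restriction_sites(s, mt_enzyme("BamHI"))
    if (length(hits) == 0) break
    substr(s, hits[1], hits[1]) <- "T"
  }
  substr(s, site_pos, site_pos + 5) <- "GGATCC"
  circular_reference(s)
}

# independent chain oracle: exhaustive DP over all predecessors (no window,
# no subsampling) with the same scoring contract as the chainer
oracle_chain_score <- function(q, r, k, gap_scale, max_ref_gap) {
  n <- length(q)
  ord <- order(q, r)
  q <- q[ord]; r <- r[ord]
  f <- rep(k, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      dq <- q[i] - q[j]; dr <- r[i] - r[j]
      if (dq <= 0 || dr <= 0 || dr - dq > max_ref_gap) next
      g <- abs(dr - dq)
      cand <- f[j] + min(k, dq) - gap_scale * log2(1 + g)
      if (cand > f[i]) f[i] <- cand
    }
  }
  max(f)
}

# repeat-shift oracle: for an error-free junction read built as
# ref[..a-1] + ref[b..], the set of zero-cost breakpoint placements is
# {(a-d, b-d)} for d = 0..D where D is the longest common suffix of the two
# flanks; the leftmost equivalent placement is (a-D, b-D)
oracle_leftmost_placement <- function(refseq, a, b, L) {
  d <- 0
  repeat {
    pa <- (a - d - 2) %% L + 1
    pb <- (b - d - 2) %% L + 1
    if (substr(refseq, pa, pa) != substr(refseq, pb, pb)) break
    d <- d + 1
  }
  c(start = (a - d - 1) %% L + 1, end = (b - d - 1) %% L + 1)
}

# brute-force single-linkage clustering oracle (O(n^2) transitive closure)
oracle_cluster <- function(signals, L, tol, min_support) {
  n <- nrow(signals)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- circular_dist(signals$start[i], signals$start[j], L) <= tol &&
      circular_dist(signals$end[i], signals$end[j], L) <= tol
  }
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[which(adj[i, ])] <- cid
    }
  }
  sizes <- table(comp)
  sort(as.integer(sizes[sizes >= min_support]), decreasing = TRUE)
}

# write a reads tibble for a set of sequences
reads_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)), seq = seqs)
}

# substring of a circular sequence (1-based, may wrap)
circ_substr <- function(s, from, len) {
  substr(paste0(s, s), from, from + len - 1)
}
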