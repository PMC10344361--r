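test_that("deletion signals come from large gaps of mapped reads only", {
  idx <- mt_index(small_ref)
  s <- small_ref$sequence
  reads <- reads_tbl(
    paste0(substr(s, 101, 300), substr(s, 701, 900)),   # 400-base gap
    paste0(substr(s, 1001, 1200), substr(s, 1261, 1460)),  # 60-base gap
    circ_substr(s, 300, 400))                           # contiguous
  a <- align_reads(reads, idx, align_params(min_cov_frac = 0.1))
  sig <- extract_del_signals(a, min_del_size = 100)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$start, 301L)
  expect_equal(sig$end, 701L)
  # lowering the floor admits the small gap too
  sig2 <- extract_del_signals(a, min_del_size = 50)
  expect_equal(nrow(sig2), 2L)
  # empty alignments give an empty, well-typed table
  a0 <- align_reads(reads_tbl(mk_seq(500)), idx)
  expect_equal(nrow(extract_del_signals(a0)), 0L)
})

test_that("clustering merges within tolerance and applies min support", {
  sig <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    start = c(301L, 301L, 301L, 305L, 2000L),
    end = c(701L, 701L, 701L, 698L, 9000L),
    size = c(400L, 400L, 400L, 393L, 7000L))
  calls <- cluster_signals(sig, L = 16569, tol = 50, min_support = 2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 301L)
  expect_equal(calls$end, 701L)
  expect_equal(calls$support, 4L)
  expect_setequal(calls$member_reads[[1]], sprintf("r%d", 1:4))

  calls1 <- cluster_signals(sig, L = 16569, tol = 50, min_support = 1)
  expect_equal(nrow(calls1), 2L)

  empty <- cluster_signals(sig[0, ], L = 16569)
  expect_equal(nrow(empty), 0L)
})

test_that("cluster support multiset matches a brute-force oracle", {
  set.seed(2101)
  L <- 16569
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    centers <- tibble::tibble(start = sample(L, 3), end = sample(L, 3))
    pick <- sample(3, n, TRUE)
    sig <- tibble::tibble(
      read_id = sprintf("r%d", seq_len(n)),
      start = (centers$start[pick] + sample(-40:40, n, TRUE) - 1) %% L + 1,
      end = (centers$end[pick] + sample(-40:40, n, TRUE) - 1) %% L + 1)
    sig$size <- circular_gap(sig$start, sig$end, L)
    calls <- cluster_signals(sig, L, tol = 60, min_support = 2)
    expect_equal(sort(calls$support, decreasing = TRUE),
                 oracle_cluster(sig, L, 60, 2))
  }
})

test_that("raising min support never increases the number of calls", {
  set.seed(2201)
  L <- 16569
  sig <- tibble::tibble(
    read_id = sprintf("r%d", 1:60),
    start = sample(L, 60, TRUE), end = sample(L, 60, TRUE))
  sig$size <- pmax(circular_gap(sig$start, sig$end, L), 1L)
  counts <- vapply(1:6, function(ms)
    nrow(cluster_signals(sig, L, tol = 100, min_support = ms)), integer(1))
  expect_true(all(diff(counts) <= 0))
  # widening tol never increases the number of clusters (pre-filter)
  ncl <- vapply(c(10, 50, 100, 300), function(tl)
    nrow(cluster_signals(sig, L, tol = tl, min_support = 1)), integer(1))
  expect_true(all(diff(ncl) <= 0))
})

test_that("VCF round trip preserves calls and the support field", {
  set.seed(2301)
  ref <- circular_reference(mk_seq(16569), "chrM")
  # note: the reader returns calls sorted by start
  calls <- tibble::tibble(start = c(2000L, 7634L), end = c(2500L, 13956L),
                          size = c(500L, 6322L), support = c(7L, 52L),
                          member_reads = list(character(0), character(0)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_deletion_vcf(calls, ref, vcf)
  lines <- readLines(vcf)
  rec <- grep("DEL002", lines, value = TRUE)
  expect_match(rec, "SVTYPE=DEL")
  expect_match(rec, "SVLEN=-6322")
  expect_match(rec, "SUPPORT=52")
  expect_match(rec, "^chrM\t7633\t")           # POS anchors the base before
  back <- read_deletion_vcf(vcf)
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
  expect_equal(back$size, calls$size)
  expect_equal(back$support, calls$support)

  # header-only file for no calls
  write_deletion_vcf(calls[0, ], ref, vcf)
  expect_false(any(!startsWith(readLines(vcf), "#")))
  expect_equal(nrow(read_deletion_vcf(vcf)), 0L)

  expect_error(write_deletion_vcf(
    tibble::tibble(start = 0L, end = 5L, size = 5L, support = 3L), ref, vcf),
    "outside")
})

test_that("origin-wrapping calls split into two records and rejoin", {
  set.seed(2401)
  ref <- circular_reference(mk_seq(16569), "chrM")
  calls <- tibble::tibble(start = 16000L, end = 500L, size = 1069L,
                          support = 9L, member_reads = list(character(0)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_deletion_vcf(calls, ref, vcf)
  body <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_length(body, 2L)
  expect_true(any(grepl("_wrapA", body)) && any(grepl("_wrapB", body)))
  back <- read_deletion_vcf(vcf)
  expect_equal(back$start, 16000L)
  expect_equal(back$end, 500L)
  expect_equal(back$size, 1069L)
})

test_that("a simulated single deletion is recovered as exactly one call", {
  ref <- random_reference(16569, seed = 2501)
  idx <- mt_index(ref)
  pop <- molecule_population(
    ref, list(tibble::tibble(start = 7634, end = 13956)), 0.5)
  sim <- simulate_run(pop, "transposase", target_depth = 40,
                      errors = perfect_reads(), seed = 2502)
  aln <- align_reads(sim$reads, idx)
  calls <- cluster_signals(extract_del_signals(aln), ref$length)
  expect_equal(nrow(calls), 1L)
  expect_lte(circular_dist(calls$start, 7634, ref$length), 50)
  expect_lte(circular_dist(calls$end, 13956, ref$length), 50)
  expect_equal(calls$size, 6322L)
  expect_gte(calls$support, 2L)
})

test_that("four planted deletions in four species give four calls", {
  ref <- random_reference(16569, seed = 2601)
  idx <- mt_index(ref)
  dels <- list(
    tibble::tibble(start = 2000, end = 4000),
    tibble::tibble(start = 6000, end = 9000),
    tibble::tibble(start = 10000, end = 12500),
    tibble::tibble(start = 13500, end = 15500))
  pop <- molecule_population(ref, dels, rep(0.2, 4))
  sim <- simulate_run(pop, "transposase", target_depth = 60,
                      errors = perfect_reads(), seed = 2602)
  aln <- align_reads(sim$reads, idx)
  calls <- cluster_signals(extract_del_signals(aln), ref$length)
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$size,
               vapply(dels, function(d)
                 circular_gap(d$start, d$end, ref$length), integer(1)))
})
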