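# minimal hand-built alignment object following the documented structure
manual_aln <- function(segments, gaps, L, read_len = 1000L) {
  ids <- unique(segments$read_id)
  structure(list(
    reads = tibble::tibble(
      read_id = ids, read_length = read_len, mapped = TRUE, strand = "+",
      score = 1, n_segments = 1L,
      aligned_bases = vapply(ids, function(i)
        sum(segments$ref_len[segments$read_id == i]), integer(1)),
      edit_distance = 0L),
    segments = segments, gaps = gaps, L = L, ref_name = "chrM"),
    class = "mt_alignments")
}

seg_row <- function(id, start, len, L, seg = 1L) {
  tibble::tibble(read_id = id, strand = "+", segment = seg,
                 read_start = 1L, read_end = len,
                 ref_start = as.integer(start), ref_len = as.integer(len),
                 ref_end = as.integer((start - 1 + len - 1) %% L + 1),
                 edit_distance = 0L)
}

test_that("coverage accumulates per segment and skips reference gaps", {
  idx <- mt_index(small_ref)
  s <- small_ref$sequence
  reads <- reads_tbl(substr(s, 1, 100), substr(s, 1, 100))
  a <- align_reads(reads, idx, align_params(min_cov_frac = 0.1))
  cov <- coverage_profile(a)
  expect_equal(cov$depth[1:100], rep(2, 100))
  expect_equal(sum(cov$depth), 200)

  jr <- reads_tbl(paste0(substr(s, 101, 300), substr(s, 701, 900)))
  aj <- align_reads(jr, idx, align_params(min_cov_frac = 0.1))
  covj <- coverage_profile(aj)
  expect_equal(sum(covj$depth[301:700]), 0)
  expect_equal(sum(covj$depth), sum(aj$segments$ref_len))

  a0 <- align_reads(reads_tbl(mk_seq(500)), idx)
  expect_equal(sum(coverage_profile(a0)$depth), 0)
})

test_that("coverage wraps the origin correctly", {
  L <- 2000L
  aln <- manual_aln(seg_row("r1", 1901L, 300L, L), tibble::tibble(), L)
  cov <- coverage_profile(aln)
  expect_equal(sum(cov$depth), 300)
  expect_equal(cov$depth[1901:2000], rep(1, 100))
  expect_equal(cov$depth[1:200], rep(1, 200))
  expect_equal(sum(cov$depth[201:1900]), 0)
})

test_that("coverage-ratio heteroplasmy follows its arithmetic", {
  L <- 16569L
  # depth 100 outside the deletion (5000, 9000), 40 inside
  depth <- rep(100, L)
  depth[5000:8999] <- 40
  cov <- tibble::tibble(pos = seq_len(L), depth = depth)
  attr(cov, "L") <- L
  class(cov) <- c("mt_coverage", class(cov))
  call <- tibble::tibble(start = 5000L, end = 9000L)
  expect_equal(heteroplasmy_coverage_ratio(cov, call), 0.60)

  depth0 <- depth; depth0[5000:8999] <- 0
  cov0 <- tibble::tibble(pos = seq_len(L), depth = depth0)
  attr(cov0, "L") <- L
  class(cov0) <- c("mt_coverage", class(cov0))
  expect_equal(heteroplasmy_coverage_ratio(cov0, call), 1.0)

  # margins exceeding the deleted interval are an error
  tiny <- tibble::tibble(start = 5000L, end = 5150L)
  expect_error(heteroplasmy_coverage_ratio(cov, tiny, margin = 100), "empty")
  # all-zero outside depth is an error
  covz <- tibble::tibble(pos = seq_len(L), depth = rep(0, L))
  attr(covz, "L") <- L
  class(covz) <- c("mt_coverage", class(covz))
  expect_error(heteroplasmy_coverage_ratio(covz, call), "zero")
})

test_that("breakpoint and cut-site margins are excluded from the outside mean", {
  L <- 16569L
  depth <- rep(100, L)
  depth[5000:8999] <- 40
  depth[12000:12100] <- 5000   # linearization spike
  cov <- tibble::tibble(pos = seq_len(L), depth = depth)
  attr(cov, "L") <- L
  class(cov) <- c("mt_coverage", class(cov))
  call <- tibble::tibble(start = 5000L, end = 9000L)
  h_with_spike <- heteroplasmy_coverage_ratio(cov, call)
  h_masked <- heteroplasmy_coverage_ratio(cov, call, site_positions = 12050L)
  expect_lt(h_masked, h_with_spike)   # spike inflates the outside mean
  expect_equal(h_masked, 0.60)
})

test_that("junction-read heteroplasmy counts J and W as specified", {
  L <- 16569L
  # 10 junction reads for deletion (5000, 9000); 10 wild-type reads across
  # each breakpoint
  segs <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:10, function(i) dplyr::bind_rows(
      seg_row(sprintf("j%d", i), 4000L, 1000L, L, 1L),
      seg_row(sprintf("j%d", i), 9000L, 1000L, L, 2L)))),
    dplyr::bind_rows(lapply(1:10, function(i)
      seg_row(sprintf("w%d", i), 4500L, 1000L, L))),
    dplyr::bind_rows(lapply(1:10, function(i)
      seg_row(sprintf("v%d", i), 8500L, 1000L, L))))
  gaps <- tibble::tibble(read_id = sprintf("j%d", 1:10),
                         start = 5000L, end = 9000L, size = 4000L)
  aln <- manual_aln(segs, gaps, L)
  call <- tibble::tibble(start = 5000L, end = 9000L)
  # J = 10, W = (10 + 10) / 2 = 10
  expect_equal(heteroplasmy_spanning_reads(aln, call), 0.5)
  # no junction reads
  aln_w <- manual_aln(segs[segs$read_id %in% sprintf("w%d", 1:10), ],
                      gaps[0, ], L)
  expect_equal(heteroplasmy_spanning_reads(aln_w, call), 0)
  # no informative reads at all -> NA, never 0
  far <- manual_aln(seg_row("x", 100L, 500L, L), gaps[0, ], L)
  expect_true(is.na(heteroplasmy_spanning_reads(far, call)))
  # a flank requirement beyond every segment length leaves no informative
  # read on either side: undefined, not zero
  expect_true(is.na(heteroplasmy_spanning_reads(aln, call, min_flank = 1001)))
})

test_that("downsampling hits the target depth and conserves coverage", {
  ref <- random_reference(16569, seed = 3001)
  idx <- mt_index(ref)
  pop <- molecule_population(ref)
  sim <- simulate_run(pop, "transposase", target_depth = 60,
                      errors = perfect_reads(), seed = 3002)
  aln <- align_reads(sim$reads, idx)
  cur <- sum(aln$reads$aligned_bases) / aln$L
  ds <- downsample_alignments(aln, 20, seed = 7)
  got <- sum(ds$reads$aligned_bases) / ds$L
  expect_lte(got, 20)
  expect_gt(got, 16)   # no overshoot removal
  # retained read count tracks the depth ratio
  expect_lt(abs(nrow(ds$reads) / nrow(aln$reads) - 20 / cur), 0.05)
  # coverage conservation: profile total equals summed aligned bases
  expect_equal(sum(coverage_profile(ds)$depth), sum(ds$segments$ref_len))
  # identity-ish when target equals current; error above it
  same <- downsample_alignments(aln, cur, seed = 8)
  expect_gte(nrow(same$reads), nrow(aln$reads) - 1)
  expect_error(downsample_alignments(aln, cur + 10), "exceeds")
  # determinism under the seed
  ds2 <- downsample_alignments(aln, 20, seed = 7)
  expect_identical(sort(ds$reads$read_id), sort(ds2$reads$read_id))
})

test_that("mtDNA/nuclear read ratio matches published table arithmetic", {
  expect_equal(mtdna_ratio(2184, 176790 - 2184), 2184 / 174606)
  expect_equal(round(mtdna_ratio(2184, 174606), 5), 0.01251)
  expect_equal(mtdna_ratio(10, 10), 1)
  expect_error(mtdna_ratio(10, 0), "denominator")
})

test_that("nuclear background reads stay unmapped at the expected rate", {
  ref <- random_reference(16569, seed = 3101)
  idx <- mt_index(ref)
  pop <- molecule_population(ref)
  sim <- simulate_run(pop, "transposase", target_depth = 8,
                      errors = perfect_reads(), nuclear_fraction = 0.5,
                      seed = 3102)
  aln <- align_reads(sim$reads, idx)
  tr <- sim$truth
  merged <- dplyr::left_join(aln$reads, tr, by = "read_id")
  expect_true(all(!merged$mapped[merged$is_nuclear]))
  expect_true(all(merged$mapped[!merged$is_nuclear]))
  ratio <- sum(!merged$is_nuclear) / sum(merged$is_nuclear)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("the protocol recommendation follows the decision workflow", {
  L <- 16569L
  no_calls <- tibble::tibble(start = integer(0), end = integer(0),
                             size = integer(0), support = integer(0))
  one <- tibble::tibble(start = 8482L, end = 13446L, size = 4964L,
                        support = 16L)
  contained <- tibble::tibble(start = 7634L, end = 13956L, size = 6322L,
                              support = 52L)
  two <- dplyr::bind_rows(one, tibble::tibble(start = 2000L, end = 3000L,
                                              size = 1000L, support = 5L))
  expect_equal(as.character(
    recommend_next_step(no_calls, 14262L, "endonuclease", L)),
    "done_negative")
  expect_equal(as.character(
    recommend_next_step(no_calls, integer(0), "transposase", L)),
    "done_negative")
  # site at 14,262 lies outside (8,482, 13,446)
  expect_equal(as.character(
    recommend_next_step(one, 14262L, "endonuclease", L)),
    "done_single_deletion")
  # constructed site 13,000 inside (7,634, 13,956)
  expect_equal(as.character(
    recommend_next_step(contained, 13000L, "endonuclease", L)),
    "redigest_pvuii")
  expect_equal(as.character(
    recommend_next_step(two, 14262L, "endonuclease", L)),
    "use_rapid_kit")
  # transposase mode always terminates
  expect_true(as.character(
    recommend_next_step(two, integer(0), "transposase", L)) %in%
      c("done_negative", "done_single_deletion"))
})

test_that("bedGraph output is 0-based half-open and run-length compressed", {
  L <- 200L
  aln <- manual_aln(seg_row("r1", 51L, 50L, L), tibble::tibble(), L)
  cov <- coverage_profile(aln)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, "chrM", bg)
  tab <- read.table(bg, sep = "\t")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$V2, c(0, 50, 100))
  expect_equal(tab$V3, c(50, 100, 200))
  expect_equal(tab$V4, c(0, 1, 0))
})

test_that("both estimators track the true fraction across the h range", {
  ref <- random_reference(16569, seed = 3201)
  idx <- mt_index(ref)
  err_c <- err_s <- numeric(0)
  for (h in c(0.1, 0.3, 0.7, 0.9)) {
    pop <- molecule_population(
      ref, list(tibble::tibble(start = 7634, end = 13956)), h)
    sim <- simulate_run(pop, "transposase", target_depth = 150,
                        errors = perfect_reads(),
                        seed = 3300 + round(100 * h))
    aln <- align_reads(sim$reads, idx)
    call <- tibble::tibble(start = 7634L, end = 13956L)
    hc <- heteroplasmy_coverage_ratio(coverage_profile(aln), call)
    hs <- heteroplasmy_spanning_reads(aln, call)
    # multi-kb reads autocorrelate coverage, so a single run at 150x has
    # ~2.5pp SD; bound each run loosely and the sweep by its mean error
    expect_lt(abs(hc - h), 0.10)
    expect_lt(abs(hs - h), 0.10)
    err_c <- c(err_c, abs(hc - h))
    err_s <- c(err_s, abs(hs - h))
  }
  expect_lte(mean(err_c), 0.05)
  expect_lte(mean(err_s), 0.05)
})
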