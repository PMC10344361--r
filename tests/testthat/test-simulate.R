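test_that("realize_molecule excises deleted intervals circularly", {
  ref10 <- circular_reference("ACGTTGCAAT")
  expect_equal(realize_molecule(ref10)$seq, "ACGTTGCAAT")
  # deletion (3,6) removes bases 3..5
  m <- realize_molecule(ref10, tibble::tibble(start = 3, end = 6))
  expect_equal(m$seq, "ACGCAAT")
  expect_equal(m$length, 7)
  expect_equal(m$map, c(1:2, 6:10))
  # wrapping deletion (9,2) removes 9,10,1
  mw <- realize_molecule(ref10, tibble::tibble(start = 9, end = 2))
  expect_equal(mw$seq, "CGTTGCA")
  expect_equal(mw$map, 2:8)
  expect_error(
    realize_molecule(ref10, tibble::tibble(start = c(3, 4), end = c(6, 8))),
    "overlapping")
  # del1-scale arithmetic
  set.seed(3)
  big <- circular_reference(mk_seq(16569))
  expect_equal(realize_molecule(big, tibble::tibble(start = 7634,
                                                    end = 13956))$length,
               16569 - 6322)
})

test_that("molecule_population validates fractions and deletions", {
  expect_error(molecule_population(small_ref,
                                   list(tibble::tibble(start = 1, end = 1)),
                                   0.5),
               "at least one base")
  expect_error(molecule_population(small_ref,
                                   list(tibble::tibble(start = 10, end = 50)),
                                   1.2),
               "fraction")
  pop <- molecule_population(small_ref,
                             list(tibble::tibble(start = 10, end = 50)), 0.3)
  expect_equal(pop$species$fraction, c(0.7, 0.3))
  expect_equal(pop$species$deletions[[2]]$size, 40L)
})

test_that("endonuclease fragmentation follows cut sites and p_uncut", {
  ref <- make_site_ref(2000, 700, seed = 11)
  mol <- realize_molecule(ref)
  set.seed(1)
  fr <- fragment_endonuclease(mol, mt_enzyme("BamHI"), breakage_rate = 0)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$length, 2000L)
  expect_equal(fr$start, 701L)  # fragment starts at the cut coordinate

  # deletion removes the site: invisible unless p_uncut
  del <- realize_molecule(ref, tibble::tibble(start = 600, end = 900))
  set.seed(2)
  expect_equal(nrow(fragment_endonuclease(del, mt_enzyme("BamHI"),
                                          p_uncut = 0, breakage_rate = 0)), 0L)
  set.seed(3)
  fu <- fragment_endonuclease(del, mt_enzyme("BamHI"), p_uncut = 1,
                              breakage_rate = 0)
  expect_equal(fu$length, del$length)
  # random breaks conserve bases
  set.seed(4)
  fb <- fragment_endonuclease(mol, mt_enzyme("BamHI"), breakage_rate = 5e-3)
  expect_equal(sum(fb$length), 2000L)
})

test_that("transposase fragmentation partitions the circle", {
  mol <- realize_molecule(small_ref)
  set.seed(21)
  for (i in 1:10) {
    fr <- fragment_transposase(mol, frag_mean = 400)
    expect_equal(sum(fr$length), mol$length)   # base conservation
    expect_true(all(fr$length >= 1))
  }
  # degenerate law: mean far above the molecule length gives one fragment
  set.seed(22)
  fr1 <- fragment_transposase(mol, frag_mean = 1e6, frag_sdlog = 0.01)
  expect_equal(nrow(fr1), 1L)
  expect_equal(fr1$length, mol$length)
})

test_that("the fragment-length law is tuned to its target mean", {
  set.seed(31)
  sdlog <- 0.55
  meanlog <- log(4403) - sdlog^2 / 2
  draws <- rlnorm(10000, meanlog, sdlog)
  expect_lt(abs(mean(draws) - 4403) / 4403, 0.10)
})

test_that("error model obeys limiting cases and binomial expectation", {
  set.seed(41)
  frag <- mk_seq(400)
  clean <- apply_error_model(frag, perfect_reads())
  corrected <- if (clean$strand == "-") cpp_revcomp(clean$seq) else clean$seq
  expect_equal(corrected, frag)

  # substitution-only at rate 1: every base differs
  sub_all <- apply_error_model(frag, error_model(0.499999, 0, 0),
                               flip_strand = FALSE)
  expect_equal(nchar(sub_all$seq), 400L)
  subbed <- mitolong:::cpp_apply_errors(frag, 1, 0, 0, 1, 4)
  expect_equal(sum(strsplit(subbed, "")[[1]] == strsplit(frag, "")[[1]]), 0L)

  # edit distance of a 10 kb fragment at (0.02, 0.02, 0.02) is ~600 +- 3 sd
  set.seed(42)
  big <- mk_seq(10000)
  set.seed(43)
  noisy <- mitolong:::cpp_apply_errors(big, 0.02, 0.02, 0.02, 1, 4)
  d <- as.integer(utils::adist(big, noisy))
  sd3 <- 3 * sqrt(10000 * 0.06 * 0.94)
  expect_lt(abs(d - 600), sd3)
})

test_that("homopolymer deletion boost shortens runs preferentially", {
  set.seed(51)
  frag <- paste0(strrep("AC", 200), strrep("A", 40), strrep("GT", 200))
  dels_plain <- dels_hp <- 0
  for (i in 1:50) {
    out <- mitolong:::cpp_apply_errors(frag, 0, 0, 0.05, 4, 4)
    dels_hp <- dels_hp + (nchar(frag) - nchar(out))
    out2 <- mitolong:::cpp_apply_errors(frag, 0, 0, 0.05, 1, 4)
    dels_plain <- dels_plain + (nchar(frag) - nchar(out2))
  }
  expect_gt(dels_hp, dels_plain)
})

test_that("simulate_run is seed-deterministic and truthful", {
  pop <- molecule_population(small_ref)
  s1 <- simulate_run(pop, "transposase", target_depth = 10, frag_mean = 400,
                     errors = perfect_reads(), seed = 61)
  s2 <- simulate_run(pop, "transposase", target_depth = 10, frag_mean = 400,
                     errors = perfect_reads(), seed = 61)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  # error-free wild-type reads are exact substrings of the doubled reference
  doubled <- paste0(small_ref$sequence, small_ref$sequence)
  for (i in seq_len(nrow(s1$reads))) {
    sq <- s1$reads$seq[i]
    if (s1$truth$strand[i] == "-") sq <- cpp_revcomp(sq)
    expect_true(grepl(sq, doubled, fixed = TRUE))
  }
  # FASTQ read-back preserves ids and sequences
  rb <- read_fastq(f1)
  expect_equal(rb$read_id, s1$reads$read_id)
  expect_equal(rb$seq, s1$reads$seq)
})

test_that("mixtures emit junction reads near the configured fraction", {
  pop <- molecule_population(
    small_ref, list(tibble::tibble(start = 500, end = 1300)), 0.5)
  sim <- simulate_run(pop, "transposase", target_depth = 40, frag_mean = 500,
                      errors = perfect_reads(), seed = 71)
  tr <- sim$truth
  expect_gt(sum(tr$junctions != ""), 0)
  expect_true(all(tr$junctions[tr$junctions != ""] == "500-1300"))
  frac_del <- mean(tr$species == "del_species1")
  # deleted molecules are shorter so they yield fewer reads per draw;
  # compare molecule draws via emitted bases instead
  bases <- tapply(nchar(sim$reads$seq), tr$species, sum)
  draws_del <- bases[["del_species1"]] / 1200
  draws_wt <- bases[["wildtype"]] / 2000
  expect_lt(abs(draws_del / (draws_del + draws_wt) - 0.5), 0.12)
  expect_true(frac_del > 0.2)
})

test_that("nuclear background reads are flagged and roughly proportioned", {
  pop <- molecule_population(small_ref)
  sim <- simulate_run(pop, "transposase", target_depth = 30, frag_mean = 400,
                      errors = perfect_reads(), nuclear_fraction = 0.5,
                      seed = 81)
  tr <- sim$truth
  expect_true(any(tr$is_nuclear))
  expect_true(all(is.na(tr$ref_start[tr$is_nuclear])))
  expect_lt(abs(mean(tr$is_nuclear) - 0.5), 0.15)
})

test_that("site-in-deletion bias suppresses deleted-molecule reads", {
  ref <- make_site_ref(2000, 800, seed = 91)   # site inside (500, 1300)
  pop <- molecule_population(
    ref, list(tibble::tibble(start = 500, end = 1300)), 0.5)
  sim <- simulate_run(pop, "endonuclease", target_depth = 30,
                      enzyme = mt_enzyme("BamHI"), p_uncut = 0.1,
                      breakage_rate = 0, errors = perfect_reads(), seed = 92)
  share_del <- mean(sim$truth$species == "del_species1")
  expect_lt(share_del, 0.5)   # strictly below the configured fraction
  expect_lt(share_del, 0.25)  # and strongly so at p_uncut = 0.1
})
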