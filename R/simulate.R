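#' Nanopore-like error model
#'
#' Per-base independent substitution / insertion / deletion probabilities.
#' The defaults (2% substitutions, 1.5% insertions, 2.5% deletions, about 6%
#' total, indel-dominated) sit at the upper end of the 4-6% error rate
#' reported for R9.4.1 nanopore reads. Deletion probability is multiplied by
#' `homopolymer_multiplier` inside homopolymer runs of at least
#' `homopolymer_min` bases, emulating the characteristic homopolymer
#' shortening of nanopore basecalls. FASTQ output carries the constant
#' quality character `quality_char` (default `-`, i.e. Q12).
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in `[0, 0.5)`.
#' @param homopolymer_multiplier Factor applied to `del_rate` inside runs.
#' @param homopolymer_min Minimum run length counted as a homopolymer.
#' @param quality_char Single FASTQ quality character.
#' @return An `error_model` object.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.025,
                        homopolymer_multiplier = 2, homopolymer_min = 4,
                        quality_char = "-") {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 0.5)) stop("error rates must be in [0, 0.5)")
  stopifnot(nchar(quality_char) == 1, homopolymer_multiplier >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 homopolymer_multiplier = homopolymer_multiplier,
                 homopolymer_min = as.integer(homopolymer_min),
                 quality_char = quality_char),
            class = "error_model")
}

#' Error-free model (convenience for breakpoint-recovery experiments)
#' @return An `error_model` with all rates zero.
#' @export
perfect_reads <- function() {
  error_model(0, 0, 0, homopolymer_multiplier = 0)
}

#' Heteroplasmic molecule population
#'
#' A mixture of circular mtDNA species: the wild type plus one or more
#' deleted species, each with a molecule fraction. Fractions must be positive
#' and sum to 1. `deletions` is a list (one element per non-wild-type
#' species) of tibbles/data frames with columns `start`, `end`
#' (deleted bases `start..end-1`; intervals may wrap the origin and must not
#' overlap within a species).
#'
#' @param ref A `circular_ref`.
#' @param deletions List of deletion tables, one per deleted species. An
#'   empty list gives a pure wild-type population.
#' @param fractions Molecule fractions of the *deleted* species, same length
#'   as `deletions`; the wild type receives the remainder.
#' @return A `molecule_population` object.
#' @export
molecule_population <- function(ref, deletions = list(), fractions = numeric(0)) {
  stopifnot(inherits(ref, "circular_ref"),
            length(deletions) == length(fractions))
  if (length(fractions) && (any(fractions <= 0) || sum(fractions) > 1 + 1e-9))
    stop("deleted-species fractions must be > 0 and sum to <= 1")
  deletions <- lapply(deletions, function(d) {
    d <- tibble::as_tibble(d)
    stopifnot(all(c("start", "end") %in% names(d)))
    sz <- circular_gap(d$start, d$end, ref$length)
    if (any(sz < 1)) stop("deletion must remove at least one base")
    d$size <- sz
    d
  })
  species <- tibble::tibble(
    species = c("wildtype", paste0("del_species", seq_along(deletions))),
    fraction = c(max(0, 1 - sum(fractions)), fractions),
    deletions = c(list(tibble::tibble(start = integer(0), end = integer(0),
                                      size = integer(0))), deletions)
  )
  species <- species[species$fraction > 0, ]
  structure(list(ref = ref, species = species), class = "molecule_population")
}

#' @exportS3Method base::print
print.molecule_population <- function(x, ...) {
  cat("<molecule_population> on", x$ref$name, paste0("(", x$ref$length, " bp):\n"))
  for (i in seq_len(nrow(x$species))) {
    d <- x$species$deletions[[i]]
    cat(sprintf("  %-14s %5.1f%%  %s\n", x$species$species[i],
                100 * x$species$fraction[i],
                if (nrow(d) == 0) "intact" else
                  paste(sprintf("del(%d,%d)=%dbp", d$start, d$end, d$size),
                        collapse = ", ")))
  }
  invisible(x)
}

#' Realize a circular molecule carrying deletions
#'
#' Excises each deleted interval from the circle. Returns the molecule
#' sequence together with the map from molecule position to reference
#' position, used by the simulator to emit ground truth.
#'
#' @param ref A `circular_ref`.
#' @param deletions Tibble with columns `start`, `end`; non-overlapping,
#'   possibly origin-wrapping.
#' @return List with `seq` (character), `map` (integer vector; `map[i]` is
#'   the reference position of molecule base `i`), `length`.
#' @export
realize_molecule <- function(ref, deletions = NULL) {
  L <- ref$length
  keep <- rep(TRUE, L)
  if (!is.null(deletions) && nrow(deletions) > 0) {
    for (i in seq_len(nrow(deletions))) {
      s <- deletions$start[i]; e <- deletions$end[i]
      sz <- circular_gap(s, e, L)
      pos <- (s - 1 + seq_len(sz) - 1) %% L + 1
      if (any(!keep[pos])) stop("overlapping deletions within one species")
      keep[pos] <- FALSE
    }
  }
  map <- which(keep)
  if (length(map) == 0) stop("deletions remove the whole molecule")
  chars <- strsplit(ref$sequence, "")[[1]]
  list(seq = paste(chars[map], collapse = ""), map = map,
       length = length(map))
}

#' Fragment a circular molecule at endonuclease cut sites
#'
#' Ligation-chemistry fragmentation: the circle is cut at every restriction
#' site found on the realized molecule. A molecule with no site (the site was
#' removed by a deletion) yields a fragment only with probability `p_uncut`,
#' linearized at a uniform random position -- uncut circles are essentially
#' invisible to adapter ligation, which is the source of the heteroplasmy
#' underestimation when the cut site falls inside the deletion. Every
#' fragment then suffers independent random breaks at `breakage_rate` per
#' internal position.
#'
#' @param molecule A realized molecule (list from [realize_molecule()]), or a
#'   plain circular DNA string.
#' @param enzyme A `restriction_enzyme`.
#' @param p_uncut Probability an uncut circle is nevertheless sequenced.
#' @param breakage_rate Per-base random nick probability.
#' @return Tibble of linear fragments with columns `start` (1-based position
#'   on the molecule), `length`.
#' @export
fragment_endonuclease <- function(molecule, enzyme, p_uncut = 0.1,
                                  breakage_rate = 1e-4) {
  seq <- if (is.list(molecule)) molecule$seq else molecule
  ml <- nchar(seq)
  cuts <- cut_positions(seq, enzyme)
  if (length(cuts) == 0) {
    if (runif(1) >= p_uncut)
      return(tibble::tibble(start = integer(0), length = integer(0)))
    cuts <- sample.int(ml, 1)
  }
  n <- length(cuts)
  lens <- if (n == 1) ml else
    as.integer((c(cuts[-1], cuts[1]) - cuts) %% ml)
  lens[lens == 0] <- ml
  frags <- tibble::tibble(start = as.integer(cuts), length = lens)
  apply_random_breaks(frags, ml, breakage_rate)
}

apply_random_breaks <- function(frags, mol_len, breakage_rate) {
  if (breakage_rate <= 0 || nrow(frags) == 0) return(frags)
  out_start <- integer(0); out_len <- integer(0)
  for (i in seq_len(nrow(frags))) {
    len <- frags$length[i]
    nb <- if (len > 1) rbinom(1, len - 1, breakage_rate) else 0L
    if (nb == 0) {
      out_start <- c(out_start, frags$start[i]); out_len <- c(out_len, len)
      next
    }
    brk <- sort(sample.int(len - 1, nb))  # break after these offsets
    pieces <- diff(c(0L, brk, len))
    starts <- frags$start[i] + c(0L, cumsum(pieces[-length(pieces)]))
    starts <- (starts - 1) %% mol_len + 1
    out_start <- c(out_start, starts); out_len <- c(out_len, pieces)
  }
  tibble::tibble(start = as.integer(out_start), length = as.integer(out_len))
}

#' Fragment a circular molecule by random transposase tagmentation
#'
#' Rapid-chemistry fragmentation: the circle is opened at a uniform random
#' phase and partitioned into consecutive fragments with lengths drawn from a
#' log-normal law (the last fragment is truncated), so every base belongs to
#' exactly one fragment.
#'
#' @inheritParams fragment_endonuclease
#' @param frag_mean Mean fragment length in bases (default 4,403 bp, the
#'   average mtDNA read length observed with the rapid kit).
#' @param frag_sdlog Log-scale standard deviation of the log-normal law.
#' @return Tibble of fragments with columns `start`, `length`.
#' @export
fragment_transposase <- function(molecule, frag_mean = 4403,
                                 frag_sdlog = 0.55) {
  ml <- if (is.list(molecule)) molecule$length else nchar(molecule)
  meanlog <- log(frag_mean) - frag_sdlog^2 / 2
  phase <- sample.int(ml, 1)
  lens <- integer(0); tot <- 0L
  while (tot < ml) {
    draw <- max(1L, as.integer(round(rlnorm(1, meanlog, frag_sdlog))))
    lens <- c(lens, draw); tot <- tot + draw
  }
  lens[length(lens)] <- lens[length(lens)] - (tot - ml)
  lens <- lens[lens > 0]
  starts <- (phase - 1 + c(0L, cumsum(lens[-length(lens)]))) %% ml + 1
  tibble::tibble(start = as.integer(starts), length = as.integer(lens))
}

#' Apply the error model to a fragment
#'
#' Chooses a strand uniformly (reverse complement with probability 0.5), then
#' mutates each base independently per the model.
#'
#' @param fragment DNA string.
#' @param model An [error_model()].
#' @param flip_strand If `FALSE`, always keep the forward strand.
#' @return List with `seq` (the read) and `strand` (`"+"`/`"-"`).
#' @export
apply_error_model <- function(fragment, model = error_model(),
                              flip_strand = TRUE) {
  if (nchar(fragment) == 0) stop("fragment is empty")
  strand <- if (flip_strand && runif(1) < 0.5) "-" else "+"
  mut <- cpp_apply_errors(fragment, model$sub_rate, model$ins_rate,
                          model$del_rate, model$homopolymer_multiplier,
                          model$homopolymer_min)
  if (strand == "-") mut <- cpp_revcomp(mut)
  list(seq = mut, strand = strand)
}

#' Simulate a nanopore-like sequencing run
#'
#' Emulates sequencing a library prepared from a large molecule population:
#' each read is drawn by (1) sampling a source molecule -- species chosen
#' with probability proportional to molecule fraction times molecule length,
#' as a uniformly sampled library fragment would be -- (2) fragmenting that
#' molecule under the selected chemistry, and (3) sequencing one uniformly
#' chosen fragment through the error model with a random strand. Reads
#' accumulate until the emitted mtDNA bases reach `target_depth * L`.
#' Because every read is an independent draw from the population, the
#' realized molecule mixture concentrates tightly around the configured
#' fractions, as in a real run where the sampled molecules are a tiny
#' subset of the library. Optionally a fraction of reads comes from an
#' i.i.d.-random nuclear background. Ground truth (source species, fragment
#' coordinates on the reference, deletion junctions spanned) is returned
#' per read.
#'
#' @param population A [molecule_population()].
#' @param mode `"transposase"` (rapid kit, random fragmentation) or
#'   `"endonuclease"` (ligation kit, restriction-site linearization).
#' @param target_depth Target mean fold-coverage of the reference.
#' @param enzyme Linearization enzyme (endonuclease mode).
#' @param p_uncut Probability an uncut circle is sequenced anyway
#'   (endonuclease mode; not a measured constant -- see the methods
#'   vignette).
#' @param breakage_rate Random nick probability per base (endonuclease mode);
#'   the default 1e-4 gives mean mtDNA read lengths near the 6.2 kb observed
#'   with the ligation kit.
#' @param frag_mean,frag_sdlog Transposase fragment-length law (log-normal).
#' @param errors An [error_model()].
#' @param nuclear_fraction Fraction of reads drawn from random background
#'   sequence (flagged `is_nuclear` in the truth table).
#' @param min_read_length Fragments shorter than this are not emitted.
#' @param seed Optional RNG seed (integer); when given, the run is
#'   byte-reproducible.
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `species`, `ref_start`, `ref_end`, `strand`,
#'   `junctions`, `is_nuclear`).
#' @export
simulate_run <- function(population, mode = c("transposase", "endonuclease"),
                         target_depth = 100,
                         enzyme = mt_enzyme("BamHI"), p_uncut = 0.1,
                         breakage_rate = 1e-4, frag_mean = 4403,
                         frag_sdlog = 0.55, errors = error_model(),
                         nuclear_fraction = 0, min_read_length = 100,
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(population, "molecule_population"))
  if (target_depth <= 0) stop("target_depth must be > 0")
  if (nuclear_fraction < 0 || nuclear_fraction >= 1)
    stop("nuclear_fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  ref <- population$ref
  L <- ref$length
  sp <- population$species
  mols <- lapply(sp$deletions, function(d) realize_molecule(ref, d))
  mol_len <- vapply(mols, function(m) m$length, integer(1))
  # a uniformly sampled library fragment comes from species s with
  # probability proportional to fraction_s * length_s
  draw_prob <- sp$fraction * mol_len

  target_bases <- target_depth * L
  emitted <- 0
  rows <- list()
  reads_seq <- character(0); reads_id <- character(0)
  idx <- 0L

  meanlog <- log(frag_mean) - frag_sdlog^2 / 2

  while (emitted < target_bases) {
    if (nuclear_fraction > 0 && runif(1) < nuclear_fraction) {
      len <- max(min_read_length,
                 as.integer(round(rlnorm(1, meanlog, frag_sdlog))))
      nuc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      er <- apply_error_model(nuc, errors)
      idx <- idx + 1L
      rid <- sprintf("read%06d", idx)
      reads_id <- c(reads_id, rid); reads_seq <- c(reads_seq, er$seq)
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = rid, species = "nuclear", ref_start = NA_integer_,
        ref_end = NA_integer_, strand = er$strand, junctions = "",
        is_nuclear = TRUE)
      next
    }
    s <- sample.int(nrow(sp), 1, prob = draw_prob)
    mol <- mols[[s]]
    frags <- switch(mode,
      transposase = fragment_transposase(mol, frag_mean, frag_sdlog),
      endonuclease = fragment_endonuclease(mol, enzyme, p_uncut, breakage_rate)
    )
    if (nrow(frags) == 0) next      # uncut circle was not sequenced
    i <- sample.int(nrow(frags), 1)
    len <- frags$length[i]
    if (len < min_read_length) next
    st <- frags$start[i]
    mol2 <- paste0(mol$seq, mol$seq)
    frag_seq <- substr(mol2, st, st + len - 1)
    mpos <- (st - 1 + seq_len(len) - 1) %% mol$length + 1
    rpos <- mol$map[mpos]
    jump <- which((diff(rpos) - 1) %% L != 0)
    junc <- if (length(jump) == 0) "" else
      paste(sprintf("%d-%d", (rpos[jump]) %% L + 1, rpos[jump + 1]),
            collapse = ";")
    er <- apply_error_model(frag_seq, errors)
    idx <- idx + 1L
    rid <- sprintf("read%06d", idx)
    reads_id <- c(reads_id, rid); reads_seq <- c(reads_seq, er$seq)
    rows[[length(rows) + 1]] <- tibble::tibble(
      read_id = rid, species = sp$species[s],
      ref_start = rpos[1], ref_end = rpos[len], strand = er$strand,
      junctions = junc, is_nuclear = FALSE)
    emitted <- emitted + nchar(er$seq)
  }

  reads <- tibble::tibble(
    read_id = reads_id, seq = reads_seq,
    qual = vapply(nchar(reads_seq),
                  function(n) strrep(errors$quality_char, n), character(1))
  )
  list(reads = reads, truth = dplyr::bind_rows(rows))
}

#' Write reads as 4-line FASTQ
#' @param reads Tibble with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#' @param path FASTQ path.
#' @return Tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(ss)),
                 seq = unname(as.character(ss)))
}

#' Write the simulation truth table as TSV
#' @param truth Truth tibble from [simulate_run()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a random circular reference
#'
#' I.i.d.-uniform bases; useful as a synthetic stand-in for the mitochondrial
#' genome in seeded experiments (the default length matches the rCRS).
#'
#' @param L Length in bases.
#' @param name Sequence name.
#' @param seed Optional RNG seed.
#' @return A `circular_ref`.
#' @export
random_reference <- function(L = 16569, name = "chrM", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  circular_reference(
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    name = name
  )
}
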