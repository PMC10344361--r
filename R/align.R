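#' Build a k-mer anchor index over the doubled circular reference
#'
#' The reference is concatenated with itself so alignments may cross the
#' origin; k-mers occurring more than `max_occ` times are masked. Defaults
#' (k = 15, max_occ = 20) suit a ~16.6 kb reference and ~5% error reads.
#'
#' @param ref A `circular_ref`.
#' @param k Anchor k-mer length (8..31).
#' @param max_occ Maximum occurrences before a k-mer is masked.
#' @return An `mt_index` object.
#' @export
mt_index <- function(ref, k = 15, max_occ = 20) {
  stopifnot(inherits(ref, "circular_ref"))
  if (k < 8 || k > 31) stop("k must be in [8, 31]")
  ptr <- cpp_build_index(ref$sequence, as.integer(k), as.integer(max_occ))
  structure(list(ptr = ptr, ref = ref, k = as.integer(k),
                 max_occ = as.integer(max_occ)),
            class = "mt_index")
}

#' @exportS3Method base::print
print.mt_index <- function(x, ...) {
  cat("<mt_index> ", x$ref$name, ": L=", x$ref$length, ", k=", x$k,
      ", max_occ=", x$max_occ, "\n", sep = "")
  invisible(x)
}

#' Look up a k-mer in the index
#' @param index An `mt_index`.
#' @param kmer A k-mer string of the index's k.
#' @return 1-based start offsets on the doubled reference (in `[1, L]`).
#' @export
lookup_kmer <- function(index, kmer) {
  cpp_lookup_kmer(index$ptr, toupper(kmer))
}

#' Default alignment parameters
#'
#' @param gap_scale Chain penalty scale: a reference gap of `g` bases between
#'   consecutive anchors costs `gap_scale * log2(1 + g)`, keeping multi-kb
#'   deletions cheap while preserving co-linearity.
#' @param max_ref_gap Largest reference gap allowed inside a chain.
#' @param refine_window Half-window (bases) searched around a candidate
#'   junction during base-level breakpoint refinement.
#' @param min_cov_frac Minimum fraction of the read covered by the chain for
#'   the read to count as mapped.
#' @param min_gap Anchor-gap excess (ref minus read advance) above which a
#'   junction is opened for refinement; smaller excesses are treated as
#'   ordinary indels.
#' @param pred_window Number of predecessor anchors examined in the chaining
#'   dynamic programme.
#' @param max_anchors Anchors retained per read (denser sets are subsampled
#'   uniformly).
#' @return Named list of parameters.
#' @export
align_params <- function(gap_scale = 1, max_ref_gap = NULL,
                         refine_window = 200, min_cov_frac = 0.4,
                         min_gap = 30, pred_window = 160, max_anchors = 2000) {
  list(gap_scale = gap_scale, max_ref_gap = max_ref_gap,
       refine_window = refine_window, min_cov_frac = min_cov_frac,
       min_gap = min_gap, pred_window = pred_window,
       max_anchors = max_anchors)
}

#' Align long reads to a circular reference
#'
#' Circular-aware split-read alignment: exact k-mer anchors on the doubled
#' reference, a gap-tolerant chaining dynamic programme (large reference gaps
#' cost only logarithmically, so deletion-spanning reads chain through their
#' junction), and banded edit-distance refinement that places each breakpoint
#' at the leftmost position minimizing total edit distance. Both strands are
#' tried; the better-scoring orientation is reported.
#'
#' @param reads Tibble with columns `read_id`, `seq` (as from
#'   [simulate_run()] or [read_fastq()]).
#' @param index An [mt_index()].
#' @param params An [align_params()] list.
#' @return An `mt_alignments` object: list with
#'   \describe{
#'     \item{reads}{per-read tibble: `read_id`, `read_length`, `mapped`,
#'       `strand`, `score`, `n_segments`, `aligned_bases`, `edit_distance`}
#'     \item{segments}{per-segment tibble: `read_id`, `strand`, `segment`,
#'       `read_start`, `read_end`, `ref_start` (1..L), `ref_len` (unwrapped
#'       span), `ref_end` (1..L; < `ref_start` when the segment wraps the
#'       origin), `edit_distance`}
#'     \item{gaps}{per-junction tibble: `read_id`, `start`, `end`, `size`
#'       (deleted interval in the package convention)}
#'     \item{L}{reference length}
#'   }
#' @export
align_reads <- function(reads, index, params = align_params()) {
  stopifnot(inherits(index, "mt_index"))
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  L <- index$ref$length
  max_ref_gap <- if (is.null(params$max_ref_gap)) L - 1L else params$max_ref_gap

  n <- nrow(reads)
  short <- nchar(reads$seq) < index$k
  if (any(short))
    warning(sum(short), " read(s) shorter than k=", index$k, " left unmapped")

  seg_rows <- vector("list", n)
  read_rows <- vector("list", n)
  gap_rows <- vector("list", n)

  for (i in seq_len(n)) {
    rid <- reads$read_id[i]
    sq <- reads$seq[i]
    res <- cpp_align_read(index$ptr, sq, params$gap_scale,
                          as.integer(max_ref_gap),
                          as.integer(params$pred_window),
                          as.integer(params$refine_window),
                          as.integer(params$min_gap),
                          params$min_cov_frac,
                          as.integer(params$max_anchors))
    segs <- res$segments
    ns <- nrow(segs)
    if (!res$mapped || ns == 0) {
      read_rows[[i]] <- tibble::tibble(
        read_id = rid, read_length = nchar(sq), mapped = FALSE,
        strand = res$strand, score = res$score, n_segments = 0L,
        aligned_bases = 0L, edit_distance = NA_integer_)
      next
    }
    rs0 <- segs[, 3] - 1L            # 0-based on doubled reference
    re0 <- segs[, 4] - 1L
    ref_start <- rs0 %% L + 1L
    ref_len <- re0 - rs0 + 1L
    ref_end <- re0 %% L + 1L
    seg_rows[[i]] <- tibble::tibble(
      read_id = rid, strand = res$strand, segment = seq_len(ns),
      read_start = segs[, 1], read_end = segs[, 2],
      ref_start = ref_start, ref_len = ref_len, ref_end = ref_end,
      edit_distance = segs[, 5])
    if (ns > 1) {
      gs <- (re0[-ns] + 1L) %% L + 1L   # first deleted base
      ge <- rs0[-1] %% L + 1L           # first base of the right segment
      gap_rows[[i]] <- tibble::tibble(
        read_id = rid, start = gs, end = ge,
        size = circular_gap(gs, ge, L))
    }
    read_rows[[i]] <- tibble::tibble(
      read_id = rid, read_length = nchar(sq), mapped = TRUE,
      strand = res$strand, score = res$score, n_segments = ns,
      aligned_bases = sum(segs[, 2] - segs[, 1] + 1L),
      edit_distance = sum(segs[, 5]))
  }

  segments <- dplyr::bind_rows(seg_rows)
  if (nrow(segments) == 0)
    segments <- tibble::tibble(
      read_id = character(0), strand = character(0), segment = integer(0),
      read_start = integer(0), read_end = integer(0),
      ref_start = integer(0), ref_len = integer(0), ref_end = integer(0),
      edit_distance = integer(0))
  gaps <- dplyr::bind_rows(gap_rows)
  if (nrow(gaps) == 0)
    gaps <- tibble::tibble(read_id = character(0), start = integer(0),
                           end = integer(0), size = integer(0))
  structure(
    list(reads = dplyr::bind_rows(read_rows),
         segments = segments, gaps = gaps,
         L = L, ref_name = index$ref$name),
    class = "mt_alignments")
}

#' @exportS3Method base::print
print.mt_alignments <- function(x, ...) {
  cat("<mt_alignments> ", nrow(x$reads), " reads (",
      sum(x$reads$mapped), " mapped), ",
      nrow(x$gaps), " deletion-sized reference gaps\n", sep = "")
  invisible(x)
}

#' @describeIn align_reads Per-segment tibble of an alignment set.
#' @param x An `mt_alignments` object.
#' @param ... Unused.
#' @export
tidy.mt_alignments <- function(x, ...) x$segments

#' @describeIn align_reads One-row summary of an alignment set.
#' @export
glance.mt_alignments <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$reads),
    n_mapped = sum(x$reads$mapped),
    mapped_frac = mean(x$reads$mapped),
    n_gaps = nrow(x$gaps),
    mean_depth = sum(x$reads$aligned_bases[x$reads$mapped]) / x$L
  )
}

#' Write alignments as a SAM file
#'
#' Minimal single-reference SAM: one line per mapped read, CIGAR with `N`
#' operations for intra-read reference gaps and soft clips at unaligned read
#' ends; `NM` carries the summed segment edit distance. Segments are written
#' on the unwrapped (doubled-reference) coordinates truncated into `[1, L]`
#' via the POS of the first segment.
#'
#' @param aln An `mt_alignments`.
#' @param reads The read tibble that produced `aln` (for sequences).
#' @param path Output path.
#' @export
write_sam <- function(aln, reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", aln$ref_name, "\tLN:", aln$L)), con)
  seqs <- setNames(reads$seq, reads$read_id)
  mapped <- aln$reads[aln$reads$mapped, ]
  for (i in seq_len(nrow(mapped))) {
    rid <- mapped$read_id[i]
    segs <- aln$segments[aln$segments$read_id == rid, ]
    sq <- seqs[[rid]]
    if (mapped$strand[i] == "-") sq <- cpp_revcomp(sq)
    cig <- character(0)
    if (segs$read_start[1] > 1) cig <- paste0(segs$read_start[1] - 1, "S")
    for (j in seq_len(nrow(segs))) {
      cig <- c(cig, paste0(segs$read_end[j] - segs$read_start[j] + 1, "M"))
      if (j < nrow(segs)) {
        gap <- circular_gap(segs$ref_end[j], segs$ref_start[j + 1], aln$L) - 1L
        cig <- c(cig, paste0(gap, "N"))
      }
    }
    tailclip <- mapped$read_length[i] - segs$read_end[nrow(segs)]
    if (tailclip > 0) cig <- c(cig, paste0(tailclip, "S"))
    flag <- if (mapped$strand[i] == "-") 16L else 0L
    writeLines(paste(rid, flag, aln$ref_name, segs$ref_start[1], 60,
                     paste(cig, collapse = ""), "*", 0, 0, sq, "*",
                     paste0("NM:i:", mapped$edit_distance[i]),
                     sep = "\t"), con)
  }
  invisible(path)
}
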