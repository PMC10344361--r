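#' Per-base coverage profile
#'
#' Each aligned segment increments depth over its reference span (modulo L);
#' intra-read reference gaps contribute nothing, which is exactly why a
#' heteroplasmic deletion appears as a proportional coverage drop.
#'
#' @param aln An `mt_alignments`.
#' @return An `mt_coverage` tibble with columns `pos`, `depth` and attributes
#'   `L`, `n_reads`, `mean_depth`.
#' @export
coverage_profile <- function(aln) {
  stopifnot(inherits(aln, "mt_alignments"))
  L <- aln$L
  d <- numeric(L + 1)
  segs <- aln$segments
  if (nrow(segs) > 0) {
    for (i in seq_len(nrow(segs))) {
      s <- segs$ref_start[i]
      len <- segs$ref_len[i]
      e <- s + len - 1L
      if (e <= L) {
        d[s] <- d[s] + 1; d[e + 1] <- d[e + 1] - 1
      } else {                      # wraps the origin
        d[s] <- d[s] + 1; d[L + 1] <- d[L + 1] - 1
        e2 <- e - L
        d[1] <- d[1] + 1; d[e2 + 1] <- d[e2 + 1] - 1
      }
    }
  }
  depth <- cumsum(d[seq_len(L)])
  out <- tibble::tibble(pos = seq_len(L), depth = depth)
  attr(out, "L") <- L
  attr(out, "n_reads") <- sum(aln$reads$mapped)
  attr(out, "mean_depth") <- mean(depth)
  class(out) <- c("mt_coverage", class(out))
  out
}

circ_positions <- function(from, len, L) {
  if (len <= 0) return(integer(0))
  (from - 1 + seq_len(len) - 1) %% L + 1
}

#' Coverage-ratio heteroplasmy estimator
#'
#' Deletion heteroplasmy as one minus the ratio of mean depth inside the
#' deleted interval to mean depth over wild-type regions: the fraction of
#' molecules missing the interval. The inside mean is trimmed by `margin`
#' bases at both breakpoints; the outside mean excludes `margin` around the
#' breakpoints, `site_margin` around any linearization cut site (those show
#' a read-start coverage spike), and any `excluded_regions`.
#'
#' @param coverage An `mt_coverage` from [coverage_profile()].
#' @param call One-row call (needs `start`, `end`); list or tibble row.
#' @param margin Bases trimmed around each breakpoint.
#' @param site_positions Optional linearization cut coordinates.
#' @param site_margin Bases excluded around each cut coordinate.
#' @param excluded_regions Optional tibble `start`, `end` (inclusive) of
#'   further regions to exclude from the outside mean.
#' @return Estimated heteroplasmy in `[0, 1]`.
#' @export
heteroplasmy_coverage_ratio <- function(coverage, call, margin = 100,
                                        site_positions = NULL,
                                        site_margin = 300,
                                        excluded_regions = NULL) {
  L <- attr(coverage, "L")
  depth <- coverage$depth
  st <- call$start[[1]]; en <- call$end[[1]]
  size <- circular_gap(st, en, L)
  inside_len <- size - 2L * margin
  if (inside_len <= 0)
    stop("deleted interval empty after trimming margins")
  inside <- circ_positions((st + margin - 1) %% L + 1, inside_len, L)

  deleted <- circ_positions(st, size, L)
  excl <- logical(L)
  excl[deleted] <- TRUE
  excl[circ_positions((st - margin - 1) %% L + 1, margin, L)] <- TRUE
  excl[circ_positions(en, margin, L)] <- TRUE
  if (!is.null(site_positions)) {
    for (sp in site_positions)
      excl[circ_positions((sp - site_margin - 1) %% L + 1,
                          2L * site_margin + 1L, L)] <- TRUE
  }
  if (!is.null(excluded_regions) && nrow(excluded_regions) > 0) {
    for (i in seq_len(nrow(excluded_regions))) {
      s <- excluded_regions$start[i]; e <- excluded_regions$end[i]
      excl[circ_positions(s, circular_gap(s, e, L) + 1L, L)] <- TRUE
    }
  }
  outside <- which(!excl)
  if (length(outside) == 0) stop("no wild-type region left after exclusions")
  out_mean <- mean(depth[outside])
  if (out_mean <= 0) stop("outside mean depth is zero")
  h <- 1 - mean(depth[inside]) / out_mean
  min(1, max(0, h))
}

#' Junction-read heteroplasmy estimator
#'
#' `h = J / (J + W)` where `J` counts reads whose reference gap matches the
#' call within `tol` with at least `min_flank` aligned bases on both sides of
#' the junction, and `W` is the wild-type evidence from reads aligned
#' contiguously across a breakpoint with `min_flank` bases on both sides.
#' Since a deleted molecule exposes one junction while an intact molecule
#' exposes two breakpoints, `W` averages the two per-breakpoint crossing
#' counts; using their sum would halve the estimate.
#'
#' @param aln An `mt_alignments`.
#' @param call One-row call (`start`, `end`).
#' @param min_flank Minimum aligned bases flanking the junction/breakpoint.
#' @param tol Breakpoint matching tolerance (bases, circular).
#' @return Heteroplasmy in `[0, 1]`, or `NA` when no informative read exists
#'   (never reported as 0).
#' @export
heteroplasmy_spanning_reads <- function(aln, call, min_flank = 100, tol = 50) {
  stopifnot(min_flank >= 1)
  L <- aln$L
  st <- call$start[[1]]; en <- call$end[[1]]

  J <- 0L
  g <- aln$gaps
  if (nrow(g) > 0) {
    segs <- aln$segments
    for (i in seq_len(nrow(g))) {
      if (circular_dist(g$start[i], st, L) > tol ||
          circular_dist(g$end[i], en, L) > tol) next
      ss <- segs[segs$read_id == g$read_id[i], ]
      ss <- ss[order(ss$segment), ]
      left_len <- 0L; right_len <- 0L
      if (nrow(ss) >= 2) {
        for (j in seq_len(nrow(ss) - 1)) {
          gs <- (ss$ref_start[j] - 1L + ss$ref_len[j]) %% L + 1L  # first deleted base
          ge <- ss$ref_start[j + 1]
          if (circular_dist(gs, g$start[i], L) <= tol &&
              circular_dist(ge, g$end[i], L) <= tol) {
            left_len <- ss$ref_len[j]; right_len <- ss$ref_len[j + 1]
          }
        }
      }
      if (left_len >= min_flank && right_len >= min_flank) J <- J + 1L
    }
  }

  W <- 0
  segs <- aln$segments
  if (nrow(segs) > 0) {
    covers <- function(seg_start, seg_len, bp) {
      off <- circular_gap(seg_start, bp, L)
      off >= min_flank & (seg_len - off) >= min_flank
    }
    w1 <- length(unique(segs$read_id[covers(segs$ref_start, segs$ref_len, st)]))
    w2 <- length(unique(segs$read_id[covers(segs$ref_start, segs$ref_len, en)]))
    W <- (w1 + w2) / 2
  }
  if (J + W == 0) return(NA_real_)
  J / (J + W)
}

#' Randomly downsample an alignment set to a target mean depth
#'
#' Uniform read subsampling without replacement: reads are kept in random
#' order until the mean depth would exceed the target.
#'
#' @param aln An `mt_alignments`.
#' @param target_mean_depth Target mean fold-coverage (must not exceed the
#'   current mean depth).
#' @param seed Optional RNG seed for reproducibility.
#' @return A filtered `mt_alignments`.
#' @export
downsample_alignments <- function(aln, target_mean_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cur <- sum(aln$reads$aligned_bases[aln$reads$mapped]) / aln$L
  if (target_mean_depth > cur)
    stop("target depth ", target_mean_depth,
         " exceeds current mean depth ", round(cur, 1))
  mapped <- aln$reads[aln$reads$mapped, ]
  ord <- sample.int(nrow(mapped))
  csum <- cumsum(mapped$aligned_bases[ord])
  keep_n <- max(1L, sum(csum / aln$L <= target_mean_depth))
  keep_ids <- mapped$read_id[ord[seq_len(keep_n)]]
  structure(
    list(reads = aln$reads[aln$reads$read_id %in% keep_ids, ],
         segments = aln$segments[aln$segments$read_id %in% keep_ids, ],
         gaps = aln$gaps[aln$gaps$read_id %in% keep_ids, ],
         L = aln$L, ref_name = aln$ref_name),
    class = "mt_alignments")
}

#' mtDNA / nuclear read-count ratio
#'
#' Relative mtDNA content from whole-DNA sequencing: reads mapped to the
#' mitochondrial reference over reads that are unmapped or nuclear.
#'
#' @param n_mapped_mt Reads mapped to mtDNA.
#' @param n_unmapped_or_nuclear All other reads (> 0).
#' @return The ratio.
#' @export
mtdna_ratio <- function(n_mapped_mt, n_unmapped_or_nuclear) {
  if (n_unmapped_or_nuclear <= 0) stop("denominator must be > 0")
  n_mapped_mt / n_unmapped_or_nuclear
}

#' Protocol recommendation after a sequencing run
#'
#' The decision workflow for mtDNA structural-variant screening: a negative
#' sample or a clean single deletion ends the analysis; a single deletion
#' containing the linearization cut site (endonuclease mode) should be
#' re-sequenced after PvuII digestion; multiple deletions under endonuclease
#' linearization call for the transposase (rapid-kit) protocol. Transposase
#' runs always terminate.
#'
#' @param calls Call tibble.
#' @param enzyme_sites Cut coordinates used for linearization (endonuclease
#'   mode).
#' @param mode `"endonuclease"` or `"transposase"`.
#' @param L Reference length.
#' @return One of `"done_negative"`, `"done_single_deletion"`,
#'   `"redigest_pvuii"`, `"use_rapid_kit"`, with attribute `rule` describing
#'   the decision path.
#' @export
recommend_next_step <- function(calls, enzyme_sites, mode, L) {
  mode <- match.arg(mode, c("endonuclease", "transposase"))
  res <- function(x, rule) structure(x, rule = rule)
  if (nrow(calls) == 0)
    return(res("done_negative", "no deletion call"))
  site_inside <- function(st, en) {
    sz <- circular_gap(st, en, L)
    any(vapply(enzyme_sites,
               function(sp) circular_gap(st, sp, L) < sz, logical(1)))
  }
  if (nrow(calls) == 1) {
    if (mode == "endonuclease" && length(enzyme_sites) > 0 &&
        site_inside(calls$start[1], calls$end[1]))
      return(res("redigest_pvuii",
                 "single deletion containing the linearization site"))
    return(res("done_single_deletion", "single deletion, site outside"))
  }
  if (mode == "endonuclease")
    return(res("use_rapid_kit", ">= 2 deletions under endonuclease mode"))
  res("done_single_deletion",
      "multiple deletions resolved under transposase mode")
}

#' Write a coverage profile as bedGraph
#' @param coverage An `mt_coverage`.
#' @param ref_name Contig name.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, ref_name, path) {
  r <- rle(coverage$depth)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, head(ends, -1))
  df <- data.frame(chrom = ref_name, start = starts0, end = ends,
                   depth = r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
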