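#' Pileup base counts over the reference
#'
#' Realigns every segment with a banded traceback and counts matched or
#' substituted read bases per reference position. Read insertions and
#' deletions are excluded, as are positions inside per-read reference gaps,
#' so base counts always sum to the pileup depth.
#'
#' @param aln An `mt_alignments`.
#' @param reads The read tibble that produced `aln` (sequences are needed to
#'   replay the base-level alignment).
#' @param ref The `circular_ref` used for alignment.
#' @return An `mt_pileup` object: list with `counts` (4 x L integer matrix,
#'   rows A/C/G/T), `depth` (integer vector), `ref`.
#' @export
pileup_counts <- function(aln, reads, ref) {
  stopifnot(inherits(aln, "mt_alignments"), inherits(ref, "circular_ref"))
  L <- ref$length
  ref2 <- paste0(ref$sequence, ref$sequence)
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  seqs <- setNames(reads$seq, reads$read_id)
  mapped <- aln$reads[aln$reads$mapped, ]
  for (i in seq_len(nrow(mapped))) {
    rid <- mapped$read_id[i]
    ss <- aln$segments[aln$segments$read_id == rid, ]
    sq <- seqs[[rid]]
    if (is.null(sq)) next
    if (mapped$strand[i] == "-") sq <- cpp_revcomp(sq)
    segm <- cbind(ss$read_start, ss$read_end,
                  ss$ref_start, ss$ref_start + ss$ref_len - 1L)
    cpp_pileup_add(counts, ref2, sq, segm, L)
  }
  structure(list(counts = counts, depth = as.integer(colSums(counts)),
                 ref = ref),
            class = "mt_pileup")
}

#' @exportS3Method base::print
print.mt_pileup <- function(x, ...) {
  cat("<mt_pileup> ", x$ref$name, ": mean depth ",
      round(mean(x$depth), 1), "\n", sep = "")
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial interval for site heteroplasmy
#'
#' Vectorised two-sided exact interval for the alternate-allele fraction.
#' The interval is asymmetric at the boundaries: with zero alternate reads
#' the lower bound is 0 while the upper bound is `1 - (alpha/2)^(1/depth)`.
#'
#' @param alt_count Alternate-read counts.
#' @param depth Total depths (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Tibble with columns `h`, `lower`, `upper`.
#' @export
site_heteroplasmy_ci <- function(alt_count, depth, level = 0.95) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(alt_count < 0 | alt_count > depth))
    stop("alt_count must be in [0, depth]")
  a <- 1 - level
  lower <- ifelse(alt_count == 0, 0,
                  qbeta(a / 2, alt_count, depth - alt_count + 1))
  upper <- ifelse(alt_count == depth, 1,
                  qbeta(1 - a / 2, alt_count + 1, depth - alt_count))
  tibble::tibble(h = alt_count / depth, lower = lower, upper = upper)
}

#' Call point variants from a pileup
#'
#' Naive frequency-threshold calling: a position is reported when its depth
#' is at least `min_depth` and the most frequent non-reference base reaches
#' fraction `min_h`. The default 5% floor reflects the detection limit
#' imposed by the raw nanopore error rate; the confidence interval is
#' attached but never used to drop a call.
#'
#' @param pileup An `mt_pileup`.
#' @param min_h Minimum alternate fraction.
#' @param min_depth Minimum depth.
#' @param level CI level.
#' @return Tibble: `pos`, `ref`, `alt`, `alt_count`, `depth`, `h`, `lower`,
#'   `upper`.
#' @export
call_point_variants <- function(pileup, min_h = 0.05, min_depth = 10,
                                level = 0.95) {
  stopifnot(min_h >= 0, min_depth >= 0)
  ref_chars <- strsplit(pileup$ref$sequence, "")[[1]]
  bases <- rownames(pileup$counts)
  depth <- pileup$depth
  ref_idx <- match(ref_chars, bases)          # NA for N positions
  cn <- pileup$counts
  alt_counts <- cn
  ok <- !is.na(ref_idx)
  alt_counts[cbind(ref_idx[ok], which(ok))] <- 0L
  top_alt <- apply(alt_counts, 2, which.max)
  top_cnt <- alt_counts[cbind(top_alt, seq_along(top_alt))]
  h <- ifelse(depth > 0, top_cnt / depth, 0)
  sel <- which(depth >= min_depth & h >= min_h & ok)
  if (length(sel) == 0)
    return(tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), alt_count = integer(0),
                          depth = integer(0), h = numeric(0),
                          lower = numeric(0), upper = numeric(0)))
  ci <- site_heteroplasmy_ci(top_cnt[sel], depth[sel], level)
  tibble::tibble(pos = sel, ref = ref_chars[sel], alt = bases[top_alt[sel]],
                 alt_count = as.integer(top_cnt[sel]),
                 depth = as.integer(depth[sel]),
                 h = ci$h, lower = ci$lower, upper = ci$upper)
}

#' Sequencing error floor from control pileups
#'
#' Computes the upper bound of the exact confidence interval of the
#' alternate-read fraction at every covered position and returns its mean
#' and standard deviation -- the per-site detection floor of the run. Only
#' covered positions enter the average.
#'
#' @param pileup An `mt_pileup`.
#' @param level CI level.
#' @return One-row tibble: `mean_upper`, `sd_upper`, `n_positions`.
#' @export
error_rate_summary <- function(pileup, level = 0.95) {
  depth <- pileup$depth
  covered <- which(depth >= 1)
  if (length(covered) == 0) stop("no covered positions")
  ref_chars <- strsplit(pileup$ref$sequence, "")[[1]]
  bases <- rownames(pileup$counts)
  ref_idx <- match(ref_chars, bases)
  refcnt <- ifelse(is.na(ref_idx), 0L,
                   pileup$counts[cbind(pmax(ref_idx, 1L), seq_along(depth))])
  alt <- depth - refcnt
  ci <- site_heteroplasmy_ci(alt[covered], depth[covered], level)
  tibble::tibble(mean_upper = mean(ci$upper), sd_upper = sd(ci$upper),
                 n_positions = length(covered))
}

#' Write point variants as VCF 4.2
#' @param variants Tibble from [call_point_variants()].
#' @param ref A `circular_ref`.
#' @param path Output path.
#' @export
write_point_vcf <- function(variants, ref, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitolong",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate fraction\">",
    "##INFO=<ID=CILO,Number=1,Type=Float,Description=\"Exact CI lower bound\">",
    "##INFO=<ID=CIHI,Number=1,Type=Float,Description=\"Exact CI upper bound\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- if (nrow(variants) == 0) character(0) else
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;CILO=%.4f;CIHI=%.4f;DP=%d",
            ref$name, variants$pos, variants$ref, variants$alt, variants$h,
            variants$lower, variants$upper, variants$depth)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
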