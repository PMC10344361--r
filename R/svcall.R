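#' Extract deletion signals from split-read alignments
#'
#' One signal per intra-read reference gap of at least `min_del_size` bases;
#' smaller gaps are treated as nanopore indel noise. Only reads spanning a
#' breakpoint junction contribute.
#'
#' @param aln An `mt_alignments` from [align_reads()].
#' @param min_del_size Minimum deleted-interval size in bases.
#' @return Tibble with columns `read_id`, `start`, `end`, `size`.
#' @export
extract_del_signals <- function(aln, min_del_size = 100) {
  stopifnot(inherits(aln, "mt_alignments"))
  g <- aln$gaps
  if (nrow(g) == 0)
    return(tibble::tibble(read_id = character(0), start = integer(0),
                          end = integer(0), size = integer(0)))
  mapped_ids <- aln$reads$read_id[aln$reads$mapped]
  dplyr::filter(g, .data$size >= min_del_size,
                .data$read_id %in% mapped_ids)
}

#' Cluster deletion signals into calls
#'
#' Single-linkage clustering: two signals link iff both breakpoints agree
#' within `tol` bases (circular distances). Consensus breakpoints are the
#' per-cluster medians (leftmost median on ties); clusters with fewer than
#' `min_support` members are discarded, matching the minimum-support filter
#' of split-read SV callers (support >= 2 by default).
#'
#' @param signals Signal tibble from [extract_del_signals()].
#' @param L Reference length.
#' @param tol Breakpoint tolerance in bases.
#' @param min_support Minimum supporting reads per call.
#' @return Tibble of calls: `start`, `end`, `size`, `support`,
#'   `member_reads` (list-column), sorted by `start`.
#' @export
cluster_signals <- function(signals, L, tol = 50, min_support = 2) {
  stopifnot(tol >= 0)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          size = integer(0), support = integer(0),
                          member_reads = list())
  n <- nrow(signals)
  if (n == 0) return(empty)

  ord <- order(signals$start, signals$end)
  s <- signals[ord, ]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  link <- function(i, j) {
    if (circular_dist(s$start[i], s$start[j], L) <= tol &&
        circular_dist(s$end[i], s$end[j], L) <= tol) union2(i, j)
  }
  for (i in seq_len(n - 1)) {
    j <- i + 1
    while (j <= n && s$start[j] - s$start[i] <= tol) { link(i, j); j <- j + 1 }
  }
  # starts close across the origin
  lo <- which(s$start <= tol + 1)
  hi <- which(s$start >= L - tol)
  for (i in lo) for (j in hi) if (i != j) link(i, j)

  comp <- as.integer(vapply(seq_len(n), find, numeric(1)))
  groups <- split(seq_len(n), comp)

  rows <- lapply(groups, function(ix) {
    st <- s$start[ix]; en <- s$end[ix]
    wrap_s <- max(st) - min(st) > L / 2
    wrap_e <- max(en) - min(en) > L / 2
    st2 <- if (wrap_s) (st + floor(L / 2) - 1) %% L + 1 else st
    en2 <- if (wrap_e) (en + floor(L / 2) - 1) %% L + 1 else en
    ms <- sort(st2)[floor((length(st2) + 1) / 2)]
    me <- sort(en2)[floor((length(en2) + 1) / 2)]
    if (wrap_s) ms <- (ms - floor(L / 2) - 1) %% L + 1
    if (wrap_e) me <- (me - floor(L / 2) - 1) %% L + 1
    tibble::tibble(start = as.integer(ms), end = as.integer(me),
                   size = circular_gap(ms, me, L),
                   support = length(ix),
                   member_reads = list(s$read_id[ix]))
  })
  calls <- dplyr::bind_rows(rows)
  calls <- calls[calls$support >= min_support, , drop = FALSE]
  if (nrow(calls) == 0) return(empty)
  dplyr::arrange(calls, .data$start)
}

#' Write deletion calls as VCF 4.2
#'
#' One `<DEL>` record per call with `SVTYPE=DEL`, `END`, negative `SVLEN` and
#' `SUPPORT`. `POS`/`END` follow the SV-VCF convention of anchoring on the
#' base *before* the deleted interval, so `POS = start - 1` and
#' `END = end - 1` for a call deleting `start..end-1`. Calls wrapping the
#' origin (start > end) are split into two records sharing an ID suffix,
#' since linear VCF cannot express a circular record; this is documented in
#' the header.
#'
#' @param calls Call tibble from [cluster_signals()].
#' @param ref A `circular_ref`.
#' @param path Output path.
#' @export
write_deletion_vcf <- function(calls, ref, path) {
  L <- ref$length
  if (nrow(calls) > 0 &&
      (any(calls$start < 1 | calls$start > L | calls$end < 1 | calls$end > L)))
    stop("call coordinates outside [1, L]")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitolong",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, L),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End anchor base of the deletion\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Negative deletion size\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##mitolong_note=deletions wrapping the circular origin are split into two records sharing an ID suffix _wrapA/_wrapB",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- character(0)
  mkrec <- function(id, pos, endpos, size, support) {
    refbase <- substr(ref$sequence, pos, pos)
    sprintf("%s\t%d\t%s\t%s\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d;SUPPORT=%d",
            ref$name, pos, id, refbase, endpos, size, support)
  }
  if (nrow(calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      st <- calls$start[i]; en <- calls$end[i]
      sz <- calls$size[i]; su <- calls$support[i]
      id <- sprintf("DEL%03d", i)
      if (st <= en) {
        recs <- c(recs, mkrec(id, max(1L, st - 1L), en - 1L, sz, su))
      } else {
        # wraps the origin: split at L / 1
        recs <- c(recs,
                  mkrec(paste0(id, "_wrapA"), st - 1, L, L - st + 1, su),
                  mkrec(paste0(id, "_wrapB"), 1, en - 1, en - 1, su))
      }
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read deletion calls from a VCF file
#'
#' Accepts `SVTYPE=DEL` records (including those from external SV callers);
#' other record types are ignored. Split origin-wrapping pairs written by
#' [write_deletion_vcf()] are re-joined.
#'
#' @param path VCF path.
#' @return Call tibble with `start`, `end`, `size`, `support`.
#' @export
read_deletion_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          size = integer(0), support = integer(0))
  if (nrow(v@fix) == 0) return(empty)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  svtype <- vapply(fix$INFO, function(x)
    sub(".*SVTYPE=([^;]+).*", "\\1", x), character(1), USE.NAMES = FALSE)
  keep <- svtype == "DEL"
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) return(empty)
  pos <- as.integer(fix$POS)
  endp <- as.integer(sub(".*;?END=([0-9]+).*", "\\1", fix$INFO))
  svlen <- abs(as.integer(sub(".*SVLEN=(-?[0-9]+).*", "\\1", fix$INFO)))
  supp <- ifelse(grepl("SUPPORT=", fix$INFO),
                 as.integer(sub(".*SUPPORT=([0-9]+).*", "\\1", fix$INFO)),
                 NA_integer_)
  id <- fix$ID
  out <- tibble::tibble(id = id, start = pos + 1L, end = endp + 1L,
                        size = svlen, support = supp)
  # rejoin wrapped pairs
  wa <- grepl("_wrapA$", out$id)
  wb <- grepl("_wrapB$", out$id)
  if (any(wa) && any(wb)) {
    base_a <- sub("_wrapA$", "", out$id[wa])
    base_b <- sub("_wrapB$", "", out$id[wb])
    joined <- lapply(intersect(base_a, base_b), function(b) {
      ra <- out[out$id == paste0(b, "_wrapA"), ]
      rb <- out[out$id == paste0(b, "_wrapB"), ]
      tibble::tibble(id = b, start = ra$start, end = rb$end,
                     size = ra$size + rb$size, support = ra$support)
    })
    out <- dplyr::bind_rows(out[!(wa | wb), , drop = FALSE],
                            dplyr::bind_rows(joined))
  }
  dplyr::arrange(out[, c("start", "end", "size", "support")], .data$start)
}

#' Write calls as a simple TSV
#' @param calls Call tibble.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls[, c("start", "end", "size", "support")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
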