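#' Circular reference genome
#'
#' Construct a circular reference from a DNA sequence. All coordinates in the
#' package are 1-based positions in `[1, L]`; a deletion `(start, end)` removes
#' bases `start..end-1` (left-closed, right-open), so its size is the circular
#' forward distance from `start` to `end`.
#'
#' @param sequence A single DNA string over `A`, `C`, `G`, `T`, `N`
#'   (lower case accepted and upper-cased; `U` is rejected).
#' @param name Sequence name, used in FASTA/VCF/bedGraph output.
#' @param annotations Optional tibble with columns `label`, `start`, `end`
#'   (1-based, inclusive) of genes/origins, used by the circular plot.
#' @return An object of class `circular_ref` with elements `name`, `sequence`,
#'   `length` and `annotations`.
#' @export
circular_reference <- function(sequence, name = "chrM", annotations = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("reference sequence is empty")
  if (grepl("U", sequence, fixed = TRUE))
    stop("RNA letter 'U' not allowed in a DNA reference")
  if (grepl("[^ACGTN]", sequence))
    stop("reference contains letters outside {A,C,G,T,N}")
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("label", "start", "end") %in% names(annotations)))
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         annotations = annotations),
    class = "circular_ref"
  )
}

#' @exportS3Method base::print
print.circular_ref <- function(x, ...) {
  cat("<circular_ref> ", x$name, ": ", x$length, " bp",
      if (!is.null(x$annotations)) paste0(", ", nrow(x$annotations), " annotations"),
      "\n", sep = "")
  invisible(x)
}

#' Read a circular reference from a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one sequence record.
#' @param annotations Optional annotation tibble (see [circular_reference()]).
#' @return A `circular_ref`.
#' @export
read_reference <- function(path, annotations = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) stop("expected single circular sequence, found ", length(ss))
  nm <- sub("\\s.*$", "", names(ss)[1])
  circular_reference(as.character(ss[[1]]), name = nm, annotations = annotations)
}

#' Write a circular reference to FASTA (60-column wrapped)
#'
#' @param ref A `circular_ref`.
#' @param path Output path.
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Read gene/origin annotations from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention at this boundary.
#'
#' @param path Path to a BED file (requires the rtracklayer package).
#' @return Tibble with columns `label`, `start`, `end`.
#' @export
read_annotations_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED annotations requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    label = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("feature", seq_along(gr)),
    start = BiocGenerics::start(gr),  # rtracklayer already converts to 1-based
    end = BiocGenerics::end(gr)
  )
}

#' Circular forward-strand distance
#'
#' Number of bases walked forward from `a` to reach `b` on a circle of
#' length `L`; always in `[0, L)`. For a deletion `(start, end)` this is its
#' size in bp.
#'
#' @param a,b 1-based positions (vectorised).
#' @param L Circle length in bases.
#' @return Integer distances.
#' @export
circular_gap <- function(a, b, L) {
  stopifnot(all(a >= 1 & a <= L), all(b >= 1 & b <= L))
  as.integer((b - a) %% L)
}

#' Minimal circular distance between two positions (either direction)
#' @inheritParams circular_gap
#' @return Integer distances in `[0, L/2]`.
#' @export
circular_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  as.integer(pmin(d, L - d))
}

#' Rotate the coordinate origin of a circular reference
#'
#' Returns the same circle written so that `new_origin` becomes position 1.
#' Annotations are remapped modulo the length.
#'
#' @param ref A `circular_ref`.
#' @param new_origin 1-based position that becomes position 1.
#' @return A `circular_ref`.
#' @export
rotate_origin <- function(ref, new_origin) {
  L <- ref$length
  if (new_origin < 1 || new_origin > L) stop("new_origin out of range [1, L]")
  seq2 <- paste0(ref$sequence, ref$sequence)
  rot <- substr(seq2, new_origin, new_origin + L - 1)
  ann <- ref$annotations
  if (!is.null(ann)) {
    ann$start <- (ann$start - new_origin) %% L + 1
    ann$end <- (ann$end - new_origin) %% L + 1
  }
  circular_reference(rot, name = ref$name, annotations = ann)
}

#' Map positions through an origin rotation
#'
#' Gives the coordinate, on the rotated circle produced by
#' [rotate_origin()]`(ref, new_origin)`, of a position expressed on the
#' original circle.
#'
#' @param pos 1-based positions on the original circle.
#' @param new_origin The origin used in the rotation.
#' @param L Circle length.
#' @return 1-based positions on the rotated circle.
#' @export
rotate_position <- function(pos, new_origin, L) {
  as.integer((pos - new_origin) %% L + 1)
}

#' Restriction enzyme definition
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (top strand, length >= 4).
#' @param cut_offset Bases from the recognition start to the top-strand cut
#'   point (0..recognition length). BamHI (`G^GATCC`) has offset 1; PvuII
#'   (`CAG^CTG`) offset 3.
#' @return A `restriction_enzyme` object.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4) stop("recognition sequence must be >= 4 bases")
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    stop("cut_offset must be within the recognition sequence")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Built-in linearization enzymes
#'
#' The two endonucleases used for mtDNA linearization before ligation-kit
#' sequencing: BamHI (cleavage site at m.14262 on the rCRS) and PvuII
#' (m.2652). Both recognitions are palindromic, so a top-strand scan finds
#' every site.
#'
#' @param name `"BamHI"` or `"PvuII"`.
#' @return A `restriction_enzyme`.
#' @export
mt_enzyme <- function(name = c("BamHI", "PvuII")) {
  name <- match.arg(name)
  switch(name,
    BamHI = restriction_enzyme("BamHI", "GGATCC", 1L),
    PvuII = restriction_enzyme("PvuII", "CAGCTG", 3L)
  )
}

#' Find restriction recognition sites on a circular sequence
#'
#' Scans the top strand of the circle, including matches that wrap the
#' origin; `N` bases never match. Positions are 1-based recognition starts.
#'
#' @param ref A `circular_ref` (or a plain DNA string treated as circular).
#' @param enzyme A `restriction_enzyme`.
#' @return Sorted integer vector of recognition-start positions (possibly
#'   empty).
#' @export
find_restriction_sites <- function(ref, enzyme) {
  seq <- if (inherits(ref, "circular_ref")) ref$sequence else toupper(ref)
  L <- nchar(seq)
  if (nchar(enzyme$recognition) > L) return(integer(0))
  doubled <- Biostrings::DNAString(paste0(seq, seq))
  hits <- Biostrings::start(
    Biostrings::matchPattern(enzyme$recognition, doubled, fixed = TRUE)
  )
  sort(unique(hits[hits <= L]))
}

#' Top-strand cut coordinates of an enzyme on a circular sequence
#'
#' The cut is placed `cut_offset` bases after each recognition start; the
#' returned coordinate is the 1-based position of the first base *after* the
#' cut (i.e. fragments start there).
#'
#' @inheritParams find_restriction_sites
#' @return Sorted integer vector of cut coordinates.
#' @export
cut_positions <- function(ref, enzyme) {
  L <- if (inherits(ref, "circular_ref")) ref$length else nchar(ref)
  sites <- find_restriction_sites(ref, enzyme)
  if (length(sites) == 0) return(integer(0))
  sort(unique(as.integer((sites - 1 + enzyme$cut_offset) %% L + 1)))
}

#' Longest homopolymer run of a circular sequence
#'
#' Scans the doubled sequence so runs wrapping the origin are counted; run
#' length is capped at the circle length.
#'
#' @param ref A `circular_ref`.
#' @return One-row tibble with columns `base`, `start`, `end`, `length`
#'   (first-occurring longest run; `start`/`end` are 1-based inclusive on the
#'   circle).
#' @export
longest_homopolymer <- function(ref) {
  L <- ref$length
  chars <- strsplit(paste0(ref$sequence, ref$sequence), "")[[1]]
  r <- rle(chars)
  len <- pmin(r$lengths, L)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- starts <= L & r$values != "N"
  len <- len[keep]; starts <- starts[keep]; vals <- r$values[keep]
  i <- which.max(len)
  tibble::tibble(
    base = vals[i],
    start = as.integer(starts[i]),
    end = as.integer((starts[i] + len[i] - 2) %% L + 1),
    length = as.integer(len[i])
  )
}
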