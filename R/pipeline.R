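#' Single-deletion presets
#'
#' Breakpoints and orthogonally measured (Southern blot / qPCR) heteroplasmy
#' fractions of the single large deletions used as worked examples throughout
#' the package. One published row (11,570-15,573 with a printed size of
#' 6,997 bp) is arithmetically inconsistent (15,573 - 11,570 = 4,003) and is
#' deliberately not included rather than silently corrected.
#'
#' @return Tibble with columns `preset`, `start`, `end`, `size`, `fraction`.
#' @export
deletion_presets <- function() {
  tibble::tibble(
    preset = c("del1", "del2", "del3", "del4", "del5", "del7", "del8", "del9"),
    start = c(7634L, 8482L, 7343L, 10955L, 8482L, 7829L, 12714L, 6341L),
    end = c(13956L, 13446L, 15602L, 15544L, 13460L, 14826L, 15862L, 14005L),
    size = c(6322L, 4964L, 8259L, 4589L, 4978L, 6997L, 3148L, 7664L),
    fraction = c(0.50, 0.35, 0.40, 0.50, 0.50, 0.50, 0.50, 0.30)
  )
}

#' Build a single-deletion population from a preset
#'
#' @param ref A `circular_ref`.
#' @param preset Preset name (see [deletion_presets()]).
#' @param fraction Optional override of the deleted-molecule fraction.
#' @return A [molecule_population()].
#' @export
preset_population <- function(ref, preset, fraction = NULL) {
  pr <- deletion_presets()
  row <- pr[pr$preset == preset, ]
  if (nrow(row) != 1) stop("unknown preset '", preset, "'")
  if (is.null(fraction)) fraction <- row$fraction
  molecule_population(
    ref,
    deletions = list(tibble::tibble(start = row$start, end = row$end)),
    fractions = fraction)
}

#' Run the full analysis pipeline
#'
#' Orchestrates align -> deletion calling -> coverage -> heteroplasmy ->
#' (optional) point variants -> protocol recommendation, optionally writing
#' all artifacts (alignments TSV, calls VCF/TSV, estimates TSV, bedGraph,
#' circular plot, point-variant VCF, recommendation, run log) to a results
#' directory.
#'
#' For samples with a single deletion call, both the coverage-ratio and the
#' junction-read estimators are reported. With two or more calls only the
#' junction-read estimator is used per call, since overlapping deletions
#' confound the coverage ratio.
#'
#' @param reads Read tibble (`read_id`, `seq`) or path to a FASTQ file.
#' @param ref A `circular_ref`.
#' @param mode `"transposase"` or `"endonuclease"` (drives the
#'   recommendation logic and coverage-spike exclusion).
#' @param enzyme Linearization enzyme used (endonuclease mode).
#' @param outdir Optional output directory; created if missing.
#' @param params [align_params()].
#' @param min_del_size,tol,min_support Deletion-calling parameters.
#' @param margin,site_margin Coverage-ratio exclusion margins.
#' @param min_flank Junction-read flank requirement.
#' @param do_pointvar Run pileup point-variant calling (slower).
#' @param make_plot Render the circular plot (requires `outdir`).
#' @param seed Seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return An `mt_run` object with elements `alignments`, `calls`,
#'   `estimates`, `coverage`, `variants`, `recommendation`, `params`.
#' @export
run_pipeline <- function(reads, ref, mode = c("transposase", "endonuclease"),
                         enzyme = mt_enzyme("BamHI"), outdir = NULL,
                         params = align_params(), min_del_size = 100,
                         tol = 50, min_support = 2, margin = 100,
                         site_margin = 300, min_flank = 100,
                         do_pointvar = FALSE, make_plot = FALSE,
                         seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1) {
    if (!file.exists(reads)) stop("input FASTQ not found: ", reads)
    reads <- read_fastq(reads)
  }
  reads <- tibble::as_tibble(reads)
  L <- ref$length
  t0 <- Sys.time()

  idx <- mt_index(ref)
  aln <- align_reads(reads, idx, params)
  signals <- extract_del_signals(aln, min_del_size)
  calls <- cluster_signals(signals, L, tol, min_support)
  cov <- coverage_profile(aln)
  sites <- if (mode == "endonuclease") cut_positions(ref, enzyme) else integer(0)

  estimates <- if (nrow(calls) == 0) {
    tibble::tibble(start = integer(0), end = integer(0), size = integer(0),
                   support = integer(0), h_coverage = numeric(0),
                   h_spanning = numeric(0), flags = character(0))
  } else {
    dplyr::bind_rows(lapply(seq_len(nrow(calls)), function(i) {
      call <- calls[i, ]
      hs <- heteroplasmy_spanning_reads(aln, call, min_flank, tol)
      hc <- if (nrow(calls) == 1)
        tryCatch(heteroplasmy_coverage_ratio(
          cov, call, margin, site_positions = sites,
          site_margin = site_margin), error = function(e) NA_real_)
      else NA_real_
      flags <- character(0)
      if (length(sites) > 0 &&
          any(circular_gap(call$start, sites, L) < call$size))
        flags <- c(flags, "enzyme_site_in_deletion")
      if (attr(cov, "mean_depth") < 100) flags <- c(flags, "low_coverage")
      tibble::tibble(start = call$start, end = call$end, size = call$size,
                     support = call$support, h_coverage = hc,
                     h_spanning = hs,
                     flags = paste(flags, collapse = ","))
    }))
  }

  rec <- recommend_next_step(calls, sites, mode, L)

  result <- structure(
    list(alignments = aln, calls = calls, estimates = estimates,
         coverage = cov, variants = NULL, recommendation = rec,
         mode = mode, ref = ref,
         params = list(align = params, min_del_size = min_del_size,
                       tol = tol, min_support = min_support, margin = margin,
                       site_margin = site_margin, min_flank = min_flank,
                       seed = seed)),
    class = "mt_run")

  if (do_pointvar) {
    pu <- pileup_counts(aln, reads, ref)
    result$variants <- call_point_variants(pu)
    result$pileup <- pu
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(aln$segments, file.path(outdir, "alignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_deletion_vcf(calls, ref, file.path(outdir, "calls.vcf"))
    write_calls_tsv(calls, file.path(outdir, "calls.tsv"))
    est_out <- estimates
    est_out$h_coverage <- ifelse(is.na(est_out$h_coverage), "NA",
                                 sprintf("%.1f", 100 * est_out$h_coverage))
    est_out$h_spanning <- ifelse(is.na(est_out$h_spanning), "NA",
                                 sprintf("%.1f", 100 * est_out$h_spanning))
    write.table(est_out, file.path(outdir, "estimates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(cov, ref$name, file.path(outdir, "coverage.bedGraph"))
    if (!is.null(result$variants))
      write_point_vcf(result$variants, ref, file.path(outdir, "variants.vcf"))
    writeLines(c(as.character(rec), attr(rec, "rule")),
               file.path(outdir, "recommendation.txt"))
    if (make_plot)
      render_mtdna_circle(cov, calls, ref$annotations,
                          out_path = file.path(outdir, "circle.png"))
    log <- c(
      paste0("mode=", mode),
      paste0("enzyme=", if (mode == "endonuclease") enzyme$name else "none"),
      paste0("seed=", if (is.null(seed)) "NA" else seed),
      paste0("n_reads=", nrow(reads)),
      paste0("n_mapped=", sum(aln$reads$mapped)),
      paste0("mean_depth=", round(attr(cov, "mean_depth"), 2)),
      paste0("n_calls=", nrow(calls)),
      paste0("recommendation=", as.character(rec)),
      paste0("elapsed_s=", round(as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")), 1)))
    writeLines(log, file.path(outdir, "run_log.txt"))
  }
  result
}

#' @exportS3Method base::print
print.mt_run <- function(x, ...) {
  cat("<mt_run> ", sum(x$alignments$reads$mapped), "/",
      nrow(x$alignments$reads), " reads mapped, mean depth ",
      round(attr(x$coverage, "mean_depth"), 1), "x\n", sep = "")
  if (nrow(x$calls) == 0) {
    cat("  no deletion calls\n")
  } else {
    for (i in seq_len(nrow(x$estimates))) {
      e <- x$estimates[i, ]
      cat(sprintf(
        "  deletion (%d, %d) size %d bp, support %d, h_cov %s, h_span %s\n",
        e$start, e$end, e$size, e$support,
        ifelse(is.na(e$h_coverage), "NA", sprintf("%.1f%%", 100 * e$h_coverage)),
        ifelse(is.na(e$h_spanning), "NA", sprintf("%.1f%%", 100 * e$h_spanning))))
    }
  }
  cat("  recommendation: ", as.character(x$recommendation), " (",
      attr(x$recommendation, "rule"), ")\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline Per-call tibble of deletion calls with both
#'   heteroplasmy estimates.
#' @param x An `mt_run`.
#' @param ... Unused.
#' @export
tidy.mt_run <- function(x, ...) x$estimates

#' @describeIn run_pipeline One-row run summary.
#' @export
glance.mt_run <- function(x, ...) {
  tibble::tibble(
    n_reads = nrow(x$alignments$reads),
    n_mapped = sum(x$alignments$reads$mapped),
    mean_depth = attr(x$coverage, "mean_depth"),
    n_calls = nrow(x$calls),
    recommendation = as.character(x$recommendation))
}

#' @describeIn run_pipeline Circular plot of the run.
#' @param object An `mt_run`.
#' @export
autoplot.mt_run <- function(object, ...) {
  plot_mtdna_circle(object$coverage, object$calls,
                    object$ref$annotations)
}
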