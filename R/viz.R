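#' Circos-style circular plot of the mitochondrial genome
#'
#' Outer ring: gene/origin annotations; middle ring: coverage depth; inner
#' chords: one per deletion call, connecting its breakpoints, with line
#' width proportional to supporting-read count (0.5-6 pt). Angles start at
#' 12 o'clock and increase clockwise, matching common mtDNA maps.
#'
#' @param coverage An `mt_coverage` (or `NULL`).
#' @param calls Call tibble (or `NULL`).
#' @param annotations Tibble `label`, `start`, `end` (or `NULL`).
#' @param L Reference length (required when `coverage` is `NULL`).
#' @param max_points Coverage is binned to at most this many arc points.
#' @return A ggplot object.
#' @export
plot_mtdna_circle <- function(coverage = NULL, calls = NULL,
                              annotations = NULL, L = NULL,
                              max_points = 1200) {
  if (is.null(L)) {
    if (is.null(coverage)) stop("supply either coverage or L")
    L <- attr(coverage, "L")
  }
  ang <- function(pos) 2 * pi * (pos - 1) / L
  px <- function(pos, r) r * sin(ang(pos))
  py <- function(pos, r) r * cos(ang(pos))

  r_chord <- 0.62
  r_cov0 <- 0.68
  r_covh <- 0.22
  r_ann <- 0.97

  circle <- tibble::tibble(pos = seq(1, L, length.out = 720))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = tibble::tibble(x = px(circle$pos, r_cov0),
                            y = py(circle$pos, r_cov0)),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "grey60",
      linewidth = 0.3)

  if (!is.null(coverage) && nrow(coverage) > 0) {
    bin <- max(1L, floor(nrow(coverage) / max_points))
    cv <- dplyr::summarise(
      dplyr::group_by(coverage, g = (.data$pos - 1) %/% bin),
      pos = .data$pos[1], depth = mean(.data$depth), .groups = "drop")
    dmax <- max(cv$depth, 1)
    rr <- r_cov0 + r_covh * cv$depth / dmax
    ribbon <- tibble::tibble(
      x = c(px(cv$pos, rr), rev(px(cv$pos, r_cov0))),
      y = c(py(cv$pos, rr), rev(py(cv$pos, r_cov0))))
    p <- p + ggplot2::geom_polygon(
      data = ribbon, ggplot2::aes(x = .data$x, y = .data$y),
      fill = "steelblue", alpha = 0.65) +
      ggplot2::annotate("text", x = 0, y = 0.02,
                        label = sprintf("mean depth %.0fx", mean(coverage$depth)),
                        size = 3.2, colour = "grey30")
  }

  if (!is.null(annotations) && nrow(annotations) > 0) {
    arcs <- dplyr::bind_rows(lapply(seq_len(nrow(annotations)), function(i) {
      s <- annotations$start[i]; e <- annotations$end[i]
      len <- circular_gap(s, e, L) + 1
      pos <- (s - 1 + seq(0, len - 1, length.out = max(2, min(60, len)))) %% L + 1
      tibble::tibble(label = annotations$label[i], pos = pos,
                     x = px(pos, r_ann), y = py(pos, r_ann))
    }))
    p <- p + ggplot2::geom_path(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$label,
                   colour = .data$label),
      linewidth = 2.2, show.legend = FALSE)
  }

  if (!is.null(calls) && nrow(calls) > 0) {
    smax <- max(calls$support, na.rm = TRUE)
    chords <- dplyr::bind_rows(lapply(seq_len(nrow(calls)), function(i) {
      t <- seq(0, 1, length.out = 40)
      x0 <- px(calls$start[i], r_chord); y0 <- py(calls$start[i], r_chord)
      x1 <- px(calls$end[i], r_chord); y1 <- py(calls$end[i], r_chord)
      # quadratic Bezier through the centre-ward control point
      tibble::tibble(
        chord = i,
        x = (1 - t)^2 * x0 + t^2 * x1,
        y = (1 - t)^2 * y0 + t^2 * y1,
        lw = pmin(6, 0.5 + 5.5 * calls$support[i] / smax))
    }))
    p <- p + ggplot2::geom_path(
      data = chords,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$chord,
                   linewidth = .data$lw),
      colour = "black", alpha = 0.8, lineend = "round") +
      ggplot2::scale_linewidth_identity()
  }

  p + ggplot2::coord_fixed() + ggplot2::theme_void()
}

#' Render the circular plot to SVG or PNG
#'
#' The output format is chosen by the file extension; anything else is an
#' error.
#'
#' @inheritParams plot_mtdna_circle
#' @param out_path Output file ending in `.svg` or `.png`.
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_mtdna_circle <- function(coverage = NULL, calls = NULL,
                                annotations = NULL, L = NULL, out_path,
                                width = 6, height = 6) {
  ext <- tolower(sub(".*\\.", "", out_path))
  if (!ext %in% c("svg", "png"))
    stop("unknown output extension '", ext, "' (use .svg or .png)")
  p <- plot_mtdna_circle(coverage, calls, annotations, L)
  if (ext == "png") {
    grDevices::png(out_path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::svg(out_path, width = width, height = height)
  }
  print(p)
  grDevices::dev.off()
  invisible(out_path)
}
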