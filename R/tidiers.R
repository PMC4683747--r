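# broom-style verbs and ggplot2 methods for scan objects.

#' Tidy a linkage scan
#'
#' @param x a `linkage_scan` object.
#' @param ... unused.
#' @return the per-position curve tibble (combined statistics and
#'   information content).
#' @export
tidy.linkage_scan <- function(x, ...) {
  x$curve
}

#' @describeIn tidy.linkage_scan one-row summary with the genome-wide peak.
#' @export
glance.linkage_scan <- function(x, ...) {
  stat <- if (x$model_name == "npl") "z" else "hlod"
  pk <- x$curve[which.max(x$curve[[stat]]), ]
  tibble::tibble(model = x$model_name, asm = x$asm,
                 n_families = x$n_families,
                 statistic = stat, peak = pk[[stat]],
                 peak_chrom = pk$chrom, peak_marker = pk$marker,
                 peak_cm = pk$cm, mean_ic = mean(x$curve$ic))
}

#' Tidy a CNV-weighted scan
#'
#' @param x a `cnv_scan` object.
#' @param ... unused.
#' @return the scored segment tibble with list columns flattened to
#'   comma-separated strings.
#' @export
tidy.cnv_scan <- function(x, ...) {
  flatten_segments(x$segments)
}

#' @describeIn tidy.cnv_scan one-row summary with the top segment.
#' @export
glance.cnv_scan <- function(x, ...) {
  if (nrow(x$segments) == 0) {
    return(tibble::tibble(model = x$model_name, asm = x$asm,
                          n_segments = 0L, n_regions = nrow(x$regions),
                          top_score = NA_real_, top_chrom = NA_character_,
                          top_start_bp = NA_real_, top_end_bp = NA_real_))
  }
  top <- rank_segments(x$segments, 1)
  tibble::tibble(model = x$model_name, asm = x$asm,
                 n_segments = nrow(x$segments), n_regions = nrow(x$regions),
                 top_score = top$score, top_chrom = top$chrom,
                 top_start_bp = top$start_bp, top_end_bp = top$end_bp)
}

#' Plot a linkage scan curve
#'
#' @param object a `linkage_scan` object.
#' @param ... unused.
#' @return a ggplot: combined statistic along the map, one panel per
#'   chromosome.
#' @export
autoplot.linkage_scan <- function(object, ...) {
  stat <- if (object$model_name == "npl") "z" else "hlod"
  lab <- if (stat == "z") "combined NPL Z" else "HLOD"
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$cm, y = .data[[stat]])) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = lab,
                  title = sprintf("Multipoint linkage scan (%s, ASM%s)",
                                  object$model_name, object$asm)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.linkage_scan
#' @param scan a `linkage_scan` object.
#' @export
plot_linkage_curve <- function(scan, ...) autoplot(scan, ...)

#' Plot CNV-weighted segment scores
#'
#' @param object a `cnv_scan` object.
#' @param ... unused.
#' @return a ggplot: segment scores along the genome (Manhattan-style,
#'   one panel per chromosome with segments drawn at their extent).
#' @export
autoplot.cnv_scan <- function(object, ...) {
  seg <- object$segments
  if (nrow(seg) == 0) {
    abort("nothing to plot: no shared CNV segments", class = "cnvlink_data_error")
  }
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_bp / 1e6,
                                       xend = .data$end_bp / 1e6,
                                       y = .data$score, yend = .data$score),
                          linewidth = 2, colour = "#d95f02") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "CNV-weighted linkage score",
                  title = sprintf("CNV-weighted scan (%s, ASM%s)",
                                  object$model_name, object$asm)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cnv_scan
#' @param scan a `cnv_scan` object.
#' @param ... passed on.
#' @export
plot_cnv_segments <- function(scan, ...) autoplot(scan, ...)
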