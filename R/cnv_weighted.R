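# CNV-weighted linkage scores: per-family average linkage score over the
# family's shared-CNV region, summed across the families covering each
# genomic segment.

#' Average family linkage score over a shared-CNV region
#'
#' Arithmetic mean of the family's per-marker linkage score (parametric LOD
#' or non-parametric Z, whichever the curve carries) over the markers whose
#' bp position lies inside the region interval.  A region containing no
#' marker falls back to the mean of the two flanking markers' scores (the
#' fallback is reported as a message).
#'
#' @param family_curve tibble with columns `chrom`, `bp` and `score` for
#'   one family.
#' @param region a one-row shared-region tibble (or any list with `chrom`,
#'   `start_bp`, `end_bp`).
#' @return a one-row tibble with `average` and `n_markers` (0 when the
#'   flanking fallback was used).
#' @export
family_average_score <- function(family_curve, region) {
  sub <- family_curve[family_curve$chrom == region$chrom, ]
  if (nrow(sub) == 0) {
    abort(paste0("chromosome absent from family curve: ", region$chrom),
          class = "cnvlink_lookup_error")
  }
  inside <- sub$bp >= region$start_bp & sub$bp <= region$end_bp
  if (any(inside)) {
    return(tibble::tibble(average = mean(sub$score[inside]),
                          n_markers = sum(inside)))
  }
  inform(paste0("region ", region$chrom, ":", region$start_bp, "-",
                region$end_bp, " contains no marker; using flanking markers"))
  below <- which(sub$bp < region$start_bp)
  above <- which(sub$bp > region$end_bp)
  flank <- c(
    if (length(below)) sub$score[below[which.max(sub$bp[below])]],
    if (length(above)) sub$score[above[which.min(sub$bp[above])]]
  )
  tibble::tibble(average = mean(flank), n_markers = 0L)
}

#' CNV-weighted linkage scores for genomic segments
#'
#' For each segment produced by [segment_genome()], sums the contributing
#' families' average linkage scores over their own shared regions covering
#' the segment.  Scores enter signed (negative NPL Z values are not
#' floored); rounding happens only at presentation time.
#'
#' @param segments segment tibble from [segment_genome()].
#' @param family_curves long tibble with columns `family_id`, `chrom`,
#'   `bp`, `score` (per-family linkage curves computed on per-carrier
#'   masked genotypes).
#' @param regions the shared-region tibble the segments were built from.
#' @return the segment tibble with added `score` column and a
#'   `contributions` list column (one tibble per segment with `family_id`,
#'   `average`, `n_markers`).
#' @export
cnv_weighted_scores <- function(segments, family_curves, regions) {
  if (nrow(segments) == 0) {
    segments$score <- numeric(0)
    segments$contributions <- list()
    return(segments)
  }
  # per-region family averages, computed once
  region_avg <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    fc <- family_curves[family_curves$family_id == regions$family_id[i], ]
    if (nrow(fc) == 0) {
      return(tibble::tibble(region_row = i,
                            family_id = regions$family_id[i],
                            average = NA_real_, n_markers = NA_integer_))
    }
    a <- family_average_score(fc, regions[i, ])
    tibble::tibble(region_row = i, family_id = regions$family_id[i],
                   average = a$average, n_markers = a$n_markers)
  })
  res <- purrr::map_dfr(seq_len(nrow(segments)), function(s) {
    rows <- segments$region_rows[[s]]
    avail <- region_avg[region_avg$region_row %in% rows &
                          !is.na(region_avg$average), ]
    contrib <- if (nrow(avail) == 0) {
      tibble::tibble(family_id = character(), average = numeric(),
                     n_markers = integer())
    } else {
      avail |>
        dplyr::group_by(.data$family_id) |>
        dplyr::summarise(average = mean(.data$average),
                         n_markers = as.integer(max(.data$n_markers)),
                         .groups = "drop")
    }
    tibble::tibble(score = sum(contrib$average),
                   contributions = list(contrib))
  })
  segments$score <- res$score
  segments$contributions <- res$contributions
  segments
}

#' Rank CNV-weighted segments
#'
#' @param track scored segment tibble from [cnv_weighted_scores()].
#' @param top_k number of segments reported (default 25).
#' @return the `top_k` highest-scoring segments, ties broken by genomic
#'   order (chromosome, then start position).
#' @export
rank_segments <- function(track, top_k = 25) {
  track |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chrom, .data$start_bp) |>
    head(top_k)
}

#' Genome-wide CNV-weighted linkage scan
#'
#' The full pipeline behind the CNV-weighted statistic: filter CNV calls by
#' length, detect within-family shared regions, segment the genome by the
#' shared-region breakpoints across families, mask each carrier's genotypes
#' inside its own CNVs, compute per-family linkage curves on the masked
#' data, and sum the per-family average scores over each segment.
#'
#' @inheritParams linkage_scan
#' @param cnv_calls validated CNV call tibble (see [read_cnv_calls()]).
#' @param min_length_bp minimum CNV length (default 10 kb).
#' @param min_carriers minimum carriers per shared region (default 2).
#' @param match_state require shared state (default `FALSE`).
#' @return an object of class `cnv_scan`: list with `segments` (scored
#'   track), `regions`, `model`, `asm` and bookkeeping.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
cnv_weighted_scan <- function(ped, genotypes, map, cnv_calls,
                              model = "dominant", asm = 1,
                              min_length_bp = 10000, min_carriers = 2,
                              match_state = FALSE, freqs = NULL) {
  calls <- filter_cnvs(cnv_calls, min_length_bp)
  regions <- family_shared_regions(calls, min_carriers, match_state)
  segments <- segment_genome(regions)
  if (nrow(segments) == 0) {
    inform("no shared CNV regions anywhere; empty result")
    return(structure(list(segments = segments, regions = regions,
                          model_name = scan_model_name(model), asm = asm,
                          family_curves = NULL),
                     class = "cnv_scan"))
  }
  masked <- mask_genotypes(genotypes, calls, map, mode = "per_carrier")
  scan <- linkage_scan(ped, masked, map, model = model, asm = asm,
                       freqs = freqs,
                       chromosomes = unique(regions$chrom))
  track <- cnv_weighted_scores(segments, scan$family_curves, regions)
  structure(list(segments = track, regions = regions,
                 model_name = scan$model_name, asm = asm,
                 family_curves = scan$family_curves),
            class = "cnv_scan")
}

scan_model_name <- function(model) {
  if (is.character(model)) model else model$name
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat("CNV-weighted linkage scan (", x$model_name, ", ASM", x$asm, ")\n",
      sep = "")
  cat(nrow(x$segments), "segments from", nrow(x$regions),
      "family-shared CNV regions\n")
  if (nrow(x$segments) > 0) {
    top <- rank_segments(x$segments, 1)
    cat("top segment: chr", top$chrom, ":", top$start_bp, "-", top$end_bp,
        " score ", round2(top$score), " (", top$n_families, " families)\n",
        sep = "")
  }
  invisible(x)
}
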