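# CNV call filtering, within-family shared-overlap regions, cross-family
# breakpoint segmentation and genotype masking.  Intervals are 1-based
# closed on the user surface; the segmentation sweep works half-open
# internally.

#' Filter CNV calls by length
#'
#' @param calls validated call tibble (see [read_cnv_calls()]).
#' @param min_length_bp minimum call length retained (default 10 kb).
#' @return the retained calls; retained/dropped counts by state are
#'   reported as a message.
#' @export
filter_cnvs <- function(calls, min_length_bp = 10000) {
  keep <- calls$length_bp >= min_length_bp
  tab <- table(state = calls$state, kept = keep)
  inform(paste0("filter_cnvs: retained ", sum(keep), "/", nrow(calls),
                " calls (",
                paste(sprintf("%s %d/%d", rownames(tab),
                              tab[, colnames(tab) == "TRUE", drop = TRUE],
                              rowSums(tab)),
                      collapse = ", "), ")"))
  calls[keep, , drop = FALSE]
}

#' Within-family shared CNV regions
#'
#' For every family and chromosome, finds the maximal sets of at least
#' `min_carriers` individuals whose CNV calls have a non-empty common
#' intersection ("strict overlap" = genomic intersection, not identical
#' breakpoints) and emits one shared region per set, with the region
#' interval equal to the common intersection.  Calls carried by a single
#' individual emit nothing (de-novo-like events never contribute).  With
#' `match_state = TRUE` deletions and duplications are processed
#' separately; by default they may share a region.
#'
#' @param calls validated (and typically length-filtered) call tibble.
#' @param min_carriers minimum number of distinct carriers (default 2).
#' @param match_state require carriers to share the deletion/duplication
#'   state (default `FALSE`).
#' @return a tibble with columns `family_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_carriers`, `carrier_ids` (list), `states` and
#'   `call_rows` (list of row indices into `calls`).
#' @export
family_shared_regions <- function(calls, min_carriers = 2,
                                  match_state = FALSE) {
  if (min_carriers < 2) abort_config("min_carriers must be at least 2")
  calls$..row <- seq_len(nrow(calls))
  grp <- if (match_state) {
    split(calls, list(calls$family_id, calls$chrom, calls$state), drop = TRUE)
  } else {
    split(calls, list(calls$family_id, calls$chrom), drop = TRUE)
  }
  out <- purrr::map_dfr(grp, function(g) {
    # every maximal mutually-overlapping set of intervals is the set of
    # intervals covering some call's start point (Helly property in 1D)
    cliques <- lapply(unique(g$start_bp), function(p) {
      sort(g$..row[g$start_bp <= p & g$end_bp >= p])
    })
    cliques <- unique(cliques)
    maximal <- vapply(seq_along(cliques), function(i) {
      !any(vapply(seq_along(cliques), function(j) {
        i != j && all(cliques[[i]] %in% cliques[[j]])
      }, logical(1)))
    }, logical(1))
    cliques <- cliques[maximal]
    purrr::map_dfr(cliques, function(rows) {
      sub <- g[match(rows, g$..row), ]
      carriers <- sort(unique(sub$individual_id))
      if (length(carriers) < min_carriers) return(NULL)
      tibble::tibble(
        family_id = sub$family_id[1], chrom = sub$chrom[1],
        start_bp = max(sub$start_bp), end_bp = min(sub$end_bp),
        n_carriers = length(carriers), carrier_ids = list(carriers),
        states = paste(sort(unique(sub$state)), collapse = "+"),
        call_rows = list(rows)
      )
    })
  })
  if (nrow(out) == 0) return(empty_regions())
  out |>
    dplyr::arrange(.data$chrom, .data$start_bp, .data$family_id) |>
    dplyr::distinct(.data$family_id, .data$chrom, .data$start_bp,
                    .data$end_bp, .data$states, .keep_all = TRUE)
}

empty_regions <- function() {
  tibble::tibble(family_id = character(), chrom = character(),
                 start_bp = numeric(), end_bp = numeric(),
                 n_carriers = integer(), carrier_ids = list(),
                 states = character(), call_rows = list())
}

#' Segment the genome by shared-region breakpoints
#'
#' Chromosome-wise sweep over the sorted boundaries of all families'
#' shared regions, producing minimal disjoint segments annotated with the
#' families whose shared region covers each segment; adjacent segments with
#' identical family sets are merged.
#'
#' @param regions shared-region tibble from [family_shared_regions()].
#' @return a tibble with columns `chrom`, `start_bp`, `end_bp` (1-based
#'   closed), `families` (list), `n_families` and `region_rows` (list of
#'   row indices into `regions`).
#' @export
segment_genome <- function(regions) {
  if (nrow(regions) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), families = list(),
                          n_families = integer(), region_rows = list()))
  }
  regions$..row <- seq_len(nrow(regions))
  purrr::map_dfr(split(regions, regions$chrom), function(g) {
    # half-open arithmetic: [start, end + 1)
    bounds <- sort(unique(c(g$start_bp, g$end_bp + 1)))
    segs <- purrr::map_dfr(seq_len(length(bounds) - 1), function(i) {
      s <- bounds[i]
      e <- bounds[i + 1]
      cover <- g$..row[g$start_bp <= s & g$end_bp + 1 >= e]
      if (length(cover) == 0) return(NULL)
      tibble::tibble(chrom = g$chrom[1], start_bp = s, end_bp = e - 1,
                     families = list(sort(unique(g$family_id[match(cover, g$..row)]))),
                     region_rows = list(sort(cover)))
    })
    merge_equal_segments(segs)
  }) |>
    dplyr::mutate(n_families = lengths(.data$families)) |>
    dplyr::select("chrom", "start_bp", "end_bp", "families", "n_families",
                  "region_rows") |>
    dplyr::arrange(.data$chrom, .data$start_bp)
}

merge_equal_segments <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  keep <- list(segs[1, ])
  for (i in 2:nrow(segs)) {
    last <- keep[[length(keep)]]
    contiguous <- segs$start_bp[i] == last$end_bp + 1
    same <- identical(segs$families[[i]], last$families[[1]])
    if (contiguous && same) {
      keep[[length(keep)]]$end_bp <- segs$end_bp[i]
      keep[[length(keep)]]$region_rows <- list(sort(union(
        last$region_rows[[1]], segs$region_rows[[i]])))
    } else {
      keep[[length(keep) + 1L]] <- segs[i, ]
    }
  }
  dplyr::bind_rows(keep)
}

#' Mask genotypes inside CNV regions
#'
#' `per_carrier` (used by the CNV-weighted analysis) sets markers falling
#' inside an individual's own CNV calls to missing for that individual
#' only, leaving non-carriers intact.  `global_remove` (used for a plain
#' linkage scan) drops markers inside any call from the table entirely.
#'
#' @param genotypes genotype tibble.
#' @param calls validated call tibble.
#' @param map genetic map tibble resolving marker bp positions.
#' @param mode "per_carrier" or "global_remove".
#' @return the masked genotype tibble.
#' @export
mask_genotypes <- function(genotypes, calls, map,
                           mode = c("per_carrier", "global_remove")) {
  mode <- match.arg(mode)
  markers <- geno_marker_names(genotypes)
  map <- map[map$marker %in% markers, ]
  if (mode == "global_remove") {
    drop <- unique(unlist(lapply(seq_len(nrow(calls)), function(i) {
      map$marker[map$chrom == calls$chrom[i] &
                   map$bp >= calls$start_bp[i] & map$bp <= calls$end_bp[i]]
    })))
    return(genotypes[, !(names(genotypes) %in% drop), drop = FALSE])
  }
  key <- paste(genotypes$family_id, genotypes$individual_id)
  for (i in seq_len(nrow(calls))) {
    hit <- map$marker[map$chrom == calls$chrom[i] &
                        map$bp >= calls$start_bp[i] &
                        map$bp <= calls$end_bp[i]]
    if (length(hit) == 0) next
    row <- which(key == paste(calls$family_id[i], calls$individual_id[i]))
    if (length(row) == 0) next
    genotypes[row, hit] <- 0L
  }
  genotypes
}
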