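# Gene-dropping null distribution for the plain linkage scan and the
# CNV-weighted scan: simulated genotypes under no linkage, replicate
# genome-wide maxima, empirical p-values and FWER thresholds.

#' Simulate genotypes by gene dropping
#'
#' Draws founder haplotypes independently per marker from the founder
#' allele frequencies and propagates them to all non-founders by Mendelian
#' segregation with Haldane recombination between adjacent markers.  The
#' pedigree structure, all phenotypes and the observed missingness pattern
#' are retained; only genotypes are replaced.
#'
#' @param ped pedigree tibble.
#' @param genotypes observed genotype tibble (provides the marker set and
#'   the missingness pattern).
#' @param map genetic map tibble.
#' @param freqs optional allele-frequency tibble; estimated from the
#'   observed founders when `NULL`.
#' @param seed optional integer seed for reproducibility.
#' @return a genotype tibble with the same shape as `genotypes`.
#' @export
gene_drop <- function(ped, genotypes, map, freqs = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- map[map$marker %in% geno_marker_names(genotypes), ]
  freqs <- freqs %||% estimate_founder_allele_freqs(ped, genotypes)
  freq1 <- freqs$freq1[match(map$marker, freqs$marker)]
  engines <- lapply(split(ped, ped$family_id), build_family_engine)
  chroms <- split(seq_len(nrow(map)), map$chrom)
  chroms <- chroms[unique(map$chrom)]
  ped_order <- dplyr::bind_rows(lapply(engines, function(e) e$ped))
  obs <- geno_code_matrix(genotypes, ped_order$family_id,
                          ped_order$individual_id, map$marker)
  sim <- drop_codes(engines, chroms, map$cm, freq1)
  sim[obs == 0L] <- 0L
  out <- dplyr::bind_cols(
    tibble::tibble(family_id = ped_order$family_id,
                   individual_id = ped_order$individual_id),
    tibble::as_tibble(`colnames<-`(sim, map$marker))
  )
  out
}

# simulate genotype code matrix for all families, rows in engine order
drop_codes <- function(engines, chroms, cm, freq1) {
  n_total <- sum(vapply(engines, function(e) length(e$ids), integer(1)))
  out <- matrix(0L, n_total, length(freq1))
  at <- 0L
  for (eng in engines) {
    n <- length(eng$ids)
    for (j in chroms) {
      theta <- haldane_theta(diff(cm[j]))
      gd <- cl_gene_drop(eng$fa, eng$mo, freq1[j], theta)
      out[at + seq_len(n), j] <- gd$geno
    }
    at <- at + n
  }
  out
}

#' Genome-wide maximum statistics over gene-dropped replicates
#'
#' Re-runs the full scoring pipeline on simulated genotypes for each
#' replicate and records the genome-wide maximum of the chosen statistic:
#' the combined NPL Z (model "npl"), the HLOD (parametric models), or the
#' maximum CNV-weighted segment score.  CNV calls are held fixed at the
#' observed positions across replicates (only genotypes are re-dropped, and
#' per-carrier masking is re-applied at the fixed positions).  Replicates
#' use seed streams derived from the master seed by replicate index, so the
#' result is reproducible and independent of evaluation order.
#'
#' @inheritParams linkage_scan
#' @param statistic "linkage" or "cnv_weighted".
#' @param cnv_calls CNV call tibble (required for "cnv_weighted").
#' @param n_replicates number of gene-dropped replicates (the reference
#'   analysis used 1000).
#' @param seed master seed (integer).
#' @param min_length_bp,min_carriers,match_state CNV pipeline parameters,
#'   as in [cnv_weighted_scan()].
#' @return an object of class `replicate_maxima`: list with `maxima`
#'   (numeric vector, one genome-wide maximum per replicate),
#'   `n_replicates`, `seed`, `statistic`, `model_name`, `asm`.
#' @export
replicate_maxima <- function(ped, genotypes, map,
                             statistic = c("linkage", "cnv_weighted"),
                             model = "npl", asm = 1, cnv_calls = NULL,
                             n_replicates = 1000, seed = 1,
                             min_length_bp = 10000, min_carriers = 2,
                             match_state = FALSE, freqs = NULL) {
  statistic <- match.arg(statistic)
  if (n_replicates < 1) {
    abort("n_replicates must be at least 1", class = "cnvlink_domain_error")
  }
  pipe <- compile_null_pipeline(ped, genotypes, map, statistic, model, asm,
                                cnv_calls, min_length_bp, min_carriers,
                                match_state, freqs)
  maxima <- vapply(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, r))
    pipe$run_one()
  }, numeric(1))
  structure(list(maxima = maxima, n_replicates = n_replicates, seed = seed,
                 statistic = statistic, model_name = pipe$model_name,
                 asm = asm, degenerate = pipe$degenerate),
            class = "replicate_maxima")
}

compile_null_pipeline <- function(ped, genotypes, map, statistic, model,
                                  asm, cnv_calls, min_length_bp,
                                  min_carriers, match_state, freqs) {
  cnv_mode <- statistic == "cnv_weighted"
  segments <- NULL
  regions <- NULL
  if (cnv_mode) {
    if (is.null(cnv_calls)) {
      abort_config("cnv_calls required for the cnv_weighted statistic")
    }
    calls <- filter_cnvs(cnv_calls, min_length_bp)
    regions <- family_shared_regions(calls, min_carriers, match_state)
    segments <- segment_genome(regions)
    if (nrow(segments) == 0) {
      warn("no shared CNV regions; replicate maxima are -Inf")
      return(list(run_one = function() -Inf, model_name = scan_model_name(model),
                  degenerate = TRUE))
    }
    map <- map[map$chrom %in% unique(regions$chrom), ]
    genotypes <- mask_genotypes(genotypes, calls, map, mode = "per_carrier")
  }
  prep <- prepare_scan(ped, genotypes, map, model, asm, freqs)
  obs <- geno_code_matrix(genotypes, prep$ped_order$family_id,
                          prep$ped_order$individual_id, prep$map$marker)
  miss <- obs == 0L
  npl_mode <- is.null(prep$model)
  seg_meta <- NULL
  if (cnv_mode) {
    # marker indices per region (into prep$map rows), flanking fallback
    region_idx <- lapply(seq_len(nrow(regions)), function(i) {
      on_chr <- which(prep$map$chrom == regions$chrom[i])
      inside <- on_chr[prep$map$bp[on_chr] >= regions$start_bp[i] &
                         prep$map$bp[on_chr] <= regions$end_bp[i]]
      if (length(inside) > 0) return(inside)
      below <- on_chr[prep$map$bp[on_chr] < regions$start_bp[i]]
      above <- on_chr[prep$map$bp[on_chr] > regions$end_bp[i]]
      c(if (length(below)) below[which.max(prep$map$bp[below])],
        if (length(above)) above[which.min(prep$map$bp[above])])
    })
    seg_meta <- lapply(seq_len(nrow(segments)), function(s) {
      rows <- segments$region_rows[[s]]
      split(rows, regions$family_id[rows])
    })
    region_fams <- regions$family_id
  }
  run_one <- function() {
    sim <- drop_codes(prep$engines, prep$chroms, prep$map$cm, prep$freq1)
    sim[miss] <- 0L
    fsm <- family_score_matrix(prep, sim, quiet = TRUE, want_ic = FALSE)
    smat <- fsm$smat
    if (!cnv_mode) {
      if (npl_mode) {
        return(max(rowSums(smat) / sqrt(ncol(smat))))
      }
      return(max(vapply(seq_len(nrow(smat)),
                        function(i) hlod(smat[i, ])$hlod, numeric(1))))
    }
    avg <- vapply(seq_along(region_idx), function(i) {
      f <- region_fams[i]
      if (!f %in% colnames(smat)) return(NA_real_)
      mean(smat[region_idx[[i]], f])
    }, numeric(1))
    seg_scores <- vapply(seg_meta, function(byfam) {
      sum(vapply(byfam, function(rows) {
        v <- avg[rows]
        if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
      }, numeric(1)))
    }, numeric(1))
    max(seg_scores)
  }
  list(run_one = run_one, model_name = prep$model_name, degenerate = FALSE)
}

#' Empirical p-value from replicate maxima
#'
#' By default the permutation-valid estimator
#' \eqn{p = (1 + \#\{max_r \ge obs\})/(n + 1)}; `method = "plugin"` gives
#' the unadjusted \eqn{\#/n} estimator for literal compatibility with
#' printed values such as 33/1000 = 0.033.
#'
#' @param observed observed genome-wide maximum statistic.
#' @param maxima numeric vector of replicate maxima, or a
#'   `replicate_maxima` object.
#' @param method "permutation" (default) or "plugin".
#' @return the empirical p-value.
#' @export
empirical_p <- function(observed, maxima, method = c("permutation", "plugin")) {
  method <- match.arg(method)
  if (inherits(maxima, "replicate_maxima")) maxima <- maxima$maxima
  if (length(maxima) == 0) {
    abort("empty replicate maxima", class = "cnvlink_domain_error")
  }
  r <- sum(maxima >= observed)
  n <- length(maxima)
  if (method == "plugin") r / n else (1 + r) / (n + 1)
}

#' FWER thresholds from replicate maxima
#'
#' The threshold for a family-wise error rate f is the smallest order
#' statistic of the replicate maxima whose exceedance fraction is at most
#' f (order statistic `n + 1 - floor(n * f)`).  The default levels are the
#' suggestive criterion FWER = 1 - e^(-1) = 0.632 (the probability that a
#' Poisson variable with mean 1 is positive, i.e. one expected false peak
#' per genome scan) and significant linkage at FWER = 0.05.
#'
#' @param maxima numeric vector of replicate maxima, or a
#'   `replicate_maxima` object.
#' @param fwers named numeric vector of target family-wise error rates.
#' @return a tibble with columns `level`, `fwer`, `order_statistic`,
#'   `threshold`.
#' @export
fwer_thresholds <- function(maxima,
                            fwers = c(suggestive = 1 - exp(-1),
                                      significant = 0.05)) {
  if (inherits(maxima, "replicate_maxima")) maxima <- maxima$maxima
  if (length(maxima) == 0) {
    abort("empty replicate maxima", class = "cnvlink_domain_error")
  }
  n <- length(maxima)
  srt <- sort(maxima)
  k <- pmin(pmax(n + 1 - floor(n * fwers), 1), n)
  tibble::tibble(level = names(fwers) %||% as.character(fwers),
                 fwer = unname(fwers), order_statistic = as.integer(k),
                 threshold = srt[k])
}

#' @export
print.replicate_maxima <- function(x, ...) {
  cat("Gene-dropping null distribution (", x$statistic, ", ",
      x$model_name, ", ASM", x$asm, ")\n", sep = "")
  cat(x$n_replicates, "replicates, seed", x$seed, "\n")
  if (all(is.finite(x$maxima))) {
    cat("maxima: min", signif(min(x$maxima), 4), "median",
        signif(stats::median(x$maxima), 4), "max",
        signif(max(x$maxima), 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.replicate_maxima <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$maxima), maximum = x$maxima)
}

#' @export
glance.replicate_maxima <- function(x, ...) {
  tibble::tibble(n_replicates = x$n_replicates, seed = x$seed,
                 statistic = x$statistic, model = x$model_name,
                 asm = x$asm, median_max = stats::median(x$maxima),
                 max_max = max(x$maxima))
}
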