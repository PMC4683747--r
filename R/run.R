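# Config-driven pipeline runners behind the command-line entry point.
# Each writes deterministic TSV outputs with a header recording version,
# seed and a hash of the effective configuration.

default_run_config <- function() {
  list(ped = NULL, map = NULL, cnv = NULL, out_dir = ".",
       models = "npl", asms = 1, seed = 1,
       min_cnv_length = 10000, min_carriers = 2, match_state = FALSE,
       reps = 1000, stat = "linkage", top_k = 25)
}

#' Load and normalise a run configuration
#'
#' @param config a named list, or the path of a YAML file.
#' @param ... individual overrides (flags beat the file).
#' @return the merged configuration list.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_config(paste0("config file not found: ", config))
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_config("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  utils::modifyList(cfg, list(...))
}

load_run_inputs <- function(cfg, need_cnv = FALSE) {
  for (f in c("ped", "map", if (need_cnv) "cnv")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      abort_config(paste0("input file missing for '", f, "': ",
                          cfg[[f]] %||% "<unset>"))
    }
  }
  ped <- read_pedigree(cfg$ped)
  map <- read_genetic_map(cfg$map)
  genotypes <- read_ped_genotypes(cfg$ped, marker_ids = map$marker)
  cnv <- if (need_cnv) read_cnv_calls(cfg$cnv) else NULL
  list(ped = ped, map = map, genotypes = genotypes, cnv = cnv)
}

output_header <- function(cfg) {
  # the hash covers the analytic configuration, not the output location
  h <- cfg[setdiff(sort(names(cfg)), "out_dir")]
  c(paste0("# cnvlink ", as.character(utils::packageVersion("cnvlink"))),
    paste0("# seed=", cfg$seed),
    paste0("# config_hash=", rlang::hash(h)))
}

write_tsv_with_header <- function(x, path, cfg) {
  writeLines(output_header(cfg), path)
  suppressWarnings(
    utils::write.table(x, path, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Run genome-wide linkage scans from a configuration
#'
#' One curve file per model and affection-status model, plus a summary of
#' chromosome-wise peaks with their 1-unit support intervals.
#'
#' @param config configuration list or YAML path (see [run_config()]);
#'   fields: `ped`, `map`, `out_dir`, `models`, `asms`, `seed`.
#' @param ... overrides.
#' @return paths of the written files, invisibly.
#' @export
run_scan <- function(config = list(), ...) {
  cfg <- run_config(config, ...)
  inp <- load_run_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summaries <- list()
  for (model in cfg$models) {
    for (asm in cfg$asms) {
      scan <- linkage_scan(inp$ped, inp$genotypes, inp$map, model = model,
                           asm = asm)
      curve <- tidy(scan)
      path <- file.path(cfg$out_dir,
                        sprintf("curve_%s_asm%s.tsv", model, asm))
      flat <- scan$family_curves |>
        tidyr::pivot_wider(names_from = "family_id", values_from = "score",
                           names_prefix = "fam_")
      out <- dplyr::left_join(curve, flat,
                              by = c("chrom", "marker", "cm", "bp"))
      write_tsv_with_header(out, path, cfg)
      paths <- c(paths, path)
      stat <- if (model == "npl") "z" else "hlod"
      summaries[[paste(model, asm)]] <- curve |>
        dplyr::group_by(.data$chrom) |>
        dplyr::reframe(model = model, asm = asm,
                       support_interval(.data$cm, .data[[stat]])) |>
        dplyr::rename(peak_statistic = "peak_score")
    }
  }
  spath <- file.path(cfg$out_dir, "scan_summary.tsv")
  write_tsv_with_header(dplyr::bind_rows(summaries), spath, cfg)
  invisible(c(paths, spath))
}

#' Run the CNV-weighted scan from a configuration
#'
#' @param config configuration list or YAML path; fields as [run_scan()]
#'   plus `cnv`, `min_cnv_length`, `min_carriers`, `match_state`, `top_k`.
#' @param ... overrides.
#' @return paths of the written files, invisibly.
#' @export
run_cnv_scan <- function(config = list(), ...) {
  cfg <- run_config(config, ...)
  inp <- load_run_inputs(cfg, need_cnv = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (model in cfg$models) {
    for (asm in cfg$asms) {
      scan <- cnv_weighted_scan(inp$ped, inp$genotypes, inp$map, inp$cnv,
                                model = model, asm = asm,
                                min_length_bp = cfg$min_cnv_length,
                                min_carriers = cfg$min_carriers,
                                match_state = cfg$match_state)
      path <- file.path(cfg$out_dir,
                        sprintf("cnv_segments_%s_asm%s.tsv", model, asm))
      write_tsv_with_header(tidy(scan), path, cfg)
      rpath <- file.path(cfg$out_dir,
                         sprintf("cnv_ranked_%s_asm%s.tsv", model, asm))
      ranked <- if (nrow(scan$segments)) {
        rank_segments(scan$segments, cfg$top_k) |>
          flatten_segments()
      } else {
        inform("no shared CNV regions anywhere; writing empty ranking")
        flatten_segments(scan$segments)
      }
      write_tsv_with_header(ranked, rpath, cfg)
      paths <- c(paths, path, rpath)
    }
  }
  invisible(paths)
}

flatten_segments <- function(segments) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), n_families = integer(),
                          score = numeric(), families = character(),
                          contributions = character()))
  }
  segments |>
    dplyr::mutate(
      families = vapply(.data$families, paste, character(1), collapse = ","),
      contributions = vapply(.data$contributions, function(ct) {
        paste(sprintf("%s:%.4f", ct$family_id, ct$average), collapse = ";")
      }, character(1))) |>
    dplyr::select("chrom", "start_bp", "end_bp", "n_families", "score",
                  "families", "contributions")
}

#' Run the gene-dropping simulation from a configuration
#'
#' Writes the replicate maxima, the FWER thresholds and the empirical
#' p-value of the observed genome-wide maximum.
#'
#' @param config configuration list or YAML path; fields as [run_scan()]
#'   plus `stat` ("linkage" or "cnv_weighted") and `reps`.
#' @param ... overrides.
#' @return paths of the written files, invisibly.
#' @export
run_simulate <- function(config = list(), ...) {
  cfg <- run_config(config, ...)
  need_cnv <- cfg$stat == "cnv_weighted"
  inp <- load_run_inputs(cfg, need_cnv = need_cnv)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (model in cfg$models) {
    for (asm in cfg$asms) {
      if (need_cnv) {
        scan <- cnv_weighted_scan(inp$ped, inp$genotypes, inp$map, inp$cnv,
                                  model = model, asm = asm,
                                  min_length_bp = cfg$min_cnv_length,
                                  min_carriers = cfg$min_carriers,
                                  match_state = cfg$match_state)
        observed <- if (nrow(scan$segments)) max(scan$segments$score) else -Inf
      } else {
        scan <- linkage_scan(inp$ped, inp$genotypes, inp$map, model = model,
                             asm = asm)
        stat <- if (model == "npl") "z" else "hlod"
        observed <- max(scan$curve[[stat]])
      }
      rm <- replicate_maxima(inp$ped, inp$genotypes, inp$map,
                             statistic = cfg$stat, model = model, asm = asm,
                             cnv_calls = inp$cnv, n_replicates = cfg$reps,
                             seed = cfg$seed,
                             min_length_bp = cfg$min_cnv_length,
                             min_carriers = cfg$min_carriers,
                             match_state = cfg$match_state)
      base <- sprintf("%s_%s_asm%s", cfg$stat, model, asm)
      mpath <- file.path(cfg$out_dir, paste0("maxima_", base, ".tsv"))
      write_tsv_with_header(tidy(rm), mpath, cfg)
      thr <- fwer_thresholds(rm)
      res <- dplyr::bind_rows(
        thr |> dplyr::mutate(kind = "threshold", value = .data$threshold),
        tibble::tibble(level = "observed", fwer = NA_real_,
                       order_statistic = NA_integer_, threshold = NA_real_,
                       kind = "observed", value = observed),
        tibble::tibble(level = "empirical_p", fwer = NA_real_,
                       order_statistic = NA_integer_, threshold = NA_real_,
                       kind = "p", value = empirical_p(observed, rm)))
      tpath <- file.path(cfg$out_dir, paste0("thresholds_", base, ".tsv"))
      write_tsv_with_header(res, tpath, cfg)
      paths <- c(paths, mpath, tpath)
    }
  }
  invisible(paths)
}

#' Generate a synthetic cohort from a configuration
#'
#' @param config configuration list or YAML path; `sim` holds arguments
#'   for [sim_config()], `out_dir` the output directory, `seed` the seed.
#' @param ... overrides.
#' @return the output directory, invisibly.
#' @export
run_synth <- function(config = list(), ...) {
  cfg <- run_config(config, ...)
  sim_args <- cfg$sim %||% list()
  sim_args$seed <- sim_args$seed %||% cfg$seed
  sc <- do.call(sim_config, sim_args)
  simulate_cohort(sc, dir = cfg$out_dir)
  invisible(cfg$out_dir)
}
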