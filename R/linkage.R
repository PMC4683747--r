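# Multipoint linkage engine: family preparation, inheritance-vector
# posteriors, NPL(all)/Kong-Cox, parametric LOD/HLOD, information content,
# support intervals, haplotype reconstruction and pedigree screening.

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under the no-interference (Haldane) model:
#' \eqn{\theta = (1 - e^{-2d/100})/2}.
#'
#' @param distance_cm non-negative genetic distance(s) in cM.
#' @return recombination fraction(s) in \[0, 0.5).
#' @examples
#' haldane_theta(c(0, 10, 1000))
#' @export
haldane_theta <- function(distance_cm) {
  if (any(distance_cm < 0)) {
    abort("genetic distances must be non-negative", class = "cnvlink_domain_error")
  }
  (1 - exp(-2 * distance_cm / 100)) / 2
}

# Per-family engine data: individuals ordered parents-before-children,
# parent indices, meiosis-bit layout and founder-slot descent matrices for
# every inheritance vector.
build_family_engine <- function(fam_ped) {
  n <- nrow(fam_ped)
  ord <- topo_order(fam_ped)
  rows <- fam_ped[ord, , drop = FALSE]
  idx <- stats::setNames(seq_len(n), rows$individual_id)
  fa <- ifelse(is.na(rows$father_id), 0L, idx[rows$father_id])
  mo <- ifelse(is.na(rows$mother_id), 0L, idx[rows$mother_id])
  is_founder <- fa == 0L
  nf <- which(!is_founder)
  B <- 2L * length(nf)
  if (B > MAX_MEIOSIS_BITS) {
    abort_capacity(paste0(
      "family ", rows$family_id[1], " has ", length(nf), " non-founders (",
      B, " meiosis bits); the exact engine is capped at ", MAX_MEIOSIS_BITS,
      " bits - split or trim the pedigree"))
  }
  V <- 2L^B
  nslots <- 2L * sum(is_founder)
  slotP <- matrix(0L, V, n)
  slotM <- matrix(0L, V, n)
  v <- 0:(V - 1)
  k <- 0L
  for (i in which(is_founder)) {
    slotP[, i] <- 2L * k + 1L
    slotM[, i] <- 2L * k + 2L
    k <- k + 1L
  }
  for (j in seq_along(nf)) {
    i <- nf[j]
    bitp <- bitwAnd(bitwShiftR(v, 2L * (j - 1L)), 1L)
    bitm <- bitwAnd(bitwShiftR(v, 2L * (j - 1L) + 1L), 1L)
    slotP[, i] <- ifelse(bitp == 0L, slotP[, fa[i]], slotM[, fa[i]])
    slotM[, i] <- ifelse(bitm == 0L, slotP[, mo[i]], slotM[, mo[i]])
  }
  list(family_id = rows$family_id[1], ids = rows$individual_id, order = ord,
       fa = as.integer(fa), mo = as.integer(mo), is_founder = is_founder,
       B = B, V = V, nslots = nslots, slotP = slotP, slotM = slotM,
       ped = rows)
}

topo_order <- function(fam_ped) {
  n <- nrow(fam_ped)
  idx <- stats::setNames(seq_len(n), fam_ped$individual_id)
  fa <- idx[fam_ped$father_id]
  mo <- idx[fam_ped$mother_id]
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[pmax(fa, 1L)]) &
      (is.na(mo) | placed[pmax(mo, 1L)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    abort_structure(paste0("pedigree cycle in family ", fam_ped$family_id[1]))
  }
  ord
}

# singlepoint likelihoods for one family over a block of markers; zeroed
# (Mendelian-inconsistent) markers are flagged and reset to uninformative
family_marker_liks <- function(eng, codes, freq1) {
  liks <- cl_marker_liks(eng$slotP, eng$slotM, codes, freq1, eng$nslots)
  bad <- colSums(liks) == 0
  if (any(bad)) {
    warn(paste0("family ", eng$family_id, ": ", sum(bad),
                " Mendelian-inconsistent marker(s) zeroed"))
    liks[, bad] <- 1
  }
  liks
}

family_posterior <- function(eng, codes, freq1, theta) {
  liks <- family_marker_liks(eng, codes, freq1)
  cl_forward_backward(liks, theta)$post
}

#' Whittemore-Halpern S_all scores over all inheritance vectors
#'
#' For each of the \eqn{2^B} inheritance vectors of one family, the
#' NPL(all) scoring function: one allele is picked from each affected
#' individual in every possible way, the picked alleles are grouped by the
#' founder allele they descend from, and the products of multiplicity
#' factorials are averaged.
#'
#' @param ped pedigree tibble restricted to one family.
#' @param affected_ids individual ids counted as affected.
#' @return numeric vector of length \eqn{2^B} in inheritance-vector order.
#' @export
sall_scores <- function(ped, affected_ids) {
  eng <- build_family_engine(ped)
  aff <- match(affected_ids, eng$ids)
  if (anyNA(aff)) abort_structure("affected id not in family")
  cl_sall(eng$slotP, eng$slotM, as.integer(aff), eng$nslots)
}

npl_family_stats <- function(eng, affected_idx) {
  s <- cl_sall(eng$slotP, eng$slotM, as.integer(affected_idx), eng$nslots)
  mu <- mean(s)
  sigma <- sqrt(max(mean(s^2) - mu^2, 0))
  list(s = s, mu = mu, sigma = sigma)
}

#' Kong-Cox linear-model LOD from per-family NPL scores
#'
#' Maximises \eqn{\ell(\delta) = \sum_i \log_{10}(1 + \delta Z_i)} over the
#' sharing parameter \eqn{\delta \in [0, \delta_{max}]}, where the upper
#' bound keeps every term's argument positive
#' (\eqn{\delta_{max} = 0.999 \cdot (-1/\min_i Z_i)} when some \eqn{Z_i < 0},
#' otherwise 10).  The one-sided p-value uses the half-chi-squared mixture.
#'
#' @param z numeric vector of per-family normalised NPL scores at one
#'   position.
#' @param tol optimisation tolerance for \eqn{\delta}.
#' @return a one-row tibble with `lod`, `delta` and `p`.
#' @export
kong_cox_lod <- function(z, tol = 1e-9) {
  z <- z[is.finite(z)]
  if (length(z) == 0) {
    return(tibble::tibble(lod = 0, delta = 0, p = 0.5))
  }
  dmax <- if (min(z) < 0) 0.999 * (-1 / min(z)) else 10
  obj <- function(d) sum(log10(1 + d * z))
  lod <- 0
  delta <- 0
  if (any(z > 0) && dmax > 0) {
    opt <- optimize(obj, c(0, dmax), maximum = TRUE, tol = tol)
    cand <- c(0, opt$maximum, dmax)
    val <- vapply(cand, obj, numeric(1))
    best <- which.max(val)
    if (val[best] > 0) {
      lod <- val[best]
      delta <- cand[best]
    }
  }
  p <- if (lod > 0) {
    0.5 * stats::pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE)
  } else {
    0.5
  }
  tibble::tibble(lod = lod, delta = delta, p = p)
}

#' Heterogeneity LOD score
#'
#' Maximises \eqn{\sum_i \log_{10}(\alpha 10^{LOD_i} + 1 - \alpha)} over the
#' proportion of linked families \eqn{\alpha \in [0, 1]} by bounded scalar
#' search.
#'
#' @param lods numeric vector of per-family LOD scores at one position.
#' @param tol optimisation tolerance for \eqn{\alpha}.
#' @return a one-row tibble with `hlod` and `alpha` (0 when no positive
#'   evidence exists).
#' @export
hlod <- function(lods, tol = 1e-6) {
  lods <- lods[is.finite(lods)]
  if (length(lods) == 0) return(tibble::tibble(hlod = 0, alpha = 0))
  r <- 10^lods
  obj <- function(a) sum(log10(a * r + 1 - a))
  opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  val <- vapply(cand, obj, numeric(1))
  best <- which.max(val)
  if (val[best] <= 0) {
    tibble::tibble(hlod = 0, alpha = 0)
  } else {
    tibble::tibble(hlod = val[best], alpha = cand[best])
  }
}

#' Entropy-based information content of inheritance-vector posteriors
#'
#' \eqn{IC = 1 - H(posterior)/H(uniform)} per position; 0 for a uniform
#' posterior (no data), 1 for a point mass (inheritance fully determined).
#'
#' @param posterior matrix of posterior probabilities, one column per
#'   position, rows summing to 1 over the inheritance vectors.
#' @return numeric vector of IC values, one per column.
#' @export
information_content <- function(posterior) {
  posterior <- as.matrix(posterior)
  hmax <- log(nrow(posterior))
  if (hmax == 0) return(rep(1, ncol(posterior)))
  h <- apply(posterior, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  1 - h / hmax
}

#' Support interval around a linkage peak
#'
#' The maximal contiguous run of grid positions around the peak whose score
#' stays within `drop` units of the peak; boundaries are the last grid
#' points satisfying the inequality (no interpolation).  A flat curve
#' returns the whole range with a warning.
#'
#' @param cm grid positions (cM, ascending).
#' @param score scores on the grid.
#' @param drop score units for the interval (1.0 gives the conventional
#'   approximate 95\% interval).
#' @return a one-row tibble with `start_cm`, `end_cm`, `peak_cm`,
#'   `peak_score`.
#' @export
support_interval <- function(cm, score, drop = 1.0) {
  stopifnot(length(cm) == length(score), length(cm) > 0)
  if (max(score) - min(score) == 0) {
    warn("flat curve; support interval spans the whole chromosome")
    return(tibble::tibble(start_cm = min(cm), end_cm = max(cm),
                          peak_cm = cm[1], peak_score = score[1]))
  }
  pk <- which.max(score)
  thr <- score[pk] - drop
  lo <- pk
  while (lo > 1 && score[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < length(score) && score[hi + 1] >= thr) hi <- hi + 1
  tibble::tibble(start_cm = cm[lo], end_cm = cm[hi],
                 peak_cm = cm[pk], peak_score = score[pk])
}

#' Parametric disease models
#'
#' Preset single-locus models: the dominant model has risk allele frequency
#' 0.0045 and penetrances (0.001, 0.50, 0.75) for 0/1/2 risk alleles; the
#' recessive model has frequency 0.065 and penetrances
#' (0.0015, 0.0015, 0.50).
#'
#' @param name "dominant" or "recessive".
#' @param q optional risk allele frequency overriding the preset.
#' @param f optional penetrance vector (f0, f1, f2) overriding the preset.
#' @return a list with elements `name`, `q`, `f`.
#' @export
disease_model <- function(name = c("dominant", "recessive"), q = NULL,
                          f = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    dominant = list(q = 0.0045, f = c(0.001, 0.50, 0.75)),
    recessive = list(q = 0.065, f = c(0.0015, 0.0015, 0.50))
  )
  q <- q %||% preset$q
  f <- f %||% preset$f
  if (q <= 0 || q >= 1) abort_config("risk allele frequency must be in (0,1)")
  if (length(f) != 3 || any(f < 0) || any(f > 1)) {
    abort_config("penetrances must be three probabilities (f0, f1, f2)")
  }
  list(name = name, q = q, f = f)
}

# P(phenotypes | v, model) for all inheritance vectors of one family
family_phen_lik <- function(eng, status, model) {
  phen <- integer(length(status))
  phen[status == "unaffected"] <- 1L
  phen[status == "affected"] <- 2L
  cl_phen_lik(eng$slotP, eng$slotM, phen, eng$is_founder, model$q, model$f,
              eng$nslots)
}

# LOD_i(x) = log10( E_post[P(phen|v)] / E_unif[P(phen|v)] )
family_param_lod <- function(phen_lik, posterior) {
  den <- mean(phen_lik)
  if (den == 0) return(rep(0, ncol(posterior)))
  num <- as.numeric(crossprod(posterior, phen_lik))
  log10(pmax(num, .Machine$double.xmin) / den)
}

#' Genome-wide multipoint linkage scan
#'
#' Runs the inheritance-vector HMM over every family and chromosome and
#' computes, at each marker position, either the non-parametric NPL(all)
#' statistics (per-family and combined Z, Kong-Cox LOD, sharing parameter
#' delta, one-sided p) or the parametric per-family LOD scores with the
#' heterogeneity LOD (HLOD) and the estimated linked-family proportion
#' alpha.  Entropy-based information content is reported in both cases.
#'
#' @param ped pedigree tibble (see [read_pedigree()]).
#' @param genotypes genotype tibble (see [read_ped_genotypes()]).
#' @param map genetic map tibble restricted to the markers in `genotypes`.
#' @param model "npl", "dominant" or "recessive", or a list from
#'   [disease_model()].
#' @param asm affection-status model (1, 2 or 3).
#' @param freqs optional allele-frequency tibble from
#'   [estimate_founder_allele_freqs()]; estimated from the data when `NULL`.
#' @param chromosomes optional subset of chromosomes to scan.
#' @return an object of class `linkage_scan` with components `curve`
#'   (combined statistics per position), `family_curves` (long tibble of
#'   per-family scores), `model`, `asm` and bookkeeping fields.  Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
linkage_scan <- function(ped, genotypes, map, model = "npl", asm = 1,
                         freqs = NULL, chromosomes = NULL) {
  prep <- prepare_scan(ped, genotypes, map, model, asm, freqs, chromosomes)
  codes <- geno_code_matrix(genotypes, prep$ped_order$family_id,
                            prep$ped_order$individual_id,
                            prep$map$marker)
  res <- scan_genotype_matrix(prep, codes)
  structure(
    list(curve = res$curve, family_curves = res$family_curves,
         model = prep$model, model_name = prep$model_name, asm = asm,
         n_families = length(prep$engines),
         excluded_families = res$excluded),
    class = "linkage_scan"
  )
}

# shared preparation for scans and simulation: family engines, per-family
# phenotype statistics, map layout and allele frequencies
prepare_scan <- function(ped, genotypes, map, model, asm, freqs = NULL,
                         chromosomes = NULL) {
  model_name <- if (is.character(model)) model else model$name
  if (is.character(model)) {
    model <- if (model == "npl") NULL else disease_model(model)
  }
  if (!is.null(chromosomes)) {
    map <- map[map$chrom %in% as.character(chromosomes), ]
  }
  map <- map[map$marker %in% geno_marker_names(genotypes), ]
  if (nrow(map) == 0) abort_config("no mapped markers in the genotype table")
  freqs <- freqs %||% estimate_founder_allele_freqs(ped, genotypes)
  freq1 <- freqs$freq1[match(map$marker, freqs$marker)]
  if (anyNA(freq1)) abort_config("allele frequency missing for mapped marker")
  ped <- apply_asm(ped, asm)
  fams <- split(ped, ped$family_id)
  engines <- lapply(fams, build_family_engine)
  # per-family phenotype machinery, fixed across positions and replicates
  for (f in names(engines)) {
    eng <- engines[[f]]
    status <- as.character(eng$ped$status)
    if (is.null(model)) {
      aff <- which(status == "affected")
      if (length(aff) >= 2 && eng$B > 0) {
        engines[[f]]$npl <- npl_family_stats(eng, aff)
      } else {
        engines[[f]]$npl <- NULL
      }
    } else {
      engines[[f]]$phen_lik <- family_phen_lik(eng, status, model)
    }
  }
  ped_order <- dplyr::bind_rows(lapply(engines, function(e) e$ped))
  chroms <- split(seq_len(nrow(map)), map$chrom)
  chroms <- chroms[unique(map$chrom)]
  list(engines = engines, ped_order = ped_order, map = map, freq1 = freq1,
       chroms = chroms, model = model, model_name = model_name, asm = asm)
}

# lean per-family score matrix (positions x families) over a genotype code
# matrix aligned with prep$ped_order and prep$map
family_score_matrix <- function(prep, codes, quiet = FALSE, want_ic = TRUE) {
  engines <- prep$engines
  nper <- vapply(engines, function(e) length(e$ids), integer(1))
  row_of <- split(seq_len(sum(nper)), rep(names(engines), nper))
  npl_mode <- is.null(prep$model)
  fam_scores <- list()
  ic_fam <- list()
  excluded <- character(0)
  for (f in names(engines)) {
    eng <- engines[[f]]
    if (npl_mode && (is.null(eng$npl) || eng$npl$sigma == 0)) {
      excluded <- c(excluded, f)
      if (!quiet) inform(paste0("family ", f,
                                " excluded from NPL (fewer than 2 affected ",
                                "or degenerate S_all)"))
      next
    }
    sc <- numeric(nrow(prep$map))
    icv <- numeric(nrow(prep$map))
    fcodes <- codes[row_of[[f]], , drop = FALSE]
    for (ch in names(prep$chroms)) {
      j <- prep$chroms[[ch]]
      theta <- haldane_theta(diff(prep$map$cm[j]))
      post <- suppress_if(quiet, family_posterior(
        eng, fcodes[, j, drop = FALSE], prep$freq1[j], theta))
      if (want_ic) icv[j] <- information_content(post)
      if (npl_mode) {
        st <- eng$npl
        sc[j] <- (as.numeric(crossprod(post, st$s)) - st$mu) / st$sigma
      } else {
        sc[j] <- family_param_lod(eng$phen_lik, post)
      }
    }
    fam_scores[[f]] <- sc
    ic_fam[[f]] <- icv
  }
  if (length(fam_scores) == 0) {
    abort("no family contributes a defined linkage curve",
          class = "cnvlink_data_error")
  }
  list(smat = do.call(cbind, fam_scores),
       ic = rowMeans(do.call(cbind, ic_fam)),
       excluded = excluded)
}

# full scan over a genotype code matrix; used by linkage_scan and re-used
# on gene-dropped genotypes
scan_genotype_matrix <- function(prep, codes, quiet = FALSE) {
  fsm <- family_score_matrix(prep, codes, quiet = quiet, want_ic = TRUE)
  smat <- fsm$smat
  excluded <- fsm$excluded
  npl_mode <- is.null(prep$model)
  curve <- tibble::tibble(chrom = prep$map$chrom, marker = prep$map$marker,
                          cm = prep$map$cm, bp = prep$map$bp, ic = fsm$ic)
  if (npl_mode) {
    curve$z <- rowSums(smat) / sqrt(ncol(smat))
    kc <- dplyr::bind_rows(apply(smat, 1, kong_cox_lod))
    curve$lod <- kc$lod
    curve$delta <- kc$delta
    curve$p <- kc$p
  } else {
    hl <- dplyr::bind_rows(apply(smat, 1, hlod))
    curve$hlod <- hl$hlod
    curve$alpha <- hl$alpha
  }
  family_curves <- tibble::as_tibble(smat) |>
    dplyr::mutate(chrom = prep$map$chrom, marker = prep$map$marker,
                  cm = prep$map$cm, bp = prep$map$bp) |>
    tidyr::pivot_longer(cols = dplyr::all_of(colnames(smat)),
                        names_to = "family_id", values_to = "score")
  list(curve = curve, family_curves = family_curves, excluded = excluded)
}

suppress_if <- function(quiet, expr) {
  if (quiet) suppressWarnings(expr) else expr
}

#' Screen families by their individual linkage curves
#'
#' A family is selected when its own curve peaks above `lod_single`
#' anywhere, or when at least two families exceed `lod_overlap` with
#' overlapping 1-unit support intervals on the same chromosome.
#'
#' @param family_curves long tibble with columns `family_id`, `chrom`,
#'   `cm`, `score` (as produced by [linkage_scan()]).
#' @param lod_single single-family selection threshold.
#' @param lod_overlap threshold for the overlapping-interval criterion.
#' @param drop support-interval drop used for the overlap test.
#' @return a tibble with one row per family: `family_id`, `selected`,
#'   `reason` ("single", "overlap" or NA), `peak_score`.
#' @export
screen_pedigrees <- function(family_curves, lod_single = 1.1,
                             lod_overlap = 1.0, drop = 1.0) {
  fams <- unique(family_curves$family_id)
  peaks <- family_curves |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(peak_score = max(.data$score), .groups = "drop")
  selected <- stats::setNames(peaks$peak_score > lod_single, peaks$family_id)
  reason <- stats::setNames(ifelse(selected, "single", NA_character_),
                            peaks$family_id)
  # overlap criterion: per chromosome, support intervals of family peaks
  # above lod_overlap
  iv <- family_curves |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::filter(max(.data$score) > lod_overlap) |>
    dplyr::reframe(suppressWarnings(
      support_interval(.data$cm, .data$score, drop)))
  if (nrow(iv) > 1) {
    for (ch in unique(iv$chrom)) {
      sub <- iv[iv$chrom == ch, ]
      if (nrow(sub) < 2) next
      for (i in seq_len(nrow(sub) - 1)) {
        for (j in seq(i + 1, nrow(sub))) {
          if (sub$family_id[i] == sub$family_id[j]) next
          if (sub$start_cm[i] <= sub$end_cm[j] &&
              sub$start_cm[j] <= sub$end_cm[i]) {
            for (f in c(sub$family_id[i], sub$family_id[j])) {
              if (!selected[[f]]) {
                selected[[f]] <- TRUE
                reason[[f]] <- "overlap"
              }
            }
          }
        }
      }
    }
  }
  tibble::tibble(family_id = fams, selected = unname(selected[fams]),
                 reason = unname(reason[fams]),
                 peak_score = peaks$peak_score[match(fams, peaks$family_id)])
}

#' Most likely inheritance path and phased haplotypes for one family
#'
#' Max-product (Viterbi) decoding of the inheritance-vector chain for a
#' single family on one chromosome, with ties broken toward the smallest
#' vector index, followed by founder-allele phasing at each marker.
#' Recombination events are reported wherever consecutive states differ.
#'
#' @param ped pedigree tibble.
#' @param genotypes genotype tibble.
#' @param map genetic map tibble.
#' @param family family id to decode.
#' @param chromosome chromosome to decode.
#' @param freqs optional allele-frequency tibble.
#' @return an object of class `viterbi_haplotypes`: list with `path`
#'   (tibble marker/cm/state), `recombinations` (tibble with the meiosis and
#'   flanking markers of each crossover) and `haplotypes` (tibble with the
#'   phased paternal/maternal allele and founder slot per individual and
#'   marker; 0 = allele unresolved by the data).
#' @export
viterbi_haplotypes <- function(ped, genotypes, map, family, chromosome,
                               freqs = NULL) {
  fam_ped <- ped[ped$family_id == as.character(family), ]
  if (nrow(fam_ped) == 0) abort_config("family not in pedigree")
  map <- map[map$chrom == as.character(chromosome), ]
  map <- map[map$marker %in% geno_marker_names(genotypes), ]
  if (nrow(map) == 0) abort_config("no mapped markers on that chromosome")
  freqs <- freqs %||% estimate_founder_allele_freqs(ped, genotypes)
  freq1 <- freqs$freq1[match(map$marker, freqs$marker)]
  eng <- build_family_engine(fam_ped)
  codes <- geno_code_matrix(genotypes, eng$ped$family_id, eng$ped$individual_id,
                            map$marker)
  liks <- family_marker_liks(eng, codes, freq1)
  theta <- haldane_theta(diff(map$cm))
  path <- cl_viterbi(liks, theta)
  rec <- which(diff(path) != 0)
  recomb <- purrr::map_dfr(rec, function(m) {
    bits <- bitwXor(path[m] - 1L, path[m + 1L] - 1L)
    flips <- which(bitwAnd(bitwShiftR(bits, 0:(eng$B - 1L)), 1L) == 1L)
    nf_ids <- eng$ids[!eng$is_founder]
    tibble::tibble(
      marker_before = map$marker[m], marker_after = map$marker[m + 1L],
      individual_id = nf_ids[ceiling(flips / 2)],
      meiosis = ifelse(flips %% 2 == 1L, "paternal", "maternal")
    )
  })
  haps <- phase_founder_alleles(eng, codes, path, freq1, map$marker)
  structure(list(family_id = eng$family_id, chrom = as.character(chromosome),
                 path = tibble::tibble(marker = map$marker, cm = map$cm,
                                       state = path),
                 recombinations = recomb, haplotypes = haps),
            class = "viterbi_haplotypes")
}

# founder-allele phasing along a fixed inheritance path: hard constraints
# propagated per marker, unresolved founder alleles left as 0
phase_founder_alleles <- function(eng, codes, path, freq1, markers) {
  n <- length(eng$ids)
  M <- length(markers)
  out <- vector("list", M)
  for (m in seq_len(M)) {
    v <- path[m]
    sp <- eng$slotP[v, ]
    sm <- eng$slotM[v, ]
    assign <- integer(eng$nslots)
    edges <- list()
    ok <- TRUE
    for (i in seq_len(n)) {
      g <- codes[i, m]
      if (g == 0L) next
      if (g == 2L) {
        edges[[length(edges) + 1L]] <- c(sp[i], sm[i])
      } else {
        a <- if (g == 1L) 1L else 2L
        if (assign[sp[i]] != 0L && assign[sp[i]] != a) ok <- FALSE
        if (assign[sm[i]] != 0L && assign[sm[i]] != a) ok <- FALSE
        assign[sp[i]] <- a
        assign[sm[i]] <- a
      }
    }
    if (ok && length(edges)) {
      changed <- TRUE
      while (changed) {
        changed <- FALSE
        for (e in edges) {
          a1 <- assign[e[1]]; a2 <- assign[e[2]]
          if (a1 != 0L && a2 == 0L) { assign[e[2]] <- 3L - a1; changed <- TRUE }
          if (a2 != 0L && a1 == 0L) { assign[e[1]] <- 3L - a2; changed <- TRUE }
        }
      }
    }
    out[[m]] <- tibble::tibble(
      marker = markers[m], individual_id = eng$ids,
      slot_pat = sp, slot_mat = sm,
      allele_pat = assign[sp], allele_mat = assign[sm]
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.viterbi_haplotypes <- function(x, ...) {
  cat("Phased inheritance path for family", x$family_id,
      "on chromosome", x$chrom, "\n")
  cat(nrow(x$path), "markers,", nrow(x$recombinations),
      "recombination event(s)\n")
  invisible(x)
}

#' @export
print.linkage_scan <- function(x, ...) {
  stat <- if (x$model_name == "npl") "z" else "hlod"
  pk <- x$curve[which.max(x$curve[[stat]]), ]
  cat("Multipoint linkage scan (", x$model_name, ", ASM", x$asm, ")\n",
      sep = "")
  cat(x$n_families, "families,", nrow(x$curve), "positions\n")
  cat("peak ", stat, " = ", signif(pk[[stat]], 4), " at ", pk$marker,
      " (chr", pk$chrom, ", ", pk$cm, " cM)\n", sep = "")
  invisible(x)
}
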