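# Synthetic cohort generator: pedigrees, dense biallelic marker maps,
# genotypes with an optional linked disease locus, hierarchical diagnoses,
# and CNVs segregating on founder haplotypes.  Emits exactly the dialects
# the IO module reads, so every other module is testable without any
# external data.

#' Simulation configuration
#'
#' Default values emulate the structure of the 46-pedigree bipolar cohort
#' the package's methods were designed around: 46 mostly three-generation
#' families averaging 7.96 members, 22 autosomes with ~942 markers each at
#' 0.169 cM spacing, founder minor-allele frequencies uniform on
#' (0.2, 0.8), ~61 CNV events per family with lognormal lengths truncated
#' at 10,046 bp (mean ~110 kb) and an even deletion/duplication split, a
#' bipolar-spectrum diagnosis mixture dominated by BP-I, and 97/366 of
#' individuals without DNA.
#'
#' @param n_families number of families.
#' @param template "cohort46" (deterministic three-generation structure
#'   matching the reference totals when `n_families = 46`, random families
#'   with the same size distribution otherwise), "nuclear" or "trio".
#' @param sibship_mean mean sibship size for the "nuclear" template.
#' @param n_chromosomes,markers_per_chrom,spacing_cm marker map layout.
#' @param maf_range range of founder allele-1 frequencies.
#' @param disease disease model from [disease_model()], or `NULL` for a
#'   null cohort (affection independent of genotype).
#' @param linked_fraction fraction of families in which the disease locus
#'   segregates at the mapped position (the remainder segregate an
#'   unlinked locus, mirroring locus heterogeneity).
#' @param disease_chrom,disease_cm position of the latent disease locus
#'   (defaults to the middle of chromosome 1).  The locus is never written
#'   to the marker output; linkage must be detected through flanking
#'   markers.
#' @param cnv_events_per_family Poisson mean of random CNV events per
#'   family.
#' @param cnv_min_length,cnv_meanlog,cnv_sdlog CNV length distribution
#'   (lognormal, truncated below).
#' @param cnv_del_prob probability a CNV event is a deletion.
#' @param cnv_placement "random" or "on_risk_haplotype" (linked families
#'   get one CNV planted on the risk haplotype overlapping the disease
#'   locus; requires a disease model).
#' @param breakpoint_jitter per-carrier fractional shrink of each CNV end,
#'   emulating call-boundary noise while keeping the shared intersection
#'   non-empty.
#' @param diagnosis_mixture probabilities of BP-I / SABP / BP-II / RUDD
#'   among affected individuals.
#' @param unaffected_mixture probabilities of never-ill / other mental
#'   disorder among unaffected individuals.
#' @param null_affected_rate affection probability in a null cohort
#'   (emulating multiplex ascertainment).
#' @param min_affected_per_family multiplex ascertainment: each family's
#'   gene drop and phenotypes are re-drawn until at least this many members
#'   are affected (up to 200 attempts), emulating the selection of
#'   high-liability families.  0 disables ascertainment.
#' @param untyped_fraction fraction of individuals without DNA.
#' @param genotype_missing_rate per-genotype missingness among typed
#'   individuals.
#' @param seed integer seed.
#' @return a validated configuration list of class `sim_config`.
#' @export
sim_config <- function(n_families = 46,
                       template = c("cohort46", "nuclear", "trio"),
                       sibship_mean = 3,
                       n_chromosomes = 22,
                       markers_per_chrom = 942,
                       spacing_cm = 0.169,
                       maf_range = c(0.2, 0.8),
                       disease = NULL,
                       linked_fraction = 0,
                       disease_chrom = 1,
                       disease_cm = NULL,
                       cnv_events_per_family = 61,
                       cnv_min_length = 10046,
                       cnv_meanlog = log(53000),
                       cnv_sdlog = 1.2,
                       cnv_del_prob = 1417 / 2806,
                       cnv_placement = c("random", "on_risk_haplotype"),
                       breakpoint_jitter = 0.03,
                       diagnosis_mixture = c(BP_I = 168, SABP = 9,
                                             BP_II = 9, RUDD = 12) / 198,
                       unaffected_mixture = c(NEVER_ILL = 0.9,
                                              OTHER_MENTAL = 0.1),
                       null_affected_rate = 0.48,
                       min_affected_per_family = 2,
                       untyped_fraction = 97 / 366,
                       genotype_missing_rate = 0.002,
                       seed = NULL) {
  template <- match.arg(template)
  cnv_placement <- match.arg(cnv_placement)
  cfg <- as.list(environment())
  if (n_families < 1) abort_config("n_families must be positive")
  if (markers_per_chrom < 2) abort_config("need at least 2 markers per chromosome")
  if (spacing_cm <= 0) abort_config("spacing_cm must be positive")
  probs <- c(linked_fraction, null_affected_rate, untyped_fraction,
             genotype_missing_rate, cnv_del_prob, diagnosis_mixture,
             unaffected_mixture)
  if (any(probs < 0) || any(probs > 1)) {
    abort_config("all probabilities must lie in [0, 1]")
  }
  if (cnv_placement == "on_risk_haplotype" && is.null(disease)) {
    abort_config("on_risk_haplotype placement requires a disease model")
  }
  structure(cfg, class = "sim_config")
}

#' Generate pedigree structures
#'
#' The "cohort46" template at its default size is deterministic and
#' reproduces the reference cohort totals exactly (46 families, 366
#' individuals, 147 founders, 219 non-founders, mean family size 7.96);
#' at other sizes, and for the other templates, families are drawn from
#' the same building blocks (a founder couple, two children, one or two
#' married-in spouses, and their own children).
#'
#' @param config a [sim_config()] list.
#' @return a pedigree tibble (diagnoses all `UNKNOWN`; assigned by
#'   [simulate_cohort()]).
#' @export
make_pedigrees <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_families
  tpl <- config$template
  if (tpl == "cohort46" && n == 46) {
    return(validate_pedigree(cohort46_pedigrees()))
  }
  fams <- lapply(seq_len(n), function(i) {
    fid <- sprintf("F%03d", i)
    switch(tpl,
      trio = build_family_tbl(fid, n_children = 1, spouses = 0,
                              grandchildren = integer(0)),
      nuclear = build_family_tbl(
        fid,
        # bounded sibship (1..5) keeps the inheritance-vector space small
        n_children = 1L + rbinom(1, 4, min(1, (config$sibship_mean - 1) / 4)),
        spouses = 0, grandchildren = integer(0)),
      cohort46 = {
        e <- 1L + rbinom(1, 1, 9 / 46)
        k <- 2L + rbinom(e, 1, 17 / 55)
        build_family_tbl(fid, n_children = 2L, spouses = e,
                         grandchildren = k)
      })
  })
  validate_pedigree(dplyr::bind_rows(fams))
}

# one family: founder couple, n_children, the first `spouses` children get
# a married-in spouse and their own children (grandchildren[j] each)
build_family_tbl <- function(fid, n_children, spouses, grandchildren) {
  if (n_children < 1) abort_config("family template needs at least one child")
  if (spouses > n_children) spouses <- n_children
  id <- function(k) sprintf("%s-%02d", fid, k)
  rows <- list(
    tibble::tibble(family_id = fid, individual_id = id(1),
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "male"),
    tibble::tibble(family_id = fid, individual_id = id(2),
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "female")
  )
  nxt <- 3L
  kids <- character(n_children)
  kid_sex <- character(n_children)
  for (c_i in seq_len(n_children)) {
    kids[c_i] <- id(nxt)
    kid_sex[c_i] <- if (c_i %% 2 == 1) "female" else "male"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      family_id = fid, individual_id = kids[c_i],
      father_id = id(1), mother_id = id(2), sex = kid_sex[c_i])
    nxt <- nxt + 1L
  }
  for (s_i in seq_len(spouses)) {
    if (spouses == 0) break
    sp <- id(nxt); nxt <- nxt + 1L
    sp_sex <- if (kid_sex[s_i] == "female") "male" else "female"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      family_id = fid, individual_id = sp, father_id = NA_character_,
      mother_id = NA_character_, sex = sp_sex)
    fa <- if (sp_sex == "male") sp else kids[s_i]
    mo <- if (sp_sex == "male") kids[s_i] else sp
    for (g_i in seq_len(grandchildren[s_i])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family_id = fid, individual_id = id(nxt), father_id = fa,
        mother_id = mo, sex = if (g_i %% 2 == 1) "male" else "female")
      nxt <- nxt + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sex <- factor(out$sex, levels = SEX_LEVELS)
  out$diagnosis <- factor("UNKNOWN", levels = DIAGNOSIS_LEVELS)
  out$has_dna <- TRUE
  out
}

# deterministic 46-family structure: 9 families with two married-in
# spouses, 37 with one (55 couples); the first 17 couples (in family
# order) have 3 children, the rest 2 -> 147 founders + 219 non-founders
cohort46_pedigrees <- function() {
  couple <- 0L
  fams <- lapply(seq_len(46), function(i) {
    e <- if (i <= 9) 2L else 1L
    k <- integer(e)
    for (j in seq_len(e)) {
      couple <<- couple + 1L
      k[j] <- if (couple <= 17) 3L else 2L
    }
    build_family_tbl(sprintf("F%03d", i), n_children = 2L, spouses = e,
                     grandchildren = k)
  })
  dplyr::bind_rows(fams)
}

#' Simulate a complete cohort
#'
#' Generates pedigrees, a genetic map, founder haplotypes, genotypes,
#' diagnoses and CNV calls.  When a disease model is configured, a latent
#' disease locus (never written to the marker output) segregates at the
#' mapped position in the linked fraction of families and at an unlinked
#' locus in the rest; diagnoses follow the model's penetrances, with
#' bipolar-spectrum subtype labels drawn from the configured mixture
#' independently of genotype.  CNV events are placed on founder haplotypes
#' and transmitted with them; in linked families with
#' `cnv_placement = "on_risk_haplotype"` one event overlaps the disease
#' locus on the risk haplotype.
#'
#' @param config a [sim_config()] list.
#' @param dir optional output directory; when given, PED, MAP, CNV and
#'   truth tables are written there.
#' @return a list with elements `pedigree`, `genotypes`, `map`, `freqs`
#'   (true simulation frequencies), `cnv_calls` and `truth` (a list with
#'   the planted locus, linked families, risk haplotypes and all CNV
#'   events; the analysis pipeline never reads it).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ped <- if (config$template == "cohort46" && config$n_families == 46) {
    validate_pedigree(cohort46_pedigrees())
  } else {
    cfg2 <- config
    cfg2$seed <- NULL
    make_pedigrees(cfg2)
  }
  map <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    cm <- (seq_len(config$markers_per_chrom) - 1) * config$spacing_cm
    tibble::tibble(chrom = as.character(ch),
                   marker = sprintf("c%02dm%04d", ch,
                                    seq_len(config$markers_per_chrom)),
                   cm = cm, bp = round(cm * 1e6) + 1)
  })
  freq1 <- runif(nrow(map), config$maf_range[1], config$maf_range[2])
  freqs <- tibble::tibble(marker = map$marker, freq1 = freq1)

  has_disease <- !is.null(config$disease)
  disease_cm <- config$disease_cm %||%
    stats::median(map$cm[map$chrom == as.character(config$disease_chrom)])
  if (has_disease &&
      !as.character(config$disease_chrom) %in% map$chrom) {
    abort_config("disease_chrom outside the simulated map")
  }
  if (has_disease) {
    rng <- range(map$cm[map$chrom == as.character(config$disease_chrom)])
    if (disease_cm < rng[1] || disease_cm > rng[2]) {
      abort_config("disease locus outside the mapped range")
    }
  }
  fam_ids <- unique(ped$family_id)
  n_linked <- round(config$linked_fraction * length(fam_ids))
  linked <- if (has_disease && n_linked > 0) {
    sample(fam_ids, n_linked)
  } else {
    character(0)
  }

  engines <- lapply(split(ped, ped$family_id)[fam_ids], build_family_engine)
  chroms <- split(seq_len(nrow(map)), map$chrom)
  chroms <- chroms[unique(map$chrom)]
  ped_order <- dplyr::bind_rows(lapply(engines, function(e) e$ped))
  n_total <- nrow(ped_order)
  geno <- matrix(0L, n_total, nrow(map))
  events <- list()
  truth_risk <- list()
  diag_all <- character(0)

  at <- 0L
  for (f in fam_ids) {
    eng <- engines[[f]]
    n <- length(eng$ids)
    nslots <- eng$nslots
    # family CNV events (random placement on founder haplotypes)
    n_ev <- rpois(1, config$cnv_events_per_family)
    ev <- NULL
    if (n_ev > 0) {
      ev_chrom <- sample(names(chroms), n_ev, replace = TRUE)
      ev_len <- pmax(stats::rlnorm(n_ev, config$cnv_meanlog, config$cnv_sdlog),
                     config$cnv_min_length / (1 - 2 * config$breakpoint_jitter))
      ev <- tibble::tibble(
        chrom = ev_chrom,
        center_bp = vapply(ev_chrom, function(ch) {
          round(runif(1, min(map$bp[chroms[[ch]]]), max(map$bp[chroms[[ch]]])))
        }, numeric(1)),
        length_bp = round(ev_len),
        state = ifelse(runif(n_ev) < config$cnv_del_prob,
                       "deletion", "duplication"),
        hap_slot = sample(nslots, n_ev, replace = TRUE),
        planted = FALSE
      )
    }
    is_linked <- f %in% linked
    risk_slot <- if (has_disease) sample(nslots, 1) else NA_integer_
    if (is_linked && config$cnv_placement == "on_risk_haplotype") {
      dbp <- round(disease_cm * 1e6) + 1
      plen <- max(round(stats::rlnorm(1, config$cnv_meanlog, config$cnv_sdlog)),
                  config$cnv_min_length / (1 - 2 * config$breakpoint_jitter))
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        chrom = as.character(config$disease_chrom), center_bp = dbp,
        length_bp = round(plen),
        state = if (runif(1) < config$cnv_del_prob) "deletion" else "duplication",
        hap_slot = risk_slot, planted = TRUE))
    }
    # gene drop per chromosome with latent positions (disease locus and
    # CNV event centres) inserted into the chain; the whole family is
    # re-drawn until the multiplex ascertainment condition holds
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      slot_at <- list() # per event row: slotP/slotM at the event position
      disease_g <- integer(n)
      for (ch in names(chroms)) {
        j <- chroms[[ch]]
        extra_cm <- numeric(0)
        extra_tag <- character(0)
        if (!is.null(ev)) {
          ev_here <- which(ev$chrom == ch)
          if (length(ev_here)) {
            extra_cm <- c(extra_cm, (ev$center_bp[ev_here] - 1) / 1e6)
            extra_tag <- c(extra_tag, paste0("ev", ev_here))
          }
        }
        if (has_disease && is_linked &&
            ch == as.character(config$disease_chrom)) {
          extra_cm <- c(extra_cm, disease_cm)
          extra_tag <- c(extra_tag, "disease")
        }
        pos_cm <- c(map$cm[j], extra_cm)
        ord <- order(pos_cm, c(rep("", length(j)), extra_tag))
        theta <- haldane_theta(pmax(diff(pos_cm[ord]), 0))
        fr <- c(freq1[j], rep(0.5, length(extra_cm)))[ord]
        gd <- cl_gene_drop(eng$fa, eng$mo, fr, theta)
        back <- order(ord)
        marker_pos <- back[seq_along(j)]
        geno[at + seq_len(n), j] <- gd$geno[, marker_pos, drop = FALSE]
        for (t in seq_along(extra_tag)) {
          col <- back[length(j) + t]
          if (extra_tag[t] == "disease") {
            disease_g <- (gd$slotP[, col] == risk_slot) +
              (gd$slotM[, col] == risk_slot)
          } else {
            slot_at[[extra_tag[t]]] <- cbind(gd$slotP[, col], gd$slotM[, col])
          }
        }
      }
      if (has_disease && !is_linked) {
        # unlinked risk locus: independent single-position drop
        gd1 <- cl_gene_drop(eng$fa, eng$mo, 0.5, numeric(0))
        disease_g <- (gd1$slotP[, 1] == risk_slot) +
          (gd1$slotM[, 1] == risk_slot)
      }
      # diagnoses
      if (has_disease) {
        pr <- config$disease$f[disease_g + 1]
        affected <- runif(n) < pr
      } else {
        affected <- runif(n) < config$null_affected_rate
      }
      if (sum(affected) >= config$min_affected_per_family ||
          attempt >= 200L) {
        break
      }
    }
    diag <- ifelse(
      affected,
      sample(names(config$diagnosis_mixture), n, replace = TRUE,
             prob = config$diagnosis_mixture),
      sample(names(config$unaffected_mixture), n, replace = TRUE,
             prob = config$unaffected_mixture))
    diag_all <- c(diag_all, diag)
    # CNV carrier calls resolved through descent at the event position
    if (!is.null(ev)) {
      for (e_i in seq_len(nrow(ev))) {
        sl <- slot_at[[paste0("ev", e_i)]]
        if (is.null(sl) && isTRUE(ev$planted[e_i])) {
          # planted event shares the disease-locus descent
          carriers <- which(disease_g > 0)
        } else if (!is.null(sl)) {
          carriers <- which(sl[, 1] == ev$hap_slot[e_i] |
                              sl[, 2] == ev$hap_slot[e_i])
        } else {
          carriers <- integer(0)
        }
        events[[length(events) + 1L]] <- tibble::tibble(
          family_id = f, chrom = ev$chrom[e_i],
          center_bp = ev$center_bp[e_i], length_bp = ev$length_bp[e_i],
          state = ev$state[e_i], hap_slot = ev$hap_slot[e_i],
          planted = ev$planted[e_i],
          carrier_ids = list(eng$ids[carriers]))
      }
    }
    truth_risk[[f]] <- tibble::tibble(family_id = f, linked = is_linked,
                                      risk_slot = risk_slot)
    at <- at + n
  }

  ped_order$diagnosis <- factor(diag_all, levels = DIAGNOSIS_LEVELS)
  # missingness: untyped individuals plus sporadic missing genotypes
  untyped <- runif(n_total) < config$untyped_fraction
  ped_order$has_dna <- !untyped
  geno[untyped, ] <- 0L
  if (config$genotype_missing_rate > 0) {
    geno[matrix(runif(length(geno)) < config$genotype_missing_rate,
                nrow(geno))] <- 0L
  }
  genotypes <- dplyr::bind_cols(
    tibble::tibble(family_id = ped_order$family_id,
                   individual_id = ped_order$individual_id),
    tibble::as_tibble(`colnames<-`(geno, map$marker)))

  events <- if (length(events)) dplyr::bind_rows(events) else NULL
  cnv_calls <- build_cnv_calls(events, ped_order, config)
  truth <- list(
    disease_chrom = if (has_disease) as.character(config$disease_chrom) else NA,
    disease_cm = if (has_disease) disease_cm else NA,
    disease_bp = if (has_disease) round(disease_cm * 1e6) + 1 else NA,
    linked_families = linked,
    risk_haplotypes = dplyr::bind_rows(truth_risk),
    cnv_events = events
  )
  out <- list(pedigree = ped_order, genotypes = genotypes, map = map,
              freqs = freqs, cnv_calls = cnv_calls, truth = truth)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# carrier-level CNV call table with per-carrier breakpoint jitter
# (shrink-only, so the within-family intersection stays non-empty)
build_cnv_calls <- function(events, ped_order, config) {
  empty <- tibble::tibble(individual_id = character(),
                          family_id = character(), chrom = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          state = character(), length_bp = numeric())
  if (is.null(events)) return(empty)
  typed <- ped_order$individual_id[ped_order$has_dna]
  rows <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    carriers <- intersect(events$carrier_ids[[i]], typed)
    if (length(carriers) == 0) return(NULL)
    half <- events$length_bp[i] / 2
    s0 <- events$center_bp[i] - half
    e0 <- events$center_bp[i] + half
    jit <- config$breakpoint_jitter * events$length_bp[i]
    tibble::tibble(
      individual_id = carriers, family_id = events$family_id[i],
      chrom = events$chrom[i],
      start_bp = pmax(1, round(s0 + runif(length(carriers), 0, jit))),
      end_bp = round(e0 - runif(length(carriers), 0, jit)),
      state = events$state[i])
  })
  if (nrow(rows) == 0) return(empty)
  rows$length_bp <- rows$end_bp - rows$start_bp + 1
  rows
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(cohort$pedigree, file.path(dir, "cohort.ped"),
                 genotypes = cohort$genotypes)
  write_genetic_map(cohort$map, file.path(dir, "cohort.map"))
  write_cnv_calls(cohort$cnv_calls, file.path(dir, "cohort.cnv.tsv"))
  readr::write_tsv(cohort$truth$risk_haplotypes,
                   file.path(dir, "truth_families.tsv"), progress = FALSE)
  if (!is.null(cohort$truth$cnv_events)) {
    ev <- cohort$truth$cnv_events
    ev$carrier_ids <- vapply(ev$carrier_ids, paste, character(1),
                             collapse = ",")
    readr::write_tsv(ev, file.path(dir, "truth_cnv_events.tsv"),
                     progress = FALSE)
  }
  loc <- tibble::tibble(disease_chrom = cohort$truth$disease_chrom,
                        disease_cm = cohort$truth$disease_cm,
                        disease_bp = cohort$truth$disease_bp)
  readr::write_tsv(loc, file.path(dir, "truth_locus.tsv"), progress = FALSE)
  invisible(dir)
}
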