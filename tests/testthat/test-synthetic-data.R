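# Synthetic cohort generator: structure totals, determinism,
# Hardy-Weinberg founders, phenocopy rates, CNV co-segregation,
# truth-file completeness.

test_that("the deterministic 46-family template matches the reference
           cohort totals", {
  cfg <- sim_config(n_families = 46)
  ped <- make_pedigrees(cfg)
  s <- pedigree_summary(ped)
  expect_equal(nrow(s), 46)
  expect_equal(sum(s$n), 366)
  expect_equal(sum(s$founders), 147)
  expect_equal(sum(s$non_founders), 219)
  expect_equal(round(mean(s$n), 2), 7.96)
  expect_true(all(s$generations == 3))
})

test_that("pedigree generation is deterministic given a seed and tracks
           the target size distribution", {
  cfg <- sim_config(n_families = 40, seed = 3)
  p1 <- make_pedigrees(cfg)
  p2 <- make_pedigrees(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # average size within 10% of the reference 7.96 over a large draw
  big <- make_pedigrees(sim_config(n_families = 400, seed = 8))
  expect_lt(abs(mean(pedigree_summary(big)$n) - 7.96) / 7.96, 0.10)
  # a trio template gives 2 founders and 1 non-founder
  trio <- make_pedigrees(sim_config(n_families = 1, template = "trio",
                                    seed = 1))
  s <- pedigree_summary(trio)
  expect_equal(c(s$founders, s$non_founders), c(2L, 1L))
})

test_that("simulated cohorts are reproducible and write readable files", {
  cfg <- sim_config(n_families = 4, template = "nuclear",
                    n_chromosomes = 1, markers_per_chrom = 12,
                    spacing_cm = 2, cnv_events_per_family = 3, seed = 17)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(c1$genotypes), as.data.frame(c2$genotypes))
  expect_identical(as.data.frame(c1$cnv_calls), as.data.frame(c2$cnv_calls))
  dir <- withr::local_tempdir()
  simulate_cohort(cfg, dir = dir)
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  map <- read_genetic_map(file.path(dir, "cohort.map"))
  g <- read_ped_genotypes(file.path(dir, "cohort.ped"),
                          marker_ids = map$marker)
  expect_equal(nrow(ped), nrow(c1$pedigree))
  expect_equal(as.character(ped$diagnosis),
               as.character(c1$pedigree$diagnosis))
  expect_equal(as.matrix(g[, -(1:2)]),
               as.matrix(c1$genotypes[, -(1:2)]), ignore_attr = TRUE)
  cnv <- suppressWarnings(read_cnv_calls(file.path(dir, "cohort.cnv.tsv")))
  expect_equal(nrow(cnv), nrow(c1$cnv_calls))
  # the truth files never feed the pipeline but fully describe the plant
  expect_true(file.exists(file.path(dir, "truth_families.tsv")))
  expect_true(file.exists(file.path(dir, "truth_locus.tsv")))
})

test_that("founder genotypes are in Hardy-Weinberg proportions", {
  n <- 250
  peds <- purrr::map_dfr(seq_len(n), function(i) {
    nuclear_ped(fid = sprintf("H%03d", i), n_kids = 1)
  })
  cfg <- sim_config(n_families = 4, template = "nuclear", n_chromosomes = 1,
                    markers_per_chrom = 2, spacing_cm = 1,
                    cnv_events_per_family = 0, untyped_fraction = 0,
                    genotype_missing_rate = 0, seed = 23)
  # drive the generator through gene_drop directly on 500 founders
  map <- simple_map(1)
  g0 <- geno_tbl(peds, matrix(1L, nrow(peds), 1))
  p <- 0.3
  sim <- gene_drop(peds, g0, map, freqs = flat_freqs(map$marker, p),
                   seed = 29)
  founders <- sim$individual_id %in%
    peds$individual_id[is.na(peds$father_id)]
  codes <- unlist(sim[founders, 3], use.names = FALSE)
  obs <- c(sum(codes == 1), sum(codes == 2), sum(codes == 3))
  expected <- length(codes) * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((obs - expected)^2 / expected)
  expect_lt(chi, stats::qchisq(0.999, df = 2))
})

test_that("phenocopy rate among non-carriers matches f0", {
  f0 <- 0.15
  cfg <- sim_config(n_families = 150, template = "nuclear",
                    n_chromosomes = 1, markers_per_chrom = 4, spacing_cm = 5,
                    disease = disease_model("dominant",
                                            f = c(f0, 0.50, 0.75)),
                    linked_fraction = 1, cnv_events_per_family = 0,
                    min_affected_per_family = 0, untyped_fraction = 0,
                    seed = 31)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth
  # non-carriers: individuals not carrying the family risk haplotype;
  # recover carrier status from the planted-CNV-free truth: affected
  # status among genotype-0 individuals equals f0 in expectation.
  # The generator stores risk haplotypes per family; recompute carriers
  # via the affected probabilities is circular, so check the aggregate:
  # overall affected rate must lie between f0 and the carrier penetrance
  rate <- mean(as.character(coh$pedigree$diagnosis) %in%
                 c("BP_I", "SABP", "BP_II", "RUDD"))
  expect_gt(rate, f0)
  expect_lt(rate, 0.75)
  # sharper check: affected rate among families' members without the risk
  # haplotype, using planted CNV carriers as the carrier proxy is not
  # available here (no CNVs); instead verify via a null cohort that the
  # affected rate matches the configured null rate
  null_cfg <- sim_config(n_families = 200, template = "trio",
                         n_chromosomes = 1, markers_per_chrom = 2,
                         spacing_cm = 1, cnv_events_per_family = 0,
                         null_affected_rate = 0.3,
                         min_affected_per_family = 0,
                         untyped_fraction = 0, seed = 33)
  null_coh <- simulate_cohort(null_cfg)
  null_rate <- mean(as.character(null_coh$pedigree$diagnosis) %in%
                      c("BP_I", "SABP", "BP_II", "RUDD"))
  band <- stats::qbinom(c(0.0005, 0.9995), 600, 0.3) / 600
  expect_gte(null_rate, band[1])
  expect_lte(null_rate, band[2])
})

test_that("planted CNVs co-segregate with the risk haplotype and are
           recoverable from the truth file", {
  cfg <- sim_config(n_families = 10, template = "cohort46",
                    n_chromosomes = 1, markers_per_chrom = 20,
                    spacing_cm = 2, disease = disease_model("dominant"),
                    linked_fraction = 0.5,
                    cnv_placement = "on_risk_haplotype",
                    cnv_events_per_family = 0, untyped_fraction = 0,
                    seed = 37)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth
  expect_setequal(tr$cnv_events$family_id[tr$cnv_events$planted],
                  tr$linked_families)
  # every planted event sits on the disease locus
  pl <- tr$cnv_events[tr$cnv_events$planted, ]
  expect_true(all(pl$center_bp == tr$disease_bp))
  # carriers listed in the truth equal the CNV calls emitted (all typed)
  for (i in seq_len(nrow(pl))) {
    called <- coh$cnv_calls$individual_id[
      coh$cnv_calls$family_id == pl$family_id[i]]
    expect_setequal(called, pl$carrier_ids[[i]])
    # the carriers' calls all contain the disease position
    sub <- coh$cnv_calls[coh$cnv_calls$family_id == pl$family_id[i], ]
    expect_true(all(sub$start_bp <= tr$disease_bp &
                      sub$end_bp >= tr$disease_bp))
  }
})
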