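# Inheritance-vector engine and linkage statistics, checked against
# closed forms and exhaustive enumeration oracles.

test_that("haldane map function matches its closed form", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(10), (1 - exp(-0.2)) / 2)
  expect_lt(abs(haldane_theta(1e6) - 0.5), 1e-12)
  expect_error(haldane_theta(-1), class = "cnvlink_domain_error")
})

test_that("singlepoint likelihoods match founder-config enumeration", {
  set.seed(31)
  ped <- nuclear_ped(n_kids = 2)
  eng <- cnvlink:::build_family_engine(ped)
  for (rep in 1:25) {
    geno <- sample(0:3, 4, replace = TRUE)
    p <- runif(1, 0.05, 0.95)
    got <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM,
                                    matrix(as.integer(geno)), p,
                                    eng$nslots)[, 1]
    expect_equal(got, oracle_marker_lik(eng, geno, p), tolerance = 1e-12)
  }
  # untyped family -> constant likelihood
  got0 <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM,
                                   matrix(rep(0L, 4)), 0.5, eng$nslots)[, 1]
  expect_true(all(got0 == 1))
  # opposite-homozygote parents with het child: every meiosis uninformative
  got1 <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM,
                                   matrix(c(1L, 3L, 2L, 0L)), 0.4,
                                   eng$nslots)[, 1]
  expect_equal(got1, rep(got1[1], eng$V))
})

test_that("half-sib likelihoods separate allele-sharing vectors", {
  # half sibs through a typed heterozygous father, kids both 1/1:
  # vectors where both receive the same paternal allele must score higher
  ped <- make_ped("H", c("dad", "m1", "m2", "k1", "k2"),
                  c(NA, NA, NA, "dad", "dad"),
                  c(NA, NA, NA, "m1", "m2"))
  eng <- cnvlink:::build_family_engine(ped)
  geno <- c(2L, 0L, 0L, 1L, 1L) # dad het, both kids hom-1
  lik <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM, matrix(geno), 0.5,
                                  eng$nslots)[, 1]
  expect_equal(lik, oracle_marker_lik(eng, geno, 0.5), tolerance = 1e-12)
  k1 <- match("k1", eng$ids)
  k2 <- match("k2", eng$ids)
  share <- eng$slotP[, k1] == eng$slotP[, k2]
  expect_gt(min(lik[share]), max(lik[!share]))
})

test_that("posterior, Viterbi and likelihood match exhaustive paths", {
  set.seed(57)
  peds <- list(
    nuclear_ped(n_kids = 1),                      # 2 bits
    make_ped("H", c("dad", "m1", "m2", "k1"),     # parent chain, 2 bits
             c(NA, NA, "dad", "dad"), c(NA, NA, "m1", "m2"))
  )
  for (ped in peds) {
    eng <- cnvlink:::build_family_engine(ped)
    n <- nrow(ped)
    for (rep in 1:6) {
      M <- sample(2:(if (eng$B <= 2) 4 else 3), 1)
      theta <- runif(M - 1, 0, 0.45)
      repeat {
        geno <- matrix(sample(0:3, n * M, replace = TRUE,
                              prob = c(0.15, 0.3, 0.3, 0.25)), n, M)
        liks <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM, geno,
                                         rep(0.4, M), eng$nslots)
        if (all(colSums(liks) > 0)) break
      }
      got <- cnvlink:::cl_forward_backward(liks, theta)
      ora <- oracle_hmm(liks, theta, eng$B)
      expect_equal(got$post, ora$post, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(exp(got$loglik), ora$lik, tolerance = 1e-8)
      expect_equal(cnvlink:::cl_viterbi(liks, theta), ora$best)
      # posterior columns sum to one
      expect_true(all(abs(colSums(got$post) - 1) < 1e-9))
    }
  }
})

test_that("single-marker posterior equals normalised singlepoint likelihood", {
  ped <- nuclear_ped(n_kids = 2)
  eng <- cnvlink:::build_family_engine(ped)
  lik <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM,
                                  matrix(c(2L, 2L, 1L, 2L)), 0.3,
                                  eng$nslots)
  post <- cnvlink:::cl_forward_backward(lik, numeric(0))$post
  expect_equal(post[, 1], lik[, 1] / sum(lik[, 1]), tolerance = 1e-12)
})

test_that("S_all for an affected sib pair is 1 / 1.25 / 1.5 by IBD state", {
  ped <- nuclear_ped(n_kids = 2)
  s <- sall_scores(ped, c("A-K1", "A-K2"))
  eng <- cnvlink:::build_family_engine(ped)
  k <- match(c("A-K1", "A-K2"), eng$ids)
  ibd <- vapply(seq_len(eng$V), function(v) {
    sum(c(eng$slotP[v, k[1]] == eng$slotP[v, k[2]],
          eng$slotM[v, k[1]] == eng$slotM[v, k[2]]))
  }, numeric(1))
  expect_equal(unique(s[ibd == 0]), 1.0)
  expect_equal(unique(s[ibd == 1]), 1.25)
  expect_equal(unique(s[ibd == 2]), 1.5)
})

test_that("NPL Z is zero on uniform posteriors and maximal on full sharing", {
  ped <- nuclear_ped(n_kids = 2)
  map <- simple_map(3)
  # untyped family: posterior uniform -> Z = 0 everywhere
  g0 <- geno_tbl(ped, matrix(0L, 4, 3))
  scan0 <- suppressWarnings(
    linkage_scan(ped, g0, map, model = "npl", asm = 1,
                 freqs = flat_freqs(map$marker)))
  expect_equal(scan0$curve$z, rep(0, 3), tolerance = 1e-9)
  expect_equal(scan0$curve$ic, rep(0, 3), tolerance = 1e-12)
  # parents 1/2 x 1/2 with both kids 1/1: kids share both alleles IBD at
  # the typed marker; Z approaches the per-family maximum (S=1.5)
  codes <- matrix(c(2L, 2L, 1L, 1L), 4, 3)
  scan1 <- linkage_scan(ped, geno_tbl(ped, codes), map, model = "npl",
                        asm = 1, freqs = flat_freqs(map$marker))
  s <- sall_scores(ped, c("A-K1", "A-K2"))
  zmax <- (1.5 - mean(s)) / sqrt(mean(s^2) - mean(s)^2)
  # hom-1/hom-1 kids are compatible with IBD<2 vectors too, so Z is close
  # to but below the algebraic maximum
  expect_gt(scan1$curve$z[1], 0.8 * zmax)
  expect_lte(scan1$curve$z[1], zmax + 1e-9)
})

test_that("Kong-Cox LOD matches a dense grid maximisation", {
  cases <- list(c(0, 0, 0), c(2, -1), c(1.4, 0.3, -0.6, 2.2), c(-1, -2))
  for (z in cases) {
    got <- kong_cox_lod(z)
    dmax <- if (min(z) < 0) 0.999 * (-1 / min(z)) else 10
    grid <- seq(0, dmax, length.out = 200001)
    vals <- vapply(grid, function(d) sum(log10(1 + d * z)), numeric(1))
    expect_equal(got$lod, max(0, max(vals)), tolerance = 1e-6)
    if (max(vals) > 1e-8) {
      expect_equal(got$delta, grid[which.max(vals)], tolerance = 1e-3)
    }
  }
  # boundary behaviour of the one-sided mixture p-value
  expect_equal(kong_cox_lod(c(0, 0))$p, 0.5)
  expect_equal(kong_cox_lod(c(0, 0))$lod, 0)
  expect_equal(kong_cox_lod(c(0, 0))$delta, 0)
  expect_gt(kong_cox_lod(c(3, 2))$lod, 0)
  expect_lt(kong_cox_lod(c(3, 2))$p, 0.05)
})

test_that("HLOD matches grid maximisation and respects its bounds", {
  cases <- list(c(1, 2, 0.5), c(3, -3), c(0, 0), c(-0.5, -1), c(2, -0.2, 1))
  for (lods in cases) {
    got <- hlod(lods)
    grid <- seq(0, 1, by = 1e-4)
    vals <- vapply(grid, function(a) sum(log10(a * 10^lods + 1 - a)),
                   numeric(1))
    expect_equal(got$hlod, max(0, max(vals)), tolerance = 1e-6)
    expect_gte(got$hlod, 0)
    expect_gte(got$alpha, 0)
    expect_lte(got$alpha, 1)
    # admissible bounds: at least the homogeneity value, at most the sum
    # of positive LODs
    expect_gte(got$hlod + 1e-9, max(0, sum(lods)))
    expect_lte(got$hlod, sum(pmax(lods, 0)) + 1e-9)
  }
  # all families positive with at least one > 0: alpha-hat = 1, HLOD = sum
  allpos <- hlod(c(1.2, 0.4, 2))
  expect_equal(allpos$alpha, 1, tolerance = 1e-4)
  expect_equal(allpos$hlod, 3.6, tolerance = 1e-6)
  expect_equal(hlod(c(0, 0))$alpha, 0)
})

test_that("parametric LOD is zero on uniform posteriors and matches the
           enumeration oracle", {
  ped <- nuclear_ped(n_kids = 2)
  eng <- cnvlink:::build_family_engine(ped)
  dm <- disease_model("recessive")
  phen <- c(1L, 1L, 2L, 2L)
  pl <- cnvlink:::cl_phen_lik(eng$slotP, eng$slotM, phen, eng$is_founder,
                              dm$q, dm$f, eng$nslots)
  expect_equal(pl, oracle_phen_lik(eng, phen, dm$q, dm$f),
               tolerance = 1e-12)
  unif <- matrix(1 / eng$V, eng$V, 3)
  expect_equal(cnvlink:::family_param_lod(pl, unif), rep(0, 3),
               tolerance = 1e-12)
  # all-unknown phenotypes: likelihood constant, LOD identically zero
  pl0 <- cnvlink:::cl_phen_lik(eng$slotP, eng$slotM, rep(0L, 4),
                               eng$is_founder, dm$q, dm$f, eng$nslots)
  expect_equal(pl0, rep(1, eng$V), tolerance = 1e-12)
})

test_that("phase-known dominant pedigree reaches k*log10(2)", {
  # three-generation phase-known segregation: homozygous-typed affected
  # grandfather pins the phase of the affected father (1/2, allele 2
  # grandpaternal); k children with no recombinants at theta = 0 and
  # near-degenerate model (q -> 0, penetrances (0, 1, 1)) give
  # LOD = k * log10(2)
  k <- 3
  kids <- sprintf("K%d", seq_len(k))
  kid_aff <- c(TRUE, TRUE, FALSE)
  ped <- make_ped("G",
                  c("GF", "GM", "F", "M", kids),
                  c(NA, NA, "GF", NA, rep("F", k)),
                  c(NA, NA, "GM", NA, rep("M", k)),
                  diagnosis = c("BP_I", "NEVER_ILL", "BP_I", "NEVER_ILL",
                                ifelse(kid_aff, "BP_I", "NEVER_ILL")))
  eng <- cnvlink:::build_family_engine(ped)
  dm <- disease_model("dominant", q = 1e-9, f = c(0, 1, 1))
  geno_of <- stats::setNames(
    c(3L, 1L, 2L, 1L, ifelse(kid_aff, 2L, 1L)),
    c("GF", "GM", "F", "M", kids))
  geno <- matrix(geno_of[eng$ids], ncol = 1)
  lik <- cnvlink:::cl_marker_liks(eng$slotP, eng$slotM, geno, 0.5,
                                  eng$nslots)
  post <- cnvlink:::cl_forward_backward(lik, numeric(0))$post
  phen <- ifelse(as.character(apply_asm(ped, 1)$status)[
    match(eng$ids, ped$individual_id)] == "affected", 2L, 1L)
  pl <- cnvlink:::cl_phen_lik(eng$slotP, eng$slotM, phen, eng$is_founder,
                              dm$q, dm$f, eng$nslots)
  lod <- cnvlink:::family_param_lod(pl, post)
  expect_equal(lod, k * log10(2), tolerance = 0.01)
})

test_that("information content spans its closed-form anchor points", {
  unif <- matrix(0.25, 4, 1)
  expect_equal(information_content(unif), 0)
  point <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(information_content(point), 1)
  half <- matrix(c(0.5, 0.5, 0, 0), 4, 1)
  expect_equal(information_content(half), 0.5)
})

test_that("masking markers to missing degrades information content", {
  ped <- nuclear_ped(n_kids = 2)
  map <- simple_map(4, spacing_cm = 5)
  codes <- matrix(c(2L, 2L, 1L, 3L), 4, 4)
  fr <- flat_freqs(map$marker, 0.5)
  ic_of <- function(g) {
    linkage_scan(ped, g, map, model = "npl", asm = 1, freqs = fr)$curve$ic
  }
  full <- ic_of(geno_tbl(ped, codes))
  for (nmask in 1:3) {
    masked <- codes
    masked[, seq_len(nmask)] <- 0L
    expect_true(all(ic_of(geno_tbl(ped, masked)) <= full + 1e-9))
  }
  all_missing <- suppressWarnings(ic_of(geno_tbl(ped, codes * 0L)))
  expect_equal(all_missing, rep(0, 4), tolerance = 1e-12)
})

test_that("support intervals follow the grid convention", {
  cm <- seq(0, 50, by = 5)
  tri <- 3 - abs(cm - 25) / 5
  si <- support_interval(cm, tri, drop = 1)
  expect_equal(si$peak_cm, 25)
  expect_equal(si$start_cm, 20)
  expect_equal(si$end_cm, 30)
  # drop larger than the curve range spans everything
  wide <- support_interval(cm, tri, drop = 10)
  expect_equal(c(wide$start_cm, wide$end_cm), c(0, 50))
  expect_warning(flat <- support_interval(cm, rep(1, length(cm))), "flat")
  expect_equal(c(flat$start_cm, flat$end_cm), c(0, 50))
})

test_that("pedigree screening applies single and overlap criteria", {
  cm <- seq(0, 40, by = 5)
  curve <- function(f, peak, at) {
    tibble::tibble(family_id = f, chrom = "1", cm = cm,
                   score = pmax(peak - abs(cm - at) / 5, 0))
  }
  fc <- dplyr::bind_rows(
    curve("single12", 1.2, 20), # selected on its own
    curve("ovlA", 1.05, 20),    # selected via overlap with ovlB
    curve("ovlB", 1.05, 25),
    curve("alone", 1.05, 20) |> dplyr::mutate(chrom = "2"), # no partner
    curve("weak", 0.6, 20)
  )
  sel <- screen_pedigrees(fc)
  expect_equal(sel$selected[sel$family_id == "single12"], TRUE)
  expect_equal(sel$reason[sel$family_id == "single12"], "single")
  expect_true(all(sel$selected[sel$family_id %in% c("ovlA", "ovlB")]))
  expect_true(all(sel$reason[sel$family_id %in% c("ovlA", "ovlB")] ==
                    "overlap"))
  expect_false(sel$selected[sel$family_id == "alone"])
  expect_false(sel$selected[sel$family_id == "weak"])
})

test_that("Viterbi places an obligate recombinant between informative
           markers and reconstructs phased haplotypes", {
  # father 1/2, mother 1/1 at four markers; K1 and K2 carry the paternal
  # allele 2 everywhere, K3 switches from allele 2 to allele 1 between
  # markers 2 and 3: one obligate crossover, cheapest in K3's paternal
  # meiosis (a single bit flip instead of two)
  ped <- nuclear_ped(n_kids = 3)
  map <- simple_map(4, spacing_cm = 10)
  codes <- rbind(rep(2L, 4), rep(1L, 4),
                 rep(2L, 4), rep(2L, 4),
                 c(2L, 2L, 1L, 1L))
  vh <- viterbi_haplotypes(ped, geno_tbl(ped, codes), map,
                           family = "A", chromosome = "1",
                           freqs = flat_freqs(map$marker))
  expect_equal(nrow(vh$recombinations), 1)
  expect_equal(vh$recombinations$meiosis, "paternal")
  expect_equal(vh$recombinations$marker_before, "m2")
  expect_equal(vh$recombinations$marker_after, "m3")
  expect_equal(vh$recombinations$individual_id, "A-K3")
  # phasing: the father is heterozygous with one allele per haplotype,
  # and K1's paternal allele is 2 at every marker
  h1 <- vh$haplotypes[vh$haplotypes$marker == "m1", ]
  dad <- h1[h1$individual_id == "A-P1", ]
  expect_setequal(c(dad$allele_pat, dad$allele_mat), c(1L, 2L))
  k1 <- vh$haplotypes[vh$haplotypes$individual_id == "A-K1", ]
  expect_true(all(k1$allele_pat == 2L))
  # no-recombination data decodes to a constant path
  flatc <- rbind(rep(2L, 4), rep(1L, 4),
                 rep(2L, 4), rep(2L, 4), rep(2L, 4))
  vh0 <- viterbi_haplotypes(ped, geno_tbl(ped, flatc), map,
                            family = "A", chromosome = "1",
                            freqs = flat_freqs(map$marker))
  expect_equal(nrow(vh0$recombinations), 0)
  expect_equal(length(unique(vh0$path$state)), 1)
})

test_that("oversized families raise a capacity error", {
  big <- nuclear_ped(n_kids = 9) # 18 meiosis bits
  expect_error(cnvlink:::build_family_engine(big),
               class = "cnvlink_capacity_error")
})
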