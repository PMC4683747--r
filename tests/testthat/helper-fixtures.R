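# Fixtures and independent oracles shared across the test files.
# The oracles deliberately use different algorithms from the package
# internals: full founder-allele-configuration enumeration for likelihoods
# and exhaustive inheritance-path enumeration for the HMM.

dx_levels <- cnvlink:::DIAGNOSIS_LEVELS

make_ped <- function(family_id, individual_id, father_id, mother_id,
                     sex = NULL, diagnosis = "UNKNOWN", has_dna = TRUE) {
  n <- length(individual_id)
  tibble::tibble(
    family_id = rep_len(family_id, n),
    individual_id = individual_id,
    father_id = father_id,
    mother_id = mother_id,
    sex = factor(rep_len(sex %||% "unknown", n),
                 levels = cnvlink:::SEX_LEVELS),
    diagnosis = factor(rep_len(diagnosis, n), levels = dx_levels),
    has_dna = rep_len(has_dna, n)
  )
}

# nuclear family: two founders + n_kids children, all affected by default
nuclear_ped <- function(fid = "A", n_kids = 2, kid_dx = "BP_I",
                        parent_dx = "NEVER_ILL") {
  kids <- sprintf("%s-K%d", fid, seq_len(n_kids))
  make_ped(fid,
           c(paste0(fid, "-P1"), paste0(fid, "-P2"), kids),
           c(NA, NA, rep(paste0(fid, "-P1"), n_kids)),
           c(NA, NA, rep(paste0(fid, "-P2"), n_kids)),
           sex = c("male", "female", rep("unknown", n_kids)),
           diagnosis = c(parent_dx, parent_dx, rep_len(kid_dx, n_kids)))
}

# genotype tibble from a code matrix (rows follow ped order)
geno_tbl <- function(ped, codes, markers = NULL) {
  markers <- markers %||% sprintf("m%d", seq_len(ncol(codes)))
  storage.mode(codes) <- "integer"
  colnames(codes) <- markers
  dplyr::bind_cols(
    tibble::tibble(family_id = ped$family_id,
                   individual_id = ped$individual_id),
    tibble::as_tibble(codes)
  )
}

# evenly spaced single-chromosome map
simple_map <- function(n_markers, spacing_cm = 10, chrom = "1",
                       markers = NULL) {
  cm <- (seq_len(n_markers) - 1) * spacing_cm
  tibble::tibble(chrom = chrom,
                 marker = markers %||% sprintf("m%d", seq_len(n_markers)),
                 cm = cm, bp = round(cm * 1e6) + 1)
}

flat_freqs <- function(markers, f = 0.5) {
  tibble::tibble(marker = markers, freq1 = rep_len(f, length(markers)))
}

# ---- oracles -------------------------------------------------------------

# singlepoint likelihood by enumeration over all founder-allele
# configurations (independent of the constraint-propagation engine)
oracle_marker_lik <- function(eng, geno, p) {
  cfgs <- as.matrix(expand.grid(rep(list(1:2), eng$nslots)))
  pr <- apply(cfgs, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  vapply(seq_len(eng$V), function(v) {
    tot <- 0
    for (c_i in seq_len(nrow(cfgs))) {
      al <- cfgs[c_i, ]
      ok <- TRUE
      for (i in seq_along(geno)) {
        g <- geno[i]
        if (g == 0) next
        a1 <- al[eng$slotP[v, i]]
        a2 <- al[eng$slotM[v, i]]
        code <- if (a1 == a2) (if (a1 == 1) 1 else 3) else 2
        if (code != g) { ok <- FALSE; break }
      }
      if (ok) tot <- tot + pr[c_i]
    }
    tot
  }, numeric(1))
}

# phenotype likelihood by enumeration over founder disease-allele configs
oracle_phen_lik <- function(eng, phen, q, f) {
  cfgs <- as.matrix(expand.grid(rep(list(0:1), eng$nslots)))
  pr <- apply(cfgs, 1, function(a) prod(ifelse(a == 1, q, 1 - q)))
  vapply(seq_len(eng$V), function(v) {
    tot <- 0
    for (c_i in seq_len(nrow(cfgs))) {
      a <- cfgs[c_i, ]
      w <- pr[c_i]
      for (i in seq_len(ncol(eng$slotP))) {
        g <- a[eng$slotP[v, i]] + a[eng$slotM[v, i]]
        w <- w * switch(phen[i] + 1L, 1, 1 - f[g + 1], f[g + 1])
      }
      tot <- tot + w
    }
    tot
  }, numeric(1))
}

# exhaustive enumeration over all inheritance-vector paths: posterior,
# best path (lexicographically smallest argmax) and data likelihood
oracle_hmm <- function(liks, theta, B) {
  V <- nrow(liks)
  M <- ncol(liks)
  paths <- as.matrix(expand.grid(rep(list(seq_len(V)), M)))
  trans <- function(u, v, th) {
    d <- sum(bitwAnd(bitwShiftR(bitwXor(u - 1L, v - 1L), 0:(B - 1)), 1L))
    th^d * (1 - th)^(B - d)
  }
  pp <- apply(paths, 1, function(vs) {
    w <- liks[vs[1], 1] / V
    for (m in seq_len(M - 1)) {
      w <- w * trans(vs[m], vs[m + 1], theta[m]) * liks[vs[m + 1], m + 1]
    }
    w
  })
  post <- vapply(seq_len(M), function(m) {
    vapply(seq_len(V), function(s) sum(pp[paths[, m] == s]), numeric(1))
  }, numeric(V)) / sum(pp)
  best <- paths[which.max(pp), ] # expand.grid order = lexicographic
  list(post = post, best = as.integer(best), lik = sum(pp))
}

# reference CNV-weighted scoring written independently of the main path:
# a direct loop over segments, families and markers
oracle_cnv_weighted <- function(segments, family_curves, regions) {
  vapply(seq_len(nrow(segments)), function(s) {
    score <- 0
    for (f in segments$families[[s]]) {
      rows <- segments$region_rows[[s]]
      rows <- rows[regions$family_id[rows] == f]
      avgs <- vapply(rows, function(r) {
        fc <- family_curves[family_curves$family_id == f &
                              family_curves$chrom == regions$chrom[r], ]
        inside <- fc$bp >= regions$start_bp[r] & fc$bp <= regions$end_bp[r]
        mean(fc$score[inside])
      }, numeric(1))
      score <- score + mean(avgs)
    }
    score
  }, numeric(1))
}
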