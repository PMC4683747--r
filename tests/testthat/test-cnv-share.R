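# CNV filtering, within-family sharing, genome segmentation, masking.

cnv_row <- function(ind, fam, chrom, start, end, state = "deletion") {
  tibble::tibble(individual_id = ind, family_id = fam, chrom = chrom,
                 start_bp = start, end_bp = end, state = state,
                 length_bp = end - start + 1)
}

test_that("length filter keeps the documented boundary cases", {
  calls <- dplyr::bind_rows(
    cnv_row("a", "F", "1", 1e6, 1e6 + 9998),       # 9,999 bp: dropped
    cnv_row("b", "F", "1", 1e6, 1e6 + 10045),      # 10,046 bp: retained
    cnv_row("c", "F", "1", 1e6, 1e6 + 2e5, "duplication")
  )
  kept <- suppressMessages(filter_cnvs(calls))
  expect_equal(kept$individual_id, c("b", "c"))
  expect_equal(nrow(suppressMessages(filter_cnvs(calls[0, ]))), 0)
  # monotone: doubling the threshold never retains more calls
  k2 <- suppressMessages(filter_cnvs(calls, 20000))
  expect_lte(nrow(k2), nrow(kept))
})

test_that("shared regions are within-family intersections of >=2 carriers", {
  calls <- dplyr::bind_rows(
    cnv_row("s1", "F1", "1", 100, 200),
    cnv_row("s2", "F1", "1", 150, 250),
    cnv_row("solo", "F2", "1", 100, 250),          # single carrier
    cnv_row("t1", "F3", "2", 500, 600, "deletion"),
    cnv_row("t2", "F3", "2", 500, 600, "duplication")
  )
  reg <- family_shared_regions(calls)
  expect_equal(nrow(reg), 2)
  r1 <- reg[reg$family_id == "F1", ]
  expect_equal(c(r1$start_bp, r1$end_bp), c(150, 200))
  expect_setequal(r1$carrier_ids[[1]], c("s1", "s2"))
  # mixed states share by default, not under match_state
  r3 <- reg[reg$family_id == "F3", ]
  expect_equal(r3$states, "deletion+duplication")
  strict <- family_shared_regions(calls, match_state = TRUE)
  expect_false("F3" %in% strict$family_id)
  # identical calls in sibs give back that interval
  ident <- dplyr::bind_rows(cnv_row("a", "F", "1", 10, 50),
                            cnv_row("b", "F", "1", 10, 50))
  ri <- family_shared_regions(ident)
  expect_equal(c(ri$start_bp, ri$end_bp), c(10, 50))
})

test_that("shared-region detection is order-invariant and carriers
           contain the interval", {
  set.seed(91)
  calls <- purrr::map_dfr(1:30, function(i) {
    s <- sample(1000, 1)
    cnv_row(sprintf("i%d", sample(6, 1)), sprintf("F%d", sample(3, 1)),
            sample(c("1", "2"), 1), s, s + sample(300, 1))
  })
  a <- family_shared_regions(calls)
  sh <- sample(nrow(calls))
  b <- family_shared_regions(calls[sh, ])
  key <- function(x) {
    k <- paste(x$family_id, x$chrom, x$start_bp, x$end_bp,
               vapply(x$carrier_ids, paste, character(1), collapse = ","))
    sort(k)
  }
  expect_equal(key(a), key(b))
  # containment audit: the region lies inside every member call
  for (i in seq_len(nrow(a))) {
    rows <- calls[a$call_rows[[i]], ]
    expect_true(all(rows$start_bp <= a$start_bp[i]))
    expect_true(all(rows$end_bp >= a$end_bp[i]))
  }
})

test_that("overlapping non-nested triples can yield several maximal sets", {
  calls <- dplyr::bind_rows(
    cnv_row("a", "F", "1", 0, 120),
    cnv_row("b", "F", "1", 100, 220),
    cnv_row("c", "F", "1", 200, 320)
  )
  reg <- family_shared_regions(calls)
  expect_equal(nrow(reg), 2) # {a,b} and {b,c}; {a,c} do not overlap
  expect_setequal(
    vapply(reg$carrier_ids, paste, character(1), collapse = ","),
    c("a,b", "b,c"))
})

test_that("segmentation sweeps breakpoints and conserves coverage", {
  regions <- dplyr::bind_rows(
    tibble::tibble(family_id = "A", chrom = "1", start_bp = 100,
                   end_bp = 200, n_carriers = 2L,
                   carrier_ids = list(c("x", "y")), states = "deletion",
                   call_rows = list(1:2)),
    tibble::tibble(family_id = "B", chrom = "1", start_bp = 150,
                   end_bp = 250, n_carriers = 2L,
                   carrier_ids = list(c("u", "v")), states = "deletion",
                   call_rows = list(3:4))
  )
  segs <- segment_genome(regions)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_bp, c(100, 150, 201))
  expect_equal(segs$end_bp, c(149, 200, 250))
  expect_equal(segs$families, list("A", c("A", "B"), "B"))
  # conservation: total family-bp coverage is preserved
  cover <- sum(vapply(seq_len(nrow(segs)), function(i) {
    segs$n_families[i] * (segs$end_bp[i] - segs$start_bp[i] + 1)
  }, numeric(1)))
  expect_equal(cover, sum(regions$end_bp - regions$start_bp + 1))
  # union length equals summed segment lengths (disjointness)
  expect_equal(sum(segs$end_bp - segs$start_bp + 1),
               max(regions$end_bp) - min(regions$start_bp) + 1)
  # identical regions merge into a single two-family segment
  same <- regions
  same$start_bp <- c(100, 100)
  same$end_bp <- c(200, 200)
  seg2 <- segment_genome(same)
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$families[[1]], c("A", "B"))
  # single family passes through unchanged
  seg1 <- segment_genome(regions[1, ])
  expect_equal(nrow(seg1), 1)
  expect_equal(c(seg1$start_bp, seg1$end_bp), c(100, 200))
})

test_that("per-carrier masking zeroes only the carrier; global removes
           markers for everyone", {
  ped <- nuclear_ped(n_kids = 2)
  map <- simple_map(5, spacing_cm = 1) # bp 1, 1e6+1, 2e6+1, 3e6+1, 4e6+1
  codes <- matrix(2L, 4, 5)
  g <- geno_tbl(ped, codes)
  calls <- cnv_row("A-K1", "A", "1", 1e6, 3.5e6) # covers markers 2,3,4
  pc <- mask_genotypes(g, calls, map, mode = "per_carrier")
  expect_equal(unlist(pc[pc$individual_id == "A-K1", 3:7], use.names = FALSE),
               c(2L, 0L, 0L, 0L, 2L))
  expect_equal(as.data.frame(pc[pc$individual_id != "A-K1", ]),
               as.data.frame(g[g$individual_id != "A-K1", ]))
  gr <- mask_genotypes(g, calls, map, mode = "global_remove")
  expect_setequal(cnvlink:::geno_marker_names(gr), c("m1", "m5"))
  # no CNVs: identity
  expect_equal(as.data.frame(mask_genotypes(g, calls[0, ], map)),
               as.data.frame(g))
})
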