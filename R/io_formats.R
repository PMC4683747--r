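# Pedigree, map and CNV file IO plus the hierarchical affection-status
# models.  All tables are tibbles; genomic coordinates are 1-based closed
# intervals on input and output.

#' Read a pedigree from a LINKAGE/PLINK PED file
#'
#' Parses the whitespace-delimited PED dialect: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, 0 = unknown), diagnosis
#' code, followed by optional genotype allele pairs.  Diagnosis codes follow
#' the nested bipolar-spectrum order: 0 unknown, 1 never ill, 2 BP-I,
#' 3 SABP, 4 BP-II, 5 RUDD, 6 other mental disorder.  Parent code "0" means
#' the parent is absent (founder).
#'
#' The pedigree is validated: both parents must be present or both absent,
#' referenced parents must exist in the same family, duplicate individuals
#' are an error, and the parent graph must be acyclic.
#'
#' @param path path to a PED file.
#' @return a tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex`, `diagnosis` and `has_dna`
#'   (any non-missing genotype; `TRUE` when the file has no genotype
#'   columns).
#' @seealso [read_ped_genotypes()] for the genotype columns,
#'   [write_pedigree()] for the inverse.
#' @export
read_pedigree <- function(path) {
  raw <- read_ws_table(path)
  if (ncol(raw) < 6) {
    abort_format("PED file needs at least 6 columns (family, individual, father, mother, sex, diagnosis)")
  }
  ped <- tibble::tibble(
    family_id = as.character(raw[[1]]),
    individual_id = as.character(raw[[2]]),
    father_id = dplyr::na_if(as.character(raw[[3]]), "0"),
    mother_id = dplyr::na_if(as.character(raw[[4]]), "0"),
    sex = sex_from_code(raw[[5]]),
    diagnosis = diagnosis_from_code(raw[[6]])
  )
  if (ncol(raw) > 6) {
    al <- as.matrix(raw[, -(1:6), drop = FALSE])
    storage.mode(al) <- "integer"
    if (ncol(al) %% 2 != 0) {
      abort_format("odd number of genotype allele columns")
    }
    ped$has_dna <- rowSums(al != 0L, na.rm = TRUE) > 0
  } else {
    ped$has_dna <- TRUE
  }
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks the structural invariants: unique (family, individual) keys,
#' parents both present or both absent, parents existing within the same
#' family, and an acyclic parent graph.  Called by [read_pedigree()]; useful
#' directly for pedigrees built in code.
#'
#' @param ped a pedigree tibble (see [read_pedigree()]).
#' @return the validated tibble, invisibly ordered as given.
#' @export
validate_pedigree <- function(ped) {
  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key)) {
    abort_format(paste0("duplicate individual: ",
                        key[duplicated(key)][1]))
  }
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent)) {
    abort_structure(paste0("individual with exactly one parent recorded: ",
                           ped$individual_id[one_parent][1]))
  }
  for (ref in c("father_id", "mother_id")) {
    have <- !is.na(ped[[ref]])
    pk <- paste(ped$family_id[have], ped[[ref]][have])
    missing <- !(pk %in% key)
    if (any(missing)) {
      abort_structure(paste0("referenced parent absent from family: ",
                             pk[missing][1]))
    }
  }
  for (fam in unique(ped$family_id)) {
    rows <- ped[ped$family_id == fam, ]
    check_acyclic(rows, fam)
  }
  ped
}

check_acyclic <- function(rows, fam) {
  n <- nrow(rows)
  idx <- stats::setNames(seq_len(n), rows$individual_id)
  fa <- idx[rows$father_id]
  mo <- idx[rows$mother_id]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (seen < n) {
    cyc <- rows$individual_id[indeg > 0L]
    abort_structure(paste0("pedigree cycle in family ", fam, " involving: ",
                           paste(cyc, collapse = ", ")))
  }
  invisible(rows)
}

#' Read genotype columns of a PED file
#'
#' @param path path to a PED file with genotype allele pairs after column 6.
#' @param marker_ids optional character vector naming the markers, typically
#'   the marker ids of the matching genetic map in file order.
#' @return a tibble with `family_id`, `individual_id` and one integer column
#'   per marker coded 0 = missing, 1 = 1/1, 2 = 1/2, 3 = 2/2.
#' @export
read_ped_genotypes <- function(path, marker_ids = NULL) {
  raw <- read_ws_table(path)
  if (ncol(raw) <= 6) abort_format("PED file has no genotype columns")
  al <- as.matrix(raw[, -(1:6), drop = FALSE])
  storage.mode(al) <- "integer"
  if (ncol(al) %% 2 != 0) abort_format("odd number of genotype allele columns")
  if (any(!al %in% 0:2)) abort_format("allele codes must be 0, 1 or 2")
  a1 <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
  a2 <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
  if (any(xor(a1 == 0L, a2 == 0L))) {
    abort_format("half-missing genotype (exactly one allele coded 0)")
  }
  codes <- ifelse(a1 == 0L, 0L, a1 + a2 - 1L) # 1/1->1, 1/2|2/1->2, 2/2->3
  marker_ids <- marker_ids %||% sprintf("m%d", seq_len(ncol(codes)))
  if (length(marker_ids) != ncol(codes)) {
    abort_format("marker_ids length does not match genotype column count")
  }
  colnames(codes) <- marker_ids
  dplyr::bind_cols(
    tibble::tibble(family_id = as.character(raw[[1]]),
                   individual_id = as.character(raw[[2]])),
    tibble::as_tibble(codes)
  )
}

#' Write a pedigree (and optionally genotypes) as a PED file
#'
#' @param ped pedigree tibble (see [read_pedigree()]).
#' @param path output path.
#' @param genotypes optional genotype tibble (see [read_ped_genotypes()]);
#'   rows are matched to the pedigree by family and individual id.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, genotypes = NULL) {
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    c(unknown = 0L, male = 1L, female = 2L)[as.character(ped$sex)],
    DIAGNOSIS_CODES[as.character(ped$diagnosis)]
  )
  if (!is.null(genotypes)) {
    codes <- geno_code_matrix(genotypes, ped$family_id, ped$individual_id)
    a1 <- matrix(0L, nrow(codes), ncol(codes))
    a2 <- a1
    a1[codes == 1L] <- 1L; a2[codes == 1L] <- 1L
    a1[codes == 2L] <- 1L; a2[codes == 2L] <- 2L
    a1[codes == 3L] <- 2L; a2[codes == 3L] <- 2L
    inter <- matrix(0L, nrow(codes), 2L * ncol(codes))
    inter[, seq(1, ncol(inter), 2)] <- a1
    inter[, seq(2, ncol(inter), 2)] <- a2
    out <- cbind(out, inter)
  }
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Summarise pedigree structure
#'
#' @param ped pedigree tibble.
#' @return a tibble with one row per family: individual, founder and
#'   non-founder counts and the number of generations.
#' @examples
#' peds <- make_pedigrees(sim_config(n_families = 3, seed = 1))
#' pedigree_summary(peds)
#' @export
pedigree_summary <- function(ped) {
  ped |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      founders = sum(is.na(.data$father_id)),
      non_founders = sum(!is.na(.data$father_id)),
      generations = family_generations(.data$individual_id, .data$father_id,
                                       .data$mother_id),
      .groups = "drop"
    )
}

family_generations <- function(id, father, mother) {
  depth <- stats::setNames(rep(NA_integer_, length(id)), id)
  get_depth <- function(i) {
    if (!is.na(depth[[i]])) return(depth[[i]])
    f <- father[match(i, id)]
    d <- if (is.na(f)) 1L else get_depth(f) + 1L
    m <- mother[match(i, id)]
    if (!is.na(m)) d <- max(d, get_depth(m) + 1L)
    depth[[i]] <<- d
    d
  }
  max(vapply(id, get_depth, integer(1)))
}

#' Read a genetic map
#'
#' Expects whitespace-delimited columns chromosome, marker id, sex-averaged
#' position in centimorgans and 1-based physical position in base pairs
#' (the PLINK `.map` layout).  Markers are sorted by cM within each
#' chromosome; markers whose bp order disagrees with the cM order (or that
#' duplicate a cM position) are dropped with a warning.
#'
#' @param path path to the map file.
#' @return a tibble with columns `chrom`, `marker`, `cm`, `bp`.
#' @export
read_genetic_map <- function(path) {
  raw <- read_ws_table(path)
  if (ncol(raw) < 4) abort_format("map file needs 4 columns (chrom, marker, cM, bp)")
  map <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    marker = as.character(raw[[2]]),
    cm = as.numeric(raw[[3]]),
    bp = as.numeric(raw[[4]])
  )
  validate_genetic_map(map)
}

#' @rdname read_genetic_map
#' @param map a map tibble built in code.
#' @export
validate_genetic_map <- function(map) {
  if (any(is.na(map$cm)) || any(map$cm < 0)) {
    abort_format("negative or missing cM position in map")
  }
  if (anyDuplicated(map$marker)) {
    abort_format(paste0("duplicate marker id: ",
                        map$marker[duplicated(map$marker)][1]))
  }
  out <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$cm, .data$bp, .by_group = TRUE) |>
    dplyr::group_modify(~ drop_nonmonotone(.x)) |>
    dplyr::ungroup()
  out
}

drop_nonmonotone <- function(x) {
  keep <- logical(nrow(x))
  last_cm <- -Inf
  last_bp <- -Inf
  for (i in seq_len(nrow(x))) {
    if (x$cm[i] > last_cm && x$bp[i] > last_bp) {
      keep[i] <- TRUE
      last_cm <- x$cm[i]
      last_bp <- x$bp[i]
    }
  }
  if (!all(keep)) {
    warn(paste0("dropped ", sum(!keep),
                " marker(s) violating cM/bp monotonicity: ",
                paste(head(x$marker[!keep], 5), collapse = ", ")))
  }
  x[keep, , drop = FALSE]
}

#' Write a genetic map
#'
#' @param map map tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "marker", "cm", "bp")], path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Interpolate genetic position from physical position
#'
#' Linear interpolation of the bp -> cM relation between the flanking
#' mapped markers; positions outside the mapped range clamp to the terminal
#' marker's cM.
#'
#' @param map map tibble.
#' @param chromosome chromosome identifier.
#' @param position_bp numeric vector of physical positions.
#' @return numeric vector of centimorgan positions.
#' @export
interpolate_cm <- function(map, chromosome, position_bp) {
  sub <- map[map$chrom == as.character(chromosome), ]
  if (nrow(sub) == 0) {
    abort(paste0("chromosome not in map: ", chromosome),
          class = "cnvlink_lookup_error")
  }
  if (nrow(sub) == 1) return(rep(sub$cm, length(position_bp)))
  stats::approx(sub$bp, sub$cm, xout = position_bp, rule = 2,
                ties = "ordered")$y
}

#' Hierarchical affection-status models
#'
#' The three nested models over the bipolar-spectrum diagnoses:
#' ASM1 = \{BP-I, SABP\}, ASM2 adds BP-II, ASM3 adds RUDD.
#'
#' @param asm 1, 2 or 3 (or "ASM1".."ASM3").
#' @return character vector of diagnosis codes counted as affected.
#' @export
asm_affected_set <- function(asm) {
  lvl <- as.integer(gsub("ASM", "", toupper(as.character(asm))))
  if (is.na(lvl) || !lvl %in% 1:3) abort_config("asm must be 1, 2 or 3")
  list(c("BP_I", "SABP"),
       c("BP_I", "SABP", "BP_II"),
       c("BP_I", "SABP", "BP_II", "RUDD"))[[lvl]]
}

#' Apply an affection-status model to a pedigree
#'
#' Maps each individual's diagnosis to affected / unaffected / unknown under
#' the chosen model.  Bipolar-spectrum diagnoses outside the model's
#' affected set (BP-II or RUDD under the narrower models) become unknown,
#' never-ill individuals are unaffected, and other mental disorders or
#' missing diagnoses are unknown.
#'
#' @param ped pedigree tibble.
#' @param asm 1, 2 or 3.
#' @return the pedigree with an added `status` factor column
#'   (affected / unaffected / unknown).
#' @export
apply_asm <- function(ped, asm) {
  affected <- asm_affected_set(asm)
  diag <- as.character(ped$diagnosis)
  status <- dplyr::case_when(
    diag %in% affected ~ "affected",
    diag %in% BIPOLAR_SPECTRUM ~ "unknown",
    diag == "NEVER_ILL" ~ "unaffected",
    TRUE ~ "unknown"
  )
  ped$status <- factor(status, levels = c("affected", "unaffected", "unknown"))
  ped
}

#' Estimate founder allele frequencies
#'
#' Per-marker frequency of allele 1 counted over the non-missing alleles of
#' pedigree founders.  Markers with no typed founder fall back to 0.5 with
#' a warning and are flagged.
#'
#' @param ped pedigree tibble.
#' @param genotypes genotype tibble (see [read_ped_genotypes()]).
#' @return a tibble with columns `marker`, `freq1`, `n_alleles`, `fallback`.
#' @export
estimate_founder_allele_freqs <- function(ped, genotypes) {
  founders <- ped[is.na(ped$father_id), ]
  codes <- geno_code_matrix(genotypes, founders$family_id,
                            founders$individual_id)
  n1 <- colSums((codes == 1L) * 2L + (codes == 2L))
  n_alleles <- colSums(codes != 0L) * 2L
  fallback <- n_alleles == 0L
  freq1 <- ifelse(fallback, 0.5, n1 / pmax(n_alleles, 1L))
  if (any(fallback)) {
    warn(paste0(sum(fallback),
                " marker(s) with no typed founder; frequency set to 0.5"))
  }
  tibble::tibble(marker = colnames(codes), freq1 = unname(freq1),
                 n_alleles = unname(as.integer(n_alleles)),
                 fallback = unname(fallback))
}

#' Read a CNV call table
#'
#' Reads a PennCNV-style tab-separated table with header columns
#' `individual_id`, `family_id`, `chrom`, `start_bp`, `end_bp`,
#' `copy_number`.  Copy numbers 0 and 1 collapse to state "deletion",
#' 3 and 4 to "duplication".  Rows with copy number 2 (not a variant) or
#' with `end_bp < start_bp` are rejected; by default rejected rows are
#' dropped with a warning, with `strict = TRUE` they raise a format error.
#'
#' @param path path to the TSV file.
#' @param strict error instead of dropping malformed rows.
#' @return a tibble of validated calls with columns `individual_id`,
#'   `family_id`, `chrom`, `start_bp`, `end_bp`, `state`, `length_bp`;
#'   the rejected rows are attached as attribute `"rejected"`.
#' @export
read_cnv_calls <- function(path, strict = FALSE) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("individual_id", "family_id", "chrom", "start_bp", "end_bp",
            "copy_number")
  if (!all(need %in% names(raw))) {
    abort_format(paste0("CNV table must have columns: ",
                        paste(need, collapse = ", ")))
  }
  validate_cnv_calls(raw, strict = strict)
}

#' @rdname read_cnv_calls
#' @param calls a raw call table built in code (same columns as the file).
#' @export
validate_cnv_calls <- function(calls, strict = FALSE) {
  cn <- as.integer(calls$copy_number)
  bad_cn <- !cn %in% c(0L, 1L, 3L, 4L)
  bad_iv <- calls$end_bp < calls$start_bp
  bad <- bad_cn | bad_iv
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed CNV row(s) (",
                  sum(bad_cn), " invalid copy number, ",
                  sum(bad_iv & !bad_cn), " reversed interval)")
    if (strict) abort_format(msg)
    warn(paste0(msg, "; dropped"))
  }
  ok <- calls[!bad, , drop = FALSE]
  out <- tibble::tibble(
    individual_id = as.character(ok$individual_id),
    family_id = as.character(ok$family_id),
    chrom = as.character(ok$chrom),
    start_bp = as.numeric(ok$start_bp),
    end_bp = as.numeric(ok$end_bp),
    state = ifelse(as.integer(ok$copy_number) < 2L, "deletion", "duplication"),
    length_bp = as.numeric(ok$end_bp) - as.numeric(ok$start_bp) + 1
  )
  attr(out, "rejected") <- calls[bad, , drop = FALSE]
  out
}

#' Write CNV calls as a TSV table
#'
#' @param calls validated call tibble (see [read_cnv_calls()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  out <- tibble::tibble(
    individual_id = calls$individual_id,
    family_id = calls$family_id,
    chrom = calls$chrom,
    start_bp = calls$start_bp,
    end_bp = calls$end_bp,
    copy_number = ifelse(calls$state == "deletion", 1L, 3L)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_ws_table <- function(path) {
  utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}
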