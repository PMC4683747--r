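# Shared constants and small helpers (internal).

# diagnosis codes used in column 6 of the PED dialect; the nested order of
# the bipolar-spectrum codes mirrors the hierarchical affection-status models
DIAGNOSIS_LEVELS <- c("UNKNOWN", "NEVER_ILL", "BP_I", "SABP", "BP_II",
                      "RUDD", "OTHER_MENTAL")
DIAGNOSIS_CODES <- stats::setNames(0:6, DIAGNOSIS_LEVELS)
BIPOLAR_SPECTRUM <- c("BP_I", "SABP", "BP_II", "RUDD")

SEX_LEVELS <- c("unknown", "male", "female")

# hard cap on meiosis bits per family (2 per non-founder)
MAX_MEIOSIS_BITS <- 16L

abort_config <- function(msg, ...) {
  abort(msg, class = "cnvlink_config_error", ...)
}
abort_format <- function(msg, ...) {
  abort(msg, class = c("cnvlink_format_error", "cnvlink_data_error"), ...)
}
abort_structure <- function(msg, ...) {
  abort(msg, class = c("cnvlink_structural_error", "cnvlink_data_error"), ...)
}
abort_capacity <- function(msg, ...) {
  abort(msg, class = "cnvlink_capacity_error", ...)
}

diagnosis_from_code <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L) || any(code > 6L)) {
    abort_format("diagnosis codes must be integers in 0..6")
  }
  factor(DIAGNOSIS_LEVELS[code + 1L], levels = DIAGNOSIS_LEVELS)
}

sex_from_code <- function(code) {
  code <- as.integer(code)
  out <- rep("unknown", length(code))
  out[code == 1L] <- "male"
  out[code == 2L] <- "female"
  factor(out, levels = SEX_LEVELS)
}

# marker columns of a genotype tibble (everything after the two id columns)
geno_marker_names <- function(genotypes) {
  setdiff(names(genotypes), c("family_id", "individual_id"))
}

# genotype tibble -> integer code matrix (rows = individuals in given order)
geno_code_matrix <- function(genotypes, family_id, individual_id,
                             markers = NULL) {
  markers <- markers %||% geno_marker_names(genotypes)
  key <- paste(genotypes$family_id, genotypes$individual_id, sep = "\r")
  want <- paste(family_id, individual_id, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    abort_data_missing <- want[is.na(idx)][1]
    abort_structure(paste0("individual absent from genotype table: ",
                           gsub("\r", "/", abort_data_missing)))
  }
  m <- as.matrix(genotypes[idx, markers, drop = FALSE])
  storage.mode(m) <- "integer"
  m[is.na(m)] <- 0L
  m
}

# deterministic per-replicate seed stream derived from a master seed
derive_seed <- function(seed, index) {
  m <- 2147483629
  s <- ((as.double(seed) %% m) * 48271) %% m
  as.integer((s + as.double(index) * 9973) %% m)
}

round2 <- function(x) round(x, 2)
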