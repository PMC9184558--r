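# Shared fixtures and independent oracles.

# Brute-force median: sort and pick (average the two central values).
# Deliberately not stats::median, so Z-score tests have an independent route.
oracle_median <- function(x) {
  x <- sort(unname(x))
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Sample (n-1) standard deviation by direct enumeration.
oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_z <- function(ratio, plate_ratios) {
  unname((ratio - oracle_median(plate_ratios)) / oracle_sd(plate_ratios))
}

# Hand-built count tibble: one plate, arbitrary wells x lines count matrix.
counts_from_matrix <- function(mat, plate_id = "P1") {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  tibble::tibble(
    plate_id = plate_id,
    well_id = rep(rownames(mat), times = ncol(mat)),
    line_id = rep(colnames(mat), each = nrow(mat)),
    uid_count = as.integer(as.vector(mat))
  )
}

# Minimal plate-role table for hand-built fixtures (no 96-well validation).
roles_table <- function(plate_id, well_id, role,
                        compound_id = NA_character_, dose_uM = NA_real_) {
  tibble::tibble(plate_id = plate_id, well_id = well_id, role = role,
                 compound_id = compound_id, dose_uM = dose_uM)
}

# Small screen design used across tests: 2 backgrounds, focal TP53 lines,
# 4 plates, 45 compounds at 2 doses. The study-scale conditions at desk size.
tiny_design <- function(seed = 1, ...) {
  suppressWarnings(make_synthetic_design(seed = seed, ...))
}

tp53_truth <- function(kill = 0.9, compound = "C001") {
  truth_model(effects = tibble::tibble(compound_id = compound, gene = "TP53",
                                       kill_fraction = kill))
}

# A non-repetitive 72-nt amplicon reference (unambiguous indel positions).
REF72 <- "ACGTACGGTTCAGGCTAAGCGGACTTAGCCATTGCAACGGTACCAGTCAAGGTCAGATCCTGATCGATGCAT"
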