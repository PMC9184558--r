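# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# The 96-well grid in row-major order: A01..A12, B01..H12.
well_grid_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
# All stochastic entry points funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

random_dna <- function(n, width) {
  if (n == 0) return(character())
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
    character(1)
  )
}

# n distinct random k-mers (rejection sampling; 4^width must comfortably
# exceed n, true for 14-nt UIDs at any realistic depth).
random_dna_distinct <- function(n, width) {
  out <- unique(random_dna(n, width))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), width)))
  }
  out
}

# Apply per-base substitution errors to a character vector of sequences.
# Each substituted base is drawn uniformly from the three other bases.
apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < error_rate
  if (any(hit)) {
    flat[hit] <- vapply(
      flat[hit],
      function(b) sample(setdiff(DNA_BASES, b), 1),
      character(1),
      USE.NAMES = FALSE
    )
  }
  vapply(
    split(flat, rep.int(seq_along(lens), lens)),
    paste, character(1), collapse = ""
  )
}

# Hamming distances between each string in `obs` and one reference string of
# the same width. Vectorised over observations.
hamming_to <- function(obs, ref) {
  width <- nchar(ref)
  stopifnot(all(nchar(obs) == width))
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  mat <- matrix(unlist(strsplit(obs, "", fixed = TRUE), use.names = FALSE),
                ncol = width, byrow = TRUE)
  rowSums(mat != matrix(ref_chars, nrow = length(obs), ncol = width, byrow = TRUE))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

read_tsv_commented <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}
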