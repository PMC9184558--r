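# Knockout-validation classifier. Amplicon consensi (one per UID) are
# aligned globally to the 66-80 bp reference spanning the predicted cut
# site; simple indels are called, left-normalised, and aggregated into
# allele fractions. A clone validates only when both alleles carry
# out-of-frame indels, the intact-site (wild-type) read fraction is below
# 1%, and the targeted exon cannot rescue the frame by being skipped.

# Global (Needleman-Wunsch/Gotoh) alignment with match +1, mismatch -1 and
# affine gaps (open -4, extend -1: a gap of length L costs 4 + L). Affine
# penalties keep a long CRISPR indel as one event instead of shredding it
# into short gaps separated by coincidental matches. Returns the per-column
# operation string: M (aligned pair), D (gap in read: reference base
# deleted), I (gap in reference: read base inserted). Indels are
# subsequently left-normalised, so traceback tie-break choices do not
# affect reported positions.
align_global <- function(read, ref, match = 1, mismatch = -1,
                         gap_open = 4, gap_ext = 1) {
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  open1 <- gap_open + gap_ext  # cost of a gap's first base
  # state matrices: M aligned, X gap in read (consumes ref), Y gap in ref
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (m > 0) X[1, 2:(m + 1)] <- -(gap_open + gap_ext * seq_len(m))
  if (n > 0) Y[2:(n + 1), 1] <- -(gap_open + gap_ext * seq_len(n))
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i], match, mismatch)
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub[j]
      X[i + 1, j + 1] <- max(M[i + 1, j] - open1, X[i + 1, j] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open1, Y[i, j + 1] - gap_ext)
    }
  }
  # traceback from the best final state
  finals <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
  state <- names(which.max(finals))
  score <- max(finals)
  ops <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == "M") {
      s <- if (a[i] == b[j]) match else mismatch
      prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      state <- names(which(abs(prev + s - M[i + 1, j + 1]) < 1e-9))[1]
      ops <- c("M", ops); i <- i - 1; j <- j - 1
    } else if (state == "X") {
      ops <- c("D", ops)
      from_m <- abs(M[i + 1, j] - open1 - X[i + 1, j + 1]) < 1e-9
      state <- if (from_m) "M" else "X"
      j <- j - 1
    } else {
      ops <- c("I", ops)
      from_m <- abs(M[i, j + 1] - open1 - Y[i + 1, j + 1]) < 1e-9
      state <- if (from_m) "M" else "Y"
      i <- i - 1
    }
    if (i == 0 && j > 0 && state == "M") state <- "X"
    if (j == 0 && i > 0 && state == "M") state <- "Y"
  }
  list(ops = ops, score = score)
}

# Extract left-normalised indels from an alignment of `read` to `ref`.
# Coordinates are 0-based: a deletion's position is the offset of its first
# deleted reference base; an insertion's position is the offset of the
# reference base immediately before the inserted sequence.
alignment_indels <- function(read, ref) {
  al <- align_global(read, ref)
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  ops <- al$ops
  ri <- 0L; qi <- 0L  # consumed reference / read bases
  indels <- list()
  n_mismatch <- 0L
  k <- 1L
  while (k <= length(ops)) {
    op <- ops[k]
    if (op == "M") {
      ri <- ri + 1L; qi <- qi + 1L
      if (a[qi] != b[ri]) n_mismatch <- n_mismatch + 1L
      k <- k + 1L
    } else {
      run <- k
      while (run <= length(ops) && ops[run] == op) run <- run + 1L
      len <- run - k
      if (op == "D") {
        pos <- ri  # 0-based offset of first deleted base
        L <- len
        while (pos > 0 && b[pos] == b[pos + L]) pos <- pos - 1L
        indels[[length(indels) + 1L]] <-
          list(kind = "deletion", length = L, position = pos)
        ri <- ri + len
      } else {
        s <- a[qi + seq_len(len)]
        pos <- ri - 1L  # 0-based offset of base before the insertion
        while (pos > 0 && s[len] == b[pos + 1L]) {
          s <- c(b[pos + 1L], s[-len])
          pos <- pos - 1L
        }
        indels[[length(indels) + 1L]] <-
          list(kind = "insertion", length = len, position = pos)
        qi <- qi + len
      }
      k <- run
    }
  }
  list(indels = indels, n_mismatch = n_mismatch, score = al$score)
}

#' Call alleles from UID-collapsed amplicon reads
#'
#' Each distinct consensus sequence is aligned globally to the reference
#' (match +1, mismatch -1, affine gaps opening -4 and extending -1 per base;
#' indels reported at their leftmost equivalent position). Sequences with no indel are `wild_type`
#' (substitution-only differences leave the targeting site intact for frame
#' purposes), one indel yields a `deletion`/`insertion` call, and more than
#' one indel is `complex`. Identical (kind, length, position) calls are
#' aggregated with their UID fractions.
#'
#' @param reads Tibble with a `sequence` column (one row per UID-collapsed
#'   molecule), or a character vector of consensus sequences.
#' @param reference Reference amplicon (66-80 nt in the assay design; any
#'   length accepted).
#' @return Tibble (`kind`, `length`, `position`, `n_uids`, `uid_fraction`)
#'   sorted by decreasing fraction. Fractions over all rows sum to 1.
#' @export
genotype_amplicon <- function(reads, reference) {
  if (is.character(reads)) reads <- tibble::tibble(sequence = reads)
  assert_columns(reads, "sequence", "reads")
  if (nrow(reads) == 0) abort("empty read set: cannot genotype")
  reference <- toupper(reference)
  total <- nrow(reads)
  uniq <- reads |>
    dplyr::count(sequence = toupper(.data$sequence), name = "n_uids")
  calls <- lapply(seq_len(nrow(uniq)), function(i) {
    seq_i <- uniq$sequence[i]
    if (seq_i == reference) {
      return(tibble::tibble(kind = "wild_type", length = 0L, position = NA_integer_))
    }
    res <- alignment_indels(seq_i, reference)
    k <- length(res$indels)
    if (k == 0) {
      tibble::tibble(kind = "wild_type", length = 0L, position = NA_integer_)
    } else if (k == 1) {
      iv <- res$indels[[1]]
      tibble::tibble(kind = iv$kind, length = as.integer(iv$length),
                     position = as.integer(iv$position))
    } else {
      tibble::tibble(kind = "complex", length = NA_integer_,
                     position = NA_integer_)
    }
  })
  dplyr::bind_cols(dplyr::bind_rows(calls), n_uids = uniq$n_uids) |>
    dplyr::group_by(.data$kind, .data$length, .data$position) |>
    dplyr::summarise(n_uids = sum(.data$n_uids), .groups = "drop") |>
    dplyr::mutate(uid_fraction = .data$n_uids / total) |>
    dplyr::arrange(dplyr::desc(.data$uid_fraction))
}

#' Is an indel out of frame?
#'
#' @param kind `"deletion"` or `"insertion"` (`wild_type`/`complex` return
#'   `NA`: frame analysis does not apply; complex alleles are handled
#'   conservatively by [classify_clone()]).
#' @param length Indel length in nt.
#' @return `TRUE` iff `length %% 3 != 0`; vectorised.
#' @export
is_out_of_frame <- function(kind, length) {
  ifelse(kind %in% c("deletion", "insertion"), length %% 3 != 0, NA)
}

#' Describe the coding-exon structure around a targeted site
#'
#' @param gene Gene symbol.
#' @param exon_lengths Ordered coding-exon lengths in nt (all positive).
#' @param target_exon_index 0-based index of the exon containing the cut
#'   site.
#' @return An `exon_model` list.
#' @export
exon_model <- function(gene, exon_lengths, target_exon_index) {
  if (any(exon_lengths <= 0)) abort("exon lengths must be positive")
  if (target_exon_index < 0 || target_exon_index >= length(exon_lengths)) {
    abort("target_exon_index out of range")
  }
  structure(list(gene = gene, exon_lengths = as.integer(exon_lengths),
                 target_exon_index = as.integer(target_exon_index)),
            class = "exon_model")
}

#' Can skipping the targeted exon rescue the reading frame?
#'
#' Splicing out an internal exon whose length is a multiple of 3 removes the
#' damaged site while leaving the downstream frame intact, so such edits can
#' be "rescued". First and last coding exons cannot be skipped this way, and
#' single-exon genes are never rescuable.
#'
#' @param model An [exon_model()].
#' @return `TRUE` iff the targeted exon is internal and its length is a
#'   multiple of 3.
#' @export
exon_skip_rescuable <- function(model) {
  n <- length(model$exon_lengths)
  if (n < 3) {
    # with < 3 exons the target is never internal
    return(FALSE)
  }
  idx <- model$target_exon_index
  internal <- idx > 0 && idx < (n - 1)
  internal && model$exon_lengths[idx + 1] %% 3 == 0
}

#' Classify a clone's knockout status
#'
#' A clone validates as a knockout only when all four rules pass:
#' \describe{
#'   \item{`biallelic`}{at least two non-wild-type alleles, or a single
#'     non-wild-type allele at UID fraction >= `homozygous_fraction`
#'     (default 0.97), treated as the same edit on both alleles;}
#'   \item{`out_of_frame`}{every non-wild-type allele is a simple indel whose
#'     length is not a multiple of 3 (complex multi-indel alleles fail this
#'     rule conservatively);}
#'   \item{`intact_site`}{the wild-type (intact targeting site) UID fraction
#'     is strictly below `wt_threshold` (default 0.01);}
#'   \item{`exon_skip`}{the targeted exon cannot rescue the frame by being
#'     skipped ([exon_skip_rescuable()]).}
#' }
#'
#' @param alleles Allele table from [genotype_amplicon()].
#' @param model An [exon_model()] for the targeted locus.
#' @param clone_id Identifier carried into the result.
#' @param wt_threshold Maximum tolerated intact-site fraction (strict `<`).
#' @param homozygous_fraction Fraction above which a single allele is
#'   treated as biallelic-identical.
#' @return A `clone_genotype` list: `clone_id`, `alleles`, `wt_fraction`,
#'   `verdict` (`"validated"`/`"not_validated"`) and `reasons`, the rule ids
#'   that failed.
#' @export
classify_clone <- function(alleles, model, clone_id = NA_character_,
                           wt_threshold = 0.01, homozygous_fraction = 0.97) {
  alleles <- tibble::as_tibble(alleles)
  assert_columns(alleles, c("kind", "length", "uid_fraction"), "alleles")
  wt_fraction <- sum(alleles$uid_fraction[alleles$kind == "wild_type"])
  non_wt <- alleles[alleles$kind != "wild_type", , drop = FALSE]
  reasons <- character(0)

  biallelic <- nrow(non_wt) >= 2 ||
    (nrow(non_wt) == 1 && non_wt$uid_fraction[1] >= homozygous_fraction)
  if (!biallelic) reasons <- c(reasons, "biallelic")

  frames_ok <- nrow(non_wt) > 0 &&
    all(non_wt$kind %in% c("deletion", "insertion")) &&
    all(is_out_of_frame(non_wt$kind, non_wt$length))
  if (!frames_ok) reasons <- c(reasons, "out_of_frame")

  if (!(wt_fraction < wt_threshold)) reasons <- c(reasons, "intact_site")

  if (exon_skip_rescuable(model)) reasons <- c(reasons, "exon_skip")

  structure(
    list(clone_id = clone_id, alleles = alleles, wt_fraction = wt_fraction,
         verdict = if (length(reasons) == 0) "validated" else "not_validated",
         reasons = reasons),
    class = "clone_genotype"
  )
}

#' @export
print.clone_genotype <- function(x, ...) {
  cat("<clone_genotype>", if (!is.na(x$clone_id)) x$clone_id else "", "\n")
  cat(sprintf("  verdict: %s%s\n", x$verdict,
              if (length(x$reasons)) paste0(" (failed: ",
                                            paste(x$reasons, collapse = ", "), ")")
              else ""))
  cat(sprintf("  wild-type fraction: %.4f; %d allele call(s)\n",
              x$wt_fraction, nrow(x$alleles)))
  invisible(x)
}

#' @export
tidy.clone_genotype <- function(x, ...) {
  dplyr::mutate(x$alleles, clone_id = x$clone_id, .before = 1)
}

#' @export
glance.clone_genotype <- function(x, ...) {
  tibble::tibble(
    clone_id = x$clone_id,
    verdict = x$verdict,
    wt_fraction = x$wt_fraction,
    n_alleles = sum(x$alleles$kind != "wild_type"),
    failed_rules = paste(x$reasons, collapse = ",")
  )
}

#' RNA-level knockout evidence rule
#'
#' A knockout is supported at the RNA level when at least `min_reads`
#' RNA-seq reads cover the mutated or flanking exons and none of them shows
#' wild-type sequence or in-frame exon skipping.
#'
#' @param covering_reads,wt_reads,inframe_skip_reads Non-negative integer
#'   read counts (vectorised).
#' @param min_reads Minimum covering reads (default 15).
#' @return Logical vector.
#' @export
rna_evidence <- function(covering_reads, wt_reads, inframe_skip_reads,
                         min_reads = 15) {
  if (any(c(covering_reads, wt_reads, inframe_skip_reads) < 0)) {
    abort("read counts must be non-negative")
  }
  covering_reads >= min_reads & wt_reads == 0 & inframe_skip_reads == 0
}
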