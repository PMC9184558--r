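# Demultiplexing of barcoded amplicon read pairs and SafeSeqS-style UID
# collapsing. Reads are parsed positionally from the primer layout:
#   read 1: UID(14) | plate barcode | ANCHOR_FWD(20) | gRNA(20)
#   read 2: well barcode | NN spacer | ANCHOR_REV(24)
# Barcodes and gRNAs are matched against their whitelists with a bounded
# Hamming distance; any ambiguity (two entries tied at the minimum distance)
# rejects the read rather than guessing.

READ_STATUSES <- c("assigned", "ambiguous", "unmatched_barcode",
                   "unmatched_grna", "malformed")

#' Match observed barcodes against a whitelist
#'
#' Returns, for each observed string, the id of the unique whitelist entry
#' within Hamming distance `max_mismatch`, or `NA` if no entry qualifies or
#' two or more tie at the minimum distance (ambiguous).
#'
#' @param observed Character vector of observed sequences, all the same
#'   length as the whitelist entries.
#' @param whitelist Named character vector of barcodes (names = ids).
#' @param max_mismatch Maximum Hamming distance accepted.
#' @return A tibble with columns `barcode_id` (`NA` when unassigned) and
#'   `ambiguous` (`TRUE` when rejection was due to a tie).
#' @export
match_barcode <- function(observed, whitelist, max_mismatch = 1) {
  width <- unique(nchar(whitelist))
  stopifnot(length(width) == 1)
  n <- length(observed)
  out <- tibble::tibble(barcode_id = rep(NA_character_, n),
                        ambiguous = rep(FALSE, n))
  ok <- !is.na(observed) & nchar(observed) == width
  if (!any(ok)) return(out)
  obs <- observed[ok]
  dmat <- vapply(whitelist, function(w) hamming_to(obs, w),
                 numeric(length(obs)))
  dmat <- matrix(dmat, nrow = length(obs))
  dmin <- apply(dmat, 1, min)
  nmin <- rowSums(dmat == dmin)
  hit <- dmin <= max_mismatch & nmin == 1
  amb <- dmin <= max_mismatch & nmin > 1
  id <- rep(NA_character_, length(obs))
  id[hit] <- names(whitelist)[apply(dmat[hit, , drop = FALSE], 1, which.min)]
  out$barcode_id[ok] <- id
  out$ambiguous[ok] <- amb
  out
}

#' Parse paired reads into (plate, well, line, UID) assignments
#'
#' Fields are sliced positionally from the primer layout; both anchors must
#' match within `max_mismatch_anchor`; plate/well barcodes and the gRNA are
#' matched by bounded Hamming distance. A read pair is `assigned` only when
#' every lookup resolves uniquely. Failure statuses: `malformed` (short read
#' or anchor failure), `unmatched_barcode`, `ambiguous` (barcode tie),
#' `unmatched_grna` (no panel gRNA within tolerance, or a tie).
#'
#' @param read1,read2 Character vectors of read sequences (or FASTQ paths,
#'   via [demux_count()]).
#' @param whitelist A `barcode_whitelist`.
#' @param panel Panel tibble; its `grna_seq` column is the line whitelist.
#' @param max_mismatch_bc,max_mismatch_anchor,max_mismatch_grna Mismatch
#'   tolerances (defaults 1, 2, 1).
#' @param uid_length UID length (default 14).
#' @return A tibble, one row per read pair: `uid`, `plate_bc_obs`,
#'   `well_bc_obs`, `grna_obs`, `plate_bc_id`, `well_bc_id`, `line_id`,
#'   `status`.
#' @export
parse_read_pairs <- function(read1, read2, whitelist, panel,
                             max_mismatch_bc = 1, max_mismatch_anchor = 2,
                             max_mismatch_grna = 1, uid_length = 14) {
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  pw <- unique(nchar(whitelist$plate_barcodes))
  ww <- unique(nchar(whitelist$well_barcodes))
  stopifnot(length(pw) == 1, length(ww) == 1)
  len1 <- uid_length + pw + nchar(ANCHOR_FWD) + 20L
  len2 <- ww + 2L + nchar(ANCHOR_REV)

  out <- tibble::tibble(
    uid = rep(NA_character_, n), plate_bc_obs = NA_character_,
    well_bc_obs = NA_character_, grna_obs = NA_character_,
    plate_bc_id = NA_character_, well_bc_id = NA_character_,
    line_id = NA_character_, status = rep(NA_character_, n)
  )
  if (n == 0) return(out)

  long_enough <- nchar(read1) >= len1 & nchar(read2) >= len2
  out$status[!long_enough] <- "malformed"
  idx <- which(long_enough)
  if (length(idx) == 0) return(out)

  r1 <- read1[idx]; r2 <- read2[idx]
  out$uid[idx] <- substr(r1, 1, uid_length)
  out$plate_bc_obs[idx] <- substr(r1, uid_length + 1, uid_length + pw)
  anchor1 <- substr(r1, uid_length + pw + 1, uid_length + pw + nchar(ANCHOR_FWD))
  out$grna_obs[idx] <- substr(r1, len1 - 19L, len1)
  out$well_bc_obs[idx] <- substr(r2, 1, ww)
  anchor2 <- substr(r2, ww + 3L, len2)

  anchors_ok <- hamming_to(anchor1, ANCHOR_FWD) <= max_mismatch_anchor &
    hamming_to(anchor2, ANCHOR_REV) <= max_mismatch_anchor
  out$status[idx[!anchors_ok]] <- "malformed"
  idx <- idx[anchors_ok]
  if (length(idx) == 0) return(out)

  pm <- match_barcode(out$plate_bc_obs[idx], whitelist$plate_barcodes, max_mismatch_bc)
  wm <- match_barcode(out$well_bc_obs[idx], whitelist$well_barcodes, max_mismatch_bc)
  gm <- match_barcode(out$grna_obs[idx],
                      stats::setNames(panel$grna_seq, panel$line_id),
                      max_mismatch_grna)
  out$plate_bc_id[idx] <- pm$barcode_id
  out$well_bc_id[idx] <- wm$barcode_id
  out$line_id[idx] <- gm$barcode_id

  status <- rep("assigned", length(idx))
  status[is.na(gm$barcode_id)] <- "unmatched_grna"
  status[is.na(pm$barcode_id) | is.na(wm$barcode_id)] <- "unmatched_barcode"
  status[pm$ambiguous | wm$ambiguous] <- "ambiguous"
  out$status[idx] <- status
  out
}

#' Collapse UIDs into molecule counts
#'
#' Within each (plate, well, line), distinct UIDs supported by at least
#' `min_reads_per_uid` read pairs count once: UIDs count molecules, reads do
#' not. UID sequencing errors are deliberately not clustered - two UIDs one
#' substitution apart are distinct molecules here - which can over-count at
#' high error rates (documented trade-off; the 14-nt UID space is sparse at
#' realistic depths).
#'
#' @param parsed Tibble from [parse_read_pairs()], with `plate_id`/`well_id`
#'   columns already joined (see [demux_count()]) or `plate_bc_id`/
#'   `well_bc_id` used as identifiers when not.
#' @param min_reads_per_uid Minimum read pairs supporting a UID (default 1).
#' @return A list: `counts` tibble (`plate_id`, `well_id`, `line_id`,
#'   `uid_count`) and `qc`, itself a list with `status_counts` (tibble
#'   `status`, `n`; sums to `nrow(parsed)`) and `duplication` (tibble
#'   `reads_per_uid`, `n_uids`).
#' @export
collapse_uids <- function(parsed, min_reads_per_uid = 1) {
  stopifnot(min_reads_per_uid >= 1)
  if (!"plate_id" %in% names(parsed)) parsed$plate_id <- parsed$plate_bc_id
  if (!"well_id" %in% names(parsed)) parsed$well_id <- parsed$well_bc_id
  status_counts <- parsed |>
    dplyr::count(status = factor(.data$status, levels = READ_STATUSES),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(status = as.character(.data$status))
  assigned <- dplyr::filter(parsed, .data$status == "assigned",
                            !is.na(.data$plate_id), !is.na(.data$well_id))
  per_uid <- assigned |>
    dplyr::count(.data$plate_id, .data$well_id, .data$line_id, .data$uid,
                 name = "n_reads")
  counts <- per_uid |>
    dplyr::filter(.data$n_reads >= min_reads_per_uid) |>
    dplyr::count(.data$plate_id, .data$well_id, .data$line_id,
                 name = "uid_count")
  duplication <- per_uid |>
    dplyr::count(reads_per_uid = .data$n_reads, name = "n_uids")
  list(counts = counts,
       qc = list(status_counts = status_counts, duplication = duplication))
}

#' Demultiplex paired FASTQ into a UID count matrix
#'
#' Reads paired FASTQ (gz-transparent), parses every pair
#' ([parse_read_pairs()]), translates barcode ids to plate/well ids via the
#' run's barcode `assignment`, and collapses UIDs ([collapse_uids()]).
#'
#' @param r1_path,r2_path Paired FASTQ files.
#' @param whitelist A `barcode_whitelist`.
#' @param panel Panel tibble.
#' @param assignment Barcode assignment (list of `plate` and `well` tibbles,
#'   as produced by [default_barcode_assignment()]). When `NULL`, barcode ids
#'   themselves are used as plate/well ids.
#' @param min_reads_per_uid Minimum read pairs per UID.
#' @inheritParams parse_read_pairs
#' @return As [collapse_uids()], plus `parsed` row count in the QC report.
#' @export
demux_count <- function(r1_path, r2_path, whitelist, panel, assignment = NULL,
                        min_reads_per_uid = 1, max_mismatch_bc = 1,
                        max_mismatch_anchor = 2, max_mismatch_grna = 1,
                        uid_length = 14) {
  r1 <- read_fastq_seqs(r1_path)
  r2 <- read_fastq_seqs(r2_path)
  if (length(r1) != length(r2)) abort("read 1 and read 2 files differ in length")
  parsed <- parse_read_pairs(r1, r2, whitelist, panel,
                             max_mismatch_bc = max_mismatch_bc,
                             max_mismatch_anchor = max_mismatch_anchor,
                             max_mismatch_grna = max_mismatch_grna,
                             uid_length = uid_length)
  if (!is.null(assignment)) {
    plate_map <- stats::setNames(assignment$plate$plate_id,
                                 assignment$plate$barcode_id)
    well_map <- stats::setNames(assignment$well$well_id,
                                assignment$well$barcode_id)
    parsed$plate_id <- unname(plate_map[parsed$plate_bc_id])
    parsed$well_id <- unname(well_map[parsed$well_bc_id])
  }
  collapse_uids(parsed, min_reads_per_uid = min_reads_per_uid)
}
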