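# Generative model of the pooled co-culture screen.
#
# The assay is end-point: pools are seeded, exposed for ~72 h, then the
# integrated gRNA barcodes are amplified and sequenced with one UID per
# template molecule. A compound's effect on a knockout line is modelled as a
# kill fraction e in [0,1] acting on that line's expected end-point
# abundance; sequencing is a multinomial (optionally Dirichlet-multinomial)
# draw of UID counts over the lines of the well.

#' Anchor sequences of the amplicon layout
#'
#' `ANCHOR_FWD` sits between the plate barcode and the 20-nt gRNA on read 1;
#' `ANCHOR_REV` follows the well barcode and a 2-nt random spacer on read 2.
#' Both derive from the lentiviral construct flanking the integrated gRNA.
#' @export
ANCHOR_FWD <- "TGTGGAAAGGACGAAACACC"

#' @rdname ANCHOR_FWD
#' @export
ANCHOR_REV <- "CGGACTAGCCTTATTTTAACTTGC"

#' Ground-truth effect model for a simulated screen
#'
#' @param effects Tibble with columns `compound_id`, `gene`, `kill_fraction`
#'   (and optionally `dose_uM` to restrict an effect to one dose): the
#'   planted compound-gene interactions. `NULL` or empty means a null screen.
#' @param staurosporine_kill Kill fraction the cytotoxic control applies to
#'   every line (default 0.95).
#' @param nutlin_effect Kill fraction the MDM2-inhibitor control applies to
#'   lines whose knockout leaves TP53 intact, i.e. every line whose
#'   `target_gene` differs from `nutlin_spared_gene` (default 0.8, reflecting
#'   the 5-10x differential sensitivity of TP53-wild-type cells).
#' @param nutlin_spared_gene Gene whose knockouts escape the nutlin control.
#' @param baseline_fitness Optional tibble (`line_id`, `fitness`) of relative
#'   growth multipliers; lines absent from it have fitness 1.
#' @return A `truth_model` object.
#' @export
truth_model <- function(effects = NULL, staurosporine_kill = 0.95,
                        nutlin_effect = 0.8, nutlin_spared_gene = "TP53",
                        baseline_fitness = NULL) {
  if (is.null(effects)) {
    effects <- tibble::tibble(compound_id = character(), gene = character(),
                              kill_fraction = double())
  }
  effects <- tibble::as_tibble(effects)
  assert_columns(effects, c("compound_id", "gene", "kill_fraction"), "effects")
  kf <- c(effects$kill_fraction, staurosporine_kill, nutlin_effect)
  if (any(kf < 0 | kf > 1)) abort("kill fractions must lie in [0, 1]")
  if (!is.null(baseline_fitness)) {
    assert_columns(baseline_fitness, c("line_id", "fitness"), "baseline_fitness")
    if (any(baseline_fitness$fitness < 0)) abort("fitness must be non-negative")
  }
  structure(
    list(effects = effects, staurosporine_kill = staurosporine_kill,
         nutlin_effect = nutlin_effect, nutlin_spared_gene = nutlin_spared_gene,
         baseline_fitness = baseline_fitness),
    class = "truth_model"
  )
}

#' @export
print.truth_model <- function(x, ...) {
  cat("<truth_model>\n")
  cat(sprintf("  %d planted compound-gene effect(s); staurosporine kill %.2f; nutlin effect %.2f (spares %s)\n",
              nrow(x$effects), x$staurosporine_kill, x$nutlin_effect,
              x$nutlin_spared_gene))
  invisible(x)
}

# Kill fraction per line for one well, given its role/compound/dose.
well_kill_fractions <- function(truth, role, compound_id, dose_uM, target_genes) {
  k <- length(target_genes)
  if (role == "staurosporine") return(rep(truth$staurosporine_kill, k))
  if (role == "nutlin3a") {
    return(ifelse(target_genes == truth$nutlin_spared_gene, 0, truth$nutlin_effect))
  }
  if (role != "compound" || is.na(compound_id) || nrow(truth$effects) == 0) {
    return(rep(0, k))
  }
  eff <- truth$effects[truth$effects$compound_id == compound_id, , drop = FALSE]
  if ("dose_uM" %in% names(eff) && !is.na(dose_uM)) {
    eff <- eff[is.na(eff$dose_uM) | eff$dose_uM == dose_uM, , drop = FALSE]
  }
  e <- rep(0, k)
  if (nrow(eff) > 0) {
    m <- match(target_genes, eff$gene)
    e[!is.na(m)] <- eff$kill_fraction[m[!is.na(m)]]
  }
  e
}

#' Simulate UID counts for a pooled screen
#'
#' For each well, the expected end-point fraction of line *i* is
#' \deqn{p_i = n_i f_i (1 - e_i) / \sum_j n_j f_j (1 - e_j)}
#' where \eqn{n_i} is the seeding share (equal within a pool), \eqn{f_i} the
#' baseline fitness and \eqn{e_i} the role- or compound-appropriate kill
#' fraction. UID counts are then drawn multinomial(`depth_w`, p), or
#' Dirichlet-multinomial with concentration `overdispersion` when the latter
#' is finite (smaller values = noisier libraries; `Inf` recovers the pure
#' multinomial). If every line in a well is killed, the well's counts are
#' zero and the truth table flags it `all_killed`.
#'
#' With `depth_scaling = TRUE` (default) a well's total UID draw is scaled by
#' its survival fraction, `depth_w = round(depth * sum(n f (1 - e)) /
#' sum(n f))`: the library yield tracks surviving cell mass, which is what
#' the staurosporine non-specific-killing filter reads out. Setting it
#' `FALSE` draws the same depth in every well regardless of killing.
#'
#' @param design A list with elements `panel`, `pools`, `plates` (see
#'   [make_synthetic_design()]), already validated.
#' @param truth A [truth_model()].
#' @param depth Baseline total UID count per fully-surviving well (scalar,
#'   or vector recycled over wells in plate-map order).
#' @param overdispersion Dirichlet concentration; `Inf` = multinomial.
#' @param depth_scaling Scale each well's depth by its survival fraction
#'   (default `TRUE`).
#' @param seed Integer seed; the same seed reproduces counts exactly.
#' @return A `screen_sim` list: `counts` (tibble `plate_id`, `well_id`,
#'   `line_id`, `uid_count`) and `truth` (tibble with per-(well, line) kill
#'   fraction and expected fraction, plus `all_killed`).
#' @export
simulate_counts <- function(design, truth = truth_model(), depth = 50000,
                            overdispersion = Inf, depth_scaling = TRUE,
                            seed = 1) {
  panel <- design$panel
  pools <- design$pools
  plates <- design$plates
  if (any(depth < 0)) abort("depth must be non-negative")
  pool_lines <- stats::setNames(pools$line_ids, pools$pool_id)
  gene_of <- stats::setNames(panel$target_gene, panel$line_id)
  fit <- rep(1, nrow(panel))
  names(fit) <- panel$line_id
  if (!is.null(truth$baseline_fitness)) {
    m <- match(truth$baseline_fitness$line_id, names(fit))
    fit[m[!is.na(m)]] <- truth$baseline_fitness$fitness[!is.na(m)]
  }
  depth <- as.integer(rep_len(depth, nrow(plates)))

  with_seed(seed, {
    nw <- nrow(plates)
    cnt_l <- vector("list", nw)
    e_l <- vector("list", nw)
    exp_l <- vector("list", nw)
    ids_l <- vector("list", nw)
    killed <- logical(nw)
    for (i in seq_len(nw)) {
      ids <- pool_lines[[plates$pool_id[i]]]
      k <- length(ids)
      e <- well_kill_fractions(truth, plates$role[i], plates$compound_id[i],
                               plates$dose_uM[i], gene_of[ids])
      w <- (1 / k) * fit[ids] * (1 - e)
      tot <- sum(w)
      if (tot > 0) {
        p <- w / tot
        if (is.finite(overdispersion)) {
          g <- rgamma(k, shape = overdispersion * p, rate = 1)
          p <- if (sum(g) > 0) g / sum(g) else p
        }
        depth_i <- if (depth_scaling) {
          round(depth[i] * tot / sum((1 / k) * fit[ids]))
        } else {
          depth[i]
        }
        cnt <- as.integer(rmultinom(1, depth_i, p))
        expected <- unname(w / tot)
      } else {
        cnt <- rep(0L, k)
        expected <- rep(NA_real_, k)
      }
      ids_l[[i]] <- ids
      cnt_l[[i]] <- cnt
      e_l[[i]] <- unname(e)
      exp_l[[i]] <- expected
      killed[i] <- tot == 0
    }
    sizes <- lengths(ids_l)
    idx <- rep.int(seq_len(nw), sizes)
    full <- tibble::tibble(
      plate_id = plates$plate_id[idx],
      well_id = plates$well_id[idx],
      line_id = unlist(ids_l, use.names = FALSE),
      uid_count = unlist(cnt_l, use.names = FALSE),
      kill_fraction = unlist(e_l, use.names = FALSE),
      expected_fraction = unlist(exp_l, use.names = FALSE),
      all_killed = killed[idx]
    )
    structure(
      list(
        counts = full[c("plate_id", "well_id", "line_id", "uid_count")],
        truth = full[c("plate_id", "well_id", "line_id", "kill_fraction",
                       "expected_fraction", "all_killed")]
      ),
      class = "screen_sim"
    )
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim>\n")
  cat(sprintf("  %d (well, line) counts over %d wells; %d planted non-zero kill fractions\n",
              nrow(x$counts),
              nrow(dplyr::distinct(x$counts, .data$plate_id, .data$well_id)),
              sum(x$truth$kill_fraction > 0)))
  invisible(x)
}

#' @export
glance.screen_sim <- function(x, ...) {
  tibble::tibble(
    n_wells = nrow(dplyr::distinct(x$counts, .data$plate_id, .data$well_id)),
    n_lines = dplyr::n_distinct(x$counts$line_id),
    total_uids = sum(x$counts$uid_count),
    n_planted_effects = sum(x$truth$kill_fraction > 0 & !x$truth$all_killed)
  )
}

#' @export
tidy.screen_sim <- function(x, ...) {
  dplyr::left_join(x$counts, x$truth,
                   by = c("plate_id", "well_id", "line_id"))
}

#' Default assignment of physical barcodes to plates and wells
#'
#' Plates get plate barcodes in order of first appearance; wells get well
#' barcodes in grid order (A01..H12). The assignment is part of the run's
#' records and is required to translate demultiplexed barcode ids back to
#' plate/well ids.
#'
#' @param plates Plate-map tibble.
#' @param whitelist A `barcode_whitelist`.
#' @return A list of two tibbles: `plate` (`plate_id`, `barcode_id`) and
#'   `well` (`well_id`, `barcode_id`).
#' @export
default_barcode_assignment <- function(plates, whitelist) {
  plate_ids <- unique(plates$plate_id)
  if (length(plate_ids) > length(whitelist$plate_barcodes)) {
    abort("whitelist has fewer plate barcodes than the design has plates")
  }
  wells <- well_grid_96()
  if (length(wells) > length(whitelist$well_barcodes)) {
    abort("whitelist has fewer well barcodes than wells")
  }
  list(
    plate = tibble::tibble(plate_id = plate_ids,
                           barcode_id = names(whitelist$plate_barcodes)[seq_along(plate_ids)]),
    well = tibble::tibble(well_id = wells,
                          barcode_id = names(whitelist$well_barcodes)[seq_along(wells)])
  )
}

#' Emit paired FASTQ for simulated UID counts
#'
#' Each UID yields at least one read pair (per-UID duplication is geometric
#' on \{1, 2, ...\} with mean `duplication_mean`). Read 1 is
#' `UID(14) + plate_barcode + ANCHOR_FWD + gRNA(20)`; read 2 is
#' `well_barcode + NN spacer + ANCHOR_REV`, mirroring the forward/reverse
#' primer structure of the assay. Substitution errors are applied to every
#' base at `read_error_rate`. Qualities are constant (Phred 40, 'I').
#'
#' @param counts Count tibble (`plate_id`, `well_id`, `line_id`, `uid_count`).
#' @param whitelist A `barcode_whitelist`.
#' @param panel Panel tibble (provides each line's gRNA barcode).
#' @param r1_path,r2_path Output FASTQ paths.
#' @param assignment Barcode assignment ([default_barcode_assignment()]);
#'   computed from `counts` and `whitelist` when `NULL`.
#' @param duplication_mean Mean read pairs per UID (>= 1).
#' @param read_error_rate Per-base substitution probability in \[0, 0.1\].
#' @param uid_length UID length in nt (default 14).
#' @param seed Integer seed.
#' @return Invisibly, a list with `r1`, `r2`, the `assignment`, and `key`, a
#'   tibble of the true (plate, well, line, uid, n_reads) per molecule.
#' @export
emit_fastq <- function(counts, whitelist, panel, r1_path, r2_path,
                       assignment = NULL, duplication_mean = 1,
                       read_error_rate = 0, uid_length = 14, seed = 1) {
  if (duplication_mean < 1) abort("duplication_mean must be >= 1")
  if (read_error_rate < 0 || read_error_rate > 0.1) {
    abort("read_error_rate must lie in [0, 0.1]")
  }
  if (is.null(assignment)) {
    assignment <- default_barcode_assignment(counts, whitelist)
  }
  plate_bc <- stats::setNames(
    unname(whitelist$plate_barcodes[assignment$plate$barcode_id]),
    assignment$plate$plate_id)
  well_bc <- stats::setNames(
    unname(whitelist$well_barcodes[assignment$well$barcode_id]),
    assignment$well$well_id)
  grna <- stats::setNames(panel$grna_seq, panel$line_id)
  if (anyNA(plate_bc[counts$plate_id]) || anyNA(well_bc[counts$well_id])) {
    abort("counts reference plates/wells with no assigned barcode")
  }
  if (anyNA(grna[counts$line_id])) abort("counts reference lines absent from the panel")

  with_seed(seed, {
    nz <- counts[counts$uid_count > 0, , drop = FALSE]
    key <- nz[rep(seq_len(nrow(nz)), nz$uid_count),
              c("plate_id", "well_id", "line_id")]
    n_mol <- nrow(key)
    if (n_mol == 0) {
      uids <- character(0); dup <- integer(0)
    } else {
      # UIDs distinct within each (well, line) so conservation is exact.
      uids <- character(n_mol)
      for (idx in split(seq_len(n_mol),
                        paste(key$plate_id, key$well_id, key$line_id))) {
        uids[idx] <- random_dna_distinct(length(idx), uid_length)
      }
      dup <- rgeom(n_mol, prob = 1 / duplication_mean) + 1L
    }
    key$uid <- uids
    key$n_reads <- dup

    rep_idx <- rep(seq_len(n_mol), dup)
    r1 <- paste0(key$uid[rep_idx], plate_bc[key$plate_id[rep_idx]],
                 ANCHOR_FWD, grna[key$line_id[rep_idx]])
    spacer <- random_dna(length(rep_idx), 2)
    r2 <- paste0(well_bc[key$well_id[rep_idx]],
                 if (length(rep_idx)) spacer else character(0), ANCHOR_REV)
    r1 <- apply_substitution_errors(r1, read_error_rate)
    r2 <- apply_substitution_errors(r2, read_error_rate)

    ids <- sprintf("read%07d", seq_along(r1))
    write_fastq(r1, ids, r1_path)
    write_fastq(r2, ids, r2_path)
    invisible(list(r1 = r1_path, r2 = r2_path, assignment = assignment,
                   key = tibble::as_tibble(key)))
  })
}

# Constant-quality FASTQ writer/reader built on Biostrings.
write_fastq <- function(seqs, ids, path) {
  dss <- Biostrings::DNAStringSet(if (length(seqs)) seqs else character(0))
  names(dss) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

read_fastq_seqs <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(dss)
}

#' Simulate UID-tagged amplicon reads over a genotyping target
#'
#' Emulates SafeSeqS-style amplicon sequencing of a CRISPR-edited locus: a
#' short (66-80 bp) reference containing the predicted cut site, a set of
#' edited alleles, and a residual wild-type fraction. Reads are drawn
#' multinomially with `wt_fraction` for the unedited sequence and the
#' remainder split evenly across alleles; each read carries a fresh UID
#' (i.e. reads are already one-per-molecule consensi).
#'
#' @param reference Reference amplicon sequence (character, ACGT).
#' @param alleles Tibble with columns `kind` (`deletion` or `insertion`),
#'   `length` (nt), `position` (0-based: first deleted base for deletions;
#'   the base before the inserted sequence for insertions), and optionally
#'   `ins_seq` for a fixed inserted sequence (random when absent).
#' @param wt_fraction Fraction of wild-type molecules in \[0, 1\].
#' @param depth Number of molecules (UIDs) to draw.
#' @param seed Integer seed.
#' @param uid_length UID length (default 14).
#' @return Tibble (`uid`, `sequence`, `allele`) where `allele` is `"wt"` or
#'   the 1-based allele index as `"allele1"`, `"allele2"`, ...
#' @export
simulate_amplicon_reads <- function(reference, alleles, wt_fraction, depth,
                                    seed = 1, uid_length = 14) {
  reference <- toupper(reference)
  if (!is_dna(reference)) abort("reference must be a DNA string over ACGT")
  if (wt_fraction < 0 || wt_fraction > 1) abort("wt_fraction must lie in [0, 1]")
  alleles <- tibble::as_tibble(alleles)
  if (nrow(alleles) > 0) {
    assert_columns(alleles, c("kind", "length", "position"), "alleles")
  }
  with_seed(seed, {
    seqs <- character(nrow(alleles))
    for (i in seq_len(nrow(alleles))) {
      ins_seq <- if ("ins_seq" %in% names(alleles) && !is.na(alleles$ins_seq[i])) {
        alleles$ins_seq[i]
      } else if (alleles$kind[i] == "insertion") {
        random_dna(1, alleles$length[i])
      } else NA_character_
      seqs[i] <- apply_indel(reference, alleles$kind[i], alleles$length[i],
                             alleles$position[i], ins_seq)
    }
    labels <- c("wt", if (nrow(alleles)) paste0("allele", seq_len(nrow(alleles))))
    probs <- c(wt_fraction,
               if (nrow(alleles)) rep((1 - wt_fraction) / nrow(alleles), nrow(alleles)))
    if (sum(probs) == 0) abort("no molecules to draw: wt_fraction 0 and no alleles")
    if (depth == 0) {
      return(tibble::tibble(uid = character(), sequence = character(),
                            allele = character()))
    }
    n <- as.integer(rmultinom(1, depth, probs / sum(probs)))
    allele <- rep(labels, n)
    sequence <- rep(c(reference, seqs), n)
    tibble::tibble(uid = random_dna_distinct(depth, uid_length),
                   sequence = sequence, allele = allele)
  })
}

# Apply one simple indel to a reference; 0-based coordinates as documented
# in simulate_amplicon_reads().
apply_indel <- function(reference, kind, length, position, ins_seq = NA) {
  n <- nchar(reference)
  if (kind == "deletion") {
    if (position < 0 || position + length > n) {
      abort("deletion falls outside the reference")
    }
    paste0(substr(reference, 1, position), substr(reference, position + length + 1, n))
  } else if (kind == "insertion") {
    if (position < 0 || position >= n) abort("insertion position outside the reference")
    if (is.na(ins_seq)) abort("insertion requires a sequence")
    if (nchar(ins_seq) != length) abort("ins_seq length disagrees with `length`")
    paste0(substr(reference, 1, position + 1), ins_seq,
           substr(reference, position + 2, n))
  } else {
    abort(sprintf("unsupported allele kind '%s'", kind))
  }
}
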