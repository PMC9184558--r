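#' Build a synthetic screen design
#'
#' Constructs a complete, valid design for a simulated pooled screen: a
#' knockout panel, one co-culture pool per parental background, and replicate
#' 96-well plates. Per plate the layout is `n_compounds` compounds at each of
#' `doses` (filling `n_compounds * length(doses)` wells) plus control wells:
#' DMSO (vehicle), one untreated, one staurosporine and one nutlin-3a well.
#' The number of DMSO wells absorbs whatever space the compound wells leave,
#' with a minimum of 2 so that leave-one-out DMSO statistics are defined.
#'
#' The default geometry mirrors the study conditions at desk scale: pools of
#' 5-7 lines from one background seeded at 5,000 cells per well, two doses
#' (1 and 10 uM), and a focal gene represented by 2-3 independent knockout
#' lines in each of two backgrounds.
#'
#' @param backgrounds Parental backgrounds to screen (>= 2 for hit calling).
#' @param target_gene The focal gene.
#' @param n_target_lines Number of knockout lines of `target_gene` per
#'   background (recycled over `backgrounds`).
#' @param filler_genes Genes supplying one line each to fill pools.
#' @param pool_size Lines per pool (1-7).
#' @param n_plates_per_background Replicate plates per background.
#' @param n_compounds Number of library compounds (ids `C001`, `C002`, ...).
#' @param doses Doses in uM applied to every compound.
#' @param seeded_cells Total cells seeded per well.
#' @param seed Seed for the random gRNA barcodes.
#' @return A list of class `screen_design` with `panel`, `pools`, `plates`.
#' @export
make_synthetic_design <- function(backgrounds = c("RPE1", "MCF10A"),
                                  target_gene = "TP53",
                                  n_target_lines = c(3, 2),
                                  filler_genes = c("EZH2", "STAG2", "NOTCH1",
                                                   "MSH2", "PTEN"),
                                  pool_size = 6,
                                  n_plates_per_background = 2,
                                  n_compounds = 45,
                                  doses = c(1, 10),
                                  seeded_cells = 5000,
                                  seed = 1) {
  if (pool_size < 1 || pool_size > 7) abort("pool_size must lie in 1..7")
  n_target_lines <- rep_len(n_target_lines, length(backgrounds))
  if (any(pool_size - n_target_lines < 0)) {
    abort("pool_size must be >= n_target_lines")
  }
  if (any(pool_size - n_target_lines > length(filler_genes))) {
    abort("not enough filler_genes to fill pools")
  }

  panel <- dplyr::bind_rows(lapply(seq_along(backgrounds), function(b) {
    bg <- backgrounds[b]
    genes <- c(rep(target_gene, n_target_lines[b]),
               filler_genes[seq_len(pool_size - n_target_lines[b])])
    clone <- stats::ave(seq_along(genes), genes, FUN = seq_along)
    tibble::tibble(
      line_id = sprintf("%s_%s_%d", bg, genes, clone),
      background = bg,
      target_gene = genes,
      grna_seq = NA_character_,
      clone_label = sprintf("clone%d", clone)
    )
  }))
  panel$grna_seq <- with_seed(seed, {
    # pairwise-distinct gRNA barcodes; distance >= 3 keeps 1-mismatch
    # matching unambiguous in the demultiplexer
    kept <- character(0)
    while (length(kept) < nrow(panel)) {
      cand <- random_dna(1, 20)
      if (length(kept) == 0 || all(hamming_to(kept, cand) >= 3)) {
        kept <- c(kept, cand)
      }
    }
    kept
  })
  panel <- validate_panel(panel)

  pools <- tibble::tibble(
    pool_id = paste0("pool_", backgrounds),
    background = backgrounds,
    line_ids = lapply(backgrounds, function(bg) panel$line_id[panel$background == bg]),
    seeded_cells = as.integer(seeded_cells)
  )

  wells <- well_grid_96()
  n_compound_wells <- n_compounds * length(doses)
  n_ctrl <- 96 - n_compound_wells
  if (n_ctrl < 5) {
    abort("n_compounds x doses leaves fewer than 5 control wells on the plate")
  }
  compound_ids <- sprintf("C%03d", seq_len(n_compounds))
  layout <- tibble::tibble(
    well_id = wells,
    compound_id = c(rep(compound_ids, times = length(doses)),
                    rep(NA_character_, n_ctrl)),
    dose_uM = c(rep(doses, each = n_compounds), rep(NA_real_, n_ctrl)),
    role = c(rep("compound", n_compound_wells),
             rep("dmso", n_ctrl - 3),
             "untreated", "staurosporine", "nutlin3a")
  )

  plates <- dplyr::bind_rows(lapply(seq_along(backgrounds), function(b) {
    dplyr::bind_rows(lapply(seq_len(n_plates_per_background), function(r) {
      dplyr::mutate(layout,
                    plate_id = sprintf("%s_plate%d", backgrounds[b], r),
                    pool_id = pools$pool_id[b],
                    .before = 1)
    }))
  }))
  plates <- suppressWarnings(validate_plates(plates, pools))

  structure(list(panel = panel, pools = pools, plates = plates),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("<screen_design>\n")
  cat(sprintf("  %d lines / %d pools / %d plates (%d wells)\n",
              nrow(x$panel), nrow(x$pools),
              length(unique(x$plates$plate_id)), nrow(x$plates)))
  invisible(x)
}

#' @export
glance.screen_design <- function(x, ...) {
  rep <- suppressWarnings(validate_design(x$panel, x$pools, x$plates, strict = FALSE))
  glance(rep)
}

#' A small example knockout panel
#'
#' Six RPE1 and six MCF10A lines covering TP53 and five other genes; handy
#' for examples and tests.
#'
#' @param seed Seed for the gRNA barcodes.
#' @return A panel tibble.
#' @export
example_panel <- function(seed = 1) {
  make_synthetic_design(seed = seed)$panel
}
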