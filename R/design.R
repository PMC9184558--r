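#' Roles a well can play on a screen plate
#'
#' Treated wells carry a compound and dose; `dmso` (vehicle-only) and
#' `untreated` wells are negative controls, `staurosporine` (broadly
#' cytotoxic) anchors the non-specific-killing filter, and `nutlin3a`
#' (MDM2 inhibitor, selectively toxic to TP53-wild-type cells) is the
#' positive control. Control roles never carry a `compound_id`.
#'
#' @export
WELL_ROLES <- c("compound", "dmso", "untreated", "staurosporine", "nutlin3a")

#' Parental cell-line backgrounds of the knockout panel
#' @export
BACKGROUNDS <- c("RPE1", "MCF10A", "RPTec")

validate_panel <- function(panel) {
  assert_columns(panel, c("line_id", "background", "target_gene", "grna_seq"),
                 "panel table")
  if (!"clone_label" %in% names(panel)) panel$clone_label <- NA_character_
  panel <- tibble::as_tibble(panel)
  dup <- panel$line_id[duplicated(panel$line_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate line_id in panel: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_bg <- setdiff(unique(panel$background), BACKGROUNDS)
  if (length(bad_bg) > 0) {
    abort(sprintf("unknown background(s): %s (expected one of %s)",
                  paste(bad_bg, collapse = ", "),
                  paste(BACKGROUNDS, collapse = ", ")))
  }
  bad <- which(nchar(panel$grna_seq) != 20L | !is_dna(panel$grna_seq))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid gRNA sequence (must be 20 nt over ACGT) in panel row(s) %s (line_id %s)",
      paste(bad, collapse = ", "),
      paste(panel$line_id[bad], collapse = ", ")))
  }
  panel
}

#' Read the knockout panel table
#'
#' One row per engineered knockout clone. Required columns: `line_id`
#' (unique), `background` (one of `r paste(BACKGROUNDS, collapse = ", ")`),
#' `target_gene`, `grna_seq` (the 20-nt integrated gRNA acting as the line's
#' genetic barcode) and optionally `clone_label`. Files are tab-separated,
#' UTF-8, with `#` comment lines.
#'
#' @param path Path to a tab-separated panel file.
#' @return A tibble with one validated row per panel line.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_panel_table(example_panel(), f)
#' read_panel_table(f)
read_panel_table <- function(path) {
  panel <- read_tsv_commented(path, readr::cols(.default = readr::col_character()))
  validate_panel(panel)
}

#' Write a panel table
#'
#' Inverse of [read_panel_table()]; round-trips field-for-field.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(panel, path) {
  panel <- validate_panel(panel)
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

validate_pools <- function(pools, panel = NULL) {
  assert_columns(pools, c("pool_id", "background", "line_ids"), "pool table")
  pools <- tibble::as_tibble(pools)
  if (!"seeded_cells" %in% names(pools)) pools$seeded_cells <- 5000L
  if (!is.list(pools$line_ids)) {
    pools$line_ids <- strsplit(as.character(pools$line_ids), ",", fixed = TRUE)
    pools$line_ids <- lapply(pools$line_ids, trimws)
  }
  sizes <- lengths(pools$line_ids)
  if (any(sizes > 7)) {
    abort(sprintf("pool(s) with more than 7 lines: %s",
                  paste(pools$pool_id[sizes > 7], collapse = ", ")))
  }
  if (any(sizes < 1)) abort("empty pool(s)")
  if (any(sizes < 5)) {
    warn(sprintf("pool(s) with fewer than 5 lines (allowed, but 5-7 is the production design): %s",
                 paste(pools$pool_id[sizes < 5], collapse = ", ")))
  }
  if (any(pools$seeded_cells <= 0)) abort("seeded_cells must be positive")
  if (!is.null(panel)) {
    unknown <- setdiff(unlist(pools$line_ids), panel$line_id)
    if (length(unknown) > 0) {
      abort(sprintf("pool references unknown line_id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    bg <- stats::setNames(panel$background, panel$line_id)
    gr <- stats::setNames(panel$grna_seq, panel$line_id)
    for (i in seq_len(nrow(pools))) {
      ids <- pools$line_ids[[i]]
      if (!all(bg[ids] == pools$background[i])) {
        abort(sprintf(
          "pool %s mixes backgrounds: lines must share the pool's parental background (%s)",
          pools$pool_id[i], pools$background[i]))
      }
      if (anyDuplicated(gr[ids])) {
        abort(sprintf("pool %s contains lines with identical gRNA barcodes; they would be indistinguishable",
                      pools$pool_id[i]))
      }
    }
  }
  pools
}

#' Read the pool table
#'
#' One row per co-culture pool: `pool_id`, `background`, `line_ids`
#' (comma-joined line ids, 5-7 per pool in the production design; smaller
#' pools are accepted with a warning) and `seeded_cells` (total cells seeded
#' per well, default 5000).
#'
#' @param path Path to a tab-separated pool file.
#' @param panel Optional panel tibble for cross-reference checks.
#' @return A tibble with `line_ids` as a list-column.
#' @export
read_pool_table <- function(path, panel = NULL) {
  pools <- read_tsv_commented(path, readr::cols(
    pool_id = readr::col_character(),
    background = readr::col_character(),
    line_ids = readr::col_character(),
    seeded_cells = readr::col_integer()
  ))
  validate_pools(pools, panel)
}

validate_plates <- function(plates, pools = NULL) {
  assert_columns(plates, c("plate_id", "well_id", "pool_id", "role"), "plate map")
  plates <- tibble::as_tibble(plates)
  if (!"compound_id" %in% names(plates)) plates$compound_id <- NA_character_
  if (!"dose_uM" %in% names(plates)) plates$dose_uM <- NA_real_
  bad_role <- setdiff(unique(plates$role), WELL_ROLES)
  if (length(bad_role) > 0) {
    abort(sprintf("unknown well role(s): %s", paste(bad_role, collapse = ", ")))
  }
  grid <- well_grid_96()
  for (pid in unique(plates$plate_id)) {
    wells <- plates$well_id[plates$plate_id == pid]
    if (length(wells) != 96L || !setequal(wells, grid) || anyDuplicated(wells)) {
      abort(sprintf("plate %s does not form the full 96-well grid (A01..H12)", pid))
    }
    roles <- plates$role[plates$plate_id == pid]
    if (!"dmso" %in% roles) abort(sprintf("plate %s has no DMSO well", pid))
    if (!"staurosporine" %in% roles) {
      abort(sprintf("plate %s has no staurosporine well (required by the non-specific-killing filter)", pid))
    }
  }
  ctrl <- plates$role != "compound" & !is.na(plates$compound_id)
  if (any(ctrl)) {
    abort("control wells must not carry a compound_id (controls are named by role)")
  }
  if (!is.null(pools)) {
    unknown <- setdiff(unique(plates$pool_id), pools$pool_id)
    if (length(unknown) > 0) {
      abort(sprintf("plate map references unknown pool_id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  plates
}

#' Read plate maps
#'
#' One row per well: `plate_id`, `well_id` (A01..H12), `pool_id`,
#' `compound_id` (empty for control roles), `dose_uM`, `role` (see
#' [WELL_ROLES]). Every plate must form the complete 96-well grid and carry
#' at least one DMSO and one staurosporine well, which downstream statistics
#' require.
#'
#' @param path Path to a tab-separated plate-map file.
#' @param pools Optional pool tibble for cross-reference checks.
#' @return A tibble of well specifications.
#' @export
read_plate_maps <- function(path, pools = NULL) {
  plates <- read_tsv_commented(path, readr::cols(
    plate_id = readr::col_character(),
    well_id = readr::col_character(),
    pool_id = readr::col_character(),
    compound_id = readr::col_character(),
    dose_uM = readr::col_double(),
    role = readr::col_character()
  ))
  validate_plates(plates, pools)
}

#' Construct a barcode whitelist
#'
#' @param plate_barcodes,well_barcodes Named character vectors of DNA
#'   barcodes (names are barcode ids; unnamed vectors get `P1..`/`W1..`).
#'   All barcodes within a list must share one length and be pairwise
#'   distinct. The production design uses 25 plate and 192 well barcodes.
#' @return An object of class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(plate_barcodes, well_barcodes) {
  name_if <- function(x, prefix) {
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    x
  }
  plate_barcodes <- name_if(toupper(plate_barcodes), "P")
  well_barcodes <- name_if(toupper(well_barcodes), "W")
  for (set in list(plate = plate_barcodes, well = well_barcodes)) {
    if (length(unique(nchar(set))) != 1) abort("barcodes within a list must share one length")
    if (!all(is_dna(set))) abort("barcodes must be DNA strings over ACGT")
    if (anyDuplicated(set)) abort("barcodes within a list must be pairwise distinct")
  }
  structure(
    list(plate_barcodes = plate_barcodes, well_barcodes = well_barcodes),
    class = "barcode_whitelist"
  )
}

#' Read a barcode whitelist table
#'
#' Columns: `kind` (`plate` or `well`), `barcode_id`, `sequence`.
#' Barcode lengths are not fixed by the assay and are inferred from the file.
#'
#' @param path Path to a tab-separated barcode file.
#' @return A `barcode_whitelist`.
#' @export
read_barcode_table <- function(path) {
  bc <- read_tsv_commented(path, readr::cols(.default = readr::col_character()))
  assert_columns(bc, c("kind", "barcode_id", "sequence"), "barcode table")
  barcode_whitelist(
    plate_barcodes = stats::setNames(bc$sequence[bc$kind == "plate"],
                                     bc$barcode_id[bc$kind == "plate"]),
    well_barcodes = stats::setNames(bc$sequence[bc$kind == "well"],
                                    bc$barcode_id[bc$kind == "well"])
  )
}

#' Generate a random barcode whitelist
#'
#' Barcodes are drawn with pairwise Hamming distance of at least
#' `min_distance` so that single-mismatch demultiplexing is unambiguous.
#'
#' @param n_plate,n_well Number of plate and well barcodes (defaults match
#'   the 25/192 production sets).
#' @param width Barcode length in nt.
#' @param min_distance Minimum pairwise Hamming distance within each list.
#' @param seed Integer seed.
#' @return A `barcode_whitelist`.
#' @export
make_barcode_whitelist <- function(n_plate = 25, n_well = 192, width = 8,
                                   min_distance = 3, seed = 1) {
  gen <- function(n, prefix) {
    kept <- character(0)
    tries <- 0L
    while (length(kept) < n) {
      cand <- random_dna(1, width)
      if (length(kept) == 0 || all(hamming_to(kept, cand) >= min_distance)) {
        kept <- c(kept, cand)
      }
      tries <- tries + 1L
      if (tries > 200000L) abort("could not generate whitelist; lower min_distance or raise width")
    }
    stats::setNames(kept, paste0(prefix, seq_len(n)))
  }
  with_seed(seed, barcode_whitelist(gen(n_plate, "P"), gen(n_well, "W")))
}

#' Bundle and cross-validate a screen design
#'
#' Checks that all cross-references resolve (pool lines exist in the panel,
#' plate wells reference known pools), that pools respect the co-culture
#' rules (at most 7 lines, one parental background per pool, distinct gRNA
#' barcodes), that each plate forms a full 96-well grid with DMSO and
#' staurosporine control wells, and that the whitelist is large enough for
#' the number of plates.
#'
#' @param panel Panel tibble ([read_panel_table()]).
#' @param pools Pool tibble ([read_pool_table()]).
#' @param plates Plate-map tibble ([read_plate_maps()]).
#' @param whitelist Optional `barcode_whitelist`.
#' @param strict If `TRUE` (default) hard violations abort; otherwise they
#'   are collected in the report.
#' @return A `design_report`: a list with `valid`, `errors`, `warnings`,
#'   and summary counts including `n_measurements`, the number of
#'   (well, line) growth measurements the design yields.
#' @export
validate_design <- function(panel, pools, plates, whitelist = NULL,
                            strict = TRUE) {
  errors <- character(0)
  warnings <- character(0)
  note <- function(cond) conditionMessage(cond)
  panel2 <- tryCatch(validate_panel(panel),
                     error = function(e) { errors <<- c(errors, note(e)); panel })
  pools2 <- withCallingHandlers(
    tryCatch(validate_pools(pools, panel2),
             error = function(e) { errors <<- c(errors, note(e)); validate_pools(pools) }),
    warning = function(w) { warnings <<- c(warnings, note(w)); invokeRestart("muffleWarning") }
  )
  plates2 <- tryCatch(validate_plates(plates, pools2),
                      error = function(e) { errors <<- c(errors, note(e)); plates })

  n_plates <- length(unique(plates2$plate_id))
  if (!is.null(whitelist)) {
    if (n_plates > length(whitelist$plate_barcodes)) {
      errors <- c(errors, sprintf(
        "%d plates exceed the %d available plate barcodes",
        n_plates, length(whitelist$plate_barcodes)))
    }
  }
  pool_size <- stats::setNames(lengths(pools2$line_ids), pools2$pool_id)
  n_measurements <- sum(pool_size[plates2$pool_id], na.rm = TRUE)

  if (strict && length(errors) > 0) {
    abort(paste(c("invalid screen design:", errors), collapse = "\n- "))
  }
  structure(
    list(
      valid = length(errors) == 0,
      errors = errors,
      warnings = warnings,
      n_lines = nrow(panel2),
      n_pools = nrow(pools2),
      n_plates = n_plates,
      n_wells = nrow(plates2),
      n_measurements = n_measurements
    ),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  cat(sprintf("  valid: %s\n", x$valid))
  cat(sprintf("  %d lines, %d pools, %d plates, %d wells, %d (well, line) measurements\n",
              x$n_lines, x$n_pools, x$n_plates, x$n_wells, x$n_measurements))
  if (length(x$errors)) cat("  errors:\n", paste0("   - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat("  warnings:\n", paste0("   - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

#' @export
glance.design_report <- function(x, ...) {
  tibble::tibble(
    valid = x$valid,
    n_lines = x$n_lines,
    n_pools = x$n_pools,
    n_plates = x$n_plates,
    n_wells = x$n_wells,
    n_measurements = x$n_measurements,
    n_errors = length(x$errors),
    n_warnings = length(x$warnings)
  )
}

#' @export
tidy.design_report <- function(x, ...) {
  tibble::tibble(
    severity = c(rep("error", length(x$errors)), rep("warning", length(x$warnings))),
    message = c(x$errors, x$warnings)
  )
}

#' Read the panel-composition summary table
#'
#' A per-gene summary of the knockout panel: gene symbol, number of gRNAs
#' designed against it, and the number of validated knockout lines obtained
#' in each parental background. The copy bundled with the package
#' (`system.file("extdata", "panel_composition.tsv", package = "poolscreen")`)
#' describes the 25-gene cancer-pathway panel.
#'
#' @param path Path to a tab-separated composition file; defaults to the
#'   bundled panel.
#' @return A tibble with columns `gene`, `n_grna`, one column per background,
#'   and `core_pathway`.
#' @export
read_panel_composition <- function(path = NULL) {
  path <- path %||% system.file("extdata", "panel_composition.tsv",
                                package = "poolscreen", mustWork = TRUE)
  read_tsv_commented(path, readr::cols(
    gene = readr::col_character(),
    chromosome = readr::col_character(),
    n_grna = readr::col_integer(),
    RPE1 = readr::col_integer(),
    MCF10A = readr::col_integer(),
    RPTec = readr::col_integer(),
    core_pathway = readr::col_character()
  ))
}

#' Arithmetic of a screen's scale
#'
#' Derives the bookkeeping quantities of a multiplexed screen from its design
#' parameters: interactions scored (compounds x lines x doses), SafeSeqS
#' primer pairs needed for genotyping (two per gRNA), lines per background,
#' panel size, total gRNAs, and theoretical gene-background combinations.
#'
#' @param composition Panel composition tibble ([read_panel_composition()]).
#' @param n_compounds Number of compounds in the library.
#' @param n_screened_lines Number of lines actually screened.
#' @param n_doses Number of doses per compound.
#' @param primer_pairs_per_grna Genotyping primer pairs designed per gRNA.
#' @return A one-row tibble of scale quantities.
#' @export
screen_scale <- function(composition = read_panel_composition(),
                         n_compounds, n_screened_lines, n_doses = 2,
                         primer_pairs_per_grna = 2) {
  bg_cols <- intersect(BACKGROUNDS, names(composition))
  tibble::tibble(
    n_genes = nrow(composition),
    n_backgrounds = length(bg_cols),
    n_grnas = sum(composition$n_grna),
    panel_size = sum(as.matrix(composition[bg_cols])),
    lines_RPE1 = sum(composition$RPE1),
    lines_MCF10A = sum(composition$MCF10A),
    lines_RPTec = sum(composition$RPTec),
    primer_pairs = primer_pairs_per_grna * sum(composition$n_grna),
    gene_background_combinations = nrow(composition) * length(bg_cols),
    interactions_scored = n_compounds * n_screened_lines * n_doses
  )
}
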