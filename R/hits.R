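# Hit calling: a (compound, line) observation is a compound of interest when
# it is statistically significant (Z at or below the line's power-dependent
# threshold), biologically significant (>50% inhibition vs same-plate DMSO)
# and sits in a well not flagged for non-specific killing. A compound is a
# hit for a gene when a strict majority of that gene's screened lines pass
# in at least two parental backgrounds.

#' Score treated wells against the compound-of-interest criteria
#'
#' @param scores Scored table: the output of [abundance_ratios()] piped
#'   through [plate_zscores()] and [inhibition()] (must carry `z`,
#'   `inhibition`, `role`).
#' @param flags Output of [nonspecific_filter()].
#' @param power Output of [classify_power()] (per-line `z_threshold`).
#' @param plates Plate-map tibble (provides `compound_id`, `dose_uM`).
#' @param inhibition_threshold Minimum inhibition (default 0.5, strict `>`).
#' @param roles Well roles to evaluate (default `"compound"`).
#' @return Tibble, one row per evaluated (well, line): identifiers, `z`,
#'   `inhibition`, `nonspecific`, `z_threshold`, `status`, `passed`.
#'   Undefined `z` or inhibition never passes.
#' @export
compounds_of_interest <- function(scores, flags, power, plates,
                                  inhibition_threshold = 0.5,
                                  roles = "compound") {
  assert_columns(scores, c("plate_id", "well_id", "line_id", "z", "inhibition",
                           "role"), "scores")
  scores |>
    dplyr::filter(.data$role %in% roles) |>
    dplyr::left_join(dplyr::select(plates, "plate_id", "well_id",
                                   "compound_id", "dose_uM"),
                     by = c("plate_id", "well_id")) |>
    dplyr::left_join(dplyr::select(flags, "plate_id", "well_id", "nonspecific"),
                     by = c("plate_id", "well_id")) |>
    dplyr::left_join(dplyr::select(power, "line_id", "status", "z_threshold"),
                     by = "line_id") |>
    dplyr::mutate(passed =
                    !is.na(.data$z) & !is.na(.data$inhibition) &
                    !is.na(.data$z_threshold) &
                    !dplyr::coalesce(.data$nonspecific, TRUE) &
                    .data$z <= .data$z_threshold &
                    .data$inhibition > inhibition_threshold) |>
    dplyr::select("compound_id", "dose_uM", "plate_id", "well_id", "line_id",
                  "z", "inhibition", "nonspecific", "status", "z_threshold",
                  "passed")
}

#' Call hits with the two-background majority rule
#'
#' A line passes for a compound when any of its observations (either dose,
#' any plate) passed the compound-of-interest criteria. A background supports
#' a (compound, gene) pair when strictly more than half of that gene's
#' screened lines in that background pass (1 of 2 is not a majority; a
#' single screened line counts 1/1). A compound is a hit for a gene when at
#' least `min_backgrounds` backgrounds support it. Genes screened in fewer
#' than `min_backgrounds` backgrounds can never be hits and are reported
#' `untestable`.
#'
#' @param coi Output of [compounds_of_interest()].
#' @param panel Panel tibble (maps lines to genes and backgrounds).
#' @param screened_lines Character vector of line ids actually screened
#'   (default: all lines appearing in `coi`).
#' @param min_backgrounds Supporting backgrounds required (default 2).
#' @return Tibble, one row per (compound, gene) with at least one screened
#'   line: vote counts per background (`votes` list-column),
#'   `n_backgrounds_supporting`, `untestable`, `hit`.
#' @export
call_hits <- function(coi, panel, screened_lines = NULL, min_backgrounds = 2) {
  screened_lines <- screened_lines %||% unique(coi$line_id)
  meta <- panel |>
    dplyr::filter(.data$line_id %in% screened_lines) |>
    dplyr::select("line_id", "background", "target_gene")
  screened <- meta |>
    dplyr::group_by(.data$target_gene, .data$background) |>
    dplyr::summarise(n_screened = dplyr::n_distinct(.data$line_id),
                     .groups = "drop")
  line_pass <- coi |>
    dplyr::inner_join(meta, by = "line_id") |>
    dplyr::group_by(.data$compound_id, .data$target_gene, .data$background,
                    .data$line_id) |>
    dplyr::summarise(line_passed = any(.data$passed, na.rm = TRUE),
                     .groups = "drop")
  votes <- line_pass |>
    dplyr::group_by(.data$compound_id, .data$target_gene, .data$background) |>
    dplyr::summarise(n_passing = sum(.data$line_passed), .groups = "drop") |>
    dplyr::left_join(screened, by = c("target_gene", "background")) |>
    dplyr::mutate(supports = .data$n_passing > .data$n_screened / 2)
  n_bg_screened <- screened |>
    dplyr::group_by(.data$target_gene) |>
    dplyr::summarise(n_backgrounds_screened = dplyr::n(), .groups = "drop")
  votes |>
    dplyr::group_by(.data$compound_id, .data$target_gene) |>
    dplyr::summarise(
      votes = list(dplyr::pick("background", "n_passing", "n_screened",
                               "supports")),
      n_backgrounds_supporting = sum(.data$supports),
      backgrounds_supporting = list(.data$background[.data$supports]),
      .groups = "drop") |>
    dplyr::left_join(n_bg_screened, by = "target_gene") |>
    dplyr::mutate(
      untestable = .data$n_backgrounds_screened < min_backgrounds,
      hit = !.data$untestable &
        .data$n_backgrounds_supporting >= min_backgrounds)
}

#' Negative-control (DMSO) false-positive rate
#'
#' Applies the compound-of-interest criteria to every DMSO (well, line)
#' evaluation as though the vehicle were a compound: Z at or below the
#' line's threshold, leave-one-out inhibition above the threshold (see
#' [inhibition()]), and the well not flagged non-specific. The returned rate
#' is the fraction of evaluations meeting all criteria.
#'
#' @inheritParams compounds_of_interest
#' @return One-row tibble: `n_evaluations`, `n_false_positive`, `fpr`.
#' @export
dmso_false_positive_rate <- function(scores, flags, power, plates,
                                     inhibition_threshold = 0.5) {
  if (!any(plates$role == "dmso")) {
    abort("the screen contains no DMSO wells to evaluate")
  }
  dmso <- compounds_of_interest(scores, flags, power, plates,
                                inhibition_threshold = inhibition_threshold,
                                roles = "dmso")
  if (nrow(dmso) == 0) abort("the screen contains no DMSO wells to evaluate")
  tibble::tibble(
    n_evaluations = nrow(dmso),
    n_false_positive = sum(dmso$passed),
    fpr = sum(dmso$passed) / nrow(dmso)
  )
}
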