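# Plate-level ratiometric statistics: abundance ratios, median-centred
# Z-scores, the staurosporine non-specific-killing filter, percent
# inhibition against same-plate DMSO wells, and the staurosporine/DMSO
# control response. Undefined quantities propagate as NA, never as zero.

#' Per-well abundance ratios
#'
#' The assay's primary readout: each line's UID count divided by the well's
#' total UID count. Wells with total 0 get `NA` ratios and are flagged so
#' downstream statistics can exclude them.
#'
#' @param counts Count tibble (`plate_id`, `well_id`, `line_id`, `uid_count`).
#' @return A tibble adding `well_total`, `ratio`, `zero_total`.
#' @export
abundance_ratios <- function(counts) {
  assert_columns(counts, c("plate_id", "well_id", "line_id", "uid_count"),
                 "counts")
  counts |>
    dplyr::group_by(.data$plate_id, .data$well_id) |>
    dplyr::mutate(
      well_total = sum(.data$uid_count),
      ratio = ifelse(.data$well_total > 0,
                     .data$uid_count / .data$well_total, NA_real_),
      zero_total = .data$well_total == 0
    ) |>
    dplyr::ungroup()
}

#' Plate-wise ratiometric Z-scores
#'
#' For each (plate, line), a well's Z-score is its abundance ratio centred on
#' the plate median of that line's ratios and scaled by their standard
#' deviation:
#' \deqn{z = (ratio - median_{plate}) / sd_{plate}}
#' The plate median and SD are computed over all wells of the plate with a
#' defined ratio for the line, including the well under evaluation
#' (`exclude_self = TRUE` switches to a leave-one-out context). The SD is the
#' sample (n-1) standard deviation by default (`sd_mode = "population"` for
#' the n denominator). Fewer than 3 usable wells, or a zero SD, leaves `z`
#' undefined (`NA`) with a warning.
#'
#' @param ratios Tibble from [abundance_ratios()].
#' @param sd_mode `"sample"` (n-1, default) or `"population"` (n).
#' @param exclude_self Leave the well under evaluation out of its own plate
#'   median/SD. Default `FALSE` (all wells pooled).
#' @return `ratios` with `plate_median`, `plate_sd` and `z` columns.
#' @export
plate_zscores <- function(ratios, sd_mode = c("sample", "population"),
                          exclude_self = FALSE) {
  sd_mode <- match.arg(sd_mode)
  assert_columns(ratios, c("plate_id", "well_id", "line_id", "ratio"), "ratios")
  sd_fun <- function(x) {
    n <- length(x)
    if (n < 2) return(NA_real_)
    s <- sd(x)
    if (sd_mode == "population") s * sqrt((n - 1) / n) else s
  }
  res <- ratios |>
    dplyr::group_by(.data$plate_id, .data$line_id) |>
    dplyr::mutate(n_defined = sum(!is.na(.data$ratio))) |>
    dplyr::mutate(
      plate_median = dplyr::if_else(
        .data$n_defined >= 3,
        if (exclude_self) {
          vapply(seq_along(.data$ratio), function(i)
            median(.data$ratio[-i], na.rm = TRUE), numeric(1))
        } else {
          rep(median(.data$ratio, na.rm = TRUE), dplyr::n())
        },
        NA_real_),
      plate_sd = dplyr::if_else(
        .data$n_defined >= 3,
        if (exclude_self) {
          vapply(seq_along(.data$ratio), function(i)
            sd_fun(.data$ratio[-i][!is.na(.data$ratio[-i])]), numeric(1))
        } else {
          rep(sd_fun(.data$ratio[!is.na(.data$ratio)]), dplyr::n())
        },
        NA_real_),
      z = dplyr::if_else(!is.na(.data$plate_sd) & .data$plate_sd > 0,
                         (.data$ratio - .data$plate_median) / .data$plate_sd,
                         NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_defined")
  starved <- ratios |>
    dplyr::group_by(.data$plate_id, .data$line_id) |>
    dplyr::summarise(n_defined = sum(!is.na(.data$ratio)), .groups = "drop") |>
    dplyr::filter(.data$n_defined < 3)
  if (nrow(starved) > 0) {
    warn(sprintf(
      "%d (plate, line) group(s) have fewer than 3 wells with defined ratios; their z-scores are undefined",
      nrow(starved)))
  }
  res
}

#' Flag non-specific cell killing against the staurosporine control
#'
#' A well is flagged non-specific when its total UID count is less than
#' two-fold the same-plate staurosporine well's total (strictly:
#' `total < fold * staurosporine_total`). With several staurosporine wells
#' their mean total is used. Such wells indicate generalised cytotoxicity
#' and are excluded from hit calling.
#'
#' @param counts Count tibble.
#' @param plates Plate-map tibble (provides well roles).
#' @param fold Fold threshold over the staurosporine total (default 2).
#' @return Tibble (`plate_id`, `well_id`, `role`, `well_total`,
#'   `stauro_total`, `nonspecific`).
#' @export
nonspecific_filter <- function(counts, plates, fold = 2) {
  totals <- counts |>
    dplyr::group_by(.data$plate_id, .data$well_id) |>
    dplyr::summarise(well_total = sum(.data$uid_count), .groups = "drop") |>
    dplyr::right_join(
      dplyr::select(plates, "plate_id", "well_id", "role"),
      by = c("plate_id", "well_id")) |>
    dplyr::mutate(well_total = dplyr::coalesce(.data$well_total, 0L))
  stauro <- totals |>
    dplyr::filter(.data$role == "staurosporine") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(stauro_total = mean(.data$well_total), .groups = "drop")
  missing <- setdiff(unique(totals$plate_id), stauro$plate_id)
  if (length(missing) > 0) {
    abort(sprintf("plate(s) without a staurosporine well: %s",
                  paste(missing, collapse = ", ")))
  }
  totals |>
    dplyr::left_join(stauro, by = "plate_id") |>
    dplyr::mutate(nonspecific = .data$well_total < fold * .data$stauro_total)
}

#' Percent inhibition relative to same-plate DMSO wells
#'
#' For each (plate, line), a treated well's inhibition is
#' `1 - ratio / mean(DMSO ratios)`, floored at 0 (growth advantages are not
#' reported as negative inhibition). Undefined when the line's mean DMSO
#' ratio is 0 or no DMSO ratio is defined. For DMSO wells themselves the
#' reference mean is computed leave-one-out (over the other DMSO wells of
#' the plate), so the negative-control false-positive evaluation is not
#' trivially anchored at 0; plates with a single DMSO well therefore leave
#' that well's inhibition undefined.
#'
#' @param ratios Tibble from [abundance_ratios()].
#' @param plates Plate-map tibble.
#' @return `ratios` with `dmso_mean_ratio` and `inhibition` columns and the
#'   well `role` joined in.
#' @export
inhibition <- function(ratios, plates) {
  ratios <- dplyr::left_join(
    ratios, dplyr::select(plates, "plate_id", "well_id", "role"),
    by = c("plate_id", "well_id"))
  dmso <- ratios |>
    dplyr::filter(.data$role == "dmso", !is.na(.data$ratio)) |>
    dplyr::group_by(.data$plate_id, .data$line_id) |>
    dplyr::summarise(dmso_sum = sum(.data$ratio), dmso_n = dplyr::n(),
                     .groups = "drop")
  ratios |>
    dplyr::left_join(dmso, by = c("plate_id", "line_id")) |>
    dplyr::mutate(
      dmso_mean_ratio = dplyr::case_when(
        is.na(.data$dmso_n) ~ NA_real_,
        # leave-one-out for the DMSO wells themselves
        .data$role == "dmso" & !is.na(.data$ratio) & .data$dmso_n > 1 ~
          (.data$dmso_sum - .data$ratio) / (.data$dmso_n - 1),
        .data$role == "dmso" ~ NA_real_,
        TRUE ~ .data$dmso_sum / .data$dmso_n
      ),
      inhibition = dplyr::if_else(
        !is.na(.data$dmso_mean_ratio) & .data$dmso_mean_ratio > 0 &
          !is.na(.data$ratio),
        pmax(0, 1 - .data$ratio / .data$dmso_mean_ratio),
        NA_real_)
    ) |>
    dplyr::select(-"dmso_sum", -"dmso_n")
}

#' Staurosporine/DMSO control response per line
#'
#' The per-line ratio of raw UID counts in staurosporine wells to raw UID
#' counts in DMSO wells of the same plate (counts, not abundance ratios).
#' When a role occupies several wells the mean per-well count is used, so
#' the statistic does not depend on how many control wells the layout
#' carries. Under effective cytotoxic control this sits well below 1. Lines
#' with a DMSO count of 0 are flagged with an undefined response.
#'
#' @param counts Count tibble.
#' @param plates Plate-map tibble.
#' @return Tibble (`plate_id`, `line_id`, `stauro_uids`, `dmso_uids`,
#'   `control_response`).
#' @export
control_response <- function(counts, plates) {
  joined <- dplyr::inner_join(
    counts, dplyr::select(plates, "plate_id", "well_id", "role"),
    by = c("plate_id", "well_id"))
  roles_present <- joined |>
    dplyr::distinct(.data$plate_id, .data$role) |>
    dplyr::filter(.data$role %in% c("staurosporine", "dmso")) |>
    dplyr::count(.data$plate_id)
  incomplete <- setdiff(unique(joined$plate_id),
                        roles_present$plate_id[roles_present$n == 2])
  if (length(incomplete) > 0) {
    abort(sprintf("plate(s) missing a staurosporine or DMSO well: %s",
                  paste(incomplete, collapse = ", ")))
  }
  role_wells <- plates |>
    dplyr::filter(.data$role %in% c("staurosporine", "dmso")) |>
    dplyr::count(.data$plate_id, .data$role, name = "n_wells")
  joined |>
    dplyr::filter(.data$role %in% c("staurosporine", "dmso")) |>
    dplyr::group_by(.data$plate_id, .data$line_id, .data$role) |>
    dplyr::summarise(uids = sum(.data$uid_count), .groups = "drop") |>
    dplyr::left_join(role_wells, by = c("plate_id", "role")) |>
    dplyr::mutate(uids = .data$uids / .data$n_wells) |>
    dplyr::select(-"n_wells") |>
    tidyr::pivot_wider(names_from = "role", values_from = "uids",
                       values_fill = 0) |>
    dplyr::rename(stauro_uids = "staurosporine", dmso_uids = "dmso") |>
    dplyr::mutate(control_response = dplyr::if_else(
      .data$dmso_uids > 0, .data$stauro_uids / .data$dmso_uids, NA_real_))
}
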