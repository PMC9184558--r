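# In-silico down-sampling power analysis. Each line's counts in DMSO wells
# are scaled down in 10% increments, the well's ratio and Z-score recomputed,
# and the smallest reduction reaching Z <= -1.5 recorded. Lines whose
# poorly-represented plates still detect a 90% reduction are "well powered"
# (hit threshold -1.5); the rest are "low powered" (threshold -1.0).

#' Down-sampling Z-score curve for one line
#'
#' For each reduction r in `reductions`, the line's UID count c in a DMSO
#' well is scaled to `round((1 - r) * c)` (deterministic scaling; set
#' `method = "binomial"` for seeded binomial thinning), the well total is
#' recomputed, and the scaled ratio is converted to a Z-score against the
#' plate's unmodified ratio distribution for that line (fixed plate context:
#' the other wells are untouched, and the plate median/SD are those of the
#' original plate). Holding the context fixed makes z exactly non-increasing
#' in r.
#'
#' @param counts Count tibble.
#' @param plates Plate-map tibble.
#' @param line_id Line to probe.
#' @param plate_ids Plates to probe (default: all plates carrying the line).
#' @param reductions Reductions to apply (default 0.1..1.0 by 0.1).
#' @param sd_mode Passed to [plate_zscores()].
#' @param method `"deterministic"` (default) or `"binomial"` thinning.
#' @param seed Seed for binomial thinning.
#' @param z_threshold Detection threshold used for
#'   `min_detectable_reduction` (default -1.5).
#' @return Tibble (`plate_id`, `well_id`, `line_id`, `reduction`,
#'   `scaled_count`, `ratio`, `z`). The smallest detectable reduction per
#'   (plate, well) is available via [min_detectable_reduction()].
#' @export
downsample_zcurve <- function(counts, plates, line_id, plate_ids = NULL,
                              reductions = seq(0.1, 1.0, by = 0.1),
                              sd_mode = "sample",
                              method = c("deterministic", "binomial"),
                              seed = 1, z_threshold = -1.5) {
  method <- match.arg(method)
  ratios <- abundance_ratios(counts)
  zs <- suppressWarnings(plate_zscores(ratios, sd_mode = sd_mode))
  curve <- downsample_zcurve_prepared(zs, plates, line_id, plate_ids,
                                      reductions, method, seed)
  attr(curve, "z_threshold") <- z_threshold
  curve
}

# Core of the down-sampling probe, reusing an already-scored table
# (columns of plate_zscores() output) so classify_power() can share work.
downsample_zcurve_prepared <- function(zs, plates, line_id, plate_ids = NULL,
                                       reductions = seq(0.1, 1.0, by = 0.1),
                                       method = "deterministic", seed = 1) {
  roles <- dplyr::select(plates, "plate_id", "well_id", "role")
  line_rows <- zs |>
    dplyr::filter(.data$line_id == !!line_id) |>
    dplyr::inner_join(roles, by = c("plate_id", "well_id"))
  if (!is.null(plate_ids)) {
    line_rows <- dplyr::filter(line_rows, .data$plate_id %in% plate_ids)
  }
  dmso <- dplyr::filter(line_rows, .data$role == "dmso", !is.na(.data$ratio))
  if (nrow(dmso) == 0) {
    return(tibble::tibble(plate_id = character(), well_id = character(),
                          line_id = character(), reduction = double(),
                          scaled_count = double(), ratio = double(),
                          z = double()))
  }
  grid <- tidyr::crossing(dmso, reduction = reductions)
  scaled <- if (method == "binomial") {
    with_seed(seed, rbinom(nrow(grid), size = grid$uid_count,
                           prob = 1 - grid$reduction))
  } else {
    round((1 - grid$reduction) * grid$uid_count)
  }
  new_total <- grid$well_total - grid$uid_count + scaled
  new_ratio <- ifelse(new_total > 0, scaled / new_total, NA_real_)
  tibble::tibble(
    plate_id = grid$plate_id, well_id = grid$well_id,
    line_id = grid$line_id, reduction = grid$reduction,
    scaled_count = scaled, ratio = new_ratio,
    z = ifelse(!is.na(grid$plate_sd) & grid$plate_sd > 0 & !is.na(new_ratio),
               (new_ratio - grid$plate_median) / grid$plate_sd, NA_real_)
  )
}

#' Down-sampling curves for every line of a screen
#'
#' Computes [downsample_zcurve()] for all lines in one pass, sharing the
#' plate scoring. Used for screen-wide detection-probability summaries
#' (e.g. the fraction of DMSO wells in which a given reduction reaches
#' Z <= -1.5).
#'
#' @inheritParams downsample_zcurve
#' @return Tibble as [downsample_zcurve()], all lines stacked.
#' @export
downsample_zcurves <- function(counts, plates,
                               reductions = seq(0.1, 1.0, by = 0.1),
                               sd_mode = "sample", z_threshold = -1.5) {
  ratios <- abundance_ratios(counts)
  zs <- suppressWarnings(plate_zscores(ratios, sd_mode = sd_mode))
  out <- dplyr::bind_rows(lapply(sort(unique(counts$line_id)), function(ln) {
    downsample_zcurve_prepared(zs, plates, ln, NULL, reductions)
  }))
  attr(out, "z_threshold") <- z_threshold
  out
}

#' Smallest detectable reduction from a down-sampling curve
#'
#' @param zcurve Output of [downsample_zcurve()].
#' @param z_threshold Detection threshold (default the curve's own, -1.5).
#' @return Tibble (`plate_id`, `well_id`, `line_id`,
#'   `min_detectable_reduction`); `NA` when even full depletion (r = 1) does
#'   not cross the threshold.
#' @export
min_detectable_reduction <- function(zcurve, z_threshold = NULL) {
  z_threshold <- z_threshold %||% attr(zcurve, "z_threshold") %||% -1.5
  zcurve |>
    dplyr::group_by(.data$plate_id, .data$well_id, .data$line_id) |>
    dplyr::summarise(
      min_detectable_reduction = if (any(!is.na(.data$z) & .data$z <= z_threshold)) {
        min(.data$reduction[!is.na(.data$z) & .data$z <= z_threshold])
      } else NA_real_,
      .groups = "drop")
}

#' Classify lines as well- or low-powered
#'
#' For each line, plates are ranked by the line's representation (its mean
#' abundance ratio across the plate's DMSO wells) and the plate at the
#' `quantile` (default 25th) percentile of that ranking - i.e. within the
#' lowest-representation quartile - is probed: if down-sampling the line by
#' `probe_reduction` (default 90%) there still yields a Z-score at or below
#' `z_well` (averaged over the plate's DMSO wells), the line is
#' `well_powered` and keeps the stringent hit threshold `z_well` (-1.5);
#' otherwise it is `low_powered` with the permissive threshold `z_low` (-1).
#'
#' @param counts Count tibble.
#' @param plates Plate-map tibble.
#' @param probe_reduction Reduction probed for the power call (default 0.9).
#' @param z_well,z_low Z thresholds for well-/low-powered lines.
#' @param quantile Percentile of the representation ranking at which the
#'   evaluation plate sits (default 0.25; ties broken by plate id).
#' @param sd_mode Passed to [plate_zscores()].
#' @return Tibble (`line_id`, `status`, `z_threshold`, `eval_plate`,
#'   `eval_representation`, `z_at_probe`) with a `per_plate` list-column of
#'   per-plate representation, probe Z and minimum detectable reduction.
#' @export
classify_power <- function(counts, plates, probe_reduction = 0.9,
                           z_well = -1.5, z_low = -1.0, quantile = 0.25,
                           sd_mode = "sample") {
  ratios <- abundance_ratios(counts)
  zs <- suppressWarnings(plate_zscores(ratios, sd_mode = sd_mode))
  if (length(unique(plates$plate_id)) == 0) abort("no plates to classify against")
  lines <- sort(unique(counts$line_id))
  res <- lapply(lines, function(ln) {
    curve <- downsample_zcurve_prepared(zs, plates, ln)
    if (nrow(curve) == 0) {
      return(tibble::tibble(
        line_id = ln, status = "low_powered", z_threshold = z_low,
        eval_plate = NA_character_, eval_representation = NA_real_,
        z_at_probe = NA_real_, per_plate = list(tibble::tibble())))
    }
    dmso_rep <- zs |>
      dplyr::inner_join(dplyr::select(plates, "plate_id", "well_id", "role"),
                        by = c("plate_id", "well_id")) |>
      dplyr::filter(.data$line_id == ln, .data$role == "dmso") |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::summarise(representation = mean(.data$ratio, na.rm = TRUE),
                       .groups = "drop")
    mdr <- min_detectable_reduction(curve, z_threshold = z_well) |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::summarise(min_detectable_reduction =
                         if (all(is.na(.data$min_detectable_reduction))) NA_real_
                         else min(.data$min_detectable_reduction, na.rm = TRUE),
                       .groups = "drop")
    probe <- curve |>
      dplyr::filter(.data$reduction == probe_reduction) |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::summarise(z_at_probe = mean(.data$z, na.rm = TRUE),
                       .groups = "drop")
    per_plate <- dmso_rep |>
      dplyr::left_join(probe, by = "plate_id") |>
      dplyr::left_join(mdr, by = "plate_id") |>
      dplyr::arrange(.data$representation, .data$plate_id)
    idx <- max(1L, ceiling(quantile * nrow(per_plate)))
    eval_row <- per_plate[idx, ]
    powered <- !is.na(eval_row$z_at_probe) && eval_row$z_at_probe <= z_well
    tibble::tibble(
      line_id = ln,
      status = if (powered) "well_powered" else "low_powered",
      z_threshold = if (powered) z_well else z_low,
      eval_plate = eval_row$plate_id,
      eval_representation = eval_row$representation,
      z_at_probe = eval_row$z_at_probe,
      per_plate = list(per_plate)
    )
  })
  dplyr::bind_rows(res)
}
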