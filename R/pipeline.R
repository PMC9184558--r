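# End-to-end orchestration: simulate (or ingest) counts, score, filter,
# power-classify, call hits, and bundle everything with a provenance
# manifest. Every stage is also available as a standalone function.

#' Pipeline configuration
#'
#' Collects every analysis constant in one auditable place. The defaults are
#' the screening assay's operating points: Z thresholds -1.5 (well-powered)
#' and -1.0 (low-powered), >50% inhibition for biological significance, a
#' two-fold staurosporine margin for the non-specific-killing filter, <1%
#' intact-site reads and >=15 covering RNA reads for knockout validation,
#' a 90% down-sampling probe at the lowest-representation quartile for the
#' power call, and a two-background strict-majority hit rule.
#'
#' @param z_well,z_low Z thresholds for well-/low-powered lines.
#' @param inhibition_threshold Minimum inhibition (strict `>`).
#' @param staurosporine_fold Fold margin of the non-specific filter.
#' @param wt_threshold Intact-site fraction bound for clone validation.
#' @param rna_min_reads Minimum covering RNA-seq reads.
#' @param probe_reduction Down-sampling probe for the power call.
#' @param power_quantile Representation quantile of the evaluation plate.
#' @param min_backgrounds Supporting backgrounds required for a hit.
#' @param min_reads_per_uid UID support filter in demultiplexing.
#' @param sd_mode `"sample"` or `"population"` SD in Z-scores.
#' @param exclude_self Leave-one-out plate context for Z-scores.
#' @param depth Simulated UID depth per well.
#' @param overdispersion Dirichlet concentration (`Inf` = multinomial).
#' @param seed Master seed for the run.
#' @return A `run_config` list.
#' @export
run_config <- function(z_well = -1.5, z_low = -1.0, inhibition_threshold = 0.5,
                       staurosporine_fold = 2, wt_threshold = 0.01,
                       rna_min_reads = 15, probe_reduction = 0.9,
                       power_quantile = 0.25, min_backgrounds = 2,
                       min_reads_per_uid = 1, sd_mode = "sample",
                       exclude_self = FALSE, depth = 50000,
                       overdispersion = Inf, seed = 1) {
  structure(
    list(z_well = z_well, z_low = z_low,
         inhibition_threshold = inhibition_threshold,
         staurosporine_fold = staurosporine_fold,
         wt_threshold = wt_threshold, rna_min_reads = rna_min_reads,
         probe_reduction = probe_reduction, power_quantile = power_quantile,
         min_backgrounds = min_backgrounds,
         min_reads_per_uid = min_reads_per_uid, sd_mode = sd_mode,
         exclude_self = exclude_self, depth = depth,
         overdispersion = overdispersion, seed = seed),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Run the full screen analysis
#'
#' Chains simulate (optional) -> score -> non-specific filter -> power ->
#' compounds of interest -> hit calls -> DMSO false-positive evaluation.
#' Either `counts` (a measured screen) or `truth` (a simulation model) must
#' be supplied; with `truth`, counts are generated by [simulate_counts()]
#' under `config$seed`.
#'
#' @param design A `screen_design` (or list with `panel`, `pools`, `plates`).
#' @param truth Optional [truth_model()] for simulation.
#' @param counts Optional measured count tibble (skips simulation).
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written as TSV plus a JSON provenance manifest and an HTML report.
#' @return A `screen_result` list: `counts`, `truth` (if simulated),
#'   `scores`, `flags`, `power`, `coi`, `hits`, `fpr`, `config`, `manifest`.
#' @export
run_pipeline <- function(design, truth = NULL, counts = NULL,
                         config = run_config(), out_dir = NULL) {
  stage <- "input validation"
  result <- tryCatch({
    if (is.null(counts)) {
      if (is.null(truth)) abort("supply either `counts` or a `truth` model")
      stage <- "simulate"
      sim <- simulate_counts(design, truth, depth = config$depth,
                             overdispersion = config$overdispersion,
                             seed = config$seed)
      counts <- sim$counts
      truth_table <- sim$truth
    } else {
      truth_table <- NULL
    }
    stage <- "score"
    scores <- counts |>
      abundance_ratios() |>
      plate_zscores(sd_mode = config$sd_mode,
                    exclude_self = config$exclude_self) |>
      inhibition(design$plates)
    stage <- "non-specific filter"
    flags <- nonspecific_filter(counts, design$plates,
                                fold = config$staurosporine_fold)
    stage <- "power classification"
    power <- classify_power(counts, design$plates,
                            probe_reduction = config$probe_reduction,
                            z_well = config$z_well, z_low = config$z_low,
                            quantile = config$power_quantile,
                            sd_mode = config$sd_mode)
    stage <- "compounds of interest"
    coi <- compounds_of_interest(scores, flags, power, design$plates,
                                 inhibition_threshold = config$inhibition_threshold)
    stage <- "hit calling"
    hits <- call_hits(coi, design$panel,
                      min_backgrounds = config$min_backgrounds)
    stage <- "DMSO false-positive evaluation"
    fpr <- dmso_false_positive_rate(scores, flags, power, design$plates,
                                    inhibition_threshold = config$inhibition_threshold)
    list(counts = counts, truth = truth_table, scores = scores, flags = flags,
         power = power, coi = coi, hits = hits, fpr = fpr)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("poolscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stage_rows = lapply(
      result[c("counts", "scores", "flags", "power", "coi", "hits")], nrow),
    n_hits = sum(result$hits$hit),
    dmso_fpr = result$fpr$fpr
  )
  result$config <- config
  result$manifest <- manifest
  class(result) <- "screen_result"
  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  %d wells scored; %d compound-of-interest observations passed\n",
              nrow(dplyr::distinct(x$counts, .data$plate_id, .data$well_id)),
              sum(x$coi$passed)))
  cat(sprintf("  %d hit(s); DMSO false-positive rate %.4f%% (%d/%d)\n",
              sum(x$hits$hit), 100 * x$fpr$fpr, x$fpr$n_false_positive,
              x$fpr$n_evaluations))
  invisible(x)
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_wells = nrow(dplyr::distinct(x$counts, .data$plate_id, .data$well_id)),
    n_lines = dplyr::n_distinct(x$counts$line_id),
    n_compounds = dplyr::n_distinct(x$coi$compound_id),
    n_well_powered = sum(x$power$status == "well_powered"),
    n_coi_passed = sum(x$coi$passed),
    n_hits = sum(x$hits$hit),
    dmso_fpr = x$fpr$fpr
  )
}

#' @export
tidy.screen_result <- function(x, ...) {
  dplyr::select(x$hits, -"votes")
}

# Flatten list-columns for TSV serialisation.
flatten_for_tsv <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(unlist(v), collapse = ","), character(1))))
}

write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    counts = result$counts, truth = result$truth, scores = result$scores,
    flags = result$flags,
    power = dplyr::select(result$power, -"per_plate"),
    coi = result$coi,
    hits = dplyr::select(result$hits, -"votes"),
    fpr = result$fpr
  )
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    readr::write_tsv(flatten_for_tsv(tables[[nm]]),
                     file.path(out_dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  write_html_report(result, file.path(out_dir, "report.html"))
  invisible(out_dir)
}

# Minimal self-contained HTML summary (no external assets).
write_html_report <- function(result, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html_table <- function(df, caption) {
    df <- flatten_for_tsv(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 5))
    rows <- apply(df, 1, function(r)
      paste0("<tr><td>", paste(esc(r), collapse = "</td><td>"), "</td></tr>"))
    paste0("<h2>", esc(caption), "</h2><table border='1' cellpadding='3'>",
           "<tr><th>", paste(esc(names(df)), collapse = "</th><th>"),
           "</th></tr>", paste(rows, collapse = ""), "</table>")
  }
  g <- glance(result)
  body <- c(
    "<html><head><meta charset='utf-8'><title>poolscreen report</title></head><body>",
    "<h1>Pooled isogenic knockout screen report</h1>",
    html_table(g, "Run summary"),
    html_table(dplyr::select(result$hits, -"votes"), "Hit calls"),
    html_table(dplyr::select(result$power, -"per_plate"), "Power classification"),
    html_table(utils::head(dplyr::arrange(result$coi, .data$z), 25),
               "Top compound-of-interest observations (lowest Z)"),
    html_table(result$fpr, "DMSO false-positive evaluation"),
    "</body></html>")
  writeLines(paste(body, collapse = "\n"), path)
  invisible(path)
}
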