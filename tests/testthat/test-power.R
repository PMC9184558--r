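# One plate: line L in wells with a fixed companion line F, two DMSO wells.
# L's counts are chosen per test to control its ratio distribution.
power_fixture <- function(l_counts, f_count = 1000,
                          roles = c("dmso", "dmso",
                                    rep("compound", length(l_counts) - 2))) {
  wells <- sprintf("W%02d", seq_along(l_counts))
  mat <- cbind(L = l_counts, F = f_count)
  rownames(mat) <- wells
  list(counts = counts_from_matrix(mat),
       plates = roles_table("P1", wells, roles))
}

test_that("down-sampling scales counts and z matches direct recomputation", {
  fx <- power_fixture(c(250, 190, 310, 160, 340, 250))
  curve <- downsample_zcurve(fx$counts, fx$plates, "L")
  w1 <- dplyr::filter(curve, well_id == "W01")
  # r = 0.1 on c = 250 -> scaled count 225; r = 1.0 -> count 0, minimal z
  expect_equal(dplyr::filter(w1, reduction == 0.1)$scaled_count, 225)
  expect_equal(dplyr::filter(w1, reduction == 1.0)$scaled_count, 0)
  expect_equal(min(w1$z), dplyr::filter(w1, reduction == 1.0)$z)

  # oracle: recompute each z by direct enumeration against the unmodified
  # plate ratio distribution
  plate_ratios <- fx$counts$uid_count[fx$counts$line_id == "L"] /
    (fx$counts$uid_count[fx$counts$line_id == "L"] + 1000)
  for (i in seq_len(nrow(w1))) {
    s <- round((1 - w1$reduction[i]) * 250)
    r <- s / (1250 - 250 + s)
    expect_equal(w1$z[i], oracle_z(r, plate_ratios), tolerance = 1e-12)
  }

  # z is non-increasing in the reduction for every probed well
  curve |>
    dplyr::group_by(well_id) |>
    dplyr::arrange(reduction, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(z) <= 1e-12)) |>
    dplyr::pull(mono) |>
    all() |>
    expect_true()

  # a line whose DMSO ratio sits several plate-SDs above zero is detectable
  # at or before the 50% reduction
  mdr <- min_detectable_reduction(curve)
  expect_true(all(mdr$min_detectable_reduction <= 0.5))

  # binomial thinning is seeded and stays within the count support
  cb <- downsample_zcurve(fx$counts, fx$plates, "L", method = "binomial",
                          seed = 5)
  cb2 <- downsample_zcurve(fx$counts, fx$plates, "L", method = "binomial",
                           seed = 5)
  expect_identical(cb, cb2)
  expect_true(all(cb$scaled_count >= 0 & cb$scaled_count <= 250))
})

test_that("power classification probes the lowest-representation quartile", {
  # good plates: L tightly distributed -> huge |z| at 90% reduction;
  # bad plates: L noisy and sparse -> the probe fails
  good <- c(250, 240, 260, 230, 270, 250)
  bad <- c(5, 50, 5, 50, 5, 50)
  build <- function(n_good, n_bad) {
    plates <- lapply(seq_len(n_good + n_bad), function(i) {
      fx <- power_fixture(if (i <= n_bad) bad else good)
      fx$counts$plate_id <- sprintf("P%02d", i)
      fx$plates$plate_id <- sprintf("P%02d", i)
      fx
    })
    list(counts = dplyr::bind_rows(lapply(plates, `[[`, "counts")),
         plates = dplyr::bind_rows(lapply(plates, `[[`, "plates")))
  }

  # 20 plates, the worst 3 fail: the 25th-percentile plate (5th lowest)
  # still detects -> well powered at threshold -1.5
  sc <- build(n_good = 17, n_bad = 3)
  pw <- classify_power(sc$counts, sc$plates)
  l <- dplyr::filter(pw, line_id == "L")
  expect_equal(l$status, "well_powered")
  expect_equal(l$z_threshold, -1.5)
  # representation ranking puts the bad plates at the bottom
  expect_true(all(c("P01", "P02", "P03") %in%
                    head(l$per_plate[[1]]$plate_id, 3)))

  # 5 plates with 4 bad: the evaluation plate is bad -> low powered
  sc2 <- build(n_good = 1, n_bad = 4)
  pw2 <- classify_power(sc2$counts, sc2$plates)
  l2 <- dplyr::filter(pw2, line_id == "L")
  expect_equal(l2$status, "low_powered")
  expect_equal(l2$z_threshold, -1.0)

  # a line detectable everywhere is well powered; a line never reaching
  # z <= -1.5 even at full depletion is low powered
  all_good <- build(n_good = 4, n_bad = 0)
  expect_equal(dplyr::filter(classify_power(all_good$counts, all_good$plates),
                             line_id == "L")$status, "well_powered")
  all_bad <- build(n_good = 0, n_bad = 4)
  l_bad <- dplyr::filter(classify_power(all_bad$counts, all_bad$plates),
                         line_id == "L")
  expect_equal(l_bad$status, "low_powered")
  curve_bad <- downsample_zcurve(all_bad$counts, all_bad$plates, "L")
  expect_true(all(is.na(min_detectable_reduction(curve_bad)$min_detectable_reduction)))
})

test_that("compound-of-interest criteria combine z, inhibition and flags", {
  coi_case <- function(z, inhibition, status, nonspecific) {
    scores <- tibble::tibble(
      plate_id = "P1", well_id = "W1", line_id = "L", role = "compound",
      z = z, inhibition = inhibition)
    flags <- tibble::tibble(plate_id = "P1", well_id = "W1",
                            nonspecific = nonspecific)
    power <- tibble::tibble(
      line_id = "L", status = status,
      z_threshold = ifelse(status == "well_powered", -1.5, -1.0))
    plates <- roles_table("P1", "W1", "compound", compound_id = "X",
                          dose_uM = 1)
    compounds_of_interest(scores, flags, power, plates)$passed
  }
  expect_true(coi_case(-1.6, 0.6, "well_powered", FALSE))
  # biological filter: inhibition must exceed 50%
  expect_false(coi_case(-1.6, 0.4, "well_powered", FALSE))
  expect_false(coi_case(-1.6, 0.5, "well_powered", FALSE))  # strict >
  # statistical filter at the line's own threshold
  expect_false(coi_case(-1.2, 0.7, "well_powered", FALSE))
  expect_true(coi_case(-1.2, 0.7, "low_powered", FALSE))
  expect_true(coi_case(-1.5, 0.7, "well_powered", FALSE))   # boundary <=
  # non-specific wells never pass; undefined values never pass
  expect_false(coi_case(-5, 0.9, "well_powered", TRUE))
  expect_false(coi_case(NA_real_, 0.9, "well_powered", FALSE))
  expect_false(coi_case(-5, NA_real_, "well_powered", FALSE))
})

test_that("hit calling needs a strict majority in two backgrounds", {
  panel <- tibble::tibble(
    line_id = c(paste0("R", 1:3), paste0("M", 1:2), "T1"),
    background = c(rep("RPE1", 3), rep("MCF10A", 2), "RPTec"),
    target_gene = c(rep("G1", 5), "G2"),
    grna_seq = strrep(c("A", "C", "G", "T", "AC", "AG"), c(20, 20, 20, 20, 10, 10)),
    clone_label = "c")
  coi_row <- function(line, passed, dose = 1) {
    tibble::tibble(compound_id = "X", dose_uM = dose, plate_id = "P1",
                   well_id = "W1", line_id = line, z = -2, inhibition = 0.8,
                   nonspecific = FALSE, status = "well_powered",
                   z_threshold = -1.5, passed = passed)
  }

  # 2/3 RPE1 and 2/2 MCF10A lines pass -> hit
  coi <- dplyr::bind_rows(coi_row("R1", TRUE), coi_row("R2", TRUE),
                          coi_row("R3", FALSE), coi_row("M1", TRUE),
                          coi_row("M2", TRUE))
  hits <- call_hits(coi, panel)
  expect_true(hits$hit[hits$target_gene == "G1"])
  expect_equal(hits$n_backgrounds_supporting[1], 2)

  # support in one background only is not a hit
  coi_one <- dplyr::bind_rows(coi_row("R1", TRUE), coi_row("R2", TRUE),
                              coi_row("R3", FALSE), coi_row("M1", FALSE),
                              coi_row("M2", FALSE))
  expect_false(call_hits(coi_one, panel)$hit[1])

  # 1 of 2 lines is not a strict majority
  coi_tie <- dplyr::bind_rows(coi_row("R1", TRUE), coi_row("R2", TRUE),
                              coi_row("R3", TRUE), coi_row("M1", TRUE),
                              coi_row("M2", FALSE))
  h_tie <- call_hits(coi_tie, panel)
  votes <- h_tie$votes[[1]]
  expect_false(votes$supports[votes$background == "MCF10A"])
  expect_false(h_tie$hit[1])

  # a line passing at either dose counts as passing
  coi_dose <- dplyr::bind_rows(
    coi_row("R1", FALSE, dose = 1), coi_row("R1", TRUE, dose = 10),
    coi_row("R2", TRUE), coi_row("R3", FALSE),
    coi_row("M1", TRUE), coi_row("M2", TRUE))
  expect_true(call_hits(coi_dose, panel)$hit[1])

  # a single screened line counts 1/1
  coi_single <- dplyr::bind_rows(coi_row("T1", TRUE), coi_row("R1", TRUE),
                                 coi_row("R2", TRUE), coi_row("R3", FALSE))
  h2 <- call_hits(coi_single, panel)
  g2 <- dplyr::filter(h2, target_gene == "G2")
  expect_equal(g2$n_backgrounds_supporting, 1)
  # gene screened in fewer than 2 backgrounds is untestable, never a hit
  expect_true(g2$untestable)
  expect_false(g2$hit)
})

test_that("the DMSO false-positive evaluation needs DMSO wells", {
  d <- tiny_design()
  sim <- simulate_counts(d, truth_model(), depth = 5000, seed = 51)
  scores <- sim$counts |> abundance_ratios() |> plate_zscores() |>
    inhibition(d$plates)
  flags <- nonspecific_filter(sim$counts, d$plates)
  power <- classify_power(sim$counts, d$plates)
  fpr <- dmso_false_positive_rate(scores, flags, power, d$plates)
  expect_equal(fpr$n_evaluations,
               sum(d$plates$role == "dmso") * 6)
  expect_lt(fpr$fpr, 0.05)

  # no DMSO wells -> error
  no_dmso <- dplyr::mutate(d$plates,
                           role = ifelse(role == "dmso", "untreated", role))
  expect_error(dmso_false_positive_rate(scores, flags, power, no_dmso),
               "DMSO")

  # all-identical counts: no z defined below threshold -> FPR 0
  mat <- rbind(D1 = c(A = 100, B = 100), D2 = c(A = 100, B = 100),
               S1 = c(A = 100, B = 100), T1 = c(A = 100, B = 100))
  cts <- counts_from_matrix(mat)
  plates <- roles_table("P1", rownames(mat),
                        c("dmso", "dmso", "staurosporine", "compound"))
  sc <- suppressWarnings(
    cts |> abundance_ratios() |> plate_zscores() |> inhibition(plates))
  fl <- nonspecific_filter(cts, plates)
  pw <- classify_power(cts, plates)
  expect_equal(dmso_false_positive_rate(sc, fl, pw, plates)$fpr, 0)
})
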