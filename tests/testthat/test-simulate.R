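test_that("multinomial sampling honours expected fractions and conservation", {
  d <- tiny_design(pool_size = 5, n_target_lines = c(1, 1))
  # null effects, equal seeding of 5 lines, deep sequencing: each line's
  # fraction within 3 binomial SDs of 0.2
  sim <- simulate_counts(d, truth_model(), depth = 1e6, seed = 11)
  well <- sim$counts |>
    dplyr::filter(plate_id == "RPE1_plate1", well_id == "A01")
  expect_equal(sum(well$uid_count), 1e6) # conservation under pure multinomial
  sd3 <- 3 * sqrt(0.2 * 0.8 / 1e6)
  expect_true(all(abs(well$uid_count / 1e6 - 0.2) < sd3))

  # same seed -> identical counts; different seed -> different draw
  sim2 <- simulate_counts(d, truth_model(), depth = 1e6, seed = 11)
  expect_identical(sim$counts, sim2$counts)
  sim3 <- simulate_counts(d, truth_model(), depth = 1e6, seed = 12)
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("kill fractions shape expected fractions as the closed form predicts", {
  d <- tiny_design(pool_size = 5, n_target_lines = c(1, 1))
  target <- d$pools$line_ids[[1]][1]
  stopifnot(grepl("TP53", target))

  # e = 0.9 for one line of an equal 5-line pool: expected fraction
  # 0.1 / (0.1 + 4) = 0.02439...
  truth <- tp53_truth(kill = 0.9)
  sim <- simulate_counts(d, truth, depth = 1e5, seed = 21)
  tr <- sim$truth |>
    dplyr::filter(line_id == target, plate_id == "RPE1_plate1", well_id == "A01")
  p_expected <- 0.1 / (0.1 + 4)
  expect_equal(tr$expected_fraction, p_expected, tolerance = 1e-12)
  obs <- sim$counts |>
    dplyr::filter(line_id == target, plate_id == "RPE1_plate1", well_id == "A01")
  tot <- sim$counts |>
    dplyr::filter(plate_id == "RPE1_plate1", well_id == "A01") |>
    dplyr::pull(uid_count) |> sum()
  sd3 <- 3 * sqrt(p_expected * (1 - p_expected) / tot)
  expect_lt(abs(obs$uid_count / tot - p_expected), sd3)

  # empirical mean over many wells approaches the closed form: the compound
  # occupies the same wells on every plate, so average over replicates/seeds
  fracs <- vapply(1:30, function(s) {
    sim_i <- simulate_counts(d, truth, depth = 2000, seed = 100 + s)
    w <- dplyr::filter(sim_i$counts, plate_id == "RPE1_plate1", well_id == "A01")
    w$uid_count[w$line_id == target] / sum(w$uid_count)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - p_expected),
            3 * sqrt(p_expected * (1 - p_expected) / (30 * 2000)) + 1e-3)

  # e = 1 for one line -> expected count 0
  sim_kill <- simulate_counts(d, tp53_truth(kill = 1), depth = 1e5, seed = 5)
  killed <- sim_kill$counts |>
    dplyr::filter(line_id == target, plate_id == "RPE1_plate1", well_id == "A01")
  expect_equal(killed$uid_count, 0L)

  # depth scaling: staurosporine wells yield ~5% of the DMSO library size
  stauro_well <- d$plates$well_id[d$plates$role == "staurosporine"][1]
  dmso_well <- d$plates$well_id[d$plates$role == "dmso"][1]
  totals <- sim$counts |>
    dplyr::filter(plate_id == "RPE1_plate1",
                  well_id %in% c(stauro_well, dmso_well)) |>
    dplyr::group_by(well_id) |>
    dplyr::summarise(n = sum(uid_count))
  ratio <- totals$n[totals$well_id == stauro_well] /
    totals$n[totals$well_id == dmso_well]
  expect_equal(ratio, 0.05, tolerance = 0.02)
})

test_that("overdispersed draws conserve totals but inflate variance", {
  d <- tiny_design(pool_size = 5, n_target_lines = c(1, 1))
  target <- d$pools$line_ids[[1]][1]
  frac <- function(overdisp, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_counts(d, truth_model(), depth = 5000,
                             overdispersion = overdisp, seed = s)
      w <- dplyr::filter(sim$counts, plate_id == "RPE1_plate1", well_id == "A01")
      w$uid_count[w$line_id == target] / sum(w$uid_count)
    }, numeric(1))
  }
  f_multi <- frac(Inf, 1:40)
  f_dm <- frac(20, 1:40)
  expect_gt(var(f_dm), var(f_multi))
  sim <- simulate_counts(d, truth_model(), depth = 5000,
                         overdispersion = 20, seed = 1)
  per_well <- sim$counts |>
    dplyr::group_by(plate_id, well_id) |>
    dplyr::summarise(n = sum(uid_count), .groups = "drop") |>
    dplyr::inner_join(d$plates, by = c("plate_id", "well_id"))
  # fully-surviving wells draw exactly the nominal depth
  expect_true(all(per_well$n[!per_well$role %in%
                               c("staurosporine", "nutlin3a")] == 5000))
})

test_that("FASTQ emission round-trips molecules, UIDs and layout", {
  d <- tiny_design(pool_size = 3, n_target_lines = c(1, 1),
                   n_plates_per_background = 1)
  wl <- make_barcode_whitelist(n_plate = 4, n_well = 96, seed = 9)
  counts <- tibble::tibble(
    plate_id = "RPE1_plate1", well_id = c("A01", "A01", "B02"),
    line_id = d$pools$line_ids[[1]], uid_count = c(1L, 100L, 50L))
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")

  # error-free, duplication mean 1: one read pair per UID, exact round trip
  out <- emit_fastq(counts[1, ], wl, d$panel, r1, r2, duplication_mean = 1,
                    read_error_rate = 0, seed = 3)
  expect_equal(nrow(out$key), 1)
  res <- demux_count(r1, r2, wl, d$panel, assignment = out$assignment)
  expect_equal(res$counts$uid_count, 1L)
  expect_equal(res$counts$plate_id, "RPE1_plate1")
  expect_equal(res$counts$well_id, "A01")
  expect_equal(res$counts$line_id, counts$line_id[1])

  # conservation: 150 UIDs at duplication mean 3 -> >=150 pairs, exactly
  # the planted number of distinct UIDs per (well, line)
  out2 <- emit_fastq(counts, wl, d$panel, r1, r2, duplication_mean = 3,
                     read_error_rate = 0, seed = 4)
  expect_gte(sum(out2$key$n_reads), 151)
  res2 <- demux_count(r1, r2, wl, d$panel, assignment = out2$assignment)
  got <- dplyr::arrange(res2$counts, well_id, line_id)
  want <- counts |>
    dplyr::filter(uid_count > 0) |>
    dplyr::arrange(well_id, line_id)
  expect_equal(got$uid_count, want$uid_count)
  expect_identical(sum(res2$qc$status_counts$n), sum(out2$key$n_reads))

  # byte-identical FASTQ under the same seed
  r1b <- withr::local_tempfile(fileext = ".fastq")
  r2b <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts, wl, d$panel, r1b, r2b, duplication_mean = 3,
             read_error_rate = 0, seed = 4)
  emit_fastq(counts, wl, d$panel, r1, r2, duplication_mean = 3,
             read_error_rate = 0, seed = 4)
  expect_identical(readLines(r1), readLines(r1b))
  expect_identical(readLines(r2), readLines(r2b))
})

test_that("demultiplexing tolerates read errors near the binomial prediction", {
  d <- tiny_design(pool_size = 3, n_target_lines = c(1, 1),
                   n_plates_per_background = 1)
  wl <- make_barcode_whitelist(n_plate = 2, n_well = 96, seed = 9)
  counts <- tibble::tibble(plate_id = "RPE1_plate1", well_id = "A01",
                           line_id = d$pools$line_ids[[1]][1],
                           uid_count = 200L)
  rate <- 0.01
  recovered <- vapply(1:5, function(s) {
    r1 <- withr::local_tempfile(fileext = ".fastq")
    r2 <- withr::local_tempfile(fileext = ".fastq")
    emit_fastq(counts, wl, d$panel, r1, r2, duplication_mean = 1,
               read_error_rate = rate, seed = s)
    res <- demux_count(r1, r2, wl, d$panel)
    if (nrow(res$counts)) sum(res$counts$uid_count) else 0L
  }, numeric(1))
  # independent per-base binomial error model: a molecule survives iff each
  # matched field stays within its mismatch tolerance (UID errors relabel
  # but never lose a molecule at duplication mean 1)
  p_ok <- stats::pbinom(1, 8, rate)^2 *          # plate + well barcode
    stats::pbinom(2, nchar(ANCHOR_FWD), rate) *  # read-1 anchor
    stats::pbinom(2, nchar(ANCHOR_REV), rate) *  # read-2 anchor
    stats::pbinom(1, 20, rate)                   # gRNA
  expect_lt(abs(mean(recovered) / 200 - p_ok), 0.02)
  expect_gte(mean(recovered) / 200, 0.95)
})

test_that("amplicon read simulation plants alleles at stated fractions", {
  alleles <- tibble::tibble(kind = c("deletion", "insertion"),
                            length = c(1L, 2L), position = c(30L, 45L))
  # wt_fraction 0: no read equals the reference
  rd <- simulate_amplicon_reads(REF72, alleles, wt_fraction = 0, depth = 500,
                                seed = 2)
  expect_equal(nrow(rd), 500)
  expect_false(any(rd$sequence == REF72))
  expect_equal(dplyr::n_distinct(rd$uid), 500)

  # wt_fraction 0.005 at depth 10,000: ~50 wild-type reads, below 1%
  rd2 <- simulate_amplicon_reads(REF72, alleles, wt_fraction = 0.005,
                                 depth = 10000, seed = 3)
  n_wt <- sum(rd2$allele == "wt")
  expect_lt(abs(n_wt - 50), 3 * sqrt(10000 * 0.005 * 0.995))
  expect_lt(n_wt / 10000, 0.01)

  # depth 0 -> empty read set; indel outside the reference errors
  expect_equal(nrow(simulate_amplicon_reads(REF72, alleles, 0.5, 0)), 0)
  bad <- tibble::tibble(kind = "deletion", length = 10L, position = 70L)
  expect_error(simulate_amplicon_reads(REF72, bad, 0, 10), "outside")
})
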