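test_that("EIC keeps the window and zero-fills empty scans", {
  tbl <- signal_table(c(1, 1, 1, 2, 3), c(999.7, 1000.3, 1001.0, 1000.1, 700),
                      c(10, 20, 30, 5, 99))
  ch <- eic(tbl, 1000, 0.5)
  expect_equal(ch$rt, c(1, 2, 3))
  expect_equal(ch$intensity, c(30, 5, 0))   # 1001.0 outside +/- 0.5; rt 3 empty
  expect_error(eic(tbl, 1000, 0), "positive")
  # per-charge halfwidth convention: QQQ 2/z, QTOF 1/z
  expect_equal(instrument_profile("QQQ")$eic_halfwidth_numerator / 4, 0.5)
  expect_equal(instrument_profile("QTOF")$eic_halfwidth_numerator / 2, 0.5)
})

test_that("ECC equals the pointwise sum of its charge-state EICs", {
  M <- peptide_mass(fusion_seq)
  sim <- simulate_run(make_two_state_spec(M, 0.5, seed = 5))
  ex <- ecc(sim$signals, M, "QQQ")
  summed <- ex$eics |>
    dplyr::summarise(intensity = sum(intensity), .by = rt) |>
    dplyr::arrange(rt)
  expect_identical(ex$ecc$intensity, summed$intensity)
  expect_equal(ex$charges, charges_in_range(M, 500, 2000))
  # apex lands within one scan interval of the injected elution apex
  apex_rt <- ex$ecc$rt[which.max(ex$ecc$intensity)]
  dens <- function(t) skew_gaussian(t, 1, 2.8, 0.08, 1)
  grid <- seq(2, 4, by = 1e-4)
  true_apex <- grid[which.max(dens(grid))]
  expect_lt(abs(apex_rt - true_apex), 0.3 / 60 + 1e-9)
})

test_that("empty tables give all-zero chromatograms", {
  empty <- signal_table(numeric(0), numeric(0), numeric(0))
  ex <- ecc(empty, 14000, "QQQ")
  expect_equal(nrow(ex$ecc), 0L)
  expect_true(all(ex$eics$intensity == 0))
})

test_that("skew-normal fitting recovers known peak parameters", {
  t <- seq(1, 6, by = 0.005)
  y <- skew_gaussian(t, area = 100, rt = 3, width = 0.1, skew = 1,
                     baseline = 0)
  fit <- fit_skewed_gaussian(new_chromatogram(t, y, "ECC"))
  expect_true(fit$converged)
  expect_equal(fit$area, 100, tolerance = 0.01)
  expect_equal(fit$rt, 3, tolerance = 0.01)
  expect_equal(fit$width, 0.1, tolerance = 0.01)
  expect_equal(fit$skew, 1, tolerance = 0.01)
  td <- tidy(fit)
  expect_true(td$converged)

  flat <- fit_skewed_gaussian(new_chromatogram(t, rep(0, length(t)), "ECC"))
  expect_false(flat$converged)
  expect_equal(flat$area, 0)

  sym <- skew_gaussian(t, area = 50, rt = 3, width = 0.12, skew = 0,
                       baseline = 10)
  fit_sym <- fit_skewed_gaussian(new_chromatogram(t, sym, "ECC"))
  expect_true(fit_sym$converged)
  expect_equal(fit_sym$skew, 0, tolerance = 0.05)
  expect_equal(fit_sym$baseline, 10, tolerance = 0.5)
})

test_that("fitted area matches the injected area on noiseless runs", {
  M <- peptide_mass(fusion_seq)
  run <- make_species_run(M, charges = 10:21, abundance = 1e7)
  ex <- ecc(run, M, "QQQ")
  fit <- fit_skewed_gaussian(ex$ecc)
  dt <- 0.3 / 60
  injected_area <- sum(ex$ecc$intensity) * dt
  expect_true(fit$converged)
  expect_lt(abs(fit$area - injected_area) / injected_area, 0.05)
})

test_that("peak validity classifier follows each criterion", {
  M <- peptide_mass(fusion_seq)
  crit <- peak_criteria()
  run_case <- function(run) {
    ex <- ecc(run, M, "QQQ")
    fit <- fit_skewed_gaussian(ex$ecc)
    assess_peak(fit, ex$ecc, ex$eics, crit)
  }

  clean <- run_case(make_species_run(M, charges = 10:21))
  expect_true(clean$valid)
  expect_length(clean$reasons, 0)
  expect_equal(clean$n_charge_states, 12L)
  expect_gte(clean$n_consecutive, 4L)

  few <- run_case(make_species_run(M, charges = 12:14))
  expect_false(few$valid)
  expect_true("charge_states" %in% few$reasons)

  gappy <- run_case(make_species_run(M, charges = c(9:11, 14:16, 19:21)))
  expect_false(gappy$valid)
  expect_equal(gappy$n_charge_states, 9L)
  expect_true("consecutive" %in% gappy$reasons)
  expect_false("charge_states" %in% gappy$reasons)

  # second elution peak at 90% of the candidate height
  main <- make_species_run(M, charges = 10:21, abundance = 1e7, rt = 2.5)
  ghost <- make_species_run(M, charges = 10:21, abundance = 0.9e7, rt = 4.5)
  both <- signal_table(c(main$rt, ghost$rt), c(main$mz, ghost$mz),
                       c(main$intensity, ghost$intensity))
  twin <- run_case(both)
  expect_false(twin$valid)
  expect_true("large_peaks" %in% twin$reasons)

  skewed <- run_case(make_species_run(M, charges = 10:21, skew = 2.5))
  expect_false(skewed$valid)
  expect_true("skew" %in% skewed$reasons)

  wide <- run_case(make_species_run(M, charges = 10:21, width = 0.3))
  expect_false(wide$valid)
  expect_true("width" %in% wide$reasons)
})

test_that("unconverged fits are reported as invalid", {
  t <- seq(1, 6, by = 0.005)
  fit <- fit_skewed_gaussian(new_chromatogram(t, rep(0, length(t)), "ECC"))
  ass <- assess_peak(fit, new_chromatogram(t, rep(0, length(t)), "ECC"),
                     tibble::tibble(charge = integer(0), rt = numeric(0),
                                    intensity = numeric(0)))
  expect_false(ass$valid)
  expect_equal(ass$reasons, "not_converged")
})

test_that("fraction modified is the modified share of total valid area", {
  M <- peptide_mass(fusion_seq)
  sim <- simulate_run(make_two_state_spec(M, 0.75, seed = 9))
  q <- fraction_modified(sim$signals, fusion_seq, dehydration1)
  expect_true(q$detected)
  expect_equal(q$fraction_modified, 0.75, tolerance = 0.05 / 0.75)
  expect_equal(sum(tidy(q)$area[tidy(q)$valid]), q$total_peptide_area)
  gl <- glance(q)
  expect_equal(gl$n_states, 2L)
  expect_equal(gl$fraction_modified, q$fraction_modified)
})

test_that("modified_labels controls which states count as modified", {
  M <- peptide_mass(fusion_seq)
  dehyd2 <- modification("dehydration", -18.0153, -18.01056, 2L)
  # unmod 20%, singly (partial) 30%, doubly (modified) 50%
  rs <- run_spec(list(
    species_spec(M, 0.2e7, "unmodified", rt = 2.8),
    species_spec(M - 18.0153, 0.3e7, "partial", rt = 2.8),
    species_spec(M - 2 * 18.0153, 0.5e7, "modified", rt = 2.8)),
    instrument = "QQQ", seed = 13)
  sim <- simulate_run(rs)
  q_strict <- fraction_modified(sim$signals, fusion_seq, dehyd2)
  expect_equal(q_strict$fraction_modified, 0.50, tolerance = 0.02)
  q_incl <- fraction_modified(sim$signals, fusion_seq, dehyd2,
                              modified_labels = c("partial", "modified"))
  expect_equal(q_incl$fraction_modified, 0.80, tolerance = 0.02)
})

test_that("an empty extract is flagged undetected", {
  noise_only <- simulate_run(run_spec(
    species_spec(peptide_mass(fusion_seq) + 5000, 1e4, "decoy", rt = 3),
    instrument = "QQQ", seed = 21))
  q <- fraction_modified(noise_only$signals, fusion_seq, dehydration1)
  expect_false(q$detected)
  expect_true(is.na(q$fraction_modified))
  expect_equal(q$total_peptide_area, 0)
})

test_that("increasing modified abundance never decreases the estimate", {
  M <- peptide_mass(fusion_seq)
  fs <- c(0.2, 0.4, 0.6, 0.8)
  est <- purrr::map_dbl(fs, function(f) {
    sim <- simulate_run(make_two_state_spec(M, f, seed = 31))
    fraction_modified(sim$signals, fusion_seq, dehydration1)$fraction_modified
  })
  expect_false(is.unsorted(est))
})
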