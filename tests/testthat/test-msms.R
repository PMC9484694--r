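test_that("intensity capping clips at multiplier x mean", {
  sp <- spectrum(c(100, 200, 300), c(10, 20, 1000))
  capped <- cap_intensities(sp, 1)
  expect_equal(capped$intensity, c(10, 20, 1030 / 3), tolerance = 1e-9)
  expect_equal(capped$mz, sp$mz)
  # ceiling above the max leaves the spectrum unchanged
  expect_equal(cap_intensities(sp, 10)$intensity, sp$intensity)
  one <- spectrum(500, 123)
  expect_equal(cap_intensities(one, 1)$intensity, 123)
  expect_error(cap_intensities(spectrum(numeric(0), numeric(0)), 1), "empty")
})

test_that("repeated capping only ever lowers intensities, never raises them", {
  set.seed(17)
  for (i in 1:10) {
    sp <- spectrum(sort(runif(40, 100, 2000)), rlnorm(40, 5, 2))
    once <- cap_intensities(sp, 1.5)
    twice <- cap_intensities(once, 1.5)
    expect_true(all(twice$intensity <= once$intensity))
    expect_true(all(once$intensity <= sp$intensity))
    # a second pass is the identity once the recomputed ceiling clears the max
    settled <- cap_intensities(sp, 1e6)
    expect_equal(settled$intensity, sp$intensity)
    expect_true(all(twice$intensity <= 1.5 * mean(once$intensity)))
  }
})

test_that("sliced background removal thresholds on neighbourhood means", {
  flat <- spectrum(seq(100, 1000, length.out = 20), rep(5, 20))
  expect_equal(nrow(remove_background(flat, 4, 1)), 20L)  # strictly-below rule

  sp <- spectrum(c(seq(100, 590, by = 10), 600), c(rep(1, 50), 100))
  kept <- remove_background(sp, 1, 3)       # threshold = 3 * 150/51 = 8.82
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$mz, 600)

  expect_equal(nrow(remove_background(sp, 5, 0)), 51L)  # snr 0: no removal
})

test_that("background removal never drops the global maximum at snr <= 1", {
  set.seed(23)
  for (i in 1:10) {
    sp <- spectrum(sort(runif(60, 100, 1500)), rexp(60, 1 / 50))
    top <- sp$mz[which.max(sp$intensity)]
    out <- remove_background(sp, sample(1:8, 1), 1)
    expect_true(top %in% out$mz)
  }
})

test_that("hypothetical b/y ions follow the fragment formulas", {
  st <- peptide_structure("GAS")
  ions <- hypothetical_ions(st)
  b2 <- dplyr::filter(ions, series == "b", index == 2, charge == 1)
  expect_equal(b2$mz, 57.02146 + 71.03711 + 1.00728, tolerance = 1e-7)
  y1 <- dplyr::filter(ions, series == "y", index == 1, charge == 1)
  expect_equal(y1$mz, 87.03203 + 18.01056 + 1.00728, tolerance = 1e-7)
  # count: (2 (L-1) b/y + 1 parent) at each of 3 charges
  L <- 3L
  expect_equal(nrow(ions), 3L * (2L * (L - 1L) + 1L))
  # the multiply charged m/z follows [M+zH]z+
  b2_2 <- dplyr::filter(ions, series == "b", index == 2, charge == 2)
  expect_equal(b2_2$mz, (b2$formula_mass + 2 * 1.00728) / 2, tolerance = 1e-9)
})

test_that("residue-localised deltas ride only on fragments retaining them", {
  st <- peptide_structure("GAS", residue_deltas = c(`3` = -18.01056))
  ions <- hypothetical_ions(st)
  b2 <- dplyr::filter(ions, series == "b", index == 2, charge == 1)
  expect_equal(b2$formula_mass, 57.02146 + 71.03711, tolerance = 1e-7)
  y1 <- dplyr::filter(ions, series == "y", index == 1, charge == 1)
  expect_equal(y1$formula_mass, 87.03203 + 18.01056 - 18.01056,
               tolerance = 1e-7)
  parent <- dplyr::filter(ions, series == "parent", charge == 1)
  expect_equal(parent$formula_mass,
               peptide_mass("GAS", "monoisotopic") - 18.01056,
               tolerance = 1e-7)
  expect_error(peptide_structure("GAS", residue_deltas = c(`4` = -18)),
               "within")
})

test_that("cleavage sites inside crosslink spans are suppressed", {
  st <- peptide_structure("GAS", crosslinks = list(c(2, 3)))
  ions <- hypothetical_ions(st)
  expect_equal(nrow(dplyr::filter(ions, series == "b", index == 2)), 0L)
  expect_equal(nrow(dplyr::filter(ions, series == "y", index == 1)), 0L)
  expect_equal(nrow(dplyr::filter(ions, series == "b", index == 1)), 3L)
  expect_equal(nrow(dplyr::filter(ions, series == "y", index == 2)), 3L)
  # nesting allowed, partial overlap rejected
  expect_no_error(peptide_structure("GASSTA",
                                    crosslinks = list(c(1, 6), c(2, 4))))
  expect_error(peptide_structure("GASSTA",
                                 crosslinks = list(c(1, 4), c(3, 6))),
               "overlap")
})

test_that("b_k + y_(L-k) equals the parent mass for every open site", {
  # independent oracle: explicit residue loops, not the cumulative sums used
  # by the implementation
  seqc <- "MKTAYIAKQR"
  L <- nchar(seqc)
  codes <- strsplit(seqc, "")[[1]]
  ions <- hypothetical_ions(peptide_structure(seqc), max_charge = 1L)
  parent <- dplyr::filter(ions, series == "parent")$formula_mass
  for (k in seq_len(L - 1L)) {
    b_oracle <- 0
    for (j in 1:k) b_oracle <- b_oracle + residue_mass(codes[j], "monoisotopic")
    y_oracle <- 18.010565
    for (j in (k + 1):L) y_oracle <- y_oracle +
        residue_mass(codes[j], "monoisotopic")
    bk <- dplyr::filter(ions, series == "b", index == k)$formula_mass
    yk <- dplyr::filter(ions, series == "y", index == L - k)$formula_mass
    expect_equal(bk, b_oracle, tolerance = 1e-10)
    expect_equal(yk, y_oracle, tolerance = 1e-10)
    # parent = residue sum + water; b carries no water, y carries one
    expect_equal(bk + yk, parent, tolerance = 1e-9)
  }
})

test_that("ion matching respects tolerance, ties and coverage", {
  st <- peptide_structure("GAS")
  ions <- hypothetical_ions(st, max_charge = 1L)
  perfect <- spectrum(ions$mz, rep(100, nrow(ions)))
  res <- match_ions(perfect, ions, 0.05)
  expect_equal(res$n_matched, nrow(ions))
  expect_equal(res$coverage, 1)

  off <- spectrum(ions$mz + 0.1, rep(100, nrow(ions)))
  expect_equal(match_ions(off, ions, 0.05)$n_matched, 0L)

  b_only <- dplyr::filter(ions, series == "b")
  res_b <- match_ions(spectrum(b_only$mz, c(10, 20)), ions, 0.05)
  expect_equal(res_b$coverage, 1)   # both sites supported by b ions alone
  expect_equal(res_b$n_matched, 2L)

  # nearest-peak tie: two peaks equidistant -> smaller m/z wins
  one_ion <- ions[ions$series == "b" & ions$index == 1, ]
  tied <- spectrum(c(one_ion$mz - 0.02, one_ion$mz + 0.02), c(5, 7))
  got <- match_ions(tied, one_ion, 0.05)
  expect_equal(got$matches$matched_mz, one_ion$mz - 0.02, tolerance = 1e-9)
})

test_that("simulated spectra annotate back to their own structure", {
  st <- peptide_structure("MKTAYIAKQRPGHW",
                          residue_deltas = c(`3` = -18.01056),
                          crosslinks = list(c(5, 8)))
  full <- simulate_msms(st, efficiency = 1, n_noise = 0, seed = 1)
  res <- annotate_spectrum(full$spectrum, st, snr_threshold = 0)
  expect_equal(res$n_matched, res$n_ions)

  none <- simulate_msms(st, efficiency = 0, n_noise = 10, seed = 2)
  res0 <- annotate_spectrum(none$spectrum, st, snr_threshold = 0)
  expect_equal(res0$n_matched, 0L)

  a <- simulate_msms(st, efficiency = 0.7, seed = 3)
  b <- simulate_msms(st, efficiency = 0.7, seed = 3)
  expect_identical(a$spectrum$mz, b$spectrum$mz)
  expect_identical(a$truth, b$truth)
})

test_that("spectra read from TSV and validate inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# fixture", "mz\tintensity", "100.5\t10", "200.25\t20"), path)
  sp <- read_spectrum_tsv(path)
  expect_equal(sp$mz, c(100.5, 200.25))
  expect_error(spectrum(c(-1, 2), c(1, 1)), "positive")
  expect_error(spectrum(c(1, 2), c(-1, 1)), ">= 0")
})
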