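# Shared fixtures built in code.

# A 140-residue stand-in for a tagged precursor-peptide fusion (~16.7 kDa
# average), large enough to show a rich ESI charge envelope in a QQQ window.
fusion_seq <- strrep("ACDEFGHIKLMNPQRSTVWY", 7)

dehydration1 <- modification("dehydration", -18.0153, -18.01056, 1L)

# Build a signal table directly from first principles: peaks at the exact
# [M+zH]z+ m/z of the given charges, equal envelope weights, skew-normal
# elution sampled on the instrument scan grid. No randomness.
make_species_run <- function(mass, charges, abundance = 1e7,
                             rt = 3, width = 0.08, skew = 1,
                             rt_window = c(1, 6), scan_interval = 0.3) {
  scan_rt <- seq(rt_window[1], rt_window[2], by = scan_interval / 60)
  elution <- skew_gaussian(scan_rt, area = 1, rt = rt, width = width,
                           skew = skew, baseline = 0)
  recs <- purrr::map_dfr(charges, function(z) {
    tibble::tibble(rt = scan_rt, mz = mz_for_charge(mass, z),
                   intensity = abundance / length(charges) * elution)
  })
  recs <- dplyr::filter(recs, intensity > 0)
  signal_table(recs$rt, recs$mz, recs$intensity, source = "fixture")
}

# Two-species run (unmodified at `mass`, modified at `mass - delta`) through
# the stochastic generator.
make_two_state_spec <- function(mass, frac_modified, delta = 18.0153,
                                total = 1e7, seed = 1, noise_rate = 5,
                                noise_mean = 2000, rt = 2.8) {
  run_spec(
    list(
      species_spec(mass, abundance = (1 - frac_modified) * total,
                   label = "unmodified", rt = rt),
      species_spec(mass - delta, abundance = frac_modified * total,
                   label = "modified", rt = rt)),
    instrument = "QQQ", noise_rate = noise_rate, noise_mean = noise_mean,
    seed = seed)
}
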