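# narrow Gaussian bands (FWHM 10, eta 0) so neighbor overlap is negligible
# and planted apex ratios are exact
two_band_replicate <- function(a2852, a2872, eta = 0) {
  w <- lipid_grid
  y <- a2852 * pseudo_voigt(w, 2852, 10, eta) +
    a2872 * pseudo_voigt(w, 2872, 10, eta) +
    0.5 * pseudo_voigt(w, 2924, 10, eta) +
    0.3 * pseudo_voigt(w, 2958, 10, eta)
  ftir_spectrum(w, y, "fix", "g")
}

test_that("lipid-to-protein ratio is the 2852/2872 intensity ratio", {
  # planted apex ratio 1.0769 at any overall gain
  for (c0 in c(0.2, 1, 4.7)) {
    tab <- replicate_band_table(two_band_replicate(1.0769 * c0, c0),
                                bands = c("ch2_sym", "ch3_sym"))
    expect_equal(lipid_protein_ratio(tab), 1.0769, tolerance = 1e-3)
  }
  # equal intensities -> 1
  tab <- replicate_band_table(two_band_replicate(0.5, 0.5),
                              bands = c("ch2_sym", "ch3_sym"))
  expect_equal(lipid_protein_ratio(tab), 1, tolerance = 1e-3)
})

test_that("chain length index is the 2924/2958 ratio and is scale-free", {
  s <- simulate_spectrum(study_preset("hela-cisplatin", noise_sd = 0))
  tab <- replicate_band_table(s)
  expect_equal(chain_length_index(tab), 1.6910, tolerance = 1e-3)
  s2 <- s; s2$absorbance <- 2 * s2$absorbance
  expect_equal(chain_length_index(replicate_band_table(s2)),
               chain_length_index(tab), tolerance = 1e-12)
})

test_that("olefinic index reproduces planted normalized apexes", {
  s1 <- simulate_spectrum(study_preset("hela-control", noise_sd = 0))
  expect_equal(olefinic_index(replicate_band_table(s1)), 0.01283,
               tolerance = 1e-4 / 0.01283)   # within 1e-4 absolute
  s2 <- simulate_spectrum(study_preset("hela-kd", noise_sd = 0))
  expect_equal(olefinic_index(replicate_band_table(s2)), 0.00747,
               tolerance = 1e-4 / 0.00747)
  # absent band -> ~0 (isolated Gaussian neighbors, no olefinic amplitude)
  tab0 <- replicate_band_table(two_band_replicate(0.5, 0.45),
                               bands = c("olefinic", "ch2_asym"))
  expect_lt(abs(tab0$intensity[tab0$band == "olefinic"]), 1e-6)
})

test_that("RNA content is the PO2-sym-normalized 1121 intensity", {
  s <- simulate_spectrum(study_preset("hela-kd-control", noise_sd = 0))
  tab <- replicate_band_table(s)
  expect_equal(rna_content(tab),
               tab$intensity[tab$band == "rna_1121"] /
                 tab$intensity[tab$band == "po2_sym"], tolerance = 1e-12)
  # equal intensities give 1 by construction of the ratio
  expect_equal(tab$intensity_norm[tab$band == "po2_sym"], 1)
  # planted x1.1668 multiplier between the knockdown groups -> +16.68%
  s2 <- simulate_spectrum(study_preset("hela-kd", noise_sd = 0))
  pc <- percent_change(rna_content(tab),
                       rna_content(replicate_band_table(s2)))
  expect_equal(as.numeric(pc), 16.68, tolerance = 0.01)
})

test_that("glycogen and protein C-O bands track their planted multipliers", {
  t1 <- replicate_band_table(
    simulate_spectrum(study_preset("hela-control", noise_sd = 0)))
  t2 <- replicate_band_table(
    simulate_spectrum(study_preset("hela-cisplatin", noise_sd = 0)))
  g1 <- glycogen_and_protein_bands(t1)
  g2 <- glycogen_and_protein_bands(t2)
  expect_equal(100 * (g2[["glycogen_996"]] / g1[["glycogen_996"]] - 1),
               -7.03, tolerance = 0.01)
  expect_equal(100 * (g2[["protein_CO_1171"]] / g1[["protein_CO_1171"]] - 1),
               31.29, tolerance = 0.01)
  # near-vanished 996 band in the knockdown (90% planted loss)
  tkd <- replicate_band_table(
    simulate_spectrum(study_preset("hela-kd", noise_sd = 0)))
  expect_lt(glycogen_and_protein_bands(tkd)[["glycogen_996"]],
            0.15 * g1[["glycogen_996"]])
})

test_that("percent change reproduces the published arithmetic", {
  expect_equal(signif(as.numeric(percent_change(1.0769, 1.3018)), 3), 20.9)
  expect_equal(as.numeric(percent_change(0.01283, 0.011987)), -6.57,
               tolerance = 0.001)
  expect_equal(signif(as.numeric(percent_change(0.03181, 0.00747)), 3), -76.5)
  expect_equal(as.numeric(percent_change(2.5, 2.5)), 0)
  expect_equal(attr(percent_change(1, 2), "direction"), "increase")
  expect_equal(attr(percent_change(2, 1), "direction"), "decrease")
  expect_error(percent_change(0, 1), "zero")
  # reversal identity: (1 + d1/100) (1 + d2/100) = 1
  for (pair in list(c(1.0769, 1.3018), c(0.03181, 0.00747), c(2, 3))) {
    d1 <- as.numeric(percent_change(pair[1], pair[2]))
    d2 <- as.numeric(percent_change(pair[2], pair[1]))
    expect_equal((1 + d1 / 100) * (1 + d2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("group comparison wires metrics, percent change and tests together", {
  # identical groups: no change, p = 1
  s <- simulate_spectrum(study_preset("hela-control", noise_sd = 0))
  g <- spectrum_group(list(s, s, s), "a")
  g2 <- spectrum_group(list(s, s, s), "b")
  cmp <- compare_groups("lipid_protein_ratio", g, g2)
  expect_equal(cmp$percent_change, 0)
  expect_equal(cmp$p_value, 1)

  # noiseless paired simulation recovers the planted contrast exactly
  pair <- simulate_study_pair("cisplatin", seed = 5, replicate_cv = 0,
                              noise_sd = 0)
  cmp2 <- compare_groups("lipid_protein_ratio", pair$control, pair$treated)
  expect_equal(signif(cmp2$percent_change, 3), 20.9)
  expect_equal(cmp2$direction, "increase")

  cmp3 <- compare_groups("po2_asym_position", pair$control, pair$treated)
  expect_lt(abs(cmp3$difference - 1.27), 0.25)
})

test_that("metric results carry consistent summaries", {
  pair <- simulate_study_pair("cisplatin", seed = 3, replicate_cv = 0.04,
                              noise_sd = 1e-3)
  mr <- compute_metric(pair$control, "lipid_protein_ratio")
  expect_equal(mr$mean, mean(mr$per_replicate))
  expect_equal(mr$sd, stats::sd(mr$per_replicate))
  expect_equal(mr$n, 3)
  expect_equal(mr$group_label, "control")
})

test_that("comparison reports are written as CSV and JSON", {
  tmp <- withr::local_tempdir()
  pair <- simulate_study_pair("cisplatin", seed = 2, replicate_cv = 0,
                              noise_sd = 0)
  rep_ <- compare_all(pair$control, pair$treated,
                      metrics = c("lipid_protein_ratio", "olefinic_index"))
  fcsv <- file.path(tmp, "report.csv"); fjson <- file.path(tmp, "report.json")
  write_report_csv(rep_, fcsv)
  write_report_json(rep_, fjson)
  got <- utils::read.csv(fcsv)
  expect_equal(got$metric, c("lipid_protein_ratio", "olefinic_index"))
  expect_equal(got$percent_change, c(20.9, -6.57), tolerance = 1e-6)
  j <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(j$metrics$percent_change, c(20.9, -6.57), tolerance = 1e-6)
})
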