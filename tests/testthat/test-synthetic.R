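test_that("spectrum simulation is deterministic and additive", {
  # zero amplitudes, zero baseline, zero noise -> all-zero trace
  m0 <- spectrum_model(c(ch2_asym = 0, po2_sym = 0), noise_sd = 0)
  s0 <- simulate_spectrum(m0)
  expect_true(all(s0$absorbance == 0))

  # same seed twice -> identical traces
  m <- spectrum_model(c(ch2_asym = 0.8), noise_sd = 1e-3, seed = 77L)
  expect_identical(simulate_spectrum(m)$absorbance,
                   simulate_spectrum(m)$absorbance)
  expect_false(identical(simulate_spectrum(m, seed = 78L)$absorbance,
                         simulate_spectrum(m)$absorbance))

  # one Gaussian band on a grid containing its center: pipeline-measured
  # apex equals the amplitude
  mg <- spectrum_model(c(ch2_asym = 0.62), fwhm = 15, eta = 0, noise_sd = 0,
                       grid = seq(2800, 3012, by = 4))
  s <- simulate_spectrum(mg)
  p <- baseline_subtract(s, default_regions()$lipid)
  expect_equal(measure_band(p, "ch2_asym")$intensity, 0.62,
               tolerance = 1e-6 / 0.62)
})

test_that("polynomial baselines and noise are applied as specified", {
  m <- spectrum_model(c(ch2_asym = 0), baseline = c(0.2, 1e-4, -1e-8),
                      noise_sd = 0)
  s <- simulate_spectrum(m)
  w <- s$wavenumbers
  expect_equal(s$absorbance, 0.2 + 1e-4 * w - 1e-8 * w^2, tolerance = 1e-12)

  mn <- spectrum_model(c(ch2_asym = 0), noise_sd = 0.01, seed = 4L)
  sn <- simulate_spectrum(mn)
  expect_equal(sd(sn$absorbance), 0.01, tolerance = 0.1)
})

test_that("group pairs honor null effects and planted multipliers", {
  base <- study_preset("hela-control", noise_sd = 0)

  # identity effect, zero CV -> both groups identical
  pair0 <- simulate_group_pair(base, group_effect(replicate_cv = 0),
                               n_per_group = 2, seed = 3)
  expect_identical(pair0$control$replicates[[1]]$absorbance,
                   pair0$treated$replicates[[1]]$absorbance)

  # amplitude multiplier on one band leaves the others essentially
  # untouched (the olefinic tail reaches the 3012 baseline anchor, so a
  # sub-percent coupling through the baseline remains)
  eff <- group_effect(multipliers = c(olefinic = 0.5), replicate_cv = 0)
  pair <- simulate_group_pair(base, eff, n_per_group = 1, seed = 3)
  t1 <- replicate_band_table(pair$control$replicates[[1]])
  t2 <- replicate_band_table(pair$treated$replicates[[1]])
  expect_equal(t2$intensity[t2$band == "ch2_asym"],
               t1$intensity[t1$band == "ch2_asym"], tolerance = 0.01)
  expect_lt(t2$intensity[t2$band == "olefinic"],
            0.6 * t1$intensity[t1$band == "olefinic"])

  expect_error(simulate_group_pair(base,
    group_effect(multipliers = c(nosuch = 2))), "unknown bands")
})

test_that("noiseless paired simulation recovers every planted metric", {
  preset_of <- list(cisplatin = c(control = "hela-control",
                                  treated = "hela-cisplatin"),
                    kd = c(control = "hela-kd-control",
                           treated = "hela-kd"))
  for (study in c("cisplatin", "kd")) {
    pair <- simulate_study_pair(study, seed = 11, replicate_cv = 0,
                                noise_sd = 0)
    for (g in c("control", "treated")) {
      spec <- ftirquant:::preset_spec(preset_of[[study]][[g]])
      t <- spec$targets
      planted <- c(
        lipid_protein_ratio = unname(t["ch2_sym"] / t["ch3_sym"]),
        chain_length_index = unname(t["ch2_asym"] / t["ch3_asym"]),
        olefinic_index = unname(t["olefinic"] / t["ch2_asym"]),
        glycogen_996 = unname(t["glycogen_996"] / t["po2_sym"]),
        glycogen_1156 = unname(t["glycogen_1156"] / t["po2_sym"]),
        protein_CO_1171 = unname(t["protein_co_1171"] / t["po2_sym"]),
        rna_content_1121 = unname(t["rna_1121"] / t["po2_sym"]))
      tab <- replicate_band_table(pair[[g]]$replicates[[1]])
      for (metric in names(planted)) {
        # planted value recovered to <= 0.2% relative error
        expect_equal(ftirquant:::metric_value(tab, metric),
                     planted[[metric]], tolerance = 2e-3)
      }
      # planted phosphate-band centers recovered well below grid resolution
      expect_lt(abs(ftirquant:::metric_value(tab, "po2_sym_position") -
                      spec$centers[["po2_sym"]]), 0.25)
      expect_lt(abs(ftirquant:::metric_value(tab, "po2_asym_position") -
                      spec$centers[["po2_asym"]]), 0.25)
    }
  }
})

test_that("planted olefinic collapse reproduces the knockdown contrast", {
  pair <- simulate_study_pair("kd", seed = 2, replicate_cv = 0, noise_sd = 0)
  cmp <- compare_groups("olefinic_index", pair$control, pair$treated)
  expect_equal(signif(cmp$percent_change, 3), -76.5)
})

test_that("DE pair simulation plants its design exactly and deterministically", {
  plan <- list(n_genes = 100, n_sig_1 = 40, n_sig_2 = 60, n_shared = 30,
               n_parallel_up = 10, n_parallel_down = 15)
  pair <- do.call(simulate_deg_pair, c(plan, seed = 21))
  r <- concordance(pair$t1, pair$t2)
  expect_equal(r$n_sig_1, 40)
  expect_equal(r$n_sig_2, 60)
  expect_equal(r$n_shared, 30)
  expect_equal(r$n_parallel, 25)
  expect_equal(r$n_parallel_up, 10)
  expect_equal(r$n_parallel_down, 15)

  pair2 <- do.call(simulate_deg_pair, c(plan, seed = 21))
  expect_identical(pair$t1$padj, pair2$t1$padj)
  expect_identical(pair$t2$log2fc, pair2$t2$log2fc)

  # the planted membership attribute agrees with brute-force set algebra
  planted <- attr(pair, "planted")
  sig1 <- pair$t1$gene_id[pair$t1$padj < 0.05]
  sig2 <- pair$t2$gene_id[pair$t2$padj < 0.05]
  expect_setequal(sig1, planted$sig1)
  expect_setequal(intersect(sig1, sig2), planted$shared)

  # zero shared genes -> missing correlation
  none <- simulate_deg_pair(50, 10, 10, 0, 0, 0, seed = 3)
  rn <- concordance(none$t1, none$t2)
  expect_equal(rn$n_shared, 0)
  expect_true(is.na(rn$pearson_r))

  expect_error(simulate_deg_pair(100, 40, 60, 50, 10, 15, seed = 1),
               "n_shared")
  expect_error(simulate_deg_pair(100, 40, 60, 30, 20, 15, seed = 1),
               "n_parallel")
})

test_that("preset calibration hits its measured targets", {
  for (name in study_presets()) {
    model <- study_preset(name, noise_sd = 0)
    s <- simulate_spectrum(model)
    tab <- replicate_band_table(s, bands = names(model$amplitudes))
    spec <- ftirquant:::preset_spec(name)
    measured <- tab$intensity[match(names(spec$targets), tab$band)]
    expect_lt(max(abs(measured - spec$targets)), 1e-9)
  }
})
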