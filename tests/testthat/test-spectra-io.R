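test_that("CSV reading handles zero traces, direction and round trips", {
  tmp <- withr::local_tempdir()

  # constant-zero trace
  f <- file.path(tmp, "zero.csv")
  writeLines(c("wavenumber,absorbance",
               sprintf("%d,0.0", seq(450, 4000, by = 50))), f)
  s <- read_spectrum_csv(f, sample_id = "z", group_label = "g")
  expect_s3_class(s, "ftir_spectrum")
  expect_true(all(s$absorbance == 0))
  expect_true(all(diff(s$wavenumbers) > 0))

  # descending listing loads identically to ascending
  w <- seq(450, 4000, by = 4)
  a <- sin(w / 100) + 2
  fa <- file.path(tmp, "asc.csv"); fd <- file.path(tmp, "desc.csv")
  writeLines(c("wavenumber,absorbance", sprintf("%.10g,%.10g", w, a)), fa)
  writeLines(c("wavenumber,absorbance",
               sprintf("%.10g,%.10g", rev(w), rev(a))), fd)
  sa <- read_spectrum_csv(fa, sample_id = "s", group_label = "g")
  sd_ <- read_spectrum_csv(fd, sample_id = "s", group_label = "g")
  expect_identical(sa$wavenumbers, sd_$wavenumbers)
  expect_identical(sa$absorbance, sd_$absorbance)
  expect_equal(sd_$metadata$original_direction, "descending")

  # write-then-read reproduces every pair bit for bit
  s2 <- ftir_spectrum(w, a + pi * 1e-7, sample_id = "rt", group_label = "g")
  frt <- file.path(tmp, "rt.csv")
  write_spectrum_csv(s2, frt)
  s3 <- read_spectrum_csv(frt, sample_id = "rt", group_label = "g")
  expect_identical(s3$wavenumbers, s2$wavenumbers)
  expect_identical(s3$absorbance, s2$absorbance)

  # tab separation also accepted
  ft <- file.path(tmp, "tab.tsv")
  writeLines(c("wavenumber\tabsorbance",
               sprintf("%.17g\t%.17g", w[1:5], a[1:5])), ft)
  expect_equal(read_spectrum_csv(ft)$absorbance, a[1:5])
})

test_that("CSV parse and validation failures are specific", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")
  writeLines(c("wavenumber,absorbance", "450,0.1", "451,oops", "452,0.2"), f)
  expect_error(read_spectrum_csv(f), "line 3")

  f2 <- file.path(tmp, "dup.csv")
  writeLines(c("450,0.1", "451,0.2", "451,0.3", "452,0.2"), f2)
  expect_error(read_spectrum_csv(f2), "duplicate wavenumber")

  expect_error(ftir_spectrum(c(1, 2, 3), c(0, NA, 0)), "finite")
  expect_error(ftir_spectrum(c(1, 3, 2), c(0, 0, 0)), "monotonic")
})

test_that("JCAMP-DX XYPOINTS and XYDATA forms are reconstructed", {
  tmp <- withr::local_tempdir()

  f <- file.path(tmp, "pts.jdx")
  writeLines(c("##TITLE=five points", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##XYPOINTS=(XY..XY)",
               "1000, 0.1; 1004, 0.2", "1008, 0.5", "1012, 0.3; 1016, 0.1",
               "##END="), f)
  s <- read_jcamp(f)
  expect_equal(s$wavenumbers, c(1000, 1004, 1008, 1012, 1016))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.5, 0.3, 0.1))
  expect_equal(s$sample_id, "five points")

  # XYDATA with YFACTOR applied to integer ordinates
  f2 <- file.path(tmp, "xy.jdx")
  writeLines(c("##TITLE=xydata", "##XUNITS=1/CM", "##FIRSTX=2000",
               "##LASTX=2016", "##NPOINTS=5", "##DELTAX=4",
               "##YFACTOR=0.001", "##XYDATA=(X++(Y..Y))",
               "2000 120 340 560", "2012 410 95", "##END="), f2)
  s2 <- read_jcamp(f2)
  expect_equal(s2$wavenumbers, seq(2000, 2016, by = 4))
  expect_equal(s2$absorbance, c(120, 340, 560, 410, 95) * 0.001)

  # descending instrument order stored ascending
  f3 <- file.path(tmp, "desc.jdx")
  writeLines(c("##XUNITS=1/CM", "##DELTAX=-4", "##YFACTOR=1",
               "##XYDATA=(X++(Y..Y))", "3000 5 6 7", "##END="), f3)
  s3 <- read_jcamp(f3)
  expect_equal(s3$wavenumbers, c(2992, 2996, 3000))
  expect_equal(s3$absorbance, c(7, 6, 5))
})

test_that("JCAMP-DX unsupported dialects and units are rejected", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "nm.jdx")
  writeLines(c("##XUNITS=NANOMETERS", "##XYPOINTS=(XY..XY)",
               "500 0.1", "##END="), f)
  expect_error(read_jcamp(f), "unsupported XUNITS")

  # SQZ-compressed ordinates
  f2 <- file.path(tmp, "sqz.jdx")
  writeLines(c("##XUNITS=1/CM", "##DELTAX=4", "##XYDATA=(X++(Y..Y))",
               "1000 A123J456", "##END="), f2)
  expect_error(read_jcamp(f2), "dialect")

  f3 <- file.path(tmp, "form.jdx")
  writeLines(c("##XUNITS=1/CM", "##XYDATA=(XY..XY)", "1000 1", "##END="), f3)
  expect_error(read_jcamp(f3), "unsupported")
})

test_that("default band catalog holds the diagnostic bands", {
  cat <- load_band_catalog()
  expect_s3_class(cat, "band_catalog")
  ole <- cat[cat$name == "olefinic", ]
  expect_equal(ole$center, 3006)
  rna <- cat[cat$name == "rna_1121", ]
  expect_equal(rna$center, 1121)
  expect_equal(rna$normalization_ref, "po2_sym")
  expect_equal(cat$center[cat$name == "po2_sym"], 1082)
  # all eleven published bands present
  expect_setequal(cat$name,
    c("olefinic", "ch3_asym", "ch2_asym", "ch3_sym", "ch2_sym", "po2_asym",
      "protein_co_1171", "glycogen_1156", "rna_1121", "po2_sym",
      "glycogen_996"))
  expect_true(all(cat$window_halfwidth > 0))
})

test_that("user band catalogs are validated and loadable from CSV and YAML", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "bad.csv")
  utils::write.csv(data.frame(
    name = "offscale", assignment = "x", center = 5000,
    window_halfwidth = 8, region_id = "lipid",
    normalization_ref = NA), f, row.names = FALSE)
  expect_error(load_band_catalog(f), "outside")

  f2 <- file.path(tmp, "ok.csv")
  utils::write.csv(data.frame(
    name = c("a", "b"), assignment = "", center = c(1000, 1100),
    window_halfwidth = 8, region_id = "fingerprint",
    normalization_ref = c(NA, "a")), f2, row.names = FALSE)
  cat2 <- load_band_catalog(f2)
  expect_equal(nrow(cat2), 2)

  f3 <- file.path(tmp, "cat.yaml")
  writeLines(c("bands:",
               "  - name: a", "    center: 1000", "    region_id: fingerprint",
               "  - name: b", "    center: 1100", "    region_id: fingerprint",
               "    normalization_ref: a"), f3)
  cat3 <- load_band_catalog(f3)
  expect_equal(cat3$normalization_ref[cat3$name == "b"], "a")
})

test_that("spectrum groups enforce consistent labelling", {
  s1 <- one_band_spectrum(2924, group_label = "a")
  s2 <- one_band_spectrum(2924, group_label = "b")
  expect_error(spectrum_group(list(s1, s2)), "different group labels")
  g <- spectrum_group(list(s1, s2), label = "merged")
  expect_equal(g$label, "merged")
  expect_true(all(vapply(g$replicates, function(s) s$group_label,
                         character(1)) == "merged"))
  expect_error(spectrum_group(list()), "at least one")
})
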