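#' Supported macromolecular metrics
#'
#' Intensity-ratio and band-position indices derived from the catalog
#' bands:
#' * `lipid_protein_ratio` - I(CH2 sym 2852) / I(CH3 sym 2872), the
#'   lipid-to-protein ratio.
#' * `chain_length_index` - I(CH2 asym 2924) / I(CH3 asym 2958), the acyl
#'   hydrocarbon chain-length index.
#' * `olefinic_index` - I(olefinic 3006) on the CH2-asym-normalized lipid
#'   trace; tracks lipid unsaturation / peroxidation.
#' * `glycogen_996`, `glycogen_1156`, `protein_CO_1171`,
#'   `rna_content_1121` - fingerprint intensities normalized to the PO2-
#'   symmetric 1082 band.
#' * `po2_sym_position`, `po2_asym_position` - sub-resolution positions
#'   (cm^-1) of the phosphate bands; group contrasts are band shifts.
#'
#' @return Character vector of metric names.
#' @export
ftir_metrics <- function() {
  c("lipid_protein_ratio", "chain_length_index", "olefinic_index",
    "glycogen_996", "glycogen_1156", "protein_CO_1171", "rna_content_1121",
    "po2_sym_position", "po2_asym_position")
}

metric_bands <- function(metric) {
  switch(metric,
    lipid_protein_ratio = c("ch2_sym", "ch3_sym"),
    chain_length_index = c("ch2_asym", "ch3_asym"),
    olefinic_index = c("olefinic", "ch2_asym"),
    glycogen_996 = c("glycogen_996", "po2_sym"),
    glycogen_1156 = c("glycogen_1156", "po2_sym"),
    protein_CO_1171 = c("protein_co_1171", "po2_sym"),
    rna_content_1121 = c("rna_1121", "po2_sym"),
    po2_sym_position = "po2_sym",
    po2_asym_position = "po2_asym",
    stop("unknown metric '", metric, "'; see ftir_metrics()")
  )
}

position_metrics <- function() c("po2_sym_position", "po2_asym_position")

#' Measure catalog bands on one replicate spectrum
#'
#' Baseline-subtracts each analysis region that holds a requested band and
#' measures raw apex intensities and positions; normalized intensities are
#' the raw intensity divided by the raw intensity of the region's reference
#' band (equivalent to measuring on the normalized trace).
#'
#' @param s an `ftir_spectrum`.
#' @param catalog a `band_catalog`.
#' @param regions named list of `analysis_region` objects.
#' @param bands band names to measure; default all catalog bands.
#' @return Data frame with one row per band: `band`, `region`, `intensity`
#'   (raw, baselined trace), `intensity_norm` (reference-band normalized;
#'   `NA` when the region has no reference), `position`, `edge`.
#' @export
replicate_band_table <- function(s, catalog = default_band_catalog(),
                                 regions = default_regions(), bands = NULL) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (is.null(bands)) bands <- catalog$name
  idx <- match(bands, catalog$name)
  if (anyNA(idx)) {
    stop("bands not in catalog: ", paste(bands[is.na(idx)], collapse = ", "))
  }
  sub <- catalog[idx, , drop = FALSE]
  # reference bands must be measured too, for normalization
  need_regions <- unique(sub$region_id)
  norm_names <- unlist(lapply(need_regions, function(rid) {
    nb <- regions[[rid]]$norm_band
    if (!is.null(nb) && !is.na(nb)) nb else character(0)
  }))
  all_bands <- unique(c(sub$name, norm_names))
  sub <- catalog[match(all_bands, catalog$name), , drop = FALSE]

  out <- list()
  for (rid in unique(sub$region_id)) {
    region <- regions[[rid]]
    if (is.null(region)) stop("no analysis region defined for '", rid, "'")
    p <- baseline_subtract(s, region)
    rows <- sub[sub$region_id == rid, , drop = FALSE]
    ms <- lapply(seq_len(nrow(rows)), function(i) {
      measure_band(p, as.list(rows[i, , drop = FALSE]))
    })
    raw <- vapply(ms, function(m) m$intensity, numeric(1))
    nb <- region$norm_band
    norm <- rep(NA_real_, length(raw))
    if (!is.null(nb) && !is.na(nb)) {
      ref <- if (nb %in% rows$name) {
        raw[match(nb, rows$name)]
      } else {
        measure_band(p, band_def(catalog, nb))$intensity
      }
      if (!is.finite(ref) || ref <= 0) {
        stop(sprintf(
          "reference band '%s' intensity %.6g is not positive in '%s' (degenerate spectrum)",
          nb, ref, s$sample_id))
      }
      norm <- raw / ref
    }
    out[[rid]] <- data.frame(
      band = rows$name, region = rid, intensity = raw,
      intensity_norm = norm,
      position = vapply(ms, function(m) m$position, numeric(1)),
      edge = vapply(ms, function(m) m$edge, logical(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(intersect(all_bands, res$band), res$band), , drop = FALSE]
}

tbl_raw <- function(m, band) {
  i <- match(band, m$band)
  if (is.na(i)) stop("band '", band, "' missing from measurement table")
  m$intensity[i]
}
tbl_norm <- function(m, band) {
  i <- match(band, m$band)
  if (is.na(i)) stop("band '", band, "' missing from measurement table")
  m$intensity_norm[i]
}
tbl_pos <- function(m, band) {
  i <- match(band, m$band)
  if (is.na(i)) stop("band '", band, "' missing from measurement table")
  m$position[i]
}

ratio_checked <- function(num, den, what) {
  if (!is.finite(den) || den <= 0) {
    stop("degenerate spectrum: ", what, " denominator intensity ",
         format(den, digits = 6), " is not positive")
  }
  num / den
}

#' Lipid-to-protein ratio for one replicate
#'
#' `I(CH2 sym 2852) / I(CH3 sym 2872)` on the baselined lipid-region
#' trace. Ratios of same-region intensities are unaffected by
#' normalization.
#'
#' @param m measurement table from [replicate_band_table()].
#' @return Dimensionless ratio.
#' @export
lipid_protein_ratio <- function(m) {
  ratio_checked(tbl_raw(m, "ch2_sym"), tbl_raw(m, "ch3_sym"),
                "CH3 symmetric")
}

#' Acyl chain-length index for one replicate
#'
#' `I(CH2 asym 2924) / I(CH3 asym 2958)` on the baselined lipid-region
#' trace.
#'
#' @inheritParams lipid_protein_ratio
#' @return Dimensionless ratio.
#' @export
chain_length_index <- function(m) {
  ratio_checked(tbl_raw(m, "ch2_asym"), tbl_raw(m, "ch3_asym"),
                "CH3 asymmetric")
}

#' Olefinic (lipid peroxidation) index for one replicate
#'
#' Apex intensity of the 3006 cm^-1 olefinic band on the lipid-region
#' trace normalized to the CH2 asymmetric (2924 cm^-1) band.
#'
#' @inheritParams lipid_protein_ratio
#' @return Intensity on the normalized trace.
#' @export
olefinic_index <- function(m) {
  ratio_checked(tbl_raw(m, "olefinic"), tbl_raw(m, "ch2_asym"),
                "CH2 asymmetric")
}

#' RNA content index for one replicate
#'
#' `I(1121) / I(PO2 sym 1082)` on the fingerprint trace.
#'
#' @inheritParams lipid_protein_ratio
#' @return Dimensionless ratio.
#' @export
rna_content <- function(m) {
  ratio_checked(tbl_raw(m, "rna_1121"), tbl_raw(m, "po2_sym"), "PO2 symmetric")
}

#' Glycogen and protein C-O band intensities for one replicate
#'
#' Intensities at 996, 1156 and 1171 cm^-1 on the PO2-sym-normalized
#' fingerprint trace.
#'
#' @inheritParams lipid_protein_ratio
#' @return Named numeric vector `glycogen_996`, `glycogen_1156`,
#'   `protein_CO_1171`.
#' @export
glycogen_and_protein_bands <- function(m) {
  c(glycogen_996 = tbl_norm(m, "glycogen_996"),
    glycogen_1156 = tbl_norm(m, "glycogen_1156"),
    protein_CO_1171 = tbl_norm(m, "protein_co_1171"))
}

metric_value <- function(m, metric) {
  switch(metric,
    lipid_protein_ratio = lipid_protein_ratio(m),
    chain_length_index = chain_length_index(m),
    olefinic_index = olefinic_index(m),
    glycogen_996 = tbl_norm(m, "glycogen_996"),
    glycogen_1156 = tbl_norm(m, "glycogen_1156"),
    protein_CO_1171 = tbl_norm(m, "protein_co_1171"),
    rna_content_1121 = rna_content(m),
    po2_sym_position = tbl_pos(m, "po2_sym"),
    po2_asym_position = tbl_pos(m, "po2_asym"),
    stop("unknown metric '", metric, "'")
  )
}

#' Evaluate a metric on every replicate of a group
#'
#' @param g an `ftir_spectrum_group`.
#' @param metric one of [ftir_metrics()].
#' @param catalog,regions band catalog and analysis regions.
#' @return A list of class `metric_result`: `metric`, `group_label`,
#'   `per_replicate`, `mean`, `sd` (sample SD, n-1), `n`.
#' @export
compute_metric <- function(g, metric, catalog = default_band_catalog(),
                           regions = default_regions()) {
  stopifnot(inherits(g, "ftir_spectrum_group"))
  bands <- metric_bands(metric)
  vals <- vapply(g$replicates, function(s) {
    metric_value(replicate_band_table(s, catalog, regions, bands = bands),
                 metric)
  }, numeric(1))
  sm <- summarize_sample(vals)
  structure(list(metric = metric, group_label = g$label,
                 per_replicate = vals, mean = sm$mean, sd = sm$sd, n = sm$n),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s [%s]: %.6g +/- %s (n = %d)\n",
              x$metric, x$group_label, x$mean,
              format(x$sd, digits = 4), x$n))
  invisible(x)
}

#' Percent change between group means
#'
#' `100 * (treated - control) / control`, with a direction label.
#' Satisfies `(1 + pc(a,b)/100) * (1 + pc(b,a)/100) = 1`.
#'
#' @param control_mean,treated_mean group means; `control_mean` must be
#'   non-zero.
#' @return Signed percent change (numeric), with attribute `direction`
#'   (`"increase"`, `"decrease"` or `"none"`).
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (!is.finite(control_mean) || control_mean == 0) {
    stop("percent change undefined: control mean is zero or non-finite")
  }
  pc <- 100 * (treated_mean - control_mean) / control_mean
  attr(pc, "direction") <-
    if (pc > 0) "increase" else if (pc < 0) "decrease" else "none"
  pc
}

#' Compare one metric between control and treated replicate groups
#'
#' Runs the per-replicate pipeline (baseline, measure, index) on both
#' groups, computes the percent change of group means (or the band shift
#' for position metrics) and a two-sided p-value.
#'
#' @param metric one of [ftir_metrics()].
#' @param control,treated `ftir_spectrum_group` objects.
#' @param catalog,regions band catalog and analysis regions.
#' @param test `"mann_whitney"` (exact for small tie-free samples, the
#'   replicate-group default) or `"t_test"` (pooled unpaired).
#' @return A list of class `comparison_result` with the two
#'   `metric_result`s, `percent_change`, `difference`
#'   (treated mean - control mean; the band shift for position metrics),
#'   `direction`, `p_value`, `test`.
#' @export
compare_groups <- function(metric, control, treated,
                           catalog = default_band_catalog(),
                           regions = default_regions(),
                           test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  mc <- compute_metric(control, metric, catalog, regions)
  mt <- compute_metric(treated, metric, catalog, regions)
  tr <- if (test == "mann_whitney") {
    mann_whitney_u(mc$per_replicate, mt$per_replicate, mode = "auto")
  } else {
    t_test_unpaired(mc$per_replicate, mt$per_replicate)
  }
  pc <- percent_change(mc$mean, mt$mean)
  structure(
    list(metric = metric, control = mc, treated = mt,
         percent_change = as.numeric(pc),
         difference = mt$mean - mc$mean,
         direction = attr(pc, "direction"),
         p_value = tr$p_two_sided, test = tr$test,
         is_position = metric %in% position_metrics()),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$is_position) {
    cat(sprintf(
      "<comparison_result> %s: shift %+.3f cm-1 (%.2f -> %.2f), p = %.4g [%s]\n",
      x$metric, x$difference, x$control$mean, x$treated$mean,
      x$p_value, x$test))
  } else {
    cat(sprintf(
      "<comparison_result> %s: %+.3g%% (%s) %.6g -> %.6g, p = %.4g [%s]\n",
      x$metric, signif(x$percent_change, 3), x$direction,
      x$control$mean, x$treated$mean, x$p_value, x$test))
  }
  invisible(x)
}

#' Compare all metrics between two replicate groups
#'
#' @inheritParams compare_groups
#' @param metrics metric names (default all of [ftir_metrics()]).
#' @return A list of class `comparison_report`: `comparisons` (list of
#'   `comparison_result`) and `table` (tidy data frame; percent changes to
#'   3 significant figures and ratios to 4 decimals are applied only by the
#'   writers, the table keeps full precision).
#' @export
compare_all <- function(control, treated, metrics = ftir_metrics(),
                        catalog = default_band_catalog(),
                        regions = default_regions(),
                        test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  comps <- lapply(metrics, compare_groups, control = control,
                  treated = treated, catalog = catalog, regions = regions,
                  test = test)
  names(comps) <- metrics
  tab <- do.call(rbind, lapply(comps, function(cx) {
    data.frame(metric = cx$metric,
               control_mean = cx$control$mean, control_sd = cx$control$sd,
               treated_mean = cx$treated$mean, treated_sd = cx$treated$sd,
               n_control = cx$control$n, n_treated = cx$treated$n,
               percent_change = cx$percent_change,
               difference = cx$difference,
               direction = cx$direction,
               p_value = cx$p_value, test = cx$test,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(comparisons = comps, table = tab,
                 control_label = control$label, treated_label = treated$label),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$control_label,
              x$treated_label))
  for (cx in x$comparisons) print(cx)
  invisible(x)
}

round_report <- function(tab) {
  tab$percent_change <- signif(tab$percent_change, 3)
  num <- c("control_mean", "control_sd", "treated_mean", "treated_sd",
           "difference")
  for (col in num) tab[[col]] <- round(tab[[col]], 4)
  tab
}

#' Write a comparison report as CSV
#'
#' Percent changes are rounded to 3 significant figures and means/SDs to 4
#' decimals, the conventional reporting precision for these indices.
#'
#' @param report a `comparison_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(round_report(report$table), path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as JSON
#'
#' @inheritParams write_report_csv
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(control = report$control_label, treated = report$treated_label,
         metrics = round_report(report$table)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
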