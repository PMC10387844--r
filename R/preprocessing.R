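interp_at <- function(s, x) {
  stats::approx(s$wavenumbers, s$absorbance, xout = x, method = "linear",
                rule = 1)$y
}

spectrum_covers <- function(s, lo, hi) {
  min(s$wavenumbers) <= lo && max(s$wavenumbers) >= hi
}

#' Subtract a two-point linear baseline over an analysis region
#'
#' The straight line through the spectrum's values at the region's two
#' anchor points (values obtained by linear interpolation onto the anchors)
#' is subtracted, and the trace is restricted to `[lo, hi]`. Adding any
#' affine function `a + b*wavenumber` to the input leaves the output
#' unchanged.
#'
#' @param s an `ftir_spectrum`.
#' @param region an `analysis_region`.
#' @return An object of class `ftir_processed`: the baselined region trace
#'   with fields `parent` (sample id), `group_label`, `region`,
#'   `wavenumbers`, `absorbance`, `normalization_factor` (`NA` until
#'   [normalize_to_band()] is applied).
#' @export
baseline_subtract <- function(s, region) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(region, "analysis_region"))
  lo <- min(region$lo, region$anchor_lo)
  hi <- max(region$hi, region$anchor_hi)
  if (!spectrum_covers(s, lo, hi)) {
    stop(sprintf(
      "spectrum '%s' (%.6g-%.6g cm-1) does not cover region '%s' span %.6g-%.6g cm-1",
      s$sample_id, min(s$wavenumbers), max(s$wavenumbers),
      region$region_id, lo, hi))
  }
  y_lo <- interp_at(s, region$anchor_lo)
  y_hi <- interp_at(s, region$anchor_hi)
  slope <- (y_hi - y_lo) / (region$anchor_hi - region$anchor_lo)
  keep <- s$wavenumbers >= region$lo & s$wavenumbers <= region$hi
  w <- s$wavenumbers[keep]
  a <- s$absorbance[keep] - (y_lo + slope * (w - region$anchor_lo))
  structure(
    list(parent = s$sample_id, group_label = s$group_label, region = region,
         wavenumbers = w, absorbance = a,
         normalization_factor = NA_real_),
    class = "ftir_processed"
  )
}

#' @export
print.ftir_processed <- function(x, ...) {
  cat(sprintf(
    "<ftir_processed> %s, region '%s' (%.6g-%.6g cm-1), %d points%s\n",
    x$parent, x$region$region_id, x$region$lo, x$region$hi,
    length(x$wavenumbers),
    if (is.na(x$normalization_factor)) ""
    else sprintf(", normalized (factor %.6g)", x$normalization_factor)))
  invisible(x)
}

#' Normalize a baselined region trace to its reference band
#'
#' Divides every absorbance value by the measured apex intensity of the
#' region's reference band (see [measure_band()]), so the reference band's
#' intensity in the output is 1. Normalizing an already-normalized trace is
#' a no-op (the reference intensity is then 1).
#'
#' @param p an `ftir_processed` trace.
#' @param catalog a `band_catalog`; the region's `norm_band` must be in it.
#' @return The normalized `ftir_processed`, with `normalization_factor`
#'   recording the (cumulative) divisor.
#' @export
normalize_to_band <- function(p, catalog = default_band_catalog()) {
  stopifnot(inherits(p, "ftir_processed"))
  nb <- p$region$norm_band
  if (is.null(nb) || is.na(nb)) {
    stop("region '", p$region$region_id, "' has no normalization band")
  }
  band <- band_def(catalog, nb)
  m <- measure_band(p, band)
  if (!is.finite(m$intensity) || m$intensity <= 0) {
    stop(sprintf(
      "normalization failed for '%s': reference band '%s' intensity %.6g is not positive (degenerate or noise-only spectrum)",
      p$parent, nb, m$intensity))
  }
  p$absorbance <- p$absorbance / m$intensity
  p$normalization_factor <-
    if (is.na(p$normalization_factor)) m$intensity
    else p$normalization_factor * m$intensity
  p
}

#' Resample a spectrum onto a wavenumber grid by linear interpolation
#'
#' @param s an `ftir_spectrum` or `ftir_processed` trace.
#' @param grid ordered wavenumber values, all within the spectrum's span
#'   (no extrapolation).
#' @return Object of the same class as `s` on the new grid.
#' @export
resample <- function(s, grid) {
  grid <- as.numeric(grid)
  if (any(grid < min(s$wavenumbers) - 1e-9) ||
      any(grid > max(s$wavenumbers) + 1e-9)) {
    stop(sprintf(
      "resample grid (%.6g-%.6g) extends beyond spectrum span (%.6g-%.6g); extrapolation is not supported",
      min(grid), max(grid), min(s$wavenumbers), max(s$wavenumbers)))
  }
  y <- stats::approx(s$wavenumbers, s$absorbance, xout = grid,
                     method = "linear", rule = 2)$y
  s$wavenumbers <- grid
  s$absorbance <- y
  s
}

#' Average a replicate group over an analysis region
#'
#' Each replicate is baseline-subtracted over the region, resampled onto a
#' common grid (the grid of the replicate with the finest median spacing,
#' restricted to the region), and the pointwise mean is returned. Intended
#' for display/export; per-replicate measurement (the default elsewhere) is
#' what group statistics are computed from.
#'
#' @param g an `ftir_spectrum_group`.
#' @param region an `analysis_region`.
#' @param normalize if `TRUE`, the averaged trace is normalized to the
#'   region's reference band.
#' @param catalog band catalog used when `normalize = TRUE`.
#' @return An `ftir_processed` averaged trace (parent = group label).
#' @export
average_group <- function(g, region, normalize = FALSE,
                          catalog = default_band_catalog()) {
  stopifnot(inherits(g, "ftir_spectrum_group"))
  if (length(g$replicates) == 0L) stop("empty spectrum group")
  proc <- lapply(g$replicates, baseline_subtract, region = region)
  spacing <- vapply(proc, function(p) stats::median(diff(p$wavenumbers)),
                    numeric(1))
  grid <- proc[[which.min(spacing)]]$wavenumbers
  mats <- vapply(proc, function(p) resample(p, grid)$absorbance,
                 numeric(length(grid)))
  avg <- proc[[1L]]
  avg$parent <- g$label
  avg$wavenumbers <- grid
  avg$absorbance <- if (length(proc) == 1L) as.numeric(mats) else rowMeans(mats)
  if (normalize) avg <- normalize_to_band(avg, catalog)
  avg
}

#' Export a processed region trace as CSV
#'
#' @param p an `ftir_processed` trace.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_processed_csv <- function(p, path) {
  stopifnot(inherits(p, "ftir_processed"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber,absorbance", con)
  writeLines(sprintf("%.17g,%.17g", p$wavenumbers, p$absorbance), con)
  invisible(path)
}
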