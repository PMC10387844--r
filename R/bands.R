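WAVENUMBER_MIN <- 450
WAVENUMBER_MAX <- 4000

#' Default band catalog
#'
#' The built-in catalog of the diagnostic bands used for macromolecular
#' quantification of cell spectra: the C-H stretching bands of the
#' 2800-3012 cm^-1 lipid region (olefinic =CH at 3006; CH3/CH2 asymmetric at
#' 2958/2924; CH3/CH2 symmetric at 2872/2852) and the fingerprint-region
#' nucleic acid / carbohydrate / protein bands (PO2- asymmetric 1234,
#' protein C-O 1171, glycogen 1156, RNA 1121, PO2- symmetric 1082,
#' glycogen 996). Fingerprint intensities are conventionally reported after
#' normalization to the PO2- symmetric band; the lipid region is normalized
#' to the CH2 asymmetric band.
#'
#' @format A data frame of class `band_catalog` with columns `name`,
#'   `assignment`, `center` (cm^-1), `window_halfwidth` (cm^-1),
#'   `region_id`, `normalization_ref`.
#' @seealso [load_band_catalog()], [default_regions()]
#' @export
default_band_catalog <- function() {
  cat <- data.frame(
    name = c("olefinic", "ch3_asym", "ch2_asym", "ch3_sym", "ch2_sym",
             "po2_asym", "protein_co_1171", "glycogen_1156", "rna_1121",
             "po2_sym", "glycogen_996"),
    assignment = c(
      "olefinic =CH stretching (unsaturated fatty acids / lipid peroxidation)",
      "CH3 asymmetric stretching",
      "CH2 asymmetric stretching",
      "CH3 symmetric stretching",
      "CH2 symmetric stretching",
      "PO2- asymmetric stretching (nucleic acids)",
      "C-O stretching (proteins) / CO-O-C stretching (cholesterol)",
      "C-O stretching (glycogen)",
      "ribose/phosphate (RNA)",
      "PO2- symmetric stretching (nucleic acids)",
      "C-O / C-C stretching (glycogen)"
    ),
    center = c(3006, 2958, 2924, 2872, 2852,
               1234, 1171, 1156, 1121, 1082, 996),
    window_halfwidth = 8,
    region_id = c(rep("lipid", 5), "fingerprint_full",
                  rep("fingerprint", 5)),
    normalization_ref = c("ch2_asym", NA, NA, NA, NA,
                          NA, "po2_sym", "po2_sym", "po2_sym", NA, "po2_sym"),
    stringsAsFactors = FALSE
  )
  validate_band_catalog(cat)
}

validate_band_catalog <- function(cat) {
  need <- c("name", "assignment", "center", "window_halfwidth",
            "region_id", "normalization_ref")
  miss <- setdiff(need, names(cat))
  if (length(miss)) stop("band catalog missing columns: ",
                         paste(miss, collapse = ", "))
  cat$center <- as.numeric(cat$center)
  cat$window_halfwidth <- as.numeric(cat$window_halfwidth)
  if (anyDuplicated(cat$name)) stop("duplicate band names in catalog")
  if (any(!is.finite(cat$center)) ||
      any(cat$center < WAVENUMBER_MIN | cat$center > WAVENUMBER_MAX)) {
    bad <- cat$name[!is.finite(cat$center) |
                    cat$center < WAVENUMBER_MIN | cat$center > WAVENUMBER_MAX]
    stop("band center outside ", WAVENUMBER_MIN, "-", WAVENUMBER_MAX,
         " cm-1 for: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(cat$window_halfwidth)) || any(cat$window_halfwidth <= 0)) {
    stop("window_halfwidth must be > 0 for every band")
  }
  refs <- cat$normalization_ref[!is.na(cat$normalization_ref)]
  unknown <- setdiff(refs, cat$name)
  if (length(unknown)) {
    stop("normalization_ref names unknown bands: ",
         paste(unknown, collapse = ", "))
  }
  class(cat) <- c("band_catalog", "data.frame")
  cat
}

#' Load a band catalog
#'
#' With no path, returns the built-in default catalog
#' ([default_band_catalog()]). Otherwise reads a CSV/TSV or YAML file with
#' fields `name`, `assignment`, `center`, `window_halfwidth`, `region_id`,
#' `normalization_ref`.
#'
#' @param path optional catalog file (`.csv`, `.tsv`, `.yml`/`.yaml`).
#' @return A `band_catalog` data frame.
#' @export
load_band_catalog <- function(path = NULL) {
  if (is.null(path)) return(default_band_catalog())
  if (!file.exists(path)) stop("band catalog file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$bands)) y <- y$bands
    cat <- do.call(rbind, lapply(y, function(b) {
      data.frame(
        name = b$name,
        assignment = if (is.null(b$assignment)) "" else b$assignment,
        center = as.numeric(b$center),
        window_halfwidth =
          if (is.null(b$window_halfwidth)) 8 else as.numeric(b$window_halfwidth),
        region_id = b$region_id,
        normalization_ref =
          if (is.null(b$normalization_ref)) NA_character_ else b$normalization_ref,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    cat <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    if (!"normalization_ref" %in% names(cat)) cat$normalization_ref <- NA_character_
    cat$normalization_ref[cat$normalization_ref %in% c("", "NA")] <- NA_character_
  }
  validate_band_catalog(cat)
}

band_def <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("band '", name, "' not in catalog")
  as.list(catalog[i, , drop = FALSE])
}

#' Define an analysis region
#'
#' An analysis region is a wavenumber interval that is baseline-corrected by
#' a straight line through the spectrum's values at two anchor points and,
#' optionally, normalized to a reference band inside it.
#'
#' @param region_id region identifier.
#' @param lo,hi region bounds (cm^-1), `lo < hi`.
#' @param anchor_lo,anchor_hi baseline anchor points inside `[lo, hi]`;
#'   default to the region edges.
#' @param norm_band name of the reference band used by
#'   [normalize_to_band()]; `NA` for none.
#' @return A list of class `analysis_region`.
#' @export
analysis_region <- function(region_id, lo, hi, anchor_lo = lo, anchor_hi = hi,
                            norm_band = NA_character_) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  anchor_lo <- as.numeric(anchor_lo); anchor_hi <- as.numeric(anchor_hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("analysis region needs lo < hi")
  }
  if (anchor_lo < lo || anchor_hi > hi || anchor_lo >= anchor_hi) {
    stop("anchors must satisfy lo <= anchor_lo < anchor_hi <= hi")
  }
  structure(list(region_id = as.character(region_id), lo = lo, hi = hi,
                 anchor_lo = anchor_lo, anchor_hi = anchor_hi,
                 norm_band = as.character(norm_band)),
            class = "analysis_region")
}

#' Default analysis regions
#'
#' Three regions cover the catalog bands: `lipid` (2800-3012 cm^-1, C-H
#' stretching; reference band CH2 asymmetric 2924), `fingerprint`
#' (894-1181 cm^-1, nucleic acid / glycogen / protein window; reference band
#' PO2- symmetric 1082) and `fingerprint_full` (890-1478 cm^-1, extended
#' fingerprint holding the PO2- asymmetric 1234 band). Baseline anchors
#' default to the region edges and are configurable per region.
#'
#' @return Named list of `analysis_region` objects.
#' @export
default_regions <- function() {
  list(
    lipid = analysis_region("lipid", 2800, 3012, norm_band = "ch2_asym"),
    fingerprint = analysis_region("fingerprint", 894, 1181,
                                  norm_band = "po2_sym"),
    fingerprint_full = analysis_region("fingerprint_full", 890, 1478,
                                       norm_band = "po2_sym")
  )
}

#' Load analysis regions from a YAML/CSV config
#'
#' @param path optional file; with no path returns [default_regions()].
#'   YAML files use a top-level `regions:` list with fields `region_id`,
#'   `lo`, `hi`, `anchor_lo`, `anchor_hi`, `norm_band`; CSV files use the
#'   same column names.
#' @return Named list of `analysis_region` objects.
#' @export
load_regions <- function(path = NULL) {
  if (is.null(path)) return(default_regions())
  if (!file.exists(path)) stop("region config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$regions)) y$regions else y
  } else {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (ext == "tsv") "\t" else ",",
                            stringsAsFactors = FALSE)
    split(df, seq_len(nrow(df)))
  }
  regs <- lapply(rows, function(r) {
    analysis_region(
      r$region_id, r$lo, r$hi,
      anchor_lo = if (is.null(r$anchor_lo) || is.na(r$anchor_lo)) r$lo else r$anchor_lo,
      anchor_hi = if (is.null(r$anchor_hi) || is.na(r$anchor_hi)) r$hi else r$anchor_hi,
      norm_band = if (is.null(r$norm_band)) NA_character_ else r$norm_band
    )
  })
  names(regs) <- vapply(regs, function(r) r$region_id, character(1))
  regs
}

region_for_band <- function(regions, band) {
  r <- regions[[band$region_id]]
  if (is.null(r)) stop("band '", band$name, "' references unknown region '",
                       band$region_id, "'")
  r
}
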