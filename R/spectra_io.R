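#' Construct an FTIR spectrum
#'
#' A spectrum is one replicate's absorbance trace on a strictly monotonic
#' wavenumber grid. Input grids may run in either direction (instruments
#' typically emit descending wavenumber); storage is always ascending, and
#' the original direction is kept in the metadata.
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotonic in either direction.
#' @param absorbance numeric vector of unitless absorbance values, same
#'   length as `wavenumbers`, all finite.
#' @param sample_id sample identifier.
#' @param group_label replicate-group label (e.g. "control").
#' @param resolution nominal spectral resolution in cm^-1 (acquisition
#'   metadata; not used in computation).
#' @param n_scans number of co-added scans (acquisition metadata).
#' @return An object of class `ftir_spectrum`: a list with fields
#'   `sample_id`, `group_label`, `wavenumbers` (ascending), `absorbance`,
#'   `resolution`, `n_scans`, `metadata`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, sample_id = "",
                          group_label = "", resolution = NA_real_,
                          n_scans = NA_integer_) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have equal length (",
         length(wavenumbers), " vs ", length(absorbance), ")")
  }
  if (length(wavenumbers) < 2L) stop("a spectrum needs at least 2 points")
  if (!all(is.finite(wavenumbers))) stop("non-finite wavenumber values")
  if (!all(is.finite(absorbance))) stop("non-finite absorbance values")
  d <- diff(wavenumbers)
  if (any(d == 0)) stop("duplicate wavenumbers in spectrum")
  asc <- all(d > 0)
  if (!asc && !all(d < 0)) {
    stop("wavenumbers must be strictly monotonic (ascending or descending)")
  }
  if (!asc) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      group_label = as.character(group_label),
      wavenumbers = wavenumbers,
      absorbance = absorbance,
      resolution = as.numeric(resolution),
      n_scans = as.integer(n_scans),
      metadata = list(original_direction = if (asc) "ascending" else "descending")
    ),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ftir_spectrum> %s [%s]: %d points, %.1f-%.1f cm-1\n",
    x$sample_id, x$group_label, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)
  ))
  invisible(x)
}

#' Group replicicate spectra
#'
#' @param replicates list of `ftir_spectrum` objects (n >= 1).
#' @param label group label; if missing, taken from the replicates, which
#'   must then all agree. Replicates are relabelled to `label`.
#' @return An object of class `ftir_spectrum_group`.
#' @export
spectrum_group <- function(replicates, label = NULL) {
  if (inherits(replicates, "ftir_spectrum")) replicates <- list(replicates)
  if (!is.list(replicates) || length(replicates) < 1L) {
    stop("a spectrum group needs at least one replicate")
  }
  ok <- vapply(replicates, inherits, logical(1), "ftir_spectrum")
  if (!all(ok)) stop("all replicates must be ftir_spectrum objects")
  labs <- vapply(replicates, function(s) s$group_label, character(1))
  if (is.null(label)) {
    u <- unique(labs)
    if (length(u) != 1L) {
      stop("replicates carry different group labels (",
           paste(u, collapse = ", "), "); pass `label` explicitly")
    }
    label <- u
  }
  replicates <- lapply(replicates, function(s) { s$group_label <- label; s })
  structure(list(label = as.character(label), replicates = replicates),
            class = "ftir_spectrum_group")
}

#' @export
print.ftir_spectrum_group <- function(x, ...) {
  cat(sprintf("<ftir_spectrum_group> '%s': n = %d replicates\n",
              x$label, length(x$replicates)))
  invisible(x)
}

split_numeric_line <- function(line) {
  sep <- if (grepl("\t", line)) "\t" else ","
  trimws(strsplit(line, sep, fixed = TRUE)[[1]])
}

#' Read a two-column spectrum CSV
#'
#' Reads a comma- or tab-separated file with columns wavenumber (cm^-1) and
#' absorbance, "." decimal, and an optional single header line
#' (auto-detected by a non-numeric first row). Rows may be listed in either
#' wavenumber direction.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param group_label replicate-group label.
#' @param resolution,n_scans optional acquisition metadata.
#' @return An `ftir_spectrum`.
#' @export
read_spectrum_csv <- function(path, sample_id = NULL, group_label = "",
                              resolution = NA_real_, n_scans = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  first <- suppressWarnings(as.numeric(split_numeric_line(lines[[1]])))
  start <- if (anyNA(first)) 2L else 1L
  if (length(lines) < start) stop("no data rows in ", path)
  w <- numeric(0); a <- numeric(0)
  for (i in seq(start, length(lines))) {
    f <- suppressWarnings(as.numeric(split_numeric_line(lines[[i]])))
    if (length(f) < 2L || anyNA(f[1:2])) {
      stop(sprintf("parse error in %s at line %d: expected two numeric columns, got '%s'",
                   path, lineno[i], lines[[i]]))
    }
    w <- c(w, f[1L]); a <- c(a, f[2L])
  }
  if (anyDuplicated(w)) {
    stop(sprintf("duplicate wavenumber %.6g in %s", w[anyDuplicated(w)], path))
  }
  ftir_spectrum(w, a, sample_id = sample_id, group_label = group_label,
                resolution = resolution, n_scans = n_scans)
}

#' Write a spectrum as two-column CSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces every (wavenumber, absorbance) pair bit-for-bit.
#'
#' @param s an `ftir_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "ftir_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavenumber,absorbance", con)
  writeLines(sprintf("%.17g,%.17g", s$wavenumbers, s$absorbance), con)
  invisible(path)
}

jcamp_labels <- function(lines) {
  idx <- grep("^\\s*##", lines)
  out <- list()
  for (i in idx) {
    m <- regmatches(lines[i], regexec("^\\s*##([^=]*)=(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) {
      key <- toupper(gsub("[ _-]", "", m[2]))
      out[[key]] <- trimws(m[3])
    }
  }
  out
}

# SQZ/DIF/DUP compressed JCAMP ordinates contain letters (outside exponent
# notation) or '@'/'%' pseudo-digits; this package reads only plain AFFN.
assert_affn <- function(lines, path) {
  stripped <- gsub("[0-9]+[eE][+-]?[0-9]+", "", lines)
  if (any(grepl("[A-DF-Za-df-z@%]", stripped))) {
    stop("unsupported JCAMP-DX dialect in ", path,
         ": compressed (SQZ/DIF/DUP) ordinates are not supported; ",
         "only plain AFFN XYDATA=(X++(Y..Y)) and XYPOINTS are read")
  }
}

num_tokens <- function(line, path) {
  toks <- strsplit(trimws(line), "[ \t,;]+")[[1]]
  toks <- toks[nzchar(toks)]
  v <- suppressWarnings(as.numeric(toks))
  if (anyNA(v)) stop("parse error in ", path, ": non-numeric token in '", line, "'")
  v
}

#' Read a JCAMP-DX spectrum
#'
#' Supports the uncompressed (AFFN) `XYDATA=(X++(Y..Y))` and `XYPOINTS`
#' forms with `XUNITS` of 1/CM. `FIRSTX`/`DELTAX` (or
#' `LASTX`/`NPOINTS`), `XFACTOR` and `YFACTOR` are honored. Compressed
#' ordinate dialects (SQZ/DIF/DUP) and non-wavenumber x units raise errors.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the JCAMP `##TITLE` or
#'   the file name.
#' @param group_label replicate-group label.
#' @return An `ftir_spectrum`.
#' @export
read_jcamp <- function(path, sample_id = NULL, group_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lab <- jcamp_labels(lines)
  if (!is.null(lab$XUNITS) &&
      !toupper(lab$XUNITS) %in% c("1/CM", "CM-1", "CM^-1", "WAVENUMBER")) {
    stop("unsupported XUNITS '", lab$XUNITS, "' in ", path,
         ": only wavenumber (1/CM) spectra are supported")
  }
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(lab$TITLE) && nzchar(lab$TITLE)) lab$TITLE
                 else tools::file_path_sans_ext(basename(path))
  }
  xf <- if (is.null(lab$XFACTOR)) 1 else as.numeric(lab$XFACTOR)
  yf <- if (is.null(lab$YFACTOR)) 1 else as.numeric(lab$YFACTOR)

  start_xy <- grep("^\\s*##XYDATA\\s*=", lines)
  start_pts <- grep("^\\s*##XYPOINTS\\s*=", lines)
  end <- grep("^\\s*##", lines)
  block_lines <- function(start) {
    nxt <- end[end > start]
    stopif <- if (length(nxt)) min(nxt) - 1L else length(lines)
    if (stopif < start + 1L) character(0) else lines[(start + 1L):stopif]
  }
  if (length(start_xy)) {
    form <- gsub("\\s", "", sub("^\\s*##XYDATA\\s*=", "", lines[start_xy[1]]))
    if (toupper(form) != "(X++(Y..Y))") {
      stop("unsupported JCAMP-DX XYDATA form '", form, "' in ", path)
    }
    body <- block_lines(start_xy[1])
    assert_affn(body, path)
    dx <- if (!is.null(lab$DELTAX)) {
      as.numeric(lab$DELTAX)
    } else if (!is.null(lab$FIRSTX) && !is.null(lab$LASTX) && !is.null(lab$NPOINTS)) {
      (as.numeric(lab$LASTX) - as.numeric(lab$FIRSTX)) /
        (as.numeric(lab$NPOINTS) - 1)
    } else {
      stop("JCAMP-DX file ", path, " lacks DELTAX and FIRSTX/LASTX/NPOINTS")
    }
    w <- numeric(0); a <- numeric(0)
    for (line in body) {
      v <- num_tokens(line, path)
      if (length(v) < 2L) next
      x0 <- v[1] * xf
      ys <- v[-1] * yf
      w <- c(w, x0 + dx * (seq_along(ys) - 1L))
      a <- c(a, ys)
    }
  } else if (length(start_pts)) {
    body <- block_lines(start_pts[1])
    assert_affn(body, path)
    v <- unlist(lapply(body, num_tokens, path = path))
    if (length(v) %% 2L != 0L) {
      stop("odd number of values in XYPOINTS block of ", path)
    }
    w <- v[seq(1, length(v), by = 2)] * xf
    a <- v[seq(2, length(v), by = 2)] * yf
  } else {
    stop("no XYDATA or XYPOINTS block found in ", path)
  }
  res <- if (!is.null(lab$RESOLUTION)) as.numeric(lab$RESOLUTION) else NA_real_
  ftir_spectrum(w, a, sample_id = sample_id, group_label = group_label,
                resolution = res)
}

#' Read every spectrum file in a directory as one replicate group
#'
#' Reads all `.csv`, `.jdx` and `.dx` files in `dir` (CSV via
#' [read_spectrum_csv()], JCAMP via [read_jcamp()]).
#'
#' @param dir directory holding one spectrum file per replicate.
#' @param label group label applied to all replicates.
#' @return An `ftir_spectrum_group`.
#' @export
read_spectrum_dir <- function(dir, label) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.(csv|jdx|dx)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no spectrum files (.csv/.jdx/.dx) found in directory: ", dir)
  }
  reps <- lapply(sort(files), function(f) {
    if (grepl("\\.csv$", f, ignore.case = TRUE)) {
      read_spectrum_csv(f, group_label = label)
    } else {
      read_jcamp(f, group_label = label)
    }
  })
  spectrum_group(reps, label = label)
}
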