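#' Pseudo-Voigt profile (unit apex)
#'
#' `eta * Lorentzian + (1 - eta) * Gaussian`, both with the same center and
#' full width at half maximum, the standard condensed-phase band-shape
#' model.
#'
#' @param x wavenumbers (cm^-1).
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param eta Lorentzian mixing fraction in `[0, 1]`.
#' @return Profile values with apex 1 at `center`.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta = 0.3) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  eta * l + (1 - eta) * g
}

default_fwhm <- function(centers) {
  # C-H stretch bands are narrower than fingerprint bands in cell spectra;
  # the crowded 1100-1180 cm-1 cluster (RNA 1121, glycogen 1156, protein
  # C-O 1171, separated by as little as 15 cm-1) must be narrower still to
  # present distinct apexes, as the corresponding shoulders in measured
  # cell spectra do
  ifelse(centers >= 2000, 15, ifelse(centers >= 1100 & centers <= 1180, 12, 20))
}

#' Define a synthetic spectrum model
#'
#' A sum of pseudo-Voigt bands plus a polynomial baseline (degree <= 2)
#' plus additive Gaussian noise, on the instrument grid. Identical seed and
#' parameters give an identical spectrum.
#'
#' @param amplitudes named numeric vector of band apex amplitudes
#'   (absorbance, >= 0); names must be catalog band names unless `centers`
#'   is supplied for all of them.
#' @param centers named numeric vector of band centers; defaults to the
#'   catalog centers for the named bands.
#' @param fwhm named numeric vector (or scalar) of band FWHMs (cm^-1);
#'   default 15 for C-H stretch bands (>= 2000 cm^-1), 20 in the
#'   fingerprint.
#' @param eta pseudo-Voigt Lorentzian fraction (default 0.3).
#' @param baseline polynomial coefficients `c(b0, b1, b2)` evaluated as
#'   `b0 + b1*w + b2*w^2`.
#' @param noise_sd additive Gaussian noise SD (absorbance).
#' @param grid wavenumber grid; default 450-4000 cm^-1 at 4 cm^-1.
#' @param seed integer seed used when the model is simulated.
#' @param catalog catalog used to resolve default centers.
#' @return A list of class `spectrum_model`.
#' @export
spectrum_model <- function(amplitudes, centers = NULL, fwhm = NULL,
                           eta = 0.3, baseline = c(0, 0, 0), noise_sd = 0,
                           grid = seq(450, 4000, by = 4), seed = 1L,
                           catalog = default_band_catalog()) {
  if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes)))) {
    stop("amplitudes must be a named vector of band amplitudes")
  }
  if (any(amplitudes < 0)) stop("band amplitudes must be >= 0")
  bands <- names(amplitudes)
  cen <- stats::setNames(catalog$center[match(bands, catalog$name)], bands)
  if (!is.null(centers)) cen[names(centers)] <- centers
  if (anyNA(cen)) {
    stop("no center known for band(s): ",
         paste(bands[is.na(cen)], collapse = ", "),
         " (not in catalog; pass `centers`)")
  }
  fw <- stats::setNames(default_fwhm(cen), bands)
  if (!is.null(fwhm)) {
    if (is.null(names(fwhm)) && length(fwhm) == 1L) fw[] <- fwhm
    else fw[names(fwhm)] <- fwhm
  }
  if (any(fw <= 0)) stop("band FWHM must be > 0")
  baseline <- c(baseline, 0, 0, 0)[1:3]
  structure(
    list(amplitudes = amplitudes, centers = cen, fwhm = fw, eta = eta,
         baseline = baseline, noise_sd = noise_sd, grid = as.numeric(grid),
         seed = as.integer(seed)),
    class = "spectrum_model")
}

model_shapes <- function(model) {
  vapply(names(model$amplitudes), function(b) {
    pseudo_voigt(model$grid, model$centers[[b]], model$fwhm[[b]], model$eta)
  }, numeric(length(model$grid)))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate one spectrum from a model
#'
#' @param model a `spectrum_model`.
#' @param seed overrides the model's seed for the noise draw.
#' @param sample_id,group_label identity carried on the output spectrum.
#' @return An `ftir_spectrum`, deterministic per seed and parameters.
#' @export
simulate_spectrum <- function(model, seed = model$seed, sample_id = "sim",
                              group_label = "") {
  stopifnot(inherits(model, "spectrum_model"))
  w <- model$grid
  trace <- as.numeric(model_shapes(model) %*% model$amplitudes)
  b <- model$baseline
  trace <- trace + b[1] + b[2] * w + b[3] * w^2
  if (model$noise_sd > 0) {
    trace <- trace + with_seed(seed, stats::rnorm(length(w), 0, model$noise_sd))
  }
  ftir_spectrum(w, trace, sample_id = sample_id, group_label = group_label,
                resolution = stats::median(diff(w)), n_scans = 20L)
}

#' Define a group effect for paired simulation
#'
#' @param multipliers named numeric vector of multiplicative factors (> 0)
#'   applied to the treated group's band amplitudes; bands not named keep
#'   factor 1.
#' @param replicate_cv relative SD of per-replicate, per-band amplitude
#'   jitter (applies to both groups).
#' @param center_shift optional named vector of additive band-center shifts
#'   (cm^-1) applied to the treated group, for planting band-position
#'   changes.
#' @return A list of class `group_effect`.
#' @export
group_effect <- function(multipliers = numeric(0), replicate_cv = 0,
                         center_shift = numeric(0)) {
  if (length(multipliers) && (is.null(names(multipliers)) ||
                              any(multipliers <= 0))) {
    stop("multipliers must be a named vector of positive factors")
  }
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  structure(list(multipliers = multipliers,
                 replicate_cv = replicate_cv,
                 center_shift = center_shift),
            class = "group_effect")
}

simulate_replicate <- function(model, rep_seed, sample_id, group_label, cv) {
  with_seed(rep_seed, {
    amps <- model$amplitudes
    if (cv > 0) {
      amps <- pmax(amps * (1 + stats::rnorm(length(amps), 0, cv)), 0)
    }
    m2 <- model
    m2$amplitudes <- amps
    m2$noise_sd <- 0
    s <- simulate_spectrum(m2, sample_id = sample_id,
                           group_label = group_label)
    if (model$noise_sd > 0) {
      s$absorbance <- s$absorbance +
        stats::rnorm(length(s$absorbance), 0, model$noise_sd)
    }
    attr(s, "planted_amplitudes") <- amps
    s
  })
}

#' Simulate a control/treated pair of replicate groups
#'
#' Control replicates draw per-band amplitude jitter (CV
#' `effect$replicate_cv`) around the base model; treated replicates apply
#' the effect multipliers (and any center shifts) first. Per-replicate
#' seeds are derived from `seed` by fixed increments, so the pair is fully
#' reproducible.
#'
#' @param base a `spectrum_model` for the control condition.
#' @param effect a `group_effect`.
#' @param n_per_group replicates per group (default 3, the usual design).
#' @param seed integer seed.
#' @param labels group labels, `c(control, treated)`.
#' @return List with `control` and `treated` `ftir_spectrum_group`s.
#' @export
simulate_group_pair <- function(base, effect, n_per_group = 3, seed = 1L,
                                labels = c("control", "treated")) {
  stopifnot(inherits(base, "spectrum_model"), inherits(effect, "group_effect"))
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  treated_model <- base
  if (length(effect$multipliers)) {
    unknown <- setdiff(names(effect$multipliers), names(base$amplitudes))
    if (length(unknown)) stop("effect multipliers name unknown bands: ",
                              paste(unknown, collapse = ", "))
    treated_model$amplitudes[names(effect$multipliers)] <-
      treated_model$amplitudes[names(effect$multipliers)] * effect$multipliers
  }
  if (length(effect$center_shift)) {
    unknown <- setdiff(names(effect$center_shift), names(base$centers))
    if (length(unknown)) stop("center shifts name unknown bands: ",
                              paste(unknown, collapse = ", "))
    treated_model$centers[names(effect$center_shift)] <-
      treated_model$centers[names(effect$center_shift)] +
      effect$center_shift
  }
  cv <- effect$replicate_cv
  ctrl <- lapply(seq_len(n_per_group), function(i) {
    simulate_replicate(base, seed + i, sprintf("%s_rep%d", labels[1], i),
                       labels[1], cv)
  })
  trt <- lapply(seq_len(n_per_group), function(i) {
    simulate_replicate(treated_model, seed + 1000L + i,
                       sprintf("%s_rep%d", labels[2], i), labels[2], cv)
  })
  list(control = spectrum_group(ctrl, labels[1]),
       treated = spectrum_group(trt, labels[2]))
}

#' Simulate a pair of DE result tables with planted overlap structure
#'
#' Gene memberships (significant sets, shared set, parallel up/down and
#' discordant subsets) are assigned by seeded sampling so that
#' [concordance()] on the output recovers the planted counts exactly.
#'
#' @param n_genes total genes per table.
#' @param n_sig_1,n_sig_2 significant genes (padj < 0.05) in each table.
#' @param n_shared significant genes shared between the tables
#'   (`<= min(n_sig_1, n_sig_2)`; also `n_genes >= n_sig_1 + n_sig_2 -
#'   n_shared`).
#' @param n_parallel_up,n_parallel_down shared genes upregulated
#'   (both log2fc > 0) / downregulated in both tables;
#'   `n_parallel_up + n_parallel_down <= n_shared`, remaining shared genes
#'   get discordant signs.
#' @param effect_sd SD of the log2 fold-change magnitudes (default 1).
#' @param seed integer seed.
#' @return List of two `deg_table`s (`t1`, `t2`) with a `planted` attribute
#'   recording the design.
#' @export
simulate_deg_pair <- function(n_genes, n_sig_1, n_sig_2, n_shared,
                              n_parallel_up, n_parallel_down,
                              effect_sd = 1, seed = 1L) {
  if (n_parallel_up + n_parallel_down > n_shared) {
    stop("n_parallel_up + n_parallel_down must be <= n_shared")
  }
  if (n_shared > min(n_sig_1, n_sig_2)) {
    stop("n_shared must be <= min(n_sig_1, n_sig_2)")
  }
  if (max(n_sig_1, n_sig_2) > n_genes ||
      n_sig_1 + n_sig_2 - n_shared > n_genes) {
    stop("n_genes too small for the requested significant sets")
  }
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    sig1 <- sample(genes, n_sig_1)
    shared <- if (n_shared > 0) sample(sig1, n_shared) else character(0)
    pool2 <- setdiff(genes, sig1)
    sig2 <- c(shared, if (n_sig_2 > n_shared)
      sample(pool2, n_sig_2 - n_shared) else character(0))

    up <- utils::head(shared, n_parallel_up)
    down <- shared[seq_len(n_parallel_down) + n_parallel_up]
    disc <- setdiff(shared, c(up, down))

    mag <- function(n) abs(stats::rnorm(n, 0, effect_sd)) + 0.1
    lfc1 <- stats::setNames(stats::rnorm(n_genes, 0, 0.2), genes)
    only1 <- setdiff(sig1, shared)
    lfc1[only1] <- sample(c(-1, 1), length(only1), TRUE) * mag(length(only1))
    lfc1[up] <- mag(length(up))
    lfc1[down] <- -mag(length(down))
    lfc1[disc] <- sample(c(-1, 1), length(disc), TRUE) * mag(length(disc))

    lfc2 <- stats::setNames(stats::rnorm(n_genes, 0, 0.2), genes)
    only2 <- setdiff(sig2, shared)
    lfc2[only2] <- sample(c(-1, 1), length(only2), TRUE) * mag(length(only2))
    # shared parallel genes: correlated magnitude, planted sign
    corr_mag <- function(ref) pmax(abs(ref) + stats::rnorm(length(ref),
                                                           0, effect_sd / 2),
                                   0.1)
    lfc2[up] <- corr_mag(lfc1[up])
    lfc2[down] <- -corr_mag(lfc1[down])
    lfc2[disc] <- -sign(lfc1[disc]) * mag(length(disc))

    padj_for <- function(sig) {
      p <- stats::runif(n_genes, 0.05, 1)
      p[match(sig, genes)] <- stats::runif(length(sig), 1e-8, 0.0499)
      p
    }
    t1 <- deg_table(data.frame(gene_id = genes, log2fc = unname(lfc1),
                               padj = padj_for(sig1),
                               stringsAsFactors = FALSE), label = "condition1")
    t2 <- deg_table(data.frame(gene_id = genes, log2fc = unname(lfc2),
                               padj = padj_for(sig2),
                               stringsAsFactors = FALSE), label = "condition2")
    out <- list(t1 = t1, t2 = t2)
    attr(out, "planted") <- list(
      n_genes = n_genes, n_sig_1 = n_sig_1, n_sig_2 = n_sig_2,
      n_shared = n_shared, n_parallel_up = n_parallel_up,
      n_parallel_down = n_parallel_down,
      sig1 = sort(sig1), sig2 = sort(sig2), shared = sort(shared),
      up = sort(up), down = sort(down), discordant = sort(disc))
    out
  })
}
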