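# Shared fixtures and independent oracles used across the suite.

# grid that contains the common catalog centers exactly (multiples of 4)
lipid_grid <- seq(2800, 3012, by = 4)
finger_grid <- seq(890, 1478, by = 4)

# Brute-force Mann-Whitney oracle: U by pair counting (not rank sums), and
# the two-sided permutation p by explicit relabeling of the data values.
mw_oracle_p <- function(x, y) {
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# textbook Pearson correlation evaluated by an explicit loop
pearson_loop <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# single pseudo-Voigt band as a raw spectrum on a chosen grid
one_band_spectrum <- function(center, amplitude = 1, fwhm = 15, eta = 0.3,
                              grid = lipid_grid, baseline = c(0, 0, 0),
                              sample_id = "fix", group_label = "g") {
  y <- amplitude * pseudo_voigt(grid, center, fwhm, eta) +
    baseline[1] + baseline[2] * grid +
    (if (length(baseline) > 2) baseline[3] * grid^2 else 0)
  ftir_spectrum(grid, y, sample_id = sample_id, group_label = group_label)
}

lipid_region <- function() default_regions()$lipid

# small DE table builder
toy_deg <- function(ids, lfc, padj, label = "toy") {
  deg_table(data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                       stringsAsFactors = FALSE), label = label)
}
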