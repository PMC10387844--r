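---
title: "Macromolecular profiling of cell FTIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macromolecular profiling of cell FTIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirquant)
```

# The measurement model

FTIR absorbance spectra of lyophilized cultured cells carry quantitative
information about the cell's macromolecular pools in the intensities and
positions of a small set of diagnostic vibrational bands. `ftirquant`
implements the standard quantification chain used in cell biospectroscopy:

1. **Region baselining.** Each analysis region is corrected by subtracting
   the straight line through the spectrum's values at two anchor points
   (obtained by linear interpolation onto the anchors). This removes
   slowly-varying scattering/offset background exactly when that background
   is affine over the region, and every downstream ratio metric is by
   construction invariant to adding `a + b*wavenumber` to the raw input.
2. **Reference-band normalization.** Where intensities are compared across
   samples (fingerprint-region bands, olefinic band), the baselined trace
   is expressed relative to a reference band measured in the same region:
   the CH2 asymmetric stretch (2924 cm^-1) for the lipid region, the PO2-
   symmetric stretch (1082 cm^-1) for the fingerprint. Ratios of intensities
   within a region are normalization-free, so the lipid-to-protein and
   chain-length indices are computed on baselined-only traces.
3. **Apex measurement.** A band's intensity is the apex height of the
   baselined trace inside the band's search window (center +/- 8 cm^-1 by
   default), and its position is refined below the sampling interval by the
   parabola through the discrete maximum and its two neighbors. Intensity is
   apex height, not integrated area, matching how these indices are
   conventionally reported (values of order 0.01 absorbance and ratios
   thereof).
4. **Indices and group contrasts.** Metrics are computed per replicate;
   group results are reported as mean +/- sample SD (n - 1) with a percent
   change of group means, `100 * (treated - control) / control`, and a
   two-sided p-value. The averaged group spectrum is produced only for
   display and export — replicate-wise measurement is what supports SDs and
   rank tests.

The nine built-in metrics are: the lipid-to-protein ratio
I(2852)/I(2872) (CH2/CH3 symmetric stretch), the acyl chain-length index
I(2924)/I(2958) (CH2/CH3 asymmetric), the olefinic (=CH, 3006 cm^-1)
lipid-unsaturation/peroxidation index on the CH2-asym-normalized trace, the
PO2-sym-normalized glycogen (996, 1156), protein C-O (1171) and RNA (1121)
intensities, and the sub-resolution positions of the two phosphate bands
(1082, 1234 cm^-1), whose group contrast is a band shift in cm^-1.

# Analysis regions, anchors and windows

| region | bounds (cm^-1) | anchors | reference band |
|---|---|---|---|
| lipid | 2800–3012 | region edges | CH2 asym 2924 |
| fingerprint | 894–1181 | region edges | PO2 sym 1082 |
| fingerprint_full | 890–1478 | region edges | PO2 sym 1082 |

Acquisition software typically lets the operator place the two baseline
anchors by hand; since "two arbitrarily selected points" is not
reproducible, the anchors default to the region edges and are configurable
per region (`analysis_region()`, YAML config). The `fingerprint_full`
region exists because the PO2 asymmetric band (1234 cm^-1) lies outside
the 894–1181 display window used for normalized fingerprint intensities.

The default search half-width of 8 cm^-1 (two grid steps at the 4 cm^-1
instrument resolution) is wide enough to track the observed phosphate-band
shifts (about 1–2 cm^-1) and narrow enough not to capture the neighboring
band 15 cm^-1 away (1156 vs 1171). A window may overrun a region edge (the
olefinic window 2998–3014 against the 3012 bound); it is then clipped to
the available trace, and a measurement whose discrete maximum sits on a
window edge carries an `edge` flag and skips refinement.

Sub-resolution positions at 4 cm^-1 spacing necessarily involve
interpolation; vendor software does this opaquely. Here the documented
choice is three-point parabolic refinement, whose worst-case error for
noiseless pseudo-Voigt bands of realistic width (FWHM 15–20 cm^-1) is
about 0.1 cm^-1 on this grid — well below both the grid spacing and the
shifts of interest. Ties in the discrete argmax resolve to the candidate
closest to the nominal center, then to the lower wavenumber, making the
measurement deterministic.

# Group statistics

Replicate groups (typically n = 3) are compared with the Mann–Whitney U
test. For tie-free data with at most 12 observations in total the
two-sided p is exact, by full enumeration of all `choose(n1+n2, n1)`
labelings: `p = P(|U - n1 n2/2| >= |u - n1 n2/2|)` under the permutation
null. With ties, or larger samples, midranks with a tie-corrected normal
approximation and continuity correction are used and flagged. Note the
smallest attainable exact two-sided p at n = 3 vs 3 is 0.1; published
sub-0.05 p-values at that sample size can only arise from an approximate
variant, and `mann_whitney_u()` exposes both so the discrepancy is visible
rather than hidden.

The unpaired t-test defaults to the pooled-variance Student form, which is
the classical "unpaired t-test" and holds its nominal size exactly for
normal equal-variance data even at n = 3 per group; the Welch form
(`var_equal = FALSE`) is available but is measurably conservative at such
small equal sizes (simulated size about 0.034 at nominal 0.05), so it is
not the default. Degenerate inputs are handled explicitly: two
zero-variance samples give p = 1 when means agree and p = 0 with a
`degenerate` flag when they do not.

# Differential-expression concordance

`concordance()` reproduces the cross-condition DE comparison procedure:
filter both result tables at a strict `padj < alpha` (records with missing
`padj` are excluded), intersect on exact `gene_id` (no alias resolution —
both tables are expected to share an annotation), count shared genes and
direction-parallel genes (same `log2fc` sign; zero fold changes excluded),
and report the Pearson correlation of the shared genes' log2 fold changes.
Fewer than 3 shared genes leaves the correlation missing with a reason
rather than a spurious value. The procedure is symmetric in its two inputs
for all shared/parallel counts and for r.

# The synthetic generator

Because the deposited datasets and raw spectra are not desk-reproducible,
every stage is exercised on synthetic data with *planted, recoverable
structure*:

* **Spectra** are sums of pseudo-Voigt bands (Lorentzian fraction
  `eta = 0.3`) plus a polynomial baseline (degree <= 2) and additive
  Gaussian noise on the 450–4000 cm^-1, 4 cm^-1 instrument grid. Band
  widths default to FWHM 15 cm^-1 for the C-H stretch region and 20 cm^-1
  in the fingerprint, except the crowded 1100–1180 cm^-1 cluster (RNA 1121,
  glycogen 1156, protein C-O 1171, separated by as little as 15 cm^-1)
  which uses 12 cm^-1: at 20 cm^-1 those bands merge into a single hump
  with no distinct apexes, which contradicts both the measured appearance
  of cell spectra (resolved shoulders) and the premise of apex-based
  quantification.
* **Calibration.** Band tails overlap and reach the baseline anchors, so a
  band's *measured* apex is not exactly its amplitude.
  `calibrate_amplitudes()` therefore fixes amplitudes by fixed-point
  iteration until the measured intensities (through the full
  baseline/measure pipeline) equal the requested targets to 1e-11. The four
  study presets (`hela-control`, `hela-cisplatin`, `hela-kd-control`,
  `hela-kd`) are calibrated so the noiseless pipeline reproduces the
  published group means exactly: control lipid-to-protein ratio 1.0769,
  chain-length 1.48, normalized olefinic 0.01283, and so on, with the two
  studies keeping their separately published control values. Quantities the
  publication leaves unstated are fixed once as representative design
  choices: absolute scales (CH2 asym apex 0.8, PO2 sym apex 0.5, PO2 asym
  apex 0.45 absorbance), the fingerprint base intensities (RNA 0.55,
  glycogen 0.30/0.40, protein C-O 0.35 of the PO2 sym apex), a 15%
  glycogen-1156 decrease (reported qualitatively), and a 90% loss of the
  996 band in the knockdown ("almost vanished"; the apex floor contributed
  by neighboring band tails makes a smaller measured value unattainable).
* **Replicate variability** is multiplicative per-band amplitude jitter
  with CV 0.04 by default — consistent with the published SDs of the ratio
  indices (about 5% of the mean) — plus spectral noise of SD 1e-3
  absorbance, a realistic detector floor. Per-replicate seeds derive from
  one seed by fixed increments, so all simulations are bit-reproducible.
* **DE tables** are generated backwards from the planned set sizes:
  significant sets, their overlap, and the parallel up/down subsets are
  sampled memberships, so `concordance()` must recover the plan exactly
  (the generator is its own oracle). Fold-change magnitudes for parallel
  genes are correlated between the tables; discordant shared genes get
  opposite signs.

What the generator deliberately does **not** emulate: water-vapor and CO2
interference fringes, Mie scattering and ATR distortions, detector drift,
instrument apodization, and band-shape asymmetry. Passing tests therefore
demonstrate correctness of the quantification chain on well-formed
absorbance spectra, not robustness to every acquisition artifact; real
data should be inspected for those artifacts before this pipeline is
applied.

# Numerical and reporting choices

* Internal storage is ascending wavenumber; instrument-order (descending)
  input is accepted and recorded. CSV round trips are bit-exact (17
  significant digits).
* The two published mentions of the PO2 symmetric band (1082 and
  1083 cm^-1) are reconciled as a single catalog center 1082 with the
  8 cm^-1 window covering both.
* The CH2/CH3 symmetric and asymmetric centers are fixed at
  2852/2872/2924/2958 cm^-1 — the standard assignments for these modes.
* Percent changes are computed from group means (not the mean of
  per-replicate changes), reproducing the published arithmetic, e.g.
  `(1.3018 - 1.0769)/1.0769 = +20.9%`. Report writers round percent
  changes to 3 significant figures and means/SDs to 4 decimals. Some
  published percentages are internally inconsistent with their own printed
  means (76.6% vs the computed 76.5% for 0.03181 -> 0.00747; 14.39% vs the
  computed 14.26% for 1.48 -> 1.6910; a 3.42% vs 6.5% chain-length change
  in different places). This package always reports the arithmetic of the
  means and leaves the discrepancy visible.
* Normalization refuses non-positive reference intensities (degenerate or
  noise-only spectra) instead of silently flipping signs; percent change
  is undefined for a zero control mean.

# Problem sizes used by the simulation-based checks

The test suite establishes its stochastic claims at sizes chosen to make
the Monte-Carlo error negligible relative to the tolerance being checked:
1000 seeded repetitions for the percent-change sampling envelope at the
study conditions (n = 3, CV 0.04, noise 1e-3); 5000 replicates for the
t-test null size against a 99% binomial interval; 200 random instances for
the exact-test/enumeration equivalence; and 100 planted centers for the
sub-resolution position sweep.

# Known limitations

* Apex-based quantification assumes resolvable band maxima; strongly
  overlapped bands would need deconvolution, which is out of scope, as are
  second-derivative band finding, bandwidth estimation, and protein
  secondary-structure (amide) analysis.
* Only linear two-point baselines and band-reference normalization are
  offered — the variants the quantification chain is defined around —
  not rubber-band/ALS baselines or vector/SNV normalization.
* JCAMP-DX support covers the plain AFFN `XYPOINTS` and
  `(X++(Y..Y))` forms; compressed dialects and vendor binary formats are
  rejected explicitly.
* The DE concordance operates on result tables; it does not re-run any
  read-level RNA-seq processing, and dataset-level published counts
  (e.g. 185/256 shared metabolic genes, r = 0.72) depend on the deposited
  data and are reproduced here only at the level of the procedure on
  synthetic tables planted at the same scale.

# A worked example

```{r example, eval = FALSE}
pair <- simulate_study_pair("cisplatin", seed = 1,
                            replicate_cv = 0, noise_sd = 0)
report <- compare_all(pair$control, pair$treated)
report$table[, c("metric", "control_mean", "treated_mean",
                 "percent_change", "p_value")]
```

With the noiseless calibrated presets this prints the published group
contrasts (+20.9% lipid-to-protein, -6.57% olefinic, -7.03% glycogen 996,
+31.29% protein C-O, +1.27 cm^-1 PO2 asym shift); with
`replicate_cv = 0.04, noise_sd = 1e-3` it shows the replicate scatter and
rank-test p-values of a realistic n = 3 experiment.
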