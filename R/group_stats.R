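#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' Computes the U statistic from midrank sums and a two-sided p-value.
#' For tie-free data with `n1 + n2 <= exact_threshold` the exact p is
#' obtained by full enumeration of all `choose(n1 + n2, n1)` group
#' labelings: `p = P(|U - n1*n2/2| >= |u - n1*n2/2|)` under the permutation
#' null. Otherwise (ties, or larger samples) a normal approximation with
#' tie-corrected variance and continuity correction is used and flagged.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"` (exact when admissible), `"exact"` (error if ties
#'   or too large), or `"normal"`.
#' @param exact_threshold largest `n1 + n2` for which enumeration is used
#'   in `"auto"`/`"exact"` mode (default 12, covering the usual n = 3 vs 3
#'   replicate design with trivial cost).
#' @return A list of class `ftir_test_result` with `test`, `statistic`
#'   (U of `x`), `p_two_sided`, `n1`, `n2`, `ties` and `exact` flags.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           exact_threshold = 12L) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)               # midranks on ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  mu <- n1 * n2 / 2

  want_exact <- switch(mode,
                       auto = !ties && n <= exact_threshold,
                       exact = TRUE,
                       normal = FALSE)
  if (mode == "exact") {
    if (ties) stop("exact Mann-Whitney p is defined here for tie-free data; ",
                   "use mode = 'auto' (midranks + normal approximation)")
    if (n > exact_threshold) stop("n1 + n2 = ", n, " exceeds exact_threshold ",
                                  exact_threshold)
  }

  if (want_exact) {
    # tie-free: ranks are a permutation of 1..n; enumerate labelings
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    exact <- TRUE
  } else {
    tt <- table(pooled)
    tiesum <- sum(tt^3 - tt)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    exact <- FALSE
  }
  structure(
    list(test = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
         statistic = u, p_two_sided = p, n1 = n1, n2 = n2,
         ties = ties, exact = exact),
    class = "ftir_test_result")
}

#' Unpaired two-sample t-test
#'
#' The classical unpaired t-test on two replicate groups. By default the
#' pooled-variance Student form is used (`var_equal = TRUE`), which holds
#' its nominal size exactly for normal equal-variance data even at n = 3
#' per group; `var_equal = FALSE` gives the Welch form
#' (Welch-Satterthwaite df). Degenerate zero-variance inputs are handled
#' explicitly: equal means give p = 1, unequal means give p = 0 with a
#' `degenerate` flag.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param var_equal use the pooled-variance Student test (default) or the
#'   Welch test.
#' @return An `ftir_test_result` with `test`, `statistic` (t),
#'   `p_two_sided`, `df`, `n1`, `n2`, `degenerate` flag.
#' @export
t_test_unpaired <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("t-test needs at least 2 values per group")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(structure(
      list(test = if (var_equal) "t_unpaired" else "t_welch",
           statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
           p_two_sided = if (eq) 1 else 0,
           df = NA_real_, n1 = length(x), n2 = length(y),
           degenerate = TRUE),
      class = "ftir_test_result"))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(
    list(test = if (var_equal) "t_unpaired" else "t_welch",
         statistic = unname(tt$statistic), p_two_sided = tt$p.value,
         df = unname(tt$parameter), n1 = length(x), n2 = length(y),
         degenerate = FALSE),
    class = "ftir_test_result")
}

#' @export
print.ftir_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test, x$statistic, x$p_two_sided, x$n1, x$n2))
  invisible(x)
}

#' Mean, sample SD and n of a replicate sample
#'
#' @param x numeric sample.
#' @return List with `mean`, `sd` (n-1 denominator; `NA` with
#'   `sd_undefined = TRUE` for a single value) and `n`.
#' @export
summarize_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("empty sample")
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
       n = length(x),
       sd_undefined = length(x) < 2L)
}
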