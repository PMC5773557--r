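#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(input copies) over a dilution series.
#' The amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (a perfectly efficient reaction doubles product every
#' cycle, slope -1/log10(2) = -3.3219, efficiency 1).
#'
#' @param copies Input copy numbers (> 0), >= 3 distinct dilution levels.
#' @param ct Observed Ct values, same length.
#' @return A `standard_curve` list: `slope` (Ct per log10 copies),
#'   `intercept` (Ct at one copy), `r_squared`, `efficiency`.
#' @export
#' @examples
#' sc <- fit_standard_curve(10^(9:3), 40 - 3.3219 * (9:3))
#' sc$efficiency  # 1
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct)) stop("copies and ct lengths differ")
  if (any(copies <= 0)) stop("copies must be > 0")
  lc <- log10(copies)
  if (length(unique(lc)) < 3) {
    stop("need >= 3 distinct dilution levels")
  }
  fit <- stats::lm(ct ~ lc)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  out <- list(slope = slope, intercept = intercept, r_squared = r2,
              efficiency = 10^(-1 / slope) - 1)
  class(out) <- "standard_curve"
  out
}

#' Absolute copy number per cell from a standard curve
#'
#' Inverts the standard curve at the sample Ct:
#' `copies_total = 10^((Ct - intercept) / slope) * dilution_factor`, divided
#' by the number of cells in the assayed sample.
#'
#' @param ct Sample Ct (scalar or vector; a vector, e.g. triplicates, is
#'   averaged before inversion).
#' @param curve A `standard_curve`.
#' @param n_cells Number of cells the cDNA derives from (>= 1).
#' @param dilution_factor Fold dilution between the quantified cDNA and the
#'   measured well (default 1).
#' @return Estimated copies per cell.
#' @export
copies_per_cell <- function(ct, curve, n_cells, dilution_factor = 1) {
  if (curve$slope >= 0) stop("standard curve slope must be negative")
  if (n_cells < 1) stop("n_cells must be >= 1")
  ct <- mean(ct)
  copies_total <- 10^((ct - curve$intercept) / curve$slope) * dilution_factor
  copies_total / n_cells
}

#' FISH proximity fraction
#'
#' Fraction of cells whose two probe centroids are closer than the
#' threshold (strictly; completely overlapped signals have distance 0 and
#' count as proximal, a centroid distance exactly at the threshold does
#' not), with an exact 95% binomial confidence interval.
#'
#' @param pairs Data frame with micron coordinates `x1`, `y1`, `x2`, `y2`
#'   (one row per cell).
#' @param threshold_um Distance threshold in microns (default 1.0).
#' @return List `fraction`, `n_proximal`, `n_cells`, `ci_lower`, `ci_upper`.
#' @export
proximity_fraction <- function(pairs, threshold_um = 1.0) {
  if (nrow(pairs) == 0) stop("need at least one spot pair")
  d <- sqrt((pairs$x1 - pairs$x2)^2 + (pairs$y1 - pairs$y2)^2)
  k <- sum(d < threshold_um)
  ci <- stats::binom.test(k, nrow(pairs))$conf.int
  list(fraction = k / nrow(pairs), n_proximal = k, n_cells = nrow(pairs),
       ci_lower = ci[1], ci_upper = ci[2])
}

#' Two-sample t-test power
#'
#' Power of the two-sample t test to detect a standardized effect size `d`
#' with `n` subjects per group. The default method uses the noncentral t
#' distribution (df = 2n - 2, noncentrality d * sqrt(n / 2)), exact under
#' the normal model; the normal approximation replaces the t by a Gaussian;
#' the Monte Carlo method simulates normal experiments and reports the
#' rejection rate.
#'
#' @param n_per_group Group size (>= 2).
#' @param effect_size Standardized difference d (>= 0).
#' @param alpha Significance level in (0, 1).
#' @param sides 1 or 2 (default 2).
#' @param method `"noncentral_t"`, `"normal_approx"` or `"montecarlo"`.
#' @param nsim Monte Carlo replicates (default 1e5).
#' @param seed Seed for the Monte Carlo method.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' ttest_power(5, 2)  # about 0.79
ttest_power <- function(n_per_group, effect_size, alpha = 0.05, sides = 2,
                        method = c("noncentral_t", "normal_approx",
                                   "montecarlo"),
                        nsim = 1e5, seed = 1L) {
  method <- match.arg(method)
  n <- n_per_group
  if (n < 2) stop("n_per_group must be >= 2")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!sides %in% c(1, 2)) stop("sides must be 1 or 2")
  df <- 2 * n - 2
  ncp <- effect_size * sqrt(n / 2)
  if (method == "noncentral_t") {
    tc <- qt(1 - alpha / sides, df)
    pw <- pt(tc, df, ncp = ncp, lower.tail = FALSE)
    if (sides == 2) pw <- pw + pt(-tc, df, ncp = ncp)
    return(pw)
  }
  if (method == "normal_approx") {
    z <- qnorm(1 - alpha / sides)
    pw <- pnorm(ncp - z)
    if (sides == 2) pw <- pw + pnorm(-z - ncp)
    return(pw)
  }
  with_seed(seed, {
    x <- matrix(rnorm(nsim * n, mean = effect_size), nsim, n)
    y <- matrix(rnorm(nsim * n), nsim, n)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (n - 1)
    vy <- rowSums((y - my)^2) / (n - 1)
    tstat <- (mx - my) / sqrt((vx + vy) / n)
    tc <- qt(1 - alpha / sides, df)
    if (sides == 2) mean(abs(tstat) > tc) else mean(tstat > tc)
  })
}

#' Parallel-plate flow-chamber shear stress
#'
#' `tau = 6 * eta * Q / (h^2 * w)` for a chamber of height `h` and width `w`
#' perfused at flow rate `Q` with a medium of viscosity `eta` (cgs units:
#' dyn s cm^-2, cm^3 s^-1, cm; tau in dyn cm^-2).
#'
#' @param eta Viscosity. @param Q Flow rate. @param h Channel height.
#' @param w Channel width. All strictly positive.
#' @return Wall shear stress tau.
#' @export
shear_stress <- function(eta, Q, h, w) {
  if (any(c(eta, Q, h, w) <= 0)) stop("all inputs must be > 0")
  6 * eta * Q / (h^2 * w)
}

#' Subcellular fraction percentages
#'
#' Converts per-fraction signals (e.g. chromatin, nucleoplasm, cytoplasm) to
#' percentages of their total.
#'
#' @param levels Named non-negative numeric vector with positive sum.
#' @return Named percentages summing to 100.
#' @export
#' @examples
#' fraction_percentages(c(Chr = 1, Nuc = 1, Cyt = 2))
fraction_percentages <- function(levels) {
  if (any(levels < 0)) stop("signals must be >= 0")
  total <- sum(levels)
  if (total <= 0) stop("total signal must be > 0")
  levels * 100 / total
}
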