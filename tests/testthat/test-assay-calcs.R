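test_that("standard curves recover slope, r2 and efficiency", {
  # perfect-efficiency slope: one cycle per two-fold dilution
  sc <- fit_standard_curve(10^(9:3), 40 - 3.3219 * (9:3))
  expect_equal(sc$slope, -3.3219, tolerance = 1e-12)
  expect_equal(sc$efficiency, 1, tolerance = 1e-3)

  # hand least-squares on a 3-point series
  sc2 <- fit_standard_curve(c(1e9, 1e8, 1e7), c(10, 13.32, 16.64))
  expect_equal(sc2$slope, -3.32, tolerance = 1e-3)
  expect_gt(sc2$r_squared, 0.9999)

  expect_error(fit_standard_curve(c(1e9, 1e9, 1e9), c(1, 2, 3)), "distinct")
  expect_error(fit_standard_curve(c(1e9, -1), c(1, 2)), "> 0")

  # noisy recovery: slope within +-0.1 at sigma = 0.2 over 50 seeds
  slopes <- vapply(1:50, function(s) {
    sim <- simulate_qpcr(list(noise_sd = 0.2), seed = s)
    fit_standard_curve(sim$copies, sim$ct)$slope
  }, numeric(1))
  expect_true(all(abs(slopes + 3.3219) < 0.1))
})

test_that("copy-number inversion is exact, linear in dilution and guarded", {
  curve <- list(slope = -3.3219, intercept = 40)
  expect_equal(copies_per_cell(40, curve, n_cells = 1), 1)
  est <- copies_per_cell(21.5, curve, n_cells = 1000)
  expect_equal(copies_per_cell(21.5, curve, 1000, dilution_factor = 10),
               est * 10)
  expect_error(copies_per_cell(20, list(slope = 2, intercept = 40), 1),
               "negative")
})

test_that("qPCR round-trip recovers a planted per-cell copy number", {
  # planted 40 copies/cell in a 1000-cell sample, triplicate Cts at
  # sigma = 0.1, curve fitted from a noisy dilution series
  truth <- list(slope = -3.3219, intercept = 40, noise_sd = 0.1)
  est <- vapply(1:20, function(s) {
    sim <- simulate_qpcr(truth, seed = s)
    curve <- fit_standard_curve(sim$copies, sim$ct)
    true_ct <- truth$intercept + truth$slope * log10(40 * 1000)
    set.seed(1000 + s)
    cts <- true_ct + rnorm(3, 0, truth$noise_sd)
    copies_per_cell(cts, curve, n_cells = 1000)
  }, numeric(1))
  expect_true(mean(abs(est - 40) / 40 < 0.10) >= 0.9)
  expect_lt(abs(mean(est) - 40) / 40, 0.10)
})

test_that("proximity scoring is strict at the threshold and matches counting", {
  pairs <- data.frame(x1 = c(0, 0, 0), y1 = c(0, 0, 0),
                      x2 = c(0, 1.0, 0.6), y2 = c(0, 0, 0))
  pf <- proximity_fraction(pairs)
  expect_equal(pf$fraction, 2 / 3)  # coincident yes, exactly 1.0 um no
  expect_identical(pf$n_proximal, 2L)

  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    p <- data.frame(x1 = runif(n, 0, 3), y1 = runif(n, 0, 3),
                    x2 = runif(n, 0, 3), y2 = runif(n, 0, 3))
    d <- sqrt((p$x1 - p$x2)^2 + (p$y1 - p$y2)^2)
    expect_equal(proximity_fraction(p)$fraction, sum(d < 1) / n)
  }
  expect_error(proximity_fraction(data.frame()), "at least one")
})

test_that("t-test power matches the noncentral-t oracle and is monotone", {
  # null case: power equals alpha
  expect_equal(ttest_power(5, 0), 0.05, tolerance = 1e-9)

  # equality with the standard noncentral-t power routine across a grid;
  # power.t.test drops the opposite-tail rejection probability, so it is
  # added back for an exact comparison
  for (n in c(3, 5, 10, 20)) {
    for (d in c(0.5, 1, 2)) {
      df <- 2 * n - 2
      opp <- pt(-qt(0.975, df), df, ncp = d * sqrt(n / 2))
      expect_equal(ttest_power(n, d),
                   stats::power.t.test(n = n, delta = d, sd = 1,
                                       sig.level = 0.05)$power + opp,
                   tolerance = 1e-9)
    }
  }

  # monotone in n and d, decreasing in alpha stringency
  pw_n <- vapply(c(3, 5, 8, 12, 20), function(n) ttest_power(n, 1),
                 numeric(1))
  expect_true(all(diff(pw_n) > 0))
  pw_d <- vapply(c(0.2, 0.5, 1, 1.5, 2), function(d) ttest_power(5, d),
                 numeric(1))
  expect_true(all(diff(pw_d) > 0))
  expect_gt(ttest_power(5, 1, alpha = 0.05), ttest_power(5, 1, alpha = 0.01))
  expect_gt(ttest_power(5, 1, sides = 1), ttest_power(5, 1, sides = 2))

  # Monte Carlo agrees with the analytic routes
  expect_lt(abs(ttest_power(5, 1.2, method = "montecarlo", nsim = 4e4,
                            seed = 7) -
                ttest_power(5, 1.2)), 0.015)
})

test_that("shear stress follows the parallel-plate formula", {
  expect_equal(shear_stress(1, 1, 1, 1), 6)
  expect_equal(shear_stress(1, 1, 2, 1), 6 / 4)  # doubling h divides by 4
  # solve Q for tau = 12 at typical chamber geometry, then recompute
  eta <- 0.01; h <- 0.025; w <- 2.5
  Q <- 12 * h^2 * w / (6 * eta)
  expect_equal(shear_stress(eta, Q, h, w), 12)
  expect_error(shear_stress(0, 1, 1, 1), "> 0")
})

test_that("fraction percentages conserve their total", {
  expect_equal(fraction_percentages(c(Chr = 1, Nuc = 1, Cyt = 2)),
               c(Chr = 25, Nuc = 25, Cyt = 50))
  expect_equal(unname(fraction_percentages(c(a = 0, b = 3, c = 0))["b"]), 100)
  set.seed(62)
  for (rep in 1:20) {
    x <- runif(sample(2:6, 1), 0, 100)
    expect_equal(sum(fraction_percentages(x)), 100, tolerance = 1e-9)
  }
  expect_error(fraction_percentages(c(0, 0)), "> 0")
})
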