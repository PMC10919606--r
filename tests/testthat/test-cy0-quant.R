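test_that("mass-to-copies conversion matches the dsrB standard series", {
  expect_equal(copies_from_mass(0.1, 390), 2.34e8, tolerance = 5e-3)
  expect_equal(copies_from_mass(1e-7, 390), 2.34e2, tolerance = 5e-3)
  # inverse proportionality in fragment length
  expect_equal(copies_from_mass(0.1, 780), copies_from_mass(0.1, 390) / 2)
  expect_error(copies_from_mass(0.1, 0), "length_bp")
})

test_that("the Richards fit recovers exact parameters from model data", {
  truth <- list(Fb = 100, Fmax = 3000, b = 1.5, c = 22, d = 0.8)
  curve <- make_richards_curve(truth$Fb, truth$Fmax, truth$b, truth$c, truth$d)
  fit <- fit_richards(curve)
  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-4, info = p)
  }
})

test_that("flat and linear curves are reported as no-fit, not errors", {
  flat <- data.frame(cycle = 1:35, fluorescence = rep(100, 35))
  expect_false(fit_richards(flat)$converged)
  drift <- data.frame(cycle = 1:35, fluorescence = 100 + 0.2 * (1:35))
  expect_false(fit_richards(drift)$converged)
  set.seed(2)
  noisy_flat <- data.frame(cycle = 1:35,
                           fluorescence = 100 + rnorm(35, 0, 15))
  expect_false(fit_richards(noisy_flat)$converged)
  expect_error(fit_richards(data.frame(cycle = 1:5, fluorescence = 1:5)),
               "at least 10 cycles")
})

test_that("fits of simulated reactions explain almost all signal variance", {
  series <- simulate_dilution_series(copies_levels = c(2.34e4, 2.34e6),
                                     replicates = 2, seed = 10)
  for (curve in series) {
    fit <- fit_richards(curve)
    expect_true(fit$converged)
    expect_lt(fit$rss,
              0.01 * sum((curve$fluorescence - mean(curve$fluorescence))^2))
  }
})

test_that("closed-form Cy0 agrees with the numeric tangent construction", {
  # spot value: logistic case c=20, b=2 gives Cy0 = 16
  expect_equal(compute_cy0(list(b = 2, c = 20, d = 1)), 16)
  for (b in c(0.5, 1, 2, 4)) {
    for (d in c(0.2, 0.5, 1, 2, 5)) {
      closed <- compute_cy0(list(b = b, c = 25, d = d))
      numeric <- oracle_cy0_numeric(b, 25, d)
      expect_equal(closed, numeric, tolerance = 1e-6,
                   info = sprintf("b=%g d=%g", b, d))
    }
  }
  expect_error(compute_cy0(list(b = 2, c = 20, d = -1)), "d > 0")
})

test_that("Cy0 is scale-invariant and translation-equivariant", {
  base <- make_richards_curve(50, 2000, 1.4, 21, 0.9)
  f1 <- fit_richards(base)
  scaled <- base
  scaled$fluorescence <- 50 + 3.7 * (base$fluorescence - 50)
  f2 <- fit_richards(scaled)
  expect_equal(f1$cy0, f2$cy0, tolerance = 1e-5)
  shifted <- make_richards_curve(50, 2000, 1.4, 21 + 4, 0.9, cycles = 40)
  f3 <- fit_richards(shifted)
  expect_equal(f3$cy0, f1$cy0 + 4, tolerance = 1e-4)
})

test_that("a perfect-doubling series has the textbook calibration slope", {
  series <- simulate_dilution_series(replicates = 1, efficiency = 1,
                                     noise_sd = 0)
  fits <- fit_curves(series)
  sc <- build_standard_curve(fits$cy0, fits$copies_per_ul)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 0.02)
  expect_gt(sc$r_squared, 0.9999)
})

test_that("collinear points give r_squared of one and a usable calibration", {
  copies <- rep(10^(3:7), each = 2)
  cy0 <- 40 - 3.3 * log10(copies)
  sc <- build_standard_curve(cy0, copies)
  expect_equal(sc$r_squared, 1)
  expect_equal(sc$detection_limit, 1e3)
  expect_error(build_standard_curve(c(20, 21), c(1e3, 1e3, 1e4)[1:2]),
               "3 distinct")
  expect_error(build_standard_curve(log10(copies), copies), "decrease")
})

test_that("a default-noise dilution series calibrates with R2 above 0.99", {
  series <- simulate_dilution_series(replicates = 3, seed = 2024)
  fits <- fit_curves(series)
  sc <- build_standard_curve(fits$cy0, fits$copies_per_ul)
  expect_gt(sc$r_squared, 0.99)
  expect_true(all(fits$converged))
  # noiseless Cy0 spacing between adjacent 10-fold levels is constant
  quiet <- simulate_dilution_series(replicates = 1, noise_sd = 0)
  qf <- fit_curves(quiet)
  spacing <- diff(qf$cy0[order(qf$copies_per_ul)])
  expect_lt(max(spacing) - min(spacing), 0.05)
})

test_that("quantification round-trips the calibration within tight log error", {
  series <- simulate_dilution_series(replicates = 3, seed = 7)
  fits <- fit_curves(series)
  sc <- build_standard_curve(fits$cy0, fits$copies_per_ul)
  q <- quantify_sample(fits$cy0, sc)
  err <- abs(log10(q$estimated_copies_per_ul) - log10(fits$copies_per_ul))
  expect_lt(median(err), 0.05)
  # round-trip of a point on the regression line is exact
  cy_line <- sc$intercept + sc$slope * log10(1e5)
  expect_equal(quantify_sample(cy_line, sc)$estimated_copies_per_ul, 1e5)
  # earlier Cy0 than the top standard flags extrapolation
  early <- quantify_sample(min(fits$cy0) - 5, sc)
  expect_false(early$in_calibration_range)
})

test_that("Cy0 decreases strictly with template input, and replicate scatter
           grows as input falls", {
  cy0_at <- function(n0, seed = NULL, noise = 0) {
    spec <- reaction_spec(c(t = n0), c(t = 0.95), noise_sd = noise,
                          seed = seed)
    fit_richards(simulate_reaction(spec))$cy0
  }
  cy0s <- vapply(10^(3:7), cy0_at, numeric(1))
  expect_true(all(diff(cy0s) < 0))
  sd_at <- function(n0) {
    sd(vapply(1:8, function(s) cy0_at(n0, seed = s, noise = 15), numeric(1)))
  }
  expect_gt(sd_at(5e2), sd_at(5e6))
})

test_that("replicate estimates aggregate as a geometric mean", {
  expect_equal(aggregate_replicates(c(100, 10000)), 1000)
  expect_equal(aggregate_replicates(c(100, NA, 10000)), 1000)
  expect_true(is.na(aggregate_replicates(c(NA_real_, NA_real_))))
})
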