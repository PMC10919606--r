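test_that("template-free, noise-free reactions give a flat baseline", {
  spec <- reaction_spec(c(t1 = 0), c(t1 = 0.95), noise_sd = 0,
                        baseline_slope = 0)
  curve <- simulate_reaction(spec)
  expect_equal(curve$fluorescence, rep(100, 35))
})

test_that("a lone template at E = 1 doubles every cycle before the plateau", {
  spec <- reaction_spec(c(t1 = 1000), c(t1 = 1), noise_sd = 0,
                        baseline_intercept = 0, baseline_slope = 0,
                        plateau_capacity = 1e12, fluorescence_scale = 1)
  curve <- simulate_reaction(spec)
  pre <- curve$fluorescence[1:12]  # far from 1e12
  expect_equal(diff(log2(pre)), rep(1, 11), tolerance = 1e-5)
})

test_that("mixtures are additive while the reaction is unsaturated", {
  args <- list(noise_sd = 0, baseline_intercept = 0, baseline_slope = 0)
  one <- simulate_reaction(do.call(reaction_spec,
    c(list(c(a = 1e4), c(a = 0.9)), args)))
  two <- simulate_reaction(do.call(reaction_spec,
    c(list(c(b = 5e3), c(b = 0.6)), args)))
  both <- simulate_reaction(do.call(reaction_spec,
    c(list(c(a = 1e4, b = 5e3), c(a = 0.9, b = 0.6)), args)))
  pre <- 1:10  # totals < 1e7 against capacity 1e11: saturation ~ 1
  expect_equal(both$fluorescence[pre],
               one$fluorescence[pre] + two$fluorescence[pre],
               tolerance = 5e-3)
})

test_that("signal is monotone in template input and bounded by the plateau", {
  sig_at <- function(n0) {
    spec <- reaction_spec(c(t = n0), c(t = 0.95), noise_sd = 0)
    simulate_reaction(spec)
  }
  curves <- lapply(10^(2:6), sig_at)
  at20 <- vapply(curves, function(cv) cv$fluorescence[20], numeric(1))
  expect_true(all(diff(at20) > 0))
  for (cv in curves) {
    expect_true(all(attr(cv, "molecules") <= 1e11 * (1 + 0.95)))
  }
  # long-run convergence below capacity
  long <- simulate_reaction(reaction_spec(c(t = 1e3), c(t = 0.95),
                                          cycles = 80, noise_sd = 0))
  expect_lt(max(attr(long, "molecules")), 1e11)
})

test_that("simulation is reproducible under a seed", {
  spec <- reaction_spec(c(t = 1e4), c(t = 0.95), seed = 77)
  expect_identical(simulate_reaction(spec)$fluorescence,
                   simulate_reaction(spec)$fluorescence)
  series1 <- simulate_dilution_series(replicates = 2, seed = 3)
  series2 <- simulate_dilution_series(replicates = 2, seed = 3)
  expect_identical(curves_to_long(series1), curves_to_long(series2))
})

test_that("dilution series cardinality and metadata are correct", {
  series <- simulate_dilution_series(replicates = 3, seed = 1)
  expect_length(series, 21)
  md <- attr(series[[1]], "metadata")
  expect_equal(md$copies_per_ul, 2.34e2)
  long <- curves_to_long(series)
  expect_equal(nrow(long), 21 * 35)
  back <- long_to_curves(long)
  expect_length(back, 21)
})

test_that("efficiencies map mismatch categories with override precedence", {
  ref <- dsrb_reference()
  model <- efficiency_model(overrides = ref$overrides)
  eC <- efficiency_from_matrix(ref$amplifiability, "DSR1762Fmix/DSR2107Rmix",
                               model)
  # perfect match category
  expect_equal(unname(eC["gBlock4"]), 0.95)
  # >1 MM templates are blocked
  expect_equal(unname(eC["gBlock6"]), 0)
  # override takes precedence over the 1-MM category for gBlock3
  expect_equal(unname(eC["gBlock3"]), 0.60)
  no_override <- efficiency_from_matrix(ref$amplifiability,
                                        "DSR1762Fmix/DSR2107Rmix",
                                        efficiency_model())
  expect_equal(unname(no_override["gBlock3"]), 0.60)  # its 1-MM category
  e_one <- efficiency_from_matrix(ref$amplifiability,
                                  "DSR1762Fmix/DSR2107Rmix",
                                  efficiency_model(e_one_mm = 0.3))
  expect_equal(unname(e_one["gBlock3"]), 0.3)
  expect_error(efficiency_from_matrix(ref$amplifiability, "nope", model),
               "unknown primer set")
  expect_error(efficiency_model(e_perfect = 1.2), "\\[0, 1\\]")
})
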