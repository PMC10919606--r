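test_that("log-normal profiles are normalized, descending and evenness-ordered", {
  p0 <- lognormal_abundance_profile(12, 1, 0)
  expect_equal(p0, rep(1 / 12, 12))
  for (sigma in c(0.5, 1, 2, 5)) {
    p <- lognormal_abundance_profile(12, 1, sigma)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0))
  }
  # Pielou evenness strictly decreases as sigma grows
  J <- vapply(c(0, 1, 2, 5),
              function(s) pielou_evenness(lognormal_abundance_profile(12, 1, s)),
              numeric(1))
  expect_true(all(diff(J) < 0))
  expect_error(lognormal_abundance_profile(12, 1, -1), "sigma")
})

test_that("profile length and normalization hold across n and parameters", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    p <- lognormal_abundance_profile(n, runif(1, -2, 2), runif(1, 0, 4))
    expect_length(p, n)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("dominance assignment gives the named group the top fractions", {
  ref <- dsrb_reference()
  profile <- lognormal_abundance_profile(12, 1, 2)
  for (mode in c("common", "rare")) {
    d <- assign_dominance(profile, ref$templates, mode, sigma = 2,
                          priority = ref$priority)
    groups <- vapply(ref$templates, `[[`, character(1), "group_label")
    got <- sum(d$abundances[names(groups)[groups == mode]])
    # no other assignment of the same multiset can give the group more mass
    expect_equal(got, sum(sort(profile, decreasing = TRUE)[1:4]))
    # the multiset of fractions never changes with mode
    expect_equal(unname(sort(d$abundances)), sort(profile))
    expect_equal(sum(d$abundances), 1, tolerance = 1e-12)
  }
  # rare-dominated, high sigma: the single top template is in the rare group
  d5 <- assign_dominance(lognormal_abundance_profile(12, 1, 5), ref$templates,
                         "rare", sigma = 5, priority = ref$priority)
  top <- names(which.max(d5$abundances))
  expect_equal(ref$templates[[top]]$group_label, "rare")
})

test_that("seeded assignment is deterministic and empty groups are rejected", {
  ref <- dsrb_reference()
  profile <- lognormal_abundance_profile(12, 1, 1)
  d1 <- assign_dominance(profile, ref$templates, "rare", seed = 99)
  d2 <- assign_dominance(profile, ref$templates, "rare", seed = 99)
  expect_identical(d1$abundances, d2$abundances)
  no_rare <- lapply(ref$templates[c("gBlock4", "gBlock5")], function(t) {
    t$group_label <- "common"; t
  })
  expect_error(assign_dominance(lognormal_abundance_profile(2, 1, 1),
                                no_rare, "rare"),
               "no members")
})

test_that("reaction copy loads follow the design and conserve the total", {
  ref <- dsrb_reference()
  d <- assign_dominance(lognormal_abundance_profile(12, 1, 1), ref$templates,
                        "common", total_concentration = 1e8,
                        priority = ref$priority)
  copies <- copies_per_template(d, reaction_volume_ul = 1)
  expect_equal(sum(copies), 1e8)
  expect_equal(unname(copies[names(which.max(d$abundances))]),
               max(d$abundances) * 1e8)
  # half-abundance sanity: fraction 0.5 of 1e8 copies/uL in 1 uL is 5e7
  flat <- d
  flat$abundances <- c(a = 0.5, b = 0.5)
  expect_equal(unname(copies_per_template(flat, 1)), c(5e7, 5e7))
})

test_that("Poisson-rounded loads are unbiased at the low-template condition", {
  ref <- dsrb_reference()
  d <- assign_dominance(lognormal_abundance_profile(12, 1, 1), ref$templates,
                        "common", total_concentration = 1e5,
                        priority = ref$priority)
  totals <- vapply(1:1000, function(s) {
    sum(copies_per_template(d, poisson = TRUE, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1e5) / 1e5, 0.01)
})

test_that("the study grid spans 2 dominance x 3 sigma x 2 concentrations", {
  ref <- dsrb_reference()
  grid <- gbtm_grid(ref$templates, priority = ref$priority)
  expect_length(grid, 12)
  modes <- vapply(grid, `[[`, character(1), "dominance_mode")
  sigmas <- vapply(grid, `[[`, numeric(1), "sigma")
  concs <- vapply(grid, `[[`, numeric(1), "total_concentration")
  expect_equal(sort(unique(modes)), c("common", "rare"))
  expect_equal(sort(unique(sigmas)), c(1, 2, 5))
  expect_equal(sort(unique(concs)), c(1e5, 1e8))
})
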