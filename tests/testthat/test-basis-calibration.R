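test_that("fourth-material adjustment inverts forward mixing", {
  mu4 <- FORMALIN_MU
  x <- c(0.27, 0.16)
  expect_equal(unname(adjust_for_fourth_material(x, 0, mu4)), x)
  mixed <- 0.7 * x + 0.3 * mu4
  expect_equal(unname(adjust_for_fourth_material(mixed, 0.3, mu4)), x,
               tolerance = 1e-14)
  expect_error(adjust_for_fourth_material(x, 1, mu4), "f4 < 1")
  expect_error(adjust_for_fourth_material(x, -0.1, mu4), "0 <= f4")
})

test_that("group cost is zero at the generating parameters and rises away", {
  b <- clot_basis()
  ctrue <- c(0.95, 3.8, 1, 0.9, 3.7, 1)
  coh <- make_clot_cohort(4, b, FORMALIN_MU, IOMEPROL_MU,
                          iomeprol_range = c(0, 0),
                          correction_factors = ctrue, seed = 3)
  mu_ct <- as.matrix(coh$measurements[, c("mu_low", "mu_high")])
  expect_equal(group_cost(ctrue, coh$formalin, mu_ct, coh$histology, b,
                          FORMALIN_MU), 0, tolerance = 1e-28)
  for (m in c(1, 2, 4, 5)) {
    cpert <- ctrue
    cpert[m] <- cpert[m] * 1.02
    expect_gt(group_cost(cpert, coh$formalin, mu_ct, coh$histology, b,
                         FORMALIN_MU), 0)
  }
  # invariant to specimen ordering
  p <- c(3, 1, 4, 2)
  expect_equal(group_cost(ctrue, coh$formalin[p], mu_ct[p, ],
                          coh$histology[p, ], b, FORMALIN_MU),
               0, tolerance = 1e-28)
})

test_that("the volume-conservation residual component is identically zero", {
  # cost computed with mu' equal to the model point differs from zero only
  # through the two attenuation components; verified by an independent
  # hand computation of the residual for one specimen
  b <- clot_basis()
  cc <- c(1.1, 0.9, 1, 1.05, 0.95, 1)
  h <- c(0.6, 0.3, 0.1)
  M <- rbind(cc[1:3] * b$mu_low, cc[4:6] * b$mu_high, rep(1, 3))
  target <- drop(M %*% h)
  mu_ct <- target[1:2]  # f4 = 0, mu' = mu_ct
  got <- group_cost(cc, 0, matrix(mu_ct, 1), matrix(h, 1), b, FORMALIN_MU)
  expect_equal(got, sum((mu_ct - target[1:2])^2) + (1 - sum(h))^2,
               tolerance = 1e-28)
})

test_that("noiseless groups are recovered with frozen factors honored", {
  b <- clot_basis()
  ctrue <- c(0.9128, 3.7418, 1, 0.8657, 3.7399, 1)
  coh <- make_clot_cohort(4, b, FORMALIN_MU, IOMEPROL_MU,
                          iomeprol_range = c(0, 0),
                          correction_factors = ctrue, seed = 17)
  mu_ct <- as.matrix(coh$measurements[, c("mu_low", "mu_high")])
  g <- optimize_group(mu_ct, coh$histology, b, FORMALIN_MU,
                      fixed = c(NA, NA, 1, NA, NA, 1), group_id = "g1")
  expect_identical(g$correction[3], 1)
  expect_identical(g$correction[6], 1)
  expect_lt(g$cost_value, 1e-10)
  free <- c(1, 2, 4, 5)
  expect_lt(max(abs(g$correction[free] / ctrue[free] - 1)), 1e-3)
  expect_equal(g$formalin_fractions, unname(coh$formalin), tolerance = 1e-4)
})

test_that("duplicating specimens leaves the optimum unchanged", {
  b <- clot_basis()
  ctrue <- c(1.05, 3.6, 1, 0.95, 3.9, 1)
  coh <- make_clot_cohort(4, b, FORMALIN_MU, IOMEPROL_MU,
                          iomeprol_range = c(0, 0),
                          correction_factors = ctrue, seed = 23)
  mu_ct <- as.matrix(coh$measurements[, c("mu_low", "mu_high")])
  fixed <- c(NA, NA, 1, NA, NA, 1)
  g1 <- optimize_group(mu_ct, coh$histology, b, FORMALIN_MU, fixed = fixed)
  g2 <- optimize_group(rbind(mu_ct, mu_ct), rbind(coh$histology, coh$histology),
                       b, FORMALIN_MU, fixed = fixed)
  expect_equal(g2$correction, g1$correction, tolerance = 1e-6)
})

test_that("optimization is reproducible for a fixed seed/config", {
  b <- clot_basis()
  coh <- make_clot_cohort(4, b, FORMALIN_MU, IOMEPROL_MU,
                          iomeprol_range = c(0, 0),
                          correction_factors = c(0.9, 3.7, 1, 0.88, 3.8, 1),
                          noise_sigma = 0.002, seed = 29)
  mu_ct <- as.matrix(coh$measurements[, c("mu_low", "mu_high")])
  fixed <- c(NA, NA, 1, NA, NA, 1)
  g1 <- optimize_group(mu_ct, coh$histology, b, FORMALIN_MU, fixed = fixed,
                       control = list(seed = 5))
  g2 <- optimize_group(mu_ct, coh$histology, b, FORMALIN_MU, fixed = fixed,
                       control = list(seed = 5))
  expect_identical(g1$correction, g2$correction)
  expect_identical(g1$cost_value, g2$cost_value)
})

test_that("free-factor recovery holds over random calibration scenarios", {
  set.seed(61)
  b <- clot_basis()
  fixed <- c(NA, NA, 1, NA, NA, 1)
  for (i in 1:20) {
    draw <- function() {
      if (runif(1) < 0.5) runif(1, 0.8, 1.2) else runif(1, 3.5, 4.0)
    }
    ctrue <- c(draw(), draw(), 1, draw(), draw(), 1)
    coh <- make_clot_cohort(4, b, FORMALIN_MU, IOMEPROL_MU,
                            iomeprol_range = c(0, 0),
                            correction_factors = ctrue, seed = 100 + i)
    mu_ct <- as.matrix(coh$measurements[, c("mu_low", "mu_high")])
    g <- optimize_group(mu_ct, coh$histology, b, FORMALIN_MU, fixed = fixed)
    free <- c(1, 2, 4, 5)
    expect_lt(max(abs(g$correction[free] / ctrue[free] - 1)), 0.01)
  }
})

test_that("inverse-cost aggregation reproduces the published weighted means", {
  agg <- aggregate_groups(published_group_factors(), clot_basis())
  # quoted agreement level ~1e-3: printed costs are rounded
  expect_equal(agg$correction[1], published_weighted_factors()[1],
               tolerance = 1e-3)
  expect_equal(sum(agg$weights), 1)
  expect_true(all(agg$weights > 0))
  # corrected attenuation = initial x weighted factor
  expect_equal(agg$attenuation$mu_low,
               clot_basis()$mu_low * agg$correction[1:3])
})

test_that("aggregation degenerates gracefully", {
  gs <- list(list(correction = rep(1.3, 6), cost_value = 0.4),
             list(correction = rep(1.3, 6), cost_value = 2.0))
  expect_equal(aggregate_groups(gs)$correction, rep(1.3, 6))
  # a zero-cost group dominates via the weight cap
  gs2 <- list(list(correction = rep(2, 6), cost_value = 0),
              list(correction = rep(1, 6), cost_value = 1))
  expect_equal(aggregate_groups(gs2)$correction, rep(2, 6), tolerance = 1e-6)
})

test_that("weighted means stay in the convex hull of group values", {
  set.seed(71)
  for (i in 1:20) {
    gs <- lapply(1:3, function(j) {
      list(correction = runif(6, 0.5, 4), cost_value = runif(1, 0.1, 2))
    })
    agg <- aggregate_groups(gs)
    fac <- agg$group_factors
    expect_true(all(agg$correction >= apply(fac, 2, min) - 1e-12))
    expect_true(all(agg$correction <= apply(fac, 2, max) + 1e-12))
  }
})

test_that("renormalizers from correction and calibration are consistent", {
  # c_s = 1/(1 - f4) computed on the calibration side must be the inverse
  # of c_a = 1 - f4 from the correction side on a shared specimen
  b <- clot_basis()
  coh <- make_clot_cohort(1, b, FORMALIN_MU, IOMEPROL_MU,
                          iomeprol_range = c(0, 0), seed = 37)
  h <- coh$histology[1, ]
  names(h) <- b$name
  fit <- fit_extra_fractions(
    c(coh$measurements$mu_low[1], coh$measurements$mu_high[1]), h, b,
    extras_set()[1, ])
  f4 <- fit$extra_fractions[["formalin"]]
  c_s_calib <- 1 / (1 - f4)
  expect_equal(fit$c_a * c_s_calib, 1, tolerance = 1e-12)
  expect_equal(fit$c_s, c_s_calib)
})
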