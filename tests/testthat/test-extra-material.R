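test_that("histology fractions are validated and normalized", {
  expect_error(histology_fractions(c(0.5, 0.5)), "exactly 3")
  expect_error(histology_fractions(c(0.5, 0.3, 0.2)), "named")
  expect_error(histology_fractions(c(a = 0.5, b = 0.3, d = 0.3)), "sum to 1")
  expect_error(histology_fractions(c(a = -0.1, b = 0.6, d = 0.5)), "\\[0, 1\\]")
  f <- histology_fractions(c(a = 0.5005, b = 0.3, d = 0.2))
  expect_equal(sum(f), 1)
})

test_that("histology point is the restricted mixing model", {
  b <- clot_basis5()
  # pure fibrin/platelets sits at the calibrated fibrin attenuation
  expect_equal(histology_point(c(fibrin = 1, RBC = 0, WBC = 0),
                               basis_set(c("fibrin", "RBC", "WBC"),
                                         c(0.2693, 0.2769, 0.2230),
                                         c(0.1636, 0.1703, 0.1361))),
               c(mu_low = 0.2693, mu_high = 0.1636))
  # equal thirds give the triangle centroid
  ctr <- histology_point(c(fibrin = 1, RBC = 1, WBC = 1) / 3, b)
  expect_equal(unname(ctr), c(mean(b$mu_low[1:3]), mean(b$mu_high[1:3])))
  # convexity: any histology point lies inside the basis bounds
  set.seed(7)
  for (i in 1:20) {
    f <- drop(random_simplex())
    names(f) <- c("fibrin", "RBC", "WBC")
    hp <- histology_point(f, b)
    expect_true(hp[1] >= min(b$mu_low[1:3]) && hp[1] <= max(b$mu_low[1:3]))
    expect_true(hp[2] >= min(b$mu_high[1:3]) && hp[2] <= max(b$mu_high[1:3]))
  }
  expect_error(histology_point(c(fibrin = 1, RBC = 0, gold = 0), b),
               "not in basis")
})

test_that("corrected_point is the affine shift along characteristic vectors", {
  hp <- c(0.2693, 0.1636)
  expect_equal(corrected_point(hp, 0, c(0.2, 0.14)),
               c(mu_low = 0.2693, mu_high = 0.1636))
  # halfway interpolation toward the extra material
  expect_equal(unname(corrected_point(hp, 0.5, c(0.2, 0.14))),
               (hp + c(0.2, 0.14)) / 2)
  # hand evaluation
  expect_equal(corrected_point(hp, 0.1, c(0.20, 0.14)),
               c(mu_low = 0.26237, mu_high = 0.16124), tolerance = 1e-12)
  expect_error(corrected_point(hp, 1.0, c(0.2, 0.14)), "sum < 1")
  expect_error(corrected_point(hp, -0.1, c(0.2, 0.14)), ">= 0")
})

test_that("renormalization scales histology by c_a and appends extras", {
  h <- c(RBC = 0.5, WBC = 0.3, fibrin = 0.2)
  expect_equal(renormalize_composition(h, c(formalin = 0)),
               c(h, formalin = 0))
  out <- renormalize_composition(h, c(formalin = 0.2))
  expect_equal(unname(out), c(0.4, 0.24, 0.16, 0.2))
  expect_equal(sum(out), 1)
  # boundary: extras approaching 1 squeeze histology to 0
  out2 <- renormalize_composition(h, c(formalin = 1 - 1e-9))
  expect_lt(max(out2[1:3]), 1e-9)
})

test_that("matching and relative errors follow their formulas", {
  expect_equal(matching_error(c(0.3, 0.15), c(0.3, 0.15)),
               c(mu_low = 0, mu_high = 0))
  expect_equal(matching_error(c(0.303, 0.15), c(0.3, 0.15))[["mu_low"]], 1)
  expect_error(matching_error(c(0.3, 0.15), c(0, 0.15)), "> 0")
  expect_equal(relative_error_pct(1.66, 1.72), 3.61, tolerance = 2e-3)
  expect_equal(relative_error_pct(0.66, 0.16), 75.8, tolerance = 1e-3)
  expect_equal(relative_error_pct(2.5, 2.5), 0)
  expect_error(relative_error_pct(0, 1), "undefined")
})

test_that("fraction -> concentration uses the stock concentration", {
  ext <- extras_set()
  iom <- ext[ext$name == "iomeprol", ]
  expect_equal(fraction_to_concentration(0.250, iom), 5.000)
  expect_equal(fraction_to_concentration(0.033, iom), 0.66)
  expect_equal(fraction_to_concentration(0, iom), 0)
  expect_equal(fraction_to_concentration(0.25, 20), 5)
  expect_error(fraction_to_concentration(0.1, ext[ext$name == "formalin", ]),
               "no stock concentration")
})

test_that("zero mismatch yields zero extra fractions and zero error", {
  b <- clot_basis5()
  h <- c(fibrin = 0.6, RBC = 0.3, WBC = 0.1)
  hp <- histology_point(h, b)
  fit <- fit_extra_fractions(hp, h, b, extras_set())
  expect_equal(unname(fit$extra_fractions), c(0, 0))
  expect_equal(fit$cost_value, 0, tolerance = 1e-20)
  expect_equal(unname(fit$matching_error_pct), c(0, 0))
  expect_equal(fit$c_a, 1)
})

test_that("a single hidden extra is recovered; dense grid agrees", {
  b <- clot_basis5()
  h <- c(fibrin = 0.55, RBC = 0.35, WBC = 0.10)
  hp <- histology_point(h, b)
  form <- extras_set()[1, ]
  mu_ct <- corrected_point(hp, 0.1, c(form$mu_low, form$mu_high))
  fit <- fit_extra_fractions(mu_ct, h, b, form)
  expect_equal(fit$extra_fractions[["formalin"]], 0.1, tolerance = 1e-8)
  expect_lt(max(fit$matching_error_pct), 1e-8)
  # independent oracle: dense grid over the admissible fraction range
  v <- hp - c(form$mu_low, form$mu_high)
  bb <- hp - mu_ct
  grid <- seq(0, 0.999, by = 1e-4)
  cost <- (bb[1] - grid * v[1])^2 + (bb[2] - grid * v[2])^2
  expect_equal(fit$extra_fractions[["formalin"]], grid[which.min(cost)],
               tolerance = 1e-4)
})

test_that("two independent extras are recovered exactly (2x2 oracle)", {
  b <- clot_basis5()
  h <- c(fibrin = 0.5, RBC = 0.4, WBC = 0.1)
  hp <- histology_point(h, b)
  ext <- extras_set()
  extra_mu <- rbind(c(ext$mu_low[1], ext$mu_high[1]),
                    c(ext$mu_low[2], ext$mu_high[2]))
  mu_ct <- corrected_point(hp, c(0.3, 0.05), extra_mu)
  fit <- fit_extra_fractions(mu_ct, h, b, ext)
  expect_equal(unname(fit$extra_fractions), c(0.3, 0.05), tolerance = 1e-8)
  expect_lt(fit$cost_value, 1e-16)
  # oracle: direct 2-unknown/2-equation solve
  A <- cbind(hp - extra_mu[1, ], hp - extra_mu[2, ])
  f_oracle <- solve(A, hp - mu_ct)
  expect_equal(unname(fit$extra_fractions), unname(f_oracle),
               tolerance = 1e-10)
})

test_that("a negative unconstrained fraction reduces to the boundary fit", {
  b <- clot_basis5()
  h <- c(fibrin = 0.55, RBC = 0.35, WBC = 0.10)
  hp <- histology_point(h, b)
  ext <- extras_set()
  form_mu <- c(ext$mu_low[1], ext$mu_high[1])
  # shift away from the iomeprol direction: only formalin can explain it
  mu_ct <- hp + 0.15 * (form_mu - hp) + c(-0.004, 0.0)
  fit <- fit_extra_fractions(mu_ct, h, b, ext)
  expect_equal(fit$extra_fractions[["iomeprol"]], 0)
  # formalin equals the constrained 1D oracle
  v <- hp - form_mu
  f1 <- sum(v * (hp - mu_ct)) / sum(v * v)
  expect_equal(fit$extra_fractions[["formalin"]], min(max(f1, 0), 1 - 1e-6),
               tolerance = 1e-10)
  expect_gt(max(fit$matching_error_pct), 0)
})

test_that("collinear characteristic vectors warn and reduce", {
  b <- clot_basis5()
  h <- c(fibrin = 0.55, RBC = 0.35, WBC = 0.10)
  hp <- histology_point(h, b)
  # two extras placed along one line through the histology point
  dir <- c(0.05, 0.01)
  ext <- basis_set(c("e1", "e2"), c(hp[1] + dir[1], hp[1] + 2 * dir[1]),
                   c(hp[2] + dir[2], hp[2] + 2 * dir[2]))
  mu_ct <- hp + 0.1 * dir
  expect_warning(fit <- fit_extra_fractions(mu_ct, h, b, ext), "collinear")
  expect_lt(fit$cost_value, 1e-16)
  expect_true(sum(fit$extra_fractions > 0) <= 1)
})

test_that("forward/inverse recovery holds over random draws", {
  set.seed(99)
  worst <- 0
  for (i in 1:200) {
    b <- clot_basis5()
    h <- drop(random_simplex())
    names(h) <- c("fibrin", "RBC", "WBC")
    hp <- histology_point(h, b)
    f_true <- c(runif(1, 0, 0.6), runif(1, 0, 0.3))
    ext <- extras_set()
    extra_mu <- rbind(c(ext$mu_low[1], ext$mu_high[1]),
                      c(ext$mu_low[2], ext$mu_high[2]))
    mu_ct <- corrected_point(hp, f_true, extra_mu)
    fit <- fit_extra_fractions(mu_ct, h, b, ext)
    worst <- max(worst, max(abs(unname(fit$extra_fractions) - f_true)))
    expect_equal(fit$c_a * fit$c_s, 1, tolerance = 1e-12)
    expect_equal(sum(fit$composition), 1, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-6)
})
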