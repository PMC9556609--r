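# Shared fixtures: the published aqueous basis attenuations, illustrative
# clot-constituent attenuations, and random generators for property tests.

WATER_MU <- c(mu_low = 0.2269, mu_high = 0.1370)      # config constant, 1/cm
FORMALIN_MU <- c(mu_low = 0.229, mu_high = 0.138)
IOMEPROL_MU <- c(mu_low = 0.433, mu_high = 0.152)     # 20 mg/ml stock

# aqueous basis solutions (regression endpoints at stock concentration)
aqueous_basis3 <- function() {
  basis_set(c("iomeprol", "eosin", "NaCl"),
            mu_low = c(0.433, 0.290, 0.306),
            mu_high = c(0.152, 0.141, 0.151),
            stock_concentration = c(20, 40, 200))
}

aqueous_basis4 <- function() {
  basis_set(c("eosin", "iomeprol", "water", "NaCl"),
            mu_low = c(0.290, 0.433, WATER_MU[1], 0.306),
            mu_high = c(0.141, 0.152, WATER_MU[2], 0.151),
            stock_concentration = c(40, 20, NA, 200))
}

# illustrative initial clot-constituent attenuations (uncorrected)
clot_basis <- function() {
  basis_set(c("fibrin", "RBC", "WBC"),
            mu_low = c(0.2892, 0.0731, 0.2230),
            mu_high = c(0.1847, 0.0450, 0.1361))
}

clot_basis5 <- function() {
  basis_set(c("fibrin", "RBC", "WBC", "formalin", "iomeprol"),
            mu_low = c(0.2892, 0.0731, 0.2230, FORMALIN_MU[1], IOMEPROL_MU[1]),
            mu_high = c(0.1847, 0.0450, 0.1361, FORMALIN_MU[2], IOMEPROL_MU[2]),
            stock_concentration = c(NA, NA, NA, NA, 20))
}

extras_set <- function() {
  basis_set(c("formalin", "iomeprol"),
            mu_low = c(FORMALIN_MU[1], IOMEPROL_MU[1]),
            mu_high = c(FORMALIN_MU[2], IOMEPROL_MU[2]),
            stock_concentration = c(NA, 20))
}

# random well-conditioned 3-material basis for property tests
random_basis3 <- function() {
  repeat {
    mu_low <- runif(3, 0.05, 0.5)
    mu_high <- runif(3, 0.02, 0.3)
    b <- basis_set(paste0("m", 1:3), mu_low, mu_high)
    k <- kappa(system_matrix(b), exact = TRUE)
    if (is.finite(k) && k < 1e5) return(b)
  }
}

# uniform draw from the interior of the probability simplex
random_simplex <- function(n = 1, k = 3) {
  g <- matrix(rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

# pipetted volumes of the six published test mixtures (ml), columns in
# eosin / iomeprol / water / NaCl order
bench_recipes <- function() {
  v <- rbind(c(0.5, 0.0, 0.5, 0.5),
             c(0.3, 0.3, 0.3, 0.3),
             c(0.1, 0.0, 1.0, 0.0),
             c(0.05, 0.05, 1.0, 0.4),
             c(0.1, 0.1, 0.5, 0.5),
             c(0.005, 0.003, 0.5, 0.5))
  colnames(v) <- c("eosin", "iomeprol", "water", "NaCl")
  v
}

# target volume fractions of those mixtures, 3-decimal table style
bench_target_fractions <- function() {
  f <- rbind(c(0.333, 0.000, 0.333, 0.333),
             c(0.250, 0.250, 0.250, 0.250),
             c(0.091, 0.000, 0.909, 0.000),
             c(0.033, 0.033, 0.667, 0.267),
             c(0.083, 0.083, 0.417, 0.417),
             c(0.005, 0.003, 0.496, 0.496))
  colnames(f) <- c("eosin", "iomeprol", "water", "NaCl")
  f
}

# published per-group correction factors and cost values (a.u.), layout
# c(fibrin_low, RBC_low, WBC_low, fibrin_high, RBC_high, WBC_high)
published_group_factors <- function() {
  list(list(correction = c(0.9128, 3.7418, 1, 0.8657, 3.7399, 1),
            cost_value = 0.9),
       list(correction = c(0.9836, 3.6263, 1, 0.9401, 3.6118, 1),
            cost_value = 1.4),
       list(correction = c(0.9180, 3.9191, 1, 0.8736, 3.9229, 1),
            cost_value = 0.8))
}

published_weighted_factors <- function() {
  c(0.9311, 3.7874, 1, 0.8859, 3.7813, 1)
}

# noiseless dilution series on the exact mixing line through water
exact_series <- function(material = "iomeprol", conc = c(1, 5, 10, 15, 20),
                         stock = 20, endpoint = IOMEPROL_MU) {
  dilution_series(material, conc,
                  mu_low = WATER_MU[1] + (endpoint[1] - WATER_MU[1]) * conc / stock,
                  mu_high = WATER_MU[2] + (endpoint[2] - WATER_MU[2]) * conc / stock,
                  stock_concentration = stock)
}
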