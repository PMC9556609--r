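# Forward simulation of test specimens with known ground truth: aqueous
# pipetted mixtures (dilution-bench style) and clot-like specimens with
# hidden formalin/contrast-agent fractions. Every other module is testable
# against these bundles without any external data.

#' Convert pipetted volumes to volume fractions
#'
#' @param volumes Named or unnamed numeric vector of pipetted volumes (ml),
#'   all `>= 0` with a positive total.
#' @return Fractions summing to 1 (same names).
#' @examples
#' volumes_to_fractions(c(eosin = 0.3, iomeprol = 0.3, water = 0.3, NaCl = 0.3))
#' @export
volumes_to_fractions <- function(volumes) {
  if (any(!is.finite(volumes)) || any(volumes < 0)) {
    stop("volumes must be finite and >= 0")
  }
  total <- sum(volumes)
  if (total <= 0) stop("total volume must be > 0")
  volumes / total
}

#' Simulate an aqueous mixture cohort
#'
#' Forward-generates specimens pipetted from aqueous basis solutions: the
#' recipe volumes give the true volume fractions, the noiseless measurement
#' is the linear mixing forward model, and (optionally) independent
#' Gaussian noise per energy is added in attenuation space.
#'
#' @param volumes n x k matrix (or data frame) of pipetted volumes in ml;
#'   columns named by basis material.
#' @param basis A [basis_set()] covering all recipe columns.
#' @param noise_sigma Per-energy additive noise SD in 1/cm; scalar or
#'   length 2. Default 0 (noiseless).
#' @param seed Integer seed; the bundle is fully reproducible per seed.
#' @return Object of class `phantom_bundle`: list with `fractions` (n x k
#'   true fractions), `noiseless` and `measurements` (data frames:
#'   `specimen_id`, `mu_low`, `mu_high`), `basis`, `noise_sigma`, `seed`.
#' @export
make_aqueous_cohort <- function(volumes, basis, noise_sigma = 0, seed = 1L) {
  volumes <- as.matrix(volumes)
  stopifnot(is_basis_set(basis))
  if (is.null(colnames(volumes))) {
    stop("volume columns must be named by basis material")
  }
  miss <- setdiff(colnames(volumes), basis$name)
  if (length(miss)) {
    stop("recipe material(s) not in basis: ", paste(miss, collapse = ", "))
  }
  fr <- t(apply(volumes, 1, volumes_to_fractions))
  sub <- basis[match(colnames(volumes), basis$name), ]
  mu <- fr %*% basis_mu_matrix(sub)  # n x 2, exact forward model
  n <- nrow(fr)
  ids <- sprintf("aq%02d", seq_len(n))
  noiseless <- data.frame(specimen_id = ids, mu_low = mu[, 1],
                          mu_high = mu[, 2], stringsAsFactors = FALSE)
  meas <- add_measurement_noise(noiseless, noise_sigma, seed)
  structure(list(fractions = fr, noiseless = noiseless, measurements = meas,
                 basis = basis, noise_sigma = rep(noise_sigma, length.out = 2),
                 seed = seed),
            class = "phantom_bundle")
}

# internal: Gaussian measurement noise, applied to measurements only
add_measurement_noise <- function(noiseless, noise_sigma, seed) {
  sig <- rep(noise_sigma, length.out = 2)
  if (any(sig < 0)) stop("noise_sigma must be >= 0")
  meas <- noiseless
  if (any(sig > 0)) {
    n <- nrow(noiseless)
    eps <- with_local_seed(seed, matrix(stats::rnorm(2 * n), ncol = 2))
    meas$mu_low <- meas$mu_low + sig[1] * eps[, 1]
    meas$mu_high <- meas$mu_high + sig[2] * eps[, 2]
  }
  meas
}

#' Sample clot-like histology compositions
#'
#' Clot constituents appear regionally as clusters, so specimen-level
#' compositions are drawn from a two-mode Dirichlet mixture: a
#' fibrin/platelets-dominant mode and an RBC-dominant mode. The WBC
#' fraction is capped (default 0.15, about the plausible upper end for
#' clots) by rejection.
#'
#' @param n Number of compositions.
#' @param modes List of Dirichlet concentration vectors (length 3, order
#'   material 1..3 = e.g. fibrin, RBC, WBC).
#' @param wbc_index Which component the cap applies to. Default 3.
#' @param wbc_cap Cap on that component. Default 0.15.
#' @param seed Integer seed.
#' @return n x 3 matrix of fractions, rows summing to 1.
#' @export
sample_histology <- function(n,
                             modes = list(c(6, 1.5, 0.4), c(1.5, 6, 0.4)),
                             wbc_index = 3L, wbc_cap = 0.15, seed = 1L) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      alpha <- modes[[(i %% length(modes)) + 1L]]
      repeat {
        g <- stats::rgamma(3, shape = alpha)
        f <- g / sum(g)
        if (f[wbc_index] <= wbc_cap) break
      }
      out[i, ] <- f
    }
    out
  })
}

#' Simulate a clot-like cohort with hidden extra materials
#'
#' Forward-generates specimens made of three histology-visible materials
#' (e.g. fibrin/platelets, RBC, WBC) plus hidden formalin and contrast
#' agent fractions. The measured attenuation is built from the *corrected*
#' basis attenuations (initial values times the true correction factors),
#' so the same bundle exercises both the extra-material correction and the
#' factor calibration:
#' \deqn{\mu^{CT} = (1 - f_{form} - f_{iom}) \mu^{Histo}_{corr}
#'       + f_{form} \mu_{formalin} + f_{iom} \mu_{iomeprol} + noise.}
#'
#' @param n Number of specimens.
#' @param basis A [basis_set()] of the 3 histology materials (initial,
#'   uncorrected attenuation assumptions).
#' @param mu_formalin,mu_iomeprol Attenuation vectors of the two hidden
#'   materials.
#' @param formalin_range,iomeprol_range Length-2 ranges in \[0, 1) from
#'   which the true hidden fractions are drawn uniformly. Defaults: formalin
#'   `c(0.05, 0.4)` (fixed specimens are substantially formalin-soaked),
#'   iomeprol `c(0, 0.065)` (up to ~1.3 mg/ml at a 20 mg/ml stock, the
#'   concentration scale reported for iodine-positive clots).
#' @param correction_factors True length-6 factor vector applied to the
#'   basis attenuations (layout as in [group_cost()]). Default all 1.
#' @param noise_sigma Per-energy additive measurement noise SD (1/cm).
#'   Default 0.
#' @param histology_modes Passed to [sample_histology()].
#' @param seed Integer seed.
#' @return Object of class `phantom_bundle`: list with `histology` (n x 3),
#'   `formalin`, `iomeprol` (true hidden fractions), `correction_factors`,
#'   `composition` (n x 5 full true fractions), `noiseless`,
#'   `measurements`, `basis`, `mu_formalin`, `mu_iomeprol`, `noise_sigma`,
#'   `seed`.
#' @export
make_clot_cohort <- function(n, basis, mu_formalin, mu_iomeprol,
                             formalin_range = c(0.05, 0.4),
                             iomeprol_range = c(0, 0.065),
                             correction_factors = rep(1, 6),
                             noise_sigma = 0,
                             histology_modes = list(c(6, 1.5, 0.4),
                                                    c(1.5, 6, 0.4)),
                             seed = 1L) {
  stopifnot(is_basis_set(basis), nrow(basis) == 3L,
            length(correction_factors) == 6L)
  rng_ok <- function(r) length(r) == 2L && all(r >= 0) && all(r < 1) &&
    r[1] <= r[2]
  if (!rng_ok(formalin_range) || !rng_ok(iomeprol_range) ||
      formalin_range[2] + iomeprol_range[2] >= 1) {
    stop("hidden-fraction ranges must lie in [0, 1) with feasible sum")
  }
  mu_formalin <- as.numeric(mu_formalin)
  mu_iomeprol <- as.numeric(mu_iomeprol)

  histology <- sample_histology(n, modes = histology_modes, seed = seed)
  extras <- with_local_seed(seed + 1L, cbind(
    formalin = stats::runif(n, formalin_range[1], formalin_range[2]),
    iomeprol = stats::runif(n, iomeprol_range[1], iomeprol_range[2])))

  mu_corr <- cbind(correction_factors[1:3] * basis$mu_low,
                   correction_factors[4:6] * basis$mu_high)  # 3 x 2
  hp <- histology %*% mu_corr                                # n x 2
  c_a <- 1 - rowSums(extras)
  mu <- c_a * hp +
    outer(extras[, 1], mu_formalin) + outer(extras[, 2], mu_iomeprol)

  ids <- sprintf("clot%02d", seq_len(n))
  noiseless <- data.frame(specimen_id = ids, mu_low = mu[, 1],
                          mu_high = mu[, 2], stringsAsFactors = FALSE)
  meas <- add_measurement_noise(noiseless, noise_sigma, seed + 2L)

  composition <- cbind(histology * c_a, extras)
  colnames(composition) <- c(basis$name, "formalin", "iomeprol")
  rownames(histology) <- rownames(composition) <- ids
  colnames(histology) <- basis$name

  structure(list(histology = histology,
                 formalin = extras[, 1], iomeprol = extras[, 2],
                 correction_factors = correction_factors,
                 composition = composition,
                 noiseless = noiseless, measurements = meas,
                 basis = basis, mu_formalin = mu_formalin,
                 mu_iomeprol = mu_iomeprol,
                 noise_sigma = rep(noise_sigma, length.out = 2),
                 seed = seed),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  n <- nrow(x$noiseless)
  kind <- if (!is.null(x$histology)) "clot-like" else "aqueous"
  cat(sprintf("Synthetic %s cohort: %d specimens (seed %d, noise SD %g/%g)\n",
              kind, n, x$seed, x$noise_sigma[1], x$noise_sigma[2]))
  invisible(x)
}
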