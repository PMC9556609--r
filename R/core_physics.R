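# Domain types and forward physics: linear attenuation mixing and the
# Hounsfield <-> linear-attenuation conversion.

#' Construct an attenuation vector
#'
#' A two-energy attenuation point: the linear attenuation coefficient of a
#' material (or mixture, or measured ROI mean) at the low and at the high
#' virtual monoenergetic energy, in 1/cm.
#'
#' @param mu_low Linear attenuation coefficient at the low energy (1/cm).
#' @param mu_high Linear attenuation coefficient at the high energy (1/cm).
#' @return Named numeric vector `c(mu_low =, mu_high =)`.
#' @examples
#' mu_vec(0.433, 0.152)
#' @export
mu_vec <- function(mu_low, mu_high) {
  mu <- c(mu_low = as.numeric(mu_low), mu_high = as.numeric(mu_high))
  if (any(!is.finite(mu))) {
    stop("attenuation coefficients must be finite, got (",
         paste(format(mu), collapse = ", "), ")")
  }
  if (any(mu < 0)) {
    stop("attenuation coefficients must be >= 0, got (",
         paste(format(mu), collapse = ", "), ")")
  }
  mu
}

#' Define a set of basis materials
#'
#' A basis set holds the named basis materials of a decomposition together
#' with their linear attenuation coefficients at the two working energies.
#' The two energies are carried along symbolically; nothing in the math
#' depends on their literal values, they only label the attenuation columns.
#'
#' @param name Character vector of unique material names.
#' @param mu_low,mu_high Numeric vectors of linear attenuation coefficients
#'   (1/cm) at the low and high energy, one entry per material.
#' @param stock_concentration Optional numeric vector, stock concentration in
#'   mg/ml for aqueous basis solutions (`NA` where not applicable). Used to
#'   convert recovered volume fractions into concentrations.
#' @param energies Numeric length-2 vector `c(e_low, e_high)` in keV with
#'   `0 < e_low < e_high`. Default `c(50, 200)`.
#' @return An object of class `basis_set`: a data frame with columns `name`,
#'   `mu_low`, `mu_high`, `stock_concentration` and an `energies` attribute.
#' @examples
#' basis_set(c("iomeprol", "eosin", "NaCl"),
#'           mu_low  = c(0.433, 0.290, 0.306),
#'           mu_high = c(0.152, 0.141, 0.151),
#'           stock_concentration = c(20, 40, 200))
#' @export
basis_set <- function(name, mu_low, mu_high, stock_concentration = NULL,
                      energies = c(50, 200)) {
  name <- as.character(name)
  if (length(name) < 2L) stop("a basis set needs at least 2 materials")
  if (anyDuplicated(name)) {
    stop("basis material names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (length(mu_low) != length(name) || length(mu_high) != length(name)) {
    stop("mu_low and mu_high must have one entry per material")
  }
  if (any(!is.finite(mu_low)) || any(!is.finite(mu_high)) ||
      any(mu_low < 0) || any(mu_high < 0)) {
    stop("attenuation coefficients must be finite and >= 0")
  }
  if (length(energies) != 2L || !all(is.finite(energies)) ||
      energies[1] <= 0 || energies[1] >= energies[2]) {
    stop("energies must satisfy 0 < e_low < e_high")
  }
  if (is.null(stock_concentration)) {
    stock_concentration <- rep(NA_real_, length(name))
  }
  if (any(!is.na(stock_concentration) & stock_concentration <= 0)) {
    stop("stock_concentration must be > 0 where present")
  }
  out <- data.frame(name = name,
                    mu_low = as.numeric(mu_low),
                    mu_high = as.numeric(mu_high),
                    stock_concentration = as.numeric(stock_concentration),
                    stringsAsFactors = FALSE)
  attr(out, "energies") <- as.numeric(energies)
  class(out) <- c("basis_set", "data.frame")
  out
}

#' @export
print.basis_set <- function(x, ...) {
  e <- attr(x, "energies")
  cat(sprintf("Basis set: %d materials at (%g, %g) keV\n", nrow(x), e[1], e[2]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @rdname basis_set
#' @param x Object to test or subset.
#' @export
is_basis_set <- function(x) inherits(x, "basis_set")

# keep class + energies attribute when subsetting rows
#' @export
`[.basis_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("name", "mu_low", "mu_high") %in% names(out))) {
    attr(out, "energies") <- attr(x, "energies")
    class(out) <- c("basis_set", "data.frame")
  }
  out
}

# internal: attenuation matrix (n x 2) of a basis set
basis_mu_matrix <- function(basis) {
  m <- cbind(mu_low = basis$mu_low, mu_high = basis$mu_high)
  rownames(m) <- basis$name
  m
}

#' Convert Hounsfield units to linear attenuation
#'
#' Virtual monoenergetic images come calibrated in Hounsfield units (HU),
#' with water at 0 HU and air at -1000 HU. The physics of the decomposition
#' is written in linear attenuation coefficients, so HU values are converted
#' at the input boundary via
#' \deqn{\mu(E) = HU(E) \cdot \mu_{water}(E) / 1000 + \mu_{water}(E)}
#' using the water attenuation at the same energy.
#'
#' @param hu Numeric vector of HU values. Values below -1000 yield negative
#'   attenuation and raise an error unless `allow_negative = TRUE`.
#' @param mu_water Water linear attenuation coefficient at the same energy
#'   (1/cm), strictly positive.
#' @param allow_negative Permit (non-physical) negative results.
#' @return Linear attenuation coefficient(s) in 1/cm.
#' @seealso [mu_to_hu()] for the exact inverse.
#' @examples
#' hu_to_mu(0, 0.2269)      # water maps to itself
#' hu_to_mu(-1000, 0.2269)  # air limit: 0
#' @export
hu_to_mu <- function(hu, mu_water, allow_negative = FALSE) {
  if (any(!is.finite(hu))) stop("HU values must be finite")
  if (!is.finite(mu_water) || mu_water <= 0) {
    stop("mu_water must be a finite positive attenuation in 1/cm")
  }
  mu <- hu * mu_water / 1000 + mu_water
  if (!allow_negative && any(mu < 0)) {
    stop("HU below -1000 gives negative attenuation (min mu = ",
         format(min(mu)), " 1/cm); set allow_negative = TRUE to override")
  }
  mu
}

#' Convert linear attenuation to Hounsfield units
#'
#' Exact algebraic inverse of [hu_to_mu()].
#'
#' @param mu Linear attenuation coefficient(s), 1/cm.
#' @param mu_water Water attenuation at the same energy (1/cm), positive.
#' @return HU value(s).
#' @examples
#' mu_to_hu(0.3266, 0.2269)  # about 439.4 HU
#' @export
mu_to_hu <- function(mu, mu_water) {
  if (any(!is.finite(mu))) stop("attenuation values must be finite")
  if (!is.finite(mu_water) || mu_water <= 0) {
    stop("mu_water must be a finite positive attenuation in 1/cm")
  }
  (mu - mu_water) / mu_water * 1000
}

#' Forward attenuation of a mixture
#'
#' Under the linear mixing model, the attenuation of a mixture at each
#' energy is the volume-fraction weighted sum of the basis attenuations:
#' \deqn{\mu_{E} = \sum_i f_i \, \mu_{i,E}.}
#' The fractions must lie in \[0, 1\] and sum to 1 (volume conservation).
#'
#' @param fractions Numeric vector of volume fractions, one per basis
#'   material, in basis order; or a named vector matching the basis names.
#' @param basis A [basis_set()].
#' @param tol Tolerance on `|sum(fractions) - 1|`. Default `1e-6`.
#' @return Attenuation vector `c(mu_low =, mu_high =)` in 1/cm.
#' @examples
#' b <- basis_set(c("iomeprol", "eosin", "NaCl"),
#'                c(0.433, 0.290, 0.306), c(0.152, 0.141, 0.151))
#' mix_attenuation(c(0.2, 0.3, 0.5), b)
#' @export
mix_attenuation <- function(fractions, basis, tol = 1e-6) {
  stopifnot(is_basis_set(basis))
  if (!is.null(names(fractions))) {
    miss <- setdiff(names(fractions), basis$name)
    if (length(miss)) {
      stop("fractions name(s) not in basis: ", paste(miss, collapse = ", "))
    }
    fractions <- fractions[match(basis$name, names(fractions))]
    fractions[is.na(fractions)] <- 0
  }
  if (length(fractions) != nrow(basis)) {
    stop("expected ", nrow(basis), " fractions (one per basis material), got ",
         length(fractions))
  }
  if (any(!is.finite(fractions))) stop("fractions must be finite")
  if (any(fractions < -tol) || any(fractions > 1 + tol)) {
    stop("fractions must lie in [0, 1]")
  }
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    stop("volume fractions must sum to 1 (got sum = ", format(s),
         ", tolerance ", format(tol), ")")
  }
  mu <- drop(crossprod(basis_mu_matrix(basis), fractions))
  c(mu_low = unname(mu[1]), mu_high = unname(mu[2]))
}
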