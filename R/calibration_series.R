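# Calibration of basis-material attenuation endpoints from aqueous dilution
# series, by per-energy ordinary least squares against concentration.

#' Construct a dilution (concentration) series
#'
#' Measurements of a water-based dilution series of one basis solution: for
#' each prepared concentration, the two-energy attenuation of the mixture.
#' Under the linear mixing model attenuation is affine in concentration,
#' \eqn{\mu(c) = (c/c_{stock}) \mu_{stock} + (1 - c/c_{stock}) \mu_{water}},
#' so a straight-line fit evaluated at the stock concentration determines
#' the basis endpoint with better statistical accuracy than a single
#' measurement of the stock itself.
#'
#' @param material Material name.
#' @param concentration Numeric vector of prepared concentrations (mg/ml),
#'   strictly positive. Replicates (repeated concentrations) are allowed.
#' @param mu_low,mu_high Measured attenuation (1/cm) at each concentration.
#' @param stock_concentration Stock concentration (mg/ml) at which the
#'   endpoint is evaluated; must be `>= max(concentration)`.
#' @return Object of class `dilution_series`.
#' @export
dilution_series <- function(material, concentration, mu_low, mu_high,
                            stock_concentration) {
  concentration <- as.numeric(concentration)
  n <- length(concentration)
  if (n < 3L) stop("a dilution series needs at least 3 points, got ", n)
  if (length(mu_low) != n || length(mu_high) != n) {
    stop("mu_low and mu_high must have one entry per concentration")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be finite and > 0")
  }
  if (!is.finite(stock_concentration) ||
      stock_concentration < max(concentration)) {
    stop("stock_concentration must be >= max(concentration)")
  }
  structure(list(material = as.character(material)[1],
                 concentration = concentration,
                 mu_low = as.numeric(mu_low),
                 mu_high = as.numeric(mu_high),
                 stock_concentration = as.numeric(stock_concentration)),
            class = "dilution_series")
}

#' Fit a dilution series and extrapolate the basis endpoint
#'
#' Two independent ordinary least-squares fits of attenuation against
#' concentration (one per energy). The basis-material endpoint is the fitted
#' line evaluated at the stock concentration; its standard error follows
#' from the parameter covariance. Relative parameter errors are reported in
#' percent, `100 * |SE / estimate|`.
#'
#' @param series A [dilution_series()].
#' @return Object of class `dilution_fit` with elements:
#'   \describe{
#'     \item{material, stock_concentration}{copied from the input.}
#'     \item{coefficients}{data frame per energy: `slope` (1/cm per mg/ml),
#'       `intercept` (1/cm), their standard errors and relative errors (%).}
#'     \item{endpoint}{attenuation vector at the stock concentration.}
#'     \item{endpoint_se}{standard error of the endpoint per energy.}
#'     \item{residual_ss}{per-energy residual sum of squares.}
#'   }
#' @examples
#' s <- dilution_series("iomeprol", c(1, 5, 10, 15, 20),
#'                      mu_low  = 0.2269 + (0.433 - 0.2269) / 20 * c(1, 5, 10, 15, 20),
#'                      mu_high = 0.1370 + (0.152 - 0.1370) / 20 * c(1, 5, 10, 15, 20),
#'                      stock_concentration = 20)
#' fit_series(s)$endpoint
#' @export
fit_series <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  conc <- series$concentration
  if (stats::var(conc) == 0) {
    stop("degenerate design: all concentrations identical, cannot fit a line")
  }
  fit_one <- function(mu) {
    X <- cbind(1, conc)
    fit <- stats::lm.fit(X, mu)
    cf <- fit$coefficients
    rss <- sum(fit$residuals^2)
    df <- length(mu) - 2L
    # parameter covariance computed directly so that exact (zero-residual)
    # fits report zero standard errors without special-casing
    sigma2 <- if (df > 0L) rss / df else 0
    V <- sigma2 * chol2inv(chol(crossprod(X)))
    x0 <- c(1, series$stock_concentration)
    endpoint <- sum(cf * x0)
    endpoint_var <- drop(t(x0) %*% V %*% x0)
    se <- sqrt(pmax(diag(V), 0))
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         intercept_se = unname(se[1]), slope_se = unname(se[2]),
         endpoint = endpoint, endpoint_se = sqrt(max(endpoint_var, 0)),
         residual_ss = rss)
  }
  lo <- fit_one(series$mu_low)
  hi <- fit_one(series$mu_high)
  rel <- function(se, est) if (est == 0) NA_real_ else 100 * abs(se / est)
  coefs <- data.frame(
    energy = c("low", "high"),
    slope = c(lo$slope, hi$slope),
    slope_se = c(lo$slope_se, hi$slope_se),
    slope_rel_err_pct = c(rel(lo$slope_se, lo$slope),
                          rel(hi$slope_se, hi$slope)),
    intercept = c(lo$intercept, hi$intercept),
    intercept_se = c(lo$intercept_se, hi$intercept_se),
    intercept_rel_err_pct = c(rel(lo$intercept_se, lo$intercept),
                              rel(hi$intercept_se, hi$intercept)),
    stringsAsFactors = FALSE)
  structure(list(material = series$material,
                 stock_concentration = series$stock_concentration,
                 coefficients = coefs,
                 endpoint = c(mu_low = lo$endpoint, mu_high = hi$endpoint),
                 endpoint_se = c(mu_low = lo$endpoint_se,
                                 mu_high = hi$endpoint_se),
                 residual_ss = c(mu_low = lo$residual_ss,
                                 mu_high = hi$residual_ss),
                 n = length(conc)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("Dilution fit for %s (n = %d, stock %g mg/ml)\n",
              x$material, x$n, x$stock_concentration))
  cat(sprintf("  endpoint: mu_low = %.4f, mu_high = %.4f 1/cm (SE %.2g, %.2g)\n",
              x$endpoint[1], x$endpoint[2], x$endpoint_se[1], x$endpoint_se[2]))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Diagnostic: do the dilution regressions pass through water?
#'
#' All series are water-based, so every fitted line, extrapolated to zero
#' concentration, should pass through the attenuation point of pure water;
#' systematic deviations indicate pipetting/volume-excess or calibration
#' errors. This check reports, per material, the absolute per-energy
#' distance of the fitted intercept from the supplied water point, plus the
#' scatter of the pairwise intersection points of the fitted lines in the
#' (mu_low, mu_high) plane. Purely diagnostic: it never raises on
#' disagreement.
#'
#' @param fits List of [fit_series()] results (at least 2).
#' @param water_mu Attenuation vector of pure water, `c(mu_low, mu_high)`.
#' @return List with `intercept_distance` (data frame: material, per-energy
#'   absolute intercept-to-water distance in 1/cm), `intersections` (data
#'   frame of pairwise line intersection points in the attenuation plane,
#'   with their Euclidean distance to the water point), and
#'   `max_pairwise_scatter` (largest distance between two intersection
#'   points).
#' @export
water_intersection_check <- function(fits, water_mu) {
  if (length(fits) < 2L) stop("need at least 2 regressions")
  stopifnot(all(vapply(fits, inherits, logical(1), "dilution_fit")))
  water_mu <- as.numeric(water_mu)

  icpt <- t(vapply(fits, function(f) {
    c(f$coefficients$intercept[1], f$coefficients$intercept[2])
  }, numeric(2)))
  dist_df <- data.frame(
    material = vapply(fits, `[[`, character(1), "material"),
    d_low = abs(icpt[, 1] - water_mu[1]),
    d_high = abs(icpt[, 2] - water_mu[2]),
    stringsAsFactors = FALSE)

  # each series traces the attenuation-plane line
  #   (intercept_low + slope_low * c, intercept_high + slope_high * c);
  # intersect them pairwise by solving for the two concentrations.
  pts <- list()
  for (a in seq_along(fits)) for (b in seq_along(fits)) {
    if (a >= b) next
    ca <- fits[[a]]$coefficients; cb <- fits[[b]]$coefficients
    A <- cbind(c(ca$slope[1], ca$slope[2]), -c(cb$slope[1], cb$slope[2]))
    rhs <- c(cb$intercept[1] - ca$intercept[1],
             cb$intercept[2] - ca$intercept[2])
    if (abs(det(A)) < .Machine$double.eps * 100) next  # parallel lines
    cc <- solve(A, rhs)
    p <- c(ca$intercept[1] + ca$slope[1] * cc[1],
           ca$intercept[2] + ca$slope[2] * cc[1])
    pts[[length(pts) + 1L]] <- data.frame(
      material_a = fits[[a]]$material, material_b = fits[[b]]$material,
      mu_low = p[1], mu_high = p[2],
      dist_to_water = sqrt(sum((p - water_mu)^2)),
      stringsAsFactors = FALSE)
  }
  inter <- if (length(pts)) do.call(rbind, pts) else
    data.frame(material_a = character(), material_b = character(),
               mu_low = numeric(), mu_high = numeric(),
               dist_to_water = numeric())
  scatter <- 0
  if (nrow(inter) > 1L) {
    xy <- as.matrix(inter[, c("mu_low", "mu_high")])
    scatter <- max(stats::dist(xy))
  }
  list(intercept_distance = dist_df, intersections = inter,
       max_pairwise_scatter = scatter)
}
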