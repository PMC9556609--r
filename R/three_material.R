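# Closed-form three-material decomposition under volume conservation.

#' Build the 3x3 decomposition system matrix
#'
#' Rows are the basis attenuations at the low energy, at the high energy,
#' and a row of ones expressing volume conservation; columns follow the
#' basis order. Solving this system against `(mu_low, mu_high, 1)` gives
#' the three volume fractions.
#'
#' @param basis A [basis_set()] of exactly 3 materials.
#' @return 3x3 numeric matrix with material names as column names.
#' @export
system_matrix <- function(basis) {
  stopifnot(is_basis_set(basis))
  if (nrow(basis) != 3L) {
    stop("three-material decomposition needs exactly 3 basis materials, got ",
         nrow(basis))
  }
  m <- rbind(basis$mu_low, basis$mu_high, rep(1, 3))
  dimnames(m) <- list(c("mu_low", "mu_high", "volume"), basis$name)
  m
}

#' Three-material decomposition of one measurement
#'
#' Solves the linear system of the two-energy mixing model plus volume
#' conservation for the three volume fractions. The fractions always sum to
#' 1 (to round-off); individual fractions may fall outside \[0, 1\] when the
#' measured point lies outside the triangle spanned by the three basis
#' points in the attenuation plane. Such solutions are returned as computed,
#' flagged via `in_gamut = FALSE`, rather than clamped: the out-of-triangle
#' geometry is meaningful (it is what the extra-material correction
#' exploits).
#'
#' @param mu_ct Measured attenuation vector `c(mu_low, mu_high)` in 1/cm.
#' @param basis A [basis_set()] of exactly 3 materials.
#' @param max_condition Conditioning ceiling for the system matrix; above
#'   it the basis is treated as linearly dependent and an error is raised.
#'   Default `1e8`.
#' @param gamut_tol Tolerance when flagging fractions outside \[0, 1\].
#' @return Object of class `three_material_fit`: list with `fractions`
#'   (named, sums to 1), `in_gamut`, `residual` (length-3 residual of the
#'   augmented system, ~0 for an exact solve), and `condition` (condition
#'   number of the system matrix).
#' @examples
#' b <- basis_set(c("iomeprol", "eosin", "NaCl"),
#'                c(0.433, 0.290, 0.306), c(0.152, 0.141, 0.151))
#' solve_three_material(c(0.3266, 0.1482), b)$fractions
#' @export
solve_three_material <- function(mu_ct, basis, max_condition = 1e8,
                                 gamut_tol = 1e-9) {
  A <- system_matrix(basis)
  mu_ct <- as.numeric(mu_ct)
  if (length(mu_ct) != 2L || any(!is.finite(mu_ct))) {
    stop("mu_ct must be a finite attenuation pair c(mu_low, mu_high)")
  }
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    stop("basis materials are (near-)linearly dependent: condition number ",
         format(cond, digits = 4), " exceeds ceiling ", format(max_condition))
  }
  b <- c(mu_ct, 1)
  f <- drop(solve(A, b))
  names(f) <- basis$name
  residual <- drop(A %*% f) - b
  structure(list(fractions = f,
                 in_gamut = all(f >= -gamut_tol & f <= 1 + gamut_tol),
                 residual = residual,
                 condition = cond),
            class = "three_material_fit")
}

#' @export
print.three_material_fit <- function(x, ...) {
  cat("Three-material decomposition\n")
  print(round(x$fractions, 6))
  cat(sprintf("  in gamut: %s; condition number: %.3g\n",
              x$in_gamut, x$condition))
  invisible(x)
}

#' Decompose a table of measurements
#'
#' Vectorized convenience wrapper around [solve_three_material()] for a
#' measurement table.
#'
#' @param measurements Data frame with columns `specimen_id`, `mu_low`,
#'   `mu_high` (1/cm), e.g. from [read_measurements()].
#' @param basis A [basis_set()] of exactly 3 materials.
#' @param ... Passed to [solve_three_material()].
#' @return Data frame: `specimen_id`, one fraction column per basis
#'   material, and `in_gamut`.
#' @export
decompose_specimens <- function(measurements, basis, ...) {
  stopifnot(all(c("specimen_id", "mu_low", "mu_high") %in% names(measurements)))
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    fit <- solve_three_material(
      c(measurements$mu_low[i], measurements$mu_high[i]), basis, ...)
    cbind(data.frame(specimen_id = measurements$specimen_id[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fit$fractions)),
          data.frame(in_gamut = fit$in_gamut))
  })
  do.call(rbind, rows)
}
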