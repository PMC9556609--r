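# Joint calibration of basis-material attenuation correction factors and
# per-specimen formalin fractions over specimen groups, plus inverse-cost
# weighted aggregation across groups.
#
# Factor layout (length 6, matching the corrected system matrix):
#   c[1:3] multiply the low-energy attenuations of materials 1..3,
#   c[4:6] multiply the high-energy attenuations of materials 1..3.

#' Remove a known fourth material from a measured attenuation
#'
#' If a fraction `f4` of the specimen volume is a material with known
#' attenuation `mu4` (here: formalin), the attenuation of the remaining
#' mixture is
#' \deqn{\mu' = (\mu^{CT} - \tilde f_4 \mu_4) / (1 - \tilde f_4),}
#' the exact inverse of mixing `f4` of that material into it.
#'
#' @param mu_ct Measured attenuation vector `c(mu_low, mu_high)`.
#' @param f4 Volume fraction of the fourth material, `0 <= f4 < 1`.
#' @param mu4 Attenuation vector of the fourth material.
#' @return Adjusted attenuation vector.
#' @export
adjust_for_fourth_material <- function(mu_ct, f4, mu4) {
  if (!is.finite(f4) || f4 < 0 || f4 >= 1) {
    stop("fourth-material fraction must satisfy 0 <= f4 < 1, got ", f4)
  }
  mu_ct <- as.numeric(mu_ct); mu4 <- as.numeric(mu4)
  out <- (mu_ct - f4 * mu4) / (1 - f4)
  c(mu_low = out[1], mu_high = out[2])
}

# internal: corrected system matrix M(c): attenuation rows scaled by the
# six factors plus the volume-conservation row of ones.
corrected_system_matrix <- function(correction, basis) {
  rbind(correction[1:3] * basis$mu_low,
        correction[4:6] * basis$mu_high,
        rep(1, 3))
}

# internal: coerce specimen inputs (matrices) and validate shapes
check_group_inputs <- function(mu_ct, histology) {
  mu_ct <- as.matrix(mu_ct); histology <- as.matrix(histology)
  if (ncol(mu_ct) != 2L) stop("mu_ct must be an n x 2 matrix")
  if (ncol(histology) != 3L) stop("histology must be an n x 3 matrix")
  if (nrow(mu_ct) != nrow(histology)) {
    stop("mu_ct and histology must describe the same specimens")
  }
  if (nrow(mu_ct) < 1L) stop("need at least one specimen")
  sums <- rowSums(histology)
  if (any(abs(sums - 1) > 5e-3)) {
    stop("histology rows must sum to 1; offending row(s): ",
         paste(which(abs(sums - 1) > 5e-3), collapse = ", "))
  }
  list(mu_ct = mu_ct, histology = histology / sums)
}

#' Calibration cost of a specimen group
#'
#' For each specimen the measured point, adjusted for its formalin
#' fraction, should equal the corrected system matrix applied to its
#' histology composition. The cost is the summed squared l2 norm of these
#' residuals (the volume-conservation component is identically zero when
#' histology sums to 1):
#' \deqn{L = \sum_j \| (\mu'_j, 1) - M(c) f_j^{Histo} \|_2^2.}
#'
#' @param correction Length-6 factor vector (see layout note above).
#' @param f4 Per-specimen formalin fractions, each in \[0, 1).
#' @param mu_ct n x 2 matrix of measured attenuations.
#' @param histology n x 3 matrix of histology fractions (rows sum to 1).
#' @param basis A [basis_set()] of the 3 histology materials holding the
#'   initial (uncorrected) attenuation assumptions.
#' @param mu_formalin Attenuation vector of formalin.
#' @return Scalar cost (units of (1/cm)^2).
#' @export
group_cost <- function(correction, f4, mu_ct, histology, basis, mu_formalin) {
  stopifnot(is_basis_set(basis), nrow(basis) == 3L, length(correction) == 6L)
  inp <- check_group_inputs(mu_ct, histology)
  n <- nrow(inp$mu_ct)
  if (length(f4) != n) stop("need one formalin fraction per specimen")
  if (any(f4 < 0 | f4 >= 1)) stop("formalin fractions must lie in [0, 1)")
  M <- corrected_system_matrix(correction, basis)
  total <- 0
  for (j in seq_len(n)) {
    mu_p <- adjust_for_fourth_material(inp$mu_ct[j, ], f4[j], mu_formalin)
    r <- c(mu_p, 1) - drop(M %*% inp$histology[j, ])
    total <- total + sum(r * r)
  }
  total
}

# internal: closed-form formalin profile. With u = 1/(1 - f4), the adjusted
# point is mu_f + u (mu_ct - mu_f), linear in u; project the model point
# onto that ray and clip u to [1, 1/(1 - f4_max)].
profile_f4 <- function(mu_ct_row, target, mu_formalin, f4_max) {
  d <- mu_ct_row - mu_formalin
  den <- sum(d * d)
  u <- if (den == 0) 1 else sum((target - mu_formalin) * d) / den
  u <- min(max(u, 1), 1 / (1 - f4_max))
  1 - 1 / u
}

# internal: per-specimen residual vector with the formalin fraction
# profiled out. The volume-conservation residual component is identically
# zero (histology rows sum to 1) and is omitted.
profiled_residuals <- function(correction, inp, basis, mu_formalin, f4_max) {
  M <- corrected_system_matrix(correction, basis)
  n <- nrow(inp$mu_ct)
  out <- numeric(2 * n)
  for (j in seq_len(n)) {
    target <- drop(M %*% inp$histology[j, ])[1:2]
    f4 <- profile_f4(inp$mu_ct[j, ], target, mu_formalin, f4_max)
    mu_p <- adjust_for_fourth_material(inp$mu_ct[j, ], f4, mu_formalin)
    out[(2 * j - 1):(2 * j)] <- mu_p - target
  }
  out
}

#' Calibrate correction factors for one specimen group
#'
#' Jointly fits the six multiplicative attenuation correction factors and
#' one formalin fraction per specimen by minimizing [group_cost()] over a
#' bounded box. The cost is neither linear nor convex in the joint
#' parameters, so a global-then-local scheme is used: the formalin
#' fraction of each specimen is profiled out in closed form (the adjusted
#' point moves linearly along the ray from formalin through the measured
#' point), and the remaining bounded problem in the free factors is solved
#' by Levenberg-Marquardt least squares from multiple starts drawn over
#' the factor box (plus the all-ones start), keeping the best minimum.
#' Results are reproducible for a fixed `seed`.
#'
#' Any factor can be frozen via `fixed` (convention for clots: both WBC
#' factors fixed at 1, since WBC contributes little attenuation and the
#' problem dimension must stay small).
#'
#' @param mu_ct n x 2 matrix of measured attenuations (1/cm).
#' @param histology n x 3 matrix of histology fractions (rows sum to 1),
#'   columns in basis order.
#' @param basis A [basis_set()] of the 3 histology materials (initial
#'   attenuation assumptions).
#' @param mu_formalin Attenuation vector of formalin.
#' @param fixed Length-6 numeric; `NA` marks a free factor, a number
#'   freezes that factor at the given value. Default: all free.
#' @param control List of optimizer settings: `n_starts` (default 12),
#'   `seed` (default 1), `bounds_c` (default `c(0.25, 5)`), `f4_max`
#'   (default 0.999), `maxit` Levenberg-Marquardt iteration cap per start
#'   (default 500), `target_cost` early-exit level once a start reaches a
#'   (numerically) zero-cost optimum (default 1e-18).
#' @param group_id Optional label stored with the result.
#' @return Object of class `group_calibration`: list with `correction`
#'   (length 6; frozen entries exactly their fixed value),
#'   `formalin_fractions`, `cost_value`, `fixed`, `group_id`, `n_specimens`,
#'   `starts_used`.
#' @export
optimize_group <- function(mu_ct, histology, basis, mu_formalin,
                           fixed = rep(NA_real_, 6), control = list(),
                           group_id = NULL) {
  stopifnot(is_basis_set(basis), nrow(basis) == 3L, length(fixed) == 6L)
  inp <- check_group_inputs(mu_ct, histology)
  n <- nrow(inp$mu_ct)
  ctl <- utils::modifyList(list(n_starts = 12L, seed = 1L,
                                bounds_c = c(0.25, 5), f4_max = 0.999,
                                maxit = 500L, target_cost = 1e-18), control)
  mu_formalin <- as.numeric(mu_formalin)
  free_idx <- which(is.na(fixed))

  full_correction <- function(free_vals) {
    correction <- ifelse(is.na(fixed), 1, fixed)
    correction[free_idx] <- free_vals
    correction
  }
  best_f4_given <- function(correction) {
    M <- corrected_system_matrix(correction, basis)
    vapply(seq_len(n), function(j) {
      target <- drop(M %*% inp$histology[j, ])[1:2]
      profile_f4(inp$mu_ct[j, ], target, mu_formalin, ctl$f4_max)
    }, numeric(1))
  }
  refine <- function(free_vals) {
    if (!length(free_idx)) {
      correction <- full_correction(numeric(0))
      f4 <- best_f4_given(correction)
      return(list(correction = correction, f4 = f4,
                  cost = group_cost(correction, f4, inp$mu_ct, inp$histology,
                                    basis, mu_formalin)))
    }
    fit <- minpack.lm::nls.lm(
      par = free_vals,
      fn = function(p) profiled_residuals(full_correction(p), inp, basis,
                                          mu_formalin, ctl$f4_max),
      lower = rep(ctl$bounds_c[1], length(free_idx)),
      upper = rep(ctl$bounds_c[2], length(free_idx)),
      control = minpack.lm::nls.lm.control(maxiter = ctl$maxit,
                                           ftol = 1e-15, ptol = 1e-15))
    correction <- full_correction(fit$par)
    list(correction = correction, f4 = best_f4_given(correction),
         cost = sum(fit$fvec^2))
  }

  # deterministic multistart without disturbing the caller's RNG stream
  starts <- matrix(1, nrow = 1, ncol = length(free_idx))
  if (length(free_idx) && ctl$n_starts > 1L) {
    extra <- with_local_seed(ctl$seed, matrix(
      stats::runif((ctl$n_starts - 1L) * length(free_idx),
                   ctl$bounds_c[1], ctl$bounds_c[2]),
      ncol = length(free_idx)))
    starts <- rbind(starts, extra)
  }

  best <- NULL
  used <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- refine(starts[s, ])
    used <- used + 1L
    if (is.null(best) || res$cost < best$cost) best <- res
    if (best$cost <= ctl$target_cost) break
  }

  structure(list(correction = best$correction,
                 formalin_fractions = best$f4,
                 cost_value = best$cost,
                 fixed = fixed,
                 group_id = group_id,
                 n_specimens = n,
                 starts_used = used),
            class = "group_calibration")
}

#' @export
print.group_calibration <- function(x, ...) {
  cat(sprintf("Group calibration%s: %d specimens, cost = %.4g\n",
              if (is.null(x$group_id)) "" else paste0(" [", x$group_id, "]"),
              x$n_specimens, x$cost_value))
  cat("  factors (low):", sprintf("%.4f", x$correction[1:3]), "\n")
  cat("  factors (high):", sprintf("%.4f", x$correction[4:6]), "\n")
  cat("  formalin fractions:", sprintf("%.4f", x$formalin_fractions), "\n")
  invisible(x)
}

#' Aggregate group calibrations by inverse-cost weighting
#'
#' Groups that reached a lower cost minimum fit the linear model better and
#' are trusted more: the final factor estimate is the mean of the group
#' factors weighted by the inverse of each group's cost value. The weight
#' normalization makes the result invariant to the (arbitrary) scale of the
#' cost. A group with (numerically) zero cost would dominate; its weight is
#' capped via `cost_floor`.
#'
#' @param groups List of [optimize_group()] results (or any lists with
#'   `correction` and `cost_value`).
#' @param basis Optional [basis_set()] of the initial attenuations; when
#'   given, the final corrected attenuation table (initial x weighted
#'   factor) is included.
#' @param cost_floor Costs below this are raised to it before inversion
#'   (weight cap). Default `1e-12`.
#' @return Object of class `calibration_summary`: list with `correction`
#'   (length-6 weighted means), `weights` (normalized), `group_factors`
#'   (matrix), `cost_values`, and (if `basis` given) `attenuation`: data
#'   frame of final corrected attenuations per material and energy.
#' @examples
#' gs <- list(list(correction = c(0.9128, 3.7418, 1, 0.8657, 3.7399, 1),
#'                 cost_value = 0.9),
#'            list(correction = c(0.9836, 3.6263, 1, 0.9401, 3.6118, 1),
#'                 cost_value = 1.4),
#'            list(correction = c(0.9180, 3.9191, 1, 0.8736, 3.9229, 1),
#'                 cost_value = 0.8))
#' aggregate_groups(gs)$correction
#' @export
aggregate_groups <- function(groups, basis = NULL, cost_floor = 1e-12) {
  if (!length(groups)) stop("no groups to aggregate")
  fac <- t(vapply(groups, function(g) as.numeric(g$correction), numeric(6)))
  costs <- vapply(groups, function(g) as.numeric(g$cost_value), numeric(1))
  if (any(costs < 0)) stop("cost values must be >= 0")
  w <- 1 / pmax(costs, cost_floor)
  w <- w / sum(w)
  correction <- drop(crossprod(fac, w))
  out <- list(correction = correction, weights = w, group_factors = fac,
              cost_values = costs)
  if (!is.null(basis)) {
    stopifnot(is_basis_set(basis), nrow(basis) == 3L)
    out$attenuation <- data.frame(
      name = basis$name,
      mu_low = basis$mu_low * correction[1:3],
      mu_high = basis$mu_high * correction[4:6],
      stringsAsFactors = FALSE)
  }
  structure(out, class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf("Calibration summary over %d groups\n", nrow(x$group_factors)))
  cat("  weights:", sprintf("%.4f", x$weights), "\n")
  cat("  weighted factors (low):", sprintf("%.4f", x$correction[1:3]), "\n")
  cat("  weighted factors (high):", sprintf("%.4f", x$correction[4:6]), "\n")
  if (!is.null(x$attenuation)) {
    cat("  corrected attenuation (1/cm):\n")
    print(x$attenuation, row.names = FALSE)
  }
  invisible(x)
}
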