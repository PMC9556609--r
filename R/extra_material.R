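# Histology-anchored correction: recover the volume fractions of one or two
# materials invisible to histology (contrast agent, fixative) from the
# mismatch between the histology-implied attenuation point and the measured
# CT point, then renormalize to a full 4- or 5-material composition.

#' Validate a histology fraction triple
#'
#' Histology reports the area (taken as volume) fractions of exactly three
#' constituents (for clots: RBC, WBC, fibrin/platelets). Each must be in
#' \[0, 1\] and they must sum to 1.
#'
#' @param fractions Named numeric vector of length 3; names are material
#'   names.
#' @param tol Tolerance on `|sum - 1|`. Default `5e-3` (three-decimal
#'   tables); values within tolerance are renormalized to sum exactly 1.
#' @return Named numeric vector summing to 1.
#' @export
histology_fractions <- function(fractions, tol = 5e-3) {
  if (length(fractions) != 3L) {
    stop("histology fractions must have exactly 3 components, got ",
         length(fractions))
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("histology fractions must be named by material")
  }
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("histology fractions must lie in [0, 1]")
  }
  s <- sum(fractions)
  if (abs(s - 1) > tol) {
    stop("histology fractions must sum to 1 (got sum = ", format(s), ")")
  }
  fractions / s
}

#' Attenuation point implied by the histology composition
#'
#' The linear mixing model restricted to the three histology materials:
#' the attenuation the specimen would have if it consisted only of the
#' constituents histology can see.
#'
#' @param histo Named histology fractions ([histology_fractions()]).
#' @param basis A [basis_set()] containing (at least) those materials.
#' @return Attenuation vector `c(mu_low, mu_high)` in 1/cm.
#' @export
histology_point <- function(histo, basis) {
  stopifnot(is_basis_set(basis))
  histo <- histology_fractions(histo)
  miss <- setdiff(names(histo), basis$name)
  if (length(miss)) {
    stop("histology material(s) not in basis: ", paste(miss, collapse = ", "))
  }
  idx <- match(names(histo), basis$name)
  mu <- drop(crossprod(basis_mu_matrix(basis)[idx, , drop = FALSE], histo))
  c(mu_low = unname(mu[1]), mu_high = unname(mu[2]))
}

#' Shift the histology point by extra-material fractions
#'
#' Moving a fraction `f_k` of the specimen volume from the histology
#' mixture to extra material k shifts the attenuation point along that
#' material's characteristic direction:
#' \deqn{\mu' = \mu^{Histo} - \sum_k \tilde f_k (\mu^{Histo} - \mu_k).}
#' At `f_k = 1` the point would coincide with the pure extra material.
#'
#' @param histo_point Attenuation vector of the histology mixture.
#' @param extra_fractions Numeric vector of extra-material volume fractions,
#'   each `>= 0`, with `sum < 1`.
#' @param extra_mu Matrix (n_extra x 2) of extra-material attenuations, or a
#'   length-2 vector for a single extra.
#' @return Shifted attenuation vector `c(mu_low, mu_high)`.
#' @export
corrected_point <- function(histo_point, extra_fractions, extra_mu) {
  histo_point <- as.numeric(histo_point)
  if (is.null(dim(extra_mu))) extra_mu <- matrix(extra_mu, nrow = 1)
  extra_mu <- as.matrix(extra_mu)
  k <- length(extra_fractions)
  if (nrow(extra_mu) != k) {
    stop("need one attenuation row per extra fraction")
  }
  if (any(extra_fractions < 0) || sum(extra_fractions) >= 1) {
    stop("extra fractions must be >= 0 with sum < 1")
  }
  shift <- colSums(extra_fractions * sweep(extra_mu, 2, histo_point))
  out <- histo_point + shift
  c(mu_low = out[1], mu_high = out[2])
}

#' Renormalize a histology composition after adding extra materials
#'
#' With extra fractions `f_k` taking up part of the volume, the histology
#' fractions are scaled by `c_a = 1 - sum(f_k)` and the extras appended, so
#' the full composition again sums to 1.
#'
#' @param histo Named histology fractions.
#' @param extra_fractions Named numeric vector of extra fractions (each
#'   `>= 0`, sum `< 1`).
#' @return Named fraction vector over `3 + n` materials, summing to 1.
#' @examples
#' renormalize_composition(
#'   c(RBC = 0.5, WBC = 0.3, fibrin = 0.2), c(formalin = 0.2))
#' @export
renormalize_composition <- function(histo, extra_fractions) {
  histo <- histology_fractions(histo)
  if (any(extra_fractions < 0) || sum(extra_fractions) >= 1) {
    stop("extra fractions must be >= 0 with sum < 1")
  }
  c_a <- 1 - sum(extra_fractions)
  c(histo * c_a, extra_fractions)
}

#' Per-energy relative matching error
#'
#' Relative difference in percent between the optimized (shifted) point and
#' the measured CT point, reported separately at each energy:
#' `100 * |optimized - measured| / measured`.
#'
#' @param optimized,measured Attenuation vectors `c(mu_low, mu_high)`.
#' @return Named vector of percent errors.
#' @export
matching_error <- function(optimized, measured) {
  optimized <- as.numeric(optimized); measured <- as.numeric(measured)
  if (any(measured <= 0)) stop("measured attenuation must be > 0")
  err <- 100 * abs(optimized - measured) / measured
  c(mu_low = err[1], mu_high = err[2])
}

#' Convert a volume fraction of an aqueous basis to a concentration
#'
#' For aqueous basis solutions the recovered volume fraction of the stock
#' solution corresponds to the concentration `fraction * stock` in the
#' specimen.
#'
#' @param fraction Volume fraction(s) in \[0, 1\].
#' @param material A single-row subset of a [basis_set()] (or any list/row
#'   with a `stock_concentration` field), or a numeric stock concentration
#'   in mg/ml.
#' @return Concentration(s) in mg/ml.
#' @examples
#' fraction_to_concentration(0.25, 20)   # 5 mg/ml
#' @export
fraction_to_concentration <- function(fraction, material) {
  stock <- if (is.numeric(material)) material else material$stock_concentration
  if (length(stock) != 1L || !is.finite(stock)) {
    stop("material has no stock concentration configured")
  }
  if (stock <= 0) stop("stock concentration must be > 0")
  fraction * stock
}

#' Relative error in percent
#'
#' `100 * |estimated - true| / true`; used to report concentration recovery
#' accuracy.
#'
#' @param true_value Reference value (nonzero).
#' @param estimated_value Estimate.
#' @return Percent error.
#' @examples
#' relative_error_pct(1.66, 1.72)  # 3.61 %
#' @export
relative_error_pct <- function(true_value, estimated_value) {
  if (any(true_value == 0)) stop("relative error undefined for true value 0")
  100 * abs(estimated_value - true_value) / abs(true_value)
}

# internal: constrained least squares  min ||b - A f||^2,  f >= 0,
# sum(f) <= smax, for 1 or 2 columns. Exact active-set enumeration.
cls_box_simplex <- function(A, b, smax) {
  k <- ncol(A)
  cost_of <- function(f) sum((b - drop(A %*% f))^2)
  clamp1 <- function(v, g) {
    # 1D minimizer of ||b - v t||^2 on [0, g]
    den <- sum(v * v)
    t <- if (den == 0) 0 else sum(v * b) / den
    min(max(t, 0), g)
  }
  if (k == 1L) {
    f <- clamp1(A[, 1], smax)
    return(list(f = f, cost = cost_of(f)))
  }
  cands <- list()
  G <- crossprod(A)
  if (abs(det(G)) > .Machine$double.eps * max(diag(G))^2) {
    fu <- drop(solve(G, crossprod(A, b)))
    if (all(fu >= 0) && sum(fu) <= smax) cands <- c(cands, list(fu))
  }
  # edges f1 = 0 and f2 = 0
  cands <- c(cands, list(c(0, clamp1(A[, 2], smax))),
                    list(c(clamp1(A[, 1], smax), 0)))
  # edge sum(f) = smax: f = (t, smax - t), t in [0, smax]
  d <- A[, 1] - A[, 2]
  den <- sum(d * d)
  t <- if (den == 0) 0 else sum(d * (b - smax * A[, 2])) / den
  t <- min(max(t, 0), smax)
  cands <- c(cands, list(c(t, smax - t)))
  costs <- vapply(cands, cost_of, numeric(1))
  best <- which.min(costs)
  list(f = cands[[best]], cost = costs[best])
}

#' Recover extra-material fractions from the CT/histology mismatch
#'
#' The core correction: histology fixes the relative composition of its
#' three visible materials, which implies the attenuation point
#' `histology_point()`. The measured CT point differs because the specimen
#' additionally contains 1 or 2 materials histology cannot see (here:
#' iodinated contrast agent and/or formalin). Their volume fractions
#' \eqn{\tilde f_k} are recovered by minimizing
#' \deqn{\| (\mu^{Histo} - \mu^{CT}) -
#'        \sum_k \tilde f_k (\mu^{Histo} - \mu_k) \|_2^2}
#' subject to \eqn{\tilde f_k \ge 0} and \eqn{\sum_k \tilde f_k \le 1 -
#' \epsilon}. With two extras whose characteristic directions are linearly
#' independent and an interior optimum, the cost is exactly zero (two
#' vectors span the attenuation plane). When the unconstrained two-extra
#' solution would need a negative fraction, the fit reduces to the boundary
#' (typically: formalin-only correction), which is where nonzero matching
#' errors arise.
#'
#' The problem is a 1- or 2-variable constrained linear least squares and
#' is solved exactly by active-set enumeration; no iterative optimizer is
#' involved.
#'
#' @param mu_ct Measured attenuation vector `c(mu_low, mu_high)` in 1/cm.
#' @param histo Named histology fractions over 3 materials.
#' @param basis A [basis_set()] containing the histology materials.
#' @param extras A [basis_set()] (or subset rows) of 1 or 2 extra materials.
#' @param eps Keeps `sum(f_k) <= 1 - eps` so the renormalizer
#'   `c_s = 1 / c_a` stays finite. Default `1e-6`.
#' @param collinear_tol Relative tolerance below which two characteristic
#'   directions are treated as collinear (degenerate geometry). Default
#'   `1e-10`.
#' @return Object of class `correction_result`: list with
#'   `extra_fractions` (named), `c_a`, `c_s`, `composition` (full fraction
#'   vector over 3 + n materials, sums to 1), `histology_point`,
#'   `optimized_point`, `path_vectors` (n x 2 matrix, the scaled
#'   characteristic vectors \eqn{\tilde f_k (\mu_k - \mu^{Histo})}),
#'   `matching_error_pct`, and `cost_value`.
#' @examples
#' b <- basis_set(c("fibrin", "RBC", "WBC", "formalin", "iomeprol"),
#'                c(0.2693, 0.2769, 0.2230, 0.229, 0.433),
#'                c(0.1636, 0.1703, 0.1361, 0.138, 0.152))
#' histo <- c(fibrin = 0.6, RBC = 0.35, WBC = 0.05)
#' truth <- corrected_point(histology_point(histo, b), c(0.2, 0.03),
#'                          basis_mu <- rbind(c(0.229, 0.138), c(0.433, 0.152)))
#' fit_extra_fractions(truth, histo, b, b[b$name %in% c("formalin", "iomeprol"), ])
#' @export
fit_extra_fractions <- function(mu_ct, histo, basis, extras, eps = 1e-6,
                                collinear_tol = 1e-10) {
  mu_ct <- as.numeric(mu_ct)
  if (length(mu_ct) != 2L || any(!is.finite(mu_ct))) {
    stop("mu_ct must be a finite attenuation pair")
  }
  histo <- histology_fractions(histo)
  if (!is.data.frame(extras)) stop("extras must be basis_set rows")
  n_extra <- nrow(extras)
  if (n_extra < 1L || n_extra > 2L) {
    stop("supported: 1 or 2 extra materials, got ", n_extra)
  }
  hp <- histology_point(histo, basis)
  extra_mu <- cbind(extras$mu_low, extras$mu_high)
  rownames(extra_mu) <- extras$name

  # columns: characteristic directions mu^Histo - mu_k; target: mu^Histo - mu^CT
  A <- hp - t(extra_mu)  # 2 x n
  b <- hp - mu_ct
  if (any(colSums(A^2) == 0)) {
    stop("degenerate geometry: an extra material coincides with the ",
         "histology point")
  }
  reduced <- FALSE
  if (n_extra == 2L) {
    cr <- A[1, 1] * A[2, 2] - A[2, 1] * A[1, 2]
    scale <- sqrt(sum(A[, 1]^2) * sum(A[, 2]^2))
    if (abs(cr) <= collinear_tol * scale) {
      warning("characteristic vectors of the two extra materials are ",
              "collinear; fitting each alone and keeping the better fit")
      fits <- lapply(1:2, function(j) {
        cls_box_simplex(A[, j, drop = FALSE], b, 1 - eps)
      })
      jbest <- which.min(vapply(fits, `[[`, numeric(1), "cost"))
      f <- c(0, 0); f[jbest] <- fits[[jbest]]$f
      sol <- list(f = f, cost = fits[[jbest]]$cost)
      reduced <- TRUE
    }
  }
  if (!reduced) sol <- cls_box_simplex(A, b, 1 - eps)
  f <- sol$f
  names(f) <- extras$name

  c_a <- 1 - sum(f)
  opt <- corrected_point(hp, f, extra_mu)
  structure(list(
    extra_fractions = f,
    c_a = c_a,
    c_s = 1 / c_a,
    composition = renormalize_composition(histo, f),
    histology_point = hp,
    optimized_point = opt,
    path_vectors = f * sweep(extra_mu, 2, hp),
    matching_error_pct = matching_error(opt, mu_ct),
    cost_value = sol$cost,
    degenerate = reduced), class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("Extra-material correction\n")
  cat("  extra fractions:",
      paste(sprintf("%s = %.4f", names(x$extra_fractions), x$extra_fractions),
            collapse = ", "), "\n")
  cat(sprintf("  c_a = %.6f (c_s = %.6f), cost = %.3g\n",
              x$c_a, x$c_s, x$cost_value))
  cat(sprintf("  matching error: %.4f%% (low), %.4f%% (high)\n",
              x$matching_error_pct[1], x$matching_error_pct[2]))
  cat("  full composition:\n")
  print(round(x$composition, 4))
  invisible(x)
}
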