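# Readers and writers: material definition files (YAML), measurement and
# histology tables (CSV), report emitters (CSV + full-precision JSON).
# Tables are comma-separated UTF-8 with a mandatory header; a units column
# is mandatory for measurements so HU and 1/cm can never be silently mixed.

#' Read a basis-material definition file
#'
#' YAML document with an `energies` entry (`[e_low, e_high]` in keV) and a
#' `materials` list; each material has `name`, `mu_low`, `mu_high`, `units`
#' (must be `"1/cm"`) and optionally `stock_concentration_mg_per_ml`.
#'
#' @param path File path.
#' @return A [basis_set()].
#' @export
read_materials <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$materials) || !length(doc$materials)) {
    stop("materials file has no 'materials' entry: ", path)
  }
  energies <- if (is.null(doc$energies)) c(50, 200) else as.numeric(doc$energies)
  get1 <- function(m, field) {
    if (is.null(m[[field]])) stop("material entry missing '", field, "' in ",
                                  path)
    m[[field]]
  }
  units <- vapply(doc$materials, function(m) as.character(get1(m, "units")),
                  character(1))
  if (!all(units == "1/cm")) {
    stop("material attenuations must be given in 1/cm (got: ",
         paste(unique(units), collapse = ", "), ")")
  }
  basis_set(
    name = vapply(doc$materials, function(m) as.character(get1(m, "name")),
                  character(1)),
    mu_low = vapply(doc$materials, function(m) as.numeric(get1(m, "mu_low")),
                    numeric(1)),
    mu_high = vapply(doc$materials, function(m) as.numeric(get1(m, "mu_high")),
                     numeric(1)),
    stock_concentration = vapply(doc$materials, function(m) {
      v <- m$stock_concentration_mg_per_ml
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1)),
    energies = energies)
}

#' Write a basis set to a material definition file
#'
#' @param basis A [basis_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_materials <- function(basis, path) {
  stopifnot(is_basis_set(basis))
  mats <- lapply(seq_len(nrow(basis)), function(i) {
    m <- list(name = basis$name[i], mu_low = basis$mu_low[i],
              mu_high = basis$mu_high[i], units = "1/cm")
    if (!is.na(basis$stock_concentration[i])) {
      m$stock_concentration_mg_per_ml <- basis$stock_concentration[i]
    }
    m
  })
  yaml::write_yaml(list(energies = as.numeric(attr(basis, "energies")),
                        materials = mats), path, precision = 15)
  invisible(path)
}

#' Read a specimen measurement table
#'
#' CSV with columns `specimen_id`, `value_low`, `value_high`, `units`.
#' Units must be uniform across the file, either `"1/cm"` (values passed
#' through) or `"HU"` (converted via [hu_to_mu()] with the supplied water
#' reference). Row order is preserved.
#'
#' @param path File path.
#' @param mu_water Water attenuation `c(mu_low, mu_high)` in 1/cm; required
#'   for HU input.
#' @return Data frame: `specimen_id`, `mu_low`, `mu_high` (1/cm).
#' @export
read_measurements <- function(path, mu_water = NULL) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "value_low", "value_high", "units")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop("measurement table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!tb$units %in% c("1/cm", "HU"))
  if (length(bad)) {
    stop("unknown units '", tb$units[bad[1]], "' in row ", bad[1], " of ", path)
  }
  mixed <- which(tb$units != tb$units[1])
  if (length(mixed)) {
    stop("mixed units in ", path, ": row ", mixed[1], " has '",
         tb$units[mixed[1]], "' but row 1 has '", tb$units[1], "'")
  }
  notnum <- which(!is.finite(tb$value_low) | !is.finite(tb$value_high))
  if (length(notnum)) {
    stop("non-numeric measurement in row ", notnum[1], " of ", path)
  }
  if (tb$units[1] == "HU") {
    if (is.null(mu_water) || length(mu_water) != 2L) {
      stop("HU measurements need a water reference mu_water = c(low, high)")
    }
    lo <- hu_to_mu(tb$value_low, mu_water[1])
    hi <- hu_to_mu(tb$value_high, mu_water[2])
  } else {
    lo <- tb$value_low
    hi <- tb$value_high
  }
  data.frame(specimen_id = as.character(tb$specimen_id),
             mu_low = lo, mu_high = hi, stringsAsFactors = FALSE)
}

#' Read a dilution-series table
#'
#' CSV with columns `material`, `concentration_mg_per_ml`, `mu_low`,
#' `mu_high`, `units` (must be `"1/cm"`); one row per prepared
#' concentration, several materials per file.
#'
#' @param path File path.
#' @param basis Optional [basis_set()] supplying stock concentrations; when
#'   given, the return value is a list of [dilution_series()] objects (one
#'   per material), otherwise the raw data frame.
#' @return Data frame, or a named list of `dilution_series`.
#' @export
read_series <- function(path, basis = NULL) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("material", "concentration_mg_per_ml", "mu_low", "mu_high",
            "units")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop("series table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(tb$units == "1/cm")) {
    stop("series attenuations must be given in 1/cm")
  }
  if (is.null(basis)) return(tb)
  stopifnot(is_basis_set(basis))
  out <- lapply(split(tb, tb$material), function(d) {
    i <- match(d$material[1], basis$name)
    if (is.na(i)) stop("series material not in basis: ", d$material[1])
    stock <- basis$stock_concentration[i]
    if (is.na(stock)) {
      stop("no stock concentration configured for ", d$material[1])
    }
    dilution_series(d$material[1], d$concentration_mg_per_ml,
                    d$mu_low, d$mu_high, stock)
  })
  out[unique(tb$material)]
}

#' Read a histology fraction table
#'
#' CSV with columns `specimen_id`, `units` (`"fraction"` or `"percent"`,
#' uniform across the file) and exactly three material columns. Percent
#' values are scaled to fractions; rows whose fractions do not sum to 1
#' within `tol` are rejected with their row numbers.
#'
#' @param path File path.
#' @param tol Tolerance on `|sum - 1|` after unit handling. Default `5e-3`.
#' @return Data frame: `specimen_id` plus three fraction columns, each row
#'   renormalized to sum exactly 1.
#' @export
read_histology <- function(path, tol = 5e-3) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(tb)) stop("missing column specimen_id")
  if (!"units" %in% names(tb)) stop("missing column units")
  mat_cols <- setdiff(names(tb), c("specimen_id", "units"))
  if (length(mat_cols) != 3L) {
    stop("expected exactly 3 material columns, got: ",
         paste(mat_cols, collapse = ", "))
  }
  if (!all(tb$units %in% c("fraction", "percent"))) {
    stop("units must be 'fraction' or 'percent'")
  }
  if (length(unique(tb$units)) > 1L) stop("mixed units in ", path)
  vals <- as.matrix(tb[, mat_cols])
  if (tb$units[1] == "percent") vals <- vals / 100
  sums <- rowSums(vals)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad)) {
    stop("histology fractions do not sum to 1 in row(s) ",
         paste(bad, collapse = ", "), " of ", path,
         " (sums: ", paste(format(sums[bad], digits = 4), collapse = ", "), ")")
  }
  out <- data.frame(specimen_id = as.character(tb$specimen_id),
                    vals / sums, stringsAsFactors = FALSE)
  names(out) <- c("specimen_id", mat_cols)
  out
}

#' Write correction results as a report table
#'
#' One row per specimen with the full composition (3-decimal fractions),
#' extra-material concentrations in mg/ml where a stock concentration is
#' known, and per-energy matching errors. A JSON sidecar (same path with
#' `.json`) carries full precision plus the per-specimen path vectors for
#' plotting.
#'
#' @param results Named list of `correction_result` objects (names =
#'   specimen ids).
#' @param path Output CSV path.
#' @param extras Optional [basis_set()] rows of the extra materials (for
#'   stock concentrations).
#' @param digits Fraction rounding in the CSV. Default 3.
#' @return `path`, invisibly.
#' @export
write_correction_report <- function(results, path, extras = NULL, digits = 3) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    comp <- round(r$composition, digits)
    row <- data.frame(specimen_id = id, t(comp), stringsAsFactors = FALSE)
    if (!is.null(extras)) {
      for (i in seq_len(nrow(extras))) {
        if (!is.na(extras$stock_concentration[i])) {
          nm <- extras$name[i]
          row[[paste0(nm, "_mg_per_ml")]] <- round(
            fraction_to_concentration(r$extra_fractions[[nm]],
                                      extras$stock_concentration[i]), 3)
        }
      }
    }
    row$matching_error_low_pct <- round(r$matching_error_pct[[1]], 4)
    row$matching_error_high_pct <- round(r$matching_error_pct[[2]], 4)
    row
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(specimen_id = character())
  utils::write.csv(tab, path, row.names = FALSE)
  full <- lapply(results, function(r) {
    list(extra_fractions = as.list(r$extra_fractions),
         c_a = r$c_a, c_s = r$c_s,
         composition = as.list(r$composition),
         histology_point = as.list(r$histology_point),
         optimized_point = as.list(r$optimized_point),
         path_vectors = apply(r$path_vectors, 1, as.list, simplify = FALSE),
         matching_error_pct = as.list(r$matching_error_pct),
         cost_value = r$cost_value)
  })
  jsonlite::write_json(full, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a calibration summary as a report table
#'
#' Emits a table shaped like a factor-calibration report: one row per group
#' plus the weighted mean, across the six material-energy factor columns,
#' and (when present) the final corrected attenuation block. Cost values
#' are also given per mille for compact display.
#'
#' @param summary A [aggregate_groups()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(summary, path) {
  stopifnot(inherits(summary, "calibration_summary"))
  fac <- summary$group_factors
  tab <- data.frame(
    row = c(sprintf("group%d", seq_len(nrow(fac))), "weighted_mean"),
    rbind(fac, summary$correction),
    cost = c(summary$cost_values, NA),
    cost_per_mille = c(1000 * summary$cost_values, NA),
    stringsAsFactors = FALSE)
  names(tab)[2:7] <- c("c1_low", "c2_low", "c3_low",
                       "c4_high", "c5_high", "c6_high")
  utils::write.csv(tab, path, row.names = FALSE)
  payload <- list(correction = summary$correction,
                  weights = summary$weights,
                  cost_values = summary$cost_values,
                  group_factors = apply(fac, 1, as.list, simplify = FALSE))
  if (!is.null(summary$attenuation)) payload$attenuation <- summary$attenuation
  jsonlite::write_json(payload, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
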