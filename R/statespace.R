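#' Construct a fabrication state-space from calibration records
#'
#' The state-space is the tabulated empirical relationship between the two
#' free fabrication variables -- the unified monomer-photoinitiator index
#' (`peg_pi`, dimensionless, on the % w/v monomer scale) and the laser focus
#' offset (`focus_z`, mm) -- and the measured material properties: Young's
#' modulus (kPa), printed linewidth (um) and relative bound-conjugate
#' fluorescence (a.u.). Properties at arbitrary fabrication coordinates are
#' obtained by Nadaraya-Watson kernel smoothing over the records
#' (see [interpolate_properties()]).
#'
#' @param records data.frame with columns `peg_pi`, `focus_z`,
#'   `conjugate_conc` (mM), `youngs_modulus` (kPa), `linewidth` (um),
#'   `bound_signal` (a.u.).
#' @param bandwidth kernel bandwidth in normalized units (default 0.1).
#' @param range_x,range_z normalization ranges for `peg_pi` (40) and
#'   `focus_z` (6); normalized distances are `(peg_pi_em - x)/range_x` and
#'   `(focus_em - z)/range_z`.
#' @param kernel_form `"product_gaussian"` (default): an isotropic 2-D
#'   Gaussian in the normalized coordinates. `"literal_summed"`: an
#'   exponential of the *sum* of the two normalized differences, retained
#'   for comparison with a non-metric variant of the weighting formula.
#' @return An object of class `state_space`.
#' @seealso [load_calibration()], [kernel_weights()],
#'   [interpolate_properties()]
#' @export
state_space <- function(records, bandwidth = 0.1, range_x = 40, range_z = 6,
                        kernel_form = c("product_gaussian", "literal_summed")) {
  kernel_form <- match.arg(kernel_form)
  if (!is.data.frame(records)) {
    nf_format_error("`records` must be a data.frame of calibration records")
  }
  required <- c("peg_pi", "focus_z", "conjugate_conc", "youngs_modulus",
                "linewidth", "bound_signal")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    nf_format_error(sprintf("calibration table is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) nf_validation_error("calibration table is empty")
  if (!all(bandwidth > 0, range_x > 0, range_z > 0)) {
    nf_validation_error("bandwidth, range_x and range_z must be positive")
  }
  .check_records(records)
  structure(
    list(records = records[, required], bandwidth = bandwidth,
         range_x = range_x, range_z = range_z, kernel_form = kernel_form),
    class = "state_space"
  )
}

.check_records <- function(records) {
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      nf_validation_error(sprintf("calibration row %s: %s",
                                  paste(idx, collapse = ", "), what))
    }
  }
  for (col in c("peg_pi", "focus_z", "conjugate_conc", "youngs_modulus",
                "linewidth", "bound_signal")) {
    bad(!is.finite(records[[col]]), sprintf("non-finite %s", col))
  }
  bad(records$youngs_modulus <= 0, "youngs_modulus must be > 0")
  bad(records$linewidth <= 0, "linewidth must be > 0")
  bad(records$conjugate_conc < 0, "conjugate_conc must be >= 0")
  bad(records$bound_signal < 0, "bound_signal must be >= 0")
  bad(abs(records$peg_pi - 50) > 40 + 1e-9,
      "peg_pi outside the ellipse domain |peg_pi - 50| <= 40")
  invisible(TRUE)
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "<state_space> %d records | peg_pi [%.3g, %.3g] | focus_z [%.3g, %.3g]\n",
    nrow(x$records), min(x$records$peg_pi), max(x$records$peg_pi),
    min(x$records$focus_z), max(x$records$focus_z)))
  cat(sprintf("  bandwidth %.3g (ranges %g x %g), kernel %s\n",
              x$bandwidth, x$range_x, x$range_z, x$kernel_form))
  invisible(x)
}

#' Read a calibration table from CSV
#'
#' The CSV dialect is comma-separated, UTF-8, dot decimal, with a required
#' header naming the columns `peg_pi, focus_z, conjugate_conc,
#' youngs_modulus, linewidth, bound_signal`. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @param ... passed on to [state_space()] (bandwidth, kernel form, ...).
#' @return A `state_space`.
#' @export
load_calibration <- function(path, ...) {
  if (!file.exists(path)) nf_format_error(sprintf("no such file: %s", path))
  records <- utils::read.csv(path, fileEncoding = "UTF-8")
  state_space(records, ...)
}

#' Write a calibration table to CSV
#'
#' @param space a `state_space` (or a bare record data.frame).
#' @param path output CSV path.
#' @export
write_calibration <- function(space, path) {
  records <- if (inherits(space, "state_space")) space$records else space
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kernel weights of the calibration records at a query point
#'
#' One positive weight per record. In the default `product_gaussian` form
#' the weight of record i is
#' \deqn{\tau_i = \frac{1}{0.1\,2\pi}
#'   \exp\left(-\tfrac12\left[(\Delta x_i/0.1)^2 +
#'   (\Delta z_i/0.1)^2\right]\right)}
#' with \eqn{\Delta x_i = (pegpi_i - x)/40} and
#' \eqn{\Delta z_i = (focus_i - z)/6}. The prefactor cancels in the
#' Nadaraya-Watson ratio and is retained only for fidelity to the weighting
#' expression; it never affects interpolation or inverse design.
#'
#' @param space a `state_space`.
#' @param x query unified monomer-photoinitiator index.
#' @param z query focus offset (mm).
#' @return numeric vector of weights, one per record, all > 0.
#' @export
kernel_weights <- function(space, x, z) {
  stopifnot(inherits(space, "state_space"))
  if (!is.finite(x) || !is.finite(z)) {
    nf_validation_error("query coordinates must be finite")
  }
  dx <- (space$records$peg_pi - x) / space$range_x
  dz <- (space$records$focus_z - z) / space$range_z
  bw <- space$bandwidth
  pref <- 1 / (bw * 2 * pi)
  if (space$kernel_form == "product_gaussian") {
    pref * exp(-0.5 * ((dx / bw)^2 + (dz / bw)^2))
  } else {
    pref * exp(-0.5 * (dx + dz) / bw)
  }
}

# Weights rescaled by their maximum before exponentiation: the
# Nadaraya-Watson ratio is invariant to the rescaling, and far-field
# queries no longer underflow to an all-zero weight vector.
.stable_weights <- function(space, x, z) {
  if (!is.finite(x) || !is.finite(z)) {
    nf_validation_error("query coordinates must be finite")
  }
  dx <- (space$records$peg_pi - x) / space$range_x
  dz <- (space$records$focus_z - z) / space$range_z
  bw <- space$bandwidth
  lw <- if (space$kernel_form == "product_gaussian") {
    -0.5 * ((dx / bw)^2 + (dz / bw)^2)
  } else {
    -0.5 * (dx + dz) / bw
  }
  exp(lw - max(lw))
}

#' Interpolate material properties at fabrication coordinates
#'
#' Nadaraya-Watson kernel-weighted means of the record properties:
#' \eqn{\hat E = \sum_i \tau_i E_i / \sum_i \tau_i} and likewise for
#' linewidth and bound-conjugate signal. Results are convex combinations of
#' the record values and therefore bounded by their extrema.
#'
#' For the bound-conjugate signal the calibration has a third axis, the
#' thiolated-conjugate concentration. When `conjugate` is supplied, the
#' bound-signal average is restricted to records at the nearest tabulated
#' `conjugate_conc` level (nearest-neighbour matching on the conjugate
#' axis); stiffness and linewidth always use all records, since they are
#' insensitive to conjugate content over the characterized range.
#'
#' @inheritParams kernel_weights
#' @param conjugate optional query conjugate concentration (mM) for the
#'   bound-signal axis.
#' @return named numeric vector `c(youngs_modulus, linewidth, bound_signal)`
#'   (kPa, um, a.u.).
#' @export
interpolate_properties <- function(space, x, z, conjugate = NULL) {
  stopifnot(inherits(space, "state_space"))
  w <- .stable_weights(space, x, z)
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) {
    nf_validation_error("kernel weights degenerate at the query point")
  }
  rec <- space$records
  e <- sum(w * rec$youngs_modulus) / sw
  lw <- sum(w * rec$linewidth) / sw
  if (is.null(conjugate)) {
    b <- sum(w * rec$bound_signal) / sw
  } else {
    levels <- unique(rec$conjugate_conc)
    nearest <- levels[which.min(abs(levels - conjugate))]
    sel <- rec$conjugate_conc == nearest
    b <- sum(w[sel] * rec$bound_signal[sel]) / sum(w[sel])
  }
  c(youngs_modulus = e, linewidth = lw, bound_signal = b)
}
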