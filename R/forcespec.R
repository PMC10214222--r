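# AFM force spectroscopy: simulation and fitting of force-displacement
# approach curves with a Sneddon conical-indenter model, finite-thickness
# (bottom-effect) correction, automated contact-point detection and
# discontinuity-based quality control.
#
# Unit conventions: piezo displacement in um, force in nN, Young's modulus
# in kPa (1 kPa == 1 nN/um^2, so no conversion factors appear), cantilever
# spring constant in N/m (= 1e3 nN/um).

# Four-term bottom-effect cone-correction series for a sample bonded to a
# rigid support, in powers of chi = delta * tan(theta) / h.
.becc_coefs <- c(0.721, 0.650, 0.491, 0.225)

#' Conical indenter model
#'
#' @param half_angle cone half-opening angle in degrees (default 18, the
#'   pyramidal-cantilever equivalent cone).
#' @param poisson Poisson ratio of the sample (default 0.5, incompressible
#'   hydrogel).
#' @param correction `"none"` for the infinite-thickness Sneddon law, or
#'   `"bottom_effect_cone"` for the finite-thickness bottom-effect
#'   correction of a gel bonded to a rigid support.
#' @return object of class `indenter_model`.
#' @export
indenter_model <- function(half_angle = 18, poisson = 0.5,
                           correction = c("none", "bottom_effect_cone")) {
  correction <- match.arg(correction)
  if (!(half_angle > 0 && half_angle < 90)) {
    nf_validation_error("half_angle must be in (0, 90) degrees")
  }
  if (!(poisson >= 0 && poisson <= 0.5)) {
    nf_validation_error("poisson must be in [0, 0.5]")
  }
  structure(list(half_angle = half_angle, poisson = poisson,
                 correction = correction),
            class = "indenter_model")
}

#' Bottom-effect correction factor
#'
#' Multiplicative finite-thickness correction to the Sneddon cone force for
#' a sample of thickness `h` bonded to a rigid support:
#' `1 + 0.721*chi + 0.650*chi^2 + 0.491*chi^3 + 0.225*chi^4` with
#' `chi = delta * tan(theta) / h`. Tends to 1 as `h -> Inf`.
#'
#' @param delta indentation depth(s), um.
#' @param half_angle cone half-angle, degrees.
#' @param h sample thickness, um.
#' @return correction factor(s) >= 1.
#' @export
becc_factor <- function(delta, half_angle, h) {
  chi <- delta * tan(half_angle * pi / 180) / h
  1 + .becc_coefs[1] * chi + .becc_coefs[2] * chi^2 +
    .becc_coefs[3] * chi^3 + .becc_coefs[4] * chi^4
}

#' Sneddon cone force law
#'
#' `F = (2/pi) * tan(theta) * E / (1 - nu^2) * delta^2` (nN for E in kPa and
#' delta in um), multiplied by [becc_factor()] when the model carries the
#' bottom-effect correction.
#'
#' @param delta indentation depth(s), um (negative values give zero force).
#' @param E Young's modulus, kPa.
#' @param model an [indenter_model()].
#' @param h sample thickness (um); required when the model's correction is
#'   `"bottom_effect_cone"`.
#' @return force(s), nN.
#' @export
sneddon_force <- function(delta, E, model = indenter_model(), h = NULL) {
  stopifnot(inherits(model, "indenter_model"))
  d <- pmax(delta, 0)
  C <- (2 / pi) * tan(model$half_angle * pi / 180) / (1 - model$poisson^2)
  f <- C * E * d^2
  if (model$correction == "bottom_effect_cone") {
    if (is.null(h) || !is.finite(h) || h <= 0) {
      nf_config_error(
        "sample thickness h is required for the bottom-effect correction")
    }
    f <- f * becc_factor(d, model$half_angle, h)
  }
  f
}

#' Simulate an AFM approach curve
#'
#' Generates a force-displacement approach curve: flat (noisy) baseline
#' before the contact point `z0`, then the Sneddon (optionally
#' bottom-effect-corrected) force of the indentation. The indentation at
#' piezo position z accounts for cantilever compliance,
#' `delta = (z - z0) - F / k`, solved per sample by fixed-point iteration.
#' Acquisition terminates at the first sample whose noiseless force reaches
#' `threshold_force`. An optional slip event adds a persistent force offset
#' from a given piezo position onward, emulating the sample slipping under
#' the tip.
#'
#' @param E true Young's modulus (kPa), > 0.
#' @param model an [indenter_model()].
#' @param z0 contact point, um along the piezo axis (curve starts at 0).
#' @param h sample thickness (um); `Inf` for thick samples. Required finite
#'   when the model applies the bottom-effect correction.
#' @param noise_sd Gaussian force noise, nN.
#' @param slip `NULL`, or `c(position, jump)`: piezo position (um) and
#'   signed force offset (nN) applied from that position onward.
#' @param seed integer seed; the curve is deterministic given the seed.
#' @param spring_constant cantilever stiffness, N/m.
#' @param approach_velocity approach speed, um/s.
#' @param sample_rate sampling rate, Hz (sample spacing =
#'   velocity / rate um).
#' @param threshold_force termination force, nN.
#' @param z_max safety cap on the piezo range, um.
#' @return object of class `force_curve`: `piezo_z`, `force`,
#'   `spring_constant`, `approach_velocity`, `threshold_force`,
#'   `sample_thickness`, plus the simulation truth in `truth`.
#' @export
simulate_curve <- function(E, model = indenter_model(), z0 = 2, h = Inf,
                           noise_sd = 0, slip = NULL, seed = NULL,
                           spring_constant = 0.05, approach_velocity = 0.5,
                           sample_rate = 100, threshold_force = 10,
                           z_max = 30) {
  if (!(is.numeric(E) && length(E) == 1L && is.finite(E) && E > 0)) {
    nf_validation_error("E must be a single positive number (kPa)")
  }
  if (noise_sd < 0) nf_validation_error("noise_sd must be >= 0")
  use_h <- if (model$correction == "bottom_effect_cone") h else NULL
  if (model$correction == "bottom_effect_cone" &&
      (is.null(h) || !is.finite(h))) {
    nf_config_error("finite sample thickness h required for bottom-effect simulation")
  }

  dz <- approach_velocity / sample_rate
  z <- seq(0, z_max, by = dz)
  zeta <- pmax(z - z0, 0)
  k_nN_um <- spring_constant * 1e3

  # F = sneddon(zeta - F/k): contraction fixed point, vectorized.
  f <- sneddon_force(zeta, E, model, h = use_h)
  for (i in 1:200) {
    f_new <- sneddon_force(pmax(zeta - f / k_nN_um, 0), E, model, h = use_h)
    if (max(abs(f_new - f)) < 1e-12) { f <- f_new; break }
    f <- f_new
  }

  cut <- which(f >= threshold_force)
  if (length(cut) > 0L) {
    keep <- seq_len(cut[1])
    z <- z[keep]; f <- f[keep]
  }
  force <- local_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  if (!is.null(slip)) {
    if (length(slip) != 2L) nf_validation_error("slip must be c(position, jump)")
    force[z >= slip[1]] <- force[z >= slip[1]] + slip[2]
  }

  structure(list(
    piezo_z = z, force = force, spring_constant = spring_constant,
    approach_velocity = approach_velocity, threshold_force = threshold_force,
    sample_thickness = if (is.finite(h)) h else NULL,
    truth = list(E = E, z0 = z0, h = h, noise_sd = noise_sd, slip = slip,
                 seed = seed, model = model)
  ), class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, z [%.3g, %.3g] um, F max %.3g nN, k = %g N/m\n",
              length(x$piezo_z), min(x$piezo_z), max(x$piezo_z),
              max(x$force), x$spring_constant))
  invisible(x)
}

.check_curve <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if (any(diff(curve$piezo_z) <= 0)) {
    nf_validation_error("piezo_z must be strictly monotone increasing")
  }
  if (any(!is.finite(curve$force))) {
    nf_validation_error("force contains non-finite samples")
  }
  invisible(TRUE)
}

# Piecewise-model residual profile used by contact-point detection:
# flat baseline for z <= z0, Sneddon-shaped quadratic growth in the
# compliance-corrected indentation after it.
.contact_rss <- function(curve, z0) {
  z <- curve$piezo_z; f <- curve$force
  pre <- z <= z0
  if (sum(pre) < 2L || sum(!pre) < 3L) return(Inf)
  b <- mean(f[pre])
  y <- f[!pre] - b
  delta <- pmax(z[!pre] - z0 - y / (curve$spring_constant * 1e3), 0)
  a <- max(0, sum(y * delta^2) / sum(delta^4))
  sum((f[pre] - b)^2) + sum((y - a * delta^2)^2)
}

#' Automated contact-point detection
#'
#' Chooses the contact point `z0` minimizing the total squared residual of
#' a piecewise model: flat baseline before `z0`, Sneddon-shaped quadratic
#' growth after. A coarse search over every 5th sample is refined by
#' golden-section/parabolic minimization between the neighbouring grid
#' points; exact ties resolve to the smaller `z0`.
#'
#' @param curve a `force_curve`.
#' @return contact point `z0` (um).
#' @export
detect_contact_point <- function(curve) {
  .check_curve(curve)
  z <- curve$piezo_z; f <- curve$force
  n <- length(z)
  if (n < 20L) nf_validation_error("curve too short (< 20 samples)")

  nb <- max(10L, n %/% 5L)
  base_scale <- stats::mad(f[seq_len(nb)])
  if (max(f) - stats::median(f[seq_len(nb)]) <
      max(5 * base_scale, 1e-12)) {
    nf_validation_error("no contact detected: curve never leaves the baseline")
  }

  idx <- seq(5L, n - 5L, by = 5L)
  rss <- vapply(z[idx], function(z0) .contact_rss(curve, z0), numeric(1))
  i_best <- idx[which.min(rss)]
  lower <- z[max(1L, i_best - 5L)]
  upper <- z[min(n, i_best + 5L)]
  opt <- stats::optimize(function(z0) .contact_rss(curve, z0),
                         lower = lower, upper = upper, tol = 1e-8)
  opt$minimum
}

#' Discontinuity (slip) quality control
#'
#' A curve is rejected when a persistent force level shift across any
#' single sample exceeds `jump_sigma` times a robust noise scale. The
#' shift at increment i is measured on 5-sample running medians of the
#' force as an inner difference spanning the increment
#' (`med5[i+3] - med5[i-2]`) minus 5/19 of an outer difference with the
#' same midpoint (`med5[i+10] - med5[i-9]`). For any locally quadratic
#' (and a fortiori linear) force trend the two terms cancel exactly, so
#' the smooth indentation ramp contributes nothing; a step discontinuity
#' survives at 14/19 of its size. The noise scale is the median absolute
#' deviation of the statistic over the whole curve (immune to the
#' isolated jump itself), floored at 15% of the 99th percentile of the
#' raw increments: on steep ramps with near-zero noise the running median
#' occasionally swaps adjacent samples, producing glitches of one
#' increment, and the floor keeps those (and the slope kink at the
#' contact point) below threshold while remaining insensitive to a
#' single slip outlier. A shift exactly at the threshold is rejected
#' (`>=` rule).
#'
#' @param curve a `force_curve`.
#' @param jump_sigma threshold multiplier (default 6).
#' @return `"accepted"` or `"rejected_discontinuity"`.
#' @export
qc_discontinuity <- function(curve, jump_sigma = 6) {
  .check_curve(curve)
  f <- curve$force
  n <- length(f)
  if (n < 60L) return("accepted")
  med5 <- stats::runmed(f, 5L, endrule = "median")
  idx <- seq.int(12L, n - 13L)  # step between f[idx] and f[idx + 1]
  s <- (med5[idx + 3L] - med5[idx - 2L]) -
    (5 / 19) * (med5[idx + 10L] - med5[idx - 9L])
  scale <- max(stats::mad(s),
               0.15 * stats::quantile(abs(diff(f)), 0.99, names = FALSE),
               1e-12)
  if (any(abs(s) >= jump_sigma * scale)) {
    "rejected_discontinuity"
  } else {
    "accepted"
  }
}

# Linear least-squares estimate of E given a contact point.
.fit_at_z0 <- function(curve, model, z0, h, tip_sample_correction) {
  z <- curve$piezo_z; f <- curve$force
  pre <- z <= z0
  post <- !pre
  if (sum(pre) < 2L || sum(post) < 5L) {
    return(list(E = NA_real_, rss = Inf, n_post = sum(post)))
  }
  b <- mean(f[pre])
  zeta <- z[post] - z0
  y <- f[post] - b
  delta <- if (tip_sample_correction) {
    pmax(zeta - y / (curve$spring_constant * 1e3), 0)
  } else {
    zeta
  }
  s <- sneddon_force(delta, 1, model, h = h)  # unit-modulus shape
  denom <- sum(s^2)
  if (denom <= 0) return(list(E = NA_real_, rss = Inf, n_post = sum(post)))
  E <- sum(y * s) / denom
  rss <- sum((f[pre] - b)^2) + sum((y - E * s)^2)
  list(E = E, rss = rss, n_post = sum(post), ss = sum(y^2))
}

#' Fit Young's modulus from an approach curve
#'
#' Least-squares Sneddon (optionally bottom-effect-corrected) fit of the
#' post-contact force. The contact point comes from
#' [detect_contact_point()] unless supplied, and is jointly refined with
#' the modulus by minimizing the residual over a window around the
#' detected value. Indentation is computed as piezo displacement minus
#' cantilever deflection (`force / spring_constant`); set
#' `tip_sample_correction = FALSE` to fit against raw piezo displacement.
#'
#' @param curve a `force_curve`.
#' @param model an [indenter_model()]; with
#'   `correction = "bottom_effect_cone"` the curve must carry a finite
#'   `sample_thickness`.
#' @param z0 optional fixed contact point (um); skips detection.
#' @param refine jointly refine `z0` by residual minimization
#'   (default TRUE; ignored when `z0` is supplied).
#' @param tip_sample_correction subtract cantilever deflection from the
#'   indentation (default TRUE).
#' @param accept_tol maximum relative fit residual
#'   (`sqrt(rss / sum(F^2))`) for `qc_status = "accepted"`.
#' @param jump_sigma passed to [qc_discontinuity()].
#' @param force_fit fit even when the discontinuity QC rejects the curve.
#' @return object of class `fit_result`: `youngs_modulus` (kPa),
#'   `contact_point` (um), `rss` (nN^2), `relative_residual`, `qc_status`
#'   (`accepted` / `rejected_discontinuity` / `rejected_fit`), `model`,
#'   `n_post`.
#' @export
fit_modulus <- function(curve, model = indenter_model(), z0 = NULL,
                        refine = TRUE, tip_sample_correction = TRUE,
                        accept_tol = 0.05, jump_sigma = 6,
                        force_fit = FALSE) {
  .check_curve(curve)
  stopifnot(inherits(model, "indenter_model"))
  h <- NULL
  if (model$correction == "bottom_effect_cone") {
    h <- curve$sample_thickness
    if (is.null(h) || !is.finite(h) || h <= 0) {
      nf_config_error(
        "curve has no sample_thickness: required for the bottom-effect correction")
    }
  }

  qc <- qc_discontinuity(curve, jump_sigma = jump_sigma)
  if (qc == "rejected_discontinuity" && !force_fit) {
    return(structure(list(
      youngs_modulus = NA_real_, contact_point = NA_real_, rss = NA_real_,
      relative_residual = NA_real_, qc_status = "rejected_discontinuity",
      model = model, n_post = NA_integer_
    ), class = "fit_result"))
  }

  fixed_z0 <- !is.null(z0)
  if (!fixed_z0) z0 <- detect_contact_point(curve)

  obj <- function(zz) .fit_at_z0(curve, model, zz, h, tip_sample_correction)$rss
  if (refine && !fixed_z0) {
    dz <- stats::median(diff(curve$piezo_z))
    window <- max(0.25, 10 * dz)
    lo <- max(min(curve$piezo_z) + 2 * dz, z0 - window)
    hi <- min(max(curve$piezo_z) - 5 * dz, z0 + window)
    if (hi > lo) z0 <- stats::optimize(obj, lower = lo, upper = hi,
                                       tol = 1e-8)$minimum
  }

  ans <- .fit_at_z0(curve, model, z0, h, tip_sample_correction)
  rel <- if (is.finite(ans$rss) && ans$ss > 0) sqrt(ans$rss / ans$ss) else Inf
  status <- if (!is.finite(ans$E) || ans$E <= 0) {
    "rejected_fit"
  } else if (rel > accept_tol) {
    "rejected_fit"
  } else {
    "accepted"
  }
  structure(list(
    youngs_modulus = ans$E, contact_point = z0, rss = ans$rss,
    relative_residual = rel, qc_status = status, model = model,
    n_post = ans$n_post
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> E = %.4g kPa, z0 = %.4g um, rel. residual %.3g, %s\n",
              x$youngs_modulus, x$contact_point, x$relative_residual,
              x$qc_status))
  invisible(x)
}

#' Read / write force curves
#'
#' Curves are stored as a two-column CSV (`piezo_z_um, force_nN`) plus a
#' JSON sidecar (same path with extension `.json`) holding the acquisition
#' metadata (spring constant, approach velocity, threshold force, sample
#' thickness).
#'
#' @param curve a `force_curve`.
#' @param path CSV path.
#' @return `read_force_curve` returns a `force_curve`.
#' @export
write_force_curve <- function(curve, path) {
  .check_curve(curve)
  utils::write.csv(
    data.frame(piezo_z_um = curve$piezo_z, force_nN = curve$force),
    path, row.names = FALSE, quote = FALSE)
  meta <- list(spring_constant = curve$spring_constant,
               approach_velocity = curve$approach_velocity,
               threshold_force = curve$threshold_force,
               sample_thickness = curve$sample_thickness)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) nf_format_error(sprintf("no such file: %s", path))
  d <- utils::read.csv(path)
  if (!all(c("piezo_z_um", "force_nN") %in% names(d))) {
    nf_format_error("force-curve CSV needs columns piezo_z_um, force_nN")
  }
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(list(
    piezo_z = d$piezo_z_um, force = d$force_nN,
    spring_constant = meta$spring_constant %||% 0.05,
    approach_velocity = meta$approach_velocity %||% 0.5,
    threshold_force = meta$threshold_force %||% 10,
    sample_thickness = meta$sample_thickness,
    truth = NULL
  ), class = "force_curve")
}
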