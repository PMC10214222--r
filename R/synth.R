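# Synthetic-data generators. Every generator is deterministic given its
# seed and returns its ground truth alongside the data, so analysis
# modules can be validated by parameter recovery rather than by eye.

#' Forward-model parameters for synthetic calibration tables
#'
#' The forward model emulates the qualitative structure of an empirical
#' fabrication state-space: Young's modulus grows as a power law of the
#' unified monomer-photoinitiator index and is attenuated exponentially by
#' defocus (less light exposure, lower conversion); linewidth grows
#' linearly with defocus (the conic beam diameter) and mildly with the
#' index; neither depends on the conjugate concentration, which only
#' drives the bound-signal channel. The functional forms are an emulation
#' chosen for monotonicity and invertibility, not a reproduction of any
#' measured calibration.
#'
#' Defaults place the noiseless surface inside the characterized envelope
#' (E in \[2, 20\] kPa, W in \[40, 300\] um) over the default grid
#' (`peg_pi` in \[10, 90\], `focus_z` in \[0, 6\]).
#'
#' @param E_base,E_exp modulus power law: `E = E_base * (peg_pi/10)^E_exp`.
#' @param E_focus_coef exponential modulus attenuation per mm of defocus.
#' @param W_base,W_focus_slope,W_pegpi_slope linewidth model:
#'   `W = W_base + W_focus_slope * focus_z + W_pegpi_slope * (peg_pi - 10)`.
#' @param bound_gain bound signal per mM of conjugate at mid index.
#' @param noise_cv relative (multiplicative) measurement noise.
#' @return object of class `forward_model_params`.
#' @export
forward_model_params <- function(E_base = 2.6, E_exp = 0.92,
                                 E_focus_coef = 0.02,
                                 W_base = 45, W_focus_slope = 35,
                                 W_pegpi_slope = 0.45,
                                 bound_gain = 1, noise_cv = 0.05) {
  if (noise_cv < 0) nf_validation_error("noise_cv must be >= 0")
  if (E_base <= 0 || E_exp <= 0 || E_focus_coef < 0) {
    nf_validation_error("modulus model requires E_base, E_exp > 0 and E_focus_coef >= 0")
  }
  structure(list(E_base = E_base, E_exp = E_exp, E_focus_coef = E_focus_coef,
                 W_base = W_base, W_focus_slope = W_focus_slope,
                 W_pegpi_slope = W_pegpi_slope, bound_gain = bound_gain,
                 noise_cv = noise_cv),
            class = "forward_model_params")
}

#' Noiseless forward evaluation of a synthetic state-space
#'
#' @param params a [forward_model_params()].
#' @param peg_pi,focus_z fabrication coordinates (vectorized).
#' @param conjugate conjugate concentration (mM), for the bound channel.
#' @return data.frame with `youngs_modulus`, `linewidth`, `bound_signal`.
#' @export
forward_properties <- function(params, peg_pi, focus_z, conjugate = 0) {
  stopifnot(inherits(params, "forward_model_params"))
  xt <- (peg_pi - 10) / 80
  E <- params$E_base * (peg_pi / 10)^params$E_exp *
    exp(-params$E_focus_coef * focus_z)
  W <- params$W_base + params$W_focus_slope * focus_z +
    params$W_pegpi_slope * (peg_pi - 10)
  bound <- conjugate * params$bound_gain * (0.85 + 0.3 * xt)
  data.frame(youngs_modulus = E, linewidth = W, bound_signal = bound)
}

#' Generate a synthetic calibration table
#'
#' Evaluates the forward model on a full grid of fabrication coordinates
#' and conjugate levels, applies multiplicative measurement noise, and
#' returns both the resulting [state_space()] and the noiseless forward
#' function for round-trip testing.
#'
#' @param params a [forward_model_params()].
#' @param peg_levels,focus_levels,conjugate_levels grid levels for the
#'   unified index, focus offset (mm) and conjugate concentration (mM).
#' @param seed integer seed for the noise realization.
#' @param ... passed to [state_space()] (bandwidth, kernel form, ...).
#' @return list with `space` (a `state_space`), `forward` (function of
#'   `(peg_pi, focus_z, conjugate = 0)` returning noiseless properties),
#'   and `params`.
#' @export
gen_calibration <- function(params = forward_model_params(),
                            peg_levels = seq(10, 90, by = 5),
                            focus_levels = seq(0, 6, by = 0.5),
                            conjugate_levels = 0,
                            seed = NULL, ...) {
  stopifnot(inherits(params, "forward_model_params"))
  grid <- expand.grid(peg_pi = peg_levels, focus_z = focus_levels,
                      conjugate_conc = conjugate_levels,
                      KEEP.OUT.ATTRS = FALSE)
  truth <- forward_properties(params, grid$peg_pi, grid$focus_z,
                              grid$conjugate_conc)
  if (any(truth$youngs_modulus <= 0) || any(truth$linewidth <= 0)) {
    nf_validation_error(
      "forward model produced non-positive properties on this grid")
  }
  n <- nrow(grid)
  noise <- local_seed(seed, matrix(stats::rnorm(3 * n), ncol = 3))
  noise <- pmax(pmin(noise, 3), -3)  # keep noisy properties positive
  cv <- params$noise_cv
  records <- data.frame(
    peg_pi = grid$peg_pi,
    focus_z = grid$focus_z,
    conjugate_conc = grid$conjugate_conc,
    youngs_modulus = truth$youngs_modulus * (1 + cv * noise[, 1]),
    linewidth = truth$linewidth * (1 + cv * noise[, 2]),
    bound_signal = pmax(0, truth$bound_signal * (1 + cv * noise[, 3]))
  )
  list(
    space = state_space(records, ...),
    forward = function(peg_pi, focus_z, conjugate = 0) {
      forward_properties(params, peg_pi, focus_z, conjugate)
    },
    params = params
  )
}

#' Generate a batch of simulated AFM curves with ground truth
#'
#' Delegates to [simulate_curve()] with per-curve seeds, contact points
#' drawn uniformly over `z0_range`, and optional random slip events.
#'
#' @param E_levels vector of true moduli (kPa).
#' @param n_per_level curves per level.
#' @param model an [indenter_model()] used for simulation.
#' @param h sample thickness (um); `Inf` = thick sample.
#' @param noise_sd force noise, nN.
#' @param slip_prob probability that a curve carries a slip event.
#' @param slip_jump signed slip force offset, nN.
#' @param z0_range range for the uniform contact-point draw, um.
#' @param seed master seed; curves are reproducible given it.
#' @param ... further acquisition settings for [simulate_curve()].
#' @return list with `curves` (list of `force_curve`) and `truth`
#'   (data.frame: `id`, `E`, `z0`, `h`, `slip`).
#' @export
gen_force_curves <- function(E_levels, n_per_level,
                             model = indenter_model(), h = Inf,
                             noise_sd = 0.05, slip_prob = 0, slip_jump = -2,
                             z0_range = c(1.5, 2.5), seed = NULL, ...) {
  if (any(E_levels <= 0)) nf_validation_error("E_levels must be positive")
  n <- length(E_levels) * n_per_level
  draws <- local_seed(seed, list(
    z0 = stats::runif(n, z0_range[1], z0_range[2]),
    slip = stats::rbinom(n, 1, slip_prob) == 1L,
    slip_at = stats::runif(n, 0.3, 0.7),     # fraction of post-contact span
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  E <- rep(E_levels, each = n_per_level)
  curves <- vector("list", n)
  truth <- data.frame(id = seq_len(n), E = E, z0 = draws$z0, h = h,
                      slip = draws$slip)
  for (i in seq_len(n)) {
    slip <- NULL
    if (draws$slip[i]) {
      # place the jump inside the indentation ramp
      probe <- simulate_curve(E[i], model = model, z0 = draws$z0[i], h = h,
                              noise_sd = 0, seed = 1L, ...)
      zmax <- max(probe$piezo_z)
      slip <- c(draws$z0[i] + draws$slip_at[i] * (zmax - draws$z0[i]),
                slip_jump)
    }
    curves[[i]] <- simulate_curve(E[i], model = model, z0 = draws$z0[i],
                                  h = h, noise_sd = noise_sd, slip = slip,
                                  seed = draws$seeds[i], ...)
  }
  list(curves = curves, truth = truth)
}

#' Parameters of a synthetic labelled image scene
#'
#' @param n_cells number of cells, >= 1.
#' @param nc_ratios per-cell nuclear:cytoplasmic marker ratio(s); recycled
#'   over cells.
#' @param lipid_fraction target fraction of cytoplasm voxels occupied by
#'   lipid droplets, in \[0, 1\].
#' @param gradient `NULL`, or a spatial trend of the nuclear marker along
#'   the niche x-axis: nuclear intensity is scaled by
#'   `(1 + gradient * (x/nx - 0.5))`.
#' @param voxel_size physical voxel size, um, as `c(z, y, x)`.
#' @param base_intensity cytoplasmic marker level (ADU).
#' @param noise `"poisson"` (shot + read noise) or `"none"`.
#' @param read_sd Gaussian read-noise SD, ADU.
#' @return object of class `image_scene_params`.
#' @export
image_scene_params <- function(n_cells = 25, nc_ratios = 2,
                               lipid_fraction = 0, gradient = NULL,
                               voxel_size = c(1, 0.5, 0.5),
                               base_intensity = 100,
                               noise = c("poisson", "none"), read_sd = 2) {
  noise <- match.arg(noise)
  if (n_cells < 1) nf_validation_error("n_cells must be >= 1")
  if (lipid_fraction < 0 || lipid_fraction > 1) {
    nf_validation_error("lipid_fraction must be in [0, 1]")
  }
  if (any(nc_ratios <= 0)) nf_validation_error("nc_ratios must be positive")
  structure(list(n_cells = as.integer(n_cells), nc_ratios = nc_ratios,
                 lipid_fraction = lipid_fraction, gradient = gradient,
                 voxel_size = voxel_size, base_intensity = base_intensity,
                 noise = noise, read_sd = read_sd),
            class = "image_scene_params")
}

# Ellipsoid voxel coordinates (z, y, x index matrix) around a center.
.ellipsoid_voxels <- function(center, radii, dims) {
  lo <- pmax(1, floor(center - radii))
  hi <- pmin(dims, ceiling(center + radii))
  g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3],
                   KEEP.OUT.ATTRS = FALSE)
  keep <- ((g$z - center[1]) / radii[1])^2 +
          ((g$y - center[2]) / radii[2])^2 +
          ((g$x - center[3]) / radii[3])^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate a labelled synthetic niche image volume
#'
#' Builds a monolayer of non-overlapping ellipsoidal nuclei with
#' surrounding cytoplasm shells inside a `(z, y, x)` volume, fills the
#' marker channel so each cell attains its prescribed
#' nuclear:cytoplasmic ratio, optionally packs lipid droplets into the
#' cytoplasm at an exact volume fraction, and emits per-cell ground truth.
#' Channels produced: `nuclear` (counterstain), `marker`, and `lipid` when
#' `lipid_fraction > 0`.
#'
#' @param params an [image_scene_params()].
#' @param dims volume dimensions `c(z, y, x)` in voxels.
#' @param nucleus_radii,cyto_radii ellipsoid semi-axes `c(z, y, x)` in
#'   voxels for nuclei and the surrounding cytoplasm.
#' @param seed integer seed.
#' @param max_tries placement attempts per cell before a packing error.
#' @return list with `volume` (a [labeled_volume()] whose labels are the
#'   ground-truth nuclei), `truth` (data.frame: `cell_id`, centroids in
#'   voxels, `nc_ratio`), and `lipid_fraction` (exact realized fraction).
#' @export
gen_niche_image <- function(params = image_scene_params(),
                            dims = c(9, 200, 200),
                            nucleus_radii = c(2, 5, 5),
                            cyto_radii = c(3, 9, 9),
                            seed = NULL, max_tries = 2000) {
  stopifnot(inherits(params, "image_scene_params"))
  local_seed(seed, {
    nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
    margin <- max(cyto_radii[2:3]) + 1
    if (2 * margin >= min(ny, nx)) {
      nf_packing_error("volume too small for the requested cell size")
    }
    min_sep <- 2 * max(cyto_radii[2:3]) + 2
    centers <- matrix(NA_real_, params$n_cells, 3)
    zc <- ceiling(nz / 2)
    placed <- 0L
    tries <- 0L
    while (placed < params$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries * params$n_cells) {
        nf_packing_error(sprintf(
          "could not place %d non-overlapping cells in a %d x %d field",
          params$n_cells, ny, nx))
      }
      cand <- c(zc, stats::runif(1, margin, ny - margin),
                stats::runif(1, margin, nx - margin))
      if (placed > 0L) {
        d <- sqrt((centers[seq_len(placed), 2] - cand[2])^2 +
                  (centers[seq_len(placed), 3] - cand[3])^2)
        if (min(d) < min_sep) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }

    labels <- array(0L, dims)
    cyto <- array(FALSE, dims)
    marker0 <- array(0, dims)
    nuclear0 <- array(5, dims)
    ratios <- rep_len(params$nc_ratios, params$n_cells)
    base <- params$base_intensity

    for (i in seq_len(params$n_cells)) {
      cvox <- .ellipsoid_voxels(centers[i, ], cyto_radii, dims)
      nvox <- .ellipsoid_voxels(centers[i, ], nucleus_radii, dims)
      cyto[cvox] <- TRUE
      labels[nvox] <- i
      gfac <- if (is.null(params$gradient)) 1 else
        1 + params$gradient * (centers[i, 3] / nx - 0.5)
      marker0[cvox] <- base
      marker0[nvox] <- base * ratios[i] * gfac
      nuclear0[nvox] <- 200
    }
    cyto[labels > 0L] <- FALSE  # cytoplasm excludes nuclear voxels

    channels <- list()
    lipid_realized <- 0
    if (params$lipid_fraction > 0) {
      lipid0 <- array(10, dims)
      cyto_idx <- which(cyto)
      n_target <- round(params$lipid_fraction * length(cyto_idx))
      droplet_r <- 2
      chosen <- logical(length(cyto_idx))
      pos <- match(seq_len(prod(dims)), cyto_idx)  # voxel -> cyto index
      while (sum(chosen) < n_target) {
        seed_idx <- cyto_idx[sample.int(length(cyto_idx), 1L)]
        ai <- arrayInd(seed_idx, dims)
        dvox <- .ellipsoid_voxels(as.numeric(ai), rep(droplet_r, 3), dims)
        lin <- (dvox[, 3] - 1L) * nz * ny + (dvox[, 2] - 1L) * nz + dvox[, 1]
        hit <- pos[lin]
        hit <- hit[!is.na(hit)]
        chosen[hit] <- TRUE
      }
      # trim the overshoot so the realized fraction is exact
      excess <- sum(chosen) - n_target
      if (excess > 0) {
        on_idx <- which(chosen)
        chosen[sample(on_idx, excess)] <- FALSE
      }
      lipid0[cyto_idx[chosen]] <- 150
      lipid_realized <- sum(chosen) / length(cyto_idx)
      channels$lipid <- lipid0
    }

    add_noise <- function(a) {
      if (params$noise == "none") return(a)
      shot <- array(stats::rpois(length(a), lambda = a), dim(a))
      shot + array(stats::rnorm(length(a), 0, params$read_sd), dim(a))
    }
    channels <- c(list(nuclear = add_noise(nuclear0),
                       marker = add_noise(marker0)),
                  lapply(channels, add_noise))

    vol <- labeled_volume(channels = channels, nuclear_labels = labels,
                          cytoplasm_mask = cyto,
                          voxel_size = params$voxel_size)
    truth <- data.frame(cell_id = seq_len(params$n_cells),
                        cz = centers[, 1], cy = centers[, 2],
                        cx = centers[, 3], nc_ratio = ratios)
    list(volume = vol, truth = truth, lipid_fraction = lipid_realized)
  })
}

#' Generate four-parameter logistic dose-response data
#'
#' @param bottom,top,ec50,hill true 4PL parameters (response =
#'   `bottom + (top - bottom) * dose^hill / (dose^hill + ec50^hill)`).
#' @param doses dose levels (>= 5 distinct values).
#' @param n_per_dose replicates per dose.
#' @param noise_sd Gaussian response noise.
#' @param seed integer seed.
#' @return list with `data` (data.frame `dose`, `response`) and `truth`.
#' @export
gen_dose_response <- function(bottom = 1, top = 3, ec50 = 2, hill = 2,
                              doses = c(0, 0.5, 1, 2, 4, 8),
                              n_per_dose = 4, noise_sd = 0.05, seed = NULL) {
  if (length(unique(doses)) < 5L) {
    nf_validation_error("need at least 5 distinct dose levels")
  }
  dose <- rep(doses, each = n_per_dose)
  mu <- .fourpl(dose, bottom, top, ec50, hill)
  response <- local_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  list(data = data.frame(dose = dose, response = response),
       truth = list(bottom = bottom, top = top, ec50 = ec50, hill = hill))
}
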