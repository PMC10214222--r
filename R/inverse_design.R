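# Inverse design: desired (Young's modulus, linewidth) -> fabrication
# variables (peg_pi, focus_z), then split of the unified index into monomer
# and photoinitiator concentrations along the characterized ellipse.

# Advertised interpolation envelope of the characterized state-space.
.envelope <- list(E = c(2, 20), W = c(40, 300), conjugate_max = 4)

#' Describe a design target
#'
#' @param E_des desired Young's modulus (kPa), > 0.
#' @param W_des desired linewidth (um), > 0.
#' @param conjugates named numeric vector of thiolated-species
#'   concentrations in mM, e.g. `c(RGD = 4)`; all >= 0.
#' @return An object of class `design_target`.
#' @export
design_target <- function(E_des, W_des, conjugates = numeric()) {
  if (!is.numeric(E_des) || length(E_des) != 1L || !is.finite(E_des) ||
      E_des <= 0) {
    nf_validation_error("E_des must be a single positive number (kPa)")
  }
  if (!is.numeric(W_des) || length(W_des) != 1L || !is.finite(W_des) ||
      W_des <= 0) {
    nf_validation_error("W_des must be a single positive number (um)")
  }
  conjugates <- unlist(conjugates)
  if (length(conjugates) > 0L) {
    if (is.null(names(conjugates)) || any(names(conjugates) == "")) {
      nf_validation_error("conjugates must be a named vector (species = mM)")
    }
    if (any(!is.finite(conjugates)) || any(conjugates < 0)) {
      nf_validation_error("conjugate concentrations must be finite and >= 0")
    }
  }
  structure(list(E_des = E_des, W_des = W_des,
                 conjugates = as.numeric(conjugates) |>
                   stats::setNames(names(conjugates))),
            class = "design_target")
}

.check_envelope <- function(target) {
  env <- .envelope
  if (target$E_des < env$E[1] || target$E_des > env$E[2]) {
    nf_envelope_error(sprintf(
      "E_des = %g kPa outside the characterized envelope [%g, %g] kPa",
      target$E_des, env$E[1], env$E[2]))
  }
  if (target$W_des < env$W[1] || target$W_des > env$W[2]) {
    nf_envelope_error(sprintf(
      "W_des = %g um outside the characterized envelope [%g, %g] um",
      target$W_des, env$W[1], env$W[2]))
  }
  if (length(target$conjugates) > 0L && any(target$conjugates > env$conjugate_max)) {
    bad <- names(target$conjugates)[target$conjugates > env$conjugate_max][1]
    nf_envelope_error(sprintf(
      "conjugate %s = %g mM exceeds the %g mM interpolation envelope",
      bad, target$conjugates[[bad]], env$conjugate_max))
  }
  invisible(TRUE)
}

#' Inverse-design objective
#'
#' Relative squared mismatch between the target properties and the
#' kernel-interpolated properties at fabrication coordinates `(x, z)`:
#' \deqn{\left(\frac{E_{des} - \hat E(x,z)}{E_{des}}\right)^2 +
#'       \left(\frac{W_{des} - \hat W(x,z)}{W_{des}}\right)^2}
#' Non-negative, and zero iff both properties are matched exactly.
#'
#' @param target a [design_target()].
#' @param space a [state_space()].
#' @param x,z query fabrication coordinates.
#' @return scalar objective value.
#' @export
design_objective <- function(target, space, x, z) {
  stopifnot(inherits(target, "design_target"))
  p <- interpolate_properties(space, x, z)
  ((target$E_des - p[["youngs_modulus"]]) / target$E_des)^2 +
    ((target$W_des - p[["linewidth"]]) / target$W_des)^2
}

#' Split the unified monomer-photoinitiator index
#'
#' The unified index couples monomer and photoinitiator concentration along
#' an ellipse: `((peg_pi - 50)/40)^2 + ((pi_conc - 0.5)/0.35)^2 = 1`. The
#' monomer concentration equals the index itself (% w/v); the
#' photoinitiator concentration is the real root of the ellipse at that
#' index. Both roots are positive over the domain, so a branch must be
#' chosen: the default `"upper"` branch
#' (`pi_conc = 0.5 + 0.35 * sqrt(1 - ((peg_pi - 50)/40)^2)`) makes the
#' initiator rise with the index mid-range, so stiffer prints use more
#' initiator; `"lower"` selects the mirror branch. At the ellipse apices
#' (`peg_pi` = 10 or 90) both branches coincide at `pi_conc = 0.5`.
#'
#' @param peg_pi unified index (vectorized); requires
#'   `|peg_pi - 50| <= 40`.
#' @param branch `"upper"` (default) or `"lower"`.
#' @return data.frame with columns `peg_conc` (% w/v) and `pi_conc`
#'   (% w/v), one row per input value.
#' @export
split_peg_pi <- function(peg_pi, branch = c("upper", "lower")) {
  branch <- match.arg(branch)
  if (any(!is.finite(peg_pi))) nf_validation_error("peg_pi must be finite")
  u <- (peg_pi - 50) / 40
  if (any(abs(u) > 1 + 1e-12)) {
    nf_domain_error(sprintf(
      "peg_pi = %g outside [10, 90]: the ellipse has no real solution",
      peg_pi[which(abs(u) > 1 + 1e-12)[1]]))
  }
  u <- pmin(1, pmax(-1, u))
  s <- if (branch == "upper") 1 else -1
  data.frame(peg_conc = peg_pi, pi_conc = 0.5 + s * 0.35 * sqrt(1 - u^2))
}

#' Solve fabrication variables for a design target
#'
#' Minimizes [design_objective()] over the fabrication coordinates with a
#' multistart derivative-free simplex search (Nelder-Mead), starting from
#' `n_starts` Latin-hypercube points spanning the bounding box of the
#' calibration records. The search runs in logistically transformed
#' coordinates so iterates remain inside that box, where the interpolant
#' is supported by data. Ties between equally optimal minima are broken
#' toward the smallest `|focus_z|`, then the smallest `peg_pi`. The
#' unified index of the best solution is split into monomer and
#' photoinitiator concentrations via [split_peg_pi()].
#'
#' @param target a [design_target()]; must lie inside the characterized
#'   envelope (E in \[2, 20\] kPa, W in \[40, 300\] um, conjugates <= 4 mM)
#'   unless `check_envelope = FALSE`.
#' @param space a [state_space()].
#' @param n_starts number of Latin-hypercube starts (default 8).
#' @param seed integer seed making the starts (and hence the solution)
#'   reproducible.
#' @param branch ellipse branch passed to [split_peg_pi()].
#' @param check_envelope set `FALSE` to bypass the envelope guard.
#' @return list with elements `variables` (class `fabrication_variables`:
#'   `peg_pi`, `focus_z`, `peg_conc`, `pi_conc`, `laser_power` = 100 % PWM,
#'   `scan_velocity` + `scan_velocity_unit`, `conjugates`) and `report`
#'   (class `solve_report`: `objective_value`, `achieved_E`, `achieved_W`,
#'   `iterations`, `converged`).
#' @export
solve_fabrication <- function(target, space, n_starts = 8, seed = NULL,
                              branch = c("upper", "lower"),
                              check_envelope = TRUE,
                              scan_velocity = 100,
                              scan_velocity_unit = "mm min^-1") {
  stopifnot(inherits(target, "design_target"), inherits(space, "state_space"))
  branch <- match.arg(branch)
  if (check_envelope) .check_envelope(target)

  rec <- space$records
  lo <- c(min(rec$peg_pi), min(rec$focus_z))
  hi <- c(max(rec$peg_pi), max(rec$focus_z))
  span <- hi - lo
  span[span == 0] <- 1  # degenerate (e.g. single-record) tables

  starts <- local_seed(seed, lhs::randomLHS(max(1L, as.integer(n_starts)), 2L))
  starts <- 0.02 + 0.96 * starts  # keep logistic transforms finite

  # Simplex search in logistically transformed coordinates: iterates stay
  # inside the calibration bounding box, where the interpolant is
  # meaningful; outside it the kernel smoother merely extrapolates the
  # edge records.
  to_box <- function(u) lo + span * stats::plogis(u)
  fn <- function(u) {
    par <- to_box(u)
    design_objective(target, space, par[1], par[2])
  }

  fits <- apply(stats::qlogis(starts), 1L, function(u0) {
    stats::optim(u0, fn, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 1000L))
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  iterations <- sum(vapply(fits, function(f) f$counts[["function"]],
                           numeric(1)))
  best_val <- min(values)
  cand <- which(values <= best_val + 1e-9)
  pars <- t(vapply(fits[cand], function(f) to_box(f$par), numeric(2)))
  ord <- order(abs(pars[, 2]), pars[, 1])
  sol <- pars[ord[1], ]
  best <- fits[[cand[ord[1]]]]

  if (!all(is.finite(sol))) {
    nf_solver_error("optimization diverged: non-finite solution")
  }
  if (abs(sol[1] - 50) > 40 + 1e-9) {
    nf_solver_error(sprintf(
      "solution peg_pi = %.3f left the ellipse domain [10, 90]; best objective %.3g",
      sol[1], best_val))
  }

  ach <- interpolate_properties(space, sol[1], sol[2])
  split <- split_peg_pi(sol[1], branch = branch)
  variables <- structure(list(
    peg_pi = unname(sol[1]), focus_z = unname(sol[2]),
    peg_conc = split$peg_conc[1], pi_conc = split$pi_conc[1],
    laser_power = 100, scan_velocity = scan_velocity,
    scan_velocity_unit = scan_velocity_unit,
    conjugates = target$conjugates, eq2_branch = branch
  ), class = "fabrication_variables")
  report <- structure(list(
    objective_value = best_val,
    achieved_E = unname(ach[["youngs_modulus"]]),
    achieved_W = unname(ach[["linewidth"]]),
    iterations = iterations,
    converged = best$convergence == 0L
  ), class = "solve_report")
  list(variables = variables, report = report)
}

#' @export
print.fabrication_variables <- function(x, ...) {
  cat(sprintf(
    "<fabrication_variables> peg_pi %.3f (peg %.3f, PI %.4f %% w/v), focus %.3f mm\n",
    x$peg_pi, x$peg_conc, x$pi_conc, x$focus_z))
  cat(sprintf("  laser %g%% PWM, scan %g %s\n",
              x$laser_power, x$scan_velocity, x$scan_velocity_unit))
  if (length(x$conjugates) > 0L) {
    cat("  conjugates:",
        paste(sprintf("%s %g mM", names(x$conjugates), x$conjugates),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a solved design to JSON
#'
#' @param solution the list returned by [solve_fabrication()].
#' @param path output file path.
#' @export
write_solution <- function(solution, path) {
  payload <- list(
    schema = "nichefab/solution/v1",
    variables = unclass(solution$variables),
    report = unclass(solution$report)
  )
  payload$variables$conjugates <- as.list(solution$variables$conjugates)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
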