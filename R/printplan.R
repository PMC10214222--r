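# Print-plan compilation: niche designs (regions with geometry + target
# properties) -> inverse-designed fabrication variables -> resist-batched,
# ordered print segments.
#
# Coordinate convention: niche frame in um, origin at the lower-left,
# x rightward, y upward. Array replicates are laid out row-major.

#' Niche region constructors
#'
#' A region couples geometry in the niche frame with a [design_target()].
#' Two geometries exist: a `filament` (an open polyline printed at the
#' target linewidth) and a `rect` (an axis-aligned rectangular domain to
#' be raster-filled).
#'
#' @param region_id unique region name.
#' @param path polyline as an `n x 2` matrix of `(x, y)` um, `n >= 2`.
#' @param linewidth filament width, um; must equal the target's `W_des`.
#' @param target a [design_target()].
#' @param origin rectangle lower-left corner `c(x, y)`, um.
#' @param width,height rectangle dimensions, um, > 0.
#' @return object of class `niche_region`.
#' @export
filament_region <- function(region_id, path, linewidth, target) {
  stopifnot(inherits(target, "design_target"))
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 2L) {
    nf_validation_error("filament path needs >= 2 (x, y) vertices")
  }
  if (linewidth <= 0) nf_validation_error("linewidth must be > 0")
  if (abs(linewidth - target$W_des) > 1e-9) {
    nf_validation_error(sprintf(
      "region %s: filament linewidth (%g) must equal target W_des (%g)",
      region_id, linewidth, target$W_des))
  }
  structure(list(region_id = as.character(region_id),
                 geometry = list(type = "filament", path = path,
                                 linewidth = linewidth),
                 target = target),
            class = "niche_region")
}

#' @rdname filament_region
#' @export
rect_region <- function(region_id, origin, width, height, target) {
  stopifnot(inherits(target, "design_target"))
  if (width <= 0 || height <= 0) {
    nf_validation_error("rectangle dimensions must be > 0")
  }
  structure(list(region_id = as.character(region_id),
                 geometry = list(type = "rect",
                                 origin = as.numeric(origin),
                                 width = width, height = height),
                 target = target),
            class = "niche_region")
}

#' Assemble a niche design
#'
#' @param name design name.
#' @param regions list of [filament_region()] / [rect_region()] objects
#'   with unique ids.
#' @param array_layout optional replicate grid:
#'   `list(rows, cols, pitch)` (pitch in um, row-major layout).
#' @return object of class `niche_design`.
#' @export
niche_design <- function(name, regions, array_layout = NULL) {
  if (length(regions) == 0L) nf_validation_error("design needs >= 1 region")
  ok <- vapply(regions, inherits, logical(1), "niche_region")
  if (!all(ok)) nf_validation_error("all regions must be niche_region objects")
  ids <- vapply(regions, `[[`, character(1), "region_id")
  if (anyDuplicated(ids)) {
    nf_validation_error(sprintf("duplicated region_id: %s",
                                ids[duplicated(ids)][1]))
  }
  structure(list(name = name, regions = regions,
                 array_layout = array_layout),
            class = "niche_design")
}

#' @export
print.niche_design <- function(x, ...) {
  cat(sprintf("<niche_design> '%s': %d region(s)\n", x$name,
              length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  %s [%s] E %g kPa, W %g um%s\n", r$region_id,
                r$geometry$type, r$target$E_des, r$target$W_des,
                if (length(r$target$conjugates) > 0L) {
                  paste0(", ", paste(sprintf("%s %g mM",
                                             names(r$target$conjugates),
                                             r$target$conjugates),
                                     collapse = ", "))
                } else ""))
  }
  invisible(x)
}

#' Validate a design against the characterized envelope
#'
#' Reports every region whose target leaves the interpolation envelope of
#' the state-space (E in \[2, 20\] kPa, W in \[40, 300\] um, conjugates
#' <= 4 mM). An empty report means the design is printable by
#' interpolation alone. Conjugate concentrations in (4, 8\] mM are flagged
#' with a note that such loadings have been printed experimentally beyond
#' the interpolated envelope.
#'
#' @param design a [niche_design()].
#' @return data.frame (possibly 0-row) with columns `region_id`, `field`,
#'   `value`, `bound`, `note`.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "niche_design"))
  env <- .envelope
  rows <- list()
  flag <- function(id, field, value, bound, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      region_id = id, field = field, value = value, bound = bound,
      note = note)
  }
  for (r in design$regions) {
    t <- r$target
    if (t$E_des < env$E[1] || t$E_des > env$E[2]) {
      flag(r$region_id, "E_des", t$E_des,
           sprintf("[%g, %g] kPa", env$E[1], env$E[2]))
    }
    if (t$W_des < env$W[1] || t$W_des > env$W[2]) {
      flag(r$region_id, "W_des", t$W_des,
           sprintf("[%g, %g] um", env$W[1], env$W[2]))
    }
    for (sp in names(t$conjugates)) {
      v <- t$conjugates[[sp]]
      if (v > env$conjugate_max) {
        flag(r$region_id, paste0("conjugate:", sp), v,
             sprintf("<= %g mM", env$conjugate_max),
             if (v <= 8) {
               "loadings up to 8 mM have been printed experimentally, beyond the interpolated envelope"
             } else "")
      }
    }
  }
  if (length(rows) == 0L) {
    data.frame(region_id = character(), field = character(),
               value = numeric(), bound = character(), note = character())
  } else {
    do.call(rbind, rows)
  }
}

# Serpentine raster of a rectangle: rows pitched by the achieved
# linewidth, overshooting the left/right edges by half a linewidth so the
# dilated footprint covers the corners.
.serpentine <- function(origin, width, height, linewidth,
                        edge_overshoot = TRUE) {
  n_rows <- max(1L, ceiling(height / linewidth))
  pitch <- height / n_rows
  ys <- origin[2] + (seq_len(n_rows) - 0.5) * pitch
  over <- if (edge_overshoot) linewidth / 2 else 0
  x0 <- origin[1] - over
  x1 <- origin[1] + width + over
  verts <- matrix(NA_real_, 2L * n_rows, 2L)
  for (i in seq_len(n_rows)) {
    xs <- if (i %% 2L == 1L) c(x0, x1) else c(x1, x0)
    verts[(2L * i - 1L):(2L * i), ] <- cbind(xs, ys[i])
  }
  verts
}

#' Compile a niche design into a print plan
#'
#' Solves fabrication variables for every region via
#' [solve_fabrication()] (regions sharing an identical target share one
#' solve, and hence one resist), generates print paths (filaments as their
#' polylines; rectangles as a serpentine raster pitched by the achieved
#' linewidth), groups segments by identical resist composition so each
#' resist is loaded exactly once, and orders batches stiff-to-soft
#' (descending monomer index) to mirror serial resist exchange.
#' Compilation is deterministic for a fixed seed and design.
#'
#' @param design a [niche_design()]; must pass [validate_design()] unless
#'   `allow_invalid = TRUE`.
#' @param space a [state_space()].
#' @param seed integer seed forwarded to the per-target solves.
#' @param allow_invalid compile even when the envelope report is non-empty.
#' @param edge_overshoot extend raster rows by half a linewidth beyond the
#'   rectangle edges so the filament footprint covers the corners.
#' @param ... further arguments to [solve_fabrication()].
#' @return object of class `print_plan`: `batches` (data.frame:
#'   `batch_id`, `peg_conc`, `pi_conc`, `conjugates` as a JSON-able list
#'   column), `segments` (list of segments: `path`, `focus_z`,
#'   `laser_power`, `scan_velocity`, `batch_id`, `region_id`),
#'   `exchange_count`, `solutions` (per unique target), `design_name`,
#'   `seed`.
#' @export
compile_plan <- function(design, space, seed = NULL, allow_invalid = FALSE,
                         edge_overshoot = TRUE, ...) {
  stopifnot(inherits(design, "niche_design"), inherits(space, "state_space"))
  report <- validate_design(design)
  if (nrow(report) > 0L && !allow_invalid) {
    nf_validation_error(sprintf(
      "design violates the envelope in region(s): %s (see validate_design())",
      paste(unique(report$region_id), collapse = ", ")))
  }

  # one solve per unique target; identical targets share a resist exactly
  keys <- vapply(design$regions, function(r) {
    t <- r$target
    paste(format(t$E_des, digits = 15), format(t$W_des, digits = 15),
          paste(names(t$conjugates), format(t$conjugates, digits = 15),
                sep = "=", collapse = ";"), sep = "|")
  }, character(1))
  uniq <- !duplicated(keys)
  solutions <- stats::setNames(vector("list", sum(uniq)), keys[uniq])
  for (k in which(uniq)) {
    key <- keys[k]
    sol <- tryCatch(
      solve_fabrication(design$regions[[k]]$target, space,
                        seed = if (is.null(seed)) NULL else
                          seed + match(key, names(solutions)),
                        check_envelope = !allow_invalid, ...),
      error = function(e) {
        nf_solver_error(sprintf("region %s failed to solve: %s",
                                design$regions[[k]]$region_id,
                                conditionMessage(e)))
      })
    solutions[[key]] <- sol
  }

  # resist batches: unique compositions (monomer, initiator, conjugates)
  comp_key <- function(v) {
    paste(sprintf("%.9f", v$peg_conc), sprintf("%.9f", v$pi_conc),
          paste(names(v$conjugates), sprintf("%.9f", v$conjugates),
                sep = "=", collapse = ";"), sep = "|")
  }
  region_comp <- vapply(keys, function(k) comp_key(solutions[[k]]$variables),
                        character(1))
  comp_levels <- unique(region_comp)
  comp_peg <- vapply(comp_levels, function(ck) {
    solutions[[keys[match(ck, region_comp)]]]$variables$peg_conc
  }, numeric(1))
  comp_levels <- comp_levels[order(-comp_peg)]  # stiff-to-soft
  batch_ids <- paste0("batch", seq_along(comp_levels))

  batches <- do.call(rbind, lapply(seq_along(comp_levels), function(i) {
    v <- solutions[[keys[match(comp_levels[i], region_comp)]]]$variables
    data.frame(batch_id = batch_ids[i], peg_conc = v$peg_conc,
               pi_conc = v$pi_conc,
               conjugates = I(list(as.list(v$conjugates))))
  }))

  segments <- list()
  for (b in seq_along(comp_levels)) {
    for (k in seq_along(design$regions)) {
      if (region_comp[k] != comp_levels[b]) next
      r <- design$regions[[k]]
      sol <- solutions[[keys[k]]]
      v <- sol$variables
      lw <- sol$report$achieved_W
      path <- if (r$geometry$type == "filament") {
        r$geometry$path
      } else {
        .serpentine(r$geometry$origin, r$geometry$width,
                    r$geometry$height, lw, edge_overshoot)
      }
      segments[[length(segments) + 1L]] <- list(
        path = path, focus_z = v$focus_z, laser_power = v$laser_power,
        scan_velocity = v$scan_velocity, batch_id = batch_ids[b],
        region_id = r$region_id, linewidth = lw)
    }
  }

  structure(list(batches = batches, segments = segments,
                 exchange_count = length(comp_levels) - 1L,
                 solutions = solutions, design_name = design$name,
                 seed = seed),
            class = "print_plan")
}

#' @export
print.print_plan <- function(x, ...) {
  cat(sprintf("<print_plan> '%s': %d batch(es), %d segment(s), %d exchange(s)\n",
              x$design_name, nrow(x$batches), length(x$segments),
              x$exchange_count))
  invisible(x)
}

#' Rasterized coverage of design regions by a plan's footprint
#'
#' Fraction of each region's area lying within half a linewidth of the
#' region's print paths, evaluated on a grid of sample points.
#'
#' @param plan a `print_plan`.
#' @param design the compiled [niche_design()].
#' @param resolution grid spacing, um.
#' @return named numeric vector of coverage fractions per region.
#' @export
plan_coverage <- function(plan, design, resolution = 5) {
  stopifnot(inherits(plan, "print_plan"), inherits(design, "niche_design"))
  seg_regions <- vapply(plan$segments, `[[`, character(1), "region_id")
  out <- numeric(0)
  for (r in design$regions) {
    segs <- plan$segments[seg_regions == r$region_id]
    if (length(segs) == 0L) { out[r$region_id] <- 0; next }
    if (r$geometry$type == "filament") {
      pts <- r$geometry$path  # footprint is the path itself
      half <- r$geometry$linewidth / 2
    } else {
      g <- r$geometry
      xs <- seq(g$origin[1] + resolution / 2, g$origin[1] + g$width,
                by = resolution)
      ys <- seq(g$origin[2] + resolution / 2, g$origin[2] + g$height,
                by = resolution)
      pts <- as.matrix(expand.grid(x = xs, y = ys))
      half <- max(vapply(segs, `[[`, numeric(1), "linewidth")) / 2
    }
    d2 <- rep(Inf, nrow(pts))
    for (s in segs) d2 <- pmin(d2, dist2_to_polyline(pts, s$path))
    out[r$region_id] <- mean(d2 <= half^2 + 1e-9)
  }
  out
}

#' Export / import a print plan
#'
#' Plans serialize to JSON (schema `nichefab/plan/v1`). Optionally an
#' additional plain-text motion listing is written with one line per path
#' vertex: `x y focus_z laser_power scan_velocity batch_id`.
#'
#' @param plan a `print_plan` with at least one segment.
#' @param path output JSON path.
#' @param motion_path optional text motion-listing path.
#' @return `read_plan` returns a `print_plan` (without solver reports).
#' @export
export_plan <- function(plan, path, motion_path = NULL) {
  stopifnot(inherits(plan, "print_plan"))
  if (length(plan$segments) == 0L) {
    nf_validation_error("refusing to export a plan with no segments")
  }
  payload <- list(
    schema = "nichefab/plan/v1",
    design_name = plan$design_name,
    seed = plan$seed,
    exchange_count = plan$exchange_count,
    batches = lapply(seq_len(nrow(plan$batches)), function(i) {
      list(batch_id = plan$batches$batch_id[i],
           peg_conc = plan$batches$peg_conc[i],
           pi_conc = plan$batches$pi_conc[i],
           conjugates = plan$batches$conjugates[[i]])
    }),
    segments = lapply(plan$segments, function(s) {
      list(path = unname(apply(s$path, 1L, as.numeric, simplify = FALSE)),
           focus_z = s$focus_z, laser_power = s$laser_power,
           scan_velocity = s$scan_velocity, batch_id = s$batch_id,
           region_id = s$region_id, linewidth = s$linewidth)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(motion_path)) {
    lines <- unlist(lapply(plan$segments, function(s) {
      sprintf("%.6g %.6g %.6g %g %g %s",
              s$path[, 1], s$path[, 2], s$focus_z, s$laser_power,
              s$scan_velocity, s$batch_id)
    }))
    writeLines(lines, motion_path)
  }
  invisible(path)
}

#' @rdname export_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) nf_format_error(sprintf("no such file: %s", path))
  p <- jsonlite::read_json(path)
  if (!identical(p$schema, "nichefab/plan/v1")) {
    nf_format_error("not a nichefab print-plan JSON (schema mismatch)")
  }
  batches <- do.call(rbind, lapply(p$batches, function(b) {
    data.frame(batch_id = b$batch_id, peg_conc = b$peg_conc,
               pi_conc = b$pi_conc, conjugates = I(list(b$conjugates)))
  }))
  segments <- lapply(p$segments, function(s) {
    list(path = do.call(rbind, lapply(s$path, unlist)),
         focus_z = s$focus_z, laser_power = s$laser_power,
         scan_velocity = s$scan_velocity, batch_id = s$batch_id,
         region_id = s$region_id, linewidth = s$linewidth)
  })
  structure(list(batches = batches, segments = segments,
                 exchange_count = p$exchange_count, solutions = NULL,
                 design_name = p$design_name, seed = p$seed),
            class = "print_plan")
}

#' Read / write niche designs as JSON
#'
#' Designs serialize to JSON (schema `nichefab/design/v1`) with one object
#' per region carrying its geometry and target. Example designs
#' reproducing published parameter sets ship in
#' `system.file("extdata", package = "nichefab")`.
#'
#' @param design a [niche_design()].
#' @param path JSON path.
#' @return `read_design` returns a `niche_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "niche_design"))
  payload <- list(
    schema = "nichefab/design/v1",
    name = design$name,
    array_layout = design$array_layout,
    regions = lapply(design$regions, function(r) {
      g <- r$geometry
      geom <- if (g$type == "filament") {
        list(type = "filament",
             path = unname(apply(g$path, 1L, as.numeric, simplify = FALSE)),
             linewidth = g$linewidth)
      } else {
        list(type = "rect", origin = g$origin, width = g$width,
             height = g$height)
      }
      list(region_id = r$region_id, geometry = geom,
           target = list(E_des = r$target$E_des, W_des = r$target$W_des,
                         conjugates = as.list(r$target$conjugates)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) nf_format_error(sprintf("no such file: %s", path))
  p <- jsonlite::read_json(path)
  if (!identical(p$schema, "nichefab/design/v1")) {
    nf_format_error("not a nichefab design JSON (schema mismatch)")
  }
  regions <- lapply(p$regions, function(r) {
    conj <- unlist(r$target$conjugates) %||% numeric()
    target <- design_target(r$target$E_des, r$target$W_des, conj)
    g <- r$geometry
    if (g$type == "filament") {
      filament_region(r$region_id, do.call(rbind, lapply(g$path, unlist)),
                      g$linewidth, target)
    } else {
      rect_region(r$region_id, unlist(g$origin), g$width, g$height, target)
    }
  })
  layout <- p$array_layout
  if (!is.null(layout)) layout <- lapply(layout, function(v) unlist(v))
  niche_design(p$name, regions, layout)
}
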