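# Image quantification: nuclear segmentation stand-in, per-cell
# nuclear:cytoplasmic marker ratios, lipid volume fractions, red-saturation
# mineralization scores, pooled niche-registered expression maps, and 4PL
# dose-response fitting.
#
# Array convention: (z, y, x), 0-based voxel positions when exported,
# 1-based inside R; the niche frame is in um with origin at the lower-left
# and y pointing up (matching the print-plan frame).

#' Bundle image channels with label masks
#'
#' @param channels named list of 3-D (`z, y, x`) intensity arrays (2-D
#'   arrays are promoted to a single slice).
#' @param nuclear_labels integer array of the same shape; 0 = background,
#'   nuclei labelled contiguously from 1.
#' @param cytoplasm_mask logical array of the same shape. The package uses
#'   the disjoint convention: the mask holds the *non-nuclear* cytoplasmic
#'   voxels. A mask that still contains the nuclei is accepted; nuclear
#'   voxels are always excluded from cytoplasmic statistics.
#' @param voxel_size physical voxel size `c(z, y, x)` in um.
#' @param niche_transform optional affine voxel-to-niche map: a list with
#'   `offset` (um, `c(x, y)`) and optionally a 2x2 `matrix`; niche coords =
#'   `matrix %*% (voxel xy * voxel size) + offset`.
#' @param replicate_id optional identifier carried into pooled maps.
#' @return object of class `labeled_volume`.
#' @export
labeled_volume <- function(channels, nuclear_labels, cytoplasm_mask,
                           voxel_size = c(1, 1, 1), niche_transform = NULL,
                           replicate_id = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    nf_validation_error("channels must be a named list of arrays")
  }
  promote <- function(a) if (length(dim(a)) == 2L)
    array(a, c(1L, dim(a))) else a
  channels <- lapply(channels, promote)
  nuclear_labels <- promote(nuclear_labels)
  cytoplasm_mask <- promote(cytoplasm_mask)
  shp <- dim(channels[[1]])
  ok <- vapply(channels, function(a) identical(dim(a), shp), logical(1))
  if (!all(ok) || !identical(dim(nuclear_labels), shp) ||
      !identical(dim(cytoplasm_mask), shp)) {
    nf_validation_error("all channels and masks must share the same shape")
  }
  k <- max(nuclear_labels)
  if (k > 0L && !setequal(unique(as.integer(nuclear_labels)), 0:k)) {
    nf_validation_error("nuclear labels must be contiguous from 1")
  }
  structure(list(channels = channels,
                 nuclear_labels = nuclear_labels,
                 cytoplasm_mask = as.logical(cytoplasm_mask) |>
                   array(shp),
                 voxel_size = voxel_size,
                 niche_transform = niche_transform,
                 replicate_id = replicate_id),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, %d nuclei, channels: %s\n",
              paste(dim(x$nuclear_labels), collapse = " x "),
              max(x$nuclear_labels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Threshold/watershed nuclei segmentation (StarDist stand-in)
#'
#' Deterministic classical segmentation of a nuclear counterstain:
#' Gaussian smoothing, Otsu threshold, Euclidean distance transform and
#' watershed splitting of touching nuclei. For a 3-D stack the
#' segmentation runs on the maximum-intensity projection and labels are
#' propagated through the thresholded volume, which assumes a cell
#' monolayer (the geometry of cells cultured on printed niches). Any
#' externally produced label image (e.g. from a trained network) can be
#' used instead wherever a label array is accepted.
#'
#' @param nuclear_channel 2-D (`y, x`) or 3-D (`z, y, x`) intensity array.
#' @param sigma Gaussian smoothing radius (pixels).
#' @param min_size discard objects smaller than this many pixels (2-D
#'   footprint).
#' @return integer label array of the input shape (0 = background),
#'   labels contiguous from 1.
#' @export
segment_nuclei_simple <- function(nuclear_channel, sigma = 2, min_size = 20) {
  a <- nuclear_channel
  is3d <- length(dim(a)) == 3L
  proj <- if (is3d) apply(a, c(2, 3), max) else a
  rng <- range(proj)
  if (diff(rng) == 0) {
    warning("blank image: no nuclei found")
    return(array(0L, dim(a)))
  }
  img <- (proj - rng[1]) / diff(rng)
  # EBImage works on (x, y) matrices; transpose in and out.
  sm <- EBImage::gblur(EBImage::Image(t(img)), sigma = sigma)
  th <- otsu_threshold(as.numeric(sm))
  mask <- sm > th
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab2 <- t(EBImage::imageData(lab))
  sizes <- tabulate(lab2[lab2 > 0])
  keep <- which(sizes >= min_size)
  lab2[!(lab2 %in% keep)] <- 0L
  lab2 <- array(match(lab2, sort(unique(lab2[lab2 > 0])), nomatch = 0L),
                dim(lab2))
  if (max(lab2) == 0L) {
    warning("blank image: no nuclei found")
    return(array(0L, dim(a)))
  }
  if (!is3d) return(lab2)
  th3 <- rng[1] + th * diff(rng)
  out <- array(0L, dim(a))
  for (z in seq_len(dim(a)[1])) {
    slice_mask <- a[z, , ] > th3
    out[z, , ] <- lab2 * slice_mask
  }
  out
}

#' Per-cell nuclear:cytoplasmic marker ratios
#'
#' For every labelled nucleus, computes the mean marker intensity over its
#' nuclear voxels and over its share of the (non-nuclear) cytoplasm, and
#' their ratio. Multi-cell fields are partitioned by assigning each
#' cytoplasmic voxel to the nearest nuclear centroid (distances in um,
#' respecting voxel anisotropy). Cells whose cytoplasm partition is empty
#' are dropped; their count is attached as attribute `n_dropped`.
#'
#' @param volume a [labeled_volume()].
#' @param channel name of the marker channel.
#' @return data.frame, one row per retained cell: `cell_id`, niche-frame
#'   centroid `x`, `y` (um), `nuclear_mean`, `cytoplasmic_mean`,
#'   `nc_ratio`, `nuclear_volume_um3`, `n_cyto_voxels`; attribute
#'   `n_dropped`.
#' @export
nc_ratio <- function(volume, channel = "marker") {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!channel %in% names(volume$channels)) {
    nf_validation_error(sprintf("channel '%s' not present (have: %s)",
                                channel,
                                paste(names(volume$channels), collapse = ", ")))
  }
  ch <- volume$channels[[channel]]
  labs <- volume$nuclear_labels
  k <- max(labs)
  if (k == 0L) nf_validation_error("no labelled nuclei in volume")

  nuc_idx <- which(labs > 0L)
  nuc_lab <- labs[nuc_idx]
  nuclear_sum <- rowsum(ch[nuc_idx], nuc_lab)
  nuclear_n <- tabulate(nuc_lab, k)
  nuclear_mean <- as.numeric(nuclear_sum) / nuclear_n

  vs <- volume$voxel_size
  nuc_pos <- arrayInd(nuc_idx, dim(labs))
  cent <- matrix(vapply(1:3, function(j) {
    as.numeric(rowsum(nuc_pos[, j] * vs[j], nuc_lab)) / nuclear_n
  }, numeric(k)), nrow = k)  # k x 3 centroids in um (z, y, x)

  cyto_idx <- which(volume$cytoplasm_mask & labs == 0L)
  if (length(cyto_idx) == 0L) {
    nf_validation_error("cytoplasm mask is empty outside the nuclei")
  }
  cyto_pos <- arrayInd(cyto_idx, dim(labs))
  d2 <- matrix(0, length(cyto_idx), k)
  for (j in 1:3) {
    d2 <- d2 + outer(cyto_pos[, j] * vs[j], cent[, j], `-`)^2
  }
  assignment <- max.col(-d2, ties.method = "first")
  cyto_sum <- rowsum(ch[cyto_idx], factor(assignment, levels = 1:k))
  cyto_n <- tabulate(assignment, k)
  cyto_mean <- ifelse(cyto_n > 0, as.numeric(cyto_sum) / cyto_n, NA_real_)

  # centroid voxel (y, x) -> niche frame
  xy_um <- cbind(x = cent[, 3], y = cent[, 2])
  tr <- volume$niche_transform
  if (!is.null(tr)) {
    m <- tr$matrix %||% diag(2)
    xy_um <- t(m %*% t(xy_um)) +
      matrix(tr$offset %||% c(0, 0), k, 2, byrow = TRUE)
  }

  out <- data.frame(
    cell_id = seq_len(k), x = xy_um[, 1], y = xy_um[, 2],
    nuclear_mean = nuclear_mean, cytoplasmic_mean = cyto_mean,
    nc_ratio = nuclear_mean / cyto_mean,
    nuclear_volume_um3 = nuclear_n * prod(vs),
    n_cyto_voxels = cyto_n
  )
  dropped <- sum(cyto_n == 0 | !is.finite(out$nc_ratio))
  out <- out[cyto_n > 0 & is.finite(out$nc_ratio), , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' Fat-to-cytoplasm volume fraction
#'
#' Thresholds the lipid channel inside the cytoplasm mask (Otsu by
#' default, or a fixed threshold) and reports the volumetric ratio of
#' lipid voxels to total cytoplasm voxels for the field of view.
#'
#' @param volume a [labeled_volume()].
#' @param channel lipid channel name.
#' @param threshold `NULL` (Otsu within the cytoplasm) or a fixed
#'   intensity threshold.
#' @return list: `ratio` (in \[0, 1\]), `threshold`, `n_cyto`, `n_lipid`.
#' @export
fat_cyto <- function(volume, channel = "lipid", threshold = NULL) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (!channel %in% names(volume$channels)) {
    nf_validation_error(sprintf("channel '%s' not present", channel))
  }
  cyto <- volume$cytoplasm_mask & volume$nuclear_labels == 0L
  n_cyto <- sum(cyto)
  if (n_cyto == 0L) nf_validation_error("empty cytoplasm: ratio undefined")
  vals <- volume$channels[[channel]][cyto]
  th <- threshold %||% otsu_threshold(vals)
  n_lipid <- sum(vals > th)
  list(ratio = n_lipid / n_cyto, threshold = th,
       n_cyto = n_cyto, n_lipid = n_lipid)
}

#' Red-saturation mineralization score
#'
#' For a colour image and region of interest, the mean of the red channel
#' divided by the mean total saturation (sum of the red, green and blue
#' means). Equals 1/3 on any achromatic region and 1 on pure red.
#'
#' @param rgb_image numeric array `(y, x, 3)`.
#' @param roi either a logical `(y, x)` mask or a polygon as an `n x 2`
#'   matrix of `(x, y)` pixel coordinates.
#' @return scalar score in \[0, 1\].
#' @export
alizarin_score <- function(rgb_image, roi = NULL) {
  d <- dim(rgb_image)
  if (length(d) != 3L || d[3] != 3L) {
    nf_validation_error("rgb_image must be a (y, x, 3) array")
  }
  mask <- if (is.null(roi)) {
    matrix(TRUE, d[1], d[2])
  } else if (is.logical(roi)) {
    if (!identical(dim(roi), d[1:2])) {
      nf_geometry_error("ROI mask shape does not match the image")
    }
    roi
  } else {
    roi <- as.matrix(roi)
    if (any(roi[, 1] < 0) || any(roi[, 1] > d[2]) ||
        any(roi[, 2] < 0) || any(roi[, 2] > d[1])) {
      nf_geometry_error("ROI polygon extends outside the image")
    }
    px <- expand.grid(x = seq_len(d[2]) - 0.5, y = seq_len(d[1]) - 0.5)
    inside <- mgcv::in.out(rbind(roi, roi[1, ]), as.matrix(px))
    matrix(inside, d[1], d[2], byrow = TRUE)
  }
  if (!any(mask)) nf_geometry_error("ROI covers no pixels")
  means <- vapply(1:3, function(c) mean(rgb_image[, , c][mask]), numeric(1))
  if (sum(means) == 0) nf_validation_error("ROI is entirely black")
  means[1] / sum(means)
}

#' Pool per-cell measurements into a niche-registered expression map
#'
#' Applies each replicate's voxel-to-niche transform, rescales intensities
#' per replicate and channel (1st-99th percentile to \[0, 1\] by default,
#' or min-max), pools all cells into the common niche frame, and bins them
#' into a mean-intensity surface. Cells falling outside the niche bounding
#' box after transformation are excluded and counted.
#'
#' @param measurements list of per-replicate data.frames with columns
#'   `x`, `y` (replicate-local um), `channel`, `value` (e.g. built from
#'   [nc_ratio()] output).
#' @param transforms list (same length) of transforms: each `NULL`
#'   (identity) or a list with `offset = c(x, y)` um and optional 2x2
#'   `matrix`, mapping replicate coordinates into the common niche frame.
#' @param niche_size `c(width, height)` of the niche bounding box, um.
#' @param bin_um surface bin size, um.
#' @param normalize `"percentile"` (1st-99th, default) or `"minmax"`.
#' @param property_regions optional named list of rectangles
#'   (`list(origin = c(x, y), width, height)`) for per-region summaries.
#' @return object of class `niche_map`: `cells` (pooled data.frame with
#'   `x`, `y`, `channel`, `intensity` in \[0, 1\], `replicate_id`),
#'   `surface` (data.frame `channel`, `bin_x`, `bin_y`, bin centers, `mean`,
#'   `n`), `regions` (per-region summaries or NULL), `n_input`,
#'   `n_excluded`.
#' @export
map_expression <- function(measurements, transforms = NULL,
                           niche_size = c(1000, 1000), bin_um = 50,
                           normalize = c("percentile", "minmax"),
                           property_regions = NULL) {
  normalize <- match.arg(normalize)
  if (!is.list(measurements) || length(measurements) == 0L) {
    nf_validation_error("measurements must be a non-empty list of data.frames")
  }
  if (is.null(transforms)) {
    nf_config_error("transforms are required (use list(NULL, ...) for identity)")
  }
  if (length(transforms) != length(measurements)) {
    nf_config_error("need one transform per replicate")
  }

  pooled <- vector("list", length(measurements))
  for (r in seq_along(measurements)) {
    m <- measurements[[r]]
    if (!all(c("x", "y", "channel", "value") %in% names(m))) {
      nf_validation_error("each replicate needs columns x, y, channel, value")
    }
    tr <- transforms[[r]]
    xy <- cbind(m$x, m$y)
    if (!is.null(tr)) {
      mat <- tr$matrix %||% diag(2)
      xy <- t(mat %*% t(xy)) +
        matrix(tr$offset %||% c(0, 0), nrow(xy), 2, byrow = TRUE)
    }
    val <- m$value
    for (ch in unique(m$channel)) {
      sel <- m$channel == ch
      v <- val[sel]
      rng <- if (normalize == "percentile") {
        stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
      } else {
        range(v)
      }
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      val[sel] <- pmin(1, pmax(0, (v - rng[1]) / diff(rng)))
    }
    pooled[[r]] <- data.frame(x = xy[, 1], y = xy[, 2],
                              channel = m$channel, intensity = val,
                              replicate_id = r)
  }
  cells <- do.call(rbind, pooled)
  n_input <- nrow(cells)
  inside <- cells$x >= 0 & cells$x <= niche_size[1] &
            cells$y >= 0 & cells$y <= niche_size[2]
  n_excluded <- sum(!inside)
  cells <- cells[inside, , drop = FALSE]
  if (nrow(cells) == 0L) {
    nf_validation_error(
      "all cells fall outside the niche bounding box after transformation")
  }

  bx <- pmin(ceiling(niche_size[1] / bin_um),
             pmax(1L, ceiling(cells$x / bin_um)))
  by <- pmin(ceiling(niche_size[2] / bin_um),
             pmax(1L, ceiling(cells$y / bin_um)))
  surface <- stats::aggregate(
    list(mean = cells$intensity),
    by = list(channel = cells$channel, bin_x = bx, bin_y = by),
    FUN = mean)
  counts <- stats::aggregate(
    list(n = cells$intensity),
    by = list(channel = cells$channel, bin_x = bx, bin_y = by),
    FUN = length)
  surface$n <- counts$n
  surface$x <- (surface$bin_x - 0.5) * bin_um
  surface$y <- (surface$bin_y - 0.5) * bin_um

  regions <- NULL
  if (!is.null(property_regions)) {
    regions <- do.call(rbind, lapply(names(property_regions), function(nm) {
      rg <- property_regions[[nm]]
      sel <- cells$x >= rg$origin[1] & cells$x <= rg$origin[1] + rg$width &
             cells$y >= rg$origin[2] & cells$y <= rg$origin[2] + rg$height
      if (!any(sel)) {
        return(data.frame(region = nm, channel = NA, mean = NA, n = 0L))
      }
      stats::aggregate(
        list(mean = cells$intensity[sel]),
        by = list(channel = cells$channel[sel]), FUN = mean) |>
        transform(region = nm, n = as.integer(table(cells$channel[sel])[channel]))
    }))
  }

  structure(list(cells = cells, surface = surface, regions = regions,
                 niche_size = niche_size, bin_um = bin_um,
                 n_input = n_input, n_excluded = n_excluded),
            class = "niche_map")
}

#' @export
print.niche_map <- function(x, ...) {
  cat(sprintf("<niche_map> %d pooled cells (%d excluded), %d surface bins, niche %g x %g um\n",
              nrow(x$cells), x$n_excluded, nrow(x$surface),
              x$niche_size[1], x$niche_size[2]))
  invisible(x)
}

.fourpl <- function(dose, bottom, top, ec50, hill) {
  # ratio form handles dose = 0 for either sign of the hill slope
  bottom + (top - bottom) / (1 + (ec50 / dose)^hill)
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Bounded least-squares fit of
#' `response = bottom + (top - bottom) * dose^hill / (dose^hill + ec50^hill)`
#' (Levenberg-Marquardt). EC50 is constrained to \[0.01, 100\] times the
#' positive dose range. A constant response returns a degenerate
#' `bottom == top` fit flagged via `degenerate = TRUE`.
#'
#' @param dose dose vector (>= 5 distinct levels, >= 0).
#' @param response response vector, same length.
#' @return object of class `sigmoid_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `rss`, `converged`, `degenerate`.
#' @export
fit_sigmoid <- function(dose, response) {
  if (length(dose) != length(response)) {
    nf_validation_error("dose and response must have equal length")
  }
  if (length(unique(dose)) < 5L) {
    nf_validation_error("need at least 5 distinct dose levels")
  }
  if (stats::sd(response) < 1e-12) {
    m <- mean(response)
    return(structure(list(bottom = m, top = m, ec50 = NA_real_,
                          hill = NA_real_, rss = sum((response - m)^2),
                          converged = TRUE, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  pos <- dose[dose > 0]
  start <- list(bottom = min(response), top = max(response),
                ec50 = stats::median(pos), hill = 1)
  lower <- c(bottom = -Inf, top = -Inf, ec50 = min(pos) * 0.01, hill = 0.1)
  upper <- c(bottom = Inf, top = Inf, ec50 = max(pos) * 100, hill = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ .fourpl(dose, bottom, top, ec50, hill),
      data = data.frame(dose = dose, response = response),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    nf_solver_error("4PL fit failed to converge from data-driven start")
  }
  p <- as.list(stats::coef(fit))
  if (p$top < p$bottom) {  # canonical orientation: top >= bottom
    tmp <- p$top; p$top <- p$bottom; p$bottom <- tmp
    p$hill <- -p$hill
  }
  structure(list(bottom = p$bottom, top = p$top, ec50 = p$ec50,
                 hill = p$hill, rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> bottom %.4g, top %.4g, ec50 %.4g, hill %.4g (rss %.3g)%s\n",
              x$bottom, x$top, x$ec50, x$hill, x$rss,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
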