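test_that("well-separated nuclei are segmented to the exact count", {
  gen <- gen_niche_image(image_scene_params(n_cells = 10, noise = "none"),
                         dims = c(7, 160, 160), seed = 3)
  lab <- segment_nuclei_simple(gen$volume$channels$nuclear)
  expect_identical(max(lab), 10L)
  # centroids near truth (y, x within ~1 voxel of the generator's centers)
  got <- t(vapply(1:10, function(i) {
    idx <- arrayInd(which(lab == i), dim(lab))
    c(mean(idx[, 2]), mean(idx[, 3]))
  }, numeric(2)))
  truth <- as.matrix(gen$truth[, c("cy", "cx")])
  d <- vapply(1:10, function(i) {
    min(sqrt(rowSums(sweep(truth, 2, got[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 1.5)
})

test_that("blank images yield zero labels with a warning", {
  expect_warning(lab <- segment_nuclei_simple(array(0, c(3, 40, 40))),
                 "blank")
  expect_identical(max(lab), 0L)
})

test_that("touching nuclei are split by the watershed", {
  img <- matrix(0, 80, 80)
  xy <- as.matrix(expand.grid(y = 1:80, x = 1:80))
  d1 <- sqrt((xy[, 1] - 40)^2 + (xy[, 2] - 32)^2)
  d2 <- sqrt((xy[, 1] - 40)^2 + (xy[, 2] - 49)^2)
  img[d1 <= 10 | d2 <= 10] <- 1  # two overlapping discs, distinct centers
  lab <- segment_nuclei_simple(img, sigma = 1)
  expect_identical(max(lab), 2L)
})

test_that("nc_ratio reproduces constructed ratios exactly", {
  # one cell, noise-free: nucleus 200, cytoplasm 100 -> ratio 2
  gen <- gen_niche_image(image_scene_params(n_cells = 1, nc_ratios = 2,
                                            noise = "none"),
                         dims = c(7, 60, 60), seed = 1)
  cells <- nc_ratio(gen$volume, "marker")
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$nuclear_mean, 200)
  expect_equal(cells$cytoplasmic_mean, 100)
  expect_equal(cells$nc_ratio, 2)

  # uniform intensity everywhere -> ratio 1 for every cell
  genu <- gen_niche_image(image_scene_params(n_cells = 5, nc_ratios = 1,
                                             noise = "none"),
                          dims = c(7, 140, 140), seed = 2)
  cellsu <- nc_ratio(genu$volume, "marker")
  expect_equal(cellsu$nc_ratio, rep(1, 5))

  # invariance to positive channel rescaling
  v <- genu$volume
  v$channels$marker <- v$channels$marker * 37.5
  expect_equal(nc_ratio(v, "marker")$nc_ratio, cellsu$nc_ratio)

  expect_error(nc_ratio(gen$volume, "missing_channel"),
               class = "nichefab_validation_error")
})

test_that("nc_ratio recovers noisy ground truth within 10% per level", {
  for (r in c(0.5, 2)) {
    gen <- gen_niche_image(image_scene_params(n_cells = 12, nc_ratios = r),
                           dims = c(9, 180, 180), seed = round(100 * r))
    cells <- nc_ratio(gen$volume, "marker")
    expect_lt(abs(stats::median(cells$nc_ratio) - r) / r, 0.1)
  }
})

test_that("fat_cyto reports exact constructed fractions", {
  gen <- gen_niche_image(image_scene_params(n_cells = 6, noise = "none"),
                         dims = c(7, 140, 140), seed = 4)
  v <- gen$volume
  # no lipid channel signal -> 0
  v$channels$lipid <- array(0, dim(v$nuclear_labels))
  v$channels$lipid[1, 1, 1] <- 1  # non-constant so Otsu is defined
  expect_equal(fat_cyto(v)$ratio, 0)

  # lipid mask constructed as exactly 30% of cytoplasm voxels
  cyto_idx <- which(v$cytoplasm_mask & v$nuclear_labels == 0L)
  n30 <- round(0.3 * length(cyto_idx))
  lip <- array(10, dim(v$nuclear_labels))
  lip[cyto_idx[seq_len(n30)]] <- 150
  v$channels$lipid <- lip
  expect_equal(fat_cyto(v)$ratio, n30 / length(cyto_idx))

  # generator-packed droplets at known fractions, Otsu threshold
  for (f in c(0.15, 0.35)) {
    g <- gen_niche_image(image_scene_params(n_cells = 6, lipid_fraction = f),
                         dims = c(7, 140, 140), seed = round(1000 * f))
    got <- fat_cyto(g$volume)$ratio
    expect_lt(abs(got - g$lipid_fraction) / g$lipid_fraction, 0.1)
  }
})

test_that("alizarin score follows the red-saturation definition", {
  pure_red <- array(0, c(12, 12, 3)); pure_red[, , 1] <- 1
  expect_equal(alizarin_score(pure_red), 1)
  gray <- array(0.42, c(12, 12, 3))
  expect_equal(alizarin_score(gray), 1 / 3)
  mixed <- array(0, c(12, 12, 3))
  mixed[, , 1] <- 120 / 255; mixed[, , 2] <- 60 / 255; mixed[, , 3] <- 60 / 255
  expect_equal(alizarin_score(mixed), 0.5)

  # polygon ROI restricted to the red half of a half-red/half-gray image
  img <- array(0.3, c(20, 40, 3))
  img[, 1:20, 2:3] <- 0  # left half pure red at 0.3
  roi <- rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20))
  expect_equal(alizarin_score(img, roi), 1)
  expect_error(alizarin_score(img, rbind(c(-5, 0), c(50, 0), c(50, 20))),
               class = "nichefab_geometry_error")
})

test_that("expression maps pool replicates into a common frame", {
  set.seed(8)
  m1 <- data.frame(x = runif(60, 50, 950), y = runif(60, 50, 950),
                   channel = "SOX2", value = rnorm(60, 5))
  # identity transform: pooled coordinates equal input centroids
  nm1 <- map_expression(list(m1), list(NULL))
  expect_equal(nm1$cells$x, m1$x)
  expect_equal(nm1$cells$y, m1$y)
  expect_true(all(nm1$cells$intensity >= 0 & nm1$cells$intensity <= 1))

  # two replicates offset by 100 um coincide after their transforms
  m2 <- m1; m2$x <- m2$x + 100
  nm <- map_expression(list(m1, m2), list(NULL, list(offset = c(-100, 0))))
  a <- nm$cells[nm$cells$replicate_id == 1, c("x", "y")]
  b <- nm$cells[nm$cells$replicate_id == 2, c("x", "y")]
  expect_lt(mean(sqrt(rowSums((a - b)^2))), 1)
  # cell-count conservation
  expect_identical(nm$n_input, nrow(nm$cells) + nm$n_excluded)

  # missing transforms are a configuration error
  expect_error(map_expression(list(m1)), class = "nichefab_config_error")
  expect_error(map_expression(list(m1), list(NULL, NULL)),
               class = "nichefab_config_error")
})

test_that("gradient scenes produce monotone binned means along x", {
  gen <- gen_niche_image(image_scene_params(n_cells = 18, nc_ratios = 2,
                                            gradient = 0.8, noise = "none"),
                         dims = c(7, 220, 220), seed = 6)
  cells <- nc_ratio(gen$volume, "marker")
  m <- data.frame(x = cells$x, y = cells$y, channel = "marker",
                  value = cells$nuclear_mean)
  nm <- map_expression(list(m), list(NULL), niche_size = c(110, 110),
                       bin_um = 110 / 3)
  prof <- tapply(nm$surface$mean, nm$surface$bin_x, mean)
  expect_true(all(diff(prof) > 0))
})

test_that("4PL fits recover parameters and flag degenerate input", {
  # noise-free samples: all four parameters to 1e-3 relative
  d <- gen_dose_response(bottom = 1, top = 3, ec50 = 2, hill = 2,
                         noise_sd = 0, seed = 1)
  fit <- fit_sigmoid(d$data$dose, d$data$response)
  expect_lt(abs(fit$bottom - 1), 1e-3)
  expect_lt(abs(fit$top - 3) / 3, 1e-3)
  expect_lt(abs(fit$ec50 - 2) / 2, 1e-3)
  expect_lt(abs(fit$hill - 2) / 2, 1e-3)

  # constant response -> degenerate bottom == top
  flat <- fit_sigmoid(c(0, 1, 2, 4, 8), rep(2.5, 5))
  expect_true(flat$degenerate)
  expect_identical(flat$bottom, flat$top)

  expect_error(fit_sigmoid(c(1, 2, 2, 1), c(1, 2, 2, 1)),
               class = "nichefab_validation_error")
})
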