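test_that("a bare slab has exactly t luminal voxels per column", {
  cf <- simulation_config(n_holes = 0, sheet_thickness_nm = 50)
  vol <- build_hole_volume(cf)
  expect_true(all(vol$counts == 50L))
  cf2 <- simulation_config(n_holes = 0, sheet_thickness_nm = 30)
  expect_true(all(build_hole_volume(cf2)$counts == 30L))
})

test_that("hole columns follow the torus cross-section depth profile", {
  cf <- simulation_config(n_holes = 1, hole_inner_diameter_nm = 100,
                          jitter = FALSE)
  vol <- build_hole_volume(cf)
  gt <- vol$ground_truth
  sub <- vol$subpixel_nm
  i0 <- round(gt$y_nm / sub + 0.5)
  x <- (seq_len(ncol(vol$counts)) - 0.5) * sub
  r <- abs(x - gt$x_nm)
  cnt <- vol$counts[i0, ]
  # no lumen within the inner radius, full slab beyond the rim, torus
  # lens in between: z(r) = 2 sqrt((t/2)^2 - (R_h - r)^2)
  expect_true(all(cnt[r <= 50 - sub] == 0L))
  expect_true(all(cnt[r >= 75 + sub] == 50L))
  mid <- r > 50 + sub & r < 75 - sub
  theory <- 2 * sqrt(pmax(25^2 - (75 - r[mid])^2, 0))
  expect_lt(max(abs(cnt[mid] - theory)), 1.01)  # within one axial voxel
})

test_that("25 holes land on a jittered grid with full ground truth", {
  cf <- simulation_config(rng_seed = 8)
  vol <- build_hole_volume(cf)
  gt <- vol$ground_truth
  expect_equal(nrow(gt), 25L)
  spacing <- 105 * 18.9 + 2 * 75
  grid <- (1:5 - 0.5) * spacing
  off_x <- vapply(gt$x_nm, function(x) min(abs(x - grid)), numeric(1))
  off_y <- vapply(gt$y_nm, function(y) min(abs(y - grid)), numeric(1))
  expect_true(all(off_x <= 0.5 * 18.9 + 1e-9))  # jitter is sub-pixel
  expect_true(all(off_y <= 0.5 * 18.9 + 1e-9))
  expect_gt(stats::sd(off_x), 0)                # and actually varies

})

test_that("rendered slab interior equals alpha * thickness + background", {
  cf <- simulation_config(n_holes = 0)
  img <- render_image(build_hole_volume(cf))
  expect_equal(img$values[20, 20], 50 * 10 + 1, tolerance = 1e-9)
  # background-only volume renders the constant background
  vol0 <- build_hole_volume(cf)
  vol0$counts[] <- 0L
  img0 <- render_image(vol0)
  expect_all_equal(img0$values, cf$background, tol = 1e-9)
})

test_that("rendering conserves flux under the normalized PSF", {
  cf <- simulation_config(n_holes = 1, hole_inner_diameter_nm = 75,
                          hole_spacing_px = 40, jitter = FALSE)
  vol <- build_hole_volume(cf)
  img <- render_image(vol)
  ss <- cf$supersample
  total_lumen <- sum(as.numeric(vol$counts))
  rendered <- sum(img$values - cf$background)
  expect_lt(abs(rendered - cf$alpha * total_lumen / ss^2) /
              (cf$alpha * total_lumen / ss^2), 1e-3)
})

test_that("shot noise is Poisson-consistent and seed-reproducible", {
  expected <- pixel_image(matrix(0, 10, 10), 18.9)
  expect_true(all(add_shot_noise(expected, 1)$values == 0))
  lam <- pixel_image(matrix(501, 100, 100), 18.9)
  noisy <- add_shot_noise(lam, 123)
  expect_lt(abs(mean(noisy$values) - 501), 3 * sqrt(501 / 1e4))
  expect_identical(add_shot_noise(lam, 99)$values,
                   add_shot_noise(lam, 99)$values)
  neg <- pixel_image(matrix(1, 2, 2), 1)
  neg$values[1] <- -1
  expect_error(add_shot_noise(neg, 1), ">= 0")
})

test_that("simulated fields are bit-reproducible under a fixed seed", {
  cf <- simulation_config(n_holes = 4, hole_spacing_px = 15, rng_seed = 31)
  a <- simulate_hole_field(cf, image_index = 2)
  b <- simulate_hole_field(cf, image_index = 2)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_hole_field(cf, image_index = 3)
  expect_false(identical(a$image$values, c$image$values))
})

test_that("the mean of many noisy realizations converges to the expected image", {
  cf <- simulation_config(n_holes = 1, hole_spacing_px = 30, rng_seed = 6)
  vol <- build_hole_volume(cf)
  expected <- render_image(vol)
  crop <- expected$values[1:32, 1:32]
  nrep <- 100L
  acc <- matrix(0, 32, 32)
  for (k in seq_len(nrep)) {
    n <- add_shot_noise(pixel_image(crop, 18.9), 1000 + k)
    acc <- acc + n$values
  }
  # chi-square over pixels: sum over pixels of (sum_k x - n lam)^2 / (n lam)
  stat <- sum((acc - nrep * crop)^2 / (nrep * crop))
  df <- length(crop)
  expect_lt(stat, stats::qchisq(0.999, df))
  expect_gt(stat, stats::qchisq(0.001, df))
})

test_that("sheet intensity ratio is zero at zero thickness and increasing", {
  cf <- simulation_config(supersample = 3)
  expect_equal(sheet_intensity_ratio(0, 100, cf), 0)
  r <- vapply(c(20, 50, 100), sheet_intensity_ratio, numeric(1),
              tubule_diameter_nm = 100, config = cf)
  expect_true(all(diff(r) > 0))
  # lookup inversion recovers the thickness
  est <- sheet_thickness_from_ratio(r[2], 100, cf,
                                    thickness_grid_nm = seq(20, 100, 20))
  expect_lt(abs(est - 50), 2)
})

test_that("er_mask covers the simulated sheet footprint", {
  sim <- simulate_hole_field(simulation_config(n_holes = 4,
                                               hole_spacing_px = 20,
                                               rng_seed = 12))
  m <- er_mask(sim$image)
  expect_gt(mean(m), 0.99)
})

test_that("config validation and YAML round trip", {
  expect_error(simulation_config(alpha = 0), "alpha")
  cf <- simulation_config(n_holes = 9, rng_seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cf, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cf))
})
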