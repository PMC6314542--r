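test_that("er_mask covers constant images and splits a half-field cleanly", {
  expect_true(all(er_mask(pixel_image(matrix(10, 40, 40), 18.9))))
  expect_error(er_mask(pixel_image(matrix(0, 20, 20), 18.9)), "no signal")
  v <- matrix(0, 60, 60); v[, 31:60] <- 100
  m <- er_mask(pixel_image(v, 18.9))
  # away from the 15-px transition band the mask matches the signal
  expect_true(all(m[, 40:60]))
  expect_false(any(m[, 1:22]))
})

test_that("local minima respect separation and the keep-deeper rule", {
  # two pits 10 px apart -> both kept
  v <- pit_image(24, rbind(c(7, 7, 5), c(7, 17, 7)))
  img <- pixel_image(v, 18.9)
  mins <- find_local_minima(img, 4)
  found <- mins[mins$value < 99, ]
  expect_equal(nrow(found), 2L)
  expect_setequal(found$row, c(7, 7))
  # pits 3 px apart, depths 5 and 7 -> only the deeper survives
  v2 <- pit_image(20, rbind(c(10, 8, 5), c(10, 11, 7)), sigma = 0.8)
  mins2 <- find_local_minima(pixel_image(v2, 18.9), 4)
  deep <- mins2[mins2$value < 99, ]
  expect_equal(nrow(deep), 1L)
  expect_equal(deep$col, 11)
})

test_that("an equal-valued plateau minimum yields one centroid seed", {
  v <- matrix(100, 15, 15)
  v[7:8, 7:8] <- 40                # 2x2 plateau, centroid (7.5, 7.5)
  mins <- find_local_minima(pixel_image(v, 18.9), 4)
  low <- mins[mins$value == 40, ]
  expect_equal(nrow(low), 1L)
  expect_true(low$row %in% 7:8 && low$col %in% 7:8)
})

test_that("local minima outside the mask are suppressed; empty mask is empty", {
  v <- pit_image(20, rbind(c(10, 10, 5)))
  mask <- matrix(FALSE, 20, 20)
  expect_equal(nrow(find_local_minima(pixel_image(v, 18.9), 4, mask)), 0L)
  mask[1:20, 1:5] <- TRUE          # pit at col 10 is outside
  m2 <- find_local_minima(pixel_image(v, 18.9), 4, mask)
  expect_false(any(m2$value < 99))
})

test_that("single-seed watershed floods the whole mask", {
  v <- pit_image(16, rbind(c(8, 8, 10)))
  img <- pixel_image(v, 18.9)
  seeds <- data.frame(row = 8L, col = 8L)
  ws <- watershed_segment(img, seeds)
  expect_true(all(ws$labels == 1L))
})

test_that("two symmetric pits split the field evenly up to tie pixels", {
  # large sigma: no flat plateau anywhere, so exact value ties occur only
  # on the mirror ridge, and those go to the earlier (lower-id) seed by
  # the documented rule
  v <- pit_image(20, rbind(c(10, 5, 10), c(10, 16, 10)), sigma = 4)
  img <- pixel_image(v, 18.9)
  seeds <- data.frame(row = c(10L, 10L), col = c(5L, 16L))
  ws <- watershed_segment(img, seeds)
  expect_setequal(unique(as.vector(ws$labels)), c(1L, 2L))
  expect_equal(ws$labels[10, 5], 1L)
  expect_equal(ws$labels[10, 16], 2L)
  n1 <- sum(ws$labels == 1L); n2 <- sum(ws$labels == 2L)
  expect_equal(n1 + n2, 400L)
  expect_gte(n1, n2)               # ties favor the earlier seed
  expect_lte(n1 - n2, 2L * 20L)    # at most the two tie columns
})

test_that("watershed matches the brute-force flooding oracle pixel for pixel", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 16L
    v <- matrix(runif(n * n), n)
    mask <- matrix(runif(n * n) > 0.15, n)
    pos <- which(mask, arr.ind = TRUE)
    k <- min(4L, nrow(pos))
    sel <- pos[sample.int(nrow(pos), k), , drop = FALSE]
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    seeds <- data.frame(row = sel[, 1], col = sel[, 2])
    ws <- watershed_segment(pixel_image(v, 1), seeds, mask)
    seed_m <- matrix(0L, n, n)
    seed_m[cbind(seeds$row, seeds$col)] <- seq_len(k)
    expect_identical(ws$labels, brute_watershed(v, seed_m, mask))
  }
})

test_that("hole delimitation applies the depth-fraction border rule", {
  # flat region with one deep pixel: depth = edge_mean - min
  v <- matrix(100, 12, 12)
  v[6, 6] <- 40
  img <- pixel_image(v, 18.9)
  ws <- watershed_segment(img, data.frame(row = 6L, col = 6L))
  h <- delimit_hole(ws, 1L, img)
  expect_equal(h$edge_mean, 100)
  expect_equal(h$min_value, 40)
  expect_equal(h$depth, 60)
  expect_equal(h$border_threshold, 64)  # 40 + 0.4 * 60
  expect_true(h$measurable)
  # minimum pixel always within the hole
  expect_true(any(h$hole_pixels[, 1] == 6 & h$hole_pixels[, 2] == 6))
})

test_that("paraboloid pit hole matches the closed-form level set", {
  n <- 41L
  R <- 15
  v <- paraboloid_pit(n, c(21, 21), R, base = 100, depth = 60)
  img <- pixel_image(v, 18.9)
  ws <- watershed_segment(img, data.frame(row = 21L, col = 21L))
  h <- delimit_hole(ws, 1L, img)
  # region edge touches the flat plateau at 100 and min is 40
  expect_equal(h$min_value, 40)
  expect_equal(h$depth, 60, tolerance = 1e-9)
  # threshold 64 crosses the paraboloid at r = R sqrt(0.4 * 60 / 60 / ... )
  # value(r) = 100 - 60 (1 - r^2/R^2) < 64  <=>  r^2 < 0.4 R^2
  r_level <- R * sqrt(0.4)
  d <- sqrt((h$hole_pixels[, 1] - 21)^2 + (h$hole_pixels[, 2] - 21)^2)
  expect_lt(max(d), r_level + 1)
  # all pixels well inside the level set are included
  inside <- which((row(v) - 21)^2 + (col(v) - 21)^2 < (r_level - 1)^2,
                  arr.ind = TRUE)
  expect_gte(nrow(h$hole_pixels), nrow(inside))
})

test_that("flat regions are flagged unmeasurable", {
  v <- matrix(50, 10, 10)
  img <- pixel_image(v, 18.9)
  ws <- watershed_segment(img, data.frame(row = 5L, col = 5L))
  h <- delimit_hole(ws, 1L, img)
  expect_false(h$measurable)
  expect_equal(nrow(h$hole_pixels), 0L)
})

test_that("raising the depth fraction never shrinks the hole", {
  set.seed(3)
  v <- pit_image(25, rbind(c(13, 13, 40)), sigma = 3) + matrix(runif(625), 25)
  img <- pixel_image(v, 18.9)
  ws <- watershed_segment(img, data.frame(row = 13L, col = 13L))
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(f)
    nrow(delimit_hole(ws, 1L, img, depth_fraction = f)$hole_pixels),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("selection keeps user-pointed regions and applies rejection rules", {
  v <- pit_image(30, rbind(c(8, 8, 30), c(8, 22, 30), c(22, 15, 30)),
                 sigma = 2)
  img <- pixel_image(v, 18.9)
  seeds <- find_local_minima(img, 4)
  interior <- matrix(FALSE, 30, 30); interior[2:29, 2:29] <- TRUE
  ws <- watershed_segment(img, seeds, interior)
  pts <- data.frame(row = c(8L, 22L), col = c(8L, 15L))
  holes <- select_and_reject(ws, img, pts)
  expect_length(holes, 2L)
  expect_true(all(vapply(holes, function(h) h$accepted, logical(1))))
  # a region touching the border is auto-rejected
  v2 <- pit_image(20, rbind(c(3, 3, 30)), sigma = 2)
  img2 <- pixel_image(v2, 18.9)
  ws2 <- watershed_segment(img2, data.frame(row = 3L, col = 3L))
  holes2 <- select_and_reject(ws2, img2, data.frame(row = 3L, col = 3L))
  expect_false(holes2[[1]]$accepted)
  expect_equal(holes2[[1]]$reason, "border")
  # a user point on an unlabeled pixel is reported and skipped
  mask <- matrix(TRUE, 30, 30); mask[1, 1] <- FALSE
  ws3 <- watershed_segment(img, seeds, mask)
  expect_warning(
    holes3 <- select_and_reject(ws3, img, data.frame(row = c(8L, 1L),
                                                     col = c(8L, 1L))),
    "skipped")
  expect_equal(nrow(attr(holes3, "skipped_points")), 1L)
})

test_that("the segmentation chain is deterministic", {
  sim <- simulate_hole_field(simulation_config(n_holes = 4, hole_spacing_px = 20,
                                               rng_seed = 9))
  px <- sim$image$pixel_size_nm
  up <- data.frame(row = round(sim$ground_truth$y_nm / px + 0.5),
                   col = round(sim$ground_truth$x_nm / px + 0.5))
  t1 <- segment_holes(sim$image, up)
  t2 <- segment_holes(sim$image, up)
  expect_identical(t1, t2)
})

test_that("simulated hole centers are recovered by local minima", {
  sim <- simulate_hole_field(simulation_config(rng_seed = 5))
  img <- sim$image
  sm <- gaussian_smooth(img, 1)
  mask <- er_mask(img)
  mins <- find_local_minima(sm, 4, mask)
  expect_gte(nrow(mins), 25L)
  px <- img$pixel_size_nm
  gt <- sim$ground_truth
  d <- vapply(seq_len(nrow(gt)), function(h)
    min(sqrt((mins$row - (gt$y_nm[h] / px + 0.5))^2 +
             (mins$col - (gt$x_nm[h] / px + 0.5))^2)), numeric(1))
  expect_gte(sum(d <= 2), 24L)
  # each true hole footprint lies inside a single watershed region
  ws <- watershed_segment(sm, mins, mask)
  a_i_px <- (gt$inner_diameter_nm / 2) / px
  frac_in_one <- vapply(seq_len(nrow(gt)), function(h) {
    ci <- gt$y_nm[h] / px + 0.5; cj <- gt$x_nm[h] / px + 0.5
    sel <- which((row(ws$labels) - ci)^2 + (col(ws$labels) - cj)^2 <=
                   a_i_px^2, arr.ind = FALSE)
    labs <- ws$labels[sel]
    max(table(labs)) / length(labs)
  }, numeric(1))
  expect_gte(mean(frac_in_one >= 0.95), 0.9)
  # and the full chain accepts nearly all true 100-nm holes
  up <- data.frame(row = round(gt$y_nm / px + 0.5),
                   col = round(gt$x_nm / px + 0.5))
  tab <- segment_holes(img, up)
  expect_gte(sum(tab$accepted), 23L)
})
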