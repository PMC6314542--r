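test_that("model profile reduces to the bare chord in the delta-kernel limit", {
  geom <- tubule_geometry("lumen")
  x <- seq(-120, 120, by = 1)
  m <- model_profile(100, 1e-3, geom, x)
  chord <- 2 * sqrt(pmax(50^2 - x^2, 0))
  chord <- chord / max(chord)
  expect_lt(max(abs(m - chord)), 1e-3)
})

test_that("surface model with vanishing inner radius equals the lumen model", {
  x <- seq(-150, 150, by = 2)
  surf <- tubule_geometry("surface", annulus_thickness_nm = 50)  # ai = 0
  lum <- tubule_geometry("lumen")
  expect_equal(model_profile(100, 50, surf, x),
               model_profile(100, 50, lum, x), tolerance = 1e-9)
  expect_error(model_profile(20, 50, tubule_geometry("surface", 15), x),
               "annulus thicker")
})

test_that("thin-shell surface model resolves a central dip for wide tubules", {
  x <- seq(-200, 200, by = 1)
  geom <- tubule_geometry("surface", 4.5)
  m <- model_profile(200, 20, geom, x)   # diameter >> FWHM
  center <- m[x == 0]
  peak <- max(m)
  expect_lt(center, peak)                # local minimum between two maxima
  # before convolution the chord projection dips at the center too
  raw <- 2 * sqrt(pmax(100^2 - x^2, 0)) -
    2 * sqrt(pmax(95.5^2 - x^2, 0))
  expect_lt(raw[x == 0], max(raw))
})

test_that("model is symmetric and blur increases its width monotonically", {
  x <- seq(-300, 300, by = 3)
  geom <- tubule_geometry("lumen")
  fwhm_of <- function(g) {
    m <- model_profile(80, g, geom, x)
    sum(m >= 0.5)                        # samples above half maximum
  }
  m <- model_profile(80, 50, geom, x)
  expect_equal(m, rev(m), tolerance = 1e-9)
  widths <- vapply(c(20, 40, 60, 80), fwhm_of, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("noiseless profiles round-trip through the fit at grid resolution", {
  geom <- tubule_geometry("lumen")
  pos <- seq(0, 800, by = 18.9)
  y <- 40 * model_profile(100, 50, geom, pos - 390) + 5
  fit <- fit_profile(data.frame(position_nm = pos, intensity = y), geom)
  expect_true(fit$fit_ok)
  expect_lte(abs(fit$diameter_nm - 100), 1)     # within one grid step
  expect_lte(abs(fit$psf_fwhm_nm - 50), 0.5)
  expect_lt(abs(fit$background - 5), 0.2)
  expect_lte(abs(fit$center_nm - 390), 18.9 / 2 + 1e-9)
})

test_that("flat or pure-noise profiles are rejected", {
  geom <- tubule_geometry("lumen")
  pos <- seq(0, 756, by = 18.9)
  flat <- fit_profile(data.frame(position_nm = pos, intensity = rep(7, length(pos))),
                      geom)
  expect_false(flat$fit_ok)
  expect_equal(flat$reason, "no structure")
  set.seed(21)
  noise <- fit_profile(data.frame(position_nm = pos,
                                  intensity = rpois(length(pos), 20)), geom)
  expect_false(noise$fit_ok)
})

test_that("short profiles carry a warning", {
  geom <- tubule_geometry("lumen")
  pos <- seq(0, 400, by = 18.9)
  y <- 40 * model_profile(100, 50, geom, pos - 200) + 5
  expect_warning(fit_profile(data.frame(position_nm = pos, intensity = y),
                             geom),
                 "700 nm")
})

test_that("diameter summaries use the sample SD convention", {
  mk <- function(d, g = 50) structure(list(diameter_nm = d, psf_fwhm_nm = g,
                                           fit_ok = TRUE), class = "tubule_fit")
  s1 <- summarize_diameters(list(mk(100)))
  expect_equal(s1$mean, 100); expect_equal(s1$sd, 0); expect_equal(s1$n, 1L)
  s3 <- summarize_diameters(list(mk(90), mk(100), mk(110)))
  expect_equal(s3$mean, 100)
  expect_equal(s3$sd, 10)               # sample convention, not 8.165
  expect_equal(s3$min, 90); expect_equal(s3$max, 110)
  # failed fits are excluded
  bad <- structure(list(diameter_nm = 999, psf_fwhm_nm = 50, fit_ok = FALSE),
                   class = "tubule_fit")
  expect_equal(summarize_diameters(list(mk(90), mk(110), bad))$n, 2L)
  expect_error(summarize_diameters(list(bad)), "no successful fits")
  # histogram bins cover the data
  expect_equal(sum(s3$histogram$count), 3L)
})

test_that("simulated tubule images agree with the analytic profile model", {
  geom <- tubule_geometry("lumen")
  cf <- simulation_config(rng_seed = 3)
  sim <- simulate_tubule_image(100, geom, cf, field_px = 64)
  px <- sim$expected$pixel_size_nm
  x <- (seq_len(64) - 0.5) * px
  obs <- sim$expected$values[32, ] - cf$background
  obs <- obs / max(obs)
  m <- model_profile(100, cf$psf_fwhm_nm, geom, x - sim$ground_truth$axis_x_nm)
  expect_lt(max(abs(obs - m)), 0.011)
  expect_error(simulate_tubule_image(0, geom, cf), "> 0")
  # reproducible under the config seed
  sim2 <- simulate_tubule_image(100, geom, cf, field_px = 64)
  expect_identical(sim$image$values, sim2$image$values)
})

test_that("fits on Poisson-noisy surface tubules recover the true diameter", {
  geom <- tubule_geometry("surface", 4.5)
  cf <- simulation_config(rng_seed = 17)
  # alpha tuned so the rendered peak is ~100 counts
  peak0 <- max(simulate_tubule_image(96, geom, cf, 48)$expected$values) - 1
  cf$alpha <- cf$alpha * 100 / peak0
  n_prof <- 12L
  sim <- simulate_tubule_image(96, geom, cf, field_px = 48)
  px <- sim$image$pixel_size_nm
  x <- (seq_len(48) - 0.5) * px
  ds <- vapply(seq_len(n_prof), function(k) {
    y <- sim$image$values[3 * k, ]
    fit_profile(data.frame(position_nm = x, intensity = y), geom,
                diameter_grid_nm = seq(20, 200, 2),
                fwhm_grid_nm = seq(20, 100, 2))$diameter_nm
  }, numeric(1))
  expect_lt(abs(median(ds) - 96), 10)
})
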