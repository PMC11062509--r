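test_that("panel calibration recovers reflectance from digital numbers", {
  raw <- matrix(100, 20, 20)
  out <- calibrate_reflectance(raw, c(2, 2, 8, 8), 0.542)
  expect_equal(attr(out, "gain"), 0.00542)
  expect_equal(mean(out[3:8, 3:8]), 0.542)

  # identity when the raster already holds reflectance
  refl <- matrix(runif(400, 0, 0.9), 20, 20)
  panel_mean <- mean(refl[3:8, 3:8])
  out2 <- calibrate_reflectance(refl, c(2, 2, 8, 8), panel_mean)
  expect_equal(out2, refl, ignore_attr = TRUE)

  # output/raw is constant everywhere (brute-force per-pixel ratio)
  set.seed(1)
  raw3 <- matrix(rexp(400, 0.01) + 1, 20, 20)
  out3 <- calibrate_reflectance(raw3, c(0, 0, 5, 5), 0.537)
  ratios <- as.vector(out3 / raw3)
  expect_lt(diff(range(ratios)), 1e-12)

  expect_error(calibrate_reflectance(matrix(0, 5, 5), c(0, 0, 2, 2), 0.5),
               class = "sg_calibration_error")
})

test_that("spectral index formulas match hand arithmetic", {
  mk <- function(nir, red = 0.1, green = 0.1, re = 0.1, blue = 0.1) {
    band_stack(list(blue = matrix(blue, 2, 2), green = matrix(green, 2, 2),
                    red = matrix(red, 2, 2), rededge = matrix(re, 2, 2),
                    nir = matrix(nir, 2, 2)), "2021-05-01")
  }
  expect_equal(compute_index(mk(0.5, red = 0.1), "ndvi")[1, 1], 0.4 / 0.6)
  expect_equal(compute_index(mk(0.3, red = 0.3), "ndvi")[1, 1], 0)
  expect_equal(compute_index(mk(0.5, red = 0.1), "osavi")[1, 1],
               1.16 * 0.4 / 0.76)
  expect_equal(compute_index(mk(0.5, green = 0.2), "gndvi")[1, 1],
               0.3 / 0.7)
  expect_equal(compute_index(mk(0.5, re = 0.25), "ndre")[1, 1],
               0.25 / 0.75)
  # zero denominator -> missing
  z <- mk(0)
  z$bands$red <- matrix(0, 2, 2)
  expect_true(all(is.na(compute_index(z, "ndvi"))))
  expect_error(compute_index(mk(0.5), "evi2"),
               class = "sg_invalid_definition")
})

test_that("mask construction and thresholds behave as specified", {
  m <- build_mask(matrix(0.9, 4, 4))
  expect_true(all(m$mask))

  # canopy/soil synthetic scene: mask true exactly on canopy pixels
  nd <- matrix(0.2, 10, 10)
  canopy <- cbind(rep(3:6, each = 4), rep(3:6, times = 4))
  nd[canopy] <- 0.85
  mk <- build_mask(nd, 0.6)
  expect_identical(unname(mk$mask), unname(nd >= 0.6))

  # raising the threshold never adds pixels
  for (th in c(0.2, 0.5, 0.7, 0.9)) {
    expect_true(all(build_mask(nd, th + 0.05)$mask <= build_mask(nd, th)$mask))
  }

  # degenerate threshold: everything masked out downstream, with a warning
  plots <- make_plot_grid(2, 2)
  idx <- matrix(0.8, plots$dims[1], plots$dims[2])
  all_false <- build_mask(idx, 1.1)
  expect_false(any(all_false$mask))
  expect_warning(v <- extract_plot_values(idx, all_false, plots),
                 "no masked pixels")
  expect_true(all(is.na(v)))
})

test_that("plot extraction equals the naive per-pixel loop oracle", {
  # 2x2 plot with known values
  r <- matrix(0, 8, 8)
  r[3:4, 3:4] <- c(0.2, 0.6, 0.4, 0.8)  # column-major fill
  pm <- plot_map(data.frame(plot_id = "p1", r0 = 2, c0 = 2, r1 = 4, c1 = 4),
                 c(8, 8))
  full <- build_mask(matrix(1, 8, 8), 0.5)
  expect_equal(unname(extract_plot_values(r, full, pm)), 0.5)

  # mask excluding the 0.2 pixel
  m2 <- matrix(TRUE, 8, 8)
  m2[3, 3] <- FALSE
  expect_equal(unname(extract_plot_values(r, m2, pm)), 0.6)

  # uniform raster: every plot mean is the constant
  plots <- make_plot_grid(3, 2)
  u <- matrix(0.37, plots$dims[1], plots$dims[2])
  expect_true(all(extract_plot_values(u, build_mask(u, 0), plots) == 0.37))

  # random rasters and masks: exact match with the scalar loop oracle
  set.seed(9)
  for (rep in 1:20) {
    rr <- matrix(runif(64), 8, 8)
    mm <- matrix(runif(64) > 0.3, 8, 8)
    r0 <- sample(0:4, 1); c0 <- sample(0:4, 1)
    r1 <- r0 + sample(1:3, 1); c1 <- c0 + sample(1:3, 1)
    pm_i <- plot_map(data.frame(plot_id = "p", r0 = r0, c0 = c0,
                                r1 = r1, c1 = c1), c(8, 8))
    got <- suppressWarnings(extract_plot_values(rr, mm, pm_i))
    expect_identical(unname(got),
                     plot_mean_oracle(rr, mm, r0, c0, r1, c1))
  }

  # plot outside the raster
  pm_out <- plot_map(data.frame(plot_id = "p", r0 = 6, c0 = 6, r1 = 9,
                                c1 = 9), c(9, 9))
  expect_error(extract_plot_values(matrix(1, 8, 8),
                                   build_mask(matrix(1, 8, 8), 0), pm_out),
               class = "sg_invalid_plot")
})

test_that("index-then-mean order matters and the pipeline uses it", {
  set.seed(4)
  nir <- matrix(runif(16, 0.3, 0.6), 4, 4)
  red <- matrix(runif(16, 0.02, 0.3), 4, 4)
  per_pixel <- mean((nir - red) / (nir + red))
  of_means <- (mean(nir) - mean(red)) / (mean(nir) + mean(red))
  expect_false(isTRUE(all.equal(per_pixel, of_means)))

  st <- band_stack(list(blue = red, green = red, red = red, rededge = red,
                        nir = nir), "2021-05-01")
  pm <- plot_map(data.frame(plot_id = "p", r0 = 0, c0 = 0, r1 = 4, c1 = 4),
                 c(4, 4))
  got <- extract_plot_values(compute_index(st, "ndvi"),
                             build_mask(matrix(1, 4, 4), 0), pm)
  expect_equal(unname(got), per_pixel)
})

test_that("trajectory assembly sorts dates and rejects duplicates", {
  v <- function(x) matrix(x, 2, 1, dimnames = list(c("a", "b"), "ndvi"))
  tr1 <- assemble_trajectories(list(v(c(0.8, 0.7))), "2021-05-01")
  expect_equal(dim(tr1$values), c(2, 1, 1))
  expect_equal(tr1$anthesis_date, as.Date("2021-05-01"))

  dates <- as.Date("2021-05-01") + c(6, 0, 3)
  vals <- list(v(c(0.5, 0.4)), v(c(0.9, 0.8)), v(c(0.7, 0.6)))
  tr2 <- assemble_trajectories(vals, dates)
  expect_equal(tr2$dates, sort(dates))
  expect_equal(unname(tr2$values["a", , "ndvi"]), c(0.9, 0.7, 0.5))
  expect_equal(unname(tr2$anthesis["a", "ndvi"]), 0.9)

  expect_error(assemble_trajectories(list(v(1), v(1)),
                                     as.Date(c("2021-05-01", "2021-05-01"))),
               class = "sg_invalid_input")
})

test_that("noise-free scene reproduces the analytic greenness mapping", {
  tr <- simulate_trial(n_acc = 16, n_snp = 30, noise_sd = 0, seed = 9)
  traj <- extract_si_trajectories(tr$stacks, tr$plots)
  for (ix in c("ndvi", "gndvi", "ndre", "osavi")) {
    expect_lt(max(abs(traj$values[, , ix] -
                        greenness_to_index(tr$greenness, ix))), 1e-9)
  }
})
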