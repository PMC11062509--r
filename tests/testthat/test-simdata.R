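test_that("weather generator honours its parameters and seed", {
  w <- simulate_weather(60, base = 20, amplitude = 0, noise_sd = 0, seed = 1)
  expect_equal(w$tmean, rep(20, 60))
  expect_equal(as.numeric(diff(w$date)), rep(1, 59))

  w1 <- simulate_weather(40, base = 18, amplitude = 6, noise_sd = 1, seed = 7)
  w2 <- simulate_weather(40, base = 18, amplitude = 6, noise_sd = 1, seed = 7)
  expect_identical(w1, w2)

  expect_error(simulate_weather(0), class = "sg_invalid_argument")

  # Monte-Carlo: seasonal mean close to the base level across seeds
  means <- vapply(1:100, function(s) {
    mean(simulate_weather(40, base = 18, amplitude = 6, noise_sd = 1,
                          seed = s)$tmean)
  }, 0)
  # sinusoid over days 0..39 contributes a positive offset; allow 3 SE plus
  # the deterministic sinusoid mean
  sinus <- mean(18 + 6 * sin(2 * pi * (0:39) / 365))
  expect_lt(abs(mean(means) - sinus), 3 * sd(means) / sqrt(100))
})

test_that("genotype generator is deterministic and hits its Fst target", {
  g1 <- simulate_genotypes(50, 80, seed = 3)
  g2 <- simulate_genotypes(50, 80, seed = 3)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))
  expect_true(all(tapply(g1$map$pos, g1$map$chrom,
                         function(p) all(diff(p) >= 0))))
  expect_true(all(c("flowering", "era", "region", "group") %in%
                    names(g1$labels)))
  expect_error(simulate_genotypes(5, 10, n_subpop = 6),
               class = "sg_invalid_argument")

  # no differentiation at fst_b = 0
  g0 <- simulate_genotypes(500, 2000, n_subpop = 2, fst_b = 0, seed = 11)
  f0 <- fst_per_snp(g0, split(seq_len(500), g0$labels$subpop))
  expect_lt(abs(mean(f0$fst, na.rm = TRUE)), 0.01)

  # genome-wide weighted Fst near the Balding-Nichols target
  gb <- simulate_genotypes(500, 2000, n_subpop = 2, fst_b = 0.1, seed = 12)
  fb <- fst_per_snp(gb, split(seq_len(500), gb$labels$subpop))
  ok <- is.finite(fb$a)
  weighted <- sum(fb$a[ok]) / sum(fb$a[ok] + fb$b[ok] + fb$c[ok])
  expect_lt(abs(weighted - 0.1), 0.02)
})

test_that("trajectory generator produces the planted genetic structure", {
  gn <- simulate_genotypes(40, 30, seed = 5)
  w <- simulate_weather(120, seed = 5)

  # no effects, no noise: identical curves
  arch0 <- trait_architecture(integer(0), numeric(0))
  s0 <- simulate_trajectories(gn, arch0, w, w$date[10], noise_sd = 0,
                              seed = 1)
  g_all <- vapply(seq_len(40), function(a) greenness_at(s0, 350, a), 0)
  expect_equal(max(g_all) - min(g_all), 0)

  # negative effect: carriers strictly greener at every AT > 0
  arch1 <- trait_architecture(7L, -0.003)
  s1 <- simulate_trajectories(gn, arch1, w, w$date[10], noise_sd = 0,
                              seed = 1)
  dos <- gn$dosage[, 7]
  if (length(unique(dos)) > 1) {
    hi <- which(dos == max(dos))[1]
    lo <- which(dos == min(dos))[1]
    for (at in c(50, 200, 450, 700)) {
      expect_gt(greenness_at(s1, at, hi), greenness_at(s1, at, lo))
    }
  }

  # missing anthesis date
  expect_error(
    simulate_trajectories(gn, arch0, w,
                          setNames(rep(w$date[10], 39),
                                   rownames(gn$dosage)[-1])),
    class = "sg_missing_data")

  # heritability recovery at the generated number of seasons
  est <- vapply(1:20, function(s) {
    gg <- simulate_genotypes(300, 120, seed = 400 + s)
    arch <- trait_architecture(c(20L, 60L, 100L), c(-0.002, 0.0015, -0.001),
                               h2_target = 0.65)
    ww <- simulate_weather(120, seed = s)
    sim <- simulate_trajectories(gg, arch, ww, ww$date[15], n_seasons = 2,
                                 poly_var = 1e-6, seed = 500 + s)
    heritability(sim$rates)$H2
  }, 0)
  expect_lt(abs(mean(est) - 0.65), 0.1)
})

test_that("scene renderer matches the endmember model and survives noise", {
  plots <- make_plot_grid(3, 3, plot_ids = sprintf("p%02d", 1:9))
  g1 <- setNames(rep(1, 9), plots$plots$plot_id)

  st <- render_orthomosaic(plots, g1, soil_fraction = 0, noise_sd = 0,
                           seed = 2)
  refl <- calibrate_stack(st)
  ndvi <- compute_index(refl, "ndvi")
  cs <- canopy_spectrum()
  canopy_ndvi <- (cs["nir"] - cs["red"]) / (cs["nir"] + cs["red"])
  r <- unlist(plots$plots[1, c("r0", "c0", "r1", "c1")])
  expect_equal(max(abs(ndvi[(r[1] + 1):r[3], (r[2] + 1):r[4]] -
                         canopy_ndvi)), 0, tolerance = 1e-12)

  # dead canopy: plot NDVI equals the soil value, below the mask threshold
  st0 <- render_orthomosaic(plots, setNames(rep(0, 9), plots$plots$plot_id),
                            soil_fraction = 0, noise_sd = 0, seed = 2)
  nd0 <- compute_index(calibrate_stack(st0), "ndvi")
  ss <- soil_spectrum()
  soil_ndvi <- (ss["nir"] - ss["red"]) / (ss["nir"] + ss["red"])
  expect_equal(unname(nd0[r[1] + 1, r[2] + 1]), unname(soil_ndvi),
               tolerance = 1e-12)
  expect_lt(soil_ndvi, 0.6)

  # noisy render still preserves the greenness ranking across plots
  pl2 <- make_plot_grid(5, 5)
  gr <- setNames(seq(0.2, 1, length.out = 25), pl2$plots$plot_id)
  st_n <- render_orthomosaic(pl2, gr, soil_fraction = 0.2, noise_sd = 0.005,
                             seed = 3)
  refl_n <- calibrate_stack(st_n)
  full_mask <- build_mask(matrix(1, pl2$dims[1], pl2$dims[2]), 0.5)
  vals <- extract_plot_values(compute_index(refl_n, "ndvi"), full_mask, pl2)
  expect_gt(cor(vals, gr, method = "spearman"), 0.99)
})

test_that("cohort resampling plants the requested era gradient", {
  set.seed(42)
  n <- 600
  dos <- matrix(rbinom(n * 20, 2, 0.5), n, 20)
  carrier <- seq_len(220)
  dos[carrier, 1] <- 0L; dos[carrier, 2] <- 0L          # hom ref-ref
  dos[-carrier, 1] <- 2L; dos[-carrier, 2] <- 2L        # hom alt-alt
  het <- 581:600
  dos[het, 1] <- 1L
  gn <- make_geno(dos)
  hap1 <- c("A", "A")

  # uniform targets at the pool frequency: flat trend
  pool <- length(setdiff(carrier, het)) / n
  gu <- assign_cohorts(gn, c(1, 2), hap1,
                       targets = setNames(rep(round(pool * 60) / 60, 4),
                                          era_levels()[1:4]),
                       bin_size = 60, seed = 1)
  tru <- haplotype_trend(assign_haplotypes(gu, c(1, 2), hap1), gu)
  expect_lt(diff(range(tru$table$freq_hap1)), 1e-9)

  # monotone gradient 0.1 -> 0.5 over 4 eras, recovered within 0.02
  targets <- setNames(seq(0.1, 0.5, length.out = 4), era_levels()[1:4])
  gg <- assign_cohorts(gn, c(1, 2), hap1, targets, bin_size = 60, seed = 2)
  trg <- haplotype_trend(assign_haplotypes(gg, c(1, 2), hap1), gg)
  expect_true(all(abs(trg$table$freq_hap1 - targets) <= 0.02))
  expect_true(all(diff(trg$table$freq_hap1) > 0))

  # infeasible target: not enough carriers
  expect_error(
    assign_cohorts(gn, c(1, 2), hap1,
                   targets = setNames(rep(1, 4), era_levels()[1:4]),
                   bin_size = 150, seed = 3),
    class = "sg_infeasible_gradient")
})

test_that("renderer rejects overlapping plots and bad greenness", {
  plots <- make_plot_grid(2, 2)
  bad <- plots$plots
  bad$c0[2] <- bad$c0[1]; bad$c1[2] <- bad$c1[1]
  bad$r0[2] <- bad$r0[1]; bad$r1[2] <- bad$r1[1]
  expect_error(plot_map(bad, plots$dims, plots$panel_region),
               class = "sg_invalid_plot_map")
  expect_error(render_orthomosaic(plots, setNames(rep(1.2, 4),
                                                  plots$plots$plot_id)),
               class = "sg_invalid_argument")
})
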