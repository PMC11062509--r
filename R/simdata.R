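# Synthetic trial generator: weather, structured genotypes, senescence
# trajectories, rendered orthomosaics and cohort labels, all with analytic
# ground truth so the downstream pipeline can be validated by recovery.

#' Canopy and soil endmember spectra
#'
#' Fixed five-band reflectance spectra used by the scene renderer. A fully
#' green canopy pixel has high NIR and low red (NDVI about 0.9); bare soil is
#' spectrally flat (NDVI 0.2), so the 0.6 NDVI mask threshold separates the
#' two by construction.
#'
#' @return Named numeric vector of band reflectances.
#' @export
canopy_spectrum <- function() {
  c(blue = 0.04, green = 0.07, red = 0.03, rededge = 0.30, nir = 0.55)
}

#' @rdname canopy_spectrum
#' @export
soil_spectrum <- function() {
  c(blue = 0.12, green = 0.18, red = 0.22, rededge = 0.26, nir = 0.33)
}

#' Breeding-era bins
#'
#' Release-period bins used for haplotype-frequency trend analysis:
#' pre-1950, 1951-1970, 1971-1990, 1991-2010, post-2010.
#'
#' @return Character vector of era levels in chronological order.
#' @export
era_levels <- function() {
  c("pre1950", "1951-1970", "1971-1990", "1991-2010", "post2010")
}

#' Simulate a daily mean-temperature series
#'
#' Sinusoid-plus-noise daily means over a growing season; deterministic for a
#' fixed seed.
#'
#' @param n_days Number of days (>= 1).
#' @param base Mean level, degrees C.
#' @param amplitude Seasonal sinusoid amplitude, degrees C.
#' @param noise_sd Daily noise standard deviation, degrees C (>= 0).
#' @param seed Integer seed.
#' @param start First calendar day.
#' @return Object of class `sg_weather`: a data frame with `date`, `tmean`.
#' @export
simulate_weather <- function(n_days, base = 20, amplitude = 6, noise_sd = 1,
                             seed = NULL, start = as.Date("2021-04-20")) {
  sg_assert(is.numeric(n_days) && length(n_days) == 1L && n_days >= 1,
            "n_days must be a positive count")
  sg_assert(noise_sd >= 0, "noise_sd must be >= 0")
  n_days <- as.integer(n_days)
  with_seed(seed, {
    day <- seq_len(n_days) - 1L
    tmean <- base + amplitude * sin(2 * pi * day / 365) +
      rnorm(n_days, sd = noise_sd)
    structure(data.frame(date = as.Date(start) + day, tmean = tmean),
              class = c("sg_weather", "data.frame"))
  })
}

wheat_chromosomes <- function(n) {
  all <- paste0(rep(1:7, times = 3), rep(c("A", "B", "D"), each = 7))
  sg_assert(n >= 1 && n <= length(all), "n_chrom must be between 1 and 21")
  all[seq_len(n)]
}

#' Simulate a structured biallelic genotype panel
#'
#' Balding-Nichols model: each SNP has an ancestral allele frequency drawn
#' uniformly on (0.05, 0.95); each subpopulation draws its own frequency from
#' a Beta distribution whose spread is set by the target differentiation
#' `fst_b`; dosages are binomial draws of two alleles. Accessions carry
#' flowering-class, era, region and population-group labels.
#'
#' @param n_acc Number of accessions.
#' @param n_snp Number of SNPs.
#' @param n_subpop Number of subpopulations (<= `n_acc`).
#' @param fst_b Target differentiation among subpopulations, in `[0, 1)`.
#' @param n_chrom Number of chromosomes the SNPs are spread over.
#' @param chrom_len Chromosome length, bp.
#' @param era_props Sampling proportions over [era_levels()].
#' @param seed Integer seed.
#' @return Object of class `sg_geno`: list with `dosage` (accession x SNP
#'   matrix in 0/1/2), `map` (snp, chrom, pos, ref, alt) and `labels`
#'   (accession, flowering, era, region, group, subpop).
#' @export
simulate_genotypes <- function(n_acc, n_snp, n_subpop = 3, fst_b = 0.1,
                               n_chrom = 3, chrom_len = 8e8,
                               era_props = c(0.10, 0.20, 0.25, 0.30, 0.15),
                               seed = NULL) {
  sg_assert(n_acc >= 2 && n_snp >= 1, "need n_acc >= 2 and n_snp >= 1")
  sg_assert(fst_b >= 0 && fst_b < 1, "fst_b must lie in [0, 1)")
  if (n_subpop > n_acc) {
    sg_stop("n_subpop cannot exceed n_acc", "sg_invalid_argument")
  }
  with_seed(seed, {
    chroms <- wheat_chromosomes(n_chrom)
    chrom <- sort(rep_len(seq_len(n_chrom), n_snp))
    pos <- integer(n_snp)
    for (c_i in seq_len(n_chrom)) {
      idx <- which(chrom == c_i)
      pos[idx] <- sort(sample.int(chrom_len, length(idx)))
    }
    chrom <- chroms[chrom]
    snp <- sprintf("s%s%d", chrom, pos)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n_snp, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")

    subpop <- sort(rep_len(seq_len(n_subpop), n_acc))
    p_anc <- runif(n_snp, 0.05, 0.95)
    dosage <- matrix(0L, n_acc, n_snp)
    for (s in seq_len(n_subpop)) {
      rows <- which(subpop == s)
      p_s <- if (fst_b > 0) {
        rbeta(n_snp, p_anc * (1 - fst_b) / fst_b,
              (1 - p_anc) * (1 - fst_b) / fst_b)
      } else {
        p_anc
      }
      dosage[rows, ] <- matrix(
        rbinom(length(rows) * n_snp, 2L, rep(p_s, each = length(rows))),
        nrow = length(rows))
    }
    acc <- sprintf("acc%04d", seq_len(n_acc))
    dimnames(dosage) <- list(acc, snp)

    groups <- c("CL", "IMC", "MCC")
    labels <- data.frame(
      accession = acc,
      flowering = sample(c("EF", "MF", "LF"), n_acc, replace = TRUE),
      era = sample(era_levels(), n_acc, replace = TRUE,
                   prob = era_props / sum(era_props)),
      region = sample(c("I", "II", "III"), n_acc, replace = TRUE),
      group = groups[(subpop - 1L) %% 3L + 1L],
      subpop = subpop,
      stringsAsFactors = FALSE)

    structure(list(dosage = dosage,
                   map = data.frame(snp = snp, chrom = chrom, pos = pos,
                                    ref = ref, alt = alt,
                                    stringsAsFactors = FALSE),
                   labels = labels),
              class = "sg_geno")
  })
}

#' @export
print.sg_geno <- function(x, ...) {
  cat(sprintf("<sg_geno> %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Subset a genotype panel by accession and/or SNP
#'
#' @param geno An `sg_geno`.
#' @param acc Accession selector (indices, names or logical), or `NULL`.
#' @param snp SNP selector (indices, names or logical), or `NULL`.
#' @return The subsetted `sg_geno`.
#' @export
geno_subset <- function(geno, acc = NULL, snp = NULL) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  if (is.null(acc)) acc <- seq_len(nrow(geno$dosage))
  if (is.null(snp)) snp <- seq_len(ncol(geno$dosage))
  if (is.character(acc)) acc <- match(acc, rownames(geno$dosage))
  if (is.character(snp)) snp <- match(snp, colnames(geno$dosage))
  sg_assert(!anyNA(acc) && !anyNA(snp), "unknown accession or SNP selector")
  structure(list(dosage = geno$dosage[acc, snp, drop = FALSE],
                 map = geno$map[snp, , drop = FALSE],
                 labels = geno$labels[acc, , drop = FALSE]),
            class = "sg_geno")
}

#' Declare a planted trait architecture
#'
#' Ground-truth additive architecture for the senescence-rate parameter:
#' which SNPs are causal, their additive effects on the logistic decline
#' rate, and (optionally) the entry-mean broad-sense heritability the
#' trajectory generator should realize.
#'
#' @param qtl_snps Distinct SNP indices or names.
#' @param effects Additive effect per QTL on the rate (per unit dosage);
#'   negative effects slow senescence (stay-green).
#' @param h2_target Optional target broad-sense heritability in `[0, 1]`,
#'   interpreted at the number of seasons the generator produces.
#' @return Object of class `sg_arch`.
#' @export
trait_architecture <- function(qtl_snps, effects, h2_target = NULL) {
  sg_assert(length(qtl_snps) == length(effects),
            "qtl_snps and effects must have equal length")
  sg_assert(!anyDuplicated(qtl_snps), "qtl_snps must be distinct")
  sg_assert(all(is.finite(effects)), "effects must be finite")
  if (!is.null(h2_target)) {
    sg_assert(h2_target > 0 && h2_target <= 1, "h2_target must be in (0, 1]")
  }
  structure(list(qtl_snps = qtl_snps, effects = effects,
                 h2_target = h2_target),
            class = "sg_arch")
}

#' Simulate post-anthesis senescence trajectories
#'
#' Canopy greenness declines as a logistic function of accumulated
#' temperature (AT): `f(AT) = 1 / (1 + exp(r AT - c))`, rescaled so
#' greenness is exactly 1 at anthesis and `g_min` at full senescence. The
#' intercept `c = r0 * midpoint` is common to the panel, so an accession's
#' rate `r` sets its own midpoint `c / r`: curves with different rates never
#' cross, and a slower rate means strictly higher greenness at every AT > 0
#' (stay-green). The per-accession rate is
#' `r = r0 + sum(effects * dosage) + polygenic + env`, and the relative
#' stay-green score of any plot is available in closed form for recovery
#' tests.
#'
#' @param geno An `sg_geno`.
#' @param arch An `sg_arch` (planted QTL and optional heritability target).
#' @param weather An `sg_weather` spanning every anthesis date.
#' @param anthesis_dates `Date` vector, one per accession (named or in
#'   accession order), or a single date recycled.
#' @param noise_sd Rate-scale environmental noise SD used when `arch` has no
#'   `h2_target`; with a target, the per-season noise variance is derived
#'   from it instead.
#' @param n_seasons Number of seasons (environments) to generate.
#' @param r0 Baseline decline rate, per degree C day.
#' @param midpoint Logistic midpoint of the baseline rate, degrees C day of
#'   AT (fixes the common intercept `c = r0 * midpoint`).
#' @param g_min Asymptotic greenness floor in `[0, 1)`.
#' @param poly_var Variance of a polygenic rate term spread over background
#'   SNPs (0 disables it).
#' @param seed Integer seed.
#' @return Object of class `sg_simtraj` with per-season realized rates, the
#'   genetic values, and the curve parameters.
#' @export
simulate_trajectories <- function(geno, arch, weather, anthesis_dates,
                                  noise_sd = 0, n_seasons = 1, r0 = 0.010,
                                  midpoint = 450, g_min = 0.15,
                                  poly_var = 0, seed = NULL) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  sg_assert(inherits(arch, "sg_arch"), "arch must be an sg_arch")
  n <- nrow(geno$dosage)
  acc <- rownames(geno$dosage)
  anthesis_dates <- as.Date(anthesis_dates)
  if (length(anthesis_dates) == 1L) {
    anthesis_dates <- rep(anthesis_dates, n)
  }
  if (!is.null(names(anthesis_dates))) {
    anthesis_dates <- anthesis_dates[acc]
  }
  if (length(anthesis_dates) != n || anyNA(anthesis_dates)) {
    sg_stop("every accession needs an anthesis date", "sg_missing_data")
  }
  names(anthesis_dates) <- acc
  span <- range(weather$date)
  sg_assert(all(anthesis_dates >= span[1] & anthesis_dates <= span[2]),
            "anthesis dates must lie within the weather span")
  sg_assert(g_min >= 0 && g_min < 1, "g_min must be in [0, 1)")

  with_seed(seed, {
    qtl <- arch$qtl_snps
    if (is.character(qtl)) qtl <- match(qtl, colnames(geno$dosage))
    sg_assert(!anyNA(qtl), "unknown QTL SNP in architecture")
    g_val <- rep(0, n)
    if (length(qtl)) {
      Xq <- scale(geno$dosage[, qtl, drop = FALSE], center = TRUE,
                  scale = FALSE)
      g_val <- as.vector(Xq %*% arch$effects)
    }
    if (poly_var > 0) {
      bg <- setdiff(seq_len(ncol(geno$dosage)), qtl)
      bg <- sample(bg, min(200L, length(bg)))
      Xb <- scale(geno$dosage[, bg, drop = FALSE], center = TRUE,
                  scale = FALSE)
      u <- as.vector(Xb %*% rnorm(length(bg)))
      if (stats::sd(u) > 0) u <- u * sqrt(poly_var) / stats::sd(u)
      g_val <- g_val + u
    }
    var_g <- stats::var(g_val)
    sd_env <- if (!is.null(arch$h2_target) && var_g > 0) {
      sqrt(n_seasons * var_g * (1 - arch$h2_target) / arch$h2_target)
    } else {
      noise_sd
    }
    rates <- matrix(r0 + g_val, n, n_seasons) +
      matrix(rnorm(n * n_seasons, sd = sd_env), n, n_seasons)
    rates <- pmax(rates, 1e-4)
    dimnames(rates) <- list(acc, paste0("season", seq_len(n_seasons)))
    structure(list(rates = rates, r_genetic = r0 + g_val,
                   midpoint = midpoint, intercept = r0 * midpoint,
                   g_min = g_min, r0 = r0, sd_env = sd_env,
                   anthesis = anthesis_dates, weather = weather,
                   arch = arch),
              class = "sg_simtraj")
  })
}

#' Evaluate the simulated greenness curve
#'
#' @param sim An `sg_simtraj`.
#' @param at Accumulated temperature(s), degrees C day; values below 0 are
#'   treated as 0 (pre-anthesis canopy is fully green).
#' @param acc Accession name or index.
#' @param season Season index.
#' @return Greenness in `[g_min, 1]`, vectorized over `at`.
#' @export
greenness_at <- function(sim, at, acc, season = 1L) {
  sg_assert(inherits(sim, "sg_simtraj"), "sim must be an sg_simtraj")
  r <- sim$rates[acc, season]
  at <- pmax(at, 0)
  f <- 1 / (1 + exp(r * at - sim$intercept))
  f0 <- 1 / (1 + exp(-sim$intercept))
  sim$g_min + (1 - sim$g_min) * f / f0
}

#' Map greenness to a spectral-index value under the scene model
#'
#' A canopy pixel with greenness `g` reflects the linear mix
#' `g * canopy + (1 - g) * soil` in every band; this returns the spectral
#' index of that mixed spectrum, i.e. the analytic plot value an ideal
#' imaging pipeline recovers from a noise-free render (soil pixels are
#' removed by the anthesis mask and do not enter the plot mean).
#'
#' @param g Greenness value(s) in `[0, 1]`.
#' @param index Index name or definition.
#' @return Index value(s), vectorized over `g`.
#' @export
greenness_to_index <- function(g, index) {
  cs <- canopy_spectrum()
  ss <- soil_spectrum()
  bands <- lapply(sg_bands(), function(b) g * cs[[b]] + (1 - g) * ss[[b]])
  names(bands) <- sg_bands()
  defn <- resolve_index(index)
  as.numeric(defn$fun(bands))
}

#' Regular plot-grid map with a calibration panel
#'
#' Lays rectangular plots on a row-by-column grid with fixed gaps, reserving
#' a panel region above the grid. Coordinates are 0-based, half-open pixel
#' rectangles.
#'
#' @param n_rows,n_cols Grid dimensions (`n_rows * n_cols` plots, or fewer if
#'   `plot_ids` is shorter).
#' @param plot_ids Plot identifiers (default `plot001`, ...).
#' @param plot_h,plot_w Plot height/width in pixels.
#' @param gap Gap between plots, pixels.
#' @param margin Outer margin, pixels.
#' @param panel_h,panel_w Calibration-panel size, pixels.
#' @return Object of class `sg_plotmap`: `plots` data frame
#'   (`plot_id, r0, c0, r1, c1`), raster `dims`, and `panel_region`.
#' @export
make_plot_grid <- function(n_rows, n_cols, plot_ids = NULL, plot_h = 6,
                           plot_w = 6, gap = 2, margin = 4, panel_h = 6,
                           panel_w = 6) {
  n_plots <- if (is.null(plot_ids)) n_rows * n_cols else length(plot_ids)
  sg_assert(n_plots <= n_rows * n_cols, "more plot_ids than grid cells")
  if (is.null(plot_ids)) plot_ids <- sprintf("plot%03d", seq_len(n_plots))
  panel_region <- c(margin, margin, margin + panel_h, margin + panel_w)
  grid_top <- margin + panel_h + gap
  ij <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  ij <- ij[seq_len(n_plots), ]
  r0 <- grid_top + (ij$row - 1L) * (plot_h + gap)
  c0 <- margin + (ij$col - 1L) * (plot_w + gap)
  plots <- data.frame(plot_id = plot_ids, r0 = r0, c0 = c0,
                      r1 = r0 + plot_h, c1 = c0 + plot_w,
                      stringsAsFactors = FALSE)
  dims <- c(grid_top + n_rows * plot_h + (n_rows - 1L) * gap + margin,
            max(margin + n_cols * plot_w + (n_cols - 1L) * gap + margin,
                2L * margin + panel_w))
  plot_map(plots, dims, panel_region)
}

#' Construct and validate a plot map
#'
#' @param plots Data frame with `plot_id, r0, c0, r1, c1` (0-based,
#'   half-open pixel rectangles).
#' @param dims Raster dimensions `c(n_rows, n_cols)`.
#' @param panel_region Optional panel rectangle.
#' @return An `sg_plotmap`. Overlapping plots, out-of-bounds plots or
#'   duplicate ids are an error.
#' @export
plot_map <- function(plots, dims, panel_region = NULL) {
  need <- c("plot_id", "r0", "c0", "r1", "c1")
  sg_assert(is.data.frame(plots) && all(need %in% names(plots)),
            "plots must have columns plot_id, r0, c0, r1, c1")
  if (anyDuplicated(plots$plot_id)) {
    sg_stop("duplicate plot_id", "sg_invalid_plot_map")
  }
  rects <- lapply(seq_len(nrow(plots)), function(i) {
    as_rect(unlist(plots[i, c("r0", "c0", "r1", "c1")]))
  })
  for (r in rects) {
    if (!rect_in_bounds(r, dims)) {
      sg_stop("plot rectangle outside raster bounds", "sg_invalid_plot_map")
    }
  }
  if (!is.null(panel_region)) {
    panel_region <- as_rect(panel_region)
    rects <- c(rects, list(panel_region))
  }
  if (length(rects) > 1L) {
    ord <- order(vapply(rects, `[`, 0L, 1L), vapply(rects, `[`, 0L, 2L))
    rects_s <- rects[ord]
    for (i in seq_along(rects_s)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (rects_overlap(rects_s[[i]], rects_s[[j]])) {
          sg_stop("plot rectangles (or panel) overlap", "sg_invalid_plot_map")
        }
      }
    }
  }
  structure(list(plots = plots, dims = as.integer(dims),
                 panel_region = panel_region),
            class = "sg_plotmap")
}

#' @export
print.sg_plotmap <- function(x, ...) {
  cat(sprintf("<sg_plotmap> %d plots on a %d x %d px raster\n",
              nrow(x$plots), x$dims[1], x$dims[2]))
  invisible(x)
}

#' Render a five-band orthomosaic of the trial
#'
#' Every canopy pixel of a plot reflects the greenness-weighted mix of the
#' fixed canopy and soil endmember spectra; a configurable fraction of pixels
#' per plot is pure soil; inter-plot background is soil; the panel region is
#' rendered at exactly the supplied panel reflectances. The returned rasters
#' are raw digital numbers: reflectance times a hidden per-band gain, so
#' downstream panel calibration is exercised non-trivially.
#'
#' @param plots An `sg_plotmap` with a panel region.
#' @param greenness Named per-plot greenness in `[0, 1]`.
#' @param panel Named panel reflectances (default [panel_reflectances()]).
#' @param soil_fraction Fraction of each plot's pixels that are pure soil,
#'   in `[0, 1)`.
#' @param noise_sd Sensor noise SD on the reflectance scale.
#' @param gains Named per-band gains; `NULL` draws them (once per call) from
#'   `runif(5, 50, 150)`. Pass the same vector across dates to share one
#'   season's gains.
#' @param date Flight date.
#' @param seed Integer seed.
#' @return A raw-DN `sg_bandstack`; the gains used are attached as
#'   `attr(, "gains")`.
#' @export
render_orthomosaic <- function(plots, greenness,
                               panel = panel_reflectances(),
                               soil_fraction = 0, noise_sd = 0, gains = NULL,
                               date = as.Date("2021-05-10"), seed = NULL) {
  sg_assert(inherits(plots, "sg_plotmap"), "plots must be an sg_plotmap")
  sg_assert(!is.null(plots$panel_region), "plot map has no panel region")
  ids <- plots$plots$plot_id
  if (!is.null(names(greenness))) greenness <- greenness[ids]
  sg_assert(length(greenness) == length(ids) && !anyNA(greenness) &&
              all(greenness >= 0 & greenness <= 1),
            "greenness must cover every plot and lie in [0, 1]")
  sg_assert(soil_fraction >= 0 && soil_fraction < 1,
            "soil_fraction must be in [0, 1)")
  cs <- canopy_spectrum()
  ss <- soil_spectrum()
  with_seed(seed, {
    if (is.null(gains)) {
      gains <- stats::runif(5, 50, 150)
      names(gains) <- sg_bands()
    }
    sg_assert(all(sg_bands() %in% names(gains)), "gains must name all bands")
    dims <- plots$dims
    bands <- lapply(sg_bands(), function(b) matrix(ss[[b]], dims[1], dims[2]))
    names(bands) <- sg_bands()
    for (i in seq_along(ids)) {
      rect <- unlist(plots$plots[i, c("r0", "c0", "r1", "c1")])
      npix <- rect_npix(rect)
      n_soil <- floor(soil_fraction * npix)
      # soil spots are fixed ground features: their layout depends only on
      # the plot, never on the flight date, so the anthesis mask removes
      # the same pixels from every flight
      soil_cells <- if (n_soil > 0) {
        with_seed(7717L + i, sample.int(npix, n_soil))
      } else {
        integer(0)
      }
      g <- greenness[i]
      for (b in sg_bands()) {
        px <- rep(g * cs[[b]] + (1 - g) * ss[[b]], npix)
        px[soil_cells] <- ss[[b]]
        bands[[b]][rect_rows(rect), rect_cols(rect)] <- px
      }
    }
    if (noise_sd > 0) {
      for (b in sg_bands()) {
        bands[[b]] <- bands[[b]] +
          matrix(rnorm(prod(dims), sd = noise_sd), dims[1], dims[2])
      }
    }
    pr <- plots$panel_region
    for (b in sg_bands()) {
      bands[[b]][rect_rows(pr), rect_cols(pr)] <- panel[[b]]
      bands[[b]] <- bands[[b]] * gains[[b]]
    }
    out <- band_stack(bands, date, pr)
    attr(out, "gains") <- gains[sg_bands()]
    out
  })
}

#' Simulate genotypes with block linkage disequilibrium
#'
#' Haplotype-copying Markov chain along one chromosome: every SNP has allele
#' frequency 1/2 and the correlation between haplotype alleles at distance
#' `d` bp is `exp(-d / scale_bp)`, so dosage LD decays as
#' `r^2(d) = exp(-2 d / scale_bp)` and crosses a critical `r^2` of `rc` at
#' `d = scale_bp * log(1 / rc) / 2` (analytic oracle for LD-decay tests).
#'
#' @param n_acc Number of (diploid) accessions.
#' @param n_snp Number of SNPs.
#' @param scale_bp Correlation decay scale, bp.
#' @param chrom Chromosome label.
#' @param chrom_len Chromosome length, bp.
#' @param seed Integer seed.
#' @return An `sg_geno` (minimal labels).
#' @export
simulate_ld_genotypes <- function(n_acc, n_snp, scale_bp = 2e6, chrom = "1A",
                                  chrom_len = 2e7, seed = NULL) {
  sg_assert(n_acc >= 2 && n_snp >= 2, "need n_acc >= 2 and n_snp >= 2")
  with_seed(seed, {
    pos <- sort(sample.int(chrom_len, n_snp))
    rho <- exp(-diff(pos) / scale_bp)
    hap <- function() {
      h <- matrix(0L, n_acc, n_snp)
      h[, 1] <- rbinom(n_acc, 1L, 0.5)
      for (j in 2:n_snp) {
        stay <- rbinom(n_acc, 1L, (1 + rho[j - 1]) / 2)
        h[, j] <- ifelse(stay == 1L, h[, j - 1], 1L - h[, j - 1])
      }
      h
    }
    dosage <- hap() + hap()
    acc <- sprintf("acc%04d", seq_len(n_acc))
    snp <- sprintf("s%s%d", chrom, pos)
    dimnames(dosage) <- list(acc, snp)
    labels <- data.frame(accession = acc, flowering = "MF", era = NA,
                         region = NA, group = NA, subpop = 1L,
                         stringsAsFactors = FALSE)
    structure(list(dosage = dosage,
                   map = data.frame(snp = snp, chrom = chrom, pos = pos,
                                    ref = "A", alt = "G",
                                    stringsAsFactors = FALSE),
                   labels = labels),
              class = "sg_geno")
  })
}

#' Resample accessions into era bins to plant a haplotype-frequency gradient
#'
#' Partitions (a subset of) the panel into fixed-size era bins so that the
#' realized frequency of the favorable haplotype (homozygous carriers of the
#' Hap1 alleles at both defining SNPs, counted over the whole bin) matches
#' the per-era targets. Sampling is without replacement: if the panel does
#' not hold enough carriers (or non-carriers) the gradient is infeasible.
#'
#' @param geno An `sg_geno`.
#' @param snps Two SNP names or indices defining the haplotype.
#' @param hap1 Two alleles (in SNP order) of the favorable haplotype.
#' @param targets Named (or era-ordered) per-era target frequencies in
#'   `[0, 1]`.
#' @param hap2 Alleles of the alternative haplotype; default is the other
#'   allele at both SNPs.
#' @param bin_size Accessions per era bin; default `floor(n_acc / n_eras)`.
#' @param seed Integer seed.
#' @return An `sg_geno` restricted to the resampled accessions, with era
#'   labels rewritten.
#' @export
assign_cohorts <- function(geno, snps, hap1, targets, hap2 = NULL,
                           bin_size = NULL, seed = NULL) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  sg_assert(all(targets >= 0 & targets <= 1), "targets must lie in [0, 1]")
  eras <- names(targets) %||% era_levels()[seq_along(targets)]
  n_era <- length(targets)
  haps <- assign_haplotypes(geno, snps, hap1, hap2)
  carrier <- haps$assignment$label == "Hap1"
  n <- nrow(geno$dosage)
  if (is.null(bin_size)) bin_size <- floor(n / n_era)
  sg_assert(bin_size >= 1, "bin_size must be >= 1")
  need <- round(targets * bin_size)
  if (sum(need) > sum(carrier) ||
      sum(bin_size - need) > sum(!carrier)) {
    sg_stop("era targets infeasible for the available carrier counts",
            "sg_infeasible_gradient")
  }
  with_seed(seed, {
    carriers <- sample(which(carrier))
    others <- sample(which(!carrier))
    idx <- integer(0)
    era_lab <- character(0)
    c_ptr <- 0L
    o_ptr <- 0L
    for (e in seq_len(n_era)) {
      take_c <- carriers[c_ptr + seq_len(need[e])]
      take_o <- others[o_ptr + seq_len(bin_size - need[e])]
      c_ptr <- c_ptr + need[e]
      o_ptr <- o_ptr + bin_size - need[e]
      idx <- c(idx, take_c, take_o)
      era_lab <- c(era_lab, rep(eras[e], bin_size))
    }
    out <- geno_subset(geno, acc = idx)
    out$labels$era <- era_lab
    out
  })
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper wiring the generator pieces together: weather, a
#' structured genotype panel with one planted stay-green QTL, per-accession
#' anthesis dates (tercile-split into EF/MF/LF), senescence trajectories,
#' a gridded plot map and rendered five-band orthomosaics at a fixed flight
#' cadence with one hidden gain vector per season.
#'
#' @param n_acc Accessions (= plots).
#' @param n_snp SNPs.
#' @param n_dates Flight dates.
#' @param cadence Days between flights.
#' @param qtl_effect Additive rate effect of the planted QTL.
#' @param soil_fraction Soil-pixel fraction per plot.
#' @param noise_sd Sensor noise SD (reflectance scale).
#' @param anthesis_spread Half-range, days, of anthesis dates around the
#'   common flight start.
#' @param seed Integer seed.
#' @return List with `weather`, `geno`, `arch`, `sim`, `plots`, `stacks`,
#'   `flight_dates`, `anthesis`, `flowering` and the per-plot `greenness`
#'   matrix actually rendered.
#' @export
simulate_trial <- function(n_acc = 100, n_snp = 500, n_dates = 8,
                           cadence = 5, qtl_effect = -0.002,
                           soil_fraction = 0.3, noise_sd = 0,
                           anthesis_spread = 3, seed = 1) {
  weather <- simulate_weather(120, base = 22, amplitude = 4, noise_sd = 1.2,
                              seed = seed)
  geno <- simulate_genotypes(n_acc, n_snp, seed = seed + 1L)
  # plant the QTL at a clearly segregating SNP (MAF closest to 0.3)
  mafs <- pmin(colMeans(geno$dosage) / 2, 1 - colMeans(geno$dosage) / 2)
  arch <- trait_architecture(qtl_snps = which.min(abs(mafs - 0.3)),
                             effects = qtl_effect)
  first_flight <- weather$date[15]
  anthesis <- first_flight +
    with_seed(seed + 2L,
              sample(seq(-anthesis_spread, 0), n_acc, replace = TRUE))
  names(anthesis) <- rownames(geno$dosage)
  rk <- rank(as.numeric(anthesis), ties.method = "first")
  flowering <- c("EF", "MF", "LF")[ceiling(3 * rk / n_acc)]
  geno$labels$flowering <- flowering
  sim <- simulate_trajectories(geno, arch, weather, anthesis,
                               noise_sd = 5e-4, seed = seed + 3L)
  n_side <- ceiling(sqrt(n_acc))
  plots <- make_plot_grid(n_side, n_side,
                          plot_ids = rownames(geno$dosage))
  flight_dates <- first_flight + cadence * (seq_len(n_dates) - 1L)
  sg_assert(max(flight_dates) <= max(weather$date),
            "flight dates exceed the weather span")
  gains <- with_seed(seed + 4L, {
    g <- stats::runif(5, 50, 150)
    names(g) <- sg_bands()
    g
  })
  greenness <- matrix(NA_real_, n_acc, n_dates,
                      dimnames = list(rownames(geno$dosage),
                                      format(flight_dates)))
  for (a in seq_len(n_acc)) {
    at <- vapply(flight_dates, function(d) {
      if (d <= anthesis[a]) 0 else
        accumulated_temperature(weather, anthesis[a], d)
    }, 0)
    greenness[a, ] <- greenness_at(sim, at, a)
  }
  stacks <- lapply(seq_len(n_dates), function(j) {
    render_orthomosaic(plots, greenness[, j],
                       soil_fraction = soil_fraction, noise_sd = noise_sd,
                       gains = gains, date = flight_dates[j],
                       seed = seed + 10L + j)
  })
  list(weather = weather, geno = geno, arch = arch, sim = sim,
       plots = plots, stacks = stacks, flight_dates = flight_dates,
       anthesis = anthesis, flowering = flowering,
       greenness = greenness, gains = gains)
}
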