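test_that("Weir-Cockerham Fst matches the independent 1984 oracle", {
  # identical allele counts: theta <= 0
  d <- rbind(matrix(rep(c(0L, 1L, 1L, 2L), 5), 20, 1),
             matrix(rep(c(0L, 1L, 1L, 2L), 5), 20, 1))
  g <- make_geno(d)
  f <- fst_per_snp(g, list(1:20, 21:40))
  expect_lte(f$fst[1], 0)

  # fixed difference: theta = 1
  g2 <- make_geno(rbind(matrix(0L, 20, 1), matrix(2L, 20, 1)))
  expect_equal(fst_per_snp(g2, list(1:20, 21:40))$fst[1], 1)

  # property: 1000 random two-population instances match the oracle
  set.seed(19)
  for (rep in 1:1000) {
    n1 <- sample(2:25, 1)
    n2 <- sample(2:25, 1)
    d1 <- rbinom(n1, 2, runif(1, 0.05, 0.95))
    d2 <- rbinom(n2, 2, runif(1, 0.05, 0.95))
    gg <- make_geno(matrix(c(d1, d2), ncol = 1))
    got <- fst_per_snp(gg, list(seq_len(n1), n1 + seq_len(n2)))
    want <- wc_oracle(d1, d2)
    if (is.na(want$theta)) {
      expect_true(is.na(got$fst[1]))
    } else {
      expect_equal(got$a[1], want$a, tolerance = 1e-12)
      expect_equal(got$b[1], want$b, tolerance = 1e-12)
      expect_equal(got$c[1], want$c, tolerance = 1e-12)
      expect_equal(got$fst[1], want$theta, tolerance = 1e-12)
    }
  }

  expect_error(fst_per_snp(g, list(integer(0), 1:40)),
               class = "sg_invalid_partition")
})

test_that("windowed Fst follows the VCFtools ratio-of-sums convention", {
  # 3 Mb chromosome, 1 Mb windows, 100 kb steps: 21 windows
  set.seed(20)
  m <- 60
  dos <- matrix(rbinom(40 * m, 2, 0.5), 40, m)
  g <- make_geno(dos, pos = sort(sample.int(3e6 - 1, m)))
  comp <- fst_per_snp(g, list(1:20, 21:40))
  w <- window_fst(comp, window = 1e6, step = 1e5, chrom_len = c("1A" = 3e6))
  expect_equal(nrow(w), 21)

  # naive double-loop oracle for every window
  for (i in seq_len(nrow(w))) {
    tot_a <- 0; tot_d <- 0; n_ok <- 0L
    for (j in seq_len(m)) {
      if (comp$pos[j] >= w$start[i] && comp$pos[j] < w$start[i] + 1e6 &&
          is.finite(comp$a[j])) {
        tot_a <- tot_a + comp$a[j]
        tot_d <- tot_d + comp$a[j] + comp$b[j] + comp$c[j]
        n_ok <- n_ok + 1L
      }
    }
    expect_equal(w$n_snps[i], n_ok)
    if (n_ok > 0 && tot_d != 0) expect_equal(w$value[i], tot_a / tot_d)
  }

  # equal per-SNP components in one window: window value = per-SNP value
  g1 <- make_geno(rbind(matrix(0L, 20, 3), matrix(2L, 20, 3)),
                  pos = c(10L, 20L, 30L))
  c1 <- fst_per_snp(g1, list(1:20, 21:40))
  w1 <- window_fst(c1, window = 1e6, step = 1e5, chrom_len = c("1A" = 1e4))
  expect_equal(w1$value[1], 1)
})

test_that("xpclr_lite is calibrated, non-negative, and oracle-consistent", {
  # neutral limit: object frequencies identical to reference
  base <- matrix(rbinom(60 * 200, 2, rep(runif(200, 0.1, 0.9), each = 60)),
                 60, 200)
  g <- make_geno(rbind(base, base), pos = sort(sample.int(2e6, 200)))
  xp <- xpclr_score(g, 1:60, 61:120, window = 1e6, step = 5e5,
                    omega = 0.01)
  expect_true(all(xp$value[is.finite(xp$value)] < 1))
  expect_true(all(xp$value[is.finite(xp$value)] >= 0))

  # single-SNP window score vs brute-force numerical integration oracle
  set.seed(21)
  d1 <- rbinom(40, 2, 0.4)
  d2 <- rbinom(40, 2, 0.85)
  gs <- make_geno(matrix(c(d1, d2), ncol = 1), pos = 500000L)
  omega <- 0.01
  xs <- xpclr_score(gs, 1:40, 41:80, window = 1e6, step = 1e6,
                    omega = omega, chrom_len = c("1A" = 1e6))
  p1 <- mean(d1) / 2
  k2 <- sum(d2)
  n2 <- 80
  dd <- abs(500000 - (1 + (1e6 - 1) / 2)) / 5e5
  ll0 <- xpclr_ll_oracle(k2, n2, p1, sqrt(omega))
  best <- -Inf
  for (cv in c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
    ci <- max(1 - exp(-dd / cv), 1e-3)
    best <- max(best, xpclr_ll_oracle(k2, n2, p1, sqrt(omega / ci)))
  }
  expect_equal(xs$value[1], 2 * max(0, best - ll0), tolerance = 1e-6)

  # joint ref/alt relabeling leaves the score unchanged
  gf <- g
  gf$dosage <- 2L - g$dosage
  tmp <- gf$map$ref; gf$map$ref <- gf$map$alt; gf$map$alt <- tmp
  xpf <- xpclr_score(gf, 1:60, 61:120, window = 1e6, step = 5e5,
                     omega = 0.01)
  expect_equal(xpf$value, xp$value, tolerance = 1e-8)

  expect_error(xpclr_score(g, 1:60, 61:120, omega = -1),
               class = "sg_invalid_drift_variance")
})

test_that("sweep calling flags exactly the top fraction with stable ties", {
  w <- data.frame(chrom = "1A", start = seq(1, by = 1e5, length.out = 100),
                  end = seq(1e6, by = 1e5, length.out = 100),
                  n_snps = 5L, stat = "fst", value = runif(100), sweep = NA)
  class(w) <- c("sg_windows", "data.frame")
  out <- call_sweeps(w, 0.05)
  expect_equal(sum(out$sweep), 5)
  expect_true(all(out$value[out$sweep] >= max(out$value[!out$sweep])))

  expect_equal(sum(call_sweeps(w, 1)$sweep), 100)

  # all equal values: the leftmost windows are flagged
  w2 <- w
  w2$value <- 0.5
  out2 <- call_sweeps(w2, 0.05)
  expect_equal(which(out2$sweep), 1:5)

  # undefined windows are never flagged
  w3 <- w
  w3$value[1:10] <- NA
  w3$n_snps[1:10] <- 0L
  out3 <- call_sweeps(w3, 0.05)
  expect_equal(sum(out3$sweep, na.rm = TRUE), ceiling(0.05 * 90))
  expect_true(all(is.na(out3$sweep[1:10])))
})

test_that("haplotype assignment and trends do exact bookkeeping", {
  # constructed 86 Hap1 (C-C) + 158 Hap2 (G-T) + 6 het cohort
  n <- 250
  dos <- matrix(rbinom(2 * n, 2, 0.5), n, 2)
  dos[1:86, ] <- 0L                          # hom ref at both
  dos[87:244, ] <- 2L                        # hom alt at both
  dos[245:250, 1] <- 1L                      # het at SNP 1
  dos[245:250, 2] <- 0L
  g <- make_geno(dos, ref = c("C", "C"), alt = c("G", "T"))
  hp <- assign_haplotypes(g, c(1, 2), hap1 = c("C", "C"),
                          hap2 = c("G", "T"))
  tab <- table(hp$assignment$label)
  expect_equal(as.integer(tab[c("Hap1", "Hap2", "other")]), c(86, 158, 6))

  g$labels$era <- "pre1950"
  tr <- haplotype_trend(hp, g)
  expect_equal(tr$table$freq_hap1[1], 86 / 250)
  expect_equal(tr$table$freq_hap2[1], 158 / 250)
  expect_equal(tr$table$freq_other[1], 6 / 250)
  expect_equal(tr$table$freq_hap1[1] + tr$table$freq_hap2[1] +
                 tr$table$freq_other[1], 1)

  # two strata with counts 10/90 vs 50/50
  g2 <- make_geno(rbind(matrix(0L, 60, 2), matrix(2L, 140, 2)),
                  ref = c("C", "C"), alt = c("G", "T"))
  g2$labels$era <- c(rep("pre1950", 10), rep("1951-1970", 50),
                     rep("pre1950", 90), rep("1951-1970", 50))
  hp2 <- assign_haplotypes(g2, c(1, 2), c("C", "C"))
  tr2 <- haplotype_trend(hp2, g2)
  expect_equal(tr2$table$freq_hap1, c(0.10, 0.50))

  expect_error(assign_haplotypes(g, c("nope", "s1A2000"), c("C", "C")),
               class = "sg_missing_snp")
})

test_that("haplotype group comparison is a Welch t test", {
  # textbook instance: means 5 vs 6, sd 1, n = 25 each -> t = -3.536
  x <- scale(rnorm(25))[, 1] + 5
  y <- scale(rnorm(25))[, 1] + 6
  g <- make_geno(rbind(matrix(0L, 25, 2), matrix(2L, 25, 2)),
                 ref = c("C", "C"), alt = c("G", "T"))
  hp <- assign_haplotypes(g, c(1, 2), c("C", "C"))
  trait <- setNames(c(x, y), rownames(g$dosage))
  res <- group_compare(trait, hp)
  expect_equal(round(res$t, 3), -3.536)

  # zero difference: t = 0, p = 1
  z <- c(scale(rnorm(30))[, 1] + 10, scale(rnorm(30))[, 1] + 10)
  g0 <- make_geno(rbind(matrix(0L, 30, 2), matrix(2L, 30, 2)),
                  ref = c("C", "C"), alt = c("G", "T"))
  hp0 <- assign_haplotypes(g0, c(1, 2), c("C", "C"))
  res0 <- group_compare(setNames(z, rownames(g0$dosage)), hp0)
  expect_equal(res0$t, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  # null calibration: p uniform under label permutation
  set.seed(22)
  vals <- rnorm(60)
  ps <- vapply(1:200, function(i) {
    perm <- sample(60)
    group_compare(setNames(vals[perm], rownames(g0$dosage)), hp0)$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  small <- make_geno(rbind(matrix(0L, 1, 2), matrix(2L, 30, 2)),
                     ref = c("C", "C"), alt = c("G", "T"))
  hps <- assign_haplotypes(small, c(1, 2), c("C", "C"))
  expect_error(group_compare(setNames(rnorm(31), rownames(small$dosage)),
                             hps),
               class = "sg_insufficient_group")
})
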