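# Population differentiation and selection: Weir-Cockerham Fst with
# VCFtools-style window aggregation, a simplified cross-population
# composite-likelihood sweep score (xpclr_lite), top-fraction sweep calls,
# two-SNP haplotype assignment, era/region frequency trends and haplotype
# trait comparisons.

# groups: list of two accession index/name vectors, or a length-n vector
# with exactly two levels. Returns list(ref = idx, obj = idx).
resolve_groups <- function(geno, groups) {
  n <- nrow(geno$dosage)
  if (is.list(groups) && length(groups) == 2L) {
    idx <- lapply(groups, function(g) {
      if (is.character(g)) match(g, rownames(geno$dosage)) else as.integer(g)
    })
  } else {
    g <- as.character(groups)
    sg_assert(length(g) == n, "group vector must have one entry per accession")
    lev <- unique(g[!is.na(g)])
    sg_assert(length(lev) == 2L, "group vector must have exactly two levels")
    idx <- list(which(g == lev[1]), which(g == lev[2]))
  }
  if (!length(idx[[1]]) || !length(idx[[2]]) ||
      anyNA(idx[[1]]) || anyNA(idx[[2]])) {
    sg_stop("both groups must be non-empty subsets of the panel",
            "sg_invalid_partition")
  }
  idx
}

group_freq_stats <- function(geno, rows) {
  G <- geno$dosage[rows, , drop = FALSE]
  storage.mode(G) <- "double"
  n <- colSums(!is.na(G))
  p <- ifelse(n > 0, colSums(G, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(G == 1, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Per-SNP Weir-Cockerham Fst components
#'
#' Two-population Weir-Cockerham (1984) variance components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals), and the per-SNP estimator `theta = a / (a + b + c)`. SNPs
#' monomorphic across both groups, or with fewer than two called accessions
#' in either group, yield `NA` components and are excluded from window
#' ratios.
#'
#' @param geno An `sg_geno`.
#' @param groups Two-group partition: list of two accession index/name
#'   vectors, or a per-accession vector with two levels.
#' @return Data frame `snp, chrom, pos, n1, n2, p1, p2, a, b, c, fst`.
#' @export
fst_per_snp <- function(geno, groups) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  idx <- resolve_groups(geno, groups)
  g1 <- group_freq_stats(geno, idx[[1]])
  g2 <- group_freq_stats(geno, idx[[2]])
  n1 <- g1$n; n2 <- g2$n
  valid <- n1 >= 2 & n2 >= 2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- ifelse(valid, (n1 * g1$p + n2 * g2$p) / (n1 + n2), NA_real_)
  s2 <- (n1 * (g1$p - pbar)^2 + n2 * (g2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * g1$h + n2 * g2$h) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(valid & is.finite(denom) & denom != 0, a / denom, NA_real_)
  bad <- !valid | !is.finite(denom) | denom == 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  data.frame(snp = geno$map$snp, chrom = geno$map$chrom, pos = geno$map$pos,
             n1 = n1, n2 = n2, p1 = g1$p, p2 = g2$p,
             a = a, b = b, c = cc, fst = fst,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Sliding-window starts on the step grid from position 1; windows are
# [start, start + window) and must fit inside [1, chrom_len].
window_starts <- function(chrom_len, window, step) {
  if (chrom_len < window) return(1)
  seq(1, chrom_len - window + 1, by = step)
}

#' Windowed weighted Fst
#'
#' VCFtools "weighted" convention: per window the ratio of sums
#' `sum(a) / sum(a + b + c)` over the member SNPs' Weir-Cockerham
#' components. Windows of `window` bp slide by `step` bp from position 1.
#'
#' @param components Output of [fst_per_snp()].
#' @param window Window size, bp (default 1 Mb).
#' @param step Step size, bp (default 100 kb).
#' @param chrom_len Optional named per-chromosome lengths; defaults to the
#'   last SNP position per chromosome.
#' @return Object of class `sg_windows`: data frame
#'   `chrom, start, end, n_snps, stat, value, sweep` (sweep is `NA` until
#'   [call_sweeps()]); empty windows carry `n_snps = 0` and `NA` value.
#' @export
window_fst <- function(components, window = 1e6, step = 1e5,
                       chrom_len = NULL) {
  sg_assert(all(c("chrom", "pos", "a", "b", "c") %in% names(components)),
            "components must come from fst_per_snp()")
  rows <- list()
  for (ch in unique(components$chrom)) {
    s <- components[components$chrom == ch, , drop = FALSE]
    L <- if (!is.null(chrom_len)) chrom_len[[ch]] else max(s$pos)
    for (st in window_starts(L, window, step)) {
      member <- s$pos >= st & s$pos < st + window
      comp <- s[member & is.finite(s$a), , drop = FALSE]
      den <- sum(comp$a + comp$b + comp$c)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + window - 1,
        n_snps = nrow(comp), stat = "fst",
        value = if (nrow(comp) && den != 0) sum(comp$a) / den else NA_real_,
        sweep = NA, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sg_windows", "data.frame")
  out
}

# log composite likelihood of the object-population allele counts given the
# reference frequencies, under binomial sampling over a truncated-normal
# drift density with boundary point masses. Vectorized over SNPs; sigma may
# vary per SNP. gl holds Gauss-Legendre nodes/weights on [0, 1].
xpclr_loglik <- function(k2, n2, p1, sigma, gl) {
  interior <- numeric(length(k2))
  for (g in seq_along(gl$x)) {
    interior <- interior + gl$w[g] *
      stats::dbinom(k2, n2, gl$x[g]) * stats::dnorm(gl$x[g], p1, sigma)
  }
  lik <- stats::pnorm(0, p1, sigma) * (k2 == 0) +
    stats::pnorm(1, p1, sigma, lower.tail = FALSE) * (k2 == n2) +
    interior
  log(pmax(lik, 1e-300))
}

#' Simplified cross-population composite-likelihood sweep scan (xpclr_lite)
#'
#' For each sliding window, compares the composite likelihood of the object
#' population's allele frequencies under a neutral drift model (truncated
#' normal around the reference frequency with genome-wide variance `omega`,
#' plus fixation point masses) against a sweep model in which drift variance
#' is inflated near the window center through the physical-distance kernel
#' `c_i = 1 - exp(-d_i / c)` (with `d_i` the SNP's distance from the center
#' normalized by the half window, and variance `omega / c_i`). The score is
#' `2 * max(0, max_c sum_i [logL_sweep - logL_neutral])` over the grid of
#' `c`; the neutral model lies in the grid's closure (`c -> 0+`), so scores
#' are non-negative.
#'
#' @param geno An `sg_geno`.
#' @param ref_group,obj_group Accession index/name vectors (reference and
#'   object populations).
#' @param window,step Window and step sizes, bp.
#' @param grid Sweep-strength grid over `(0, 1]`.
#' @param omega Genome-wide drift variance; default is the median of
#'   `(p2 - p1)^2 / (p1 (1 - p1))` over SNPs with reference frequency in
#'   `(0.05, 0.95)`.
#' @param nodes Gauss-Legendre quadrature nodes for the drift integral.
#' @param chrom_len Optional named per-chromosome lengths.
#' @return An `sg_windows` data frame with `stat = "xpclr_lite"`.
#' @export
xpclr_score <- function(geno, ref_group, obj_group, window = 1e6,
                        step = 1e5, grid = c(0.01, 0.02, 0.05, 0.1, 0.2,
                                             0.5, 1),
                        omega = NULL, nodes = 48, chrom_len = NULL) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  idx <- resolve_groups(geno, list(ref_group, obj_group))
  g1 <- group_freq_stats(geno, idx[[1]])
  g2 <- group_freq_stats(geno, idx[[2]])
  usable <- g1$n >= 1 & g2$n >= 1 & is.finite(g1$p) & is.finite(g2$p)
  if (is.null(omega)) {
    mid <- usable & g1$p > 0.05 & g1$p < 0.95
    sg_assert(any(mid), "no intermediate-frequency SNPs to estimate omega",
              "sg_invalid_drift_variance")
    omega <- stats::median((g2$p[mid] - g1$p[mid])^2 /
                             (g1$p[mid] * (1 - g1$p[mid])))
  }
  if (!is.finite(omega) || omega <= 0) {
    sg_stop("drift variance omega must be positive",
            "sg_invalid_drift_variance")
  }
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  k2 <- round(2 * g2$n * g2$p)
  n2 <- 2 * g2$n
  rows <- list()
  for (ch in unique(geno$map$chrom)) {
    on_ch <- which(geno$map$chrom == ch & usable)
    pos <- geno$map$pos[on_ch]
    L <- if (!is.null(chrom_len)) chrom_len[[ch]] else
      max(geno$map$pos[geno$map$chrom == ch])
    for (st in window_starts(L, window, step)) {
      member <- on_ch[pos >= st & pos < st + window]
      mpos <- geno$map$pos[member]
      if (!length(member)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = st, end = st + window - 1, n_snps = 0L,
          stat = "xpclr_lite", value = NA_real_, sweep = NA,
          stringsAsFactors = FALSE)
        next
      }
      center <- st + (window - 1) / 2
      d <- abs(mpos - center) / (window / 2)
      ll0 <- sum(xpclr_loglik(k2[member], n2[member], g1$p[member],
                              sqrt(omega), gl))
      best <- -Inf
      for (cv in grid) {
        ci <- pmax(1 - exp(-d / cv), 1e-3)
        ll <- sum(xpclr_loglik(k2[member], n2[member], g1$p[member],
                               sqrt(omega / ci), gl))
        if (ll > best) best <- ll
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + window - 1,
        n_snps = length(member), stat = "xpclr_lite",
        value = 2 * max(0, best - ll0), sweep = NA,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sg_windows", "data.frame")
  out
}

#' Flag the top fraction of windows as selective sweeps
#'
#' Flags the `ceiling(top_fraction * n_defined)` highest-valued windows
#' (ties at the cut broken towards the leftmost genomic coordinate);
#' windows with no defined value (e.g. `n_snps = 0`) are never flagged.
#'
#' @param stats An `sg_windows` data frame.
#' @param top_fraction Fraction of defined windows to flag (default 0.05).
#' @return The input with the logical `sweep` column filled in.
#' @export
call_sweeps <- function(stats, top_fraction = 0.05) {
  sg_assert(is.data.frame(stats) && all(c("value", "chrom", "start") %in%
                                          names(stats)),
            "stats must be an sg_windows data frame")
  defined <- which(is.finite(stats$value))
  sg_assert(length(defined) >= 1L, "no window has a defined value",
            "sg_empty_result")
  sg_assert(top_fraction > 0 && top_fraction <= 1,
            "top_fraction must be in (0, 1]")
  n_flag <- ceiling(top_fraction * length(defined))
  ord <- defined[order(-stats$value[defined], stats$chrom[defined],
                       stats$start[defined])]
  stats$sweep <- FALSE
  stats$sweep[is.na(stats$value)] <- NA
  stats$sweep[ord[seq_len(n_flag)]] <- TRUE
  stats
}

#' Assign accessions to two-SNP haplotype groups
#'
#' An accession is `Hap1` when homozygous for the Hap1 allele at both
#' defining SNPs, `Hap2` likewise; heterozygous, missing or recombinant
#' configurations fall into `other` (inbred-panel convention: heterozygotes
#' are excluded, not phased).
#'
#' @param geno An `sg_geno`.
#' @param snps Two SNP names or indices.
#' @param hap1 Hap1 alleles, one per SNP (in `snps` order).
#' @param hap2 Hap2 alleles; default is the other allele at each SNP.
#' @return Object of class `sg_haps`: `assignment` data frame
#'   (`accession, label`) plus the defining SNPs and alleles.
#' @export
assign_haplotypes <- function(geno, snps, hap1, hap2 = NULL) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  sg_assert(length(snps) == 2L && length(hap1) == 2L,
            "need exactly two defining SNPs and two Hap1 alleles")
  idx <- if (is.character(snps)) match(snps, geno$map$snp) else
    as.integer(snps)
  if (anyNA(idx) || any(idx < 1L | idx > nrow(geno$map))) {
    sg_stop("defining SNP absent from the panel", "sg_missing_snp")
  }
  ref <- geno$map$ref[idx]
  alt <- geno$map$alt[idx]
  sg_assert(all(hap1 == ref | hap1 == alt),
            "hap1 alleles must match the ref or alt allele at each SNP")
  if (is.null(hap2)) hap2 <- ifelse(hap1 == ref, alt, ref)
  sg_assert(all(hap2 == ref | hap2 == alt),
            "hap2 alleles must match the ref or alt allele at each SNP")
  hom_allele <- function(dos, j) {
    ifelse(is.na(dos), NA_character_,
           ifelse(dos == 0L, ref[j], ifelse(dos == 2L, alt[j], "het")))
  }
  a1 <- hom_allele(geno$dosage[, idx[1]], 1L)
  a2 <- hom_allele(geno$dosage[, idx[2]], 2L)
  label <- rep("other", nrow(geno$dosage))
  label[!is.na(a1) & !is.na(a2) & a1 == hap1[1] & a2 == hap1[2]] <- "Hap1"
  label[!is.na(a1) & !is.na(a2) & a1 == hap2[1] & a2 == hap2[2]] <- "Hap2"
  structure(list(assignment = data.frame(accession = rownames(geno$dosage),
                                         label = label,
                                         stringsAsFactors = FALSE),
                 snps = geno$map$snp[idx], hap1 = hap1, hap2 = hap2),
            class = "sg_haps")
}

#' @export
print.sg_haps <- function(x, ...) {
  tab <- table(factor(x$assignment$label, c("Hap1", "Hap2", "other")))
  cat(sprintf("<sg_haps> %s x %s: Hap1 %d, Hap2 %d, other %d\n",
              x$snps[1], x$snps[2], tab["Hap1"], tab["Hap2"], tab["other"]))
  invisible(x)
}

#' Haplotype-frequency trend across strata
#'
#' Per-stratum Hap1/Hap2/other fractions (denominator: every accession in
#' the stratum, so the three fractions sum to 1) and, for ordered strata
#' (eras), the Cochran-Armitage trend test of the Hap1 proportion.
#'
#' @param haps An `sg_haps`.
#' @param labels Accession label data frame (e.g. `geno$labels`) containing
#'   `accession` and the stratum column, or an `sg_geno`.
#' @param strata Stratum column name: `"era"`, `"region"` or `"group"`.
#' @param order Stratum order; defaults to [era_levels()] for eras, sorted
#'   unique values otherwise.
#' @return Object of class `sg_trend`: `table` data frame
#'   (`stratum, n, n_hap1, n_hap2, n_other, freq_hap1, freq_hap2,
#'   freq_other`) plus `trend_chisq`, `trend_p` (Cochran-Armitage, `NA` for
#'   fewer than two usable strata).
#' @export
haplotype_trend <- function(haps, labels, strata = "era", order = NULL) {
  sg_assert(inherits(haps, "sg_haps"), "haps must be an sg_haps")
  if (inherits(labels, "sg_geno")) labels <- labels$labels
  sg_assert(strata %in% names(labels),
            paste0("labels has no column '", strata, "'"))
  df <- merge(haps$assignment, labels[, c("accession", strata)],
              by = "accession")
  sg_assert(nrow(df) == nrow(haps$assignment),
            "every assigned accession needs a stratum label",
            "sg_missing_data")
  if (is.null(order)) {
    order <- if (strata == "era") {
      intersect(era_levels(), unique(df[[strata]]))
    } else {
      sort(unique(df[[strata]]))
    }
  }
  tab <- lapply(order, function(s) {
    in_s <- df[[strata]] == s & !is.na(df[[strata]])
    n <- sum(in_s)
    counts <- table(factor(df$label[in_s], c("Hap1", "Hap2", "other")))
    data.frame(stratum = s, n = n,
               n_hap1 = as.integer(counts["Hap1"]),
               n_hap2 = as.integer(counts["Hap2"]),
               n_other = as.integer(counts["other"]),
               freq_hap1 = if (n > 0) counts[["Hap1"]] / n else NA_real_,
               freq_hap2 = if (n > 0) counts[["Hap2"]] / n else NA_real_,
               freq_other = if (n > 0) counts[["other"]] / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  usable <- tab$n > 0
  trend_chisq <- trend_p <- NA_real_
  if (sum(usable) >= 2L && sum(tab$n_hap1[usable]) > 0) {
    tt <- suppressWarnings(
      stats::prop.trend.test(tab$n_hap1[usable], tab$n[usable]))
    trend_chisq <- unname(tt$statistic)
    trend_p <- tt$p.value
  }
  structure(list(table = tab, strata = strata, trend_chisq = trend_chisq,
                 trend_p = trend_p),
            class = "sg_trend")
}

#' @export
print.sg_trend <- function(x, ...) {
  cat(sprintf("<sg_trend> by %s; Cochran-Armitage p = %.3g\n",
              x$strata, x$trend_p))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare trait values between haplotype groups
#'
#' Welch two-sided t test of Hap1 versus Hap2 accessions per trait.
#'
#' @param trait Named numeric vector (one trait) or accession x trait
#'   matrix.
#' @param haps An `sg_haps`.
#' @return Data frame `trait, n1, n2, mean_hap1, mean_hap2, diff, t, df, p`.
#' @export
group_compare <- function(trait, haps) {
  sg_assert(inherits(haps, "sg_haps"), "haps must be an sg_haps")
  if (is.vector(trait)) {
    trait <- matrix(trait, ncol = 1, dimnames = list(names(trait), "trait"))
  }
  lab <- haps$assignment$label[match(rownames(trait),
                                     haps$assignment$accession)]
  out <- lapply(colnames(trait), function(tr) {
    x <- trait[lab == "Hap1" & !is.na(lab), tr]
    y <- trait[lab == "Hap2" & !is.na(lab), tr]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      sg_stop("each haplotype group needs at least 2 accessions",
              "sg_insufficient_group")
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(trait = tr, n1 = length(x), n2 = length(y),
               mean_hap1 = mean(x), mean_hap2 = mean(y),
               diff = mean(x) - mean(y), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
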