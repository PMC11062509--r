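# Phenotype-level statistics: broad-sense heritability by expected mean
# squares, pairwise-complete correlation matrices, LD decay summaries.

#' Broad-sense heritability across environments
#'
#' One-way random model `y_ij = mu + g_i + e_ij` fitted by the
#' expected-mean-squares (method-of-moments) estimator:
#' `sigma2_e = MS_error`, `sigma2_G = (MS_geno - MS_error) / n_rep` with
#' negatives clamped to zero, where `n_rep` is the (harmonic mean)
#' replication per genotype. Heritability on an entry-mean basis over the
#' `n` environments: `H2 = sigma2_G / (sigma2_G + sigma2_e / n)`.
#'
#' @param trait Numeric matrix, accessions in rows, environments (>= 2) in
#'   columns; missing cells allowed.
#' @return Object of class `sg_h2`: list with `sigma2_G`, `sigma2_e`,
#'   `n_env`, `H2`.
#' @export
heritability <- function(trait) {
  sg_assert(is.matrix(trait) && is.numeric(trait),
            "trait must be a numeric accession x environment matrix")
  if (ncol(trait) < 2L) {
    sg_stop("heritability needs at least 2 environments",
            "sg_insufficient_environments")
  }
  sg_assert(nrow(trait) >= 3L, "heritability needs at least 3 accessions")
  n_env <- ncol(trait)
  long <- data.frame(
    geno = factor(rep(rownames(trait) %||% seq_len(nrow(trait)), n_env)),
    value = as.vector(trait))
  long <- long[is.finite(long$value), ]
  counts <- table(long$geno)
  counts <- counts[counts > 0]
  sg_assert(length(counts) >= 3L && sum(counts) > length(counts),
            "not enough complete observations")
  aov_tab <- suppressWarnings(
    stats::anova(stats::lm(value ~ geno, data = long,
                           na.action = stats::na.omit)))
  ms_geno <- aov_tab[["Mean Sq"]][1]
  ms_err <- aov_tab[["Mean Sq"]][2]
  if (!is.finite(ms_err)) ms_err <- 0   # saturated fit: no residual df
  n_rep <- length(counts) / sum(1 / as.numeric(counts))  # harmonic mean
  sigma2_e <- ms_err
  sigma2_G <- max(0, (ms_geno - ms_err) / n_rep)
  h2 <- if (sigma2_G == 0 && sigma2_e == 0) NA_real_ else
    sigma2_G / (sigma2_G + sigma2_e / n_env)
  structure(list(sigma2_G = sigma2_G, sigma2_e = sigma2_e, n_env = n_env,
                 H2 = h2),
            class = "sg_h2")
}

#' @export
print.sg_h2 <- function(x, ...) {
  cat(sprintf(
    "<sg_h2> H2 = %.3f  (sigma2_G = %.4g, sigma2_e = %.4g, n_env = %d)\n",
    x$H2, x$sigma2_G, x$sigma2_e, x$n_env))
  invisible(x)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param traits Numeric matrix, accessions in rows, traits in columns.
#' @param min_pairs Minimum complete pairs for an entry (default 3); entries
#'   with fewer pairs, or involving a constant column, are `NA` with a
#'   warning.
#' @return Trait x trait correlation matrix.
#' @export
pearson_matrix <- function(traits, min_pairs = 3L) {
  sg_assert(is.matrix(traits) && is.numeric(traits),
            "traits must be a numeric matrix")
  p <- ncol(traits)
  nm <- colnames(traits) %||% paste0("trait", seq_len(p))
  out <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  dropped <- 0L
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- is.finite(traits[, i]) & is.finite(traits[, j])
      if (sum(ok) < min_pairs ||
          stats::sd(traits[ok, i]) == 0 || stats::sd(traits[ok, j]) == 0) {
        if (i != j) dropped <- dropped + 1L
        next
      }
      out[i, j] <- out[j, i] <- stats::cor(traits[ok, i], traits[ok, j])
    }
  }
  if (dropped > 0) {
    warning(sprintf(
      "%d correlation(s) undefined (constant column or < %d complete pairs)",
      dropped, min_pairs))
  }
  out
}

#' Linkage-disequilibrium decay
#'
#' Composite (genotype-dosage) `r^2` for all intra-chromosomal SNP pairs up
#' to `max_dist`, binned by distance; the decay distance is where the
#' monotone (running-minimum) smoothed binned curve first crosses the
#' critical `r^2`, found by linear interpolation between the bracketing bin
#' centers.
#'
#' @param geno An `sg_geno`.
#' @param max_dist Maximum pair distance, bp.
#' @param n_bins Number of equal-width distance bins.
#' @param critical_r2 Critical `r^2` defining the decay distance
#'   (default 0.1).
#' @return Object of class `sg_ld`: `bins` data frame
#'   (`center, mean_r2, n_pairs`), `decay_distance` (bp, `NA` when the curve
#'   never crosses), `critical_r2`.
#' @export
ld_decay <- function(geno, max_dist = 2e7, n_bins = 40, critical_r2 = 0.1) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  breaks <- seq(0, max_dist, length.out = n_bins + 1L)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (ch in unique(geno$map$chrom)) {
    idx <- which(geno$map$chrom == ch)
    if (length(idx) < 2L) next
    pos <- geno$map$pos[idx]
    ord <- order(pos)
    idx <- idx[ord]
    pos <- pos[ord]
    X <- geno$dosage[, idx, drop = FALSE]
    m <- length(idx)
    for (j in seq_len(m - 1L)) {
      k_max <- findInterval(pos[j] + max_dist, pos)
      if (k_max <= j) next
      ks <- (j + 1L):k_max
      r <- suppressWarnings(stats::cor(X[, j], X[, ks, drop = FALSE]))
      r2 <- as.numeric(r)^2
      d <- pos[ks] - pos[j]
      ok <- is.finite(r2)
      if (!any(ok)) next
      b <- pmin(pmax(ceiling(d[ok] / (max_dist / n_bins)), 1L), n_bins)
      for (u in seq_along(b)) {
        sums[b[u]] <- sums[b[u]] + r2[ok][u]
        counts[b[u]] <- counts[b[u]] + 1L
      }
    }
  }
  if (sum(counts) == 0L) {
    sg_stop("no SNP pairs within max_dist", "sg_empty_result")
  }
  centers <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  mean_r2 <- ifelse(counts > 0, sums / counts, NA_real_)
  bins <- data.frame(center = centers, mean_r2 = mean_r2, n_pairs = counts)
  used <- bins[is.finite(bins$mean_r2), ]
  sm <- cummin(used$mean_r2)
  decay <- NA_real_
  cross <- which(sm < critical_r2)
  if (length(cross)) {
    i <- cross[1]
    if (i == 1L) {
      decay <- used$center[1]
    } else {
      x0 <- used$center[i - 1L]; y0 <- sm[i - 1L]
      x1 <- used$center[i]; y1 <- sm[i]
      decay <- x0 + (y0 - critical_r2) / (y0 - y1) * (x1 - x0)
    }
  }
  structure(list(bins = bins, decay_distance = decay,
                 critical_r2 = critical_r2),
            class = "sg_ld")
}

#' @export
print.sg_ld <- function(x, ...) {
  cat(sprintf("<sg_ld> decay to r2 = %g at %.3g bp (%d pairs)\n",
              x$critical_r2, x$decay_distance, sum(x$bins$n_pairs)))
  invisible(x)
}
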