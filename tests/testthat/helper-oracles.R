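# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: scalar loops, generic optimizers, closed forms.

# Build an sg_geno directly from a dosage matrix (for hand-constructed cases)
make_geno <- function(dosage, chrom = NULL, pos = NULL, ref = NULL,
                      alt = NULL, labels = NULL) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  acc <- rownames(dosage) %||% sprintf("acc%04d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("1A", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  snp <- sprintf("s%s%d", chrom, pos)
  dimnames(dosage) <- list(acc, snp)
  if (is.null(labels)) {
    labels <- data.frame(accession = acc, flowering = "MF", era = NA,
                         region = NA, group = NA, subpop = 1L,
                         stringsAsFactors = FALSE)
  }
  structure(list(dosage = dosage,
                 map = data.frame(snp = snp, chrom = chrom, pos = pos,
                                  ref = ref, alt = alt,
                                  stringsAsFactors = FALSE),
                 labels = labels),
            class = "sg_geno")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir-Cockerham (1984) two-population components, scalar arithmetic,
# written directly from the published formulas (r = 2 populations).
wc_oracle <- function(d1, d2) {
  n1 <- sum(!is.na(d1)); n2 <- sum(!is.na(d2))
  p1 <- mean(d1, na.rm = TRUE) / 2; p2 <- mean(d2, na.rm = TRUE) / 2
  h1 <- mean(d1 == 1, na.rm = TRUE); h2 <- mean(d2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * ssq -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if ((a + b + cc) == 0) NA_real_ else a / (a + b + cc))
}

# Direct REML mixed-model Wald p-value: full covariance, generic optimizer,
# no eigendecomposition trick.
direct_reml_p <- function(y, W, x, K) {
  n <- length(y)
  M <- cbind(W, x)
  q <- ncol(M)
  ll <- function(loglam) {
    V <- exp(loglam) * K + diag(n)
    Vi <- solve(V)
    A <- t(M) %*% Vi %*% M
    beta <- solve(A, t(M) %*% Vi %*% y)
    resid <- y - M %*% beta
    rss <- as.numeric(t(resid) %*% Vi %*% resid)
    -0.5 * (as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(A)$modulus) + (n - q) * log(rss))
  }
  opt <- stats::optimize(ll, log(c(1e-5, 1e5)), maximum = TRUE, tol = 1e-10)
  cand <- c(opt$maximum, log(1e-5), log(1e5))
  lam <- exp(cand[which.max(vapply(cand, ll, 0))])
  V <- lam * K + diag(n)
  Vi <- solve(V)
  A <- t(M) %*% Vi %*% M
  beta <- solve(A, t(M) %*% Vi %*% y)
  resid <- y - M %*% beta
  sigma2 <- as.numeric(t(resid) %*% Vi %*% resid) / (n - q)
  se <- sqrt(sigma2 * solve(A)[q, q])
  stats::pf((beta[q] / se)^2, 1, n - q, lower.tail = FALSE)
}

# Naive per-pixel plot mean: scalar double loop over the rectangle.
plot_mean_oracle <- function(raster, mask, r0, c0, r1, c1) {
  acc <- c()
  for (i in (r0 + 1):r1) {
    for (j in (c0 + 1):c1) {
      if (mask[i, j] && !is.na(raster[i, j])) acc <- c(acc, raster[i, j])
    }
  }
  if (length(acc)) mean(acc) else NA_real_
}

# xpclr_lite single-SNP log-likelihood by adaptive quadrature.
xpclr_ll_oracle <- function(k2, n2, p1, sigma) {
  interior <- stats::integrate(function(p) {
    stats::dbinom(k2, n2, p) * stats::dnorm(p, p1, sigma)
  }, 0, 1, rel.tol = 1e-12)$value
  log(stats::pnorm(0, p1, sigma) * (k2 == 0) +
        stats::pnorm(1, p1, sigma, lower.tail = FALSE) * (k2 == n2) +
        interior)
}

# Transitive-closure grouping of significant positions (brute force):
# two SNPs share a QTL iff connected through gaps <= gap.
qtl_groups_oracle <- function(pos, gap) {
  pos <- sort(pos)
  n <- length(pos)
  if (!n) return(list())
  grp <- rep(1L, n)
  for (i in seq_len(n - 1)) {
    grp[i + 1] <- if (pos[i + 1] - pos[i] <= gap) grp[i] else grp[i] + 1L
  }
  lapply(unique(grp), function(g) range(pos[grp == g]))
}
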