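# Mixed-linear-model association scan with kinship: EMMA-style
# eigendecomposition, restricted-likelihood profiling over the variance
# ratio lambda, Wald tests, significance thresholds and QTL grouping.

# MAF / missingness filter with mean imputation of residual missing calls.
# Returns the numeric dosage matrix and the indices kept.
filter_dosages <- function(geno, maf = 0.05, max_missing = 0.1) {
  X <- geno$dosage
  storage.mode(X) <- "double"
  miss <- colMeans(is.na(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  variable <- apply(X, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) > 1L
  })
  keep <- which(miss <= max_missing & mafs >= maf & mafs > 0 & variable)
  X <- X[, keep, drop = FALSE]
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[!nas, j])
    }
  }
  list(X = X, keep = keep, maf = mafs[keep])
}

#' Centered relatedness (kinship) matrix
#'
#' `K = X_c X_c' / m` over the `m` SNPs passing the MAF/missingness filters,
#' with column-centered dosages — the centered-relatedness convention of
#' mixed-model GWAS.
#'
#' @param geno An `sg_geno`.
#' @param maf Minor-allele-frequency filter (default 0.05).
#' @param max_missing Per-SNP missingness filter (default 0.1).
#' @return Symmetric positive semi-definite accession x accession matrix.
#' @export
kinship <- function(geno, maf = 0.05, max_missing = 0.1) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  f <- filter_dosages(geno, maf = maf, max_missing = max_missing)
  if (ncol(f$X) < 2L) {
    sg_stop("fewer than 2 polymorphic SNPs after filters; kinship degenerate",
            "sg_degenerate_kinship")
  }
  Xc <- scale(f$X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / ncol(Xc)
  dimnames(K) <- list(rownames(geno$dosage), rownames(geno$dosage))
  K
}

#' Principal-component covariates for population structure
#'
#' Top-`k` principal-component scores of the centered, unit-variance-scaled
#' dosage matrix.
#'
#' @param geno An `sg_geno`.
#' @param k Number of components (`k = 0` gives an empty covariate block).
#' @param maf,max_missing Filters as in [kinship()].
#' @return Accession x `k` score matrix.
#' @export
pca_covariates <- function(geno, k, maf = 0.05, max_missing = 0.1) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  n <- nrow(geno$dosage)
  sg_assert(k >= 0 && k < n, "k must satisfy 0 <= k < n_acc")
  if (k == 0L) {
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(geno$dosage),
                                                    NULL)))
  }
  f <- filter_dosages(geno, maf = maf, max_missing = max_missing)
  Xs <- scale(f$X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  sv <- svd(Xs, nu = min(k, n), nv = 0)
  rank <- sum(sv$d > max(dim(Xs)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    warning(sprintf("requested %d PCs but rank is %d; returning %d",
                    k, rank, rank))
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(scores) <- rownames(geno$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# REML log-likelihood of the rotated model at variance ratio lambda.
# yt, Mt are eigen-rotated response/design; d the kinship eigenvalues.
# Returns the profile restricted log-likelihood up to an additive constant,
# plus the GLS pieces needed for the Wald test.
reml_pieces <- function(log_lambda, yt, Mt, d) {
  lambda <- exp(log_lambda)
  w <- lambda * d + 1
  Mw <- Mt / w
  A <- crossprod(Mt, Mw)
  b <- crossprod(Mw, yt)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rssw <- sum(yt^2 / w) - sum(b * beta)
  rssw <- max(rssw, .Machine$double.xmin)
  q <- ncol(Mt)
  n <- length(yt)
  ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(ch))) +
                  (n - q) * log(rssw))
  list(ll = ll, beta = beta, chol = ch, rssw = rssw, lambda = lambda)
}

reml_ll <- function(log_lambda, yt, Mt, d) {
  p <- reml_pieces(log_lambda, yt, Mt, d)
  if (is.null(p)) -Inf else p$ll
}

# Profile REML over log lambda in [log 1e-5, log 1e5] and return the Wald
# test of the last design column.
reml_fit <- function(yt, Mt, d, lambda_fixed = NULL) {
  if (is.null(lambda_fixed)) {
    opt <- stats::optimize(reml_ll, interval = log(c(1e-5, 1e5)),
                           yt = yt, Mt = Mt, d = d, maximum = TRUE,
                           tol = 1e-8)
    # guard the boundaries: optimize() never evaluates the endpoints
    cand <- c(opt$maximum, log(1e-5), log(1e5))
    ll <- vapply(cand, reml_ll, 0, yt = yt, Mt = Mt, d = d)
    log_lambda <- cand[which.max(ll)]
  } else {
    log_lambda <- log(lambda_fixed)
  }
  p <- reml_pieces(log_lambda, yt, Mt, d)
  if (is.null(p)) sg_stop("singular design in mixed-model fit",
                          "sg_collinearity")
  n <- length(yt)
  q <- ncol(Mt)
  sigma2 <- p$rssw / (n - q)
  Ainv_qq <- chol2inv(p$chol)[q, q]
  beta <- p$beta[q]
  se <- sqrt(sigma2 * Ainv_qq)
  fstat <- (beta / se)^2
  pval <- stats::pf(fstat, 1, n - q, lower.tail = FALSE)
  list(beta = beta, se = se, p = pval, lambda = p$lambda, df = n - q)
}

#' Univariate mixed-linear-model association scan
#'
#' Model `y = W alpha + x beta + u + eps` with `u ~ N(0, lambda tau^-1 K)`
#' and `eps ~ N(0, tau^-1 I)`. The kinship matrix is eigendecomposed once;
#' response, covariates and each SNP are rotated into the eigenbasis, the
#' restricted likelihood is profiled over `lambda` on `[1e-5, 1e5]`
#' (per SNP by default, or once at the no-SNP null in `"null-lambda"` mode)
#' and `beta = 0` is tested by a Wald F test with `n - q` denominator
#' degrees of freedom. With `K = I` the scan reduces exactly to the ordinary
#' least-squares F test.
#'
#' @param y Named numeric phenotype vector (one value per accession;
#'   accessions with missing phenotype are dropped).
#' @param geno An `sg_geno`.
#' @param K Kinship matrix (default [kinship()] of `geno`).
#' @param covariates Optional accession x c covariate matrix (PCs etc.).
#' @param mode `"per-snp-lambda"` (default) re-optimizes `lambda` for every
#'   SNP; `"null-lambda"` reuses the null-model optimum for all SNPs.
#' @param maf,max_missing SNP filters.
#' @return Object of class `sg_assoc`: data frame with one row per tested
#'   SNP (`snp, chrom, pos, maf, beta, se, lambda, p, r2`), where `r2` is
#'   the proportion of phenotypic variance `beta^2 var(x) / var(y)`.
#' @export
mlm_scan <- function(y, geno, K = NULL, covariates = NULL,
                     mode = c("per-snp-lambda", "null-lambda"),
                     maf = 0.05, max_missing = 0.1) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  mode <- match.arg(mode)
  acc <- rownames(geno$dosage)
  if (!is.null(names(y))) y <- y[acc]
  sg_assert(length(y) == length(acc), "y must have one value per accession")
  keep_acc <- which(is.finite(y))
  g <- if (length(keep_acc) < length(acc)) {
    geno_subset(geno, acc = keep_acc)
  } else {
    geno
  }
  y <- as.numeric(y[keep_acc])
  n <- length(y)
  if (is.null(K)) K <- kinship(g) else K <- K[keep_acc, keep_acc,
                                              drop = FALSE]
  W <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cov <- as.matrix(covariates)
    if (!is.null(rownames(cov))) cov <- cov[rownames(g$dosage), , drop = FALSE]
    else cov <- cov[keep_acc, , drop = FALSE]
    W <- cbind(W, cov)
  }
  if (qr(W)$rank < ncol(W)) {
    sg_stop("covariate block is singular", "sg_collinearity")
  }
  f <- filter_dosages(g, maf = maf, max_missing = max_missing)
  sg_assert(ncol(f$X) >= 1L, "no SNPs pass the filters", "sg_no_snps")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  yt <- as.vector(Ut %*% y)
  Wt <- Ut %*% W
  Xt <- Ut %*% f$X
  lambda_fixed <- NULL
  if (mode == "null-lambda") {
    opt <- stats::optimize(reml_ll, interval = log(c(1e-5, 1e5)), yt = yt,
                           Mt = Wt, d = d, maximum = TRUE, tol = 1e-8)
    lambda_fixed <- exp(opt$maximum)
  }
  var_y <- stats::var(y)
  m <- ncol(Xt)
  beta <- se <- pv <- lam <- r2 <- numeric(m)
  for (j in seq_len(m)) {
    fit <- reml_fit(yt, cbind(Wt, Xt[, j]), d, lambda_fixed = lambda_fixed)
    beta[j] <- fit$beta
    se[j] <- fit$se
    pv[j] <- fit$p
    lam[j] <- fit$lambda
    r2[j] <- fit$beta^2 * stats::var(f$X[, j]) / var_y
  }
  out <- data.frame(snp = g$map$snp[f$keep], chrom = g$map$chrom[f$keep],
                    pos = g$map$pos[f$keep], maf = f$maf, beta = beta,
                    se = se, lambda = lam, p = pv, r2 = r2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mode") <- mode
  class(out) <- c("sg_assoc", "data.frame")
  out
}

#' Genome-wide significance threshold
#'
#' Returns the uniform p-value cutoff (default 2.60e-4), or per-chromosome
#' cutoffs `1 / m_eff` when requested. The effective marker number per
#' chromosome is `m_eff = m / (1 + (m - 1) * max(0, r2bar - 1/(n-1)))`,
#' where `r2bar` is the mean pairwise dosage `r^2` within a sliding
#' neighbourhood; subtracting the `1/(n-1)` finite-sample null expectation
#' makes `m_eff` equal `m` for independent SNPs by construction.
#'
#' @param cutoff Uniform cutoff (> 0).
#' @param per_chromosome If `TRUE`, derive `1 / m_eff` per chromosome from
#'   `geno`.
#' @param geno An `sg_geno` (required for per-chromosome cutoffs).
#' @param window Neighbourhood half-width, SNPs, for the mean `r^2`.
#' @return Single cutoff, or named per-chromosome vector.
#' @export
significance_threshold <- function(cutoff = 2.60e-4,
                                   per_chromosome = FALSE, geno = NULL,
                                   window = 50L) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0) {
    sg_stop("cutoff must be a positive number", "sg_invalid_config")
  }
  if (!per_chromosome) return(cutoff)
  sg_assert(inherits(geno, "sg_geno"),
            "per-chromosome cutoffs need a genotype panel")
  n <- nrow(geno$dosage)
  chroms <- unique(geno$map$chrom)
  out <- vapply(chroms, function(ch) {
    idx <- which(geno$map$chrom == ch)
    idx <- idx[order(geno$map$pos[idx])]
    m <- length(idx)
    if (m < 2L) return(1)
    X <- geno$dosage[, idx, drop = FALSE]
    storage.mode(X) <- "double"
    r2s <- numeric(0)
    for (j in seq_len(m - 1L)) {
      ks <- (j + 1L):min(m, j + window)
      r <- suppressWarnings(stats::cor(X[, j], X[, ks, drop = FALSE]))
      r2s <- c(r2s, as.numeric(r)^2)
    }
    r2bar <- mean(r2s, na.rm = TRUE)
    excess <- max(0, r2bar - 1 / (n - 1))
    m_eff <- m / (1 + (m - 1) * excess)
    1 / m_eff
  }, 0)
  names(out) <- chroms
  out
}

#' Group significant SNPs into QTL intervals
#'
#' Single-linkage chaining per chromosome: significant SNPs whose
#' consecutive (position-sorted) gaps are at most `gap` form one QTL;
#' singleton significant SNPs form width-zero intervals. The result is
#' invariant to input order and idempotent.
#'
#' @param assoc An `sg_assoc`.
#' @param cutoff Significance cutoff on `p`.
#' @param gap Maximum inter-marker distance within a QTL, bp (default 5 Mb).
#' @return Object of class `sg_qtl`: data frame
#'   `chrom, start, end, n_snps, peak_snp, peak_p, r2` (peak single-SNP
#'   `r2` within the interval); zero rows when nothing is significant.
#' @export
group_qtl <- function(assoc, cutoff = 2.60e-4, gap = 5e6) {
  sg_assert(inherits(assoc, "sg_assoc") || is.data.frame(assoc),
            "assoc must be an sg_assoc")
  sig <- assoc[is.finite(assoc$p) & assoc$p <= cutoff, , drop = FALSE]
  rows <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) > gap))
    for (g_i in unique(grp)) {
      b <- s[grp == g_i, , drop = FALSE]
      peak <- which.min(b$p)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = min(b$pos), end = max(b$pos),
        n_snps = nrow(b), peak_snp = b$snp[peak], peak_p = b$p[peak],
        r2 = max(b$r2), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_snps = integer(), peak_snp = character(),
               peak_p = numeric(), r2 = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sg_qtl", "data.frame")
  out
}

#' Candidate-gene-interval association scan
#'
#' Runs the mixed-model scan restricted to the SNPs inside a genomic
#' interval (a candidate gene and its flanks), with the same kinship and
#' threshold machinery as the genome-wide scan.
#'
#' @param y Phenotype vector as in [mlm_scan()].
#' @param geno An `sg_geno`.
#' @param K Kinship matrix of the full panel.
#' @param interval List or vector with `chrom`, `start`, `end` (bp).
#' @param ... Passed to [mlm_scan()].
#' @return An `sg_assoc` restricted to the interval.
#' @export
candidate_gene_scan <- function(y, geno, K = NULL, interval, ...) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  chrom <- as.character(interval[["chrom"]])
  start <- as.numeric(interval[["start"]])
  end <- as.numeric(interval[["end"]])
  idx <- which(geno$map$chrom == chrom & geno$map$pos >= start &
                 geno$map$pos <= end)
  if (!length(idx)) {
    sg_stop("no SNPs inside the candidate interval", "sg_no_snps")
  }
  if (is.null(K)) K <- kinship(geno)
  mlm_scan(y, geno_subset(geno, snp = idx), K = K, ...)
}
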