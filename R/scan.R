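#' Thin SNPs to one per genomic window
#'
#' Within each non-overlapping `window_bp` window (anchored at position 1),
#' keeps the SNP with the lowest missing rate; ties break to the lowest
#' position. The thinned set feeds the kinship estimate.
#'
#' @param x a `VariantTable`
#' @param window_bp window size in bp
#' @return character vector of kept snp_ids
#' @export
thin_snps_by_window <- function(x, window_bp = 10000) {
  stopifnot(inherits(x, "VariantTable"))
  miss <- snp_missing(x)
  df <- data.frame(id = x$snps$snp_id, chrom = x$snps$chrom,
                   pos = x$snps$pos, miss = miss,
                   win = (x$snps$pos - 1L) %/% as.integer(window_bp),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$win, df$miss, df$pos), ]
  df$id[!duplicated(df[c("chrom", "win")])]
}

#' Identity-by-state kinship matrix
#'
#' K[i, j] is the mean over SNPs non-missing in both samples of
#' 1 - |g_i - g_j| / 2: identical homozygotes contribute 1, opposite
#' homozygotes 0, a hom/het pair 1/2. Typically computed on a
#' window-thinned SNP subset (see [thin_snps_by_window()]).
#'
#' @param x a `VariantTable`
#' @param snps optional snp_id subset
#' @return n x n symmetric matrix with sample ids as dimnames
#' @export
kinship_ibs <- function(x, snps = NULL) {
  stopifnot(inherits(x, "VariantTable"))
  if (!is.null(snps)) x <- subset_variants(x, snps = snps)
  g <- x$calls
  n <- nrow(g)
  if (n < 2) stop("kinship needs at least 2 samples")
  G0 <- (!is.na(g) & g == 0L) * 1
  G1 <- (!is.na(g) & g == 1L) * 1
  G2 <- (!is.na(g) & g == 2L) * 1
  M <- G0 + G1 + G2                       # non-missing indicator
  shared <- tcrossprod(M)
  if (any(shared == 0))
    stop("some sample pair shares zero non-missing SNPs")
  # sum of |g_i - g_j|: codes differ by 1 for (0,1)/(1,2), by 2 for (0,2)
  d01 <- tcrossprod(G0, G1); d12 <- tcrossprod(G1, G2)
  d02 <- tcrossprod(G0, G2)
  dist <- (d01 + t(d01) + d12 + t(d12)) + 2 * (d02 + t(d02))
  K <- 1 - dist / (2 * shared)
  dimnames(K) <- list(x$sample_ids, x$sample_ids)
  K
}

#' Population-structure covariates from genotype principal components
#'
#' Top principal components of the centered, per-SNP mean-imputed dosage
#' matrix, with signs fixed as in [pca_transcriptomes()]. Fills the role a
#' model-based ancestry inference would play as fixed covariates in the
#' mixed model.
#'
#' @param x a `VariantTable`
#' @param n_pc number of components (0 gives a zero-column matrix,
#'   i.e. intercept-only covariates downstream)
#' @return n_samples x n_pc matrix
#' @export
structure_covariates <- function(x, n_pc = 3) {
  stopifnot(inherits(x, "VariantTable"))
  n <- n_samples(x)
  if (n_pc >= n) stop("n_pc must be smaller than the sample count")
  if (n_pc == 0)
    return(matrix(0, n, 0, dimnames = list(x$sample_ids, NULL)))
  d <- dosage_imputed(x)
  d <- d[, apply(d, 2, stats::var) > 0, drop = FALSE]
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  fx <- fix_signs(pc$rotation[, seq_len(n_pc), drop = FALSE],
                  pc$x[, seq_len(n_pc), drop = FALSE])
  rownames(fx$scores) <- x$sample_ids
  fx$scores
}

#' Hidden expression confounders
#'
#' Residualizes each gene's transformed expression on the structure
#' covariates (plus intercept), then takes the top `k` sample-space
#' principal components of the residual matrix. These PEER-style factors
#' enter the mixed model as fixed covariates; columns are zero-mean and
#' orthogonal.
#'
#' @param set an `ExpressionSet` with a transformed matrix, or a
#'   genes x samples matrix
#' @param k number of factors (0 returns a zero-column matrix)
#' @param covariates optional n x c structure-covariate matrix
#' @return n_samples x k factor score matrix
#' @export
hidden_factors <- function(set, k = 14, covariates = NULL) {
  m <- if (inherits(set, "ExpressionSet")) {
    if (is.null(set$transformed))
      stop("expression set has no transformed matrix")
    set$transformed
  } else as.matrix(set)
  x <- t(m)                               # samples x genes
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the sample count")
  if (k == 0) return(matrix(0, n, 0, dimnames = list(rownames(x), NULL)))
  W <- cbind(rep(1, n), covariates)
  x[is.na(x)] <- 0
  resid <- x - W %*% qr.coef(qr(W), x)
  pc <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  fx <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                  pc$x[, seq_len(k), drop = FALSE])
  rownames(fx$scores) <- rownames(x)
  fx$scores
}

# profiled REML log-likelihood (up to constants) at variance ratio delta,
# in the eigenbasis of K: values d, rotated response yt, design Wt
reml_ll <- function(delta, d, yt, Wt) {
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Ws <- Wt * sw
  ys <- yt * sw
  M <- crossprod(Ws)
  a <- tryCatch(solve(M, crossprod(Ws, ys)), error = function(e) NULL)
  if (is.null(a)) return(-Inf)
  rss <- sum((ys - Ws %*% a)^2)
  nq <- length(yt) - ncol(Wt)
  -0.5 * (nq * log(rss) + sum(log(d + delta)) +
            determinant(M, logarithm = TRUE)$modulus)
}

#' Fit the per-gene null mixed model (P3D variance components)
#'
#' Fits y = W alpha + u + e with cov(u) = sigma_g^2 K and
#' cov(e) = sigma_e^2 I by REML, profiling over the variance ratio
#' delta = sigma_e^2 / sigma_g^2 on a 101-point grid over
#' log10(delta) in \[-5, 5\] followed by local refinement. K is
#' eigendecomposed once; the fitted delta is reused for every SNP of this
#' gene (the P3D convention). A non-PSD kinship gets a 1e-6 ridge, noted in
#' the `"ridged"` attribute.
#'
#' @param y complete numeric response (samples with missing y dropped by
#'   the caller; K and covariates subset accordingly)
#' @param covariates optional n x c matrix of fixed covariates (structure
#'   PCs, hidden factors); an intercept is always added
#' @param K n x n kinship matrix; `NULL` means identity (pure OLS)
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)` to share
#'   across genes
#' @return list of class `p3d_fit`: `delta`, `sigma_g2`, `sigma_e2`, `U`,
#'   `d`, `yt`, `Wt`, `q`, `n`, `grid_ll`
#' @export
fit_null_p3d <- function(y, covariates = NULL, K = NULL, eig = NULL) {
  n <- length(y)
  if (anyNA(y)) stop("y must be complete (drop missing samples first)")
  W <- cbind(intercept = rep(1, n), covariates)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    warning("dropping ", ncol(W) - qrW$rank, " collinear covariate column(s)")
    W <- W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
  }
  ridged <- FALSE
  if (is.null(K)) {
    U <- NULL; d <- rep(1, n)
    yt <- y; Wt <- W
  } else {
    if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
    d <- eig$values
    if (min(d) < 1e-10) {
      d <- d + 1e-6 - min(0, min(d))
      ridged <- TRUE
    }
    U <- eig$vectors
    yt <- crossprod(U, y)[, 1]
    Wt <- crossprod(U, W)
  }
  grid <- 10^seq(-5, 5, length.out = 101)
  ll <- vapply(grid, reml_ll, numeric(1), d = d, yt = yt, Wt = Wt)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(ld) reml_ll(10^ld, d, yt, Wt),
                         lower = log10(lo), upper = log10(hi),
                         maximum = TRUE)
  delta <- 10^opt$maximum
  if (opt$objective < ll[i]) delta <- grid[i]
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  Ws <- Wt * sw; ys <- yt * sw
  a <- solve(crossprod(Ws), crossprod(Ws, ys))
  rss <- sum((ys - Ws %*% a)^2)
  sigma_g2 <- rss / (n - ncol(Wt))
  structure(list(delta = delta, sigma_g2 = sigma_g2,
                 sigma_e2 = delta * sigma_g2, U = U, d = d, yt = yt,
                 Wt = Wt, q = ncol(Wt), n = n, grid_ll = ll,
                 grid = grid, ridged = ridged),
            class = "p3d_fit")
}

#' @export
print.p3d_fit <- function(x, ...) {
  cat(sprintf(
    "P3D null fit: n = %d, q = %d, delta = %.4g (sigma_g2 = %.4g, sigma_e2 = %.4g)\n",
    x$n, x$q, x$delta, x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' Scan one gene's expression against a SNP matrix
#'
#' Generalized-least-squares single-SNP tests in the rotated system of a
#' fitted [fit_null_p3d()] model, reusing its variance ratio for every SNP
#' (P3D). Missing dosages must already be mean-imputed per SNP
#' ([dosage_imputed()]). Each SNP gets a Wald t-test with
#' df = n - q - 1 (q the fixed-effect rank including the intercept) and a
#' partial determination coefficient t^2 / (t^2 + df). Monomorphic SNPs
#' (zero post-imputation variance) are skipped.
#'
#' @param fit a `p3d_fit`
#' @param G numeric n x p dosage matrix (columns named by snp_id)
#' @return data.frame: `snp_id`, `beta`, `se`, `p`, `partial_r2`
#' @export
scan_gene <- function(fit, G) {
  stopifnot(inherits(fit, "p3d_fit"))
  G <- as.matrix(G)
  if (nrow(G) != fit$n) stop("dosage rows do not match the fitted samples")
  keep <- which(matrixStats_colVars(G) > 1e-12)
  out <- data.frame(snp_id = colnames(G),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    partial_r2 = NA_real_, stringsAsFactors = FALSE)
  if (!length(keep)) return(out[0, ])
  Gt <- if (is.null(fit$U)) G[, keep, drop = FALSE]
    else crossprod(fit$U, G[, keep, drop = FALSE])
  sw <- sqrt(1 / (fit$d + fit$delta))
  ys <- fit$yt * sw
  Ws <- fit$Wt * sw
  Gs <- Gt * sw
  qrW <- qr(Ws)
  Q <- qr.Q(qrW)
  yr <- ys - Q %*% crossprod(Q, ys)
  Gr <- Gs - Q %*% crossprod(Q, Gs)
  gg <- colSums(Gr^2)
  ok <- gg > 1e-12
  gy <- crossprod(Gr, yr)[, 1]
  beta <- ifelse(ok, gy / gg, NA_real_)
  yy <- sum(yr^2)
  df <- fit$n - fit$q - 1
  rss <- pmax(yy - beta^2 * gg, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  out$beta[keep] <- beta
  out$se[keep] <- se
  out$p[keep] <- pmin(pmax(p, .Machine$double.xmin), 1)
  out$partial_r2[keep] <- tstat^2 / (tstat^2 + df)
  out[keep[ok], , drop = FALSE]
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Benjamini-Hochberg rejection threshold
#'
#' Step-up BH over a pooled p-value vector: the cutoff is the largest
#' p_(k) with p_(k) <= k * fdr / m; every p at or below the cutoff is
#' rejected. With zero rejections the cutoff is 0 (nothing passes).
#'
#' @param p p-values pooled over all tests of one condition
#' @param fdr target false-discovery rate
#' @param condition optional condition label carried through
#' @return list of class `ScanThreshold`: `condition`, `cutoff`,
#'   `n_tests`, `n_rejected`
#' @export
bh_threshold <- function(p, fdr = 0.05, condition = NA_character_) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("empty p-value vector")
  m <- length(p)
  ps <- sort(p)
  k <- which(ps <= seq_len(m) * fdr / m)
  cutoff <- if (length(k)) ps[max(k)] else 0
  structure(list(condition = condition, cutoff = cutoff, n_tests = m,
                 n_rejected = if (length(k)) max(k) else 0L),
            class = "ScanThreshold")
}

#' @export
print.ScanThreshold <- function(x, ...) {
  cat(sprintf("BH threshold [%s]: p <= %.3g (%d of %d tests rejected)\n",
              x$condition, x$cutoff, x$n_rejected, x$n_tests))
  invisible(x)
}

#' Genome-wide eQTL association scan for one condition
#'
#' Drives [fit_null_p3d()] and [scan_gene()] over every gene of a
#' transformed expression set: mixed linear model with IBS kinship,
#' structure covariates and hidden factors, P3D variance components per
#' gene, per-SNP mean imputation, and a pooled within-condition BH
#' threshold. Samples are matched between expression and genotypes by id;
#' genes with missing expression drop those samples (and re-fit on the
#' subset).
#'
#' @param genotypes a QC'd `VariantTable`
#' @param expr an `ExpressionSet` carrying a transformed matrix
#' @param covariates optional structure-covariate matrix (rows = genotype
#'   samples); see [structure_covariates()]
#' @param factors optional hidden-factor matrix; see [hidden_factors()]
#' @param kinship n x n kinship (`NULL` for none / identity)
#' @param fdr BH target for the condition threshold
#' @param genes optional subset of genes to scan
#' @return list of class `eqtl_scan`: `records` (gene_id, snp_id, chrom,
#'   pos, condition, beta, se, p, partial_r2), `threshold` (a
#'   `ScanThreshold`), `condition`
#' @export
eqtl_scan <- function(genotypes, expr, covariates = NULL, factors = NULL,
                      kinship = NULL, fdr = 0.05, genes = NULL) {
  stopifnot(inherits(genotypes, "VariantTable"),
            inherits(expr, "ExpressionSet"))
  if (is.null(expr$transformed))
    stop("expression set has no transformed matrix; run quantile_normalize",
         " + inverse_normal_transform first")
  x <- expr$transformed
  samples <- intersect(genotypes$sample_ids, colnames(x))
  if (!length(samples)) stop("no shared samples between genotypes and expression")
  vt <- subset_variants(genotypes, samples = samples)
  x <- x[, samples, drop = FALSE]
  if (!is.null(covariates)) covariates <-
      covariates[samples, , drop = FALSE]
  if (!is.null(factors)) factors <- factors[samples, , drop = FALSE]
  if (!is.null(kinship)) kinship <- kinship[samples, samples]
  W <- cbind(covariates, factors)
  if (!is.null(W) && ncol(W) == 0) W <- NULL
  G <- dosage_imputed(vt)
  eig <- if (!is.null(kinship)) eigen(kinship, symmetric = TRUE) else NULL
  Gt_full <- if (!is.null(eig)) crossprod(eig$vectors, G) else G
  if (is.null(genes)) genes <- rownames(x)
  recs <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    y <- x[genes[gi], ]
    ok <- !is.na(y)
    if (sum(ok) < 10) next
    if (all(ok)) {
      fit <- fit_null_p3d(y, covariates = W, K = kinship, eig = eig)
      # reuse the shared rotation: scan in the eigenbasis directly
      sc <- scan_gene_rotated(fit, Gt_full, colnames(G))
    } else {
      Ksub <- if (!is.null(kinship)) kinship[ok, ok] else NULL
      Wsub <- if (!is.null(W)) W[ok, , drop = FALSE] else NULL
      fit <- fit_null_p3d(y[ok], covariates = Wsub, K = Ksub)
      sc <- scan_gene(fit, G[ok, , drop = FALSE])
    }
    if (!nrow(sc)) next
    sc$gene_id <- genes[gi]
    recs[[gi]] <- sc
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    stop("no testable gene/SNP combination")
  idx <- match(records$snp_id, vt$snps$snp_id)
  records$chrom <- vt$snps$chrom[idx]
  records$pos <- vt$snps$pos[idx]
  records$condition <- expr$condition
  records <- records[, c("gene_id", "snp_id", "chrom", "pos", "condition",
                         "beta", "se", "p", "partial_r2")]
  rownames(records) <- NULL
  thr <- bh_threshold(records$p, fdr = fdr, condition = expr$condition)
  structure(list(records = records, threshold = thr,
                 condition = expr$condition), class = "eqtl_scan")
}

# scan_gene when G has already been rotated into the eigenbasis shared
# with the fit (complete-expression fast path)
scan_gene_rotated <- function(fit, Gt, snp_ids) {
  sw <- sqrt(1 / (fit$d + fit$delta))
  ys <- fit$yt * sw
  Ws <- fit$Wt * sw
  Gs <- Gt * sw
  keep <- which(matrixStats_colVars(Gt) > 1e-12)
  if (!length(keep))
    return(data.frame(snp_id = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0),
                      partial_r2 = numeric(0)))
  Gs <- Gs[, keep, drop = FALSE]
  qrW <- qr(Ws)
  Q <- qr.Q(qrW)
  yr <- ys - Q %*% crossprod(Q, ys)
  Gr <- Gs - Q %*% crossprod(Q, Gs)
  gg <- colSums(Gr^2)
  ok <- gg > 1e-12
  gy <- crossprod(Gr, yr)[, 1]
  beta <- gy / gg
  df <- fit$n - fit$q - 1
  rss <- pmax(sum(yr^2) - beta^2 * gg, 0)
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  p <- pmin(pmax(2 * stats::pt(-abs(tstat), df), .Machine$double.xmin), 1)
  data.frame(snp_id = snp_ids[keep][ok], beta = beta[ok], se = se[ok],
             p = p[ok], partial_r2 = (tstat^2 / (tstat^2 + df))[ok],
             stringsAsFactors = FALSE)
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eQTL scan [", x$condition, "]: ", nrow(x$records),
      " gene-SNP tests over ", length(unique(x$records$gene_id)),
      " genes\n", sep = "")
  print(x$threshold)
  invisible(x)
}
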