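#' Candidate-region variant association
#'
#' Per-variant mixed-model association of a candidate region's variants
#' (SNPs and bi-allelically coded InDels alike) with one gene's
#' transformed expression, reusing the genome-wide scan machinery
#' ([fit_null_p3d()] + [scan_gene()]) so region statistics stay consistent
#' with genome-wide conventions. Monomorphic variants are skipped.
#'
#' @param variants a `VariantTable` restricted to the region
#' @param expr named numeric: transformed expression per sample
#' @param covariates optional fixed-covariate matrix (rows = samples)
#' @param kinship optional kinship matrix (`NULL` fits OLS)
#' @return data.frame: `snp_id`, `chrom`, `pos`, `beta`, `se`, `p`,
#'   `partial_r2`
#' @export
region_association <- function(variants, expr, covariates = NULL,
                               kinship = NULL) {
  stopifnot(inherits(variants, "VariantTable"))
  samples <- intersect(variants$sample_ids, names(expr))
  if (!length(samples)) stop("no shared samples")
  y <- as.numeric(expr[samples])
  ok <- !is.na(y)
  samples <- samples[ok]; y <- y[ok]
  if (stats::var(y) == 0) stop("expression vector has zero variance")
  vt <- subset_variants(variants, samples = samples)
  W <- if (!is.null(covariates)) covariates[samples, , drop = FALSE] else NULL
  K <- if (!is.null(kinship)) kinship[samples, samples] else NULL
  fit <- fit_null_p3d(y, covariates = W, K = K)
  sc <- scan_gene(fit, dosage_imputed(vt))
  idx <- match(sc$snp_id, vt$snps$snp_id)
  sc$chrom <- vt$snps$chrom[idx]
  sc$pos <- vt$snps$pos[idx]
  sc[, c("snp_id", "chrom", "pos", "beta", "se", "p", "partial_r2")]
}

#' Group samples into haplotypes over significant variants
#'
#' Samples are grouped by their exact allele string across the significant
#' variants (p below `p_cut`); samples missing any of those calls are
#' excluded. Groups with more than `min_count` members are kept, ordered
#' by size. When an expression vector is supplied each group gets its
#' mean and SD.
#'
#' @param variants a `VariantTable`
#' @param pvals named per-variant p-values (names = snp_id), e.g. from
#'   [region_association()]
#' @param p_cut significance cutoff selecting the defining variants
#' @param min_count groups must exceed this member count
#' @param expr optional named expression vector for group summaries
#' @return data.frame of class `HaplotypeGroup`: `haplotype_id`,
#'   `allele_string`, `n_members`, `members` (comma-joined),
#'   `expr_mean`, `expr_sd`
#' @export
define_haplotypes <- function(variants, pvals, p_cut = 1e-6,
                              min_count = 5, expr = NULL) {
  sig <- names(pvals)[!is.na(pvals) & pvals < p_cut]
  if (!length(sig))
    return(structure(data.frame(haplotype_id = character(0),
                                allele_string = character(0),
                                n_members = integer(0),
                                members = character(0),
                                expr_mean = numeric(0),
                                expr_sd = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("HaplotypeGroup", "data.frame")))
  g <- variants$calls[, match(sig, variants$snps$snp_id), drop = FALSE]
  complete <- !apply(is.na(g), 1, any)
  g <- g[complete, , drop = FALSE]
  strings <- apply(g, 1, paste, collapse = "")
  groups <- split(rownames(g), strings)
  sizes <- vapply(groups, length, 0L)
  keep <- sizes > min_count
  groups <- groups[keep][order(sizes[keep], decreasing = TRUE)]
  out <- data.frame(
    haplotype_id = if (length(groups)) paste0("H", seq_along(groups))
      else character(0),
    allele_string = names(groups),
    n_members = vapply(groups, length, 0L),
    members = vapply(groups, paste, "", collapse = ","),
    expr_mean = NA_real_, expr_sd = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(expr) && nrow(out)) {
    out$expr_mean <- vapply(groups, function(m)
      mean(expr[m], na.rm = TRUE), numeric(1))
    out$expr_sd <- vapply(groups, function(m)
      stats::sd(expr[m], na.rm = TRUE), numeric(1))
  }
  rownames(out) <- NULL
  class(out) <- c("HaplotypeGroup", "data.frame")
  out
}

#' Pairwise LD matrices (r-squared and D')
#'
#' r-squared is the squared dosage correlation over samples non-missing in
#' both variants. D' uses the inbred-panel shortcut: homozygous samples
#' are treated as gametes (heterozygotes excluded pairwise), haplotype
#' frequencies are counted directly, and D is normalized by its
#' frequency-bound maximum. Monomorphic pairs are `NA`.
#'
#' @param variants a `VariantTable`
#' @return list: `r2` and `dprime` symmetric matrices (snp_id dimnames)
#' @export
pairwise_ld <- function(variants) {
  g <- variants$calls
  p <- ncol(g)
  if (p < 2) stop("need at least 2 variants")
  ids <- variants$snps$snp_id
  gd <- g; storage.mode(gd) <- "double"
  r <- suppressWarnings(stats::cor(gd, use = "pairwise.complete.obs"))
  r2 <- r^2
  dimnames(r2) <- list(ids, ids)
  diag(r2) <- ifelse(apply(gd, 2, function(v)
    stats::var(v, na.rm = TRUE) > 0), 1, NA_real_)
  dp <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  hom <- g == 0L | g == 2L
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- which(hom[, i] & hom[, j])
    if (length(ok) < 2) next
    a <- g[ok, i] / 2; b <- g[ok, j] / 2
    pa <- mean(a); pb <- mean(b)
    if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
    D <- mean(a * b) - pa * pb
    dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
      else min(pa * pb, (1 - pa) * (1 - pb))
    dp[i, j] <- dp[j, i] <- if (dmax > 0) abs(D) / dmax else NA_real_
  }
  diag(dp) <- diag(r2)
  list(r2 = r2, dprime = dp)
}

#' Genome-wide LD-decay distance
#'
#' Computes pairwise r-squared for variant pairs within `max_dist` on the
#' same chromosome, averages it in `bin_bp` distance bins, enforces
#' monotone decay with an isotonic (non-increasing) fit, and reports the
#' first bin midpoint at which the smoothed mean drops below `r2_target`.
#' If the curve never crosses the target the estimate is censored at
#' `max_dist`.
#'
#' @param variants a `VariantTable`
#' @param r2_target decay threshold (the conventional r-squared < 0.2)
#' @param max_dist maximum pair distance considered, bp
#' @param bin_bp distance bin width, bp
#' @return list of class `ld_decay`: `distance` (bp; `Inf` when censored),
#'   `censored`, `bins` (data.frame: mid, mean_r2, smoothed, n_pairs)
#' @export
ld_decay <- function(variants, r2_target = 0.2, max_dist = 100000,
                     bin_bp = 100) {
  g <- dosage_imputed(variants)
  keep <- which(matrixStats_colVars(g) > 0)
  g <- g[, keep, drop = FALSE]
  pos <- variants$snps$pos[keep]
  chrom <- variants$snps$chrom[keep]
  cmat <- stats::cor(g)^2
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  same <- chrom[idx[, 1]] == chrom[idx[, 2]]
  d <- abs(pos[idx[, 1]] - pos[idx[, 2]])
  use <- same & d <= max_dist & d > 0
  d <- d[use]
  r2 <- cmat[idx[use, , drop = FALSE]]
  if (!length(d)) stop("no variant pairs within max_dist")
  bin <- (d - 1) %/% bin_bp
  mean_r2 <- tapply(r2, bin, mean)
  n_pairs <- tapply(r2, bin, length)
  mids <- (as.numeric(names(mean_r2)) + 0.5) * bin_bp
  ord <- order(mids)
  mids <- mids[ord]; mean_r2 <- as.numeric(mean_r2)[ord]
  n_pairs <- as.numeric(n_pairs)[ord]
  smoothed <- if (length(mids) > 1)
    -stats::isoreg(mids, -mean_r2)$yf else mean_r2
  cross <- which(smoothed < r2_target)
  censored <- !length(cross)
  structure(list(distance = if (censored) Inf else mids[cross[1]],
                 censored = censored,
                 bins = data.frame(mid = mids, mean_r2 = mean_r2,
                                   smoothed = smoothed,
                                   n_pairs = n_pairs)),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  if (x$censored)
    cat("LD decay: r2 never crosses the target within the window\n")
  else
    cat(sprintf("LD decay distance: %.0f bp (%d distance bins)\n",
                x$distance, nrow(x$bins)))
  invisible(x)
}
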