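#' Quantile-normalize samples of an expression set
#'
#' Equalizes the value distribution across samples: after normalization
#' every sample's sorted values equal the across-sample mean order
#' statistics (ties within a sample receive the mean of the reference
#' values they span). Delegates to `limma::normalizeQuantiles`.
#'
#' @param set an `ExpressionSet` (or a genes x samples matrix)
#' @return the input with its abundance matrix normalized
#' @export
quantile_normalize <- function(set) {
  m <- if (inherits(set, "ExpressionSet")) set$abundance else as.matrix(set)
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(set)
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (inherits(set, "ExpressionSet")) {
    set$abundance <- qn
    set
  } else qn
}

#' Rank-based inverse normal transform, per gene
#'
#' Each gene's values are mapped to normal quantiles of their (average-tie)
#' ranks: value_i -> qnorm((rank_i - a) / (n + 1 - 2a)) with the Blom-type
#' offset a = 3/8 for n <= 10 and a = 1/2 for n > 10 (the `qqnorm`
#' convention). Missing values stay missing and are excluded from n.
#' Constant genes transform to all zeros and are flagged in the
#' `"constant_genes"` attribute of the transformed matrix.
#'
#' @param set an `ExpressionSet` (transform stored in `$transformed`) or a
#'   genes x samples matrix (transformed matrix returned)
#' @return same class as the input
#' @export
inverse_normal_transform <- function(set) {
  m <- if (inherits(set, "ExpressionSet")) set$abundance else as.matrix(set)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  constant <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    ok <- !is.na(v)
    n <- sum(ok)
    if (n == 0) next
    if (length(unique(v[ok])) < 2) {
      out[i, ok] <- 0
      constant[i] <- TRUE
      next
    }
    a <- if (n > 10) 0.5 else 3 / 8
    r <- rank(v[ok], ties.method = "average")
    out[i, ok] <- stats::qnorm((r - a) / (n + 1 - 2 * a))
  }
  if (any(constant))
    attr(out, "constant_genes") <- rownames(m)[constant]
  if (inherits(set, "ExpressionSet")) {
    set$transformed <- out
    set
  } else out
}

#' Expressed-gene filter
#'
#' Keeps genes whose (untransformed) abundance exceeds `min_value` in at
#' least `ceil(min_fraction * n_samples)` samples. The comparison is strict
#' (`> min_value`) by default; set `inclusive = TRUE` for `>=`.
#'
#' @param set an `ExpressionSet` or genes x samples matrix
#' @param min_value abundance threshold (FPKM-like scale)
#' @param min_fraction minimum fraction of samples above threshold
#' @param inclusive use `>=` instead of `>` for the value comparison
#' @return character vector of surviving gene ids
#' @export
expression_filter <- function(set, min_value = 0.05, min_fraction = 0.2,
                              inclusive = FALSE) {
  m <- if (inherits(set, "ExpressionSet")) set$abundance else as.matrix(set)
  need <- ceiling(min_fraction * ncol(m))
  hits <- if (inclusive) rowSums(m >= min_value, na.rm = TRUE)
    else rowSums(m > min_value, na.rm = TRUE)
  rownames(m)[hits >= need]
}

#' Call differentially expressed genes between condition pairs
#'
#' For every pair of conditions and every gene, computes (over accessions
#' present in both conditions) the fraction whose absolute log2 fold change
#' (with pseudo-count `eps`) exceeds `lfc_min`, and a paired Wilcoxon
#' signed-rank p-value, BH-adjusted across genes within the pair. A gene is
#' a DEG when, in at least one pair, the changed fraction is `>=
#' min_fraction` and the FDR is below `fdr`.
#'
#' @param sets named list of `ExpressionSet`s (raw abundance), one per
#'   condition, with accession ids as column names
#' @param lfc_min absolute log2 fold-change threshold per accession
#' @param min_fraction minimum fraction of accessions changed
#' @param fdr BH false-discovery-rate threshold
#' @param eps pseudo-count added before the ratio
#' @return data.frame with one row per gene x condition pair
#'   (`gene_id`, `condition_pair`, `fraction_changed`, `p`, `fdr`,
#'   `is_deg`), plus a `"deg_genes"` attribute listing genes significant in
#'   any pair
#' @export
call_degs <- function(sets, lfc_min = 1.0, min_fraction = 0.2, fdr = 0.05,
                      eps = 0.01) {
  stopifnot(length(sets) >= 2)
  conds <- names(sets)
  res <- list()
  for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
    a <- sets[[i]]$abundance; b <- sets[[j]]$abundance
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) < 6)
      stop("fewer than 6 paired accessions between ", conds[i], " and ",
           conds[j])
    genes <- intersect(rownames(a), rownames(b))
    a <- a[genes, shared, drop = FALSE]; b <- b[genes, shared, drop = FALSE]
    lfc <- log2((a + eps) / (b + eps))
    frac <- rowMeans(abs(lfc) > lfc_min, na.rm = TRUE)
    pv <- vapply(seq_along(genes), function(g) {
      d <- lfc[g, ]
      d <- d[is.finite(d)]
      if (length(d) < 6 || all(d == 0)) return(1)
      stats::wilcox.test(d, exact = FALSE)$p.value
    }, numeric(1))
    q <- stats::p.adjust(pv, method = "BH")
    res[[paste(conds[i], conds[j], sep = "_vs_")]] <- data.frame(
      gene_id = genes,
      condition_pair = paste(conds[i], conds[j], sep = "_vs_"),
      fraction_changed = frac, p = pv, fdr = q,
      is_deg = frac >= min_fraction & q < fdr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "deg_genes") <-
    sort(unique(out$gene_id[out$is_deg]))
  out
}

#' Z-scored condition-mean profiles for clustering
#'
#' Builds the genes x conditions matrix of per-condition mean abundance,
#' z-scored within each gene, as expected by [kmeans_profiles()].
#'
#' @param sets named list of `ExpressionSet`s
#' @param genes genes to include (default: common to all sets)
#' @return genes x conditions numeric matrix
#' @export
condition_profiles <- function(sets, genes = NULL) {
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(sets, function(s) rownames(s$abundance)))
  prof <- vapply(sets, function(s)
    rowMeans(s$abundance[genes, , drop = FALSE], na.rm = TRUE),
    numeric(length(genes)))
  prof <- t(scale(t(prof)))
  prof[is.na(prof)] <- 0               # constant profiles
  rownames(prof) <- genes
  prof
}

#' Cluster expression-response profiles by k-means
#'
#' Runs k-means (25 restarts, Euclidean) on per-gene profiles and relabels
#' the clusters canonically by descending centroid slope over the
#' condition gradient, so cluster 1 is the most induced profile, cluster k
#' the most repressed, and (for k = 3) the middle cluster holds variable /
#' flat profiles. Output is deterministic given `seed`.
#'
#' @param profiles genes x conditions matrix (see [condition_profiles()])
#' @param k number of clusters
#' @param seed RNG seed for the restarts
#' @return list of class `ClusterAssignment`: `cluster` (named integer),
#'   `centroids` (k x conditions), `sizes`
#' @export
kmeans_profiles <- function(profiles, k = 3, seed = 1) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of genes")
  set.seed(seed)
  if (k == 1) {
    ctr <- matrix(colMeans(profiles), 1)
    colnames(ctr) <- colnames(profiles)
    return(structure(list(
      cluster = stats::setNames(rep(1L, nrow(profiles)), rownames(profiles)),
      centroids = ctr, sizes = nrow(profiles)), class = "ClusterAssignment"))
  }
  km <- stats::kmeans(profiles, centers = k, nstart = 25, iter.max = 100)
  grad <- seq_len(ncol(profiles))
  slope <- apply(km$centers, 1, function(ctr)
    stats::cov(ctr, grad) / stats::var(grad))
  ord <- order(slope, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cl <- relabel[km$cluster]
  names(cl) <- rownames(profiles)
  structure(list(cluster = cl,
                 centroids = km$centers[ord, , drop = FALSE],
                 sizes = as.integer(table(factor(cl, levels = seq_len(k))))),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment:", length(x$cluster), "genes in",
      nrow(x$centroids), "clusters; sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of transcriptomes across conditions
#'
#' Stacks the samples of all conditions (columns suffixed by condition),
#' standardizes each gene to unit variance, and runs `prcomp`. Constant
#' genes are dropped with a warning; component signs are fixed by making
#' each loading vector's largest-magnitude element positive.
#'
#' @param sets named list of `ExpressionSet`s
#' @param genes genes to use (default: common to all sets)
#' @param n_pc components to return
#' @return list: `scores` (samples x PCs, with `condition` attribute),
#'   `var_explained`, `loadings`
#' @export
pca_transcriptomes <- function(sets, genes = NULL, n_pc = 10) {
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(sets, function(s) rownames(s$abundance)))
  blocks <- lapply(names(sets), function(cond) {
    m <- t(sets[[cond]]$abundance[genes, , drop = FALSE])
    rownames(m) <- paste(rownames(m), cond, sep = ".")
    m
  })
  x <- do.call(rbind, blocks)
  condition <- rep(names(sets), vapply(blocks, nrow, 0L))
  const <- apply(x, 2, stats::var, na.rm = TRUE) < .Machine$double.eps
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene column(s) before PCA")
    x <- x[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  n_pc <- min(n_pc, ncol(pc$x))
  fx <- fix_signs(pc$rotation[, seq_len(n_pc), drop = FALSE],
                  pc$x[, seq_len(n_pc), drop = FALSE])
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- fx$scores
  attr(scores, "condition") <- condition
  list(scores = scores, var_explained = ve[seq_len(n_pc)],
       loadings = fx$rotation)
}

#' FPKM from raw counts
#'
#' counts x 1e9 / (gene length x library total). Provided as a helper; the
#' pipeline's canonical input is an abundance matrix.
#'
#' @param counts genes x samples integer matrix
#' @param lengths_bp per-gene exonic length in bp
#' @return genes x samples FPKM matrix
#' @export
fpkm <- function(counts, lengths_bp) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths_bp) == nrow(counts))
  totals <- colSums(counts)
  sweep(counts * 1e9 / lengths_bp, 2, totals, "/")
}
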