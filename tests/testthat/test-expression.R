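mk_set <- function(m, condition = "WW") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_set(condition, m)
}

test_that("quantile normalization maps samples onto mean order statistics", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  out <- quantile_normalize(mk_set(m))$abundance
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))
  # already-identical samples unchanged
  m2 <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(unname(quantile_normalize(mk_set(m2))$abundance),
               unname(m2))
  # column means equal after transform
  set.seed(2)
  m3 <- matrix(rexp(50 * 8), 50, 8)
  out3 <- quantile_normalize(mk_set(m3))$abundance
  expect_lt(diff(range(colMeans(out3))), 1e-10)
})

test_that("single-sample quantile normalization warns and is identity", {
  m <- matrix(1:3, 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_warning(out <- quantile_normalize(mk_set(m)), "single sample")
  expect_equal(out$abundance, m)
})

test_that("inverse normal transform follows the qqnorm offset convention", {
  # n = 3 distinct values, a = 3/8: ranks map to (r - 3/8) / 3.25
  m <- matrix(c(5, 1, 9), 1, 3,
              dimnames = list("g1", c("s1", "s2", "s3")))
  out <- inverse_normal_transform(mk_set(m))$transformed
  expect_equal(unname(out[1, ]),
               qnorm((c(2, 1, 3) - 3 / 8) / 3.25))
  expect_equal(unname(out[1, "s2"]), qnorm(0.625 / 3.25))
  expect_equal(unname(out[1, "s1"]), 0)
  # monotonicity and zero median for odd n, and for n > 10 the a = 1/2 rule
  set.seed(3)
  v <- matrix(rexp(21), 1, 21, dimnames = list("g", sprintf("s%d", 1:21)))
  tv <- inverse_normal_transform(mk_set(v))$transformed[1, ]
  expect_identical(order(tv), order(v[1, ]))
  expect_equal(unname(median(tv)), 0)
  expect_equal(unname(sort(tv)[1]), qnorm((1 - 0.5) / 21))
})

test_that("missing values stay missing and constant genes are flagged", {
  m <- rbind(g1 = c(1, NA, 3, 2), g2 = c(7, 7, 7, 7))
  colnames(m) <- sprintf("s%d", 1:4)
  out <- inverse_normal_transform(mk_set(m))$transformed
  expect_true(is.na(out["g1", "s2"]))
  expect_equal(unname(out["g2", ]), rep(0, 4))
  expect_identical(attr(out, "constant_genes"), "g2")
  # per-gene mean ~ 0 on complete rows
  expect_lt(abs(mean(out["g2", ])), 1e-8)
})

test_that("transform of a normalized set is rank-idempotent", {
  set.seed(8)
  m <- matrix(rexp(30 * 12), 30, 12)
  s <- mk_set(m)
  once <- inverse_normal_transform(quantile_normalize(s))$transformed
  again <- inverse_normal_transform(exp(once))   # monotone re-entry
  expect_equal(unname(again), unname(once), tolerance = 1e-12)
})

test_that("expression filter applies the fraction rule at its boundary", {
  n <- 200
  m <- rbind(low = c(rep(1, 38), rep(0.01, n - 38)),    # 19% above
             edge = c(rep(1, 40), rep(0.01, n - 40)),   # exactly 20%
             high = rep(1, n))
  colnames(m) <- sprintf("s%d", 1:n)
  keep <- expression_filter(mk_set(m), min_value = 0.05,
                            min_fraction = 0.2)
  expect_false("low" %in% keep)
  expect_true("edge" %in% keep)
  expect_true("high" %in% keep)
})

test_that("expression filter equals brute-force counting and is monotone", {
  set.seed(21)
  m <- matrix(rexp(30 * 25, rate = 10), 30, 25)
  keep <- expression_filter(mk_set(m))
  want <- rownames(mk_set(m)$abundance)[
    vapply(seq_len(30), function(i)
      sum(m[i, ] > 0.05) >= ceiling(0.2 * 25), logical(1))]
  expect_identical(keep, want)
  stricter <- expression_filter(mk_set(m), min_fraction = 0.4)
  expect_true(all(stricter %in% keep))
})

test_that("DEG calls respond to forced shifts and ignore identical genes", {
  set.seed(12)
  n <- 50
  base <- matrix(rexp(40 * n, 0.2), 40, n,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("acc%02d", 1:n)))
  doubled <- base
  doubled[1:5, ] <- base[1:5, ] * 4   # forced everywhere
  sets <- list(WW = mk_set(base, "WW"), WS1 = mk_set(doubled, "WS1"))
  out <- call_degs(sets)
  degs <- attr(out, "deg_genes")
  expect_true(all(sprintf("g%02d", 1:5) %in% degs))
  expect_false(any(sprintf("g%02d", 6:40) %in% degs))
})

test_that("DEG substitute has high recall and controlled FDR on truth", {
  set.seed(13)
  n_genes <- 400; n_acc <- 60; n_true <- 40
  ww <- matrix(rexp(n_genes * n_acc, 0.2), n_genes, n_acc,
               dimnames = list(sprintf("g%03d", 1:n_genes),
                               sprintf("a%02d", 1:n_acc)))
  ws <- ww * matrix(exp(rnorm(n_genes * n_acc, 0, 0.2)),
                    n_genes, n_acc)          # null jitter
  ws[1:n_true, ] <- ws[1:n_true, ] * 5      # true shifts
  out <- call_degs(list(WW = mk_set(ww, "WW"), WS1 = mk_set(ws, "WS1")))
  degs <- attr(out, "deg_genes")
  truth <- sprintf("g%03d", 1:n_true)
  recall <- mean(truth %in% degs)
  fdp <- if (length(degs)) mean(!(degs %in% truth)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdp, 0.1)
})

test_that("DEG caller demands at least 6 paired accessions", {
  m <- matrix(rexp(10 * 4), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("a%d", 1:4)))
  expect_error(call_degs(list(A = mk_set(m, "A"), B = mk_set(m, "B"))),
               "fewer than 6")
})

test_that("k-means recovers planted archetypes with canonical labels", {
  set.seed(4)
  up <- t(replicate(30, c(-1, 0, 1) + rnorm(3, 0, 0.05)))
  dn <- t(replicate(30, c(1, 0, -1) + rnorm(3, 0, 0.05)))
  var_ <- t(replicate(30, c(0, 1, 0) + rnorm(3, 0, 0.05)))
  prof <- rbind(up, dn, var_)
  rownames(prof) <- sprintf("g%02d", seq_len(nrow(prof)))
  truth <- rep(c("up", "down", "var"), each = 30)
  out <- kmeans_profiles(prof, k = 3, seed = 42)
  expect_equal(rand_index_adjusted(out$cluster, truth), 1)
  # canonical order: cluster 1 rising, cluster 3 falling
  expect_true(all(out$cluster[1:30] == 1))
  expect_true(all(out$cluster[31:60] == 3))
  expect_true(all(out$cluster[61:90] == 2))
  # determinism
  out2 <- kmeans_profiles(prof, k = 3, seed = 42)
  expect_identical(out$cluster, out2$cluster)
})

test_that("k = 1 yields the mean profile; k > n errors", {
  prof <- matrix(rnorm(12), 4, 3,
                 dimnames = list(letters[1:4], NULL))
  out <- kmeans_profiles(prof, k = 1, seed = 1)
  expect_equal(unname(out$centroids[1, ]), unname(colMeans(prof)))
  expect_error(kmeans_profiles(prof, k = 10, seed = 1), "exceeds")
})

test_that("PCA variance fraction matches the 2D closed form", {
  set.seed(6)
  rho <- 0.7
  n <- 20000
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  m <- rbind(gene1 = exp(x1), gene2 = exp(0.5 * x2))
  # work on the log scale via ranks: use values directly as abundance
  m <- rbind(gene1 = x1 - min(x1), gene2 = x2 - min(x2))
  colnames(m) <- sprintf("s%d", 1:n)
  out <- pca_transcriptomes(list(WW = mk_set(m, "WW")), n_pc = 2)
  rho_hat <- cor(m[1, ], m[2, ])
  expect_equal(out$var_explained[1], (1 + rho_hat) / 2, tolerance = 1e-10)
  # orthogonality of scores
  expect_lt(abs(cor(out$scores[, 1], out$scores[, 2])), 1e-10)
})

test_that("PCA drops constant genes with a warning", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = rep(2, 4), g3 = c(4, 2, 8, 1))
  colnames(m) <- sprintf("s%d", 1:4)
  expect_warning(out <- pca_transcriptomes(list(A = mk_set(m, "A")),
                                           n_pc = 2),
                 "constant")
  expect_identical(nrow(out$loadings), 2L)
})

test_that("PCA separates conditions along the stress gradient", {
  set.seed(9)
  cfg <- sim_config(n_samples = 80, n_snps = 300, n_genes = 40,
                    n_local_eqtl = 0, n_distant_eqtl = 0,
                    condition_shift_sd = 1, frac_responsive = 0.5,
                    seed = 404)
  sim <- simulate_drought_study(cfg)
  out <- pca_transcriptomes(sim$expression, n_pc = 3)
  cond <- attr(out$scores, "condition")
  cen <- vapply(c("WW", "WS1", "WS2"), function(cc)
    colMeans(out$scores[cond == cc, 1:2, drop = FALSE]), numeric(2))
  d_ws1 <- sqrt(sum((cen[, "WW"] - cen[, "WS1"])^2))
  d_ws2 <- sqrt(sum((cen[, "WW"] - cen[, "WS2"])^2))
  expect_gt(d_ws2, d_ws1)
})

test_that("fpkm helper normalizes by length and library size", {
  counts <- matrix(c(100, 200, 50, 100), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- fpkm(counts, lengths_bp = c(1000, 2000))
  expect_equal(out["g1", "s1"], 100 * 1e9 / (1000 * 300))
  expect_equal(out["g2", "s2"], 100 * 1e9 / (2000 * 150))
})
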