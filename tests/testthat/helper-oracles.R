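# Independent oracles and small fixture builders shared across tests.
# Oracles apply the rules directly (enumeration / brute force) and never
# call the implementation paths they check.

# random small variant table
random_variant_table <- function(n_samples = 8, n_snps = 12,
                                 miss_rate = 0.1, het_rate = 0.15,
                                 chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- sort(sample.int(1e5, n_snps))
  calls <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
                  n_samples, n_snps)
  calls[matrix(runif(n_samples * n_snps) < het_rate,
               n_samples, n_snps)] <- 1L
  calls[matrix(runif(n_samples * n_snps) < miss_rate,
               n_samples, n_snps)] <- NA_integer_
  rownames(calls) <- sprintf("S%02d", seq_len(n_samples))
  variant_table(
    data.frame(snp_id = sprintf("v%03d", seq_len(n_snps)),
               chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    calls)
}

# brute-force per-sample concordance by direct cell enumeration
oracle_concordance <- function(a, b) {
  samples <- intersect(a$sample_ids, b$sample_ids)
  snps <- intersect(a$snps$snp_id, b$snps$snp_id)
  per <- sapply(samples, function(s) {
    num <- den <- 0
    for (v in snps) {
      ga <- a$calls[s, v]; gb <- b$calls[s, v]
      if (!is.na(ga) && !is.na(gb)) {
        den <- den + 1
        if (ga == gb) num <- num + 1
      }
    }
    if (den == 0) NA_real_ else num / den
  })
  list(per_sample = per, mean = mean(per, na.rm = TRUE))
}

# step-up BH rejection set by direct enumeration over all cutoffs
oracle_bh_reject <- function(p, fdr = 0.05) {
  m <- length(p)
  ps <- sort(p)
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * fdr / m) kmax <- k
  if (kmax == 0) rep(FALSE, m) else p <= ps[kmax]
}

# brute-force eQTL consolidation: direct rule application with no data
# structures beyond plain loops. snps: data.frame(snp_id, chrom, pos, p,
# partial_r2); geno_calls: samples x snps matrix aligned to snp order.
oracle_consolidate <- function(snps, geno_calls, annotation,
                               gap_bp = 5000, r2_min = 0.1,
                               max_dist_bp = 250000) {
  n <- nrow(snps)
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  geno_calls <- geno_calls[, ord, drop = FALSE]
  cl <- seq_len(n)
  # step 1: chain by distance (< gap_bp, same chromosome)
  for (i in seq_len(max(0L, n - 1L))) {
    if (snps$chrom[i + 1] == snps$chrom[i] &&
        snps$pos[i + 1] - snps$pos[i] < gap_bp)
      cl[cl == cl[i + 1]] <- cl[i]
  }
  lead_of <- function(idx) {
    d <- snps[idx, , drop = FALSE]
    idx[order(d$p, -d$partial_r2, d$pos)][1]
  }
  r2_of <- function(i, j) {
    gi <- geno_calls[, i]; gj <- geno_calls[, j]
    ok <- !is.na(gi) & !is.na(gj)
    if (sum(ok) < 2 || var(gi[ok]) == 0 || var(gj[ok]) == 0) return(0)
    cor(gi[ok], gj[ok])^2
  }
  # step 2: merge transitively over the pairwise LD relation on the
  # distance-cluster leads (leads elected once, before merging)
  ids <- unique(cl)
  if (length(ids) > 1) {
    leads <- vapply(ids, function(id) lead_of(which(cl == id)), 0L)
    grp <- seq_along(ids)
    repeat {
      changed <- FALSE
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (a >= b || grp[a] == grp[b]) next
        la <- leads[a]; lb <- leads[b]
        if (snps$chrom[la] != snps$chrom[lb]) next
        if (abs(snps$pos[la] - snps$pos[lb]) > max_dist_bp) next
        if (r2_of(la, lb) > r2_min) {
          grp[grp == grp[b]] <- grp[a]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (a in seq_along(ids)) cl[cl == ids[a]] <- -grp[a]
  }
  # step 3: merge clusters whose (re-elected) leads share a host gene body
  ids <- unique(cl)
  if (length(ids) > 1) {
    leads <- vapply(ids, function(id) lead_of(which(cl == id)), 0L)
    host <- vapply(leads, function(l) {
      hit <- which(annotation$chrom == snps$chrom[l] &
                     annotation$start <= snps$pos[l] &
                     annotation$end >= snps$pos[l])
      if (length(hit)) annotation$gene_id[hit[1]] else NA_character_
    }, character(1))
    grp <- seq_along(ids)
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b || is.na(host[a]) || is.na(host[b])) next
      if (host[a] == host[b]) grp[grp == grp[b]] <- grp[a]
    }
    for (a in seq_along(ids)) cl[cl == ids[a]] <- -1000L - grp[a]
  }
  # report: sorted member snp_id sets with elected lead
  lapply(unique(cl), function(id) {
    idx <- which(cl == id)
    list(members = sort(snps$snp_id[idx]),
         lead = snps$snp_id[lead_of(idx)])
  })
}

# independent MR oracle: fit both stage regressions with lm() and plug
# the summary-statistic formulas in directly
oracle_mr <- function(z, x, y) {
  b_zx <- unname(coef(lm(x ~ z))[2])
  b_zy <- unname(coef(lm(y ~ z))[2])
  R2_zx <- summary(lm(x ~ z))$r.squared
  R2_xy <- summary(lm(y ~ x))$r.squared
  b_xy <- b_zy / b_zx
  var_bxy <- (var(y) * (1 - R2_xy)) / (length(z) * var(x) * R2_zx)
  list(b_xy = b_xy, var_bxy = var_bxy, T_MR = b_xy^2 / var_bxy)
}

# adjusted Rand index for cluster-recovery checks
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
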