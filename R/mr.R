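#' Two-stage least-squares Mendelian randomization test
#'
#' Uses a genetic instrument z (an eQTL lead-SNP dosage) to estimate the
#' confounder-free effect of an exposure x (transformed gene expression)
#' on an outcome y (the phenotype): b_xy = b_zy / b_zx with b_zy, b_zx the
#' simple least-squares slopes of y and x on z. The sampling variance is
#' var(b_xy) = var(y) (1 - R2_xy) / (n var(x) R2_zx) with R2_xy the
#' variance fraction of y explained by x and R2_zx that of x explained by
#' z (sample variances, n-1 denominator). T_MR = b_xy^2 / var(b_xy) is
#' referred to a chi-square with 1 df. Samples missing any of z, x, y are
#' dropped.
#'
#' @param z instrument dosage vector (additive coding; het = 1)
#' @param x exposure (transformed expression) vector
#' @param y outcome (phenotype) vector
#' @return list of class `mr_test`: `n`, `b_zx`, `b_zy`, `R2_zx`, `R2_xy`,
#'   `b_xy`, `var_bxy`, `T_MR`, `p`, `direction`
#' @export
mr_test <- function(z, x, y) {
  ok <- !is.na(z) & !is.na(x) & !is.na(y)
  z <- z[ok]; x <- x[ok]; y <- y[ok]
  n <- length(z)
  if (n < 3) stop("fewer than 3 complete observations")
  vz <- stats::var(z); vx <- stats::var(x); vy <- stats::var(y)
  if (vz == 0) stop("undefined instrument: z is monomorphic")
  if (vx == 0) stop("x has zero variance")
  b_zx <- stats::cov(z, x) / vz
  b_zy <- stats::cov(z, y) / vz
  R2_zx <- stats::cor(z, x)^2
  R2_xy <- if (vy > 0) stats::cor(x, y)^2 else 0
  if (b_zx == 0 || R2_zx == 0)
    stop("undefined instrument: b_zx = 0 (no z-x association)")
  b_xy <- b_zy / b_zx
  var_bxy <- (vy * (1 - R2_xy)) / (n * vx * R2_zx)
  if (var_bxy == 0) {
    warning("R2_xy = 1: sampling variance is 0, p reported as 0")
    T_MR <- if (b_xy == 0) 0 else Inf
  } else T_MR <- b_xy^2 / var_bxy
  p <- stats::pchisq(T_MR, df = 1, lower.tail = FALSE)
  structure(list(n = n, b_zx = b_zx, b_zy = b_zy, R2_zx = R2_zx,
                 R2_xy = R2_xy, b_xy = b_xy, var_bxy = var_bxy,
                 T_MR = T_MR, p = p,
                 direction = if (b_xy >= 0) "positive" else "negative"),
            class = "mr_test")
}

#' @export
print.mr_test <- function(x, ...) {
  cat(sprintf(
    "MR 2SLS: n = %d, b_xy = %.4g (var %.3g), T_MR = %.3g, p = %.3g [%s]\n",
    x$n, x$b_xy, x$var_bxy, x$T_MR, x$p, x$direction))
  invisible(x)
}

#' Experiment-wise MR significance threshold
#'
#' Two conventions: `"reciprocal"` sets the cutoff to 1 / n_tests (the
#' convention behind a printed 3.33e-5 at 30,006 tests);
#' `"bonferroni_0.05"` sets alpha / n_tests.
#'
#' @param n_tests number of MR tests performed
#' @param convention threshold convention
#' @param alpha family-wise error rate for the Bonferroni convention
#' @return list of class `MRThreshold`: `n_tests`, `cutoff`, `convention`
#' @export
mr_threshold <- function(n_tests,
                         convention = c("reciprocal", "bonferroni_0.05"),
                         alpha = 0.05) {
  convention <- match.arg(convention)
  if (n_tests < 1) stop("n_tests must be positive")
  cutoff <- switch(convention,
                   reciprocal = 1 / n_tests,
                   bonferroni_0.05 = alpha / n_tests)
  structure(list(n_tests = as.integer(n_tests), cutoff = cutoff,
                 convention = convention), class = "MRThreshold")
}

#' Mendelian-randomization scan over called eQTLs
#'
#' Runs one [mr_test()] per (gene, condition) with a called eQTL: the
#' instrument is that condition's lead SNP (the gene's most significant
#' eQTL lead within the condition), the exposure is the gene's transformed
#' expression under the same condition, and the outcome is the
#' condition-independent phenotype. The experiment-wise threshold is
#' computed from the number of tests actually performed.
#'
#' @param eqtls an `eqtl_set` (see [call_eqtls()])
#' @param genotypes the `VariantTable` (instrument dosages; missing calls
#'   dropped per test, het coded 1)
#' @param expression named list of `ExpressionSet`s with transformed
#'   matrices, one per condition
#' @param phenotype a `PhenotypeVector`
#' @param convention,alpha see [mr_threshold()]
#' @return list of class `mr_scan`: `records` (one row per test with the
#'   `mr_test` fields plus `gene_id`, `condition`, `snp_id`,
#'   `significant`), `threshold`, `best` (per-gene minimum-p record)
#' @export
mr_scan <- function(eqtls, genotypes, expression, phenotype,
                    convention = c("reciprocal", "bonferroni_0.05"),
                    alpha = 0.05) {
  convention <- match.arg(convention)
  rows <- list()
  for (gene in unique(eqtls$gene_id)) {
    ge <- eqtls[eqtls$gene_id == gene, , drop = FALSE]
    for (cond in unique(ge$condition)) {
      gc <- ge[ge$condition == cond, , drop = FALSE]
      lead <- gc[which.min(gc$lead_p), ]
      es <- expression[[cond]]
      if (is.null(es) || is.null(es$transformed)) next
      if (!(gene %in% rownames(es$transformed))) next
      samples <- Reduce(intersect, list(genotypes$sample_ids,
                                        colnames(es$transformed),
                                        names(phenotype)))
      z <- as.numeric(genotypes$calls[samples,
             match(lead$lead_snp, genotypes$snps$snp_id)])
      x <- es$transformed[gene, samples]
      y <- as.numeric(phenotype[samples])
      t <- tryCatch(mr_test(z, x, y), error = function(e) NULL)
      if (is.null(t)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene, condition = cond, snp_id = lead$lead_snp,
        n = t$n, b_zx = t$b_zx, b_zy = t$b_zy, R2_zx = t$R2_zx,
        R2_xy = t$R2_xy, b_xy = t$b_xy, var_bxy = t$var_bxy,
        T_MR = t$T_MR, p = t$p, direction = t$direction,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), condition = character(0),
               snp_id = character(0), n = integer(0), b_zx = numeric(0),
               b_zy = numeric(0), R2_zx = numeric(0), R2_xy = numeric(0),
               b_xy = numeric(0), var_bxy = numeric(0), T_MR = numeric(0),
               p = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  thr <- if (nrow(records))
    mr_threshold(nrow(records), convention, alpha) else
    structure(list(n_tests = 0L, cutoff = NA_real_,
                   convention = convention), class = "MRThreshold")
  records$significant <- if (nrow(records)) records$p < thr$cutoff
    else logical(0)
  best <- if (nrow(records)) {
    b <- do.call(rbind, lapply(split(records, records$gene_id),
                               function(d) d[which.min(d$p), ]))
    rownames(b) <- NULL
    b
  } else records
  structure(list(records = records, threshold = thr, best = best),
            class = "mr_scan")
}

#' @export
print.mr_scan <- function(x, ...) {
  cat("MR scan:", nrow(x$records), "tests over",
      length(unique(x$records$gene_id)), "genes\n")
  if (x$threshold$n_tests > 0)
    cat(sprintf("  %s threshold: p < %.3g; %d significant\n",
                x$threshold$convention, x$threshold$cutoff,
                sum(x$records$significant)))
  invisible(x)
}

#' @export
summary.mr_scan <- function(object, ...) {
  d <- classify_direction(object)
  cat("MR scan summary\n")
  cat("  tests:", object$threshold$n_tests,
      " cutoff:", format(object$threshold$cutoff, digits = 3), "\n")
  cat("  prioritized genes:", d$n_total,
      sprintf("(%d positive, %d negative)\n",
              d$n_positive, d$n_negative))
  invisible(d)
}

#' Split significant MR genes by effect direction
#'
#' Positive regulators have b_xy > 0 (expression raises the phenotype),
#' negative b_xy < 0. Operates on the per-gene best records of a
#' [mr_scan()] (each gene counted once).
#'
#' @param scan an `mr_scan`
#' @return list: `positive`, `negative` (gene id vectors), `n_positive`,
#'   `n_negative`, `n_total`
#' @export
classify_direction <- function(scan) {
  stopifnot(inherits(scan, "mr_scan"))
  sig <- scan$best[scan$best$p < scan$threshold$cutoff, , drop = FALSE]
  if (nrow(sig) && any(sig$b_xy == 0))
    stop("significant record with b_xy = 0 should be impossible (T_MR = 0)")
  pos <- sig$gene_id[sig$b_xy > 0]
  neg <- sig$gene_id[sig$b_xy < 0]
  list(positive = pos, negative = neg, n_positive = length(pos),
       n_negative = length(neg), n_total = length(pos) + length(neg))
}
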