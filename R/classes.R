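#' Construct a variant table
#'
#' The central genotype container: SNP metadata plus a sample-by-SNP matrix
#' of additive genotype codes. Codes are 0 (reference homozygote), 1
#' (heterozygote), 2 (alternate homozygote) and `NA` for missing. Codes stay
#' ref/alt-anchored throughout; minor/major status and MAF are always
#' derived on demand (see [snp_maf()]), never stored.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; `snp_id` must be unique and `pos >= 1`.
#' @param calls integer matrix, samples in rows, SNPs in columns, values in
#'   \{0, 1, 2, NA\}. Column names must equal `snps$snp_id`.
#' @param sample_ids character vector of row identities; defaults to
#'   `rownames(calls)`.
#' @return An object of class `VariantTable`.
#' @export
variant_table <- function(snps, calls, sample_ids = rownames(calls)) {
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id in variant table")
  if (any(snps$pos < 1L))
    stop("SNP positions must be >= 1 (1-based)")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but snps has ", nrow(snps),
         " rows")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  rownames(calls) <- sample_ids
  colnames(calls) <- snps$snp_id
  rownames(snps) <- NULL
  structure(list(snps = snps, calls = calls,
                 sample_ids = as.character(sample_ids)),
            class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat("VariantTable:", nrow(x$snps), "SNPs x", length(x$sample_ids),
      "samples\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  mr <- mean(is.na(x$calls))
  cat(sprintf("  overall missing fraction: %.4f\n", mr))
  invisible(x)
}

#' Number of SNPs / samples in a variant table
#' @param x a `VariantTable`
#' @return integer count
#' @export
n_snps <- function(x) nrow(x$snps)

#' @rdname n_snps
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Per-SNP minor allele frequency
#'
#' Allele frequency of the alternate allele is computed from non-missing
#' calls as (het + 2 x alt-hom) / (2 x non-missing); the MAF is the smaller
#' of that and its complement. All-missing SNPs yield `NA`.
#'
#' @param x a `VariantTable`
#' @return numeric vector named by snp_id
#' @export
snp_maf <- function(x) {
  g <- x$calls
  nm <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)   # each alt-hom contributes 2, het 1
  f <- ifelse(nm > 0, alt / (2 * nm), NA_real_)
  maf <- pmin(f, 1 - f)
  names(maf) <- x$snps$snp_id
  maf
}

#' Per-SNP missing-call fraction
#' @param x a `VariantTable`
#' @return numeric vector named by snp_id
#' @export
snp_missing <- function(x) {
  m <- colMeans(is.na(x$calls))
  names(m) <- x$snps$snp_id
  m
}

#' Subset a variant table by SNPs and/or samples
#'
#' @param x a `VariantTable`
#' @param snps character snp_ids, or logical/integer index into SNP columns
#' @param samples character sample ids, or logical/integer index
#' @return a `VariantTable`
#' @export
subset_variants <- function(x, snps = NULL, samples = NULL) {
  ci <- seq_len(n_snps(x))
  ri <- seq_len(n_samples(x))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, x$snps$snp_id) else ci[snps]
    if (anyNA(ci)) stop("unknown snp_id in subset")
  }
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, x$sample_ids) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id in subset")
  }
  variant_table(x$snps[ci, , drop = FALSE],
                x$calls[ri, ci, drop = FALSE],
                x$sample_ids[ri])
}

#' Dosage matrix with per-SNP mean imputation
#'
#' Returns the numeric genotype matrix with each SNP's missing calls
#' replaced by that SNP's mean observed dosage (the convention used in the
#' association scan).
#'
#' @param x a `VariantTable`
#' @return numeric matrix, samples x SNPs
#' @export
dosage_imputed <- function(x) {
  g <- x$calls
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

#' Construct a gene annotation table
#'
#' @param gene_id,chrom,start,end,strand vectors of equal length; coordinates
#'   are 1-based inclusive with `start <= end`; strand in `+`/`-`.
#' @param is_tf logical flag marking transcription-factor genes
#' @param tf_family optional TF family label (`NA` for non-TFs)
#' @return data.frame of class `GeneAnnotation`
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand = "+",
                            is_tf = FALSE, tf_family = NA_character_) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   is_tf = as.logical(is_tf),
                   tf_family = as.character(tf_family),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id")
  if (any(df$start > df$end)) stop("gene start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Construct a per-condition expression set
#'
#' @param condition condition label (e.g. `"WW"`, `"WS1"`, `"WS2"`)
#' @param abundance nonnegative genes x samples matrix (FPKM-like scale);
#'   rownames are gene ids, colnames sample ids
#' @param transformed optional matrix of the same shape holding the
#'   quantile-normalized + inverse-normal transformed values
#' @return list of class `ExpressionSet`
#' @export
expression_set <- function(condition, abundance, transformed = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs gene rownames and sample colnames")
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundance values must be nonnegative")
  if (!is.null(transformed)) {
    transformed <- as.matrix(transformed)
    if (!identical(dim(transformed), dim(abundance)))
      stop("transformed matrix shape differs from abundance")
  }
  structure(list(condition = as.character(condition)[1],
                 abundance = abundance, transformed = transformed),
            class = "ExpressionSet")
}

#' @export
print.ExpressionSet <- function(x, ...) {
  cat("ExpressionSet [", x$condition, "]: ", nrow(x$abundance), " genes x ",
      ncol(x$abundance), " samples", sep = "")
  cat(if (is.null(x$transformed)) " (raw abundance only)\n"
      else " (+ transformed matrix)\n")
  invisible(x)
}

#' Construct a phenotype vector
#'
#' One quantitative value per sample (e.g. seedling survival rate under
#' drought, a fraction in \[0,1\]).
#'
#' @param values numeric vector
#' @param sample_ids sample identifiers; defaults to `names(values)`
#' @return named numeric of class `PhenotypeVector`
#' @export
phenotype_vector <- function(values, sample_ids = names(values)) {
  if (is.null(sample_ids)) stop("phenotype needs sample ids")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids in phenotype")
  if (length(values) != length(sample_ids))
    stop("values and sample_ids lengths differ")
  structure(as.numeric(values), names = as.character(sample_ids),
            class = "PhenotypeVector")
}

#' @export
print.PhenotypeVector <- function(x, ...) {
  cat("PhenotypeVector:", length(x), "samples, range [",
      sprintf("%.3f", min(x, na.rm = TRUE)), ",",
      sprintf("%.3f", max(x, na.rm = TRUE)), "]\n")
  invisible(x)
}
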