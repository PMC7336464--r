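#' Resolve heterozygous calls in an inbred panel
#'
#' Heterozygous calls in a mostly-homozygous (inbred) panel are treated as
#' artefacts. At SNPs with MAF below `maf_threshold` the minor allele is
#' attributed to sequencing error, so het calls are recoded to the
#' major-allele homozygote; at SNPs with MAF at or above the threshold the
#' het call is ambiguous and is masked as missing. Homozygous calls are
#' never touched. All-missing SNPs are left untouched and flagged in the
#' `"all_missing"` attribute.
#'
#' @param x a `VariantTable`
#' @param maf_threshold MAF boundary between the two rules
#' @return a `VariantTable`
#' @export
resolve_heterozygotes <- function(x, maf_threshold = 0.05) {
  stopifnot(inherits(x, "VariantTable"))
  maf <- snp_maf(x)
  g <- x$calls
  nm <- colSums(!is.na(g))
  altf <- ifelse(nm > 0, colSums(g, na.rm = TRUE) / (2 * nm), NA_real_)
  major_code <- ifelse(altf > 0.5, 2L, 0L)     # code of the major allele
  het <- which(g == 1L, arr.ind = TRUE)
  if (nrow(het)) {
    j <- het[, 2]
    low <- !is.na(maf[j]) & maf[j] < maf_threshold
    g[het[low, , drop = FALSE]] <- major_code[j[low]]
    g[het[!low, , drop = FALSE]] <- NA_integer_
  }
  out <- variant_table(x$snps, g, x$sample_ids)
  attr(out, "all_missing") <- x$snps$snp_id[nm == 0]
  out
}

#' Filter SNPs on MAF and missingness
#'
#' Keeps SNPs with minor allele frequency `>= maf_min` and missing fraction
#' strictly `< missing_max` (both bounds as conventionally printed:
#' MAF >= 5%, missing rate < 0.6). Intended to run after
#' [resolve_heterozygotes()].
#'
#' @param x a `VariantTable`
#' @param maf_min inclusive MAF lower bound
#' @param missing_max exclusive missing-fraction upper bound
#' @return a `VariantTable`
#' @export
filter_snps <- function(x, maf_min = 0.05, missing_max = 0.6) {
  stopifnot(inherits(x, "VariantTable"))
  maf <- snp_maf(x)
  miss <- snp_missing(x)
  keep <- !is.na(maf) & maf >= maf_min & miss < missing_max
  subset_variants(x, snps = keep)
}

# align two tables on shared samples and on SNPs matched by
# (chrom, pos, ref, alt), detecting ref/alt swaps (codes recoded 2<->0)
align_tables <- function(a, b) {
  samples <- intersect(a$sample_ids, b$sample_ids)
  key_a <- paste(a$snps$chrom, a$snps$pos)
  key_b <- paste(b$snps$chrom, b$snps$pos)
  ia <- which(key_a %in% key_b)
  if (!length(samples) || !length(ia))
    stop("no overlapping samples and SNPs between the two tables")
  ib <- match(key_a[ia], key_b)
  same <- a$snps$ref[ia] == b$snps$ref[ib] & a$snps$alt[ia] == b$snps$alt[ib]
  swap <- a$snps$ref[ia] == b$snps$alt[ib] & a$snps$alt[ia] == b$snps$ref[ib]
  use <- same | swap
  ia <- ia[use]; ib <- ib[use]; swap <- swap[use]
  if (!length(ia)) stop("no allele-compatible overlapping SNPs")
  ga <- a$calls[samples, ia, drop = FALSE]
  gb <- b$calls[samples, ib, drop = FALSE]
  if (any(swap)) gb[, swap] <- 2L - gb[, swap, drop = FALSE]
  list(samples = samples, ia = ia, ga = ga, gb = gb)
}

#' Genotype concordance between two panels
#'
#' For each shared sample, the fraction of overlapping SNPs (matched on
#' chromosome, position and alleles, with ref/alt swaps recoded) at which
#' both calls are non-missing and agree. Pairs with either call missing are
#' excluded from the denominator.
#'
#' @param a,b `VariantTable`s sharing sample and SNP identities
#' @param pooled if `TRUE`, also a single rate pooled over all genotype
#'   cells rather than the mean of per-sample rates
#' @return list with `per_sample` (named numeric), `mean`, and `pooled`
#' @export
concordance_rate <- function(a, b, pooled = FALSE) {
  al <- align_tables(a, b)
  both <- !is.na(al$ga) & !is.na(al$gb)
  agree <- both & (al$ga == al$gb)
  denom <- rowSums(both)
  if (all(denom == 0))
    stop("no sample has a non-missing overlapping call in both tables")
  per <- ifelse(denom > 0, rowSums(agree) / denom, NA_real_)
  names(per) <- al$samples
  list(per_sample = per, mean = mean(per, na.rm = TRUE),
       pooled = if (pooled) sum(agree) / sum(both) else NULL)
}

#' Mask discordant calls between two panels
#'
#' Returns `a` with every call that disagrees with `b` (both non-missing,
#' after allele-swap reconciliation) set to missing. Agreeing calls and
#' calls present in only one source are kept.
#'
#' @param a primary `VariantTable` (frame of the output)
#' @param b comparison `VariantTable`
#' @return a `VariantTable` with `a`'s SNPs and samples
#' @export
mask_discordant <- function(a, b) {
  al <- align_tables(a, b)
  g <- a$calls
  sub <- g[al$samples, al$ia, drop = FALSE]
  disc <- !is.na(al$ga) & !is.na(al$gb) & (al$ga != al$gb)
  sub[disc] <- NA_integer_
  g[al$samples, al$ia] <- sub
  variant_table(a$snps, g, a$sample_ids)
}
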