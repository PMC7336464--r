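#' Read genotypes from a VCF file
#'
#' Consumes the GT field of a VCF 4.x file and returns a [variant_table()].
#' Only bi-allelic SNP records are kept: multi-allelic records and records
#' whose REF/ALT are not single bases are skipped, with a message giving the
#' skipped count. When `maf_min`/`missing_max` are supplied the per-SNP
#' filters are applied at load time (MAF computed from non-missing calls;
#' kept if `MAF >= maf_min` and missing fraction `< missing_max`).
#'
#' @param path VCF file (plain text or bgzipped)
#' @param maf_min optional minor-allele-frequency lower bound (inclusive)
#' @param missing_max optional missing-fraction upper bound (exclusive)
#' @return a `VariantTable`
#' @export
read_vcf <- function(path, maf_min = NULL, missing_max = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(first, "##fileformat=VCF"))
    stop("parse error at line 1 of ", path, ": missing ##fileformat=VCF header")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no variant records in ", path)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !is.na(fix$ALT)
  if (any(!keep))
    message("read_vcf: skipped ", sum(!keep),
            " multi-allelic or non-SNP record(s)")
  if (!any(keep)) stop("no bi-allelic SNPs survive in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- gt_to_code(gt)               # SNPs x samples
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  vt <- variant_table(
    snps = data.frame(snp_id = ids, chrom = fix$CHROM,
                      pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, stringsAsFactors = FALSE),
    calls = t(code), sample_ids = colnames(gt))
  if (!is.null(maf_min) || !is.null(missing_max)) {
    maf <- snp_maf(vt)
    miss <- snp_missing(vt)
    ok <- rep(TRUE, n_snps(vt))
    if (!is.null(maf_min)) ok <- ok & !is.na(maf) & maf >= maf_min
    if (!is.null(missing_max)) ok <- ok & miss < missing_max
    if (!any(ok)) stop("no SNPs survive the MAF/missingness filters")
    vt <- subset_variants(vt, snps = ok)
  }
  vt
}

# "0/0"-style GT strings (phased or unphased, any ploidy-2 separator) to
# additive codes; anything containing '.' is missing.
gt_to_code <- function(gt) {
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  code[g == "0/0"] <- 0L
  code[g == "0/1" | g == "1/0"] <- 1L
  code[g == "1/1"] <- 2L
  code
}

#' Write a variant table as VCF 4.2
#'
#' Plain-text writer; GT is the only FORMAT field, hom/het codes rendered as
#' `0/0`, `0/1`, `1/1` and missing as `./.`.
#'
#' @param x a `VariantTable`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "VariantTable"))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$sample_ids), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  g <- t(x$calls)                      # SNPs x samples
  body <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  body[ok] <- gt_str[g[ok] + 1L]
  lines <- paste(x$snps$chrom, x$snps$pos, x$snps$snp_id, x$snps$ref,
                 x$snps$alt, ".", "PASS", ".", "GT",
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features only; coordinates stay 1-based inclusive. The TF
#' family is read from the attribute named by `tf_attribute` (a gene with
#' that attribute present is flagged `is_tf`).
#'
#' @param path GFF3 file
#' @param tf_attribute attribute key carrying the TF family label
#' @return a `GeneAnnotation`
#' @export
read_gff3 <- function(path, tf_attribute = "tf_family") {
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  genes <- gr[types == "gene"]
  if (!length(genes))
    stop("no gene features in ", path, "; feature types found: ",
         paste(unique(types), collapse = ", "))
  md <- as.data.frame(genes)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    as.character(md$gene_id)
  fam <- if (tf_attribute %in% names(md)) as.character(md[[tf_attribute]])
    else rep(NA_character_, nrow(md))
  gene_annotation(gene_id = ids, chrom = as.character(md$seqnames),
                  start = md$start, end = md$end,
                  strand = ifelse(as.character(md$strand) == "-", "-", "+"),
                  is_tf = !is.na(fam), tf_family = fam)
}

#' Write a gene annotation as GFF3
#'
#' @param ann a `GeneAnnotation`
#' @param path output file
#' @param tf_attribute attribute key used for the TF family label
#' @return `path`, invisibly
#' @export
write_gff3 <- function(ann, path, tf_attribute = "tf_family") {
  stopifnot(inherits(ann, "GeneAnnotation"))
  attrs <- paste0("ID=", ann$gene_id)
  has_fam <- !is.na(ann$tf_family)
  attrs[has_fam] <- paste0(attrs[has_fam], ";", tf_attribute, "=",
                           ann$tf_family[has_fam])
  lines <- paste(ann$chrom, "dyneqtl", "gene", ann$start, ann$end, ".",
                 ann$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a genes-x-samples TSV matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' `NA` cells stay missing (never coerced to zero). Ragged rows raise an
#' error naming the offending row.
#'
#' @param path TSV file
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged TSV: row ", which(nf != nf[1])[1], " has ",
         nf[nf != nf[1]][1], " fields, expected ", nf[1])
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a per-condition expression matrix as an `ExpressionSet`
#' @param path TSV file (see [read_matrix()])
#' @param condition condition label to attach
#' @return an `ExpressionSet`
#' @export
read_expression <- function(path, condition) {
  expression_set(condition, read_matrix(path))
}

#' Write a matrix or data.frame as TSV
#'
#' Matrices are written with their rownames in a leading id column so
#' [read_matrix()] round-trips them exactly (decimal text, 17 significant
#' digits).
#'
#' @param x matrix or data.frame
#' @param path output file
#' @param id_col name of the leading id column for matrices
#' @return `path`, invisibly
#' @export
write_table <- function(x, path, id_col = "id") {
  fmt <- function(v) {
    if (is.double(v)) {
      out <- sprintf("%.17g", v)       # shortest exact decimal round-trip
      out[is.na(v)] <- "NA"
      out
    } else v
  }
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), apply(x, 2, fmt), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c(id_col, colnames(x))
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    df[] <- lapply(df, fmt)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV (sample_id, value)
#' @param path two-column TSV with a header
#' @return a `PhenotypeVector`
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  phenotype_vector(df[[2]], df[[1]])
}

#' Export intervals as BED
#'
#' The package keeps 1-based inclusive coordinates everywhere internally;
#' BED is the one exported 0-based half-open format, converted exactly at
#' this boundary (`start - 1`, `end`).
#'
#' @param chrom,start,end,name vectors of equal length (1-based inclusive)
#' @param path output BED file
#' @param score optional numeric score column
#' @return `path`, invisibly
#' @export
write_bed <- function(chrom, start, end, name, path, score = 0) {
  df <- data.frame(chrom = chrom, start = as.integer(start) - 1L,
                   end = as.integer(end), name = name, score = score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
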