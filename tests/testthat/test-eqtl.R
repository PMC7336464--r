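snp_df <- function(pos, p = NULL, chrom = "chr1") {
  n <- length(pos)
  data.frame(snp_id = sprintf("v%03d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos),
             p = if (is.null(p)) 10^-runif(n, 6, 12) else p,
             partial_r2 = runif(n, 0.05, 0.4), stringsAsFactors = FALSE)
}

test_that("distance grouping chains by the strict 5-kb rule", {
  s <- snp_df(c(100, 2000, 4900, 30000))
  out <- group_by_distance(s, gap_bp = 5000)
  expect_identical(out$cluster, c(1L, 1L, 1L, 2L))
  # gaps 1900 and 2900 chain; 25100 does not
  one <- group_by_distance(snp_df(500), gap_bp = 5000)
  expect_identical(one$cluster, 1L)
  # distance exactly gap_bp does not chain (strict <)
  s2 <- group_by_distance(snp_df(c(1000, 6000)), gap_bp = 5000)
  expect_identical(s2$cluster, c(1L, 2L))
  # chromosomes never join
  s3 <- snp_df(c(100, 600), chrom = c("chr1", "chr2"))
  expect_identical(group_by_distance(s3)$cluster, c(1L, 2L))
})

test_that("distance grouping equals brute-force chaining on random inputs", {
  set.seed(171)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    s <- snp_df(sort(sample.int(60000, n)))
    out <- group_by_distance(s, gap_bp = 5000)
    # brute force: scan sorted positions, split where gap >= 5000
    want <- cumsum(c(TRUE, diff(s$pos) >= 5000))
    expect_identical(out$cluster, as.integer(want))
  }
})

ld_toy <- function(r2_high = TRUE, n = 60) {
  # two SNP pairs: v001/v002 in high LD if requested, else independent
  set.seed(42)
  z1 <- rbinom(n, 2, 0.5)
  z2 <- if (r2_high) ifelse(runif(n) < 0.9, z1, rbinom(n, 2, 0.5))
    else rbinom(n, 2, 0.5)
  calls <- cbind(z1, z2)
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("S%02d", 1:n)
  list(z1 = z1, z2 = z2, calls = calls)
}

test_that("LD merging joins clusters above r2 within the distance cap", {
  toy <- ld_toy(r2_high = TRUE)
  mk <- function(pos2) {
    vt <- variant_table(
      data.frame(snp_id = c("v001", "v002"), chrom = "chr1",
                 pos = c(1000L, pos2), ref = "A", alt = "G",
                 stringsAsFactors = FALSE), toy$calls)
    s <- data.frame(snp_id = c("v001", "v002"), chrom = "chr1",
                    pos = c(1000L, pos2), p = c(1e-8, 1e-7),
                    partial_r2 = c(0.3, 0.25), stringsAsFactors = FALSE)
    s$cluster <- c(1L, 2L)
    list(vt = vt, s = s)
  }
  # r2 ~ 0.8, 25 kb apart -> merge
  x <- mk(26000L)
  expect_identical(length(unique(merge_by_ld(x$s, x$vt)$cluster)), 1L)
  # 400 kb apart -> stay separate despite LD
  y <- mk(401000L)
  expect_identical(length(unique(merge_by_ld(y$s, y$vt)$cluster)), 2L)
  # independent SNPs (r2 ~ 0) -> stay separate
  toy2 <- ld_toy(r2_high = FALSE)
  vt2 <- variant_table(
    data.frame(snp_id = c("v001", "v002"), chrom = "chr1",
               pos = c(1000L, 26000L), ref = "A", alt = "G",
               stringsAsFactors = FALSE), toy2$calls)
  s2 <- x$s
  expect_identical(length(unique(merge_by_ld(s2, vt2)$cluster)), 2L)
})

test_that("gene-body merging respects 1-based inclusive containment", {
  ann <- gene_annotation(c("gX", "gY"), "chr1", c(1000L, 9000L),
                         c(5000L, 12000L))
  s <- snp_df(c(1200, 4800, 5001))
  s$cluster <- 1:3
  out <- merge_by_gene(s, ann)
  # leads at 1200 and 4800 inside gX merge; 5001 is 1 bp past the end
  expect_identical(out$cluster[1], out$cluster[2])
  expect_false(out$cluster[3] == out$cluster[1])
})

test_that("locality classification uses the 20-kb body-anchored window", {
  ann <- gene_annotation("g", "chr1", 1000000L, 1005000L)
  expect_identical(classify_locality("chr1", 1020001, "g", ann), "local")
  expect_identical(classify_locality("chr1", 1025000, "g", ann), "local")
  expect_identical(classify_locality("chr1", 1025001, "g", ann), "distant")
  expect_identical(classify_locality("chr1", 979999, "g", ann), "distant")
  expect_identical(classify_locality("chr1", 980000, "g", ann), "local")
  expect_identical(classify_locality("chr1", 1002000, "g", ann), "local")
  expect_identical(classify_locality("chr2", 1002000, "g", ann), "distant")
  expect_error(classify_locality("chr1", 1, "nope", ann), "absent")
})

make_scan <- function(records, condition, cutoff) {
  structure(list(records = records,
                 threshold = structure(list(condition = condition,
                                            cutoff = cutoff,
                                            n_tests = nrow(records),
                                            n_rejected = sum(records$p <= cutoff)),
                                       class = "ScanThreshold"),
                 condition = condition), class = "eqtl_scan")
}

test_that("the minimum-support rule gates eQTL calling", {
  set.seed(181)
  vt <- random_variant_table(n_samples = 30, n_snps = 6,
                             pos = c(1000L, 2000L, 3000L, 4000L, 5000L,
                                     6000L))
  ann <- gene_annotation("gA", "chr1", 1L, 500L)
  rec <- function(n_sig) data.frame(
    gene_id = "gA", snp_id = vt$snps$snp_id[seq_len(n_sig)],
    chrom = "chr1", pos = vt$snps$pos[seq_len(n_sig)], condition = "WW",
    beta = 1, se = 0.1, p = 1e-9, partial_r2 = 0.2,
    stringsAsFactors = FALSE)
  expect_identical(nrow(call_eqtls(make_scan(rec(2), "WW", 1e-6), vt, ann)),
                   0L)
  out3 <- call_eqtls(make_scan(rec(3), "WW", 1e-6), vt, ann)
  expect_identical(nrow(out3), 1L)
  expect_identical(out3$n_snps, 3L)
  # min_snps = 1 lets everything through
  out1 <- call_eqtls(make_scan(rec(1), "WW", 1e-6), vt, ann, min_snps = 1)
  expect_identical(nrow(out1), 1L)
})

test_that("consolidation equals the brute-force oracle on random instances", {
  set.seed(191)
  ann <- gene_annotation(sprintf("g%d", 1:3), "chr1",
                         c(4000L, 20000L, 40000L),
                         c(9000L, 26000L, 46000L))
  for (rep in 1:300) {
    n <- sample(3:30, 1)
    vt <- random_variant_table(n_samples = 25, n_snps = n,
                               pos = sort(sample.int(60000, n)),
                               miss_rate = 0.05)
    s <- data.frame(snp_id = vt$snps$snp_id, chrom = vt$snps$chrom,
                    pos = vt$snps$pos, p = 10^-runif(n, 6, 12),
                    partial_r2 = runif(n, 0.05, 0.4),
                    stringsAsFactors = FALSE)
    got <- merge_by_gene(
      merge_by_ld(group_by_distance(s, 5000), vt), ann)
    got_sets <- lapply(split(got$snp_id, got$cluster), sort)
    want <- oracle_consolidate(s, vt$calls, ann)
    want_sets <- lapply(want, `[[`, "members")
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
    # leads agree too
    got_leads <- vapply(split(got, got$cluster), function(d)
      dyneqtl:::elect_lead(d)$snp_id, character(1))
    want_leads <- vapply(want, `[[`, "", "lead")
    expect_setequal(unname(got_leads), want_leads)
  }
})

test_that("consolidation is order-independent and partitions its input", {
  set.seed(201)
  ann <- gene_annotation("g1", "chr1", 4000L, 9000L)
  n <- 20
  vt <- random_variant_table(n_samples = 25, n_snps = n,
                             pos = sort(sample.int(40000, n)))
  s <- data.frame(snp_id = vt$snps$snp_id, chrom = vt$snps$chrom,
                  pos = vt$snps$pos, p = 10^-runif(n, 6, 12),
                  partial_r2 = runif(n, 0.05, 0.4),
                  stringsAsFactors = FALSE)
  run <- function(d) {
    out <- merge_by_gene(merge_by_ld(group_by_distance(d, 5000), vt), ann)
    sort(vapply(split(out$snp_id, out$cluster),
                function(v) paste(sort(v), collapse = ","), ""))
  }
  base <- run(s)
  for (rep in 1:5) expect_identical(run(s[sample(n), ]), base)
  # member sets partition the input
  expect_identical(sort(unname(unlist(strsplit(base, ",")))),
                   sort(s$snp_id))
})

test_that("dynamics classification follows the condition-occupancy rule", {
  set.seed(211)
  n <- 40
  z <- rbinom(n, 2, 0.5)
  calls <- cbind(z, z, rbinom(n, 2, 0.5))
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("S%02d", 1:n)
  vt <- variant_table(
    data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
               pos = c(1000L, 3000L, 200000L), ref = "A", alt = "G",
               stringsAsFactors = FALSE), calls)
  eq <- function(cond, lead, locality = "local")
    data.frame(gene_id = "gA", condition = cond, lead_snp = lead,
               lead_chrom = "chr1",
               lead_pos = vt$snps$pos[match(lead, vt$snps$snp_id)],
               lead_p = 1e-9, lead_r2 = 0.2, n_snps = 3L, members = lead,
               locality = locality, stringsAsFactors = FALSE)
  # same locus (leads within 5 kb / high LD) in all three -> static
  all3 <- rbind(eq("WW", "a"), eq("WS1", "b"), eq("WS2", "a"))
  d <- classify_dynamics(all3, vt)
  expect_identical(nrow(d), 1L)
  expect_identical(d$dynamics, "static")
  expect_false(d$stress_only)
  # stress conditions only -> dynamic, stress_only
  d2 <- classify_dynamics(rbind(eq("WS1", "a"), eq("WS2", "b")), vt)
  expect_identical(d2$dynamics, "dynamic")
  expect_true(d2$stress_only)
  # WW only -> dynamic, not stress_only
  d3 <- classify_dynamics(eq("WW", "a"), vt)
  expect_identical(d3$dynamics, "dynamic")
  expect_false(d3$stress_only)
  # distinct loci stay distinct (far apart, no LD)
  d4 <- classify_dynamics(rbind(eq("WW", "a"), eq("WS1", "c")), vt)
  expect_identical(nrow(d4), 2L)
  expect_true(all(d4$dynamics == "dynamic"))
})

test_that("count summaries reproduce half-up percentage arithmetic", {
  out <- summarize_counts(static_local = 9168, dynamic_local = 11365,
                          static_distant = 10398, dynamic_distant = 42642)
  get <- function(cls) out$percent[out$class == cls]
  expect_identical(out$count[out$class == "static"], 19566)
  expect_identical(out$count[out$class == "dynamic"], 54007)
  expect_equal(get("static"), 26.6)
  expect_equal(get("dynamic"), 73.4)
  expect_equal(get("static_local"), 44.7)
  expect_equal(get("static_distant"), 19.6)
  # half-up, not banker's
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(44.65, 1), 44.7)
})

test_that("eQTL BED export spans member SNPs with exact basis conversion", {
  set.seed(221)
  vt <- random_variant_table(n_samples = 10, n_snps = 4,
                             pos = c(100L, 600L, 900L, 5000L))
  eq <- data.frame(gene_id = "g", condition = "WW", lead_snp = "v002",
                   lead_chrom = "chr1", lead_pos = 600L, lead_p = 1e-8,
                   lead_r2 = 0.2, n_snps = 3L,
                   members = "v001,v002,v003", locality = "local",
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  eqtl_bed(eq, vt, f)
  bed <- read.table(f, sep = "\t")
  expect_identical(bed$V2, 99L)    # 100 -> 0-based 99
  expect_identical(bed$V3, 900L)   # inclusive end kept as half-open end
})
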