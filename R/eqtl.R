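#' Group significant SNPs by physical distance
#'
#' Single-linkage chaining: adjacent SNPs on the same chromosome whose
#' position difference is strictly below `gap_bp` join one cluster;
#' different chromosomes never join.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` (any extra columns
#'   carried through)
#' @param gap_bp chaining distance in bp
#' @return the input with an integer `cluster` column
#' @export
group_by_distance <- function(snps, gap_bp = 5000) {
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  n <- nrow(snps)
  if (!n) { snps$cluster <- integer(0); return(snps) }
  new_cluster <- c(TRUE, snps$chrom[-1] != snps$chrom[-n] |
                     diff(snps$pos) >= gap_bp)
  snps$cluster <- cumsum(new_cluster)
  rownames(snps) <- NULL
  snps
}

# elect the lead row of a cluster: min p, ties to larger partial_r2, then
# smaller position
elect_lead <- function(df) {
  ord <- order(df$p, -df$partial_r2, df$pos)
  df[ord[1], , drop = FALSE]
}

# squared dosage correlation between two SNP columns over samples
# non-missing in both; monomorphic pairs give 0
snp_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(0)
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) return(0)
  stats::cor(g1[ok], g2[ok])^2
}

# merge clusters transitively given a logical merge matrix (connected
# components); returns component index per cluster
components_of <- function(adj) {
  k <- nrow(adj)
  comp <- seq_len(k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (adj[i, j]) {
    ci <- comp[i]; cj <- comp[j]
    if (ci != cj) comp[comp == cj] <- ci
  }
  match(comp, unique(comp))
}

#' Merge distance-clusters that share an LD block
#'
#' Clusters whose lead SNPs are on the same chromosome within
#' `max_dist_bp` of each other and in LD (r-squared strictly above
#' `r2_min`, computed from dosage correlation over samples non-missing in
#' both) merge transitively; the merged cluster's lead is the overall most
#' significant SNP. Monomorphic leads have undefined r-squared, treated as
#' 0.
#'
#' @param snps output of [group_by_distance()] plus `p` and `partial_r2`
#'   columns
#' @param genotypes a `VariantTable` providing the dosages
#' @param r2_min LD threshold (exclusive)
#' @param max_dist_bp maximum lead-to-lead distance for a merge
#' @return the input with `cluster` relabeled after merging
#' @export
merge_by_ld <- function(snps, genotypes, r2_min = 0.1,
                        max_dist_bp = 250000) {
  if (!nrow(snps)) return(snps)
  leads <- do.call(rbind, lapply(split(snps, snps$cluster), elect_lead))
  k <- nrow(leads)
  if (k > 1) {
    g <- genotypes$calls[, match(leads$snp_id, genotypes$snps$snp_id),
                         drop = FALSE]
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (leads$chrom[i] != leads$chrom[j]) next
      if (abs(leads$pos[i] - leads$pos[j]) > max_dist_bp) next
      if (snp_r2(g[, i], g[, j]) > r2_min) adj[i, j] <- adj[j, i] <- TRUE
    }
    comp <- components_of(adj)
    snps$cluster <- comp[match(snps$cluster, leads$cluster)]
  } else snps$cluster <- 1L
  snps
}

#' Merge clusters whose leads fall inside the same gene body
#'
#' Lead-SNP gene containment is evaluated on 1-based inclusive gene bodies;
#' clusters whose leads lie inside the same gene merge (lead re-elected as
#' the overall most significant member).
#'
#' @param snps clustered SNP table (see [merge_by_ld()])
#' @param annotation a `GeneAnnotation`
#' @return the input with `cluster` relabeled after merging
#' @export
merge_by_gene <- function(snps, annotation) {
  if (!nrow(snps)) return(snps)
  leads <- do.call(rbind, lapply(split(snps, snps$cluster), elect_lead))
  host <- vapply(seq_len(nrow(leads)), function(i) {
    hit <- which(annotation$chrom == leads$chrom[i] &
                   annotation$start <= leads$pos[i] &
                   annotation$end >= leads$pos[i])
    if (length(hit)) annotation$gene_id[hit[1]] else NA_character_
  }, character(1))
  new_id <- ifelse(is.na(host), paste0("solo", seq_along(host)), host)
  comp <- match(new_id, unique(new_id))
  snps$cluster <- comp[match(snps$cluster, leads$cluster)]
  snps
}

#' Classify an eQTL as local or distant
#'
#' Local means the lead SNP lies on the etrait gene's chromosome within
#' the window `[start - window_bp, end + window_bp]` anchored on the gene
#' body; everything else is distant.
#'
#' @param lead_chrom,lead_pos lead SNP coordinates
#' @param gene_id etrait gene
#' @param annotation a `GeneAnnotation`
#' @param window_bp flanking window in bp
#' @return `"local"` or `"distant"`
#' @export
classify_locality <- function(lead_chrom, lead_pos, gene_id, annotation,
                              window_bp = 20000) {
  i <- match(gene_id, annotation$gene_id)
  if (is.na(i)) stop("etrait gene ", gene_id, " absent from annotation")
  if (lead_chrom == annotation$chrom[i] &&
      lead_pos >= annotation$start[i] - window_bp &&
      lead_pos <= annotation$end[i] + window_bp) "local" else "distant"
}

#' Consolidate scan results into eQTLs
#'
#' Applies the full consolidation chain per etrait gene and condition:
#' (0) keep only genome-wide significant SNPs (at each condition's BH
#' cutoff) and require at least `min_snps` of them per etrait-condition;
#' (1) chain SNPs closer than `gap_bp`; (2) merge clusters whose leads
#' share an LD block (r-squared above `r2_min` within `max_dist_bp`);
#' (3) merge clusters whose leads fall in the same gene body. The lead SNP
#' (minimum p, ties to larger partial r-squared then smaller position)
#' represents each eQTL, which is then classified local or distant.
#'
#' @param scans list of `eqtl_scan` objects (one per condition)
#' @param genotypes the scanned `VariantTable`
#' @param annotation a `GeneAnnotation`
#' @param min_snps minimum significant SNPs per etrait-condition
#' @param min_snps_scope `"etrait_condition"` applies `min_snps` before
#'   grouping (default); `"cluster"` applies it to each final cluster
#' @param gap_bp,r2_min,max_dist_bp,window_bp consolidation parameters
#' @return data.frame of class `eqtl_set`: one row per eQTL with columns
#'   `gene_id`, `condition`, `lead_snp`, `lead_chrom`, `lead_pos`,
#'   `lead_p`, `lead_r2`, `n_snps`, `members` (comma-joined snp_ids,
#'   position-sorted), `locality`, `resolved_gene`
#' @export
call_eqtls <- function(scans, genotypes, annotation, min_snps = 3,
                       min_snps_scope = c("etrait_condition", "cluster"),
                       gap_bp = 5000, r2_min = 0.1, max_dist_bp = 250000,
                       window_bp = 20000) {
  min_snps_scope <- match.arg(min_snps_scope)
  if (inherits(scans, "eqtl_scan")) scans <- list(scans)
  rows <- list()
  for (scan in scans) {
    sig <- scan$records[scan$records$p <= scan$threshold$cutoff, ,
                        drop = FALSE]
    if (!nrow(sig)) next
    for (gene in unique(sig$gene_id)) {
      gs <- sig[sig$gene_id == gene, , drop = FALSE]
      if (min_snps_scope == "etrait_condition" && nrow(gs) < min_snps)
        next
      gs <- group_by_distance(gs, gap_bp = gap_bp)
      gs <- merge_by_ld(gs, genotypes, r2_min = r2_min,
                        max_dist_bp = max_dist_bp)
      gs <- merge_by_gene(gs, annotation)
      for (cl in unique(gs$cluster)) {
        mem <- gs[gs$cluster == cl, , drop = FALSE]
        if (min_snps_scope == "cluster" && nrow(mem) < min_snps) next
        lead <- elect_lead(mem)
        host <- which(annotation$chrom == lead$chrom &
                        annotation$start <= lead$pos &
                        annotation$end >= lead$pos)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gene, condition = scan$condition,
          lead_snp = lead$snp_id, lead_chrom = lead$chrom,
          lead_pos = lead$pos, lead_p = lead$p,
          lead_r2 = lead$partial_r2, n_snps = nrow(mem),
          members = paste(mem$snp_id[order(mem$pos)], collapse = ","),
          locality = classify_locality(lead$chrom, lead$pos, gene,
                                       annotation, window_bp),
          resolved_gene = if (length(host)) annotation$gene_id[host[1]]
            else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), condition = character(0),
               lead_snp = character(0), lead_chrom = character(0),
               lead_pos = integer(0), lead_p = numeric(0),
               lead_r2 = numeric(0), n_snps = integer(0),
               members = character(0), locality = character(0),
               resolved_gene = character(0), stringsAsFactors = FALSE)
  class(out) <- c("eqtl_set", "data.frame")
  out
}

#' Classify per-etrait eQTL dynamics across conditions
#'
#' Groups each etrait's per-condition eQTLs into cross-condition loci
#' (lead SNPs within `gap_bp` of each other OR in LD with r-squared above
#' `r2_min` — the same tolerances used within a condition) and labels each
#' locus static (detected in every condition) or dynamic (one or two
#' conditions). `stress_only` flags loci detected under at least one
#' stress condition but not the reference (first) condition.
#'
#' @param eqtls an `eqtl_set` (see [call_eqtls()])
#' @param genotypes the `VariantTable` (for lead-SNP LD)
#' @param conditions all study conditions, reference first
#' @param gap_bp,r2_min cross-condition locus-identity tolerances
#' @return data.frame: `gene_id`, `locus_id`, `lead_snp`, `locality`,
#'   `conditions_detected` (comma-joined), `n_conditions`, `dynamics`,
#'   `stress_only`
#' @export
classify_dynamics <- function(eqtls, genotypes,
                              conditions = c("WW", "WS1", "WS2"),
                              gap_bp = 5000, r2_min = 0.1) {
  out <- list()
  for (gene in unique(eqtls$gene_id)) {
    ge <- eqtls[eqtls$gene_id == gene, , drop = FALSE]
    k <- nrow(ge)
    adj <- matrix(FALSE, k, k)
    if (k > 1) {
      g <- genotypes$calls[, match(ge$lead_snp, genotypes$snps$snp_id),
                           drop = FALSE]
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        same_chrom <- ge$lead_chrom[i] == ge$lead_chrom[j]
        near <- same_chrom && abs(ge$lead_pos[i] - ge$lead_pos[j]) < gap_bp
        linked <- same_chrom && snp_r2(g[, i], g[, j]) > r2_min
        if (near || linked) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    comp <- components_of(adj)
    for (cl in unique(comp)) {
      sub <- ge[comp == cl, , drop = FALSE]
      dets <- intersect(conditions, unique(sub$condition))
      lead <- sub[order(sub$lead_p), ][1, ]
      out[[length(out) + 1]] <- data.frame(
        gene_id = gene, locus_id = paste0(gene, "_L", cl),
        lead_snp = lead$lead_snp, locality = lead$locality,
        conditions_detected = paste(dets, collapse = ","),
        n_conditions = length(dets),
        dynamics = if (length(dets) == length(conditions)) "static"
          else "dynamic",
        stress_only = !(conditions[1] %in% dets) &&
          any(conditions[-1] %in% dets),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), locus_id = character(0),
               lead_snp = character(0), locality = character(0),
               conditions_detected = character(0),
               n_conditions = integer(0), dynamics = character(0),
               stress_only = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Summary table from static/dynamic x local/distant counts
#'
#' The count-and-percentage arithmetic used by [summarize_calls()],
#' exposed directly so published count tables can be fed through it.
#' Percentages are computed as 100 * part / whole and rounded half-up to
#' one decimal.
#'
#' @param static_local,dynamic_local,static_distant,dynamic_distant counts
#' @return data.frame with class totals and percentages
#' @export
summarize_counts <- function(static_local, dynamic_local, static_distant,
                             dynamic_distant) {
  local <- static_local + dynamic_local
  distant <- static_distant + dynamic_distant
  static <- static_local + static_distant
  dynamic <- dynamic_local + dynamic_distant
  total <- local + distant
  pct <- function(part, whole)
    if (whole > 0) round_half_up(100 * part / whole, 1) else 0
  data.frame(
    class = c("static", "dynamic", "local", "distant", "static_local",
              "dynamic_local", "static_distant", "dynamic_distant"),
    count = c(static, dynamic, local, distant, static_local,
              dynamic_local, static_distant, dynamic_distant),
    denominator = c(total, total, total, total, local, local, distant,
                    distant),
    percent = c(pct(static, total), pct(dynamic, total),
                pct(local, total), pct(distant, total),
                pct(static_local, local), pct(dynamic_local, local),
                pct(static_distant, distant),
                pct(dynamic_distant, distant)),
    stringsAsFactors = FALSE)
}

#' Summarize eQTL classifications
#'
#' Counts and percentages (one decimal, half-up) of static/dynamic by
#' local/distant over cross-condition loci, plus per-condition eQTL
#' counts.
#'
#' @param dynamics output of [classify_dynamics()]
#' @param eqtls the `eqtl_set` the dynamics were derived from
#' @return list: `by_class` (see [summarize_counts()]), `per_condition`
#'   (named counts), `n_loci`, `n_eqtls`
#' @export
summarize_calls <- function(dynamics, eqtls) {
  tab <- table(factor(dynamics$dynamics, c("static", "dynamic")),
               factor(dynamics$locality, c("local", "distant")))
  by_class <- summarize_counts(tab["static", "local"],
                               tab["dynamic", "local"],
                               tab["static", "distant"],
                               tab["dynamic", "distant"])
  per_condition <- table(eqtls$condition)
  list(by_class = by_class,
       per_condition = stats::setNames(as.integer(per_condition),
                                       names(per_condition)),
       n_loci = nrow(dynamics), n_eqtls = nrow(eqtls))
}

#' Export eQTL intervals as BED
#'
#' Each eQTL's member-SNP span (min to max member position) becomes one
#' BED record named by gene and condition (0-based half-open conversion at
#' the boundary).
#'
#' @param eqtls an `eqtl_set`
#' @param genotypes the `VariantTable` (member positions)
#' @param path output file
#' @return `path`, invisibly
#' @export
eqtl_bed <- function(eqtls, genotypes, path) {
  pos <- stats::setNames(genotypes$snps$pos, genotypes$snps$snp_id)
  spans <- t(vapply(strsplit(eqtls$members, ",", fixed = TRUE),
                    function(m) range(pos[m]), numeric(2)))
  write_bed(eqtls$lead_chrom, spans[, 1], spans[, 2],
            paste(eqtls$gene_id, eqtls$condition, sep = "|"), path,
            score = round(-log10(pmax(eqtls$lead_p, 1e-300)), 2))
  invisible(path)
}
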