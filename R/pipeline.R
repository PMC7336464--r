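#' Run the full eQTL analysis on a (simulated or real) study
#'
#' Chains the pipeline end to end: genotype QC (heterozygote resolution,
#' MAF/missingness filter), expression normalization (quantile + inverse
#' normal), structure covariates, hidden factors, the per-condition mixed
#' model scan, eQTL consolidation, cross-condition dynamics, and the
#' TF network.
#'
#' @param study list with elements `genotypes` (a `VariantTable`),
#'   `annotation` (a `GeneAnnotation`), `expression` (named list of
#'   `ExpressionSet`s) — the shape returned by
#'   [simulate_drought_study()]
#' @param n_pcs genotype principal components used as structure covariates
#' @param n_factors hidden expression factors per condition
#' @param kinship `"all"` builds the IBS kinship from every QC'd SNP
#'   (appropriate when the panel spans a single region or chromosome,
#'   where window thinning would leave too few SNPs and give each locus a
#'   large kinship share), `"thinned"` uses the 10-kb-window thinned set,
#'   `"none"` omits the random effect
#' @param fdr pooled within-condition BH target
#' @param min_snps minimum significant SNPs per etrait-condition
#' @return list of class `drought_analysis`: `genotypes` (QC'd),
#'   `expression` (transformed sets), `covariates`, `factors`, `scans`,
#'   `eqtls`, `dynamics`, `network`, `summary`
#' @export
run_study_analysis <- function(study, n_pcs = 3, n_factors = 14,
                               kinship = c("all", "thinned", "none"),
                               fdr = 0.05, min_snps = 3) {
  kinship <- match.arg(kinship)
  vt <- filter_snps(resolve_heterozygotes(study$genotypes))
  K <- switch(kinship,
              all = kinship_ibs(vt),
              thinned = kinship_ibs(vt, thin_snps_by_window(vt)),
              none = NULL)
  pcs <- structure_covariates(vt, n_pc = n_pcs)
  scans <- list(); ess <- list(); facs <- list()
  for (cond in names(study$expression)) {
    es <- inverse_normal_transform(quantile_normalize(
      study$expression[[cond]]))
    fac <- hidden_factors(es, k = n_factors, covariates = pcs)
    scans[[cond]] <- eqtl_scan(vt, es, covariates = pcs, factors = fac,
                               kinship = K, fdr = fdr)
    ess[[cond]] <- es
    facs[[cond]] <- fac
  }
  eqtls <- call_eqtls(scans, vt, study$annotation, min_snps = min_snps)
  dynamics <- classify_dynamics(eqtls, vt,
                                conditions = names(study$expression))
  network <- resolve_eqtls_to_tfs(eqtls, study$annotation)
  structure(list(genotypes = vt, expression = ess, covariates = pcs,
                 factors = facs, scans = scans, eqtls = eqtls,
                 dynamics = dynamics, network = network,
                 summary = summarize_calls(dynamics, eqtls)),
            class = "drought_analysis")
}

#' @export
print.drought_analysis <- function(x, ...) {
  cat("Drought eQTL analysis:", nrow(x$eqtls), "eQTLs over",
      length(unique(x$eqtls$gene_id)), "etraits;",
      nrow(x$dynamics), "cross-condition loci;",
      nrow(x$network), "TF network edges\n")
  invisible(x)
}

#' Score recovery of the planted regulatory architecture
#'
#' Compares an analysis of a simulated study against its truth ledger:
#' a planted local effect counts as recovered when a local eQTL for the
#' gene is called with a lead SNP within 20 kb of the causal SNP (in any
#' condition); its dynamics label is correct when the cross-condition
#' locus matches the planted activity (static iff active in every
#' condition). Network edges are scored per (regulator, target) pair.
#'
#' @param sim a [simulate_drought_study()] result
#' @param analysis the [run_study_analysis()] result for it
#' @return list: `local_recovered`, `static_correct`, `dynamic_correct`,
#'   `label_correct`, `edge_precision`, `edge_recall`, plus raw counts
#' @export
score_recovery <- function(sim, analysis) {
  tr <- sim$truth$effects
  loc <- tr[tr$kind == "local", , drop = FALSE]
  pos <- stats::setNames(analysis$genotypes$snps$pos,
                         analysis$genotypes$snps$snp_id)
  all_conds <- names(sim$expression)
  planted_static <- vapply(strsplit(loc$conditions, ",", fixed = TRUE),
                           function(v) length(v) == length(all_conds),
                           logical(1))
  eq <- analysis$eqtls
  dyn <- analysis$dynamics
  recovered <- label <- rep(NA, nrow(loc))
  for (i in seq_len(nrow(loc))) {
    called <- eq[eq$gene_id == loc$gene[i] & eq$locality == "local", ,
                 drop = FALSE]
    near <- nrow(called) > 0 && !is.na(pos[loc$snp[i]]) &&
      any(abs(pos[called$lead_snp] - pos[loc$snp[i]]) <= 20000)
    recovered[i] <- near
    if (near) {
      d <- dyn[dyn$gene_id == loc$gene[i] & dyn$locality == "local", ,
               drop = FALSE]
      got <- if (nrow(d)) d$dynamics[which.max(d$n_conditions)] else NA
      label[i] <- identical(got, if (planted_static[i]) "static"
                            else "dynamic")
    } else label[i] <- FALSE
  }
  truedist <- tr[tr$kind == "distant", , drop = FALSE]
  truekey <- paste(truedist$regulator, truedist$gene)
  callkey <- paste(analysis$network$regulator, analysis$network$target)
  list(local_recovered = mean(recovered),
       static_correct = if (any(planted_static))
         mean(label[planted_static]) else NA_real_,
       dynamic_correct = if (any(!planted_static))
         mean(label[!planted_static]) else NA_real_,
       label_correct = mean(label),
       edge_precision = if (length(callkey))
         mean(callkey %in% truekey) else NA_real_,
       edge_recall = if (length(truekey))
         mean(truekey %in% callkey) else NA_real_,
       n_planted_local = nrow(loc),
       n_planted_static = sum(planted_static),
       n_planted_distant = nrow(truedist),
       n_called_eqtls = nrow(eq), n_called_edges = length(callkey),
       n_true_edges_called = sum(callkey %in% truekey))
}
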