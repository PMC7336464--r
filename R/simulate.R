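#' Simulation configuration
#'
#' Bundles every knob of the synthetic drought-study generator. Defaults
#' emulate the structure of a diverse inbred maize association panel: three
#' ancestral subpopulations, LD decaying on a ~1.6 kb scale, MAF drawn
#' above 0.05, three water regimes (WW, WS1, WS2), local (within 20 kb) and
#' TF-mediated distant expression effects of which ~27% are constitutive
#' (active in all conditions) and the rest condition-activated, 14 hidden
#' confounding factors, and a phenotype linearly mediated by a subset of
#' gene expressions under the severe-stress condition.
#'
#' @param n_samples,n_snps,n_genes panel dimensions
#' @param n_subpops number of ancestral subpopulations
#' @param fst Balding-Nichols differentiation between subpopulations
#' @param maf_range range of ancestral allele frequencies
#' @param ld_decay_bp distance scale of LD decay (copying-process scale)
#' @param snp_spacing_bp mean spacing between adjacent SNPs
#' @param gene_length_bp length of each (tiled) gene body
#' @param conditions condition labels, first is the unstressed reference
#' @param n_local_eqtl,n_distant_eqtl planted causal effect counts
#' @param n_tf_genes genes flagged as transcription factors
#' @param frac_static share of causal effects active in every condition
#' @param effect_r2_range variance fraction a planted local effect explains
#' @param distant_r2_range variance fraction a planted distant (TF-mediated)
#'   effect contributes to its target, on the mediator scale; defaults to
#'   `effect_r2_range`
#' @param n_hidden_factors hidden confounders per condition
#' @param factor_sd scale of the (sparse, 80% zero) factor loadings
#' @param polygenic_var variance of an infinitesimal structured genetic
#'   background per gene (0 disables; used for calibration studies)
#' @param condition_shift_sd scale of per-gene drought-response shifts
#'   (monotone over the stress gradient) applied to a `frac_responsive`
#'   share of genes
#' @param frac_responsive share of genes with a condition main effect
#' @param n_phenotype_genes expression traits mediating the phenotype
#' @param phenotype_effects optional numeric vector of mediation
#'   coefficients (length `n_phenotype_genes`); drawn U(0.3, 0.8) with
#'   random sign when `NULL`
#' @param noise_sd residual SD for expression (and, by default, the
#'   phenotype)
#' @param pheno_noise_sd residual SD of the phenotype; defaults to
#'   `noise_sd`
#' @param het_rate,missing_rate genotype heterozygote / missing-call rates
#' @param seed RNG seed (mandatory)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_samples = 200, n_snps = 2000, n_genes = 50,
                       n_subpops = 3, fst = 0.1, maf_range = c(0.05, 0.5),
                       ld_decay_bp = 1600, snp_spacing_bp = 250,
                       gene_length_bp = 4000,
                       conditions = c("WW", "WS1", "WS2"),
                       n_local_eqtl = 10, n_distant_eqtl = 10,
                       n_tf_genes = max(2L, round(0.1 * n_genes)),
                       frac_static = 0.27,
                       effect_r2_range = c(0.05, 0.4),
                       distant_r2_range = effect_r2_range,
                       n_hidden_factors = 14, factor_sd = 0.3,
                       polygenic_var = 0, condition_shift_sd = 0.5,
                       frac_responsive = 0.3,
                       n_phenotype_genes = 3, phenotype_effects = NULL,
                       noise_sd = 0.5, pheno_noise_sd = noise_sd,
                       het_rate = 0.01, missing_rate = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(n_samples > 0, n_snps > 0, n_genes > 0, n_subpops > 0,
            fst > 0, fst < 1,
            all(effect_r2_range > 0), all(effect_r2_range < 1),
            all(distant_r2_range > 0), all(distant_r2_range < 1),
            frac_static >= 0, frac_static <= 1, length(conditions) >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate structured genotypes and a tiled gene annotation
#'
#' Draws a single-chromosome inbred panel under the Balding-Nichols model:
#' ancestral allele frequencies are uniform on `maf_range`, subpopulation
#' frequencies are Beta-distributed around them with differentiation `fst`,
#' and samples are split evenly over subpopulations. Within-chromosome LD
#' comes from a haplotype copying process: each SNP's latent uniform is
#' copied from its left neighbour with probability `exp(-d / ld_decay_bp)`
#' (d the inter-SNP distance), so expected r-squared decays on the
#' `ld_decay_bp` scale. Samples are inbred (calls 0/2) apart from a small
#' heterozygote rate; missing calls are injected uniformly. Genes are tiled
#' evenly along the chromosome; `n_tf_genes` random genes carry a TF family
#' label.
#'
#' @param config a [sim_config()]
#' @return list with elements `genotypes` (a `VariantTable`), `annotation`
#'   (a `GeneAnnotation`) and `subpop` (integer subpopulation per sample)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; p <- config$n_snps
  if (p < 5 * (config$n_local_eqtl + config$n_distant_eqtl))
    stop("n_snps too small to host the requested eQTLs")
  chrom_len <- p * config$snp_spacing_bp
  pos <- sort(sample.int(chrom_len, p))
  subpop <- rep(seq_len(config$n_subpops), length.out = n)
  # ancestral frequencies and subpopulation deviations are autocorrelated
  # along the chromosome (shared genealogy makes nearby loci
  # frequency-coherent; without this the haplotype copying below cannot
  # produce realistic local r^2). The frequency process decorrelates on a
  # slower scale than the copying process.
  ar1 <- function(scale_bp) {
    rho <- exp(-diff(pos) / scale_bp)
    z <- numeric(p)
    z[1] <- stats::rnorm(1)
    innov <- stats::rnorm(p - 1)
    for (j in 2:p)
      z[j] <- rho[j - 1] * z[j - 1] + sqrt(1 - rho[j - 1]^2) * innov[j - 1]
    z
  }
  p_anc <- config$maf_range[1] +
    diff(config$maf_range) * stats::pnorm(ar1(4 * config$ld_decay_bp))
  fst <- config$fst
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  # Balding-Nichols marginals through spatially coherent latents
  p_sub <- matrix(0, config$n_subpops, p)
  for (s in seq_len(config$n_subpops))
    p_sub[s, ] <- stats::qbeta(stats::pnorm(ar1(4 * config$ld_decay_bp)),
                               a, b)
  # haplotype copying: latent uniforms shared along the chromosome; the
  # copy probability uses scale 2 x ld_decay_bp so that r^2 (roughly the
  # squared copy correlation) decays on the ld_decay_bp scale itself
  u <- matrix(stats::runif(n * p), n, p)
  keep_prob <- exp(-diff(pos) / (2 * config$ld_decay_bp))
  for (j in 2:p) {
    k <- stats::runif(n) < keep_prob[j - 1]
    u[k, j] <- u[k, j - 1]
  }
  freq <- p_sub[subpop, , drop = FALSE]          # n x p
  calls <- matrix(0L, n, p)
  calls[u < freq] <- 2L                           # inbred: hom alt
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * p) < config$het_rate, n, p)
    calls[het] <- 1L
  }
  if (config$missing_rate > 0) {
    mis <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
    calls[mis] <- NA_integer_
  }
  samples <- sprintf("S%03d", seq_len(n))
  rownames(calls) <- samples
  vt <- variant_table(
    data.frame(snp_id = sprintf("snp%05d", seq_len(p)), chrom = "chr1",
               pos = pos, ref = "A", alt = "G", stringsAsFactors = FALSE),
    calls, samples)
  # evenly tiled gene bodies
  ng <- config$n_genes
  starts <- round(seq(1, chrom_len - config$gene_length_bp,
                      length.out = ng))
  ann <- gene_annotation(
    gene_id = sprintf("gene%04d", seq_len(ng)), chrom = "chr1",
    start = starts, end = starts + config$gene_length_bp - 1L,
    strand = rep(c("+", "-"), length.out = ng))
  tf_pool <- c("bZIP", "NAC", "AP2-EREBP", "WRKY", "MYB", "HB", "C2H2",
               "TCP", "C3H", "AUX-IAA")
  tf_idx <- sample.int(ng, min(config$n_tf_genes, ng))
  ann$is_tf[tf_idx] <- TRUE
  ann$tf_family[tf_idx] <- sample(tf_pool, length(tf_idx), replace = TRUE)
  list(genotypes = vt, annotation = ann, subpop = subpop)
}

# draw the condition-activity set of one causal effect
draw_activity <- function(conditions, frac_static) {
  if (stats::runif(1) < frac_static) return(conditions)
  k <- sample(1:min(2L, length(conditions)), 1)
  sample(conditions, k)
}

#' Simulate per-condition expression with a known regulatory architecture
#'
#' Per gene g and condition c the log-abundance is
#' baseline + condition shift + local SNP effects + distant effects
#' transmitted through the regulating TF's own simulated expression +
#' sparse hidden-factor loadings x factor scores + Gaussian noise
#' (+ optionally an infinitesimal structured polygenic background);
#' abundance is its exponential. Local effects are anchored on a SNP within
#' 20 kb of the gene (TF regulators get their causal SNP inside the gene
#' body so distant signals resolve to the TF). Effects are constitutive
#' with probability `frac_static`, otherwise active in a random 1-2
#' condition subset. Effect sizes are calibrated so a planted effect
#' explains the configured variance fraction of its gene's non-genetic
#' variance budget. Every planted effect is written to the truth ledger.
#'
#' @param geno result of [simulate_genotypes()]
#' @param config the same [sim_config()]
#' @return list: `expression` (named list of `ExpressionSet` per condition),
#'   `truth` (data.frame ledger), `factors` (true factor scores per
#'   condition)
#' @export
simulate_expression <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  vt <- geno$genotypes; ann <- geno$annotation
  n <- n_samples(vt); ng <- nrow(ann); conds <- config$conditions
  dose <- dosage_imputed(vt)
  pos <- vt$snps$pos

  tf_genes <- ann$gene_id[ann$is_tf]
  n_reg <- min(length(tf_genes), max(1L, ceiling(config$n_distant_eqtl / 4)))
  regulators <- if (config$n_distant_eqtl > 0)
    sample(tf_genes, n_reg) else character(0)

  # local eQTL genes: regulators first (causal SNP inside the body), rest
  # drawn from the remaining genes with any SNP within 20 kb
  pick_snp <- function(gene, inside_only = FALSE) {
    g <- ann[ann$gene_id == gene, ]
    win <- if (inside_only) c(g$start, g$end) else
      c(g$start - 20000L, g$end + 20000L)
    cand <- which(pos >= win[1] & pos <= win[2])
    if (!length(cand) && inside_only)            # fall back to the window
      cand <- which(pos >= g$start - 20000L & pos <= g$end + 20000L)
    if (!length(cand)) return(NA_integer_)
    # prefer causal variants that are taggable: at least two nearby SNPs
    # in strong LD (r^2 >= 0.5), mirroring the survivorship built into
    # reported eQTLs, which are conditioned on multi-SNP support
    n_tags <- vapply(cand, function(s) {
      near <- which(abs(pos - pos[s]) <= 2 * config$ld_decay_bp)
      near <- setdiff(near, s)
      if (!length(near)) return(0L)
      r2 <- suppressWarnings(
        stats::cor(dose[, near, drop = FALSE], dose[, s]))^2
      sum(r2 >= 0.5, na.rm = TRUE)
    }, integer(1))
    tagged <- cand[n_tags >= 2L]
    if (length(tagged)) cand <- tagged
    cand[which.max(apply(dose[, cand, drop = FALSE], 2, stats::var))]
  }
  n_extra <- max(0L, config$n_local_eqtl - length(regulators))
  others <- setdiff(ann$gene_id, regulators)
  local_genes <- c(regulators,
                   if (n_extra > 0) sample(others, min(n_extra, length(others))))
  local_snp <- integer(0)
  kept <- character(0)
  for (g in local_genes) {
    s <- NA_integer_
    for (attempt in 1:100) {
      s <- pick_snp(g, inside_only = g %in% regulators)
      if (!is.na(s)) break
      g <- sample(setdiff(others, kept), 1)
    }
    if (is.na(s)) stop("no SNP within 20 kb of gene ", g,
                       " after 100 attempts")
    kept <- c(kept, g); local_snp <- c(local_snp, s)
  }
  local_genes <- kept

  # distant targets are disjoint from local-eQTL genes so each planted
  # effect has an unambiguous recovery signature
  targets <- if (config$n_distant_eqtl > 0)
    sample(setdiff(ann$gene_id, c(regulators, local_genes)),
           config$n_distant_eqtl)
    else character(0)
  target_reg <- if (length(targets))
    regulators[rep_len(seq_along(regulators), length(targets))]
    else character(0)

  # loadings: sparse, shared across conditions
  k <- config$n_hidden_factors
  lam <- matrix(0, ng, max(k, 1))
  if (k > 0) {
    nz <- matrix(stats::runif(ng * k) > 0.8, ng, k)
    lam[nz] <- stats::rnorm(sum(nz), 0, config$factor_sd)
  }
  v_factor <- rowSums(lam^2)
  v_env <- v_factor + config$noise_sd^2 + config$polygenic_var

  baseline <- stats::rnorm(ng, log(5), 0.5)
  responsive <- stats::runif(ng) < config$frac_responsive
  delta <- ifelse(responsive, stats::rnorm(ng, 0, config$condition_shift_sd), 0)
  stress_level <- seq(0, length(conds) - 1)       # 0, 1, 2 over the gradient
  names(stress_level) <- conds

  # calibrated effect draws -> ledger
  gi <- match(local_genes, ann$gene_id)
  r2_loc <- stats::runif(length(local_genes), config$effect_r2_range[1],
                         config$effect_r2_range[2])
  # regulator TFs behave like eQTL hotspots: constitutive cis-regulation
  # from the upper half of the effect range, so the mediated distant
  # signal exists in every condition the distant link is active in
  is_reg <- local_genes %in% regulators
  if (any(is_reg))
    r2_loc[is_reg] <- stats::runif(sum(is_reg),
                                   mean(config$effect_r2_range),
                                   config$effect_r2_range[2])
  vg <- apply(dose[, local_snp, drop = FALSE], 2, stats::var)
  beta_loc <- sqrt(r2_loc / (1 - r2_loc) * v_env[gi] / pmax(vg, 1e-8))
  act_loc <- lapply(seq_along(local_genes), function(i)
    if (is_reg[i]) conds else draw_activity(conds, config$frac_static))

  ti <- match(targets, ann$gene_id)
  r2_dis <- if (length(targets))
    stats::runif(length(targets), config$distant_r2_range[1],
                 config$distant_r2_range[2]) else numeric(0)
  beta_dis <- if (length(targets))
    sqrt(r2_dis / (1 - r2_dis) * v_env[ti]) else numeric(0)
  act_dis <- lapply(seq_along(targets), function(i)
    draw_activity(conds, config$frac_static))

  poly_b <- if (config$polygenic_var > 0)
    matrix(stats::rnorm(ncol(dose) * ng), ncol(dose), ng) else NULL
  dose_std <- if (config$polygenic_var > 0)
    scale(dose)[, , drop = FALSE] else NULL
  if (!is.null(dose_std)) dose_std[is.na(dose_std)] <- 0

  sets <- list(); fac_list <- list()
  for (cond in conds) {
    logx <- matrix(rep(baseline + delta * stress_level[cond], each = n),
                   n, ng)
    # local genetic effects
    for (i in seq_along(local_genes)) {
      if (!(cond %in% act_loc[[i]])) next
      logx[, gi[i]] <- logx[, gi[i]] + beta_loc[i] * dose[, local_snp[i]]
    }
    if (!is.null(poly_b))
      logx <- logx + (dose_std %*% poly_b) *
        sqrt(config$polygenic_var / ncol(dose))
    fac <- if (k > 0) matrix(stats::rnorm(n * k), n, k) else
      matrix(0, n, 0)
    if (k > 0) logx <- logx + fac %*% t(lam[, seq_len(k), drop = FALSE])
    logx <- logx + matrix(stats::rnorm(n * ng, 0, config$noise_sd), n, ng)
    # distant effects mediated by the regulator TF's expression
    for (i in seq_along(targets)) {
      if (!(cond %in% act_dis[[i]])) next
      reg_x <- logx[, match(target_reg[i], ann$gene_id)]
      logx[, ti[i]] <- logx[, ti[i]] + beta_dis[i] *
        as.numeric(scale(reg_x))
    }
    ab <- t(exp(logx))
    rownames(ab) <- ann$gene_id; colnames(ab) <- vt$sample_ids
    sets[[cond]] <- expression_set(cond, ab)
    fac_list[[cond]] <- fac
  }

  truth <- rbind(
    if (length(local_genes)) data.frame(
      kind = "local", gene = local_genes,
      snp = vt$snps$snp_id[local_snp], regulator = NA_character_,
      conditions = vapply(act_loc, paste, "", collapse = ","),
      r2 = r2_loc, beta = beta_loc, stringsAsFactors = FALSE),
    if (length(targets)) data.frame(
      kind = "distant", gene = targets, snp = vt$snps$snp_id[
        local_snp[match(target_reg, local_genes)]],
      regulator = target_reg,
      conditions = vapply(act_dis, paste, "", collapse = ","),
      r2 = r2_dis, beta = beta_dis, stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(kind = character(0), gene = character(0),
                        snp = character(0), regulator = character(0),
                        conditions = character(0), r2 = numeric(0),
                        beta = numeric(0), stringsAsFactors = FALSE)
  list(expression = sets, truth = truth, factors = fac_list)
}

#' Simulate an expression-mediated phenotype
#'
#' The phenotype (emulating seedling survival rate under drought) is a
#' linear combination of a few genes' transformed expression under the most
#' severe condition, plus Gaussian noise, affinely mapped into \[0,1\].
#' The ledger records both the raw coefficients and the realized slopes
#' after the affine mapping (the slopes actually present in the returned
#' vector, which recovery checks should target).
#'
#' @param expr result of [simulate_expression()]
#' @param config the same [sim_config()]
#' @return list: `phenotype` (a `PhenotypeVector`), `truth` (data.frame with
#'   columns gene, raw_effect, effect)
#' @export
simulate_phenotype <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  cond <- config$conditions[length(config$conditions)]
  es <- expr$expression[[cond]]
  es <- inverse_normal_transform(quantile_normalize(es))
  x <- es$transformed
  genes <- sample(rownames(x), config$n_phenotype_genes)
  if (!all(genes %in% rownames(x))) stop("phenotype gene not in expression set")
  cg <- config$phenotype_effects
  if (is.null(cg))
    cg <- stats::runif(length(genes), 0.3, 0.8) *
      sample(c(-1, 1), length(genes), replace = TRUE)
  if (length(cg) != length(genes))
    stop("phenotype_effects length must equal n_phenotype_genes")
  y <- drop(cg %*% x[genes, , drop = FALSE]) +
    stats::rnorm(ncol(x), 0, config$pheno_noise_sd)
  rng <- range(y)
  scale_fac <- if (diff(rng) > 0) 1 / diff(rng) else 0
  y01 <- if (scale_fac > 0) (y - rng[1]) * scale_fac else rep(0.5, length(y))
  list(phenotype = phenotype_vector(y01, colnames(x)),
       truth = data.frame(gene = genes, raw_effect = cg,
                          effect = cg * scale_fac, stringsAsFactors = FALSE))
}

#' Run the full synthetic drought study
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_expression()] and [simulate_phenotype()].
#'
#' @param config a [sim_config()]
#' @return list with `genotypes`, `annotation`, `subpop`, `expression`
#'   (list of `ExpressionSet`), `phenotype`, `truth` (list: `effects`,
#'   `phenotype`), `factors`
#' @export
simulate_drought_study <- function(config) {
  geno <- simulate_genotypes(config)
  expr <- simulate_expression(geno, config)
  phen <- simulate_phenotype(expr, config)
  list(genotypes = geno$genotypes, annotation = geno$annotation,
       subpop = geno$subpop, expression = expr$expression,
       phenotype = phen$phenotype,
       truth = list(effects = expr$truth, phenotype = phen$truth),
       factors = expr$factors)
}

#' Write a simulated study to disk
#'
#' Emits VCF, GFF3, one abundance TSV per condition, a phenotype TSV and
#' the truth-ledger TSVs under `dir`.
#'
#' @param sim result of [simulate_drought_study()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_gff3(sim$annotation, file.path(dir, "genes.gff3"))
  for (cond in names(sim$expression))
    write_table(sim$expression[[cond]]$abundance,
                file.path(dir, paste0("expression_", cond, ".tsv")),
                id_col = "gene_id")
  write_table(data.frame(sample_id = names(sim$phenotype),
                         value = as.numeric(sim$phenotype)),
              file.path(dir, "phenotype.tsv"))
  write_table(sim$truth$effects, file.path(dir, "truth_effects.tsv"))
  write_table(sim$truth$phenotype, file.path(dir, "truth_phenotype.tsv"))
  invisible(dir)
}
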