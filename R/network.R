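#' Resolve distant eQTLs to TF-target network edges
#'
#' Every distant eQTL whose lead SNP lies inside a transcription-factor
#' gene body yields a directed edge TF -> etrait (self-edges excluded).
#' Edges are deduplicated per (regulator, target) with condition sets
#' unioned; a lead inside two overlapping TF genes yields both edges with
#' a warning.
#'
#' @param eqtls an `eqtl_set` (see [call_eqtls()])
#' @param annotation a `GeneAnnotation` with `is_tf`/`tf_family`
#' @return data.frame of class `eqtl_network`: `regulator`, `target`,
#'   `regulator_family`, `conditions` (comma-joined), `n_eqtls`
#' @export
resolve_eqtls_to_tfs <- function(eqtls, annotation) {
  dist <- eqtls[eqtls$locality == "distant", , drop = FALSE]
  tfs <- annotation[annotation$is_tf, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(dist))) {
    hit <- which(tfs$chrom == dist$lead_chrom[i] &
                   tfs$start <= dist$lead_pos[i] &
                   tfs$end >= dist$lead_pos[i])
    if (length(hit) > 1)
      warning("lead SNP ", dist$lead_snp[i], " inside ", length(hit),
              " overlapping TF genes; emitting all edges")
    for (h in hit) {
      if (tfs$gene_id[h] == dist$gene_id[i]) next
      rows[[length(rows) + 1]] <- data.frame(
        regulator = tfs$gene_id[h], target = dist$gene_id[i],
        regulator_family = tfs$tf_family[h],
        conditions = dist$condition[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(regulator = character(0), target = character(0),
                      regulator_family = character(0),
                      conditions = character(0), n_eqtls = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("eqtl_network", "data.frame")
    return(out)
  }
  e <- do.call(rbind, rows)
  key <- paste(e$regulator, e$target)
  agg <- lapply(split(e, key), function(d) data.frame(
    regulator = d$regulator[1], target = d$target[1],
    regulator_family = d$regulator_family[1],
    conditions = paste(sort(unique(unlist(
      strsplit(d$conditions, ",", fixed = TRUE)))), collapse = ","),
    n_eqtls = nrow(d), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  class(out) <- c("eqtl_network", "data.frame")
  out
}

#' Hierarchy height per TF node
#'
#' For each regulator TF, the out-degree O counts its TF -> target edges
#' and the in-degree I counts edges whose target is this TF (regulation of
#' a TF by another TF). The height is h = (O - I) / (O + I), in \[-1, 1\]:
#' +1 for a pure source, -1 for a TF that only receives regulation.
#' Nodes with O + I = 0 are excluded.
#'
#' @param edges an `eqtl_network` (see [resolve_eqtls_to_tfs()])
#' @param by `"gene"` scores each TF gene; `"family"` aggregates O and I
#'   over family members before computing h
#' @return data.frame of class `HierarchyScore`: `node`, `out_degree`,
#'   `in_degree`, `height`
#' @export
hierarchy_height <- function(edges, by = c("gene", "family")) {
  by <- match.arg(by)
  if (by == "family") {
    fam <- stats::setNames(edges$regulator_family, edges$regulator)
    reg <- edges$regulator_family
    tgt <- ifelse(edges$target %in% names(fam),
                  fam[edges$target], NA_character_)
    nodes <- unique(reg)
  } else {
    reg <- edges$regulator
    tgt <- edges$target
    nodes <- unique(reg)
  }
  O <- vapply(nodes, function(nd) sum(reg == nd), 0L)
  I <- vapply(nodes, function(nd) sum(!is.na(tgt) & tgt == nd), 0L)
  keep <- (O + I) > 0
  out <- data.frame(node = nodes[keep], out_degree = O[keep],
                    in_degree = I[keep],
                    height = (O[keep] - I[keep]) / (O[keep] + I[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("HierarchyScore", "data.frame")
  out
}

#' Assign hierarchy tiers
#'
#' Heights are min-max normalized to \[0, 1\] and cut into `n_tiers`
#' equal-width bands: tier 1 is the top band (master regulators), the last
#' tier the bottom. If all heights are equal every node lands in the
#' middle tier with a warning. A quantile mode (equal-count tiers) is
#' available as an alternative interpretation.
#'
#' @param scores a `HierarchyScore` (see [hierarchy_height()])
#' @param n_tiers number of tiers
#' @param mode `"width"` for equal-width bands of normalized height,
#'   `"quantile"` for equal-count bands
#' @return the input with `height_norm` and integer `tier` columns
#' @export
assign_tiers <- function(scores, n_tiers = 3,
                         mode = c("width", "quantile")) {
  mode <- match.arg(mode)
  h <- scores$height
  if (!length(h)) stop("no scored nodes")
  rng <- range(h)
  if (diff(rng) == 0) {
    warning("all hierarchy heights equal; assigning the middle tier")
    scores$height_norm <- rep(0.5, length(h))
    scores$tier <- rep(as.integer(ceiling(n_tiers / 2)), length(h))
    return(scores)
  }
  hn <- (h - rng[1]) / diff(rng)
  scores$height_norm <- hn
  if (mode == "width") {
    # equal-width bands counted from the bottom: [2/3, 1] -> tier 1,
    # [1/3, 2/3) -> tier 2, [0, 1/3) -> tier 3 (for n_tiers = 3)
    band <- n_tiers - pmin(floor(hn * n_tiers), n_tiers - 1L)
  } else {
    qs <- stats::quantile(hn, probs = seq(0, 1, length.out = n_tiers + 1))
    band <- n_tiers + 1L -
      as.integer(cut(hn, breaks = unique(qs), include.lowest = TRUE))
    band <- pmin(pmax(band, 1L), n_tiers)
  }
  scores$tier <- as.integer(band)
  scores
}

#' Export the regulatory network
#'
#' Writes a deterministic edge-list TSV, a node-score TSV and a GraphML
#' file (tier and condition attributes attached) under `path_prefix`.
#'
#' @param edges an `eqtl_network`
#' @param scores tiered `HierarchyScore` (gene-level), or `NULL`
#' @param path_prefix file prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_scores.tsv` and `<prefix>.graphml`
#' @return named character vector of the written paths, invisibly
#' @export
export_network <- function(edges, scores = NULL, path_prefix) {
  p_edges <- paste0(path_prefix, "_edges.tsv")
  p_scores <- paste0(path_prefix, "_scores.tsv")
  p_graphml <- paste0(path_prefix, ".graphml")
  write_table(as.data.frame(edges), p_edges)
  if (!is.null(scores)) write_table(as.data.frame(scores), p_scores)
  nodes <- sort(unique(c(edges$regulator, edges$target)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$regulator, nodes),
                                    match(edges$target, nodes)))
    g <- igraph::set_edge_attr(g, "conditions", value = edges$conditions)
  }
  if (!is.null(scores) && nrow(scores)) {
    tier <- scores$tier[match(nodes, scores$node)]
    g <- igraph::set_vertex_attr(g, "tier",
                                 value = ifelse(is.na(tier), 0L, tier))
  }
  igraph::write_graph(g, p_graphml, format = "graphml")
  invisible(c(edges = p_edges, scores = p_scores, graphml = p_graphml))
}
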