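# Condition-specific module detection on a functional-interaction network:
# edges weighted by expression correlation within a condition, weighted
# community detection, size / average-PCC filtering, signature enrichment
# and cross-condition pairing by shared signature genes.

#' Weight network edges by Pearson correlation within a condition
#'
#' Every edge whose two endpoint genes are measured gets weight = Pearson
#' correlation of the two genes' log2 values across the condition samples;
#' edges with an unmeasured endpoint are dropped (count messaged). A
#' zero-variance gene contributes weight 0 with a warning.
#'
#' @param net igraph network over genes.
#' @param expr An `expr_matrix`.
#' @param condition_samples Character vector of >= 3 sample ids.
#' @return The network with a `weight` edge attribute in \[-1, 1\].
#' @export
pcc_weight_edges <- function(net, expr, condition_samples) {
  condition_samples <- intersect(condition_samples, colnames(expr$values))
  if (length(condition_samples) < 3)
    stop("need at least 3 condition samples")
  X <- expr$values[, condition_samples, drop = FALSE]
  measured <- rownames(X)
  ev <- igraph::ends(net, igraph::E(net))
  keep <- ev[, 1] %in% measured & ev[, 2] %in% measured
  if (any(!keep))
    message(sum(!keep), " edge(s) with unmeasured endpoint dropped")
  net <- igraph::delete_edges(net, igraph::E(net)[!keep])
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) {
    igraph::E(net)$weight <- numeric(0)
    return(net)
  }
  Xc <- X - rowMeans(X)
  ss <- sqrt(rowSums(Xc^2))
  zero_var <- ss == 0
  if (any(zero_var[unique(as.vector(ev))]))
    warning("zero-variance gene(s); their edges weighted 0")
  num <- rowSums(Xc[ev[, 1], , drop = FALSE] * Xc[ev[, 2], , drop = FALSE])
  den <- ss[ev[, 1]] * ss[ev[, 2]]
  w <- ifelse(den > 0, num / den, 0)
  igraph::E(net)$weight <- pmin(1, pmax(-1, w))
  net
}

# avg_pcc over a module's internal edges (raw signed weights)
module_avg_pcc <- function(net, genes) {
  sub <- igraph::induced_subgraph(net, intersect(genes, igraph::V(net)$name))
  w <- igraph::E(sub)$weight
  if (!length(w)) return(NA_real_)
  mean(w)
}

new_gene_module <- function(module_id, condition, genes, avg_pcc,
                            enrichment_p = NA_real_,
                            shared_genes = character()) {
  structure(list(module_id = module_id, condition = condition,
                 genes = sort(genes), avg_pcc = avg_pcc,
                 enrichment_p = enrichment_p, shared_genes = shared_genes),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("<gene_module> %s [%s]: %d genes, avg PCC %.3f%s\n",
              x$module_id, x$condition, length(x$genes), x$avg_pcc,
              if (!is.na(x$enrichment_p))
                sprintf(", enrichment p %.3g", x$enrichment_p) else ""))
  invisible(x)
}

#' Detect expression-coherent modules by weighted community detection
#'
#' Correlation weights are mapped to \[0, 1\] via (w + 1) / 2 and the network
#' partitioned by weighted-modularity (Louvain) community detection;
#' singleton communities are discarded. Deterministic for a given seed (RNG
#' state is restored on exit).
#'
#' @param weighted_net igraph network with a correlation `weight` attribute
#'   (see [pcc_weight_edges()]).
#' @param seed Integer seed for the clustering.
#' @param condition Condition label stored on the modules.
#' @return List of `gene_module` objects with `avg_pcc` filled (raw signed
#'   correlations over internal edges).
#' @export
detect_modules <- function(weighted_net, seed = 1L, condition = "condition") {
  if (igraph::vcount(weighted_net) == 0) return(list())
  if (is.null(igraph::E(weighted_net)$weight))
    stop("network has no weight attribute; run pcc_weight_edges first")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  w01 <- (igraph::E(weighted_net)$weight + 1) / 2
  comm <- igraph::cluster_louvain(weighted_net, weights = w01)
  memb <- igraph::membership(comm)
  groups <- split(names(memb), memb)
  groups <- groups[lengths(groups) >= 2]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    out[[i]] <- new_gene_module(
      sprintf("%s.m%02d", condition, i), condition, groups[[i]],
      module_avg_pcc(weighted_net, groups[[i]]))
  }
  out
}

#' Filter modules by size and average internal correlation
#'
#' Keeps modules with at least `module_min_size` genes and average internal
#' edge PCC of at least `module_min_avg_pcc` (inclusive boundaries).
#'
#' @param modules List of `gene_module` objects.
#' @param config An [analysis_config()].
#' @return Filtered list (idempotent).
#' @export
filter_modules <- function(modules, config = analysis_config()) {
  Filter(function(m)
    length(m$genes) >= config$module_min_size &&
      !is.na(m$avg_pcc) && m$avg_pcc >= config$module_min_avg_pcc,
    modules)
}

#' Test each module for enrichment of a signature gene set
#'
#' Hypergeometric upper-tail test of the overlap between each module and the
#' signature over the supplied universe (the measured genes on the network).
#'
#' @param modules List of `gene_module` objects.
#' @param signature Character vector of signature gene ids.
#' @param universe Character vector, the gene universe.
#' @param p_threshold Significance flag threshold (default 0.05).
#' @return The modules with `enrichment_p` filled and a logical
#'   `significant` element added.
#' @export
enrich_modules <- function(modules, signature, universe, p_threshold = 0.05) {
  signature <- intersect(signature, universe)
  lapply(modules, function(m) {
    m$enrichment_p <- overlap_pvalue(intersect(m$genes, universe),
                                     signature, universe)
    m$significant <- m$enrichment_p < p_threshold
    m
  })
}

#' Pair modules across conditions by shared signature genes
#'
#' Returns every cross-condition module pair whose gene sets overlap each
#' other and the signature, with the shared genes
#' (A intersect B intersect signature), sorted by decreasing shared count and
#' then lexicographically by module ids (deterministic).
#'
#' @param modules_a,modules_b Module lists from two conditions.
#' @param signature Character vector of signature gene ids.
#' @return Data frame with columns `module_a`, `module_b`, `n_shared`,
#'   `shared` (list column of gene vectors).
#' @export
shared_module_pairs <- function(modules_a, modules_b, signature) {
  rows <- list()
  for (ma in modules_a) for (mb in modules_b) {
    shared <- sort(intersect(intersect(ma$genes, mb$genes), signature))
    if (!length(shared)) next
    rows[[length(rows) + 1L]] <- data.frame(
      module_a = ma$module_id, module_b = mb$module_id,
      n_shared = length(shared))
    rows[[length(rows)]]$shared <- list(shared)
  }
  if (!length(rows))
    return(data.frame(module_a = character(), module_b = character(),
                      n_shared = integer()))
  out <- do.call(rbind, rows)
  out[order(-out$n_shared, out$module_a, out$module_b), , drop = FALSE]
}
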