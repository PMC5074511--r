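# End-to-end orchestration: signatures -> four measures -> per-dataset
# Q fusion -> overall rank, plus the cross-series origin-specific signature
# and a thin wrapper over the module stage.

#' Subtype labels present in a CSC expression matrix
#' @param expr An `expr_matrix` with `<subtype>.CSC` / `<subtype>.nonCSC`
#'   groups.
#' @return Character vector of subtype labels.
#' @export
csc_subtypes <- function(expr) {
  g <- unique(expr$groups)
  sort(unique(sub("\\.(CSC|nonCSC)$", "", g[grepl("\\.(CSC|nonCSC)$", g)])))
}

#' Run the full origin-prioritization pipeline
#'
#' Calls population signatures from the normal matrix and CSC signatures
#' from every CSC dataset, computes the four measures for every
#' subtype x population x direction cell, fuses each dataset's eight rank
#' lists per subtype with the Q statistic, and averages per-dataset ranks
#' into the overall rank.
#'
#' @param normal_expr `expr_matrix` of normal populations.
#' @param csc_datasets Named list of CSC `expr_matrix` objects.
#' @param onto An `ontology_annotation`.
#' @param net igraph interaction network.
#' @param config An [analysis_config()].
#' @return List of class `origin_result`: `population_signatures`,
#'   `csc_signatures` (per dataset), `measures` (per dataset, from
#'   [score_all()]), `fusion` (per dataset, per subtype), `overall` (per
#'   subtype, named rank vector), `top_origin` (named character).
#' @export
prioritize_origins <- function(normal_expr, csc_datasets, onto, net,
                               config = analysis_config()) {
  if (is.null(onto$ic)) onto <- compute_ic(onto)
  pop_sigs <- call_population_signatures(normal_expr, config)
  universe <- rownames(normal_expr$values)
  measures <- fusion <- csc_sigs <- setNames(vector("list",
                                                    length(csc_datasets)),
                                             names(csc_datasets))
  per_dataset_ranks <- list()
  for (d in names(csc_datasets)) {
    expr <- csc_datasets[[d]]
    subtypes <- csc_subtypes(expr)
    sigs <- lapply(setNames(subtypes, subtypes), function(s) {
      cs <- call_csc_signatures(expr, s, config)
      list(up = cs$up, down = cs$down)
    })
    csc_sigs[[d]] <- sigs
    measures[[d]] <- score_all(sigs, pop_sigs, normal_expr, onto, net,
                               universe)
    fusion[[d]] <- lapply(setNames(subtypes, subtypes), function(s)
      fuse_dataset(measures[[d]], s))
    for (s in subtypes) {
      r <- setNames(fusion[[d]][[s]]$rank, fusion[[d]][[s]]$population)
      per_dataset_ranks[[s]] <- c(per_dataset_ranks[[s]], list(r))
    }
  }
  overall <- lapply(per_dataset_ranks, overall_rank)
  top <- vapply(overall, function(r) names(r)[1], "")
  structure(list(population_signatures = pop_sigs, csc_signatures = csc_sigs,
                 measures = measures, fusion = fusion, overall = overall,
                 top_origin = top, config = config),
            class = "origin_result")
}

#' @export
print.origin_result <- function(x, ...) {
  cat("<origin_result> top-ranked origin per subtype:\n")
  for (s in names(x$top_origin))
    cat(sprintf("  %-12s -> %s (overall rank %.1f)\n", s, x$top_origin[[s]],
                x$overall[[s]][1]))
  invisible(x)
}

#' Origin-specific signature of one subtype against one population
#'
#' For every CSC dataset, contrasts the subtype's CSC samples against the
#' candidate origin population's normal samples on their common genes
#' (cross-series contrast), then intersects the calls across datasets via
#' [origin_specific_signature()].
#'
#' @param csc_datasets Named list of CSC `expr_matrix` objects.
#' @param normal_expr `expr_matrix` of normal populations.
#' @param subtype Subtype label.
#' @param population Candidate origin population label.
#' @param config An [analysis_config()].
#' @param center Passed to [merge_expression()].
#' @return List with `up`, `down` (consistent genes) and `diffs` (the
#'   per-dataset differential tables).
#' @export
origin_specific_contrast <- function(csc_datasets, normal_expr, subtype,
                                     population,
                                     config = analysis_config(),
                                     center = FALSE) {
  diffs <- lapply(csc_datasets, function(expr) {
    keep <- group_samples(expr, paste0(subtype, ".CSC"))
    sub <- expression_matrix(expr$values[, keep, drop = FALSE],
                             expr$groups[keep])
    popkeep <- group_samples(normal_expr, population)
    popm <- expression_matrix(normal_expr$values[, popkeep, drop = FALSE],
                              normal_expr$groups[popkeep])
    merged <- merge_expression(sub, popm, center = center)
    differential(merged, paste0(subtype, ".CSC"), population, config)
  })
  sig <- origin_specific_signature(diffs)
  c(sig, list(diffs = diffs))
}

#' Run the module stage for one condition
#'
#' Weights the network by within-condition expression correlation, detects
#' communities, computes signature enrichment on all modules, and applies
#' the size / average-PCC filter.
#'
#' @param net igraph network.
#' @param expr `expr_matrix` supplying the condition samples.
#' @param condition_samples Sample ids defining the condition (>= 3).
#' @param signature Character vector of signature genes for enrichment.
#' @param config An [analysis_config()].
#' @param seed Clustering seed.
#' @param condition Condition label.
#' @return List with `weighted` (the weighted network), `modules` (all
#'   detected, enrichment filled), `filtered` (after [filter_modules()]).
#' @export
module_stage <- function(net, expr, condition_samples, signature,
                         config = analysis_config(), seed = 1L,
                         condition = "condition") {
  wnet <- pcc_weight_edges(net, expr, condition_samples)
  mods <- detect_modules(wnet, seed = seed, condition = condition)
  universe <- intersect(rownames(expr$values), igraph::V(wnet)$name)
  mods <- enrich_modules(mods, signature, universe, config$p_threshold)
  list(weighted = wnet, modules = mods,
       filtered = filter_modules(mods, config))
}
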