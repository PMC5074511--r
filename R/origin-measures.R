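# The four concordance measures between a CSC signature and a candidate
# normal population: hypergeometric overlap p-value, gene signature score
# (GSS), Lin/BMA ontology semantic similarity (SSS), and mean shortest-path
# length on an interaction network (SP).

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= q) for the overlap q = |A intersect B| when |B| genes are drawn
#' without replacement from a universe containing |A| successes. A zero
#' overlap returns 1.
#'
#' @param set_a,set_b Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector, the gene universe.
#' @return Probability in (0, 1].
#' @export
overlap_pvalue <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("sets must be contained in the universe")
  q <- length(intersect(set_a, set_b))
  if (q == 0) return(1)
  phyper(q - 1, length(set_a), length(universe) - length(set_a),
         length(set_b), lower.tail = FALSE)
}

#' Gene signature score of one normal sample
#'
#' GSS = sum_g x_g (y_g - z_g) / sum_g |x_g| over the signature genes present
#' in the matrix, where x_g is the signature's log2 fold change, y_g the
#' sample's log2 value and z_g the mean log2 value of g across all samples of
#' the matrix. Higher scores mean the sample leans toward the signature's
#' expression pattern.
#'
#' @param signature A `signature_set`.
#' @param normal_expr An `expr_matrix`.
#' @param sample Sample id in `normal_expr`.
#' @param z Optional precomputed named vector of gene means (all samples).
#' @return Score (NaN with a warning when no signature gene is measured);
#'   attribute `n_used` counts contributing genes.
#' @export
gss_sample <- function(signature, normal_expr, sample, z = NULL) {
  if (!sample %in% colnames(normal_expr$values))
    stop("unknown sample: ", sample)
  g <- intersect(signature$genes, rownames(normal_expr$values))
  if (!length(g)) {
    warning("no signature gene of '", signature$label, "' present in matrix")
    return(structure(NaN, n_used = 0L))
  }
  if (is.null(z)) z <- rowMeans(normal_expr$values)
  x <- signature$log2fc[g]
  y <- normal_expr$values[g, sample]
  structure(sum(x * (y - z[g])) / sum(abs(x)), n_used = length(g))
}

#' Gene signature score of a population (mean over its samples)
#'
#' @param signature A `signature_set`.
#' @param normal_expr An `expr_matrix`.
#' @param population Group label in `normal_expr`.
#' @return Mean of [gss_sample()] over the population's samples, with
#'   attribute `n_used`.
#' @export
gss_population <- function(signature, normal_expr, population) {
  samples <- group_samples(normal_expr, population)
  if (!length(samples)) stop("population has no samples: ", population)
  z <- rowMeans(normal_expr$values)
  scores <- vapply(samples, function(s)
    as.numeric(gss_sample(signature, normal_expr, s, z = z)), numeric(1))
  g <- intersect(signature$genes, rownames(normal_expr$values))
  structure(mean(scores), n_used = length(g))
}

# ---- semantic similarity --------------------------------------------------

# Ancestor closure (including the term itself) for every term, computed in
# one bottom-up pass ordered by depth.
term_ancestors <- function(onto) {
  ord <- names(sort(onto$.depth))
  anc <- setNames(vector("list", length(ord)), ord)
  for (t in ord) {
    anc[[t]] <- unique(c(t, unlist(anc[onto$parents[[t]]], use.names = FALSE)))
  }
  anc
}

#' Compute information content from the annotation corpus
#'
#' IC(t) = -ln(n_t / n_root) where n_t counts genes annotated to t or any of
#' its descendants (annotations propagate to ancestors) and n_root counts all
#' annotated genes. Terms annotating no gene receive `NA` and are excluded
#' from similarity computations.
#'
#' @param onto An `ontology_annotation` with annotations.
#' @return The same object with its `ic` field filled.
#' @export
compute_ic <- function(onto) {
  if (!length(onto$gene2terms)) stop("no annotations present")
  anc <- term_ancestors(onto)
  counts <- setNames(integer(length(onto$terms)), onto$terms)
  for (ts in onto$gene2terms) {
    hit <- unique(unlist(anc[ts], use.names = FALSE))
    counts[hit] <- counts[hit] + 1L
  }
  n_root <- counts[[onto$root]]
  ic <- ifelse(counts > 0, -log(counts / n_root), NA_real_)
  onto$ic <- setNames(ic, onto$terms)
  onto
}

#' Lin similarity of two ontology terms
#'
#' 2 IC(MICA) / (IC(t1) + IC(t2)) with MICA the common ancestor (terms
#' included) of maximal information content. Identical terms with positive IC
#' score 1; terms whose ICs sum to 0 score 0.
#'
#' @param t1,t2 Term ids with positive annotation counts.
#' @param onto An `ontology_annotation` with IC computed (see
#'   [compute_ic()]; called automatically if absent).
#' @return Similarity in \[0, 1\].
#' @export
lin_sim <- function(t1, t2, onto) {
  if (is.null(onto$ic)) onto <- compute_ic(onto)
  if (!t1 %in% onto$terms || !t2 %in% onto$terms)
    stop("unknown term: ", paste(setdiff(c(t1, t2), onto$terms), collapse = ", "))
  if (is.na(onto$ic[t1]) || is.na(onto$ic[t2]))
    stop("term without annotated genes: ",
         paste(c(t1, t2)[is.na(onto$ic[c(t1, t2)])], collapse = ", "))
  denom <- onto$ic[[t1]] + onto$ic[[t2]]
  if (denom == 0) return(0)
  if (t1 == t2) return(1)
  anc <- term_ancestors(onto)
  common <- intersect(anc[[t1]], anc[[t2]])
  mica_ic <- max(onto$ic[common], na.rm = TRUE)
  2 * mica_ic / denom
}

# Full term x term Lin similarity matrix over terms with defined IC.
# Quadratic in the number of annotated terms; intended for the compact
# ontologies this pipeline works with.
term_sim_matrix <- function(onto) {
  if (is.null(onto$ic)) onto <- compute_ic(onto)
  anc <- term_ancestors(onto)
  terms <- onto$terms[!is.na(onto$ic)]
  ic <- onto$ic[terms]
  n <- length(terms)
  M <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    ai <- anc[[terms[i]]]
    for (j in i:n) {
      denom <- ic[i] + ic[j]
      if (denom == 0) { s <- 0 }
      else if (i == j) { s <- 1 }
      else {
        common <- intersect(ai, anc[[terms[j]]])
        common <- common[!is.na(onto$ic[common])]
        s <- if (length(common)) 2 * max(onto$ic[common]) / denom else 0
      }
      M[i, j] <- M[j, i] <- s
    }
  }
  M
}

# Best-match-average combination of a similarity matrix with optional row
# and column multiplicities.
bma_combine <- function(M, wrow = NULL, wcol = NULL) {
  if (is.null(wrow)) wrow <- rep(1, nrow(M))
  if (is.null(wcol)) wcol <- rep(1, ncol(M))
  rmax <- apply(M, 1, max)
  cmax <- apply(M, 2, max)
  (sum(wrow * rmax) / sum(wrow) + sum(wcol * cmax) / sum(wcol)) / 2
}

#' Best-match-average Lin similarity between two gene sets
#'
#' Gene-gene similarity is the BMA over the two genes' term sets (mean of
#' each term's best Lin match in the other set, averaged over both
#' directions); set-set similarity applies the same BMA to the gene-gene
#' matrix. Genes without usable annotations are excluded and counted.
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @param onto An `ontology_annotation`.
#' @param termsim Optional precomputed matrix from the internal term
#'   similarity routine (performance path for repeated calls).
#' @return Similarity in \[0, 1\] (NaN with a warning when either set has no
#'   annotated gene); attribute `n_used` = c(annotated in A, annotated in B).
#' @export
setsim_bma <- function(genes_a, genes_b, onto, termsim = NULL) {
  if (is.null(onto$ic)) onto <- compute_ic(onto)
  if (is.null(termsim)) termsim <- term_sim_matrix(onto)
  gene_terms <- usable_gene_terms(onto, termsim)
  bma_setsim_core(genes_a, genes_b, gene_terms, termsim)
}

# per-gene annotation terms restricted to terms with defined IC
usable_gene_terms <- function(onto, termsim) {
  usable <- rownames(termsim)
  lapply(onto$gene2terms, function(ts) ts[ts %in% usable])
}

bma_setsim_core <- function(genes_a, genes_b, gene_terms, termsim) {
  ta <- gene_terms[intersect(genes_a, names(gene_terms))]
  tb <- gene_terms[intersect(genes_b, names(gene_terms))]
  ta <- ta[lengths(ta) > 0]; tb <- tb[lengths(tb) > 0]
  if (!length(ta) || !length(tb)) {
    warning("no annotated genes in one of the sets")
    return(structure(NaN, n_used = c(length(ta), length(tb))))
  }
  # genes with identical term profiles share similarities; compute on unique
  # profiles and expand with multiplicities
  key <- function(x) {
    k <- character(length(x))
    s1 <- lengths(x) == 1L
    k[s1] <- unlist(x[s1], use.names = FALSE)
    k[!s1] <- vapply(x[!s1], function(t) paste(sort(t), collapse = "|"),
                     "", USE.NAMES = FALSE)
    k
  }
  ka <- key(ta); kb <- key(tb)
  pa <- ta[!duplicated(ka)]; names(pa) <- ka[!duplicated(ka)]
  pb <- tb[!duplicated(kb)]; names(pb) <- kb[!duplicated(kb)]
  G <- matrix(0, length(pa), length(pb), dimnames = list(names(pa), names(pb)))
  single_a <- lengths(pa) == 1L; single_b <- lengths(pb) == 1L
  if (any(single_a) && any(single_b)) {
    # singleton term profiles index the term matrix directly
    G[single_a, single_b] <- termsim[unlist(pa[single_a]),
                                     unlist(pb[single_b]), drop = FALSE]
  }
  for (i in which(!single_a)) for (j in seq_along(pb))
    G[i, j] <- bma_combine(termsim[pa[[i]], pb[[j]], drop = FALSE])
  for (j in which(!single_b)) for (i in which(single_a))
    G[i, j] <- bma_combine(termsim[pa[[i]], pb[[j]], drop = FALSE])
  wa <- as.vector(table(factor(ka, levels = names(pa))))
  wb <- as.vector(table(factor(kb, levels = names(pb))))
  structure(bma_combine(G, wa, wb), n_used = c(length(ta), length(tb)))
}

# ---- shortest path --------------------------------------------------------

#' Mean shortest-path length between two gene sets
#'
#' Mean unweighted shortest-path length over all pairs (a, b) with a and b
#' distinct genes present in the network; unreachable pairs are excluded and
#' counted.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param net An igraph network (treated as unweighted).
#' @return Mean length (NaN with a warning when no connected pair exists);
#'   attributes `n_pairs` (pairs used) and `n_excluded` (unreachable pairs).
#' @export
mean_shortest_path <- function(set_a, set_b, net) {
  v <- igraph::V(net)$name
  a <- intersect(unique(set_a), v)
  b <- intersect(unique(set_b), v)
  if (!length(a) || !length(b)) {
    warning("a gene set does not intersect the network")
    return(structure(NaN, n_pairs = 0L, n_excluded = 0L))
  }
  D <- igraph::distances(net, v = a, to = b, weights = NA)
  same <- outer(a, b, "==")
  vals <- D[!same]
  finite <- is.finite(vals)
  if (!any(finite)) {
    warning("no connected pair between the two sets")
    return(structure(NaN, n_pairs = 0L, n_excluded = sum(!finite)))
  }
  structure(mean(vals[finite]), n_pairs = sum(finite),
            n_excluded = sum(!finite))
}

# ---- all measures ---------------------------------------------------------

#' Compute all four measures for every subtype x population x direction
#'
#' For each subtype and candidate population, the up direction pairs the
#' subtype's up signature with the population's over-expressed set and the
#' down direction pairs down with under-expressed: 8 values per
#' (subtype, population) cell (4 measures x 2 directions).
#'
#' @param csc_signatures Named list: subtype -> list(up=, down=)
#'   `signature_set`s.
#' @param population_signatures Named list: population -> list(over=, under=)
#'   `signature_set`s.
#' @param normal_expr `expr_matrix` of the normal populations (GSS substrate).
#' @param onto `ontology_annotation` (SSS substrate).
#' @param net igraph network (SP substrate).
#' @param universe Gene universe for the overlap test (default: genes of
#'   `normal_expr`).
#' @return Data frame with columns `subtype`, `population`, `direction`,
#'   `measure` (`enrich_p`, `gss`, `sss`, `sp`), `value`, `n_used`. NaN
#'   values are retained, never dropped.
#' @export
score_all <- function(csc_signatures, population_signatures, normal_expr,
                      onto, net, universe = rownames(normal_expr$values)) {
  if (is.null(onto$ic)) onto <- compute_ic(onto)
  termsim <- term_sim_matrix(onto)
  gene_terms <- usable_gene_terms(onto, termsim)
  z <- rowMeans(normal_expr$values)
  subtypes <- names(csc_signatures)
  pops <- names(population_signatures)
  dirs <- c(up = "over", down = "under")
  rows <- list()
  add <- function(subtype, population, direction, measure, value, n_used) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subtype = subtype, population = population, direction = direction,
      measure = measure, value = as.numeric(value), n_used = n_used)
  }
  vnames <- igraph::V(net)$name
  for (s in subtypes) {
    for (dir in names(dirs)) {
      sig <- csc_signatures[[s]][[dir]]
      sig_genes <- sig$genes
      empty <- length(sig_genes) == 0
      # one distance matrix per (subtype, direction): sources are the CSC
      # signature genes, targets the union of all population genes
      a_net <- intersect(sig_genes, vnames)
      all_pop_genes <- unique(unlist(lapply(population_signatures,
                                            function(p) p[[dirs[[dir]]]]$genes)))
      b_net <- intersect(all_pop_genes, vnames)
      D <- if (length(a_net) && length(b_net))
        igraph::distances(net, v = a_net, to = b_net, weights = NA) else NULL
      for (p in pops) {
        psig <- population_signatures[[p]][[dirs[[dir]]]]
        pg <- psig$genes
        if (empty || !length(pg)) {
          for (m in c("enrich_p", "gss", "sss", "sp")) add(s, p, dir, m, NaN, 0L)
          next
        }
        q <- length(intersect(sig_genes, pg))
        add(s, p, dir, "enrich_p", overlap_pvalue(sig_genes, pg, universe), q)
        samples <- group_samples(normal_expr, p)
        g_in <- intersect(sig_genes, rownames(normal_expr$values))
        gss <- if (length(g_in)) {
          x <- sig$log2fc[g_in]
          Y <- normal_expr$values[g_in, samples, drop = FALSE]
          mean(colSums(x * (Y - z[g_in])) / sum(abs(x)))
        } else NaN
        add(s, p, dir, "gss", gss, length(g_in))
        sss <- suppressWarnings(bma_setsim_core(sig_genes, pg, gene_terms,
                                                termsim))
        add(s, p, dir, "sss", sss, min(attr(sss, "n_used")))
        if (!is.null(D)) {
          pg_net <- intersect(pg, b_net)
          if (length(pg_net)) {
            Dp <- D[, pg_net, drop = FALSE]
            same <- outer(rownames(Dp), pg_net, "==")
            vals <- Dp[!same]
            fin <- is.finite(vals)
            sp <- if (any(fin)) mean(vals[fin]) else NaN
            add(s, p, dir, "sp", sp, min(length(a_net), length(pg_net)))
          } else add(s, p, dir, "sp", NaN, 0L)
        } else add(s, p, dir, "sp", NaN, 0L)
      }
    }
  }
  do.call(rbind, rows)
}
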