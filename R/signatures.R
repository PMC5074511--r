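# Signature calling: two-sample t tests row-wise over a log2 expression
# matrix, thresholded at p < p_threshold and a fold-change gate
# (|log2fc| > log2(fc_threshold)). "up/down" labels CSC contrasts,
# "over/under" labels normal-population-vs-rest contrasts; both use the
# same machinery.

# Vectorized row-wise two-sample t test (Welch or pooled). Degenerate rows:
# zero variance in both groups with equal means -> p = 1; zero standard
# error with a non-zero mean difference -> p = 0.
row_ttest <- function(A, B, var_equal = FALSE) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  d <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(d))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- ifelse(se2 > 0,
              2 * pt(-abs(d / sqrt(se2)), df),
              ifelse(d == 0, 1, 0))
  list(mean_a = ma, mean_b = mb, log2fc = d, pvalue = p)
}

#' Differential expression between two sample groups
#'
#' Two-sided two-sample t test per gene on log2 values; log2 fold change is
#' the difference of group means of log2 values, so a 2-fold gate corresponds
#' to |log2fc| > 1. A gene is called `up` when `pvalue < p_threshold` and
#' `log2fc > log2(fc_threshold)`, `down` for the mirrored condition, `none`
#' otherwise.
#'
#' @param expr An `expr_matrix` of log2 values.
#' @param group_a,group_b Group labels; each must have at least 2 samples.
#' @param config An [analysis_config()] (supplies `p_threshold`,
#'   `fc_threshold` and the t-test variant, Welch by default).
#' @return Data frame with columns `gene`, `mean_a`, `mean_b`, `log2fc`,
#'   `pvalue`, `call`.
#' @export
differential <- function(expr, group_a, group_b, config = analysis_config()) {
  ia <- which(expr$groups == group_a)
  ib <- which(expr$groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop(sprintf("groups '%s' (%d) and '%s' (%d) must each have >= 2 samples",
                 group_a, length(ia), group_b, length(ib)))
  tt <- row_ttest(expr$values[, ia, drop = FALSE],
                  expr$values[, ib, drop = FALSE],
                  var_equal = config$ttest == "pooled")
  thr <- log2(config$fc_threshold)
  call <- rep("none", length(tt$log2fc))
  call[tt$pvalue < config$p_threshold & tt$log2fc > thr] <- "up"
  call[tt$pvalue < config$p_threshold & tt$log2fc < -thr] <- "down"
  data.frame(gene = rownames(expr$values), mean_a = tt$mean_a,
             mean_b = tt$mean_b, log2fc = tt$log2fc,
             pvalue = tt$pvalue, call = call, row.names = NULL)
}

# Build a signature_set for one direction from a differential table.
diff_to_signature <- function(diff, direction, label) {
  keep <- diff$call == if (direction == "up") "up" else "down"
  g <- diff$gene[keep]
  # t-test p-values of called genes are < 1 and > 0 except exact-zero
  # degenerate rows; clamp those into (0, 1] for the signature contract
  p <- pmax(diff$pvalue[keep], .Machine$double.xmin)
  signature_set(label, g, setNames(diff$log2fc[keep], g),
                setNames(p, g), direction)
}

#' Call over/under-expressed signatures for every normal population
#'
#' Each population is contrasted against the union of all other populations
#' (one-vs-rest); genes passing the p and fold-change gates form the
#' population's over-expressed (`up` direction) and under-expressed (`down`)
#' signature sets.
#'
#' @param expr An `expr_matrix` whose groups are the populations.
#' @param config An [analysis_config()].
#' @return Named list: population -> list(over = `signature_set`,
#'   under = `signature_set`).
#' @export
call_population_signatures <- function(expr, config = analysis_config()) {
  pops <- unique(expr$groups)
  if (length(pops) < 2) stop("need at least 2 populations")
  out <- lapply(pops, function(p) {
    relab <- ifelse(expr$groups == p, p, ".rest")
    e <- expression_matrix(expr$values, setNames(relab, names(expr$groups)))
    d <- differential(e, p, ".rest", config)
    list(over = diff_to_signature(d, "up", paste0(p, ".over")),
         under = diff_to_signature(d, "down", paste0(p, ".under")))
  })
  setNames(out, pops)
}

#' Call the up/down signature of one subtype's CSC contrast
#'
#' Contrasts groups `<subtype>.CSC` and `<subtype>.nonCSC`.
#'
#' @param expr An `expr_matrix` containing both groups.
#' @param subtype Subtype label.
#' @param config An [analysis_config()].
#' @return List with elements `up` and `down` (`signature_set`s) and
#'   `diff` (the full differential table).
#' @export
call_csc_signatures <- function(expr, subtype, config = analysis_config()) {
  ga <- paste0(subtype, ".CSC"); gb <- paste0(subtype, ".nonCSC")
  if (!all(c(ga, gb) %in% expr$groups))
    stop("matrix lacks group(s): ",
         paste(setdiff(c(ga, gb), expr$groups), collapse = ", "))
  d <- differential(expr, ga, gb, config)
  list(up = diff_to_signature(d, "up", paste0(subtype, ".up")),
       down = diff_to_signature(d, "down", paste0(subtype, ".down")),
       diff = d)
}

#' Intersect differential calls across datasets into an origin-specific signature
#'
#' Genes called `up` in every dataset's contrast form the up set; `down`
#' likewise. A gene with conflicting calls across datasets is excluded by
#' construction.
#'
#' @param diffs_per_dataset List (length >= 1) of differential tables from
#'   [differential()] for the same contrast in different datasets.
#' @return List with character vectors `up` and `down`.
#' @export
origin_specific_signature <- function(diffs_per_dataset) {
  if (!length(diffs_per_dataset)) stop("empty list of differential results")
  calls <- function(dir) lapply(diffs_per_dataset,
                                function(d) d$gene[d$call == dir])
  list(up = sort(Reduce(intersect, calls("up"))),
       down = sort(Reduce(intersect, calls("down"))))
}
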