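#' stemtrace: cell-of-origin prioritization for cancer-subtype stem cells
#'
#' Scores candidate normal cell populations against cancer-stem-cell (CSC)
#' expression signatures by four concordance measures, fuses the resulting
#' rank lists with an order-statistics Q statistic, and provides downstream
#' network-module detection and promoter motif scanning. A synthetic-data
#' generator with planted ground truth exercises every stage.
#'
#' @importFrom stats t.test pt phyper cor rnorm runif sd setNames
#' @importFrom utils read.delim write.table head combn
#' @keywords internal
"_PACKAGE"

#' Construct an expression matrix with sample group labels
#'
#' The substrate of every stage: a genes x samples matrix of log2
#' intensities plus a sample -> group mapping.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must carry
#'   unique, non-empty rownames (gene ids) and colnames (sample ids); all
#'   values finite.
#' @param groups Named character vector mapping every sample id to a group
#'   label (e.g. `"luminalB.CSC"` or a normal population name).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `groups` (groups reordered to match the column order).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(gid)) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(sid)) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(values))) stop("non-finite values in expression matrix")
  groups <- as.character(groups)[match(sid, names(groups))]
  if (anyNA(groups))
    stop("missing group label for sample(s): ",
         paste(sid[is.na(groups)], collapse = ", "))
  names(groups) <- sid
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %d groups\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

#' Samples belonging to one or more groups
#' @param expr An `expr_matrix`.
#' @param groups Character vector of group labels.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(expr, groups) {
  names(expr$groups)[expr$groups %in% groups]
}

#' Construct a signature gene set
#'
#' An up- or down-regulated (over/under-expressed) gene set with per-gene
#' log2 fold change and p-value, as called by [differential()].
#'
#' @param label Text label, e.g. `"luminalB.up"`.
#' @param genes Character vector of member gene ids (no duplicates).
#' @param log2fc Named numeric: log2 fold change for every member gene.
#' @param pvalue Named numeric: p-value in (0, 1] for every member gene.
#' @param direction `"up"` or `"down"`; up requires all log2fc > 0, down all
#'   log2fc < 0.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(label, genes, log2fc, pvalue, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in signature set ", label)
  log2fc <- log2fc[genes]; pvalue <- pvalue[genes]
  if (length(genes)) {
    if (anyNA(log2fc)) stop("log2fc missing for some genes in ", label)
    if (anyNA(pvalue)) stop("pvalue missing for some genes in ", label)
    if (any(pvalue <= 0 | pvalue > 1)) stop("pvalues must lie in (0, 1]")
    if (direction == "up" && any(log2fc <= 0))
      stop("direction 'up' requires all log2fc > 0")
    if (direction == "down" && any(log2fc >= 0))
      stop("direction 'down' requires all log2fc < 0")
  }
  structure(list(label = label, genes = genes,
                 log2fc = log2fc, pvalue = pvalue, direction = direction),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s (%s): %d genes\n",
              x$label, x$direction, length(x$genes)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' procedure's standard operating points: raw p < 0.05 with a 2-fold-change gate for signature
#' calling, module average-PCC filter at 0.5, 2000-bp promoters, and a core
#' similarity cutoff of 1 (strictest motif output).
#'
#' @param p_threshold Significance threshold for signature calls.
#' @param fc_threshold Fold-change gate (linear scale; 2 means |log2fc| > 1).
#' @param ttest `"welch"` (default) or `"pooled"` two-sample t test.
#' @param module_min_size Minimum module size kept by [filter_modules()].
#' @param module_min_avg_pcc Minimum average internal edge correlation kept
#'   by [filter_modules()] (inclusive).
#' @param promoter_length Promoter length in bases upstream of the TSS.
#' @param css_cutoff Core similarity cutoff for motif hits, in \[0, 1\].
#' @param mss_cutoffs Named numeric of per-matrix matrix-similarity cutoffs.
#' @param mss_default Fallback matrix-similarity cutoff for matrices absent
#'   from `mss_cutoffs`; set to `NA` to make a missing entry a hard error.
#' @param pseudocount Pseudocount added to PWM counts when building profiles.
#' @param seed Integer seed used by stages with internal randomness.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(p_threshold = 0.05, fc_threshold = 2,
                            ttest = c("welch", "pooled"),
                            module_min_size = 7, module_min_avg_pcc = 0.5,
                            promoter_length = 2000, css_cutoff = 1.0,
                            mss_cutoffs = numeric(), mss_default = 0.95,
                            pseudocount = 1e-4, seed = 1L) {
  ttest <- match.arg(ttest)
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1")
  if (css_cutoff < 0 || css_cutoff > 1) stop("css_cutoff must be in [0, 1]")
  if (module_min_size < 2) stop("module_min_size must be at least 2")
  structure(list(p_threshold = p_threshold, fc_threshold = fc_threshold,
                 ttest = ttest, module_min_size = module_min_size,
                 module_min_avg_pcc = module_min_avg_pcc,
                 promoter_length = promoter_length, css_cutoff = css_cutoff,
                 mss_cutoffs = mss_cutoffs, mss_default = mss_default,
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Construct a position weight matrix record
#'
#' @param name Matrix identifier.
#' @param counts 4 x L non-negative numeric matrix with rownames
#'   `c("A","C","G","T")`; L >= 5 and every position must have a positive
#'   column sum.
#' @param pseudocount Non-negative pseudocount carried with the record.
#' @return An object of class `pwm_record`.
#' @export
pwm_record <- function(name, counts, pseudocount = 1e-4) {
  if (!is.matrix(counts) || nrow(counts) != 4)
    stop("counts must be a 4 x L matrix")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (!identical(rownames(counts), c("A", "C", "G", "T")))
    stop("counts rows must be A, C, G, T")
  if (ncol(counts) < 5) stop("PWM '", name, "' has fewer than 5 positions")
  if (any(counts < 0) || !all(is.finite(counts)))
    stop("PWM counts must be finite and non-negative")
  if (any(colSums(counts) <= 0))
    stop("PWM '", name, "' has an all-zero position")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  structure(list(name = name, counts = counts, pseudocount = pseudocount),
            class = "pwm_record")
}

#' @export
print.pwm_record <- function(x, ...) {
  cat(sprintf("<pwm_record> %s, %d positions\n", x$name, ncol(x$counts)))
  invisible(x)
}
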