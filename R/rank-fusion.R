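# Rank fusion: per-measure candidate ranking, rank ratios, the
# order-statistics Q statistic, per-dataset fusion, and the overall rank
# averaged across datasets.

# Measures where smaller values are better. gss and sss rank descending.
.ascending_measures <- c("enrich_p", "sp")

#' Rank candidate populations for one measure and direction
#'
#' Orientation: `enrich_p` and `sp` rank ascending (smaller is better),
#' `gss` and `sss` descending. Ties receive the average rank. NaN values are
#' dropped; fewer than 2 usable values drops the whole list (returns `NULL`).
#'
#' @param values Data frame from [score_all()] (rows of one subtype).
#' @param measure One of `"enrich_p"`, `"gss"`, `"sss"`, `"sp"`.
#' @param direction `"up"` or `"down"`.
#' @return Named numeric of ranks (1 = best), or `NULL` when the list is
#'   dropped.
#' @export
rank_candidates <- function(values, measure, direction) {
  rows <- values[values$measure == measure & values$direction == direction, ]
  v <- setNames(rows$value, rows$population)
  v <- v[!is.na(v)]
  if (length(v) < 2) return(NULL)
  if (!measure %in% .ascending_measures) v <- -v
  rank(v, ties.method = "average")
}

kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (xi in x) {
    y <- xi - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Order-statistics Q statistic of a sorted rank-ratio vector
#'
#' Evaluates the recursion `V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i}
#' r_{N-k+1}^i / i!` with `V_0 = 1` and returns `N! V_N` clamped to
#' \[0, 1\]: the probability that N iid uniform(0,1) order statistics are
#' componentwise at most the given ratios. Smaller Q means stronger combined
#' evidence across rank lists.
#'
#' @param ratios Numeric vector of rank ratios in (0, 1\], sorted ascending,
#'   length 1..20.
#' @return Probability in \[0, 1\].
#' @export
q_statistic <- function(ratios) {
  r <- as.numeric(ratios)
  N <- length(r)
  if (N < 1 || N > 20) stop("need between 1 and 20 rank ratios")
  if (any(!is.finite(r)) || any(r <= 0) || any(r > 1))
    stop("rank ratios must lie in (0, 1]")
  if (is.unsorted(r)) stop("rank ratios must be sorted ascending")
  V <- numeric(N + 1)
  V[1] <- 1
  for (k in seq_len(N)) {
    i <- seq_len(k)
    terms <- (-1)^(i - 1) * V[k - i + 1] * r[N - k + 1]^i / factorial(i)
    V[k + 1] <- if (k > 10) kahan_sum(terms) else sum(terms)
  }
  min(max(factorial(N) * V[N + 1], 0), 1)
}

#' Fuse the per-measure rank lists of one subtype into a Q-ranked list
#'
#' Collects each population's ranks across the available (at most 8) lists,
#' converts them to rank ratios using each list's own candidate count, sorts
#' them ascending and applies [q_statistic()] with N = number of lists in
#' which the population appears. Populations are ranked by ascending Q; ties
#' break by mean ratio, then population id (deterministic).
#'
#' @param values Data frame from [score_all()] restricted to one dataset.
#' @param subtype Subtype label to fuse.
#' @return Data frame with columns `population`, `q_value`, `rank`,
#'   `n_lists`, `mean_ratio`, ordered by `rank`.
#' @export
fuse_dataset <- function(values, subtype) {
  sub <- values[values$subtype == subtype, ]
  if (!nrow(sub)) stop("no measure rows for subtype ", subtype)
  pops <- sort(unique(sub$population))
  ratios <- setNames(vector("list", length(pops)), pops)
  for (m in c("enrich_p", "gss", "sss", "sp")) {
    for (dir in c("up", "down")) {
      rk <- rank_candidates(sub, m, dir)
      if (is.null(rk)) next
      rr <- rk / length(rk)
      for (p in names(rr)) ratios[[p]] <- c(ratios[[p]], rr[[p]])
    }
  }
  n_lists <- lengths(ratios)
  keep <- n_lists > 0
  if (any(!keep))
    warning("population(s) with no usable rank list excluded: ",
            paste(pops[!keep], collapse = ", "))
  pops <- pops[keep]
  q <- vapply(ratios[pops], function(r) q_statistic(sort(r)), numeric(1))
  mr <- vapply(ratios[pops], mean, numeric(1))
  ord <- order(q, mr, pops)
  out <- data.frame(population = pops[ord], q_value = q[ord],
                    rank = seq_along(ord), n_lists = n_lists[pops][ord],
                    mean_ratio = mr[ord], row.names = NULL)
  out
}

#' Average per-dataset ranks into the overall rank
#'
#' @param per_dataset List of named numeric vectors (population -> rank), one
#'   per dataset. A population missing from some datasets is averaged over
#'   the datasets where it appears, with a warning.
#' @return Named numeric of overall ranks (arithmetic means), sorted
#'   ascending.
#' @export
overall_rank <- function(per_dataset) {
  if (!length(per_dataset)) stop("need at least one dataset rank map")
  pops <- unique(unlist(lapply(per_dataset, names)))
  M <- vapply(per_dataset, function(r) r[pops], numeric(length(pops)))
  M <- matrix(M, nrow = length(pops), dimnames = list(pops, NULL))
  if (anyNA(M))
    warning("population(s) missing from some datasets: ",
            paste(pops[apply(M, 1, anyNA)], collapse = ", "))
  sort(rowMeans(M, na.rm = TRUE))
}
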