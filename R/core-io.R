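# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV + groups TSV, network SIF/TSV, OBO ontology + gene->term
# annotations, GMT gene sets, TRANSFAC matrices. Writers emit data at full
# precision so write/read round-trips are exact; derived result tables use
# 6 significant digits (see write_result_table).

fmt_num <- function(x) sprintf("%.17g", x)

#' Read an expression matrix and its sample group labels
#'
#' @param path TSV file: header row of sample ids, first column gene ids,
#'   numeric log2 values. Duplicate gene rows are collapsed by their
#'   arithmetic mean with a warning.
#' @param groups_path Two-column TSV (no header): sample id, group label.
#'   Every sample in `path` must appear.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, groups_path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", sep = "\t")
  if (ncol(df) < 2) stop("expression file needs a gene column and >=1 sample")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                 genes[bad[1]], colnames(vals)[bad[2]], path))
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    warning(sprintf("%d duplicate gene row(s) collapsed by mean in %s",
                    ndup, path))
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(num) <- genes
  g <- read.delim(groups_path, header = FALSE, colClasses = "character",
                  sep = "\t")
  if (ncol(g) < 2) stop("groups file must have two columns")
  groups <- setNames(g[[2]], g[[1]])
  missing <- setdiff(colnames(num), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  expression_matrix(num, groups[colnames(num)])
}

#' Write an expression matrix and its group labels
#' @param expr An `expr_matrix`.
#' @param path,groups_path Output TSV paths (see [read_expression()]).
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, path, groups_path) {
  m <- expr$values
  out <- cbind(gene = rownames(m),
               matrix(fmt_num(m), nrow = nrow(m), dimnames = dimnames(m)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(expr$groups), unname(expr$groups)),
              groups_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(expr)
}

#' Combine two expression matrices on their common genes
#'
#' Used for cross-series contrasts (e.g. CSC samples from one series versus a
#' normal population from another). Optionally centers each gene within each
#' source matrix first, since cross-series scaling is otherwise undefined.
#'
#' @param a,b `expr_matrix` objects with disjoint sample ids.
#' @param center Logical; gene-wise centering per source matrix before
#'   binding (default `FALSE`).
#' @return An `expr_matrix` on the intersected gene set.
#' @export
merge_expression <- function(a, b, center = FALSE) {
  common <- intersect(rownames(a$values), rownames(b$values))
  if (!length(common)) stop("no genes in common between the two matrices")
  if (length(intersect(colnames(a$values), colnames(b$values))))
    stop("sample ids overlap between the two matrices")
  va <- a$values[common, , drop = FALSE]
  vb <- b$values[common, , drop = FALSE]
  if (center) {
    va <- va - rowMeans(va)
    vb <- vb - rowMeans(vb)
  }
  expression_matrix(cbind(va, vb), c(a$groups, b$groups))
}

#' Read an undirected interaction network
#'
#' Accepts a 2- or 3-column TSV / whitespace-delimited edge list
#' (nodeA, nodeB\[, weight\]). Duplicate edges are merged (weights averaged)
#' and self-loops dropped with a message.
#'
#' @param path Edge-list file.
#' @return An undirected [igraph::graph] (possibly with a `weight` edge
#'   attribute).
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad))
    stop(sprintf("malformed network line %d: '%s'", bad[1], lines[bad[1]]))
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  w <- rep(NA_real_, length(parts))
  has_w <- nf == 3
  w[has_w] <- suppressWarnings(as.numeric(vapply(parts[has_w], `[`, "", 3L)))
  if (anyNA(w[has_w]))
    stop("non-numeric weight on network line ",
         which(has_w)[which(is.na(w[has_w]))[1]])
  loops <- a == b
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  df <- data.frame(a = a[!loops], b = b[!loops])
  if (any(has_w)) df$weight <- w[!loops]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  attrs <- if (any(has_w)) list(weight = "mean") else list()
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = attrs)
}

#' Write a network as an edge list
#' @param net An igraph graph.
#' @param path Output TSV path.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, path) {
  e <- igraph::as_data_frame(net, what = "edges")
  if ("weight" %in% names(e)) e$weight <- fmt_num(e$weight)
  write.table(e, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' Read an ontology (minimal OBO) plus gene annotations
#'
#' Parses `[Term]` stanzas with `id:` and `is_a:` tags (one namespace;
#' obsolete terms skipped). The parent graph must be acyclic with a single
#' root. Annotations to unknown terms are skipped with a warning.
#'
#' @param obo_path OBO file.
#' @param anno_path Two-column TSV (no header): gene id, term id.
#' @return An object of class `ontology_annotation`: list with `terms`,
#'   `parents` (named list), `root`, `gene2terms` (named list), and `ic`
#'   (`NULL` until [compute_ic()]).
#' @export
read_ontology <- function(obo_path, anno_path) {
  lines <- readLines(obo_path)
  terms <- list(); cur <- NULL; in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete)
      terms[[cur$id]] <<- cur$parents
    cur <<- NULL; obsolete <<- FALSE
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- list(id = NULL, parents = character()); next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || is.null(cur) && !in_term) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      p <- trimws(sub("^is_a:", "", ln))
      p <- trimws(sub("!.*$", "", p))
      cur$parents <- c(cur$parents, p)
    } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) obsolete <- TRUE
  }
  flush()
  anno <- read.delim(anno_path, header = FALSE, colClasses = "character",
                     sep = "\t")
  if (ncol(anno) < 2) stop("annotation file must have two columns")
  known <- anno[[2]] %in% names(terms)
  if (any(!known))
    warning(sum(!known), " annotation(s) to unknown terms skipped")
  gene2terms <- lapply(split(anno[[2]][known], anno[[1]][known]), unique)
  ontology_annotation(names(terms), terms, gene2terms)
}

#' Construct an ontology-annotation object
#'
#' @param terms Character vector of term ids.
#' @param parents Named list: term id -> character vector of parent term ids
#'   (`is_a`, acyclic, single root).
#' @param gene2terms Named list: gene id -> character vector of term ids.
#' @param ic Optional named numeric of information-content values.
#' @return An `ontology_annotation`.
#' @export
ontology_annotation <- function(terms, parents, gene2terms, ic = NULL) {
  terms <- as.character(terms)
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) if (is.null(p)) character() else as.character(p))
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown))
    stop("is_a parent(s) not defined as terms: ", paste(unknown, collapse = ", "))
  roots <- terms[lengths(parents) == 0]
  if (length(roots) != 1)
    stop("ontology must have exactly one root, found ", length(roots))
  # cycle check + topological depth via repeated stripping
  depth <- setNames(rep(NA_real_, length(terms)), terms)
  depth[roots] <- 0
  remaining <- setdiff(terms, roots)
  repeat {
    ready <- remaining[vapply(parents[remaining],
                              function(p) all(!is.na(depth[p])), logical(1))]
    if (!length(ready)) break
    for (t in ready) depth[t] <- max(depth[parents[[t]]]) + 1
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining))
    stop("cyclic is_a relationships involving: ",
         paste(head(remaining, 5), collapse = ", "))
  gene2terms <- lapply(gene2terms, function(x) unique(as.character(x)))
  structure(list(terms = terms, parents = parents, root = roots,
                 gene2terms = gene2terms, ic = ic,
                 .depth = depth),
            class = "ontology_annotation")
}

#' @export
print.ontology_annotation <- function(x, ...) {
  cat(sprintf("<ontology_annotation> %d terms (root %s), %d annotated genes%s\n",
              length(x$terms), x$root, length(x$gene2terms),
              if (is.null(x$ic)) " (IC not computed)" else ""))
  invisible(x)
}

#' Write an ontology and annotations back to OBO + TSV
#' @param onto An `ontology_annotation`.
#' @param obo_path,anno_path Output paths.
#' @return Invisibly, `onto`.
#' @export
write_ontology <- function(onto, obo_path, anno_path) {
  con <- file(obo_path, "w"); on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in onto$terms) {
    p <- onto$parents[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 if (length(p)) paste0("is_a: ", p)), con)
  }
  anno <- data.frame(gene = rep(names(onto$gene2terms),
                                lengths(onto$gene2terms)),
                     term = unlist(onto$gene2terms, use.names = FALSE))
  write.table(anno, anno_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(onto)
}

#' Read gene sets in GMT format
#' @param path GMT file (name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, "", 1L))
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read TRANSFAC-format position weight matrices
#'
#' Supports standard TRANSFAC records (`NA`/`ID` name line, a `P0`/`PO`
#' header, numbered position rows with A C G T counts, `//` separators) and a
#' plain 4-row dialect with rows labelled `A:`/`C:`/`G:`/`T:`.
#'
#' @param path Matrix file.
#' @param pseudocount Pseudocount stored on each record.
#' @return List of [pwm_record()] objects.
#' @export
read_pwm <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  recs <- list(); name <- NULL; rows <- list(); base_rows <- list()
  flush <- function() {
    if (length(rows)) {
      counts <- t(do.call(rbind, rows))  # 4 x L from L x 4 rows
      rownames(counts) <- c("A", "C", "G", "T")
      recs[[length(recs) + 1L]] <<-
        pwm_record(if (is.null(name)) paste0("M", length(recs) + 1L) else name,
                   counts, pseudocount)
    } else if (length(base_rows) == 4) {
      counts <- do.call(rbind, base_rows[c("A", "C", "G", "T")])
      recs[[length(recs) + 1L]] <<-
        pwm_record(if (is.null(name)) paste0("M", length(recs) + 1L) else name,
                   counts, pseudocount)
    }
    name <<- NULL; rows <<- list(); base_rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (ln == "//") { flush(); next }
    tag <- sub("^([A-Za-z0-9]+).*$", "\\1", ln)
    if (tag %in% c("NA", "ID")) {
      name <- trimws(sub("^..\\s*", "", ln))
    } else if (tag %in% c("P0", "PO", "XX", "DE", "BF", "AC", "CC")) {
      next
    } else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(ln, "\\s+")[[1]]
      nums <- suppressWarnings(as.numeric(f[2:5]))
      if (length(f) < 5 || anyNA(nums))
        stop("position row with fewer than 4 numeric fields at line ", i)
      rows[[length(rows) + 1L]] <- nums
    } else if (grepl("^[ACGT][:|]", ln)) {
      b <- substr(ln, 1, 1)
      nums <- suppressWarnings(as.numeric(strsplit(trimws(substring(ln, 3)),
                                                   "\\s+")[[1]]))
      if (anyNA(nums)) stop("non-numeric count at line ", i)
      base_rows[[b]] <- nums
    }
  }
  flush()
  recs
}

#' Write position weight matrices in TRANSFAC format
#' @param pwms List of `pwm_record` objects.
#' @param path Output path.
#' @return Invisibly, `pwms`.
#' @export
write_pwm <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0("NA  ", p$name), con)
    writeLines("P0      A      C      G      T", con)
    for (i in seq_len(ncol(p$counts)))
      writeLines(sprintf("%02d  %s", i,
                         paste(fmt_num(p$counts[, i]), collapse = "  ")), con)
    writeLines("//", con)
  }
  invisible(pwms)
}

#' Write a result table as TSV with 6 significant digits
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `df`.
#' @export
write_result_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
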