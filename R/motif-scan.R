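# Match-style PWM scanning: information-weighted, min-max-normalized matrix
# similarity (MSS) over the full matrix and core similarity (CSS) over the 5
# most informative consecutive positions. Coordinates are 0-based half-open;
# hit offsets are reported on the forward strand of the scanned sequence.

.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_seq <- function(s) {
  v <- strsplit(toupper(as.character(s)), "")[[1]]
  code <- .base_code[v]
  code[is.na(code)] <- 0L  # ambiguous bases score as the position minimum
  unname(code)
}

#' Build a scanning profile from a PWM record
#'
#' Column-normalizes counts with the record's pseudocount, computes the
#' per-position information vector `I(i) = sum_b f(i,b) ln(4 f(i,b))` and
#' locates the 5-position core as the window of consecutive positions with
#' maximal summed information (leftmost on ties).
#'
#' @param rec A [pwm_record()].
#' @return An object of class `pwm_profile` with elements `record`, `freqs`
#'   (4 x L), `info`, `core_start` (1-based index of the core's first
#'   position).
#' @export
build_profile <- function(rec) {
  counts <- rec$counts
  L <- ncol(counts)
  if (L < 5) stop("PWM must have at least 5 positions")
  pc <- rec$pseudocount
  f <- sweep(counts + pc, 2, colSums(counts) + 4 * pc, "/")
  xlogx <- function(x) ifelse(x > 0, x * log(4 * x), 0)
  info <- colSums(xlogx(f))
  core_sums <- vapply(seq_len(L - 4), function(i) sum(info[i:(i + 4)]),
                      numeric(1))
  structure(list(record = rec, freqs = f, info = info,
                 core_start = which.max(core_sums)),
            class = "pwm_profile")
}

#' @export
print.pwm_profile <- function(x, ...) {
  cat(sprintf("<pwm_profile> %s, %d positions, core at %d-%d\n",
              x$record$name, ncol(x$freqs), x$core_start, x$core_start + 4))
  invisible(x)
}

# Information-weighted score of coded windows over selected positions.
# codes: integer matrix (windows x L), 0 = ambiguous.
weighted_score <- function(profile, codes, positions) {
  W <- sweep(profile$freqs, 2, profile$info, "*")  # 4 x L, rows bases
  Wmin <- profile$info * apply(profile$freqs, 2, min)
  cur <- numeric(nrow(codes))
  for (i in positions) {
    ci <- codes[, i]
    v <- ifelse(ci == 0L, Wmin[i], W[ci + 4L * (i - 1L)])
    cur <- cur + v
  }
  cur
}

score_bounds <- function(profile, positions) {
  mn <- sum(profile$info[positions] *
              apply(profile$freqs[, positions, drop = FALSE], 2, min))
  mx <- sum(profile$info[positions] *
              apply(profile$freqs[, positions, drop = FALSE], 2, max))
  c(mn, mx)
}

normalize_score <- function(cur, bounds) {
  if (bounds[2] == bounds[1]) {
    warning("degenerate profile: max score equals min score; scoring 1")
    return(rep(1, length(cur)))
  }
  (cur - bounds[1]) / (bounds[2] - bounds[1])
}

#' Matrix and core similarity of one window
#'
#' `mss = (Current - Min) / (Max - Min)` where `Current` is the
#' information-weighted sum of the window's base frequencies and `Min`/`Max`
#' the bounds attained by the per-position worst/best base; `css` applies the
#' same normalization restricted to the 5 core positions. Ambiguous bases
#' score as the position minimum.
#'
#' @param profile A [build_profile()] result.
#' @param window Character string over A/C/G/T of the profile's length.
#' @return Named numeric `c(mss =, css =)`, each in \[0, 1\].
#' @export
match_scores <- function(profile, window) {
  code <- encode_seq(window)
  L <- ncol(profile$freqs)
  if (length(code) != L)
    stop("window length ", length(code), " does not match profile length ", L)
  codes <- matrix(code, nrow = 1)
  core <- profile$core_start:(profile$core_start + 4)
  mss <- normalize_score(weighted_score(profile, codes, seq_len(L)),
                         score_bounds(profile, seq_len(L)))
  css <- normalize_score(weighted_score(profile, codes, core),
                         score_bounds(profile, core))
  c(mss = mss, css = css)
}

#' Consensus sequence of a PWM profile (per-position argmax base)
#' @param profile A `pwm_profile` or `pwm_record`.
#' @return Character string.
#' @export
pwm_consensus <- function(profile) {
  if (inherits(profile, "pwm_record")) profile <- build_profile(profile)
  paste(c("A", "C", "G", "T")[apply(profile$freqs, 2, which.max)],
        collapse = "")
}

#' Read transcript coordinates from a BED file
#'
#' BED is 0-based half-open; the TSS is `chromStart` for `+` strand
#' transcripts and `chromEnd` for `-` strand.
#'
#' @param path BED file with at least 6 columns
#'   (chrom, start, end, name, score, strand).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `tss`.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character", sep = "\t")
  if (ncol(df) < 6) stop("BED file must have at least 6 columns")
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), name = df[[4]],
                    strand = df[[6]])
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out
}

#' Extract promoter sequences upstream of transcription start sites
#'
#' For a `+` strand transcript the promoter is `[TSS - length, TSS)` on the
#' forward strand; for `-` strand, the reverse complement of
#' `[TSS, TSS + length)`. Promoters are truncated at contig boundaries with a
#' warning; transcripts on unknown contigs are skipped with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] of contigs.
#' @param transcripts Data frame with columns `chrom`, `strand`, `tss`
#'   (0-based), `name` (see [read_bed()]).
#' @param length Promoter length in bases (default 2000).
#' @return A `DNAStringSet` named by transcript name.
#' @export
extract_promoters <- function(genome, transcripts, length = 2000) {
  seqs <- character(0); nms <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    if (!tr$chrom %in% names(genome)) {
      warning("transcript '", tr$name, "' on unknown contig '", tr$chrom,
              "' skipped")
      next
    }
    clen <- Biostrings::width(genome[tr$chrom])
    if (tr$strand == "+") {
      from <- max(0L, tr$tss - length); to <- tr$tss       # 0-based half-open
    } else {
      from <- tr$tss; to <- min(clen, tr$tss + length)
    }
    if (to <= from) {
      warning("transcript '", tr$name, "' yields an empty promoter; skipped")
      next
    }
    if (to - from < length)
      warning("promoter of '", tr$name, "' truncated to ", to - from,
              " bases at contig boundary")
    s <- Biostrings::subseq(genome[[tr$chrom]], start = from + 1L, end = to)
    if (tr$strand == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s)); nms <- c(nms, tr$name)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  out
}

# All-window coded matrix of a coded sequence for a profile of length L.
window_codes <- function(code, L) {
  n_off <- length(code) - L + 1L
  if (n_off < 1) return(matrix(integer(0), nrow = 0, ncol = L))
  matrix(code[outer(seq_len(n_off) - 1L, seq_len(L), "+")], nrow = n_off)
}

#' Scan promoter sequences with PWM profiles on both strands
#'
#' Emits a hit wherever the core similarity reaches `config$css_cutoff` and
#' the matrix similarity reaches the matrix's cutoff
#' (`config$mss_cutoffs[[name]]`, falling back to `config$mss_default`;
#' a missing cutoff with `mss_default = NA` is a hard error). Offsets are
#' 0-based window starts on the forward strand of the promoter sequence,
#' for both strands.
#'
#' @param promoters Named `DNAStringSet` (or named character vector).
#' @param profiles List of `pwm_profile` (or `pwm_record`) objects.
#' @param config An [analysis_config()].
#' @return Data frame with columns `sequence_id`, `matrix`, `strand`,
#'   `offset`, `mss`, `css`.
#' @export
scan_promoters <- function(promoters, profiles, config = analysis_config()) {
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "pwm_record")) build_profile(p) else p)
  mat_names <- vapply(profiles, function(p) p$record$name, "")
  cutoffs <- config$mss_cutoffs[mat_names]
  names(cutoffs) <- mat_names
  fallback <- is.na(cutoffs)
  if (any(fallback)) {
    if (is.na(config$mss_default))
      stop("no mss cutoff for matrix(es): ",
           paste(mat_names[fallback], collapse = ", "))
    cutoffs[fallback] <- config$mss_default
  }
  seqs <- vapply(seq_along(promoters), function(i)
    as.character(promoters[[i]]), "")
  names(seqs) <- names(promoters)
  hits <- list()
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    L <- ncol(prof$freqs)
    core <- prof$core_start:(prof$core_start + 4)
    b_all <- score_bounds(prof, seq_len(L))
    b_core <- score_bounds(prof, core)
    for (sid in names(seqs)) {
      code_f <- encode_seq(seqs[[sid]])
      n <- length(code_f)
      if (n < L) next
      rc <- c(0L, 4L, 3L, 2L, 1L)[rev(code_f) + 1L]
      for (strand in c("+", "-")) {
        code <- if (strand == "+") code_f else rc
        codes <- window_codes(code, L)
        mss <- normalize_score(weighted_score(prof, codes, seq_len(L)), b_all)
        css <- normalize_score(weighted_score(prof, codes, core), b_core)
        pass <- which(css >= config$css_cutoff & mss >= cutoffs[[pi]])
        if (!length(pass)) next
        off <- pass - 1L                       # 0-based on scanned strand
        if (strand == "-") off <- n - off - L  # map back to forward strand
        hits[[length(hits) + 1L]] <- data.frame(
          sequence_id = sid, matrix = mat_names[pi], strand = strand,
          offset = off, mss = mss[pass], css = css[pass])
      }
    }
  }
  if (!length(hits))
    return(data.frame(sequence_id = character(), matrix = character(),
                      strand = character(), offset = integer(),
                      mss = numeric(), css = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$matrix, out$sequence_id, out$offset, out$strand), ,
      drop = FALSE]
}

#' Matrix-by-gene hit incidence summary
#'
#' Counts, per matrix, the genes whose promoter carries at least one hit
#' (the per-module regulator summary).
#'
#' @param hits Data frame from [scan_promoters()].
#' @param gene_of Optional named character mapping sequence id -> gene id
#'   (defaults to identity).
#' @return Data frame with columns `matrix`, `n_genes`, `genes`.
#' @export
motif_hit_summary <- function(hits, gene_of = NULL) {
  if (!nrow(hits))
    return(data.frame(matrix = character(), n_genes = integer(),
                      genes = character()))
  g <- if (is.null(gene_of)) hits$sequence_id else gene_of[hits$sequence_id]
  sets <- lapply(split(g, hits$matrix), function(x) sort(unique(x)))
  data.frame(matrix = names(sets), n_genes = lengths(sets),
             genes = vapply(sets, paste, "", collapse = ","),
             row.names = NULL)
}
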