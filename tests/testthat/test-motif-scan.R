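# Match-style PWM scoring: profile construction, MSS/CSS against an
# exhaustive window oracle, strand handling, promoter extraction, and
# planted-site recovery.

peaked_pwm <- function(name = "M", cons = c(1, 2, 3, 4, 1), strength = 9) {
  counts <- matrix(1, 4, length(cons),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(cons, seq_along(cons))] <- strength
  pwm_record(name, counts)
}

test_that("profile information and core localization follow the definitions", {
  # uniform position carries zero information; a certain position ln 4
  counts <- matrix(c(4, 4, 4, 4,
                     16, 0, 0, 0,
                     8, 8, 0, 0,
                     0, 0, 16, 0,
                     4, 4, 4, 4,
                     16, 0, 0, 0), 4, 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  prof <- build_profile(pwm_record("T1", counts, pseudocount = 0))
  expect_equal(prof$info[1], 0, tolerance = 1e-12)
  expect_equal(prof$info[2], log(4), tolerance = 1e-12)
  expect_equal(prof$info[3], 0.5 * log(2) * 2, tolerance = 1e-12)
  # core = 5 consecutive positions with max summed info -> positions 2..6
  expect_equal(prof$core_start, 2)
  # leftmost tie rule: symmetric profile
  sym <- matrix(c(16, 0, 0, 0,  4, 4, 4, 4,  4, 4, 4, 4,
                  4, 4, 4, 4,  4, 4, 4, 4,  16, 0, 0, 0), 4, 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(build_profile(pwm_record("T2", sym, pseudocount = 0))$core_start,
               1)
  expect_error(build_profile(pwm_record("T3", counts[, 1:5])), NA)
})

test_that("consensus scores 1, anticonsensus scores 0", {
  rec <- peaked_pwm(cons = c(1, 2, 3, 4, 2, 3))
  prof <- build_profile(rec)
  expect_equal(unname(match_scores(prof, "ACGTCG")),
               c(1, 1), tolerance = 1e-12)
  # per-position argmin base: any base with count 1; A where consensus != A
  anti <- "CAAAAA"
  s <- match_scores(prof, anti)
  expect_equal(unname(s["mss"]), 0, tolerance = 1e-12)
  expect_error(match_scores(prof, "ACGT"), "length")
})

test_that("match scores agree with the exhaustive 4^5 window oracle", {
  set.seed(13)
  counts <- matrix(runif(20, 0.5, 12), 4, 5,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  rec <- pwm_record("R", counts, pseudocount = 1e-4)
  prof <- build_profile(rec)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                      b5 = bases, stringsAsFactors = FALSE)
  windows <- apply(grid, 1, paste, collapse = "")
  got <- t(vapply(windows, function(w) match_scores(prof, w), numeric(2)))
  want_mss <- vapply(windows, function(w)
    oracle_score(prof$freqs, prof$info, w, 1:5), numeric(1))
  core <- prof$core_start:(prof$core_start + 4)
  want_css <- vapply(windows, function(w)
    oracle_score(prof$freqs, prof$info, w, core), numeric(1))
  expect_equal(unname(got[, 1]), unname(want_mss), tolerance = 1e-12)
  expect_equal(unname(got[, 2]), unname(want_css), tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("scores are invariant under rescaling all counts", {
  rec1 <- peaked_pwm(cons = c(2, 4, 1, 3, 3, 1))
  rec2 <- pwm_record("S", rec1$counts * 7.5, pseudocount = 0)
  rec1 <- pwm_record("S", rec1$counts, pseudocount = 0)
  for (w in c("CTAGGA", "AAAAAA", "CTAGCA"))
    expect_equal(match_scores(build_profile(rec1), w),
                 match_scores(build_profile(rec2), w), tolerance = 1e-12)
})

test_that("ambiguous bases score as the position minimum", {
  rec <- peaked_pwm(cons = c(1, 1, 1, 1, 1))
  prof <- build_profile(rec)
  s_n <- match_scores(prof, "ANAAA")
  s_min <- match_scores(prof, "ACAAA")  # C is a minimal base at position 2
  expect_equal(s_n, s_min, tolerance = 1e-12)
})

test_that("promoter extraction honors strand and boundary conventions", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep(c("A", "C", "G", "T"), length.out = 50), collapse = "")))
  tx <- data.frame(chrom = c("chr1", "chr1", "chr1", "chrX"),
                   strand = c("+", "+", "-", "+"),
                   tss = c(20, 5, 30, 10),
                   name = c("t_plus", "t_trunc", "t_minus", "t_unknown"))
  expect_warning(expect_warning(
    pr <- extract_promoters(genome, tx, length = 10),
    "truncated"), "unknown contig")
  expect_equal(names(pr), c("t_plus", "t_trunc", "t_minus"))
  chr1 <- as.character(genome[[1]])
  expect_equal(as.character(pr[["t_plus"]]), substr(chr1, 11, 20))
  expect_equal(as.character(pr[["t_trunc"]]), substr(chr1, 1, 5))
  expect_equal(as.character(pr[["t_minus"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr1, 31, 40)))))
})

test_that("scanning finds planted sites on both strands at css = 1", {
  rec <- peaked_pwm("P", cons = c(1, 2, 3, 1, 4, 2, 3, 1), strength = 97)
  cons <- pwm_consensus(rec)
  set.seed(5)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  fwd <- paste0(bg(40), cons, bg(40))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  rev <- paste0(bg(30), rc, bg(30))
  proms <- Biostrings::DNAStringSet(c(p_fwd = fwd, p_rev = rev))
  cfg <- analysis_config(css_cutoff = 1.0, mss_default = 0.99)
  hits <- scan_promoters(proms, list(build_profile(rec)), cfg)
  fwd_hit <- hits[hits$sequence_id == "p_fwd" & hits$strand == "+", ]
  expect_equal(fwd_hit$offset, 40)
  expect_equal(fwd_hit$mss, 1, tolerance = 1e-12)
  rev_hit <- hits[hits$sequence_id == "p_rev" & hits$strand == "-", ]
  expect_equal(rev_hit$offset, 30)
  # all emitted hits respect the cutoffs
  expect_true(all(hits$css >= 1 - 1e-12 & hits$mss >= 0.99))
  # empty promoter set
  expect_equal(nrow(scan_promoters(Biostrings::DNAStringSet(),
                                   list(build_profile(rec)), cfg)), 0)
  # matrix without a cutoff errors when no default is available
  cfg_na <- analysis_config(css_cutoff = 1, mss_default = NA)
  expect_error(scan_promoters(proms, list(build_profile(rec)), cfg_na), "P")
})

test_that("reverse-complement scanning is strand-symmetric", {
  rec <- peaked_pwm("P", cons = c(3, 1, 4, 2, 2, 1), strength = 50)
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  s <- paste0(substr(s, 1, 100), pwm_consensus(rec), substr(s, 107, 200))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cfg <- analysis_config(css_cutoff = 0.9, mss_default = 0.9)
  h1 <- scan_promoters(Biostrings::DNAStringSet(c(x = s)),
                       list(build_profile(rec)), cfg)
  h2 <- scan_promoters(Biostrings::DNAStringSet(c(x = rc)),
                       list(build_profile(rec)), cfg)
  expect_equal(nrow(h1), nrow(h2))
  # a + hit at offset o maps to a - hit at n - o - L
  L <- ncol(rec$counts)
  mapped <- sort(nchar(s) - h1$offset - L)
  expect_equal(sort(h2$offset), mapped)
  expect_equal(sort(h1$mss), sort(h2$mss), tolerance = 1e-12)
})

test_that("the hit summary counts genes with at least one hit per matrix", {
  hits <- data.frame(
    sequence_id = c("g1.tr1", "g1.tr1", "g2.tr1", "g3.tr1"),
    matrix = c("M1", "M1", "M1", "M2"),
    strand = "+", offset = 0L, mss = 1, css = 1)
  gene_of <- setNames(c("g1", "g2", "g3"),
                      c("g1.tr1", "g2.tr1", "g3.tr1"))
  s <- motif_hit_summary(hits, gene_of)
  expect_equal(s$n_genes[s$matrix == "M1"], 2L)
  expect_equal(s$n_genes[s$matrix == "M2"], 1L)
})

test_that("simulated planted motif sites are all recovered at css 1", {
  sim <- simulate_all(sim_params(seed = 23))
  profs <- lapply(sim$pwms, build_profile)
  cfg <- analysis_config(css_cutoff = 1.0, mss_default = 0.95)
  hits <- scan_promoters(sim$promoters, profs, cfg)
  planted <- sim$truth$planted_motif_sites
  found <- merge(planted, hits,
                 by = c("sequence_id", "matrix", "offset"))
  expect_equal(nrow(found), nrow(planted))  # zero misses
  expect_true(all(found$mss >= 0.95))
})
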