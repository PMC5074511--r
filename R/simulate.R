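# Synthetic-data generator. Emulates the structure of the study design the
# pipeline targets: one normal series with 4 surface-marker-sorted mammary
# populations (population-specific over/under-expressed genes), two CSC
# series with per-subtype CSC vs non-CSC contrasts whose signatures overlap
# a planted true origin, an interaction network in which shared genes are
# proximal, an ontology annotating signature genes to population-specific
# terms, and promoters carrying planted consensus sites of one PWM.

#' Simulation parameters
#'
#' Defaults define the study conditions used throughout the test-suite and
#' acceptance runs: 2000 genes, 4 normal populations and 4 subtypes with 4
#' samples per group, 150 signature genes per group and direction, 60% of
#' each CSC signature drawn from its true origin's signature, a 2 log2-unit
#' effect over N(8, 1) baselines with N(0, 0.5^2) sample noise, and two CSC
#' pseudo-datasets differing by an independent noise draw plus a per-gene
#' N(0, 0.2^2) dataset offset.
#'
#' @param n_genes,n_populations,n_subtypes,samples_per_group Counts.
#' @param n_signature_per_group Planted signature genes per group per
#'   direction.
#' @param shared_fraction Fraction of each CSC generating set drawn from the
#'   true origin's set, in \[0, 1\].
#' @param effect_size Planted shift in log2 units (> 0).
#' @param noise_sd Per-sample Gaussian noise sd (log2 units).
#' @param n_datasets Number of CSC pseudo-datasets.
#' @param dataset_offset_sd Sd of the per-gene dataset-level offset.
#' @param network_extra_edges Random edges added beyond the planted
#'   structure.
#' @param module_size Genes per planted module.
#' @param module_cor Target pairwise noise correlation of planted module
#'   genes (a shared latent factor replaces this fraction of their noise
#'   variance, leaving per-gene marginal variance unchanged).
#' @param n_background_terms Ontology terms annotating non-signature genes.
#' @param promoter_length Length of simulated promoter sequences.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000, n_populations = 4, n_subtypes = 4,
                       samples_per_group = 4, n_signature_per_group = 150,
                       shared_fraction = 0.6, effect_size = 2.0,
                       noise_sd = 0.5, n_datasets = 2,
                       dataset_offset_sd = 0.2, network_extra_edges = 6000,
                       module_size = 12, module_cor = 0.8,
                       n_background_terms = 30, promoter_length = 2000,
                       seed = 1L) {
  p <- list(n_genes = n_genes, n_populations = n_populations,
            n_subtypes = n_subtypes, samples_per_group = samples_per_group,
            n_signature_per_group = n_signature_per_group,
            shared_fraction = shared_fraction, effect_size = effect_size,
            noise_sd = noise_sd, n_datasets = n_datasets,
            dataset_offset_sd = dataset_offset_sd,
            network_extra_edges = network_extra_edges,
            module_size = module_size, module_cor = module_cor,
            n_background_terms = n_background_terms,
            promoter_length = promoter_length, seed = as.integer(seed))
  if (effect_size <= 0) stop("effect_size must be positive")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (shared_fraction > 0 && shared_fraction * n_signature_per_group < 1)
    stop("shared_fraction * n_signature_per_group must be at least 1")
  if (module_cor < 0 || module_cor >= 1)
    stop("module_cor must lie in [0, 1)")
  if (2 * n_populations * n_signature_per_group > n_genes)
    stop("population signature sets exceed n_genes")
  free <- n_genes - 2 * n_populations * n_signature_per_group
  per_subtype_free <- 2 * ceiling((1 - shared_fraction) * n_signature_per_group)
  if (per_subtype_free > free)
    stop("not enough non-signature genes for the CSC generating sets")
  structure(p, class = "sim_params")
}

.canonical_pops <- c("bipotent", "lum_progenitor", "mature_luminal",
                     "myoepithelial")
.canonical_subtypes <- c("luminalA", "luminalB", "her2", "basal")

sim_core <- function(params, null) {
  set.seed(params$seed)
  n <- params$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  k <- params$n_populations
  pops <- if (k == 4) .canonical_pops else paste0("pop", seq_len(k))
  ns <- params$n_subtypes
  subtypes <- if (ns == 4) .canonical_subtypes else paste0("subtype", seq_len(ns))
  m <- params$n_signature_per_group
  spg <- params$samples_per_group
  eff <- params$effect_size

  perm <- sample(genes)
  pop_over <- pop_under <- setNames(vector("list", k), pops)
  at <- 0
  for (p in pops) {
    pop_over[[p]] <- perm[at + seq_len(m)]; at <- at + m
    pop_under[[p]] <- perm[at + seq_len(m)]; at <- at + m
  }
  free_pool <- perm[-seq_len(at)]

  true_origin <- setNames(sample(pops, ns, replace = TRUE), subtypes)

  # planted modules live on the free pool: no hub-star edges and no role in
  # the CSC-vs-nonCSC contrasts, so module coherence is purely the planted
  # latent factor. Their genes are down-shifted in every CSC-dataset sample
  # below, which places them in the origin-specific (CSC vs origin)
  # signature, emulating a coherently down-regulated module in the cancer
  # state. Condition "csc" is CSC dataset 1, condition "origin" the normal
  # series.
  msz <- params$module_size
  focus <- subtypes[min(2L, ns)]
  mod_pool <- sample(free_pool, 3 * msz)
  csc_fill_pool <- setdiff(free_pool, mod_pool)

  n_shared <- if (null) 0L else round(params$shared_fraction * m)
  csc_up <- csc_down <- shared_up <- shared_down <-
    setNames(vector("list", ns), subtypes)
  for (s in subtypes) {
    if (null) {
      pick <- sample(genes, 2 * m)
      csc_up[[s]] <- pick[seq_len(m)]
      csc_down[[s]] <- pick[m + seq_len(m)]
      shared_up[[s]] <- shared_down[[s]] <- character()
    } else {
      p <- true_origin[[s]]
      shared_up[[s]] <- sample(pop_over[[p]], n_shared)
      shared_down[[s]] <- sample(pop_under[[p]], n_shared)
      fill <- sample(csc_fill_pool, 2 * (m - n_shared))
      csc_up[[s]] <- c(shared_up[[s]], fill[seq_len(m - n_shared)])
      csc_down[[s]] <- c(shared_down[[s]], fill[m - n_shared + seq_len(m - n_shared)])
    }
  }
  if (null) true_origin[] <- NA_character_
  ov1 <- max(2L, round(2 * msz / 3)); ov2 <- max(2L, round(msz / 2))
  csc_mod1 <- mod_pool[seq_len(msz)]
  origin_mod1 <- c(csc_mod1[seq_len(ov1)],
                   mod_pool[msz + seq_len(msz - ov1)])
  csc_mod2 <- mod_pool[2 * msz - ov1 + seq_len(msz)]
  origin_mod2 <- c(csc_mod2[seq_len(ov2)],
                   mod_pool[3 * msz - ov1 + seq_len(min(msz - ov2, ov1))])
  planted_modules <- list(csc = list(csc_mod1, csc_mod2),
                          origin = list(origin_mod1, origin_mod2))

  mu <- rnorm(n, 8, 1)
  names(mu) <- genes

  # noise generator: planted module genes draw a fraction module_cor of
  # their noise variance from a per-module latent factor (fresh per matrix),
  # so they are pairwise correlated while every gene keeps the same marginal
  # noise sd -- differential calls are unaffected in distribution
  all_mods <- c(planted_modules$csc, planted_modules$origin)
  mod_idx <- lapply(all_mods, function(mod) match(mod, genes))
  mod_union <- unique(unlist(planted_modules))
  rho <- params$module_cor
  module_noise <- function(n_samp) {
    E <- matrix(rnorm(n * n_samp), n, n_samp)
    if (rho > 0 && length(all_mods)) {
      FM <- matrix(0, n, n_samp)
      k_g <- integer(n)
      for (mi in seq_along(all_mods)) {
        u <- rnorm(n_samp)
        idx <- mod_idx[[mi]]
        FM[idx, ] <- FM[idx, ] + rep(u, each = length(idx))
        k_g[idx] <- k_g[idx] + 1L
      }
      sel <- k_g > 0
      FM[sel, ] <- FM[sel, ] / sqrt(k_g[sel])
      E[sel, ] <- sqrt(rho) * FM[sel, ] + sqrt(1 - rho) * E[sel, ]
    }
    E * params$noise_sd
  }

  # normal series: one group per population
  n_norm <- k * spg
  norm_vals <- module_noise(n_norm) + mu
  norm_samples <- character(n_norm); norm_groups <- character(n_norm)
  j <- 0
  for (p in pops) for (r in seq_len(spg)) {
    j <- j + 1
    norm_samples[j] <- sprintf("norm.%s.%d", p, r)
    norm_groups[j] <- p
    norm_vals[match(pop_over[[p]], genes), j] <-
      norm_vals[match(pop_over[[p]], genes), j] + eff
    norm_vals[match(pop_under[[p]], genes), j] <-
      norm_vals[match(pop_under[[p]], genes), j] - eff
  }
  dimnames(norm_vals) <- list(genes, norm_samples)
  normal <- expression_matrix(norm_vals, setNames(norm_groups, norm_samples))

  # CSC pseudo-datasets
  csc_datasets <- vector("list", params$n_datasets)
  names(csc_datasets) <- paste0("d", seq_len(params$n_datasets))
  for (d in seq_len(params$n_datasets)) {
    offset <- rnorm(n, 0, params$dataset_offset_sd)
    n_csc <- ns * 2 * spg
    vals <- module_noise(n_csc) + mu + offset
    samples <- character(n_csc); grp <- character(n_csc)
    j <- 0
    for (s in subtypes) for (cls in c("CSC", "nonCSC")) for (r in seq_len(spg)) {
      j <- j + 1
      samples[j] <- sprintf("d%d.%s.%s.%d", d, s, cls, r)
      grp[j] <- paste0(s, ".", cls)
      if (cls == "CSC") {
        vals[match(csc_up[[s]], genes), j] <-
          vals[match(csc_up[[s]], genes), j] + eff
        vals[match(csc_down[[s]], genes), j] <-
          vals[match(csc_down[[s]], genes), j] - eff
      }
    }
    # planted module genes are coherently down in the cancer condition
    vals[match(mod_union, genes), ] <- vals[match(mod_union, genes), ] - eff
    dimnames(vals) <- list(genes, samples)
    csc_datasets[[d]] <- expression_matrix(vals, setNames(grp, samples))
  }

  # interaction network: per-population hub stars keep each signature set
  # (and hence the planted shared genes) within distance 2; planted modules
  # are cliques; plus random background edges
  ea <- character(0); eb <- character(0)
  for (sets in list(pop_over, pop_under)) for (p in pops) {
    g <- sets[[p]]
    ea <- c(ea, rep(g[1], length(g) - 1)); eb <- c(eb, g[-1])
  }
  for (cond in planted_modules) for (mod in cond) {
    pr <- combn(mod, 2)
    ea <- c(ea, pr[1, ]); eb <- c(eb, pr[2, ])
    # modules are dense complexes with sparse external connectivity
    ea <- c(ea, mod[1:2])
    eb <- c(eb, sample(setdiff(genes, mod_union), 2))
  }
  ra <- sample(genes, params$network_extra_edges, replace = TRUE)
  rb <- sample(genes, params$network_extra_edges, replace = TRUE)
  ok <- ra != rb & !(ra %in% mod_union) & !(rb %in% mod_union)
  ea <- c(ea, ra[ok]); eb <- c(eb, rb[ok])
  network <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(ea, eb), directed = FALSE,
    vertices = data.frame(name = genes)))

  # ontology: root <- {signature, background} <- leaf terms; every gene
  # annotated to exactly one leaf
  sig_terms <- as.vector(outer(pops, c("over", "under"),
                               function(p, d) paste0("T:", p, ".", d)))
  bg_terms <- sprintf("T:BG%02d", seq_len(params$n_background_terms))
  terms <- c("T:ROOT", "T:SIG", "T:BGROOT", sig_terms, bg_terms)
  parents <- c(list(character(), "T:ROOT", "T:ROOT"),
               rep(list("T:SIG"), length(sig_terms)),
               rep(list("T:BGROOT"), length(bg_terms)))
  names(parents) <- terms
  gene_term <- setNames(sample(bg_terms, n, replace = TRUE), genes)
  for (p in pops) {
    gene_term[pop_over[[p]]] <- paste0("T:", p, ".over")
    gene_term[pop_under[[p]]] <- paste0("T:", p, ".under")
  }
  ontology <- ontology_annotation(terms, parents,
                                  lapply(as.list(gene_term), identity))

  # PWMs and promoters: promoters of the first csc-condition module carry an
  # exact consensus site of the designated matrix
  make_pwm <- function(name, L) {
    cons <- sample(1:4, L, replace = TRUE)
    counts <- matrix(1, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(cons, seq_len(L))] <- 97
    pwm_record(name, counts)
  }
  pwms <- list(make_pwm("TF_PLANTED", 10), make_pwm("TF_DECOY1", 9),
               make_pwm("TF_DECOY2", 11))
  consensus <- pwm_consensus(pwms[[1]])
  Lc <- nchar(consensus)
  promoter_genes <- unique(c(unlist(planted_modules$csc),
                             sample(free_pool, 20)))
  plen <- params$promoter_length
  seqs <- vapply(promoter_genes, function(g)
    paste(sample(c("A", "C", "G", "T"), plen, replace = TRUE), collapse = ""),
    "")
  site_rows <- list()
  for (g in planted_modules$csc[[1]]) {
    pos <- sample.int(plen - Lc + 1, 1)          # 1-based insertion point
    substr(seqs[[g]], pos, pos + Lc - 1) <- consensus
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      sequence_id = paste0(g, ".tr1"), matrix = "TF_PLANTED",
      offset = pos - 1L)                          # 0-based, forward strand
  }
  promoters <- Biostrings::DNAStringSet(seqs)
  names(promoters) <- paste0(promoter_genes, ".tr1")
  planted_sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(sequence_id = character(), matrix = character(),
               offset = integer())

  truth <- list(
    true_origin = true_origin,
    population_signatures = list(over = pop_over, under = pop_under),
    csc_signatures = list(up = csc_up, down = csc_down),
    planted_shared_genes = setNames(lapply(subtypes, function(s)
      list(up = shared_up[[s]], down = shared_down[[s]])), subtypes),
    planted_modules = planted_modules,
    planted_motif_sites = planted_sites,
    planted_pwm = "TF_PLANTED",
    focus_subtype = focus,
    seed = params$seed)

  structure(list(
    normal = normal, csc_datasets = csc_datasets, network = network,
    ontology = ontology, promoters = promoters, pwms = pwms,
    truth = truth, params = params,
    conditions = list(csc = colnames(csc_datasets[[1]]$values),
                      origin = colnames(normal$values))),
    class = "stemtrace_sim")
}

#' Simulate all pipeline inputs with planted ground truth
#'
#' Generates the normal-population expression matrix, the CSC pseudo-dataset
#' matrices, an interaction network, an ontology with gene annotations,
#' promoter sequences, PWMs, and a ground-truth record (true origin per
#' subtype, planted shared genes, planted modules, planted motif sites). All
#' randomness derives from `params$seed`; identical parameters give
#' identical output.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `stemtrace_sim` with elements `normal`,
#'   `csc_datasets`, `network`, `ontology`, `promoters`, `pwms`, `truth`,
#'   `params`, and `conditions` (the sample sets defining the two
#'   module-detection conditions).
#' @export
simulate_all <- function(params = sim_params()) sim_core(params, null = FALSE)

#' Simulate the matched null: CSC signatures unrelated to any population
#'
#' Identical generative process to [simulate_all()] except that the CSC
#' generating sets are drawn uniformly from all genes, independent of every
#' population (shared fraction forced to 0), so signature overlaps are
#' hypergeometric-null. Used to calibrate the false-positive behavior of the
#' rank fusion.
#'
#' @param params A [sim_params()] object.
#' @return Same structure as [simulate_all()]; `truth$true_origin` is `NA`.
#' @export
simulate_null <- function(params = sim_params()) sim_core(params, null = TRUE)

#' @export
print.stemtrace_sim <- function(x, ...) {
  cat(sprintf(paste0("<stemtrace_sim> %d genes; normal: %d samples / %d ",
                     "populations; %d CSC dataset(s) of %d samples\n"),
              nrow(x$normal$values), ncol(x$normal$values),
              length(unique(x$normal$groups)), length(x$csc_datasets),
              ncol(x$csc_datasets[[1]]$values)))
  invisible(x)
}

#' Write all simulated inputs to a directory in the pipeline's file formats
#'
#' Expression + groups TSVs, network edge list, OBO + annotation TSV,
#' promoters FASTA, TRANSFAC matrices, signature GMTs of the generating
#' sets, and `truth.json`.
#'
#' @param sim A `stemtrace_sim`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_expression(sim$normal, fp("normal.tsv"), fp("normal.groups.tsv"))
  for (d in names(sim$csc_datasets))
    write_expression(sim$csc_datasets[[d]], fp(paste0("csc.", d, ".tsv")),
                     fp(paste0("csc.", d, ".groups.tsv")))
  write_network(sim$network, fp("network.tsv"))
  write_ontology(sim$ontology, fp("ontology.obo"), fp("annotations.tsv"))
  Biostrings::writeXStringSet(sim$promoters, fp("promoters.fa"))
  write_pwm(sim$pwms, fp("matrices.transfac"))
  gen <- c(setNames(sim$truth$population_signatures$over,
                    paste0(names(sim$truth$population_signatures$over), ".over")),
           setNames(sim$truth$population_signatures$under,
                    paste0(names(sim$truth$population_signatures$under), ".under")))
  write_gmt(gen, fp("population_generating_sets.gmt"))
  truth <- sim$truth
  truth$true_origin <- as.list(truth$true_origin)  # keep names in JSON
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
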