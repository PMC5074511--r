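# The four concordance measures, each against an independent oracle or a
# hand-computed value.

test_that("overlap p-value matches exhaustive enumeration on small universes", {
  # spot checks including the worked cases
  expect_equal(overlap_pvalue(letters[1:5], letters[6:10], letters[1:10]), 1)
  expect_equal(overlap_pvalue(letters[1:5], letters[1:5], letters[1:10]),
               1 / choose(10, 5), tolerance = 1e-12)
  # universe 20, |a| = 6, |b| = 5, q = 3: closed-form tail sum
  u20 <- sprintf("u%02d", 1:20)
  got <- overlap_pvalue(u20[1:6], u20[c(1:3, 19:20)], u20)
  want <- sum(vapply(3:5, function(x)
    choose(6, x) * choose(14, 5 - x), numeric(1))) / choose(20, 5)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(want, enum_overlap_pvalue(20, 6, 5, 3), tolerance = 1e-12)
  # systematic sweep over small universes
  for (nn in c(6, 9, 12)) {
    uni <- sprintf("x%02d", seq_len(nn))
    for (na in c(2, nn %/% 2)) for (nb in c(3, nn %/% 2)) {
      for (q in 0:min(na, nb)) {
        a <- uni[seq_len(na)]
        b <- uni[c(seq_len(q), setdiff(seq_len(nn), seq_len(na)))[seq_len(nb)]]
        if (length(intersect(a, b)) != q) next
        expect_equal(overlap_pvalue(a, b, uni),
                     enum_overlap_pvalue(nn, na, nb, q), tolerance = 1e-12)
      }
    }
  }
})

test_that("overlap p-value is monotone decreasing in the overlap", {
  uni <- sprintf("x%02d", 1:30)
  prev <- 1.0001
  for (q in 0:8) {
    b <- uni[c(seq_len(q), 23:30)][1:8]
    p <- overlap_pvalue(uni[1:10], b, uni)
    expect_lt(p, prev)
    prev <- p
  }
  expect_error(overlap_pvalue(c("zz"), uni[1], uni), "universe")
})

test_that("GSS evaluates its formula on hand-worked cases", {
  em <- toy_expr(c(9, 7, 8, 8, 6, 10), c("g1", "g2", "g3"),
                 c("s1", "s2"), c("P", "P"))
  # single gene, x = 2: z(g1) = 8, y(s1) = 9 -> (2 * 1)/2 = 1
  sig1 <- signature_set("t", "g1", c(g1 = 2), c(g1 = 0.01), "up")
  expect_equal(as.numeric(gss_sample(sig1, em, "s1")), 1, tolerance = 1e-12)
  # centered case: y = z -> 0 (g2 is constant across samples)
  sig3 <- signature_set("t3", "g2", c(g2 = 1.5), c(g2 = 0.01), "up")
  expect_equal(as.numeric(gss_sample(sig3, em, "s1")), 0, tolerance = 1e-12)
  # mixed-direction two-gene set: x = (1, -1), y - z = (1, -1) -> 1;
  # built directly since the constructor enforces one direction per set
  m <- matrix(c(9, 7, 3, 5), 2, 2, dimnames = list(c("u", "d"),
                                                   c("s1", "s2")))
  em2 <- expression_matrix(m, c(s1 = "P", s2 = "P"))
  sigm <- structure(list(label = "mix", genes = c("u", "d"),
                         log2fc = c(u = 1, d = -1),
                         pvalue = c(u = 0.01, d = 0.01), direction = "up"),
                    class = "signature_set")
  expect_equal(as.numeric(gss_sample(sigm, em2, "s1")), 1, tolerance = 1e-12)
})

test_that("GSS negates under signature negation and shifts cancel", {
  set.seed(7)
  m <- matrix(rnorm(40, 8, 1), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:4)))
  em <- expression_matrix(m, setNames(rep("P", 4), colnames(m)))
  x <- setNames(runif(5, 0.5, 2), rownames(m)[1:5])
  sig <- signature_set("s", names(x), x, setNames(rep(0.01, 5), names(x)),
                       "up")
  neg <- structure(list(label = "n", genes = names(x), log2fc = -x,
                        pvalue = sig$pvalue, direction = "down"),
                   class = "signature_set")
  g1 <- as.numeric(gss_sample(sig, em, "s2"))
  expect_equal(as.numeric(gss_sample(neg, em, "s2")), -g1, tolerance = 1e-12)
  # adding a constant to every sample's value of a gene leaves GSS unchanged
  m2 <- m; m2["g03", ] <- m2["g03", ] + 5
  em_shift <- expression_matrix(m2, em$groups)
  expect_equal(as.numeric(gss_sample(sig, em_shift, "s2")), g1,
               tolerance = 1e-12)
  # population score of identical samples equals the single-sample score
  m3 <- m[, c(1, 1, 1), drop = FALSE]; colnames(m3) <- paste0("t", 1:3)
  em3 <- expression_matrix(m3, setNames(rep("P", 3), colnames(m3)))
  expect_equal(as.numeric(gss_population(sig, em3, "P")),
               as.numeric(gss_sample(sig, em3, "t1")), tolerance = 1e-12)
})

test_that("information content follows annotation counts", {
  onto <- compute_ic(chain_ontology())
  expect_equal(unname(onto$ic["root"]), 0)
  expect_equal(unname(onto$ic["t1"]), -log(2 / 4), tolerance = 1e-12)
  expect_equal(unname(onto$ic["t2"]), -log(1 / 4), tolerance = 1e-12)
  # child IC >= parent IC along every edge
  for (t in onto$terms) for (p in onto$parents[[t]])
    expect_gte(onto$ic[[t]], onto$ic[[p]])
})

test_that("Lin similarity: identity, root-only meeting, and the chain value", {
  onto <- compute_ic(chain_ontology())
  expect_equal(lin_sim("t1", "t1", onto), 1)
  expect_equal(lin_sim("root", "t2", onto), 0)  # MICA is root, ic 0
  got <- lin_sim("t1", "t2", onto)
  want <- 2 * log(2) / (log(2) + log(4))        # MICA = t1
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(abs(got - 0.663), 0.005)
  expect_error(lin_sim("t1", "nope", onto), "unknown term")
  # two siblings meeting only at root score 0
  sib <- compute_ic(ontology_annotation(
    c("root", "a", "b"),
    list(root = character(), a = "root", b = "root"),
    list(g1 = "a", g2 = "b")))
  expect_equal(lin_sim("a", "b", sib), 0)
})

test_that("BMA combination reproduces the worked 2x2 example", {
  M <- matrix(c(1.0, 0.4, 0.2, 0.6), 2, 2)  # rows genes of A
  expect_equal(stemtrace:::bma_combine(M), 0.8, tolerance = 1e-12)
})

test_that("set similarity is symmetric, bounded, and exact on toys", {
  onto <- compute_ic(chain_ontology())
  expect_equal(as.numeric(setsim_bma("g1", "g1", onto)), 1)
  sib <- compute_ic(ontology_annotation(
    c("root", "a", "b"),
    list(root = character(), a = "root", b = "root"),
    list(g1 = "a", g2 = "b")))
  expect_equal(as.numeric(setsim_bma("g1", "g2", sib)), 0)
  s12 <- as.numeric(setsim_bma(c("g1", "g3"), c("g2", "g4"), onto))
  s21 <- as.numeric(setsim_bma(c("g2", "g4"), c("g1", "g3"), onto))
  expect_equal(s12, s21, tolerance = 1e-12)
  expect_true(s12 >= 0 && s12 <= 1)
  expect_warning(r <- setsim_bma("unannotated", "g1", onto), "no annotated")
  expect_true(is.nan(r))
})

test_that("mean shortest path matches hand enumeration on a path graph", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("a", "b"), b = c("b", "c")), directed = FALSE)
  expect_equal(as.numeric(mean_shortest_path("a", "c", g)), 2)
  expect_equal(as.numeric(mean_shortest_path(c("a", "b"), "c", g)), 1.5)
  # a gene in both sets contributes only via pairs of distinct genes
  expect_equal(as.numeric(mean_shortest_path("a", c("a", "c"), g)), 2)
  # symmetry
  expect_equal(as.numeric(mean_shortest_path("c", c("a", "b"), g)), 1.5)
  # unreachable pairs excluded and counted
  g2 <- igraph::add_vertices(g, 1, name = "z")
  r <- mean_shortest_path(c("a", "z"), "c", g2)
  expect_equal(as.numeric(r), 2)
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_warning(mean_shortest_path("z", "a", g2), "no connected pair")
})

test_that("mean shortest path agrees with a dense all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    labels <- sprintf("v%02d", 1:n)
    adj <- matrix(0, n, n)
    edges <- which(upper.tri(adj))[runif(sum(upper.tri(adj))) < 0.08]
    adj[edges] <- 1
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(
      `dimnames<-`(adj, list(labels, labels)), mode = "undirected")
    A <- sample(labels, 5); B <- sample(labels, 6)
    got <- suppressWarnings(as.numeric(mean_shortest_path(A, B, g)))
    want <- dense_mean_sp(adj, labels, A, B)
    if (is.nan(want)) expect_true(is.nan(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("score_all fills every cell and marks empty signatures NaN", {
  params <- sim_params(n_genes = 400, n_signature_per_group = 25,
                       network_extra_edges = 1200, seed = 5)
  sim <- simulate_all(params)
  pop_sigs <- call_population_signatures(sim$normal)
  expr <- sim$csc_datasets[[1]]
  subtypes <- csc_subtypes(expr)
  sigs <- lapply(setNames(subtypes, subtypes), function(s) {
    cs <- call_csc_signatures(expr, s)
    list(up = cs$up, down = cs$down)
  })
  # force one empty down-signature
  sigs[[1]]$down <- signature_set(paste0(subtypes[1], ".down"), character(),
                                  numeric(), numeric(), "down")
  mv <- score_all(sigs, pop_sigs, sim$normal, sim$ontology, sim$network)
  expect_equal(nrow(mv), 4 * 4 * 2 * 4)  # subtypes x pops x dirs x measures
  bad <- mv[mv$subtype == subtypes[1] & mv$direction == "down", ]
  expect_true(all(is.nan(bad$value)))
  good <- mv[!(mv$subtype == subtypes[1] & mv$direction == "down"), ]
  expect_true(all(is.finite(good$value)))
  expect_true(all(mv$value[mv$measure == "enrich_p" & is.finite(mv$value)] <= 1))
  expect_true(all(mv$value[mv$measure == "sss" & is.finite(mv$value)] >= 0))
})
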