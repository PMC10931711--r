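test_that("factor-event correlation keeps strong monotone relationships", {
  set.seed(1)
  n <- 30
  pd <- matrix(runif(2 * n, 0.2, 0.8), 2, n)
  p <- toy_pdui(pd)
  ex <- rbind(F1 = pd[1, ] * 10 + 1,         # perfect monotone with event 1
              F2 = runif(n))
  colnames(ex) <- colnames(p)
  edges <- quiet(factor_event_correlation(expression_table(ex), p))
  e1 <- edges[edges$factor == "F1" & edges$event_id == rownames(p)[1], ]
  expect_equal(e1$rho, 1)
  expect_lt(e1$p, 1e-10)
  expect_error(quiet(factor_event_correlation(
    expression_table(ex[, 1:3]), toy_pdui(pd[, 1:3]))), ">= 5")
})

test_that("null factor-event pairs pass p < 0.05 at roughly the nominal rate", {
  set.seed(10)
  n <- 100
  pd <- toy_pdui(matrix(runif(10 * n), 10, n))
  ex <- matrix(rlnorm(50 * n), 50, n,
               dimnames = list(sprintf("F%02d", 1:50), colnames(pd)))
  edges <- quiet(factor_event_correlation(expression_table(ex), pd,
                                          rho_threshold = 0))
  expect_lt(abs(nrow(edges) / 500 - 0.05), 0.04)
})

test_that("planted copula regulators are recovered with accurate rho", {
  co <- simulate_cohort(simulation_config(
    n_responders = 50, n_nonresponders = 50, n_events = 50, n_diff_events = 0,
    n_genes = 100, n_factors = 4, n_regulated_per_factor = 8,
    n_immune_events = 0, regulation_strength = 0.6, missing_rate = 0, seed = 2))
  ft <- co$truth$factor_targets
  fx <- expression_table(unclass(co$expr)[co$truth$factors, , drop = FALSE])
  edges <- quiet(factor_event_correlation(fx, co$pdui))
  key <- paste(edges$factor, edges$event_id)
  hit <- paste(ft$factor, ft$event_id) %in% key
  expect_gte(mean(hit), 0.9)
  got <- merge(edges, ft, by = c("factor", "event_id"))
  expect_lt(abs(mean(abs(got$rho)) - 0.6), 0.15)
})

test_that("ATF network unions correlation and PPI evidence with restriction", {
  ce <- data.frame(factor = "F1", event_id = "GA|chr1|10",
                   rho = 0.8, p = 0.001)
  ppi <- interaction_table(data.frame(
    gene_a = c("F1", "F2", "GB"), gene_b = c("F2", "OUTSIDER", "F1"),
    combined_score = c(900L, 950L, 800L)))
  g <- build_atf_network(ce, ppi, factors = c("F1", "F2"),
                         event_ids = c("GA|chr1|10", "GB|chr2|20"),
                         directions = c("GA|chr1|10" = "shortened",
                                        "GB|chr2|20" = "lengthened"))
  expect_equal(igraph::vcount(g), 4)  # OUTSIDER excluded
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$type[igraph::V(g)$name %in% c("F1", "F2")],
                  "factor")
  expect_equal(igraph::V(g)$direction[igraph::V(g)$name == "GA"], "shortened")
  # parallel correlation + PPI evidence merges to one edge
  ppi2 <- interaction_table(data.frame(gene_a = "F1", gene_b = "GA",
                                       combined_score = 901L))
  g2 <- build_atf_network(ce, ppi2, c("F1"), "GA|chr1|10")
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$type, "both")
  expect_equal(igraph::E(g2)$rho, 0.8)
  expect_equal(igraph::E(g2)$score, 901)
})

test_that("centralities behave correctly on canonical small graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  cs <- centrality_suite(star, epc_samples = 200)
  for (alg in c("Degree", "Betweenness", "Stress", "Closeness")) {
    expect_equal(unname(which.max(cs$scores[, alg])), 1)
    expect_equal(unname(cs$ranks["hub", alg]), 1)
    leaf_scores <- cs$scores[paste0("leaf", 1:4), alg]
    expect_true(all(leaf_scores == leaf_scores[1]))  # leaves tie
  }
  path <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C")), directed = FALSE)
  cp <- centrality_suite(path, epc_samples = 100)
  expect_equal(unname(cp$scores["B", "Betweenness"]), 1)
  expect_equal(unname(cp$scores[c("A", "C"), "Betweenness"]), c(0, 0))
  expect_equal(unname(cp$scores["B", "Stress"]), 1)
  tri <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")),
    directed = FALSE)
  ct <- centrality_suite(tri, epc_samples = 100)
  expect_equal(unname(ct$scores[, "MCC"]), rep(2, 3))    # (3-1)! per node
  expect_equal(unname(ct$scores[, "ClusteringCoefficient"]), rep(1, 3))
  expect_equal(unname(ct$scores[, "MNC"]), rep(2, 3))
})

test_that("Degree/Betweenness/Closeness match a brute-force all-pairs oracle", {
  for (s in 1:5) {
    g <- random_igraph(10 + s %% 3, p = 0.35, seed = s)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    n <- igraph::vcount(g)
    if (n < 3) next
    cs <- centrality_suite(g, epc_samples = 50)
    adj <- lapply(igraph::as_adj_list(g), as.integer)
    o <- oracle_bfs(adj, n)
    nm <- igraph::V(g)$name
    expect_equal(unname(cs$scores[nm, "Degree"]),
                 unname(vapply(adj, length, 1L)[seq_len(n)]))
    # harmonic closeness
    H <- 1 / o$D; diag(H) <- 0
    expect_equal(unname(cs$scores[nm, "Closeness"]), unname(rowSums(H)))
    # betweenness via pair-dependency accumulation from the oracle counts
    btw <- vapply(seq_len(n), function(v) {
      tot <- 0
      for (s_ in seq_len(n)) for (t_ in seq_len(n)) {
        if (s_ >= t_ || s_ == v || t_ == v) next
        if (o$D[s_, v] + o$D[v, t_] == o$D[s_, t_])
          tot <- tot + o$S[s_, v] * o$S[v, t_] / o$S[s_, t_]
      }
      tot
    }, numeric(1))
    expect_equal(unname(cs$scores[nm, "Betweenness"]), btw, tolerance = 1e-9)
    # stress is the unweighted analogue of the same accumulation
    str_ <- vapply(seq_len(n), function(v) {
      tot <- 0
      for (s_ in seq_len(n)) for (t_ in seq_len(n)) {
        if (s_ >= t_ || s_ == v || t_ == v) next
        if (o$D[s_, v] + o$D[v, t_] == o$D[s_, t_])
          tot <- tot + o$S[s_, v] * o$S[v, t_]
      }
      tot
    }, numeric(1))
    expect_equal(unname(cs$scores[nm, "Stress"]), str_)
  }
})

test_that("MCC equals (n-1)! on cliques and EPC noise shrinks with samples", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  cs <- centrality_suite(k5, epc_samples = 50)
  expect_equal(unname(cs$scores[, "MCC"]), rep(factorial(4), 5))
  g <- random_igraph(8, p = 0.5, seed = 3)
  e_small <- vapply(1:12, function(s)
    irapass:::epc_scores(g, samples = 60, seed = s)[1], numeric(1))
  e_big <- vapply(1:12, function(s)
    irapass:::epc_scores(g, samples = 1500, seed = s)[1], numeric(1))
  expect_gt(sd(e_small), 2 * sd(e_big))
})

test_that("Borda master-factor aggregation is deterministic and order-invariant", {
  set.seed(5)
  g <- random_igraph(12, p = 0.4, seed = 9)
  igraph::V(g)$type <- rep(c("factor", "event_gene"), 6)
  cs <- centrality_suite(g, epc_samples = 200)
  mf <- master_factors(cs, g, k = 3)
  # permuting algorithm columns leaves the aggregate unchanged
  cs2 <- cs
  perm <- sample(colnames(cs$scores))
  cs2$scores <- cs$scores[, perm]
  cs2$ranks <- cs$ranks[, perm]
  mf2 <- master_factors(cs2, g, k = 3)
  expect_equal(mf$factor, mf2$factor)
  expect_equal(mf$borda, mf2$borda)
  # a unanimously top-ranked node aggregates to rank 1
  hub <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(hub)$name <- paste0("n", 1:6)
  igraph::V(hub)$type <- "factor"
  ch <- centrality_suite(hub, epc_samples = 100)
  mh <- master_factors(ch, hub, k = 2)
  expect_equal(mh$factor[1], "n1")
  expect_warning(master_factors(ch, hub, k = 99), "returning all")
})

test_that("immune-score correlations are exact for self and antisymmetric", {
  set.seed(8)
  n <- 20
  fx <- matrix(rlnorm(3 * n), 3, n,
               dimnames = list(c("F1", "F2", "F3"), sprintf("S%02d", 1:n)))
  scores <- cbind(ImmuneScore = fx["F1", ], Other = rnorm(n))
  rownames(scores) <- colnames(fx)
  groups <- setNames(rep("all", n), colnames(fx))
  res <- immune_correlation(expression_table(fx), scores, groups)
  self <- res$all[res$all$factor == "F1" & res$all$score == "ImmuneScore", ]
  expect_equal(self$rho, 1)
  res_neg <- immune_correlation(expression_table(fx), -scores, groups)
  expect_equal(res_neg$all$rho, -res$all$rho)
  expect_warning(immune_correlation(expression_table(fx[, 1:3]),
                                    scores[1:3, ], groups[1:3]), "skipped")
})
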