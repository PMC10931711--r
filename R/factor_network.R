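#' Spearman correlation edges between APA factors and differential events
#'
#' Spearman rho (pairwise-complete observations) between each factor's
#' expression and each differential event's PDUI; an edge is kept iff
#' `p < p_threshold` and `|rho| >= rho_threshold`. p-values use the
#' t-approximation of the Spearman statistic.
#'
#' @param expr an [expression_table()] restricted to the APA-factor genes.
#' @param pdui a [pdui_table()] restricted to the differential events.
#' @param p_threshold significance cutoff (default 0.05, strict `<`).
#' @param rho_threshold correlation magnitude cutoff (default 0.3,
#'   inclusive; set to 0 to filter on p only).
#' @param min_obs minimum shared samples (default 5; fewer is an error).
#' @return data.frame factor, event_id, rho, p.
#' @export
factor_event_correlation <- function(expr, pdui, p_threshold = 0.05,
                                     rho_threshold = 0.3, min_obs = 5) {
  shared <- align_samples(colnames(expr), colnames(pdui))
  if (length(shared) < min_obs) stop("need >= ", min_obs, " shared samples")
  X <- t(unclass(expr)[, shared, drop = FALSE])
  Y <- t(unclass(pdui)[, shared, drop = FALSE])
  n_pair <- crossprod(!is.na(X) * 1, !is.na(Y) * 1)
  suppressWarnings(
    rho <- cor(X, Y, method = "spearman", use = "pairwise.complete.obs"))
  df <- n_pair - 2
  tstat <- rho * sqrt(df / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tstat), pmax(df, 1))
  p <- pmax(p, 1e-300)
  keep <- which(!is.na(rho) & p < p_threshold & abs(rho) >= rho_threshold &
                  n_pair >= min_obs, arr.ind = TRUE)
  data.frame(factor = rownames(rho)[keep[, 1]],
             event_id = colnames(rho)[keep[, 2]],
             rho = rho[keep], p = p[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the APA-events-to-APA-factors (ATF) network
#'
#' Union graph of factor-event correlation edges and protein-interaction
#' edges. Event nodes are represented by their parental gene symbol and
#' annotated with the differential direction when supplied; PPI edges are
#' restricted to pairs where both endpoints are factors or event parental
#' genes; parallel correlation+PPI evidence collapses to one edge carrying
#' both attributes.
#'
#' @param cor_edges data.frame from [factor_event_correlation()].
#' @param ppi an [interaction_table()] (may be NULL).
#' @param factors character vector of APA-factor gene symbols.
#' @param event_ids character vector of differential event ids.
#' @param directions optional named vector event_id -> direction
#'   (`shortened`/`lengthened`).
#' @return an \pkg{igraph} graph with vertex attributes `type`
#'   (`factor`/`event_gene`) and `direction`, and edge attributes `type`
#'   (`correlation`/`ppi`/`both`), `rho`, `p`, `score`.
#' @export
build_atf_network <- function(cor_edges, ppi = NULL, factors, event_ids,
                              directions = NULL) {
  ev_gene <- setNames(event_gene(event_ids), event_ids)
  nodes <- data.frame(name = c(factors, unique(unname(ev_gene))),
                      type = c(rep("factor", length(factors)),
                               rep("event_gene", length(unique(ev_gene)))),
                      stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  nodes$direction <- NA_character_
  if (!is.null(directions)) {
    dg <- tapply(directions[event_ids], ev_gene[event_ids],
                 function(d) paste(unique(d[!is.na(d)]), collapse = "/"))
    nodes$direction[match(names(dg), nodes$name)] <- unname(dg)
  }
  edges <- data.frame(from = character(), to = character(), type = character(),
                      rho = numeric(), p = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(cor_edges)) {
    ce <- data.frame(from = cor_edges$factor,
                     to = unname(ev_gene[cor_edges$event_id]),
                     type = "correlation", rho = cor_edges$rho,
                     p = cor_edges$p, score = NA_real_,
                     stringsAsFactors = FALSE)
    ce <- ce[ce$from != ce$to, , drop = FALSE]
    edges <- rbind(edges, ce)
  }
  if (!is.null(ppi) && nrow(ppi)) {
    inset <- ppi$gene_a %in% nodes$name & ppi$gene_b %in% nodes$name
    pe <- ppi[inset, , drop = FALSE]
    if (nrow(pe))
      edges <- rbind(edges, data.frame(from = pe$gene_a, to = pe$gene_b,
                                       type = "ppi", rho = NA_real_,
                                       p = NA_real_, score = pe$combined_score,
                                       stringsAsFactors = FALSE))
  }
  if (nrow(edges)) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(dup)) {
      merged <- lapply(split(edges[dup, , drop = FALSE], key[dup]), function(d) {
        data.frame(from = d$from[1], to = d$to[1],
                   type = if (length(unique(d$type)) > 1) "both" else d$type[1],
                   rho = d$rho[which(!is.na(d$rho))[1]],
                   p = d$p[which(!is.na(d$p))[1]],
                   score = d$score[which(!is.na(d$score))[1]],
                   stringsAsFactors = FALSE)
      })
      edges <- rbind(edges[!dup, , drop = FALSE], do.call(rbind, merged))
    }
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Twelve-centrality topology analysis
#'
#' Computes the twelve hub-detection scores of the cytoHubba family on the
#' largest connected component of a network: Degree, Betweenness, Stress,
#' Closeness (harmonic: sum of reciprocal distances), EcCentricity
#' (1/eccentricity), Radiality, ClusteringCoefficient, MNC (size of the
#' largest connected component of the open neighborhood), DMNC
#' (E(N)/V(N)^1.7 on that component), MCC (sum over maximal cliques
#' containing the node of (|C|-1)!), BottleNeck (number of single-source
#' shortest-path trees, parent ties broken by smallest node id, in which the
#' node's subtree covers at least n/4 of the tree) and EPC (mean size of the
#' node's component over Monte-Carlo edge-percolation samples). Nodes outside
#' the analyzed component get NA scores and rank last.
#'
#' @param graph an \pkg{igraph} undirected graph (e.g. from
#'   [build_atf_network()]).
#' @param seed RNG seed for the EPC Monte-Carlo.
#' @param epc_samples percolation samples (default 1000).
#' @param epc_retain per-edge retention probability (default 0.5).
#' @param mcc_max_nodes refuse exact clique enumeration above this component
#'   size (default 2000).
#' @return object of class `centrality_rankings`: list with `scores` and
#'   `ranks` (nodes x 12 matrices, all graph nodes) and `component` (node
#'   names analyzed). Higher score = more central for every algorithm.
#' @export
centrality_suite <- function(graph, seed = 1, epc_samples = 1000,
                             epc_retain = 0.5, mcc_max_nodes = 2000) {
  if (igraph::vcount(graph) == 0) stop("empty network")
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(graph, keep)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n > mcc_max_nodes)
    stop("component has ", n, " nodes; exact maximal-clique enumeration (MCC) ",
         "is infeasible — raise mcc_max_nodes or exclude MCC")
  D <- igraph::distances(g)
  diam <- max(D)
  scores <- matrix(NA_real_, igraph::vcount(graph), 12,
                   dimnames = list(igraph::V(graph)$name, CENTRALITY_ALGORITHMS))
  sc <- function(x) setNames(as.numeric(x), nm)
  s <- list(
    Degree = sc(igraph::degree(g)),
    Betweenness = sc(igraph::betweenness(g)),
    Closeness = sc(igraph::harmonic_centrality(g)),
    ClusteringCoefficient = sc({
      cc <- igraph::transitivity(g, type = "local", isolates = "zero"); cc
    }),
    EcCentricity = sc(1 / pmax(igraph::eccentricity(g), 1e-12)),
    Radiality = sc(if (n > 1) (rowSums(diam + 1 - D) - (diam + 1)) / (n - 1) else 0),
    Stress = sc(stress_centrality(g, D)),
    MNC = NA, DMNC = NA, MCC = NA, BottleNeck = NA, EPC = NA)
  md <- mnc_dmnc(g)
  s$MNC <- sc(md$mnc); s$DMNC <- sc(md$dmnc)
  s$MCC <- sc(mcc_scores(g))
  s$BottleNeck <- sc(bottleneck_scores(g, D))
  s$EPC <- sc(epc_scores(g, samples = epc_samples, retain = epc_retain,
                         seed = seed))
  for (alg in CENTRALITY_ALGORITHMS) scores[nm, alg] <- s[[alg]][nm]
  ranks <- apply(scores, 2, function(x) {
    r <- rank(-x, ties.method = "min", na.last = "keep")
    r[is.na(r)] <- n + 1  # outside the analyzed component: rank last
    r
  })
  structure(list(scores = scores, ranks = ranks, component = nm,
                 settings = list(seed = seed, epc_samples = epc_samples,
                                 epc_retain = epc_retain)),
            class = "centrality_rankings")
}

#' @export
CENTRALITY_ALGORITHMS <- c("Betweenness", "BottleNeck", "Closeness",
                           "ClusteringCoefficient", "Degree", "DMNC",
                           "EcCentricity", "EPC", "MCC", "MNC", "Radiality",
                           "Stress")

# number of shortest paths through each node:
# sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t)
stress_centrality <- function(g, D = igraph::distances(g)) {
  n <- igraph::vcount(g)
  if (n <= 2) return(rep(0, n))
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  Sg <- matrix(0, n, n)
  for (src in seq_len(n)) {
    sigma <- numeric(n); sigma[src] <- 1
    for (d in sort(unique(D[src, ]))) {
      if (d == 0 || is.infinite(d)) next
      for (v in which(D[src, ] == d)) {
        preds <- adj[[v]][D[src, adj[[v]]] == d - 1]
        sigma[v] <- sum(sigma[preds])
      }
    }
    Sg[src, ] <- sigma
  }
  vapply(seq_len(n), function(v) {
    through <- outer(Sg[, v], Sg[v, ]) * (outer(D[, v], D[v, ], `+`) == D)
    through[v, ] <- 0; through[, v] <- 0; diag(through) <- 0
    sum(through) / 2
  }, numeric(1))
}

mnc_dmnc <- function(g, eps = 1.7) {
  n <- igraph::vcount(g)
  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(g, nb)
    cp <- igraph::components(sub)
    big <- which.max(cp$csize)
    mnc[v] <- cp$csize[big]
    subc <- igraph::induced_subgraph(sub, which(cp$membership == big))
    dmnc[v] <- igraph::ecount(subc) / igraph::vcount(subc)^eps
  }
  list(mnc = mnc, dmnc = dmnc)
}

# MCC(v) = sum over maximal cliques C containing v of (|C|-1)!
mcc_scores <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  cl <- igraph::max_cliques(g, min = 2)
  for (C in cl) {
    idx <- as.integer(C)
    out[idx] <- out[idx] + factorial(length(idx) - 1)
  }
  out
}

# BottleNeck: for each root, a BFS shortest-path tree with parent ties broken
# by smallest node id; a node scores +1 per tree in which its subtree holds
# >= n/4 of the nodes.
bottleneck_scores <- function(g, D = igraph::distances(g)) {
  n <- igraph::vcount(g)
  ord_id <- order(igraph::V(g)$name)  # smallest lexicographic id first
  pos <- match(seq_len(n), ord_id)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  out <- numeric(n)
  for (root in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    for (v in seq_len(n)) {
      if (v == root || is.infinite(D[root, v])) next
      preds <- adj[[v]][D[root, adj[[v]]] == D[root, v] - 1]
      parent[v] <- preds[which.min(pos[preds])]
    }
    size <- rep(1L, n)
    for (v in order(D[root, ], decreasing = TRUE)) {
      if (!is.na(parent[v])) size[parent[v]] <- size[parent[v]] + size[v]
    }
    in_tree <- !is.infinite(D[root, ])
    thresh <- sum(in_tree) / 4
    out[in_tree] <- out[in_tree] + (size[in_tree] >= thresh)
  }
  out
}

# EPC: mean size of the component containing each node over Monte-Carlo
# edge-percolation samples (each edge kept independently with prob `retain`).
epc_scores <- function(g, samples = 1000, retain = 0.5, seed = 1) {
  set.seed(seed)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  acc <- numeric(n)
  for (b in seq_len(samples)) {
    drop <- which(runif(m) > retain)
    gs <- igraph::delete_edges(g, drop)
    cp <- igraph::components(gs)
    acc <- acc + cp$csize[cp$membership]
  }
  acc / samples
}

#' Aggregate centrality rankings into master APA factors
#'
#' Borda aggregation: per algorithm, factor nodes are ranked by score
#' (best = 1); the Borda score is the sum of ranks over the twelve
#' algorithms (smaller is better). Ties are broken by Degree, then
#' lexicographically. `"intersection-topN"` instead counts appearances in
#' each algorithm's top-k.
#'
#' @param rankings a `centrality_rankings` from [centrality_suite()].
#' @param graph the network the rankings were computed on (for node types).
#' @param node_type which nodes to aggregate over (default `"factor"`).
#' @param k number of master factors to return (default 10; if larger than
#'   the number of factor nodes, all are returned with a warning).
#' @param aggregation `"borda"` (default) or `"intersection-topN"`.
#' @return data.frame: factor, borda (or topn_count), degree, plus the
#'   per-algorithm rank columns; first `k` rows are the master factors.
#' @export
master_factors <- function(rankings, graph, node_type = "factor", k = 10,
                           aggregation = c("borda", "intersection-topN")) {
  aggregation <- match.arg(aggregation)
  types <- setNames(igraph::V(graph)$type, igraph::V(graph)$name)
  fnodes <- names(types)[types == node_type]
  fnodes <- intersect(fnodes, rownames(rankings$scores))
  if (!length(fnodes)) stop("no nodes of type ", node_type)
  sc <- rankings$scores[fnodes, , drop = FALSE]
  fr <- apply(sc, 2, function(x) {
    r <- rank(-x, ties.method = "min", na.last = "keep")
    r[is.na(r)] <- length(x) + 1
    r
  })
  if (is.null(dim(fr))) fr <- matrix(fr, nrow = 1, dimnames = list(fnodes, colnames(sc)))
  if (aggregation == "borda") {
    agg <- rowSums(fr)
    o <- order(agg, -ifelse(is.na(sc[, "Degree"]), -Inf, sc[, "Degree"]), fnodes)
  } else {
    agg <- rowSums(fr <= k)
    o <- order(-agg, -ifelse(is.na(sc[, "Degree"]), -Inf, sc[, "Degree"]), fnodes)
  }
  if (k > length(fnodes)) {
    warning("k exceeds the number of ", node_type, " nodes; returning all")
    k <- length(fnodes)
  }
  out <- data.frame(factor = fnodes[o],
                    aggregate = agg[o],
                    degree = sc[o, "Degree"],
                    fr[o, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[2] <- if (aggregation == "borda") "borda" else "topn_count"
  attr(out, "k") <- k
  attr(out, "master") <- out$factor[seq_len(k)]
  out
}

#' Per-group correlation of master factors with immune scores
#'
#' Spearman correlations between factor expression and externally supplied
#' per-sample immune scores (ImmuneScore, ESTIMATEscore, TIDE, IPS, ...),
#' computed within each sample group, with BH adjustment across the whole
#' factor x score matrix per group. Groups with fewer than `min_samples`
#' samples are skipped with a warning.
#'
#' @param factor_expr an [expression_table()] restricted to factors.
#' @param score_vectors data.frame/matrix (samples x scores) of immune
#'   scores, rownames = sample ids.
#' @param groups named per-sample group labels.
#' @param min_samples minimum group size (default 5).
#' @return named list (per group) of data.frames factor, score, rho, p, q.
#' @export
immune_correlation <- function(factor_expr, score_vectors, groups,
                               min_samples = 5) {
  score_vectors <- as.matrix(score_vectors)
  out <- list()
  for (grp in unique(groups[!is.na(groups)])) {
    ss <- names(groups)[!is.na(groups) & groups == grp]
    ss <- intersect(intersect(ss, colnames(factor_expr)), rownames(score_vectors))
    if (length(ss) < min_samples) {
      warning("group ", grp, " has < ", min_samples, " samples; skipped")
      next
    }
    X <- t(unclass(factor_expr)[, ss, drop = FALSE])
    S <- score_vectors[ss, , drop = FALSE]
    suppressWarnings(rho <- cor(X, S, method = "spearman",
                                use = "pairwise.complete.obs"))
    n <- length(ss)
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- pmax(2 * pt(-abs(tstat), n - 2), 1e-300)
    d <- data.frame(factor = rownames(rho)[row(rho)],
                    score = colnames(rho)[col(rho)],
                    rho = as.vector(rho), p = as.vector(p),
                    stringsAsFactors = FALSE)
    d$q <- bh_fdr(d$p)
    out[[grp]] <- d
  }
  out
}
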