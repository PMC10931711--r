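# fixtures and independent oracles used across the suite

toy_pdui <- function(values, events = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(events))
    events <- event_id(sprintf("GENE%02d", seq_len(nrow(m))), "chr1",
                       1000 + seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(events, samples)
  pdui_table(m)
}

# brute-force two-group mean-difference permutation oracle (one event)
enumerate_perm_p <- function(x, labels, group_a) {
  n <- length(x)
  idx_a <- utils::combn(n, sum(labels == group_a))
  d_obs <- abs(mean(x[labels == group_a], na.rm = TRUE) -
                 mean(x[labels != group_a], na.rm = TRUE))
  d_all <- apply(idx_a, 2, function(ia)
    abs(mean(x[ia], na.rm = TRUE) - mean(x[-ia], na.rm = TRUE)))
  sum(d_all >= d_obs) / ncol(idx_a)
}

# 20-line running-sum GSEA oracle
oracle_es <- function(stat, set, weight = 1) {
  ord <- order(stat, decreasing = TRUE)
  ranked <- stat[ord]
  hit <- names(ranked) %in% set
  N <- length(ranked); Nh <- sum(hit)
  w <- abs(ranked)^weight
  inc <- if (sum(w[hit]) > 0) w * hit / sum(w[hit]) else hit / Nh
  dec <- (!hit) / (N - Nh)
  walk <- cumsum(inc - dec)
  unname(walk[which.max(abs(walk))])
}

# flood-fill connected components oracle
oracle_components <- function(edges, nodes) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- k
      nb <- c(edges$to[edges$from == u], edges$from[edges$to == u])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# all-pairs BFS oracle: distances and shortest-path counts
oracle_bfs <- function(adj, n) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (u in frontier) for (v in adj[[u]]) {
        if (is.infinite(D[s, v])) {
          D[s, v] <- d; nxt <- c(nxt, v)
        }
        if (D[s, v] == d && D[s, u] == d - 1) S[s, v] <- S[s, v] + S[s, u]
      }
      frontier <- unique(nxt)
    }
  }
  list(D = D, S = S)
}

random_igraph <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  full <- t(utils::combn(n, 2))
  keep <- full[runif(nrow(full)) < p, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = letters[keep[, 1]], to = letters[keep[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = letters[seq_len(n)]))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
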