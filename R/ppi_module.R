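#' Largest connected component of a protein-interaction network
#'
#' Returns the component with the most nodes; exact size ties are broken by
#' the component containing the lexicographically smallest node id.
#'
#' @param ppi an [interaction_table()] or an \pkg{igraph} graph.
#' @return an \pkg{igraph} induced subgraph.
#' @export
largest_component <- function(ppi) {
  g <- if (inherits(ppi, "igraph")) ppi else
    igraph::graph_from_data_frame(
      data.frame(from = ppi$gene_a, to = ppi$gene_b,
                 score = ppi$combined_score), directed = FALSE)
  if (igraph::vcount(g) == 0) stop("empty graph")
  cp <- igraph::components(g)
  best <- which(cp$csize == max(cp$csize))
  if (length(best) > 1) {
    first_node <- vapply(best, function(ci)
      min(igraph::V(g)$name[cp$membership == ci]), "")
    best <- best[order(first_node)[1]]
  }
  igraph::induced_subgraph(g, which(cp$membership == best))
}

#' Personalized PageRank impact scores
#'
#' Power iteration on the column-stochastic transition matrix of an
#' undirected graph, with teleport mass `1 - damping` distributed uniformly
#' over the seed genes; mass at dangling (degree-zero) nodes is redistributed
#' to the teleport vector. Iteration stops when the L1 change drops below
#' `tolerance`; scores sum to 1.
#'
#' @param graph an \pkg{igraph} graph (typically from [largest_component()]).
#' @param seeds character vector of seed gene symbols; seeds absent from the
#'   graph are dropped with a warning (none left is an error).
#' @param damping damping factor in (0,1) (default 0.85).
#' @param tolerance L1 convergence threshold (default 1e-10).
#' @param max_iterations iteration cap (default 1000; exceeding it is an
#'   error reporting the residual).
#' @return named numeric vector of per-node impact scores (sums to 1).
#' @export
personalized_pagerank <- function(graph, seeds, damping = 0.85,
                                  tolerance = 1e-10, max_iterations = 1000) {
  if (damping <= 0 || damping >= 1) stop("damping must be in (0,1)")
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  missing_seeds <- setdiff(seeds, nodes)
  if (length(missing_seeds))
    warning("seeds outside the component dropped: ",
            paste(missing_seeds, collapse = ", "))
  seeds <- intersect(seeds, nodes)
  if (!length(seeds)) stop("no seed present in the component")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::colSums(A)
  s <- numeric(n); names(s) <- nodes
  s[seeds] <- 1 / length(seeds)
  x <- s
  dangling <- deg == 0
  for (it in seq_len(max_iterations)) {
    spread <- numeric(n)
    if (any(!dangling)) {
      xn <- x[!dangling] / deg[!dangling]
      spread[!dangling] <- xn
    }
    x_new <- damping * as.numeric(A %*% spread) +
      (damping * sum(x[dangling]) + (1 - damping)) * s
    names(x_new) <- nodes
    resid <- sum(abs(x_new - x))
    x <- x_new
    if (resid < tolerance) return(x / sum(x))
  }
  stop("PageRank failed to converge in ", max_iterations,
       " iterations (L1 residual ", format(resid), ")")
}

#' Top-k feature-based module
#'
#' The `top_k` genes with the highest impact scores, ties broken by node id;
#' if the graph holds fewer genes, all are returned with a warning.
#'
#' @param scores named score vector from [personalized_pagerank()].
#' @param top_k module size (default 200).
#' @param seeds optional seed genes, flagged in the output.
#' @return data.frame gene, score, rank, is_seed.
#' @export
top_module <- function(scores, top_k = 200, seeds = character()) {
  if (top_k < 1) stop("top_k must be >= 1")
  if (top_k > length(scores)) {
    warning("graph has fewer than top_k nodes; returning all")
    top_k <- length(scores)
  }
  o <- order(-scores, names(scores))[seq_len(top_k)]
  data.frame(gene = names(scores)[o], score = scores[o],
             rank = seq_len(top_k), is_seed = names(scores)[o] %in% seeds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Feature-based module extraction pipeline
#'
#' Convenience wrapper: restrict the PPI network to its largest connected
#' component, run personalized PageRank seeded on the parental genes of the
#' model's features, and return the top-k module.
#'
#' @param ppi an [interaction_table()].
#' @param model an [irapass_model()] (or a character vector of seed genes).
#' @param top_k module size (default 200).
#' @param damping damping factor (default 0.85).
#' @param ... passed to [personalized_pagerank()].
#' @return list: `module` (data.frame), `scores`, `component_size`, `seeds`.
#' @export
ppi_feature_module <- function(ppi, model, top_k = 200, damping = 0.85, ...) {
  seeds <- if (inherits(model, "irapass_model"))
    unique(event_gene(model$features)) else unique(as.character(model))
  g <- largest_component(ppi)
  scores <- personalized_pagerank(g, seeds, damping = damping, ...)
  list(module = top_module(scores, top_k = top_k, seeds = seeds),
       scores = scores, component_size = igraph::vcount(g),
       seeds = intersect(seeds, igraph::V(g)$name))
}
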