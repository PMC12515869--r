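#' Generate a planted-partition PPI graph
#'
#' Builds an undirected simple graph in which each planted cluster is an
#' Erdos-Renyi block with internal edge probability `p_in` and all remaining
#' node pairs are connected with probability `p_out`. Nodes not covered by
#' any cluster form background. Used as a fixture with known community
#' structure for complex-detection tests.
#'
#' @param n_nodes Total number of nodes.
#' @param clusters List of `c(size, p_in)` pairs; sizes must sum to at most
#'   `n_nodes`.
#' @param p_out Between-cluster (and background) edge probability.
#' @param seed Integer seed.
#' @return An [igraph::igraph] with vertex attribute `planted` (cluster
#'   index, 0 for background).
#' @export
generate_ppi_graph <- function(n_nodes, clusters, p_out, seed = 1L) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 0L)
  sizes <- vapply(clusters, function(cl) as.integer(cl[[1]]), integer(1))
  p_ins <- vapply(clusters, function(cl) as.numeric(cl[[2]]), numeric(1))
  if (sum(sizes) > n_nodes) stop_validation("cluster sizes exceed n_nodes")
  if (any(c(p_ins, p_out) < 0) || any(c(p_ins, p_out) > 1)) {
    stop_validation("edge probabilities must lie in [0, 1]")
  }
  membership <- rep(0L, n_nodes)
  if (length(sizes)) {
    membership[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  }
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  with_seed(seed, {
    edges <- character(0)
    if (n_nodes >= 2L) {
      pairs <- utils::combn(n_nodes, 2)
      same <- membership[pairs[1, ]] == membership[pairs[2, ]] &
        membership[pairs[1, ]] > 0L
      p <- ifelse(same, p_ins[pmax(membership[pairs[1, ]], 1L)], p_out)
      keep <- runif(ncol(pairs)) < p
      edges <- rbind(nodes[pairs[1, keep]], nodes[pairs[2, keep]])
    }
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, n_nodes, name = nodes, planted = membership)
    if (length(edges)) g <- igraph::add_edges(g, as.vector(edges))
    g
  })
}

#' Generate random gene sets over a universe
#'
#' Each set is a uniform sample without replacement from `universe`, with a
#' size drawn uniformly within `size_range`. Serializable to GMT via
#' [write_gmt()].
#'
#' @param universe Character vector of ids (non-empty).
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer vector `c(min, max)`; `max` must not
#'   exceed `length(universe)`.
#' @param seed Integer seed.
#' @return Named list of character vectors (`set01`, `set02`, ...).
#' @export
generate_gene_sets <- function(universe, n_sets, size_range, seed = 1L) {
  if (length(universe) == 0L) stop_validation("'universe' must be non-empty")
  n_sets <- assert_count(n_sets, "n_sets")
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] < 1L ||
      size_range[1] > size_range[2]) {
    stop_validation("'size_range' must be c(min, max) with 1 <= min <= max")
  }
  if (size_range[2] > length(universe)) {
    stop_validation("max set size exceeds universe size")
  }
  if (n_sets == 0L) return(setNames(list(), character(0)))
  with_seed(seed, {
    size_pool <- seq(size_range[1], size_range[2])
    sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
    sets <- lapply(sizes, function(k) sort(sample(universe, k)))
    setNames(sets, sprintf("set%02d", seq_len(n_sets)))
  })
}
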