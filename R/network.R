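#' Build a simple undirected PPI graph from an edge list
#'
#' Self-loops and duplicate edges are rejected at load; an optional score
#' column can be filtered with `min_score`.
#'
#' @param edges data.frame with two character columns (`from`, `to`) and an
#'   optional numeric `score`.
#' @param min_score Keep only edges with `score >= min_score` (requires a
#'   score column).
#' @return An [igraph::igraph], undirected and simple.
#' @export
ppi_graph <- function(edges, min_score = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (!is.null(min_score)) {
    if (ncol(edges) < 3L) stop_validation("no score column to filter on")
    edges <- edges[edges[[3]] >= min_score, , drop = FALSE]
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (any(a == b)) stop_validation("self-loops are not allowed")
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) stop_validation("duplicate edges are not allowed")
  igraph::graph_from_data_frame(data.frame(from = a, to = b), directed = FALSE)
}

#' Maximal subgraph with minimum degree k
#'
#' The k-core: the (unique, order-independent) maximal subgraph in which
#' every node has degree at least `k`, equivalent to iteratively pruning
#' nodes of degree below `k`.
#'
#' @param graph An undirected [igraph::igraph].
#' @param k Non-negative integer.
#' @return The induced k-core subgraph (possibly empty).
#' @export
k_core <- function(graph, k) {
  k <- assert_count(k, "k")
  core <- igraph::coreness(graph)
  igraph::induced_subgraph(graph, which(core >= k))
}

## Graphs built outside ppi_graph() may lack vertex names.
ensure_named <- function(graph) {
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  graph
}

## Density of a simple undirected graph: 2E / (n (n - 1)); 0 for n < 2.
graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) return(0)
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each node, takes the closed neighborhood, finds its highest k-core,
#' and returns `k_max` times the density of that core (the core-clustering
#' coefficient). Isolated nodes get weight 0.
#'
#' @param graph An undirected [igraph::igraph].
#' @return Named numeric vector of weights (by vertex name).
#' @export
vertex_weights <- function(graph) {
  graph <- ensure_named(graph)
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  w <- setNames(numeric(n), nm)
  if (n == 0L) return(w)
  nbhd <- igraph::ego(graph, order = 1, mode = "all")
  for (i in seq_len(n)) {
    sub <- igraph::induced_subgraph(graph, nbhd[[i]])
    if (igraph::ecount(sub) == 0L) next
    core_no <- igraph::coreness(sub)
    kmax <- max(core_no)
    core <- igraph::induced_subgraph(sub, which(core_no >= kmax))
    w[i] <- kmax * graph_density(core)
  }
  w
}

#' Score of a candidate complex
#'
#' Density of the induced subgraph times the number of members — the score
#' convention reported by MCODE.
#'
#' @param graph An undirected [igraph::igraph].
#' @param members Character vector of at least 2 vertex names.
#' @return Numeric score.
#' @export
cluster_score <- function(graph, members) {
  if (length(members) < 2L) stop_validation("a cluster needs >= 2 members")
  sub <- igraph::induced_subgraph(graph, members)
  graph_density(sub) * length(members)
}

#' MCODE molecular complex detection
#'
#' Stage 1 weights every vertex by its core-clustering coefficient
#' ([vertex_weights()]). Stage 2 seeds complexes from unvisited vertices in
#' descending weight order (ties broken lexicographically by name) and grows
#' each complex breadth-first, including unvisited neighbors whose weight is
#' at least `(1 - node_score_cutoff)` times the seed weight, up to
#' `max_depth` steps from the seed. Post-processing drops complexes without
#' a 2-core, optionally removes singly-connected members (`haircut`) and
#' optionally adds boundary neighbors whose closed-neighborhood density
#' exceeds `fluff_threshold` (`fluff`). Complexes are returned in descending
#' score order (ties by seed name).
#'
#' @param graph An undirected [igraph::igraph].
#' @param node_score_cutoff Relative weight tolerance for inclusion,
#'   in \[0, 1\]. Default 0.2.
#' @param haircut Remove members with fewer than 2 connections inside the
#'   complex. Default `TRUE`.
#' @param fluff Add dense boundary neighbors. Default `FALSE`.
#' @param fluff_threshold Closed-neighborhood density required of fluffed
#'   nodes. Default 0.8.
#' @param max_depth Breadth-first search depth limit. Default 100.
#' @return data.frame with one row per complex: `cluster` (rank), `score`,
#'   `n_members`, `seed`, `members` (semicolon-joined, sorted). Zero rows if
#'   no complex survives.
#' @export
mcode_find_complexes <- function(graph, node_score_cutoff = 0.2,
                                 haircut = TRUE, fluff = FALSE,
                                 fluff_threshold = 0.8, max_depth = 100L) {
  assert_fraction(node_score_cutoff, "node_score_cutoff")
  assert_fraction(fluff_threshold, "fluff_threshold")
  max_depth <- assert_count(max_depth, "max_depth", min = 1L)
  graph <- ensure_named(graph)
  nm <- igraph::V(graph)$name
  w <- vertex_weights(graph)
  visited <- setNames(rep(FALSE, length(nm)), nm)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  neighbors_of <- setNames(lapply(adj, function(v) nm[as.integer(v)]), nm)
  order_seeds <- nm[order(-w, nm)]
  complexes <- list()
  for (seed in order_seeds) {
    if (visited[[seed]]) next
    threshold <- (1 - node_score_cutoff) * w[[seed]]
    members <- seed
    visited[[seed]] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (nb in neighbors_of[[v]]) {
          if (!visited[[nb]] && w[[nb]] >= threshold) {
            visited[[nb]] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < 2L) next
    if (haircut) {
      deg <- igraph::degree(sub)
      members <- igraph::V(sub)$name[deg >= 2L]
      if (length(members) < 2L) next
    }
    if (fluff) {
      boundary <- setdiff(unique(unlist(neighbors_of[members])), members)
      keep <- vapply(boundary, function(b) {
        nbh <- unique(c(b, neighbors_of[[b]]))
        graph_density(igraph::induced_subgraph(graph, nbh)) > fluff_threshold
      }, logical(1))
      members <- c(members, boundary[keep])
    }
    complexes[[length(complexes) + 1L]] <-
      list(seed = seed, members = sort(members),
           score = cluster_score(graph, members))
  }
  if (length(complexes) == 0L) {
    return(data.frame(cluster = integer(0), score = numeric(0),
                      n_members = integer(0), seed = character(0),
                      members = character(0)))
  }
  scores <- vapply(complexes, `[[`, numeric(1), "score")
  seeds <- vapply(complexes, `[[`, character(1), "seed")
  ord <- order(-scores, seeds)
  data.frame(cluster = seq_along(ord), score = scores[ord],
             n_members = vapply(complexes[ord], function(cl)
               length(cl$members), integer(1)),
             seed = seeds[ord],
             members = vapply(complexes[ord], function(cl)
               paste(cl$members, collapse = ";"), character(1)),
             stringsAsFactors = FALSE)
}
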