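# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use naive element-wise code paths so they
# stay independent of the package implementation.

## Benjamini-Hochberg step-up by the defining formula:
## q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, mapped back.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

## k-core by literal iterative pruning on an adjacency matrix.
kcore_oracle_nodes <- function(adj, k) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE])
    deg[!alive] <- Inf
    kill <- alive & deg < k
    if (!any(kill)) break
    alive[kill] <- FALSE
  }
  which(alive)
}

## MCODE vertex weight from first principles on an adjacency matrix.
vertex_weight_oracle <- function(adj, v) {
  nbhd <- sort(unique(c(v, which(adj[v, ] > 0))))
  sub <- adj[nbhd, nbhd, drop = FALSE]
  if (sum(sub) == 0) return(0)
  kmax <- 0L
  core_nodes <- integer(0)
  for (k in 0:(nrow(sub))) {
    nodes <- kcore_oracle_nodes(sub, k)
    if (length(nodes) == 0L) break
    kmax <- k
    core_nodes <- nodes
  }
  n <- length(core_nodes)
  if (n < 2L) return(0)
  e <- sum(sub[core_nodes, core_nodes]) / 2
  kmax * (2 * e / (n * (n - 1)))
}

## GSEA enrichment score by an explicit position-by-position walk.
es_oracle <- function(metric_sorted, set, weight = 1) {
  ids <- names(metric_sorted)
  n <- length(ids)
  hit <- ids %in% set
  nr <- sum(abs(metric_sorted[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) abs(metric_sorted[i])^weight / nr else
        1 / sum(hit)
    } else {
      cur <- cur - 1 / (n - sum(hit))
    }
    running[i] <- cur
  }
  mx <- max(running)
  mn <- min(running)
  if (mx + mn >= -1e-12) mx else mn  # ties resolve positive
}

## Hypergeometric upper tail by summing the mass function.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Random simple graph as an igraph with names "1".."n".
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}

## Adjacency matrix of a named igraph (for oracles).
adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

## Small 2x2-group intensity table.
toy_table <- function(values, groups = c("control", "control", "case", "case")) {
  intensity_table(values, groups)
}

## Build a synthetic quantified + tested dataset in one call.
run_synth <- function(design, n_proteins = 1000L, proteome_seed = design$seed) {
  proteome <- generate_proteome(n_proteins, seed = proteome_seed)
  catalog <- suppressWarnings(generate_lactylome(proteome, design))
  tabs <- generate_intensities(catalog, design)
  map <- setNames(catalog$accession, catalog$site)
  quant <- quantify_sites(tabs$sites, tabs$proteins, map)
  list(proteome = proteome, catalog = catalog, tabs = tabs, quant = quant)
}

## Uniform-composition random K-centered windows.
random_windows <- function(n, w, alphabet = c("A", "C", "D", "E", "F", "G",
                                              "H", "I", "K", "L", "M", "N",
                                              "P", "Q", "R", "S", "T", "V",
                                              "W", "Y")) {
  vapply(seq_len(n), function(i) {
    chars <- sample(alphabet, 2 * w + 1, replace = TRUE)
    chars[w + 1] <- "K"
    paste(chars, collapse = "")
  }, character(1))
}
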