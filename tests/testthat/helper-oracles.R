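# Independent brute-force oracles used to cross-check the implementation.

# betweenness by exhaustive shortest-path enumeration (igraph only supplies
# the path lists; the pair-dependency accounting is done by hand here)
brute_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  if (length(nodes) < 3) return(bc)
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = nodes[i], to = nodes[j],
                                   weights = NA)$vpaths
      )
      if (length(paths) == 0) next
      interior <- unlist(lapply(paths, function(p) {
        nm <- names(p)
        nm[-c(1, length(nm))]
      }))
      if (length(interior)) {
        tab <- table(interior)
        bc[names(tab)] <- bc[names(tab)] + as.numeric(tab) / length(paths)
      }
    }
  }
  bc
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of draws
brute_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Benjamini-Hochberg by the literal step-up definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- rep(NA_real_, m)
  sorted <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(pmin(sorted, 1))))
  adj[ord] <- adj_sorted
  adj
}

# Newman-Girvan modularity straight from the formula (unweighted)
brute_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  ends <- igraph::as_edgelist(g, names = TRUE)
  memb <- membership[igraph::V(g)$name]
  q <- 0
  for (com in unique(memb)) {
    inside <- names(memb)[memb == com]
    e_cc <- sum(ends[, 1] %in% inside & ends[, 2] %in% inside)
    d_c <- sum(igraph::degree(g)[inside])
    q <- q + e_cc / m - (d_c / (2 * m))^2
  }
  q
}

random_small_graph <- function(n_nodes, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n_nodes, p)
    if (igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- paste0("n", seq_len(n_nodes))
  g
}

# two 4-cliques joined by a single bridge edge (m = 13)
two_clique_bridge <- function() {
  edges <- rbind(t(utils::combn(paste0("a", 1:4), 2)),
                 t(utils::combn(paste0("b", 1:4), 2)),
                 c("a1", "b1"))
  build_graph(tibble::tibble(node_a = edges[, 1], node_b = edges[, 2]))
}

tiny_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = c("R", "A", "B", "C"),
      name = c("root", "mid A", "leaf B", "leaf C"),
      namespace = "biological_process"
    ),
    edges = tibble::tibble(
      child = c("A", "B", "C"),
      parent = c("R", "A", "A"),
      relation = c("is_a", "is_a", "part_of")
    )
  )
}

small_sim_config <- function(...) {
  sim_config(
    n_genes = 300,
    planted_degs = c(stats::setNames(rep(3, 40), sprintf("G%04d", 1:40))),
    sbm_blocks = c(20, 20),
    n_go_terms = 10,
    planted_terms = c(T_ONE = 1L, T_TWO = 2L),
    seed = 42,
    ...
  )
}
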