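path_graph <- function(nodes) {
  build_graph(tibble::tibble(node_a = nodes[-length(nodes)], node_b = nodes[-1]))
}

test_that("graph construction deduplicates and drops self-loops", {
  edges <- tibble::tibble(node_a = c("A", "A", "B", "C"),
                          node_b = c("B", "B", "C", "C"))
  expect_warning(g <- build_graph(edges), "self-loop")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  simple <- build_graph(tibble::tibble(node_a = c("A", "B", "C"),
                                       node_b = c("B", "C", "D")))
  expect_equal(igraph::vcount(simple), 4)
  expect_equal(igraph::ecount(simple), 3)
})

test_that("shortest-path subnetwork keeps all tied paths and seed distances", {
  # path 1-2-3: the middle node is pulled in
  g <- path_graph(c("1", "2", "3"))
  sub <- shortest_path_subnetwork(g, c("1", "3"))
  expect_setequal(igraph::V(sub)$name, c("1", "2", "3"))

  # 4-cycle: both tied shortest paths between opposite corners
  cyc <- build_graph(tibble::tibble(node_a = c("1", "2", "3", "4"),
                                    node_b = c("2", "3", "4", "1")))
  sub <- shortest_path_subnetwork(cyc, c("1", "3"))
  expect_setequal(igraph::V(sub)$name, c("1", "2", "3", "4"))
  expect_equal(igraph::ecount(sub), 4)

  # off-path branches are excluded
  branch <- build_graph(tibble::tibble(node_a = c("1", "2", "2"),
                                       node_b = c("2", "3", "X")))
  sub <- shortest_path_subnetwork(branch, c("1", "3"))
  expect_false("X" %in% igraph::V(sub)$name)

  # unmapped seeds are reported, not fatal (but >= 2 must map)
  expect_message(sub <- shortest_path_subnetwork(g, c("1", "3", "FAT3")),
                 "FAT3")
  expect_equal(attr(sub, "unmapped"), "FAT3")
  expect_error(shortest_path_subnetwork(g, c("1", "ZZZ")), "ZZZ")
})

test_that("subnetwork preserves pairwise seed distances on random graphs", {
  set.seed(31)
  for (trial in 1:20) {
    g <- random_small_graph(sample(5:9, 1), p = 0.45)
    comp <- igraph::components(g)
    big <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    if (length(big) < 3) next
    seeds <- sample(big, min(3, length(big)))
    sub <- shortest_path_subnetwork(g, seeds)
    d_full <- igraph::distances(g, v = seeds, to = seeds, weights = NA)
    d_sub <- igraph::distances(sub, v = seeds, to = seeds, weights = NA)
    expect_equal(d_sub, d_full)
  }
})

test_that("centralities match closed forms on path, star, and clique", {
  pg <- centralities(path_graph(c("A", "B", "C")))
  expect_equal(pg$betweenness[pg$node == "B"], 1)
  expect_equal(pg$betweenness[pg$node != "B"], c(0, 0))

  star <- build_graph(tibble::tibble(node_a = "hub", node_b = paste0("leaf", 1:5)))
  st <- centralities(star)
  expect_equal(st$betweenness[st$node == "hub"], choose(5, 2))
  expect_equal(st$degree[st$node == "hub"], 5L)

  k4 <- build_graph(tibble::tibble(node_a = t(utils::combn(LETTERS[1:4], 2))[, 1],
                                   node_b = t(utils::combn(LETTERS[1:4], 2))[, 2]))
  expect_true(all(centralities(k4)$betweenness == 0))

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(centralities(empty)), 0)
})

test_that("betweenness agrees with exhaustive path enumeration on small graphs", {
  set.seed(17)
  for (trial in 1:30) {
    g <- random_small_graph(sample(4:8, 1))
    got <- centralities(g)
    oracle <- brute_betweenness(g)
    expect_equal(stats::setNames(got$betweenness, got$node), oracle[got$node],
                 tolerance = 1e-10)
  }
})

test_that("quadrant classification uses strict above-the-mean rules", {
  rec <- tibble::tibble(node = c("n1", "n2", "n3"),
                        degree = c(1L, 1L, 4L),
                        betweenness = c(0, 0, 1))
  out <- classify_quadrants(rec)
  expect_equal(as.character(out$quadrant), c("NHNB", "NHNB", "HB"))

  same <- tibble::tibble(node = letters[1:4], degree = 2L, betweenness = 0.5)
  expect_true(all(classify_quadrants(same)$quadrant == "NHNB"))

  set.seed(4)
  rnd <- tibble::tibble(node = paste0("n", 1:50),
                        degree = sample(1:20, 50, TRUE),
                        betweenness = runif(50, 0, 30))
  q <- classify_quadrants(rnd)
  expect_equal(sum(table(q$quadrant)), 50)  # quadrants partition the nodes
  # invariant under relabeling
  rnd2 <- rnd
  rnd2$node <- paste0("x", 1:50)
  expect_equal(as.character(classify_quadrants(rnd2)$quadrant),
               as.character(q$quadrant))
})

test_that("walktrap cuts at maximal modularity and matches hand computation", {
  g <- two_clique_bridge()
  comm <- walktrap_communities(g)
  expect_equal(dplyr::n_distinct(comm$membership), 2)
  expect_equal(comm$membership[paste0("a", 1:4)],
               rep(comm$membership[["a1"]], 4), ignore_attr = TRUE)
  expect_equal(comm$modularity, 12 / 13 - 1 / 2, tolerance = 1e-4)
  expect_equal(comm$modularity, modularity_q(g, comm$membership))

  k6 <- build_graph(tibble::tibble(node_a = t(utils::combn(letters[1:6], 2))[, 1],
                                   node_b = t(utils::combn(letters[1:6], 2))[, 2]))
  expect_equal(dplyr::n_distinct(walktrap_communities(k6)$membership), 1)

  # isolated nodes become singleton communities
  iso <- igraph::add_vertices(g, 2, name = c("z1", "z2"))
  ci <- walktrap_communities(iso)
  expect_equal(length(unique(ci$membership[c("z1", "z2")])), 2)
  expect_error(walktrap_communities(g, steps = 0), "steps")
})

test_that("walktrap recovers a planted 4x20 block partition", {
  cfg <- sim_config(n_genes = 80, sbm_blocks = rep(20, 4),
                    p_in = 0.5, p_out = 0.01,
                    planted_degs = numeric(0), seed = 20220916)
  net <- simulate_interactome(cfg)
  g <- build_graph(as_channel_edges(net$links, "string_detailed"))
  comm <- walktrap_communities(g, use_weights = FALSE)
  truth <- net$truth$true_partition[names(comm$membership)]
  ari <- adjusted_rand_index(comm$membership, truth)
  expect_gte(ari, 0.9)
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(comm$membership, truth),
               tolerance = 1e-12)
})

test_that("modularity matches the Newman-Girvan formula", {
  g <- two_clique_bridge()
  nodes <- igraph::V(g)$name
  memb <- stats::setNames(ifelse(grepl("^a", nodes), 1L, 2L), nodes)
  expect_equal(modularity_q(g, memb), 0.4231, tolerance = 1e-4)
  expect_equal(modularity_q(g, memb), brute_modularity(g, memb))

  # one community: Q = 0
  expect_equal(modularity_q(g, stats::setNames(rep(1, 8), igraph::V(g)$name)), 0)

  # moving one clique member across the bridge strictly lowers Q
  worse <- memb
  worse["a2"] <- 2
  expect_lt(modularity_q(g, worse), modularity_q(g, memb))
  expect_equal(modularity_q(g, worse), brute_modularity(g, worse))

  expect_error(modularity_q(g, memb[-1]), "assignment")
})

test_that("community selection requires HB nodes and Pan-DEGs under AND", {
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 3, 3), paste0("n", 1:7))
  centr <- tibble::tibble(
    node = paste0("n", 1:7),
    degree = c(9L, 1L, 1L, 9L, 1L, 1L, 1L),
    betweenness = c(9, 0, 0, 9, 0, 0, 0)
  ) |> classify_quadrants()
  # community 1: HB + PanDEG; community 2: HB only; community 3: PanDEG only
  sel <- select_communities(memb, centr, pan_degs = c("n2", "n6"))
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE))
  sel_or <- select_communities(memb, centr, pan_degs = c("n2", "n6"), rule = "OR")
  expect_equal(sel_or$selected, c(TRUE, TRUE, TRUE))
  expect_warning(select_communities(memb, centr, pan_degs = character()),
                 "No community")
})
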