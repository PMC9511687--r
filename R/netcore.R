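#' Build a simple undirected graph from scored edges
#'
#' @param edges Tibble `node_a`, `node_b` and optionally `combined` (stored
#'   as the `weight` edge attribute). Self-loops are dropped with a warning;
#'   parallel edges are merged keeping the maximum weight.
#' @return An undirected [igraph::igraph] object.
#' @export
build_graph <- function(edges) {
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  df <- data.frame(from = edges$node_a, to = edges$node_b)
  if ("combined" %in% names(edges)) df$weight <- edges$combined
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "max")
}

#' Shortest-path subnetwork spanned by seed genes
#'
#' Extracts the union of all nodes and edges lying on any unweighted (hop
#' count) shortest path between every pair of seeds — the construction that
#' turns Pan-DEG seeds into the autophagy-lipid-proteostasis (ALP) network.
#' All tied shortest paths are included. Seeds absent from the graph are
#' reported (attribute `unmapped`), not fatal; disconnected seed pairs
#' contribute nothing and are counted in attribute `n_unreachable_pairs`.
#'
#' A node v is on a shortest s-t path iff d(s,v) + d(v,t) = d(s,t), and an
#' edge (u,v) iff d(s,u) + 1 + d(v,t) = d(s,t) in either orientation; both
#' tests use BFS distances from the seeds only.
#'
#' @param g Graph from [build_graph()].
#' @param seeds Character vector of seed node names (>= 2 must map).
#' @return Subgraph (igraph) whose seed pairwise distances equal those in
#'   `g`, with attributes `seeds`, `unmapped`, `n_unreachable_pairs`.
#' @export
shortest_path_subnetwork <- function(g, seeds) {
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(g)$name)
  unmapped <- setdiff(seeds, present)
  if (length(unmapped)) {
    inform(sprintf("%d seed(s) could not be mapped to the interactome: %s",
                   length(unmapped), paste(unmapped, collapse = ", ")))
  }
  if (length(present) < 2) {
    abort(sprintf("Need >= 2 mappable seeds; unmapped: %s",
                  paste(unmapped, collapse = ", ")))
  }
  D <- igraph::distances(g, v = present, weights = NA)
  ends <- igraph::as_edgelist(g, names = TRUE)
  keep_edge <- rep(FALSE, nrow(ends))
  n_unreachable <- 0L
  du_all <- D[, ends[, 1], drop = FALSE]
  dv_all <- D[, ends[, 2], drop = FALSE]
  for (i in seq_len(length(present) - 1)) {
    for (j in seq(i + 1, length(present))) {
      dst <- D[i, present[j]]
      if (!is.finite(dst)) {
        n_unreachable <- n_unreachable + 1L
        next
      }
      on_path <- (du_all[i, ] + 1 + dv_all[j, ] == dst) |
        (dv_all[i, ] + 1 + du_all[j, ] == dst)
      keep_edge <- keep_edge | (!is.na(on_path) & on_path)
    }
  }
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[keep_edge],
                                     delete.vertices = TRUE)
  attr(sub, "seeds") <- intersect(present, igraph::V(sub)$name)
  attr(sub, "unmapped") <- unmapped
  attr(sub, "n_unreachable_pairs") <- n_unreachable
  sub
}

#' Node degree and betweenness centralities
#'
#' Degree is the incident-edge count; betweenness is computed on the
#' unweighted graph over unordered source-target pairs, endpoints excluded,
#' unnormalized (Brandes' algorithm via igraph).
#'
#' @param g Graph from [build_graph()].
#' @return Tibble `node`, `degree`, `betweenness`.
#' @export
centralities <- function(g) {
  if (igraph::vcount(g) == 0) {
    return(tibble(node = character(), degree = integer(), betweenness = double()))
  }
  tibble(
    node = igraph::V(g)$name,
    degree = as.integer(unname(igraph::degree(g))),
    betweenness = unname(igraph::betweenness(g, directed = FALSE, weights = NA,
                                             normalized = FALSE))
  )
}

#' Hub/bottleneck quadrant classification
#'
#' A node is a hub iff its degree is strictly above the network mean degree,
#' and a bottleneck iff its betweenness is strictly above the mean
#' betweenness; the two flags yield the four quadrants HB (hub-bottleneck),
#' HNB, NHB and NHNB, which partition the node set.
#'
#' @param records Tibble from [centralities()].
#' @return Input with an added `quadrant` factor column.
#' @export
classify_quadrants <- function(records) {
  if (nrow(records) == 0) abort("Need >= 1 node to classify.")
  hub <- records$degree > mean(records$degree)
  bottleneck <- records$betweenness > mean(records$betweenness)
  records$quadrant <- factor(
    dplyr::case_when(
      hub & bottleneck ~ "HB",
      hub & !bottleneck ~ "HNB",
      !hub & bottleneck ~ "NHB",
      .default = "NHNB"
    ),
    levels = c("HB", "HNB", "NHB", "NHNB")
  )
  records
}

#' Walktrap community detection
#'
#' Runs the Pons-Latapy random-walk community algorithm (t-step walk
#' distances, Ward-style agglomerative merging) and cuts the merge
#' dendrogram at the modularity-optimal partition.
#'
#' @param g Graph from [build_graph()].
#' @param steps Random-walk length t (default 4).
#' @param use_weights Use the `weight` edge attribute (combined scores) if
#'   present; `FALSE` treats the graph as unweighted.
#' @return Object of class `alp_communities`: list with `membership` (named
#'   integer vector), `merges`, `modularity` (at the optimal cut) and the
#'   graph. Isolated nodes become singleton communities.
#' @export
walktrap_communities <- function(g, steps = 4, use_weights = TRUE) {
  if (igraph::vcount(g) == 0) abort("Graph is empty.")
  if (steps < 1) abort("`steps` must be >= 1.")
  gw <- g
  if (!use_weights && "weight" %in% igraph::edge_attr_names(gw)) {
    gw <- igraph::delete_edge_attr(gw, "weight")
  }
  iso <- igraph::V(gw)[igraph::degree(gw) == 0]$name
  core <- if (length(iso)) igraph::delete_vertices(gw, iso) else gw
  membership <- integer(0)
  merges <- NULL
  if (igraph::vcount(core) > 0) {
    wt <- igraph::cluster_walktrap(core, steps = steps)
    membership <- stats::setNames(as.integer(igraph::membership(wt)),
                                  igraph::V(core)$name)
    merges <- wt$merges
  }
  if (length(iso)) {
    extra <- stats::setNames(seq_along(iso) + max(membership, 0L), iso)
    membership <- c(membership, extra)
  }
  membership <- membership[igraph::V(gw)$name]
  structure(
    list(membership = membership, merges = merges,
         modularity = modularity_q(gw, membership), graph = gw),
    class = "alp_communities"
  )
}

#' @export
print.alp_communities <- function(x, ...) {
  cat(sprintf("<alp_communities> %d nodes, %d communities, modularity %.4f\n",
              length(x$membership), dplyr::n_distinct(x$membership), x$modularity))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c ( e_cc / m - (d_c / 2m)^2 ): within-community edge fraction
#' minus its expectation under the degree-preserving null model. Uses edge
#' weights when the graph carries them.
#'
#' @param g Graph.
#' @param membership Named (or graph-ordered) community vector covering all
#'   nodes.
#' @return Modularity in \[-0.5, 1\].
#' @export
modularity_q <- function(g, membership) {
  nodes <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    if (!all(nodes %in% names(membership))) {
      abort("Every node needs a community assignment.")
    }
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    abort("Every node needs a community assignment.")
  }
  if (anyNA(membership)) abort("Every node needs a community assignment.")
  igraph::modularity(g, as.integer(factor(membership)))
}

#' Select communities containing hubs-bottlenecks and Pan-DEGs
#'
#' Applies the two selection criteria — presence of at least one HB node
#' and of at least one Pan-DEG — to each community (conjunctively by
#' default; `rule = "OR"` relaxes to either).
#'
#' @param communities An `alp_communities` object (or named membership
#'   vector).
#' @param centrality Tibble from [classify_quadrants()].
#' @param pan_degs Character vector of Pan-DEG gene ids (or tibble with a
#'   `gene` column).
#' @param rule `"AND"` (default) or `"OR"`.
#' @return Tibble `community`, `n_members`, `n_hb`, `n_pandeg`, `has_hb`,
#'   `has_pandeg`, `selected`, `members` (list-column). Warns when nothing
#'   qualifies.
#' @export
select_communities <- function(communities, centrality, pan_degs,
                               rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  membership <- if (inherits(communities, "alp_communities")) {
    communities$membership
  } else {
    communities
  }
  if (is.data.frame(pan_degs)) pan_degs <- pan_degs$gene
  hb_nodes <- centrality$node[centrality$quadrant == "HB"]
  out <- tibble(node = names(membership), community = as.integer(membership)) |>
    group_by(.data$community) |>
    summarise(
      n_members = n(),
      n_hb = sum(.data$node %in% hb_nodes),
      n_pandeg = sum(.data$node %in% pan_degs),
      members = list(.data$node),
      .groups = "drop"
    ) |>
    mutate(
      has_hb = .data$n_hb > 0,
      has_pandeg = .data$n_pandeg > 0,
      selected = if (rule == "AND") .data$has_hb & .data$has_pandeg
                 else .data$has_hb | .data$has_pandeg
    ) |>
    select("community", "n_members", "n_hb", "n_pandeg",
           "has_hb", "has_pandeg", "selected", "members")
  if (!any(out$selected)) warn("No community satisfies the selection criteria.")
  out
}
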