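#' Map raw chemical identifiers to canonical ids
#'
#' Joins raw chemical ids (e.g. STITCH `CIDm...` accessions) against a
#' user-supplied mapping table (canonical lipid ids and names); unmapped
#' ids are reported, not fatal, and duplicate raw ids pointing at one
#' canonical id collapse onto a single node.
#'
#' @param raw_ids Character vector of raw chemical ids.
#' @param mapping Tibble `raw`, `canonical`, `name`.
#' @return Tibble `raw`, `canonical`, `name` (NA canonical where unmapped),
#'   one row per input id.
#' @export
map_chemical_ids <- function(raw_ids, mapping) {
  mapping <- as_tibble(mapping)
  if (nrow(mapping) == 0) abort("Chemical mapping table is empty.")
  stopifnot(all(c("raw", "canonical", "name") %in% names(mapping)))
  out <- tibble(raw = as.character(raw_ids)) |>
    left_join(distinct(mapping, .data$raw, .keep_all = TRUE), by = "raw")
  unmapped <- out$raw[is.na(out$canonical)]
  if (length(unmapped)) {
    inform(sprintf("%d chemical id(s) could not be mapped: %s",
                   length(unmapped), paste(unmapped, collapse = ", ")))
  }
  out
}

is_chemical_id <- function(ids) grepl("^CID[ms]", ids)

#' Build the lipid-droplet protein (LDP) multilayer network
#'
#' Extracts the shortest-path subnetwork of a mixed chemical-protein
#' interaction (CPI) graph spanned by lipid-droplet-associated seed
#' proteins and seed lipid molecules; protein-protein, protein-chemical
#' and chemical-chemical hops count equally. Node kind (`protein` /
#' `chemical`) is stored as a vertex attribute.
#'
#' @param cpi_graph Mixed graph from [build_graph()] over combined PPI +
#'   CPI edges (chemical nodes identified by `CIDm`/`CIDs` prefixes or a
#'   pre-set `kind` vertex attribute).
#' @param seed_proteins,seed_chemicals Seed identifier vectors.
#' @return An `ldp_network`: igraph with `kind` vertex attribute and the
#'   subnetwork attributes of [shortest_path_subnetwork()].
#' @export
build_ldp <- function(cpi_graph, seed_proteins, seed_chemicals = character()) {
  seeds <- unique(c(seed_proteins, seed_chemicals))
  if (length(seeds) == 0) abort("No seeds supplied.")
  sub <- shortest_path_subnetwork(cpi_graph, seeds)
  if (!"kind" %in% igraph::vertex_attr_names(sub)) {
    igraph::V(sub)$kind <- if_else(is_chemical_id(igraph::V(sub)$name),
                                   "chemical", "protein")
  }
  class(sub) <- c("ldp_network", class(sub))
  sub
}

#' Overlay transcriptome and proteome layers on an LDP network
#'
#' Annotates protein nodes with whichever expression layers contain them:
#' `transcriptome` (meta-log2FC of Pan-DEGs) and `proteome` (log-ratios
#' from a lipid-droplet proteome table). A protein present in only one
#' layer carries only that value; chemical nodes never carry expression
#' layers. Topology is untouched.
#'
#' @param network An [build_ldp()] result.
#' @param transcriptome Named numeric vector gene -> meta-log2FC (or tibble
#'   `gene`, `meta_log2fc`).
#' @param proteome Named numeric vector gene -> log-ratio (or tibble
#'   `gene`, `log_ratio`).
#' @return The network with `transcriptome` and `proteome` vertex
#'   attributes (NA where a node is absent from a layer).
#' @export
overlay <- function(network, transcriptome = NULL, proteome = NULL) {
  as_lookup <- function(x, value_col) {
    if (is.null(x)) return(stats::setNames(numeric(0), character(0)))
    if (is.data.frame(x)) stats::setNames(x[[value_col]], x$gene) else x
  }
  tr <- as_lookup(transcriptome, "meta_log2fc")
  pr <- as_lookup(proteome, "log_ratio")
  nodes <- igraph::V(network)$name
  protein <- igraph::V(network)$kind == "protein"
  tv <- unname(tr[nodes]); pv <- unname(pr[nodes])
  tv[!protein] <- NA_real_; pv[!protein] <- NA_real_
  igraph::V(network)$transcriptome <- tv
  igraph::V(network)$proteome <- pv
  network
}

#' Export a network for Cytoscape-style visualization
#'
#' `graphml` writes a single self-contained file whose re-import reproduces
#' the network (topology plus node attributes); `sif` writes topology
#' (`node  pp|cp|cc  node` interaction lines) with a sidecar node-attribute
#' TSV; `tsv` writes an edge table and a node-attribute table.
#'
#' @param network igraph (optionally with `kind`/layer vertex attributes).
#' @param path Output path; for `sif`/`tsv` the basename is reused for the
#'   sidecar files.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0) abort("Refusing to export an empty network.")
  node_table <- function() {
    at <- igraph::vertex_attr(network)
    as_tibble(at[order(names(at) != "name")])
  }
  if (format == "graphml") {
    g <- network
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  ends <- igraph::as_edgelist(network, names = TRUE)
  attr_path <- paste0(sub("\\.(sif|tsv)$", "", path), "_nodes.tsv")
  readr::write_tsv(node_table(), attr_path)
  if (format == "sif") {
    kind <- if ("kind" %in% igraph::vertex_attr_names(network)) {
      stats::setNames(igraph::V(network)$kind, igraph::V(network)$name)
    } else {
      stats::setNames(rep("protein", igraph::vcount(network)), igraph::V(network)$name)
    }
    rel <- dplyr::case_when(
      kind[ends[, 1]] == "chemical" & kind[ends[, 2]] == "chemical" ~ "cc",
      kind[ends[, 1]] == "chemical" | kind[ends[, 2]] == "chemical" ~ "cp",
      .default = "pp"
    )
    writeLines(paste(ends[, 1], rel, ends[, 2], sep = "\t"), path)
  } else {
    edges <- tibble(node_a = ends[, 1], node_b = ends[, 2])
    if ("weight" %in% igraph::edge_attr_names(network)) {
      edges$combined <- igraph::E(network)$weight
    }
    readr::write_tsv(edges, path)
  }
  invisible(c(path, attr_path))
}

#' Re-import a GraphML network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return igraph with node attributes restored.
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # GraphML has no NA literal; igraph serializes NA as NaN, so undo that
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.numeric(v) && any(is.nan(v))) {
      v[is.nan(v)] <- NA_real_
      g <- igraph::set_vertex_attr(g, at, value = v)
    }
  }
  g
}
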