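#' Pipeline run configuration
#'
#' Collects the thresholds and knobs of every stage: DEG selection
#' (|log2FC| >= 2.0, FDR < 0.05), interactome combination (prior 0.041, no
#' score cutoff by default), walktrap walk length (4), community selection
#' rule (HB AND Pan-DEG), enrichment levels (p < 0.01, FDR < 0.05) and
#' heatmap k-means group counts (3 row / 7 column groups).
#'
#' @param sim A [sim_config()] describing the synthetic inputs (ignored
#'   when `inputs` points at real-mode files).
#' @param inputs Optional named list of file paths (as produced by
#'   [write_synthetic_inputs()]); when given, all inputs are read from
#'   disk instead of simulated in memory.
#' @param lfc_min,fdr_max DEG thresholds.
#' @param de_method `"moderated_t"` or `"welch_t"`.
#' @param prior,min_combined Combined-score prior and cutoff.
#' @param walktrap_steps Random-walk length.
#' @param community_rule `"AND"` or `"OR"`.
#' @param enrich_p,enrich_fdr Enrichment significance levels.
#' @param k_rows,k_cols Heatmap k-means group counts (clamped to the
#'   matrix dimensions with a message).
#' @param overlay_rho,overlay_frac Proteome-layer correlation and coverage
#'   used in synthetic mode.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param outdir Optional output directory for TSV/GraphML/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            lfc_min = 2.0, fdr_max = 0.05,
                            de_method = "moderated_t",
                            prior = 0.041, min_combined = 0,
                            walktrap_steps = 4,
                            community_rule = "AND",
                            enrich_p = 0.01, enrich_fdr = 0.05,
                            k_rows = 3, k_cols = 7,
                            overlay_rho = 0.7, overlay_frac = 0.8,
                            seed = sim$seed, outdir = NULL) {
  stopifnot(lfc_min > 0, fdr_max > 0, fdr_max <= 1,
            enrich_p > 0, enrich_fdr > 0, walktrap_steps >= 1)
  structure(
    list(sim = sim, inputs = inputs, lfc_min = lfc_min, fdr_max = fdr_max,
         de_method = de_method, prior = prior, min_combined = min_combined,
         walktrap_steps = walktrap_steps, community_rule = community_rule,
         enrich_p = enrich_p, enrich_fdr = enrich_fdr,
         k_rows = k_rows, k_cols = k_cols,
         overlay_rho = overlay_rho, overlay_frac = overlay_frac,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Gene-to-category map implied by a simulation config
#'
#' Blocks 1-3 of the SBM map to the autophagy, lipid-metabolism and
#' proteostasis categories; everything else is "other".
#'
#' @param config A [sim_config()].
#' @return Tibble `gene`, `category`.
#' @export
gene_categories <- function(config) {
  part <- synthetic_truth(config)$true_partition
  cats <- c("autophagy", "lipid_metabolism", "proteostasis")
  tibble(gene = gene_ids(config$n_genes)) |>
    mutate(block = unname(part[.data$gene]),
           category = if_else(!is.na(.data$block) & .data$block <= 3,
                              cats[pmin(.data$block, 3)], "other")) |>
    select("gene", "category")
}

#' Generate every pipeline input from one simulation config
#'
#' @param config A [sim_config()].
#' @return Named list: `single`, `meta_a`, `meta_b` (expression matrices),
#'   `links_raw`, `cpi_links_raw`, `dag`, `annotations`, `categories`,
#'   `chemical_map`, `proteome`, `truth`.
#' @export
simulate_pipeline_inputs <- function(config) {
  seed <- config$seed
  meta_design <- default_design("meta")
  single <- simulate_expression(config, default_design("single"),
                                seed = stage_seed(seed, 1))
  meta_a <- simulate_expression(config, dplyr::filter(meta_design, .data$dataset == "DS2"),
                                seed = stage_seed(seed, 2))
  meta_b <- simulate_expression(config, dplyr::filter(meta_design, .data$dataset == "DS3"),
                                seed = stage_seed(seed, 3))
  net <- simulate_interactome(config, seed = stage_seed(seed, 4))
  cpi <- simulate_cpi_links(config, seed = stage_seed(seed, 5))
  go <- simulate_go(config, net$truth, seed = stage_seed(seed, 6))
  chems <- unique(cpi$chemical)
  chemical_map <- tibble(
    raw = chems,
    canonical = sprintf("LM%04d", seq_along(chems)),
    name = sprintf("synthetic lipid %d", seq_along(chems))
  )
  lipid_genes <- names(net$truth$true_partition)[net$truth$true_partition == 2]
  eff <- config$planted_degs
  proteome <- simulate_proteome_overlay(
    genes = union(lipid_genes, sprintf("G%04d", 96:99)),
    transcriptome = eff,
    rho = 0.7, subset_frac = 0.8, seed = stage_seed(seed, 7)
  )
  list(single = single$expr, meta_a = meta_a$expr, meta_b = meta_b$expr,
       links_raw = as_raw_links(net$links), cpi_links_raw = as_raw_links(cpi, stitch = TRUE),
       dag = go$dag, annotations = go$annotations,
       categories = gene_categories(config), chemical_map = chemical_map,
       proteome = proteome, truth = net$truth)
}

# keep generator tables in the on-disk dialect (ids + 0-1000 integer scores)
as_raw_links <- function(links, stitch = FALSE) {
  if (stitch && !"chemical" %in% names(links)) return(links)
  links
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$inputs)) {
    # the pipeline's master seed drives the generators too, so one --seed
    # reproduces the whole run
    cfg_sim <- config$sim
    cfg_sim$seed <- config$seed
    sim <- simulate_pipeline_inputs(cfg_sim)
    sim$links <- as_channel_edges(sim$links_raw, "string_detailed")
    sim$cpi <- as_channel_edges(sim$cpi_links_raw, "stitch_detailed")
    return(sim)
  }
  paths <- config$inputs
  needed <- c("expr_single", "samples_single", "expr_meta_a", "samples_meta_a",
              "expr_meta_b", "samples_meta_b", "links", "obo", "annotations")
  for (nm in needed) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      abort(sprintf("Config error: required input '%s' missing or not found at '%s'.",
                    nm, paths[[nm]] %||% "<unset>"))
    }
  }
  opt <- function(nm, reader, default = NULL) {
    if (is.null(paths[[nm]])) return(default)
    if (!file.exists(paths[[nm]])) {
      abort(sprintf("Config error: input '%s' not found at '%s'.", nm, paths[[nm]]))
    }
    reader(paths[[nm]])
  }
  list(
    single = read_expression(paths$expr_single, paths$samples_single),
    meta_a = read_expression(paths$expr_meta_a, paths$samples_meta_a),
    meta_b = read_expression(paths$expr_meta_b, paths$samples_meta_b),
    links = parse_links(paths$links, "string_detailed"),
    cpi = opt("cpi_links", function(p) parse_links(p, "stitch_detailed")),
    dag = parse_go(paths$obo),
    annotations = read_annotations(paths$annotations),
    categories = opt("categories", function(p) readr::read_tsv(p, col_types = "cc")),
    chemical_map = opt("chemical_map", function(p) readr::read_tsv(p, col_types = "ccc")),
    proteome = opt("proteome", function(p) readr::read_tsv(p, col_types = "cd")),
    truth = NULL
  )
}

run_dge_stage <- function(em, analysis, config) {
  cmps <- all_comparisons(em, analysis)
  records <- bind_rows(purrr::map(cmps, fit_pairwise_de, em = em,
                                  method = config$de_method))
  filtered <- filter_degs(records, config$lfc_min, config$fdr_max)
  list(records = records, filtered = filtered,
       up = nonredundant_union(filtered, "up"),
       down = nonredundant_union(filtered, "down"))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: differential expression for the single- and
#' meta-analysis (the meta datasets are jointly quantile-normalized before
#' cross-dataset contrasts), Pan-DEG intersection, combined-score
#' interactome assembly, shortest-path subnetwork extraction over Pan-DEG
#' seeds, centrality quadrant classification, walktrap community detection
#' and selection, per-community GO over-representation with the k-means
#' heatmap, and the chemical-protein multilayer overlay. With no planted
#' or detected Pan-DEGs the network stages are skipped with a warning.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `alp_run` holding every stage result plus a
#'   `summary` list of per-stage counts; deterministic given the seed.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  inputs <- load_pipeline_inputs(config)
  single <- run_dge_stage(inputs$single, "single", config)
  meta_em <- combine_datasets(inputs$meta_a, inputs$meta_b)
  meta <- run_dge_stage(meta_em, "meta", config)
  pan <- pan_deg_intersect(single$filtered, meta$filtered,
                           categories = inputs$categories)
  res <- list(config = config, truth = inputs$truth,
              degs_single = single, degs_meta = meta, pan_degs = pan)

  if (nrow(pan) >= 2) {
    scored <- threshold_edges(
      combine_scores(inputs$links, prior = config$prior),
      config$min_combined
    )
    ppi <- build_graph(scored)
    alp <- shortest_path_subnetwork(ppi, pan$gene)
    centr <- classify_quadrants(centralities(alp))
    comm <- walktrap_communities(alp, steps = config$walktrap_steps)
    selection <- select_communities(comm, centr, pan$gene,
                                    rule = config$community_rule)
    res <- c(res, list(scored_edges = scored, ppi_graph = ppi, alp_network = alp,
                       centrality = centr, communities = comm,
                       selection = selection))

    ann <- propagate(inputs$dag, inputs$annotations)
    selected <- dplyr::filter(selection, .data$selected)
    annotated <- unique(ann$propagated$gene)
    enr <- bind_rows(purrr::map2(selected$community, selected$members,
      function(id, members) {
        enrich(intersect(members, annotated), ann,
               p_max = config$enrich_p, fdr_max = config$enrich_fdr,
               cluster_id = as.character(id))
      }))
    hm <- NULL
    if (nrow(enr)) {
      kr <- min(config$k_rows, dplyr::n_distinct(enr$cluster))
      kc <- min(config$k_cols, dplyr::n_distinct(enr$term))
      if (kr < config$k_rows || kc < config$k_cols) {
        inform(sprintf("k-means groups clamped to matrix size (%d rows, %d cols).", kr, kc))
      }
      hm <- heatmap_matrix(enr, k_rows = kr, k_cols = kc,
                           seed = stage_seed(config$seed, 8))
    }
    res <- c(res, list(annotation = ann, enrichment = enr, heatmap = hm))

    if (!is.null(inputs$cpi) && nrow(inputs$cpi)) {
      cpi_scored <- threshold_edges(
        combine_scores(inputs$cpi, prior = config$prior), config$min_combined)
      mixed <- build_graph(bind_rows(scored, cpi_scored))
      seeds_p <- intersect(
        pan$gene[pan$category == "lipid_metabolism"],
        igraph::V(mixed)$name
      )
      chem_ids <- unique(inputs$cpi$node_a[is_chemical_id(inputs$cpi$node_a)])
      if (!is.null(inputs$chemical_map)) {
        mapped <- map_chemical_ids(chem_ids, inputs$chemical_map)
        chem_ids <- mapped$raw[!is.na(mapped$canonical)]
      }
      ldp <- NULL
      if (length(seeds_p) + length(chem_ids) >= 2) {
        ldp <- build_ldp(mixed, seeds_p, chem_ids)
        ldp <- overlay(ldp,
                       transcriptome = stats::setNames(pan$meta_log2fc, pan$gene),
                       proteome = inputs$proteome)
      }
      res <- c(res, list(ldp_network = ldp))
    }
  } else {
    warn("Fewer than 2 Pan-DEGs: network, enrichment and multilayer stages skipped.")
  }
  res$summary <- summarize_run(res)
  class(res) <- "alp_run"
  if (!is.null(config$outdir)) write_run(res, config$outdir)
  res
}

summarize_run <- function(res) {
  pan <- res$pan_degs
  quad <- function(q) {
    if (is.null(res$centrality)) return(0L)
    sum(res$centrality$quadrant == q)
  }
  s <- list(
    seed = res$config$seed,
    degs_single_redundant_up = res$degs_single$up$n_redundant,
    degs_single_unique_up = res$degs_single$up$n_unique,
    degs_single_unique_down = res$degs_single$down$n_unique,
    degs_meta_redundant_up = res$degs_meta$up$n_redundant,
    degs_meta_unique_up = res$degs_meta$up$n_unique,
    degs_meta_unique_down = res$degs_meta$down$n_unique,
    n_pan_degs = nrow(pan),
    pan_degs_by_category = as.list(table(pan$category)),
    network_nodes = if (is.null(res$alp_network)) 0L else igraph::vcount(res$alp_network),
    network_edges = if (is.null(res$alp_network)) 0L else igraph::ecount(res$alp_network),
    unmapped_seeds = if (is.null(res$alp_network)) character() else attr(res$alp_network, "unmapped"),
    n_hb = quad("HB"), n_hnb = quad("HNB"), n_nhb = quad("NHB"), n_nhnb = quad("NHNB"),
    modularity = if (is.null(res$communities)) NA_real_ else res$communities$modularity,
    n_communities = if (is.null(res$communities)) 0L else dplyr::n_distinct(res$communities$membership),
    n_selected_communities = if (is.null(res$selection)) 0L else sum(res$selection$selected),
    enriched_terms_per_cluster = if (is.null(res$enrichment) || !nrow(res$enrichment)) {
      list()
    } else {
      as.list(table(res$enrichment$cluster))
    },
    ldp_nodes = if (is.null(res$ldp_network)) 0L else igraph::vcount(res$ldp_network),
    ldp_edges = if (is.null(res$ldp_network)) 0L else igraph::ecount(res$ldp_network),
    version = as.character(utils::packageVersion("alpnet"))
  )
  s$config_hash <- rlang::hash(res$config[setdiff(names(res$config), "outdir")])
  s$summary_hash <- rlang::hash(s)
  s
}

#' @export
print.alp_run <- function(x, ...) {
  s <- x$summary
  cat("<alp_run>\n")
  cat(sprintf("  Pan-DEGs: %d (%s)\n", s$n_pan_degs,
              paste(sprintf("%s=%s", names(s$pan_degs_by_category),
                            unlist(s$pan_degs_by_category)), collapse = ", ")))
  cat(sprintf("  ALP network: %d nodes / %d edges; quadrants HB=%d HNB=%d NHB=%d NHNB=%d\n",
              s$network_nodes, s$network_edges, s$n_hb, s$n_hnb, s$n_nhb, s$n_nhnb))
  cat(sprintf("  Communities: %d (%d selected), modularity %.4f\n",
              s$n_communities, s$n_selected_communities, s$modularity))
  cat(sprintf("  Enriched terms: %d across %d clusters; LDP network: %d nodes / %d edges\n",
              if (is.null(x$enrichment)) 0L else nrow(x$enrichment),
              length(s$enriched_terms_per_cluster), s$ldp_nodes, s$ldp_edges))
  invisible(x)
}

#' @export
glance.alp_run <- function(x, ...) {
  s <- x$summary
  tibble(
    n_pan_degs = s$n_pan_degs, network_nodes = s$network_nodes,
    network_edges = s$network_edges, n_hb = s$n_hb, n_hnb = s$n_hnb,
    n_nhb = s$n_nhb, n_nhnb = s$n_nhnb, n_communities = s$n_communities,
    n_selected_communities = s$n_selected_communities,
    modularity = s$modularity,
    n_enriched = if (is.null(x$enrichment)) 0L else nrow(x$enrichment),
    ldp_nodes = s$ldp_nodes, ldp_edges = s$ldp_edges
  )
}

write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(res$degs_single$filtered, p("degs_single.tsv"))
  readr::write_tsv(res$degs_meta$filtered, p("degs_meta.tsv"))
  readr::write_tsv(res$pan_degs, p("pan_degs.tsv"))
  if (!is.null(res$centrality)) readr::write_tsv(res$centrality, p("centrality.tsv"))
  if (!is.null(res$communities)) {
    comm_tbl <- tidy(res$communities) |>
      left_join(select(res$selection, "community", "selected"), by = "community")
    readr::write_tsv(comm_tbl, p("communities.tsv"))
  }
  if (!is.null(res$enrichment)) readr::write_tsv(res$enrichment, p("enrichment.tsv"))
  if (!is.null(res$heatmap)) {
    as_tibble(res$heatmap$matrix, rownames = "cluster") |>
      readr::write_tsv(p("heatmap_matrix.tsv"))
  }
  if (!is.null(res$alp_network)) {
    export_network(res$alp_network, p("alp_network.graphml"), "graphml")
    export_network(res$alp_network, p("alp_network.sif"), "sif")
  }
  if (!is.null(res$ldp_network)) {
    export_network(res$ldp_network, p("ldp_network.graphml"), "graphml")
  }
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  cfg$sim <- cfg$sim[setdiff(names(cfg$sim), c("design", "channel_model", "planted_degs"))]
  jsonlite::write_json(list(config = unclass(cfg)[setdiff(names(cfg), c("inputs", "sim"))],
                            sim = cfg$sim, seed = res$config$seed),
                       p("config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
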