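#' Read an expression matrix and sample sheet from TSV
#'
#' Expression TSV: first column gene ids, remaining columns one per sample.
#' Sample sheet TSV: columns `sample`, `dataset`, `condition`, `timepoint`.
#'
#' @param expr_path,samples_path File paths.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_path, samples_path) {
  df <- readr::read_tsv(expr_path, show_col_types = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  expression_matrix(values, samples)
}

#' @rdname read_expression
#' @param em An [expression_matrix()].
#' @export
write_expression <- function(em, expr_path, samples_path) {
  as_tibble(em$values, rownames = "gene") |> readr::write_tsv(expr_path)
  readr::write_tsv(em$samples, samples_path)
  invisible(c(expr_path, samples_path))
}

#' Read/write gene -> GO term annotations as TSV
#'
#' @param path TSV with columns `gene`, `term`.
#' @return Tibble `gene`, `term`.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' @rdname read_annotations
#' @param annotations Tibble `gene`, `term`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Write every synthetic pipeline input to disk in its real-mode dialect
#'
#' Materializes the artifacts the real-data readers consume: expression +
#' sample-sheet TSVs for the single-analysis dataset and the two
#' meta-analysis datasets, STRING-like and STITCH-like link tables, an
#' OBO-subset ontology, an annotation TSV, a gene-category TSV, a chemical
#' mapping TSV, a proteome overlay TSV, and a `truth.json` recording the
#' planted structure and seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_pipeline_inputs(config)
  write_expression(sim$single, p("expr_single.tsv"), p("samples_single.tsv"))
  write_expression(sim$meta_a, p("expr_meta_a.tsv"), p("samples_meta_a.tsv"))
  write_expression(sim$meta_b, p("expr_meta_b.tsv"), p("samples_meta_b.tsv"))
  write_links(as_channel_edges(sim$links_raw, "string_detailed"),
              p("protein_links.txt"), "string_detailed")
  write_links(as_channel_edges(sim$cpi_links_raw, "stitch_detailed"),
              p("chemical_links.txt"), "stitch_detailed")
  write_obo(sim$dag, p("ontology.obo"))
  write_annotations(sim$annotations, p("annotations.tsv"))
  readr::write_tsv(sim$categories, p("categories.tsv"))
  readr::write_tsv(sim$chemical_map, p("chemical_map.tsv"))
  readr::write_tsv(sim$proteome, p("proteome_overlay.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(true_deg_up = truth$true_deg_set$up,
         true_deg_down = truth$true_deg_set$down,
         true_partition = as.list(truth$true_partition),
         true_enriched_terms = truth$true_enriched_terms,
         seed = truth$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA
  )
  paths <- list(
    expr_single = p("expr_single.tsv"), samples_single = p("samples_single.tsv"),
    expr_meta_a = p("expr_meta_a.tsv"), samples_meta_a = p("samples_meta_a.tsv"),
    expr_meta_b = p("expr_meta_b.tsv"), samples_meta_b = p("samples_meta_b.tsv"),
    links = p("protein_links.txt"), cpi_links = p("chemical_links.txt"),
    obo = p("ontology.obo"), annotations = p("annotations.tsv"),
    categories = p("categories.tsv"), chemical_map = p("chemical_map.tsv"),
    proteome = p("proteome_overlay.tsv"), truth = p("truth.json")
  )
  invisible(paths)
}
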