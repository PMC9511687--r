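#' Gene Ontology DAG container
#'
#' Validated directed acyclic graph of GO terms. Construction fails on
#' cycles (naming the offending terms) and on terms without a namespace.
#'
#' @param terms Tibble `id`, `name`, `namespace` (`biological_process`,
#'   `cellular_component` or `molecular_function`).
#' @param edges Tibble `child`, `parent`, `relation` (`is_a` or `part_of`).
#' @return Object of class `go_dag`.
#' @export
go_dag <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  if (any(is.na(terms$namespace) | terms$namespace == "")) {
    bad <- terms$id[is.na(terms$namespace) | terms$namespace == ""]
    abort(sprintf("Format error: term(s) without namespace: %s",
                  paste(bad, collapse = ", ")))
  }
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown)) {
    abort(sprintf("Edges reference unknown term(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  g <- dag_igraph(terms, edges)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    abort(sprintf("Cycle detected among term(s): %s",
                  paste(sort(cyc), collapse = ", ")))
  }
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

dag_igraph <- function(terms, edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges$child, to = edges$parent,
               relation = edges$relation),
    directed = TRUE,
    vertices = data.frame(name = terms$id)
  )
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges (%s)\n", nrow(x$terms),
              nrow(x$edges), paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Parse an OBO-subset ontology file
#'
#' Supports `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete` tags (the subset needed for
#' over-representation and semantic-similarity analysis). Obsolete terms
#' are skipped with a count; cycles and missing namespaces are format
#' errors.
#'
#' @param path OBO file path.
#' @return A [go_dag()].
#' @export
parse_go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0) abort("No [Term] stanzas found.")
  bounds <- c(starts, length(lines) + 1L)
  n_obsolete <- 0L
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    chunk <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\s*(\\[|$)", chunk)]
    tag_val <- function(tag) {
      hit <- grep(sprintf("^%s:\\s*", tag), chunk, value = TRUE)
      sub(sprintf("^%s:\\s*", tag), "", hit)
    }
    if (length(tag_val("is_obsolete")) && any(tag_val("is_obsolete") == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    id <- tag_val("id")[1]
    if (is.na(id) || !length(id)) abort("Format error: [Term] stanza without id.")
    nm <- tag_val("name")[1] %||% NA_character_
    ns <- tag_val("namespace")[1]
    terms[[length(terms) + 1L]] <- tibble(
      id = id, name = nm %||% NA_character_,
      namespace = if (length(ns)) ns else NA_character_
    )
    isa <- sub("\\s*!.*$", "", tag_val("is_a"))
    if (length(isa)) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = trimws(isa),
                                            relation = "is_a")
    }
    rel <- tag_val("relationship")
    rel <- rel[grepl("^part_of\\s", rel)]
    if (length(rel)) {
      parents <- trimws(sub("\\s*!.*$", "", sub("^part_of\\s+", "", rel)))
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = parents,
                                            relation = "part_of")
    }
  }
  if (n_obsolete) inform(sprintf("Skipped %d obsolete term(s).", n_obsolete))
  terms <- bind_rows(terms)
  edges <- if (length(edges)) bind_rows(edges) else {
    tibble(child = character(), parent = character(), relation = character())
  }
  edges <- filter(edges, .data$parent %in% terms$id)
  go_dag(terms, edges)
}

#' Write a DAG in the OBO subset dialect
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  stanza <- function(i) {
    id <- dag$terms$id[i]
    e <- filter(dag$edges, .data$child == id)
    c("[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      paste0("namespace: ", dag$terms$namespace[i]),
      paste0("is_a: ", e$parent[e$relation == "is_a"]),
      paste0("relationship: part_of ", e$parent[e$relation == "part_of"]),
      "")
  }
  writeLines(c("format-version: 1.2", "",
               unlist(purrr::map(seq_len(nrow(dag$terms)), stanza))), path)
  invisible(path)
}

#' Propagate direct annotations up the DAG (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to all of the term's
#' ancestors; this closes the direct annotation table over ancestors and
#' builds the term-to-gene index used by the hypergeometric test.
#'
#' @param dag A [go_dag()].
#' @param direct Tibble `gene`, `term` of direct annotations. Annotations
#'   to terms absent from `dag` are skipped with a warning.
#' @return Object of class `annotation_set`: list with `direct`,
#'   `propagated` (tibble `term`, `gene`, `namespace`) and `term_genes`
#'   (named list).
#' @export
propagate <- function(dag, direct) {
  direct <- as_tibble(direct)
  unknown <- setdiff(unique(direct$term), dag$terms$id)
  if (length(unknown)) {
    warn(sprintf("Skipping annotations to %d unknown term(s): %s",
                 length(unknown), paste(unknown, collapse = ", ")))
    direct <- filter(direct, !.data$term %in% unknown)
  }
  if (nrow(direct) == 0) {
    empty <- tibble(term = character(), gene = character(),
                    namespace = character())
    return(structure(list(direct = direct, propagated = empty,
                          term_genes = list()),
                     class = "annotation_set"))
  }
  g <- dag_igraph(dag$terms, dag$edges)
  reach <- igraph::distances(g, mode = "out")
  anc <- purrr::map(seq_len(nrow(reach)), function(i) colnames(reach)[is.finite(reach[i, ])])
  names(anc) <- rownames(reach)
  propagated <- direct |>
    mutate(term_set = anc[.data$term]) |>
    select("gene", "term_set") |>
    tidyr::unnest_longer("term_set", values_to = "term") |>
    distinct(.data$term, .data$gene) |>
    left_join(select(dag$terms, "id", "namespace"), by = c(term = "id")) |>
    arrange(.data$term, .data$gene)
  structure(
    list(direct = direct, propagated = propagated,
         term_genes = split(propagated$gene, propagated$term)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes, %d direct / %d propagated annotations\n",
              dplyr::n_distinct(x$direct$gene), nrow(x$direct), nrow(x$propagated)))
  invisible(x)
}

#' Hypergeometric over-representation of GO terms in a gene cluster
#'
#' For every term with at least one annotated universe gene, tests the
#' upper-tail hypergeometric probability P(X >= k) of drawing k
#' term-annotated genes in a cluster of size n from a universe of N genes
#' of which K carry the term. BH adjustment is applied within each
#' namespace family; results are filtered to `p_raw < p_max` and
#' `fdr < fdr_max` unless `filter = FALSE`.
#'
#' @param cluster Character vector of genes (must lie within the universe).
#' @param ann An [propagate()] result.
#' @param universe Universe gene set; defaults per namespace to all genes
#'   with at least one annotation in that namespace.
#' @param namespaces Namespaces tested (BP and CC by default).
#' @param p_max Raw-p significance level (default 0.01).
#' @param fdr_max FDR level (default 0.05).
#' @param filter Apply the two thresholds (default `TRUE`).
#' @param cluster_id Optional label stored in the `cluster` column.
#' @return Tibble `cluster`, `term`, `namespace`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `fdr`, `q` (q reported as the BH value).
#' @export
enrich <- function(cluster, ann, universe = NULL,
                   namespaces = c("biological_process", "cellular_component"),
                   p_max = 0.01, fdr_max = 0.05, filter = TRUE,
                   cluster_id = NA_character_) {
  cluster <- unique(cluster)
  res <- purrr::map(namespaces, function(ns) {
    ns_prop <- dplyr::filter(ann$propagated, .data$namespace == ns)
    if (nrow(ns_prop) == 0) return(NULL)
    uni <- if (is.null(universe)) unique(ns_prop$gene) else unique(universe)
    if (!all(cluster %in% uni)) {
      abort(sprintf("Cluster contains gene(s) outside the universe: %s",
                    paste(setdiff(cluster, uni), collapse = ", ")))
    }
    ns_prop <- dplyr::filter(ns_prop, .data$gene %in% uni)
    if (nrow(ns_prop) == 0) return(NULL)
    ns_prop |>
      group_by(.data$term) |>
      summarise(K = n(), k = sum(.data$gene %in% cluster), .groups = "drop") |>
      mutate(
        namespace = ns,
        n = length(cluster),
        N = length(uni),
        p_raw = stats::phyper(.data$k - 1, .data$K, .data$N - .data$K,
                              .data$n, lower.tail = FALSE),
        fdr = bh_adjust(.data$p_raw),
        q = .data$fdr
      )
  })
  out <- bind_rows(res) |>
    mutate(cluster = cluster_id) |>
    select("cluster", "term", "namespace", "k", "n", "K", "N",
           "p_raw", "fdr", "q") |>
    arrange(.data$p_raw)
  if (filter) out <- dplyr::filter(out, .data$p_raw < p_max, .data$fdr < fdr_max)
  out
}

# Wang S-values: contribution of every ancestor of `term`, decaying by the
# relation weight along the best (max-product) child->parent path
wang_svalues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  sv <- stats::setNames(1, term)
  frontier <- term
  while (length(frontier)) {
    nxt <- character(0)
    for (child in frontier) {
      e <- dag$edges[dag$edges$child == child, , drop = FALSE]
      if (nrow(e) == 0) next
      contrib <- unname(weights[e$relation]) * sv[[child]]
      for (i in seq_len(nrow(e))) {
        p <- e$parent[i]
        cur <- if (p %in% names(sv)) sv[[p]] else NA_real_
        if (is.na(cur) || contrib[i] > cur) {
          sv[p] <- contrib[i]
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sv
}

#' Wang graph-based semantic similarity of two GO terms
#'
#' Each term's ancestors receive S-values decaying by the relation weight
#' (0.8 per `is_a`, 0.6 per `part_of` edge by default) along the strongest
#' path from the term; similarity is the S-value mass on shared ancestors
#' relative to the two terms' total semantic values:
#' `sim = sum_{a in common}(S1(a) + S2(a)) / (SV(t1) + SV(t2))`.
#'
#' @param t1,t2 Term ids (same namespace; cross-namespace pairs return 0
#'   with a warning).
#' @param dag A [go_dag()].
#' @param weights Named relation weights.
#' @return Similarity in \[0, 1\]; symmetric; 1 for identical terms.
#' @export
wang_similarity <- function(t1, t2, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  ns <- stats::setNames(dag$terms$namespace, dag$terms$id)
  if (is.na(ns[t1]) || is.na(ns[t2])) abort("Unknown term id.")
  if (ns[t1] != ns[t2]) {
    warn("Cross-namespace term pair: similarity defined as 0.")
    return(0)
  }
  s1 <- wang_svalues(t1, dag, weights)
  s2 <- wang_svalues(t2, dag, weights)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' @rdname wang_similarity
#' @param terms Term ids for a pairwise similarity matrix.
#' @export
wang_similarity_matrix <- function(terms, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  n <- length(terms)
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- wang_similarity(terms[i], terms[j], dag, weights)
    }
  }
  m
}

#' Cluster-by-term enrichment heatmap matrix with k-means grouping
#'
#' Builds the clusters x terms matrix of -log10(FDR) (0 where a term is not
#' significant for a cluster, capped for readability) and groups rows and
#' columns independently with k-means (Euclidean distance, 100 restarts,
#' fixed seed) — the layout used for community-level GO heatmaps with 3 row
#' superclusters and 7 column groups by default.
#'
#' @param results Enrichment tibble (from [enrich()] over clusters) with
#'   columns `cluster`, `term`, `fdr`.
#' @param k_rows,k_cols Number of k-means groups for rows/columns; must not
#'   exceed the respective dimension.
#' @param seed Seed for the k-means restarts.
#' @param cap Cap on -log10(FDR) cells.
#' @return Object of class `alp_heatmap`: list with `matrix`, `row_groups`,
#'   `col_groups`.
#' @export
heatmap_matrix <- function(results, k_rows = 3, k_cols = 7, seed = 1, cap = 10) {
  if (nrow(results) == 0) abort("Need >= 1 significant enrichment result.")
  wide <- results |>
    mutate(score = pmin(-log10(.data$fdr), cap)) |>
    select("cluster", "term", "score") |>
    tidyr::pivot_wider(names_from = "term", values_from = "score",
                       values_fill = 0, values_fn = max)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$cluster)
  if (k_rows > nrow(m) || k_cols > ncol(m)) {
    abort(sprintf("k (%d rows, %d cols) exceeds matrix dimension (%d x %d).",
                  k_rows, k_cols, nrow(m), ncol(m)))
  }
  km_groups <- function(x, k, sub_seed) {
    ux <- unique(x)
    k_eff <- min(k, nrow(ux))
    groups <- if (k_eff >= nrow(ux)) {
      seq_len(nrow(ux))  # every distinct profile its own group
    } else {
      with_seed(sub_seed, stats::kmeans(ux, centers = k_eff, nstart = 100))$cluster
    }
    key <- apply(x, 1, paste, collapse = "\r")
    ukey <- apply(ux, 1, paste, collapse = "\r")
    stats::setNames(groups[match(key, ukey)], rownames(x))
  }
  structure(
    list(matrix = m,
         row_groups = km_groups(m, k_rows, seed),
         col_groups = km_groups(t(m), k_cols, seed + 1L)),
    class = "alp_heatmap"
  )
}
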