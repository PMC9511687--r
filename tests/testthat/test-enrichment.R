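obo_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("OBO subset parsing builds a validated DAG", {
  path <- obo_fixture(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: child", "namespace: biological_process",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: old", "namespace: biological_process",
    "is_obsolete: true", "",
    "[Term]", "id: GO:4", "name: part", "namespace: biological_process",
    "relationship: part_of GO:2 ! child", ""
  ))
  expect_message(dag <- parse_go(path), "1 obsolete")
  expect_setequal(dag$terms$id, c("GO:1", "GO:2", "GO:4"))
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag$edges$relation[dag$edges$child == "GO:4"], "part_of")

  # serialization round trip
  out <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, out)
  again <- parse_go(out)
  expect_equal(dplyr::arrange(again$terms, id), dplyr::arrange(dag$terms, id))
  expect_equal(dplyr::arrange(again$edges, child), dplyr::arrange(dag$edges, child))

  cyc <- obo_fixture(c(
    "[Term]", "id: A", "name: a", "namespace: biological_process", "is_a: B", "",
    "[Term]", "id: B", "name: b", "namespace: biological_process", "is_a: A", ""
  ))
  expect_error(parse_go(cyc), "Cycle.*A.*B")

  no_ns <- obo_fixture(c("[Term]", "id: A", "name: a", ""))
  expect_error(parse_go(no_ns), "namespace")
})

test_that("true-path propagation closes annotations over ancestors", {
  dag <- tiny_dag()
  ann <- propagate(dag, tibble::tibble(gene = "g1", term = "B"))
  prop_g1 <- ann$propagated$term[ann$propagated$gene == "g1"]
  expect_setequal(prop_g1, c("B", "A", "R"))

  # diamond: two routes to the root count a gene once
  diamond <- go_dag(
    terms = tibble::tibble(id = c("R", "P1", "P2", "L"), name = "t",
                           namespace = "biological_process"),
    edges = tibble::tibble(child = c("P1", "P2", "L", "L"),
                           parent = c("R", "R", "P1", "P2"),
                           relation = "is_a")
  )
  ann <- propagate(diamond, tibble::tibble(gene = "g1", term = "L"))
  expect_equal(sum(ann$propagated$term == "R" & ann$propagated$gene == "g1"), 1)

  # namespace root collects every annotated gene
  direct <- tibble::tibble(gene = c("g1", "g2", "g3"), term = c("B", "C", "A"))
  ann <- propagate(tiny_dag(), direct)
  expect_setequal(ann$term_genes[["R"]], c("g1", "g2", "g3"))

  expect_warning(propagate(tiny_dag(), tibble::tibble(gene = "g", term = "NOPE")),
                 "unknown")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N=10, K=4, n=5, k=3 -> 66/252
  expect_equal(stats::phyper(2, 4, 6, 5, lower.tail = FALSE), 66 / 252)

  dag <- tiny_dag()
  universe <- paste0("g", 1:10)
  direct <- tibble::tibble(gene = paste0("g", 1:4), term = "B")
  # pad every gene so the BP universe is all 10 genes
  direct <- dplyr::bind_rows(direct, tibble::tibble(gene = universe, term = "C"))
  ann <- propagate(dag, direct)
  res <- enrich(paste0("g", c(1, 2, 3, 7, 8)), ann, filter = FALSE)
  row <- res[res$term == "B", ]
  expect_equal(row$k, 3L)
  expect_equal(row$K, 4L)
  expect_equal(row$N, 10L)
  expect_equal(row$p_raw, 66 / 252, tolerance = 1e-12)
  expect_equal(row$p_raw, brute_hyper(10, 4, 5, 3), tolerance = 1e-12)
  expect_true(all(res$fdr >= res$p_raw - 1e-12))

  # k = 0 gives p = 1; cluster = universe gives p = 1 everywhere
  none <- enrich(paste0("g", 7:10), ann, filter = FALSE)
  expect_equal(none$p_raw[none$term == "B"], 1)
  all_in <- enrich(universe, ann, filter = FALSE)
  expect_true(all(all_in$p_raw == 1))

  expect_error(enrich(c("g1", "not_there"), ann), "universe")

  # randomized agreement with enumeration for N <= 12
  set.seed(8)
  for (trial in 1:25) {
    N <- sample(5:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 brute_hyper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("uniform random annotation yields super-uniform null p-values", {
  set.seed(12)
  genes <- paste0("g", 1:200)
  terms <- tibble::tibble(id = c("R", paste0("L", 1:40)), name = "t",
                          namespace = "biological_process")
  dag <- go_dag(terms, tibble::tibble(child = paste0("L", 1:40), parent = "R",
                                      relation = "is_a"))
  direct <- tibble::tibble(
    gene = rep(genes, each = 4),
    term = as.vector(replicate(200, sample(paste0("L", 1:40), 4)))
  )
  ann <- propagate(dag, direct)
  ps <- unlist(lapply(1:20, function(i) {
    res <- enrich(sample(genes, 20), ann, filter = FALSE)
    res$p_raw[res$term != "R"]
  }))
  # the discrete hypergeometric tail is valid (super-uniform): the rejection
  # fraction never exceeds alpha beyond Monte-Carlo error
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps < alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
  expect_gt(mean(ps < 0.5), 0.1)  # but not degenerate
})

test_that("Wang similarity reproduces S-value hand computations", {
  dag <- tiny_dag()
  expect_equal(wang_similarity("B", "B", dag), 1.0)
  # child against its root parent via one is_a edge: (1 + 0.8) / (1 + 1.8)
  expect_equal(wang_similarity("A", "R", dag), 1.8 / 2.8, tolerance = 1e-4)
  # same configuration through a part_of edge: (1 + 0.6) / (1 + 1.6)
  po <- go_dag(
    terms = tibble::tibble(id = c("P", "Q"), name = "t",
                           namespace = "biological_process"),
    edges = tibble::tibble(child = "Q", parent = "P", relation = "part_of")
  )
  expect_equal(wang_similarity("Q", "P", po), 1.6 / 2.6, tolerance = 1e-4)
  # deeper pairs: hand S-values for B (B=1, A=.8, R=.64) vs A (A=1, R=.8)
  expect_equal(wang_similarity("B", "A", dag), (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8),
               tolerance = 1e-10)
  # symmetry
  expect_equal(wang_similarity("B", "C", dag), wang_similarity("C", "B", dag))

  # similarity to an ancestor strictly decreases with path length
  chain <- go_dag(
    terms = tibble::tibble(id = c("R", "M", "L"), name = "t",
                           namespace = "biological_process"),
    edges = tibble::tibble(child = c("M", "L"), parent = c("R", "M"),
                           relation = "is_a")
  )
  expect_gt(wang_similarity("L", "M", chain), wang_similarity("L", "R", chain))

  # disjoint roots share no ancestor
  split_dag <- go_dag(
    terms = tibble::tibble(id = c("R1", "R2", "X", "Y"), name = "t",
                           namespace = "biological_process"),
    edges = tibble::tibble(child = c("X", "Y"), parent = c("R1", "R2"),
                           relation = "is_a")
  )
  expect_equal(wang_similarity("X", "Y", split_dag), 0)

  cross <- go_dag(
    terms = tibble::tibble(id = c("B1", "C1"), name = "t",
                           namespace = c("biological_process", "cellular_component")),
    edges = tibble::tibble(child = character(), parent = character(),
                           relation = character())
  )
  expect_warning(s <- wang_similarity("B1", "C1", cross), "namespace")
  expect_equal(s, 0)

  m <- wang_similarity_matrix(c("R", "A", "B"), dag)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(R = 1, A = 1, B = 1))
})

test_that("heatmap matrix groups rows and columns deterministically", {
  res <- tibble::tibble(
    cluster = rep(c("c1", "c2", "c3", "c4"), each = 2),
    term = rep(c("t1", "t2"), 4),
    fdr = c(1e-8, 1, 1e-8, 1, 1, 1e-6, 1, 1e-6)
  )
  hm <- heatmap_matrix(res, k_rows = 2, k_cols = 2, seed = 3)
  expect_equal(dim(hm$matrix), c(4, 2))
  expect_true(all(hm$matrix >= 0 & hm$matrix <= 10))  # -log10 capped at 10
  # identical rows land in the same group; the two blocks separate
  expect_equal(hm$row_groups[["c1"]], hm$row_groups[["c2"]])
  expect_equal(hm$row_groups[["c3"]], hm$row_groups[["c4"]])
  expect_false(hm$row_groups[["c1"]] == hm$row_groups[["c3"]])
  expect_identical(hm, heatmap_matrix(res, k_rows = 2, k_cols = 2, seed = 3))

  one <- heatmap_matrix(res, k_rows = 1, k_cols = 1, seed = 3)
  expect_equal(dplyr::n_distinct(one$row_groups), 1)

  expect_error(heatmap_matrix(res, k_rows = 9, k_cols = 2), "dimension")
  expect_error(heatmap_matrix(res[0, ], 1, 1), "significant")

  p <- ggplot2::autoplot(hm)
  expect_s3_class(p, "ggplot")
  td <- generics::tidy(hm)
  expect_equal(nrow(td), 8)
})
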