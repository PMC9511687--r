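#' Expression matrix with sample metadata
#'
#' Light container pairing a log2-intensity matrix (genes x samples) with a
#' sample sheet. Duplicate gene ids are collapsed by maximum mean intensity
#' (the usual probe-to-gene rule on microarrays).
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param samples Tibble with columns `sample`, `dataset`, `condition`
#'   (`"fermentation"` or `"propagation"`), `timepoint` (hours).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  samples <- as_tibble(samples)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (!all(c("sample", "dataset", "condition", "timepoint") %in% names(samples))) {
    abort("`samples` needs columns sample, dataset, condition, timepoint.")
  }
  if (!setequal(colnames(values), samples$sample)) {
    abort("Every sample column must have a metadata row (and vice versa).")
  }
  if (any(!is.finite(values))) abort("Expression values must all be finite.")
  values <- values[, samples$sample, drop = FALSE]
  if (anyDuplicated(rownames(values))) {
    means <- rowMeans(values)
    keep <- !duplicated(rownames(values)[order(-means)])
    ord <- order(-means)[keep]
    values <- values[sort(ord), , drop = FALSE]
  }
  structure(list(values = values, samples = samples), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$dataset), collapse = ", ")))
  invisible(x)
}

#' Define a pairwise fermentation-vs-propagation comparison
#'
#' @param group_a,group_b Lists `list(condition =, timepoint =)`; `group_a`
#'   is the numerator (fermentation) side, so `log2fc = mean(a) - mean(b)`.
#' @param analysis `"single"` or `"meta"`.
#' @param label Optional label; defaults to `"ferm8h_vs_prop0h"` style.
#' @return A list of class `comparison`.
#' @export
comparison <- function(group_a, group_b, analysis = c("single", "meta"),
                       label = NULL) {
  analysis <- match.arg(analysis)
  if (identical(group_a, group_b)) abort("Comparison groups must differ.")
  label <- label %||% sprintf("%s%gh_vs_%s%gh",
                              substr(group_a$condition, 1, 4), group_a$timepoint,
                              substr(group_b$condition, 1, 4), group_b$timepoint)
  structure(list(label = label, group_a = group_a, group_b = group_b,
                 analysis = analysis), class = "comparison")
}

group_samples <- function(em, group) {
  em$samples |>
    filter(.data$condition == group$condition,
           .data$timepoint == group$timepoint) |>
    dplyr::pull("sample")
}

#' Per-gene differential expression for one pairwise comparison
#'
#' Fits the two-group contrast with limma's empirical-Bayes moderated
#' t-statistic (`method = "moderated_t"`, the standard microarray engine) or
#' a plain per-gene Welch t-test (`method = "welch_t"`). P-values are
#' BH-adjusted within the comparison.
#'
#' @param em An [expression_matrix()].
#' @param cmp A [comparison()].
#' @param method `"moderated_t"` or `"welch_t"`.
#' @return Tibble `gene`, `comparison`, `log2fc`, `p_raw`, `p_adj`,
#'   `direction` (one row per gene). `log2fc` is mean(group_a) -
#'   mean(group_b) in log2 units.
#' @export
fit_pairwise_de <- function(em, cmp, method = c("moderated_t", "welch_t")) {
  method <- match.arg(method)
  sa <- group_samples(em, cmp$group_a)
  sb <- group_samples(em, cmp$group_b)
  if (length(sa) < 2 || length(sb) < 2) {
    abort(sprintf("Invalid design for '%s': both groups need >= 2 replicates (got %d and %d).",
                  cmp$label, length(sa), length(sb)))
  }
  a <- em$values[, sa, drop = FALSE]
  b <- em$values[, sb, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)
  flat <- va == 0 & vb == 0

  if (method == "moderated_t") {
    mat <- cbind(a, b)
    grp <- factor(rep(c("a", "b"), c(ncol(a), ncol(b))), levels = c("b", "a"))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(mat, design))
    p <- fit$p.value[, "grpa"]
  } else {
    na <- ncol(a); nb <- ncol(b)
    se2a <- va / na; se2b <- vb / nb
    tt <- log2fc / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  }
  if (any(flat)) {
    warn(sprintf("%d gene(s) with zero variance in both groups: p set to 1.", sum(flat)))
    p[flat] <- 1
  }
  p[is.na(p)] <- 1
  tibble(
    gene = rownames(em$values),
    comparison = cmp$label,
    log2fc = unname(log2fc),
    p_raw = unname(p),
    p_adj = bh_adjust(unname(p)),
    direction = if_else(log2fc < 0, "down", "up")
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving wrapper around `stats::p.adjust(method = "BH")` with
#' input validation (false discovery rate control under independence).
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  assert_probability(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Threshold DEG records on effect size and FDR
#'
#' Keeps records with `|log2fc| >= lfc_min` and `p_adj < fdr_max` — the
#' selection rule applied to every pairwise contrast.
#'
#' @param records Tibble from [fit_pairwise_de()].
#' @param lfc_min Minimum absolute log2 fold change (default 2.0).
#' @param fdr_max FDR significance level (default 0.05, strict `<`).
#' @return Filtered tibble.
#' @export
filter_degs <- function(records, lfc_min = 2.0, fdr_max = 0.05) {
  if (lfc_min <= 0 || fdr_max <= 0) abort("Thresholds must be positive.")
  filter(records, abs(.data$log2fc) >= lfc_min, .data$p_adj < fdr_max)
}

#' Non-redundant DEG set for one direction
#'
#' Collapses per-comparison significant records to the unique gene set for a
#' direction, also reporting the redundant (record-level) total, mirroring
#' the unique-vs-redundant DEG tallies of a multi-contrast screen.
#'
#' @param records Filtered DEG tibble (one or more comparisons).
#' @param direction `"up"` or `"down"`.
#' @return List with `genes` (unique ids), `n_unique`, `n_redundant`.
#' @export
nonredundant_union <- function(records, direction = c("up", "down")) {
  direction <- match.arg(direction)
  hits <- filter(records, .data$direction == !!direction)
  list(genes = sort(unique(hits$gene)),
       n_unique = dplyr::n_distinct(hits$gene),
       n_redundant = nrow(hits))
}

#' Pan-DEG intersection of single- and meta-analysis
#'
#' A Pan-DEG is a gene significant (after [filter_degs()]) in at least one
#' comparison of each analysis, in the same direction. Its meta-log2FC is
#' the mean of all its significant log2 fold changes across both analyses,
#' with the sample SD (0 for a single value); category labels come from an
#' external gene-to-category map (autophagy / lipid_metabolism /
#' proteostasis), defaulting to "other".
#'
#' @param single_records,meta_records Filtered DEG tibbles per analysis.
#' @param categories Optional tibble `gene`, `category` or named character
#'   vector.
#' @param direction Direction to intersect (`"up"` for the network seeds).
#' @return Tibble `gene`, `category`, `meta_log2fc`, `sd`, `n_contributing`.
#' @export
pan_deg_intersect <- function(single_records, meta_records, categories = NULL,
                              direction = "up") {
  s <- filter(single_records, .data$direction == !!direction)
  m <- filter(meta_records, .data$direction == !!direction)
  common <- intersect(unique(s$gene), unique(m$gene))
  cat_map <- categories_lookup(categories)
  bind_rows(s, m) |>
    filter(.data$gene %in% common) |>
    group_by(.data$gene) |>
    summarise(
      meta_log2fc = mean(.data$log2fc),
      sd = if (n() > 1) stats::sd(.data$log2fc) else 0,
      n_contributing = n(),
      .groups = "drop"
    ) |>
    mutate(category = cat_map(.data$gene)) |>
    select("gene", "category", "meta_log2fc", "sd", "n_contributing") |>
    arrange(dplyr::desc(.data$meta_log2fc))
}

categories_lookup <- function(categories) {
  if (is.null(categories)) return(function(g) rep("other", length(g)))
  if (is.data.frame(categories)) {
    categories <- stats::setNames(categories$category, categories$gene)
  }
  function(g) {
    out <- unname(categories[g])
    out[is.na(out)] <- "other"
    out
  }
}

#' Per-comparison DEG frequency table
#'
#' Tallies significant records by comparison, direction and category — the
#' absolute-frequency table of DEGs per pairwise contrast.
#'
#' @param records Filtered DEG tibble.
#' @param categories Optional gene-to-category map (see
#'   [pan_deg_intersect()]).
#' @return Tibble `comparison`, `direction`, `category`, `n` (zero-row for
#'   empty input).
#' @export
per_comparison_counts <- function(records, categories = NULL) {
  cat_map <- categories_lookup(categories)
  if (nrow(records) == 0) {
    return(tibble(comparison = character(), direction = character(),
                  category = character(), n = integer()))
  }
  records |>
    mutate(category = cat_map(.data$gene)) |>
    count(.data$comparison, .data$direction, .data$category, name = "n") |>
    tidyr::complete(.data$comparison, .data$direction, .data$category,
                    fill = list(n = 0L))
}

#' All fermentation-vs-propagation comparisons in a design
#'
#' @param em An [expression_matrix()].
#' @param analysis Label stored on each comparison.
#' @return List of [comparison()] objects, fermentation x propagation
#'   timepoints.
#' @export
all_comparisons <- function(em, analysis = "single") {
  tps <- function(cond) sort(unique(em$samples$timepoint[em$samples$condition == cond]))
  grid <- tidyr::expand_grid(ferm = tps("fermentation"), prop = tps("propagation"))
  purrr::pmap(grid, function(ferm, prop) {
    comparison(list(condition = "fermentation", timepoint = ferm),
               list(condition = "propagation", timepoint = prop),
               analysis = analysis)
  })
}

#' Combine two datasets for cross-dataset (meta-analysis) contrasts
#'
#' Column-binds two expression matrices on their common genes and puts the
#' arrays on a common scale. The default, median centering, shifts every
#' array to the shared grand median: robust to a realistic fraction of
#' differential genes, it preserves true fold changes even when condition
#' is confounded with dataset (one dataset all fermentation, the other all
#' propagation). Joint quantile normalization (`method = "quantile"`,
#' limma's implementation) is available but attenuates genuine condition
#' effects in exactly that confounded design, because the shared reference
#' distribution mixes shifted and unshifted tails.
#'
#' @param em_a,em_b [expression_matrix()] objects.
#' @param method `"median"` (default) or `"quantile"`.
#' @return A single combined [expression_matrix()].
#' @export
combine_datasets <- function(em_a, em_b, method = c("median", "quantile")) {
  method <- match.arg(method)
  common <- intersect(rownames(em_a$values), rownames(em_b$values))
  if (length(common) == 0) abort("Datasets share no genes.")
  values <- cbind(em_a$values[common, , drop = FALSE],
                  em_b$values[common, , drop = FALSE])
  if (method == "quantile") {
    values <- limma::normalizeQuantiles(values)
  } else {
    meds <- apply(values, 2, stats::median)
    values <- sweep(values, 2, meds) + mean(meds)
  }
  expression_matrix(values, bind_rows(em_a$samples, em_b$samples))
}
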