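#' Simulation configuration with planted ground truth
#'
#' Bundles every knob of the synthetic-data generators: a two-condition
#' multi-timepoint expression design with planted log2 effects and Gaussian
#' noise, a stochastic-block-model (SBM) interactome with per-channel
#' Beta-distributed confidence scores, a small GO DAG with terms planted on
#' SBM blocks, and an optional chemical layer for the chemical-protein
#' network. The defaults describe the study conditions the package is tested
#' under: effect size 3.0 log2 units with noise SD 0.3 and 3 replicates per
#' group, and a 4 x 20 SBM with within-block edge probability 0.5 against
#' 0.01 between blocks.
#'
#' @param n_genes Number of simulated genes.
#' @param design Tibble with columns `condition` (`"fermentation"` or
#'   `"propagation"`), `timepoint` (hours) and `n_replicates`. The default
#'   mirrors an industrial brewing time course: fermentation sampled at
#'   8/30/60 h against propagation at 0/8/30 h.
#' @param planted_degs Named numeric vector of true log2 effects added to
#'   fermentation samples (positive = upregulated during fermentation).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param base_mean Baseline log2 intensity.
#' @param sbm_blocks Integer vector of SBM block sizes; blocks are filled
#'   with the first `sum(sbm_blocks)` genes in order.
#' @param p_in,p_out Within-/between-block edge probabilities.
#' @param channel_model Two-element list (`within`, `between`), each a list
#'   of per-channel `c(shape1, shape2)` Beta parameters for the
#'   `experiments` and `databases` evidence channels.
#' @param n_go_terms Number of background (uniformly annotated) GO terms.
#' @param planted_terms Named integer vector mapping planted term ids to the
#'   SBM block they annotate.
#' @param n_chemicals Number of chemical nodes attached to block-2 proteins
#'   (the synthetic lipid layer) in the chemical-protein table.
#' @param chem_p_attach Attachment probability of a chemical to each
#'   protein of its target block.
#' @param seed Integer seed; identical configs give byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       design = default_design("single"),
                       planted_degs = default_planted_degs(),
                       noise_sd = 0.3,
                       base_mean = 8,
                       sbm_blocks = c(20, 20, 20, 20),
                       p_in = 0.5,
                       p_out = 0.01,
                       channel_model = list(
                         within = list(experiments = c(8, 2), databases = c(6, 3)),
                         between = list(experiments = c(2, 8), databases = c(1.5, 8))
                       ),
                       n_go_terms = 30,
                       planted_terms = c(T_AUTO = 1L, T_LIPID = 2L,
                                         T_PROTEO = 3L, T_MITO = 4L),
                       n_chemicals = 6,
                       chem_p_attach = 0.3,
                       seed = 20220916) {
  assert_probability(c(p_in, p_out), "p_in/p_out")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (sum(sbm_blocks) > n_genes) {
    abort("SBM block sizes must sum to at most `n_genes`.")
  }
  design <- as_tibble(design)
  stopifnot(all(c("condition", "timepoint", "n_replicates") %in% names(design)))
  if (length(planted_terms) && any(planted_terms > length(sbm_blocks))) {
    abort("`planted_terms` references a block beyond `sbm_blocks`.")
  }
  structure(
    list(n_genes = n_genes, design = design, planted_degs = planted_degs,
         noise_sd = noise_sd, base_mean = base_mean, sbm_blocks = sbm_blocks,
         p_in = p_in, p_out = p_out, channel_model = channel_model,
         n_go_terms = n_go_terms, planted_terms = planted_terms,
         n_chemicals = n_chemicals, chem_p_attach = chem_p_attach,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param analysis `"single"` (one dataset, fermentation 8/30/60 h vs
#'   propagation 0/8/30 h) or `"meta"` (one fermentation time-course dataset
#'   crossed with one propagation dataset).
#' @export
default_design <- function(analysis = c("single", "meta")) {
  analysis <- match.arg(analysis)
  if (analysis == "single") {
    tibble(
      dataset = "DS1",
      condition = rep(c("fermentation", "propagation"), each = 3),
      timepoint = c(8, 30, 60, 0, 8, 30),
      n_replicates = 3L
    )
  } else {
    bind_rows(
      tibble(dataset = "DS2", condition = "fermentation",
             timepoint = c(8, 30, 60, 80, 102), n_replicates = 3L),
      tibble(dataset = "DS3", condition = "propagation",
             timepoint = c(0, 4, 8, 30), n_replicates = 3L)
    )
  }
}

#' @rdname sim_config
#' @export
default_planted_degs <- function() {
  # all SBM member genes planted up (they seed the network stage);
  # a handful of extra up genes outside the interactome emulate seeds that
  # cannot be mapped, and a few down genes exercise direction handling
  up_block <- stats::setNames(rep(3, 80), gene_ids(80))
  up_unmapped <- stats::setNames(rep(3, 5), sprintf("G%04d", 81:85))
  down <- stats::setNames(rep(-3, 5), sprintf("G%04d", 91:95))
  c(up_block, up_unmapped, down)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Planted truth accessor
#'
#' Assembles the ground-truth record for a configuration: true DEG sets per
#' direction, the gene-to-block partition over interactome nodes, and the
#' planted enriched terms.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(config) {
  eff <- config$planted_degs
  blocks <- rep(seq_along(config$sbm_blocks), config$sbm_blocks)
  nodes <- gene_ids(sum(config$sbm_blocks))
  structure(
    list(
      true_deg_set = list(up = names(eff)[eff > 0], down = names(eff)[eff < 0]),
      true_partition = stats::setNames(blocks, nodes),
      true_enriched_terms = names(config$planted_terms),
      seed = config$seed
    ),
    class = "synthetic_truth"
  )
}

#' Simulate a log2 expression matrix with planted effects
#'
#' Draws i.i.d. Gaussian log2 intensities around `base_mean`, adding each
#' planted effect to every fermentation sample of its gene (microarray
#' convention: additive effects and noise on the log2 scale).
#'
#' @param config A [sim_config()].
#' @param design Optional design tibble overriding `config$design`.
#' @param seed Optional seed overriding `config$seed` (used by the pipeline
#'   to give each simulated dataset its own stream).
#' @return A list with `expr` (an [expression_matrix()]) and `truth`
#'   (a [synthetic_truth()]).
#' @export
simulate_expression <- function(config, design = NULL, seed = NULL) {
  design <- as_tibble(design %||% config$design)
  if (!"dataset" %in% names(design)) design$dataset <- "DS1"
  if (nrow(design) < 2 || any(design$n_replicates < 2)) {
    abort("Invalid design: need >= 2 groups with >= 2 replicates each.")
  }
  genes <- gene_ids(config$n_genes)
  samples <- design |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::uncount(.data$n_replicates, .id = "replicate") |>
    mutate(sample = sprintf("%s_%s_%gh_r%d", .data$dataset,
                            substr(.data$condition, 1, 4),
                            .data$timepoint, .data$replicate)) |>
    select("sample", "dataset", "condition", "timepoint")

  eff <- stats::setNames(rep(0, length(genes)), genes)
  planted <- intersect(names(config$planted_degs), genes)
  eff[planted] <- config$planted_degs[planted]

  values <- with_seed(seed %||% config$seed, {
    m <- matrix(
      stats::rnorm(length(genes) * nrow(samples), config$base_mean, config$noise_sd),
      nrow = length(genes), dimnames = list(genes, samples$sample)
    )
    ferm <- samples$condition == "fermentation"
    m[, ferm] <- m[, ferm] + eff
    m
  })
  list(expr = expression_matrix(values, samples), truth = synthetic_truth(config))
}

#' Simulate a STRING-like interactome with block structure
#'
#' Draws a stochastic block model over the first `sum(sbm_blocks)` genes and
#' attaches Beta-distributed `experiments` / `databases` channel scores:
#' high-mode within blocks, low-mode between. Scores are emitted on the
#' 0-1000 integer grid of STRING's `protein.links.detailed` dialect.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return A list with `links` (tibble `protein1`, `protein2`,
#'   `experiments`, `databases` with integer scores) and `truth`.
#' @export
simulate_interactome <- function(config, seed = NULL) {
  assert_probability(c(config$p_in, config$p_out), "p_in/p_out")
  truth <- synthetic_truth(config)
  part <- truth$true_partition
  nodes <- names(part)
  pairs <- utils::combn(nodes, 2)
  same <- part[pairs[1, ]] == part[pairs[2, ]]
  links <- with_seed(seed %||% config$seed, {
    p <- ifelse(same, config$p_in, config$p_out)
    keep <- stats::runif(length(p)) < p
    cm <- config$channel_model
    draw <- function(n, within, ch) {
      par <- if (within) cm$within[[ch]] else cm$between[[ch]]
      as.integer(round(1000 * stats::rbeta(n, par[1], par[2])))
    }
    w <- same[keep]
    tibble(
      protein1 = pairs[1, keep],
      protein2 = pairs[2, keep],
      experiments = ifelse(w, draw(sum(keep), TRUE, "experiments"),
                           draw(sum(keep), FALSE, "experiments")),
      databases = ifelse(w, draw(sum(keep), TRUE, "databases"),
                         draw(sum(keep), FALSE, "databases"))
    )
  })
  list(links = links, truth = truth)
}

#' Simulate a STITCH-like chemical-protein link table
#'
#' Adds `n_chemicals` chemical nodes (ids `CIDm...`), each attached with
#' probability `chem_p_attach` to the proteins of block 2 (the synthetic
#' lipid-metabolism block), with within-block-like channel scores.
#'
#' @param config A [sim_config()].
#' @param block Target block index for chemical attachment.
#' @param seed Optional seed override.
#' @return A tibble `chemical`, `protein`, `experiments`, `databases`.
#' @export
simulate_cpi_links <- function(config, block = 2L, seed = NULL) {
  part <- synthetic_truth(config)$true_partition
  targets <- names(part)[part == block]
  chems <- sprintf("CIDm%08d", seq_len(config$n_chemicals))
  with_seed(seed %||% (config$seed + 7L), {
    grid <- tidyr::expand_grid(chemical = chems, protein = targets)
    grid <- grid[stats::runif(nrow(grid)) < config$chem_p_attach, ]
    cm <- config$channel_model$within
    grid |>
      mutate(
        experiments = as.integer(round(1000 * stats::rbeta(n(), cm$experiments[1], cm$experiments[2]))),
        databases = as.integer(round(1000 * stats::rbeta(n(), cm$databases[1], cm$databases[2])))
      )
  })
}

#' Simulate a GO DAG and annotation table with planted enrichment
#'
#' Builds one rooted DAG per namespace (biological process and cellular
#' component) with a layer of mid-level terms and `n_go_terms` background
#' leaves annotated uniformly at random. Each planted term annotates 90% of
#' its SBM block's genes and each other gene with probability 0.02, so a
#' community recovering the block is strongly enriched for the term.
#'
#' @param config A [sim_config()].
#' @param truth A [synthetic_truth()]; defaults to `synthetic_truth(config)`.
#' @param seed Optional seed override.
#' @return A list with `dag` (a [go_dag()]) and `annotations`
#'   (tibble `gene`, `term` of direct annotations).
#' @export
simulate_go <- function(config, truth = synthetic_truth(config), seed = NULL) {
  genes <- gene_ids(config$n_genes)
  n_bg <- config$n_go_terms
  roots <- tibble(
    id = c("BP:ROOT", "CC:ROOT"),
    name = c("biological process root", "cellular component root"),
    namespace = c("biological_process", "cellular_component")
  )
  mids <- tibble(
    id = sprintf("BP:MID%d", 1:3),
    name = sprintf("process group %d", 1:3),
    namespace = "biological_process"
  )
  bg <- tibble(
    id = sprintf("BP:BG%03d", seq_len(n_bg)),
    name = sprintf("background process %d", seq_len(n_bg)),
    namespace = "biological_process"
  )
  planted <- tibble(
    id = names(config$planted_terms),
    name = sprintf("planted process for block %d", config$planted_terms),
    namespace = "biological_process"
  )
  cc <- tibble(
    id = sprintf("CC:BG%03d", 1:5),
    name = sprintf("background component %d", 1:5),
    namespace = "cellular_component"
  )
  terms <- bind_rows(roots, mids, planted, bg, cc)
  edges <- with_seed(seed %||% (config$seed + 13L), {
    bind_rows(
      tibble(child = mids$id, parent = "BP:ROOT", relation = "is_a"),
      tibble(child = planted$id,
             parent = sample(mids$id, nrow(planted), replace = TRUE),
             relation = "is_a"),
      tibble(child = bg$id,
             parent = sample(mids$id, n_bg, replace = TRUE),
             relation = sample(c("is_a", "part_of"), n_bg,
                               replace = TRUE, prob = c(0.8, 0.2))),
      tibble(child = cc$id, parent = "CC:ROOT", relation = "is_a")
    )
  })
  dag <- go_dag(terms, edges)
  ann <- with_seed(seed %||% (config$seed + 17L), {
    part <- truth$true_partition
    planted_ann <- purrr::imap(config$planted_terms, function(block, term) {
      members <- names(part)[part == block]
      inside <- sample(members, ceiling(0.9 * length(members)))
      others <- setdiff(genes, members)
      n_out <- min(stats::rbinom(1, length(others), 0.02),
                   floor(0.05 * length(others)))
      outside <- sample(others, n_out)
      tibble(gene = c(inside, outside), term = term)
    })
    background_ann <- purrr::map(genes, function(g) {
      k <- sample(2:4, 1)
      tibble(gene = g, term = c(sample(bg$id, k), sample(cc$id, 1)))
    })
    bind_rows(c(unname(planted_ann), background_ann)) |> distinct()
  })
  list(dag = dag, annotations = ann)
}

#' Simulate a proteome overlay correlated with a transcriptome vector
#'
#' Emulates a lipid-droplet proteome table: log-ratios for a subset of
#' genes, drawn bivariate-normally so their Pearson correlation with a
#' supplied transcriptome vector is `rho` in expectation (exact when
#' `rho = 1`).
#'
#' @param genes Character vector of gene ids to sample from.
#' @param transcriptome Optional named numeric vector (e.g. meta-log2FC);
#'   defaults to standard-normal draws.
#' @param rho Target Pearson correlation in \[-1, 1\].
#' @param subset_frac Fraction of `genes` receiving a proteome value.
#' @param seed Integer seed.
#' @return A tibble `gene`, `log_ratio`.
#' @export
simulate_proteome_overlay <- function(genes, transcriptome = NULL, rho = 0.7,
                                      subset_frac = 1, seed = 1) {
  if (length(genes) == 0) abort("`genes` must be non-empty.")
  assert_probability(abs(rho), "abs(rho)")
  with_seed(seed, {
    keep <- sort(sample(seq_along(genes), max(1, round(subset_frac * length(genes)))))
    g <- genes[keep]
    x <- if (is.null(transcriptome)) {
      stats::rnorm(length(g))
    } else {
      as.numeric(transcriptome[g])
    }
    x[is.na(x)] <- 0
    xs <- if (stats::sd(x) > 0) as.numeric(scale(x)) else x * 0
    y <- rho * xs + sqrt(max(0, 1 - rho^2)) * stats::rnorm(length(g))
    tibble(gene = g, log_ratio = y)
  })
}
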