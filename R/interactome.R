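#' Parse a STRING/STITCH-style detailed links table
#'
#' Reads the whitespace-delimited `protein.links.detailed` dialect
#' (`protein1 protein2 <channels...>`; STITCH variant: `chemical protein
#' <channels...>`), scales the 0-1000 integer channel scores to \[0, 1\],
#' canonicalizes node order and collapses reversed duplicate pairs keeping
#' the per-channel maximum.
#'
#' @param path File path (plain text, whitespace-delimited, with header).
#' @param dialect `"string_detailed"` or `"stitch_detailed"`.
#' @param channels Channel columns that must be present.
#' @return Tibble `node_a`, `node_b` (with `node_a < node_b`) plus one
#'   column per channel, scores in \[0, 1\].
#' @export
parse_links <- function(path, dialect = c("string_detailed", "stitch_detailed"),
                        channels = c("experiments", "databases")) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_channel_edges(df, dialect = dialect, channels = channels)
}

#' @rdname parse_links
#' @param df Data frame already holding the link-table columns (integer
#'   scores on the 0-1000 grid).
#' @export
as_channel_edges <- function(df, dialect = c("string_detailed", "stitch_detailed"),
                             channels = c("experiments", "databases")) {
  dialect <- match.arg(dialect)
  id_cols <- if (dialect == "string_detailed") c("protein1", "protein2") else c("chemical", "protein")
  missing_id <- setdiff(id_cols, names(df))
  if (length(missing_id)) {
    abort(sprintf("Format error: missing identifier column(s) %s.",
                  paste(missing_id, collapse = ", ")))
  }
  missing_ch <- setdiff(channels, names(df))
  if (length(missing_ch)) {
    abort(sprintf("Format error: header lacks channel column(s) %s.",
                  paste(missing_ch, collapse = ", ")))
  }
  for (ch in channels) {
    v <- df[[ch]]
    bad <- which(!is.finite(v) | v != round(v) | v < 0 | v > 1000)
    if (length(bad)) {
      abort(sprintf("Parse error: non-integer or out-of-range score in column '%s' at line %d.",
                    ch, bad[1] + 1L))
    }
  }
  a <- as.character(df[[id_cols[1]]])
  b <- as.character(df[[id_cols[2]]])
  if (any(a == b)) abort("Self-interactions are not allowed in a link table.")
  out <- tibble(node_a = pmin(a, b), node_b = pmax(a, b))
  for (ch in channels) out[[ch]] <- df[[ch]] / 1000
  out |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(across(all_of(channels), max), .groups = "drop")
}

#' Write channel edges back to the STRING-like dialect
#'
#' @param edges Tibble from [parse_links()]/[as_channel_edges()].
#' @param path Output path (space-delimited text with header).
#' @param dialect Output dialect (controls the identifier column names).
#' @export
write_links <- function(edges, path,
                        dialect = c("string_detailed", "stitch_detailed")) {
  dialect <- match.arg(dialect)
  id_cols <- if (dialect == "string_detailed") c("protein1", "protein2") else c("chemical", "protein")
  channels <- setdiff(names(edges), c("node_a", "node_b"))
  out <- edges
  for (ch in channels) out[[ch]] <- as.integer(round(1000 * out[[ch]]))
  names(out)[1:2] <- id_cols
  utils::write.table(out, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

#' Probabilistic combination of evidence channel scores
#'
#' Combines the `experiments` and `databases` confidence channels into one
#' score with the prior-corrected noisy-OR used for STRING combined scores:
#' each channel score is corrected for the random-expectation prior `p`
#' (`s' = max(0, (s - p) / (1 - p))`), the corrected scores are combined as
#' `S' = 1 - prod(1 - s')`, and the prior is restored
#' (`S = S' (1 - p) + p`). A single channel therefore passes through
#' unchanged (when above the prior), and the combined score is monotone
#' non-decreasing in every channel.
#'
#' @param edges Channel-edge tibble (see [as_channel_edges()]).
#' @param channels Channels entering the combination; a requested channel
#'   absent from `edges` contributes score 0.
#' @param prior Prior probability of a true interaction (STRING's published
#'   value 0.041 by default).
#' @return Tibble `node_a`, `node_b`, `combined`.
#' @export
combine_scores <- function(edges, channels = c("experiments", "databases"),
                           prior = 0.041) {
  if (!is.numeric(prior) || prior < 0 || prior >= 1) {
    abort("`prior` must lie in [0, 1).")
  }
  corrected <- purrr::map(channels, function(ch) {
    s <- if (ch %in% names(edges)) edges[[ch]] else rep(0, nrow(edges))
    assert_probability(s, ch)
    pmax(0, (s - prior) / (1 - prior))
  })
  one_minus <- purrr::reduce(purrr::map(corrected, function(s) 1 - s), `*`,
                             .init = rep(1, nrow(edges)))
  tibble(node_a = edges$node_a, node_b = edges$node_b,
         combined = (1 - one_minus) * (1 - prior) + prior)
}

#' Keep edges at or above a combined-score cutoff
#'
#' @param edges Scored-edge tibble from [combine_scores()].
#' @param min_combined Cutoff in \[0, 1\]; 0 keeps everything.
#' @return Filtered tibble.
#' @export
threshold_edges <- function(edges, min_combined = 0) {
  assert_probability(min_combined, "min_combined")
  filter(edges, .data$combined >= min_combined)
}
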