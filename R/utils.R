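#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct left_join bind_rows count n rename if_else across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_int pmap walk imap
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# single RNG discipline: every stochastic entry point takes a seed and
# restores the caller's RNG state on exit
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# deterministic per-stage sub-seed, kept well inside 32-bit range
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1013L) %% 2147483647L
}

assert_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovered community structure against a planted partition.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("Labelings must have equal length.")
  if (length(a) == 0) return(NaN)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
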