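# broom-style tidiers for the package's result objects.

#' Tidy a chi-squared test result
#'
#' @param x A `chi2_test` object ([chi2_2x2()]).
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `sided`.
#' @export
tidy.chi2_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = 1L, p_value = x$p_value, sided = x$sided)
}

#' Tidy a hypergeometric overlap result
#'
#' @param x An `overlap_result` object ([hypergeom_overlap()]).
#' @param ... Unused.
#' @return One-row tibble with the parameters, overlap fraction and p-value.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(k = x$k, K = x$K, n = x$n, N = x$N,
         fraction_of_set1 = x$fraction_of_set1,
         p_value = x$p_value, alternative = x$alternative)
}

#' @rdname tidy.overlap_result
#' @export
glance.overlap_result <- function(x, ...) tidy(x, ...)

#' Tidy a concordance table
#'
#' @param x A `concordance_result` object ([concordance_table()]).
#' @param ... Unused.
#' @return Tibble with one row per CHD7 stratum: counts and concordant
#'   fraction.
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble(chd7_bound = c(TRUE, FALSE),
         concordant = x$table[, 1], discordant = x$table[, 2],
         fraction_concordant = unname(x$fractions))
}

#' One-row summary of a concordance table
#'
#' Counts plus the one-sided chi-squared test comparing strata.
#'
#' @param x A `concordance_result` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.concordance_result <- function(x, ...) {
  test <- chi2_2x2(x, sided = "one")
  tibble(n_pairs = sum(x$table),
         fraction_bound = unname(x$fractions[1]),
         fraction_unbound = unname(x$fractions[2]),
         statistic = test$statistic, p_value = test$p_value)
}

#' Tidy a vertical:horizontal ratio result
#'
#' @param x A `vh_ratio` object ([vh_ratio()]).
#' @param ... Unused.
#' @return One-row tibble with pooled and per-animal summaries.
#' @export
tidy.vh_ratio <- function(x, ...) {
  tibble(pooled_ratio = x$pooled_ratio, mean_ratio = x$mean_ratio,
         sem_ratio = x$sem_ratio, n_vertical = x$n_vertical,
         n_horizontal = x$n_horizontal, n_events = x$n_events,
         n_animals = nrow(x$per_animal))
}
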