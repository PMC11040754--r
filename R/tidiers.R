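# broom-style tidy()/glance() methods for the package's fitted/test
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation distance test
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, null summary
#'   and both tail p-values.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = mean(x$null),
         null_sd = sd(x$null), p_closer = x$p_closer,
         p_farther = x$p_farther, n_query = x$n_query,
         n_perm = x$n_perm)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x)

#' Tidy an adjacent-homolog spacing test
#'
#' @param x A `spacing_test` object.
#' @param ... Unused.
#' @return Tibble of histogram bins with observed counts and null
#'   proportions.
#' @export
tidy.spacing_test <- function(x, ...) {
  tibble(bin = seq_along(x$observed), observed = x$observed,
         null_prop = x$null_prop)
}

#' @rdname tidy.spacing_test
#' @export
glance.spacing_test <- function(x, ...) {
  tibble(statistic = x$statistic, p = x$p, n_pairs = x$n_pairs,
         n_rand = x$n_rand)
}

#' Tidy LTR-gene distance statistics
#'
#' @param x An `ltr_distance_stats` object.
#' @param ... Unused.
#' @return The per-superfamily statistics tibble.
#' @export
tidy.ltr_distance_stats <- function(x, ...) x$stats

#' @rdname tidy.ltr_distance_stats
#' @export
glance.ltr_distance_stats <- function(x, ...) {
  tibble(n_superfamilies = nrow(x$stats),
         n_elements = sum(x$stats$n))
}
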