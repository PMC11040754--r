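# ggplot2 figures for the main result types.

#' Plot the pan/core rarefaction curve
#'
#' Mean pan-gene and core-gene counts by panel size with their 99%
#' sampling intervals as ribbons.
#'
#' @param curve Tibble from [pan_core_curve()].
#' @return A ggplot object.
#' @export
plot_pan_core_curve <- function(curve) {
  long <- bind_rows(
    tibble(size = curve$size, set = "pan", mean = curve$pan_mean,
           lo = curve$pan_lo, hi = curve$pan_hi),
    tibble(size = curve$size, set = "core", mean = curve$core_mean,
           lo = curve$core_lo, hi = curve$core_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$mean,
                                     colour = .data$set,
                                     fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Accessions sampled", y = "Gene count",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of the group-frequency scan
#'
#' @param scan Tibble from [frequency_change_scan()].
#' @param fdr FDR line to draw.
#' @return A ggplot object.
#' @export
plot_frequency_scan <- function(scan, fdr = 0.001) {
  ggplot2::ggplot(scan,
                  ggplot2::aes(x = log2(.data$fold_change),
                               y = -log10(pmax(.data$q, 1e-300)),
                               colour = .data$verdict)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(favorable = "#d95f02",
                                            unfavorable = "#7570b3",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (focal / other)",
                  y = "-log10 FDR-adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of LTR insertion ages by superfamily
#'
#' @param ages Tibble from [date_ltr()] joined with a `superfamily`
#'   column (e.g. from the element table).
#' @param binwidth Bin width in Myr.
#' @return A ggplot object.
#' @export
plot_ltr_ages <- function(ages, binwidth = 0.25) {
  stopifnot("T_years" %in% names(ages))
  if (!"superfamily" %in% names(ages)) ages$superfamily <- "all"
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$T_years / 1e6,
                                     fill = .data$superfamily)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::labs(x = "Insertion age (Myr)", y = "Elements",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a permutation distance test
#'
#' Null distribution of mean distances with the observed value marked.
#'
#' @param object A `perm_test` from [distance_permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed,
                        colour = "#d95f02", linewidth = 1) +
    ggplot2::labs(x = "Null mean distance (bp)", y = "Permutations",
                  subtitle = sprintf("observed = %.0f bp; p(closer) = %.3g",
                                     object$observed, object$p_closer)) +
    ggplot2::theme_minimal()
}
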