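#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a plateau analysis
#'
#' One row per combination size: number of combinations, mean and SD of
#' their mean bootstrap supports.
#'
#' @param x A `plateau_analysis`.
#' @param ... Unused.
#' @return A tibble: `k`, `n`, `mean_bs`, `sd_bs`.
#' @method tidy plateau_analysis
#' @export
tidy.plateau_analysis <- function(x, ...) {
  x$per_k
}

#' One-row summary of a plateau analysis
#'
#' @param x A `plateau_analysis`.
#' @param ... Unused.
#' @return A tibble: `slope`, `intercept`, `r_squared`, `plateau_k`,
#'   `plateau_mean_bs`, `n_combinations`.
#' @method glance plateau_analysis
#' @export
glance.plateau_analysis <- function(x, ...) {
  tibble::tibble(
    slope = x$fit$slope,
    intercept = x$fit$intercept,
    r_squared = x$fit$r_squared,
    plateau_k = x$plateau_k,
    plateau_mean_bs = x$per_k$mean_bs[x$per_k$k == x$plateau_k],
    n_combinations = x$n_combinations
  )
}

#' Plot mean BS against combination size
#'
#' Mean with one-SD error bars per combination size, overlaid with the
#' fitted regression line.
#'
#' @param object A `plateau_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plateau_analysis
#' @export
autoplot.plateau_analysis <- function(object, ...) {
  per_k <- object$per_k
  ggplot2::ggplot(per_k, ggplot2::aes(x = .data$k, y = .data$mean_bs)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_bs - .data$sd_bs,
                   ymax = .data$mean_bs + .data$sd_bs),
      width = 0.15, color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$fit$slope,
                         intercept = object$fit$intercept,
                         linetype = "dashed", color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$plateau_k, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = per_k$k) +
    ggplot2::labs(x = "hotspots combined", y = "mean bootstrap support (%)") +
    ggplot2::theme_minimal()
}

#' Plot per-locus sequence variability and GC content
#'
#' Loci in rank order, SV as bars, GC content as a line on a secondary
#' axis-free overlay; the tracked top loci are highlighted.
#'
#' @param sv_table Tibble from [mean_sv_table()].
#' @param top Number of top loci to highlight (default 10).
#' @return A ggplot.
#' @export
plot_sv_ranks <- function(sv_table, top = 10) {
  df <- dplyr::mutate(sv_table,
                      locus = factor(.data$locus, levels = .data$locus),
                      hotspot = .data$rank <= top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_sv, fill = .data$hotspot)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$gc_percent, group = 1),
                       color = "darkgreen") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "mean SV (%) / GC (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot per-taxon InDel counts by region
#'
#' Stacked bars of InDel event counts in LSC, SSC and IR per taxon.
#'
#' @param profiles Tibble from [indel_profile()].
#' @return A ggplot.
#' @export
plot_indel_profile <- function(profiles) {
  long <- profiles |>
    dplyr::select("taxon_id", LSC = "n_lsc", SSC = "n_ssc", IR = "n_ir") |>
    tidyr::pivot_longer(-"taxon_id", names_to = "region", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_id, y = .data$n,
                                     fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "InDel events") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
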