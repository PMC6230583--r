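#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot discriminant coordinates of a structure result
#'
#' @param object a `bs_structure` from [dapc_cluster()].
#' @param ... unused.
#' @return A ggplot: lines on the first two discriminant axes, coloured by
#'   subpopulation.
#' @export
autoplot.bs_structure <- function(object, ...) {
  df <- dplyr::left_join(object$coords, object$assignment, by = "line_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$LD1, .data$LD2, colour = .data$subpop)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Linear discriminant 1", y = "Linear discriminant 2",
                  colour = "Subpopulation",
                  title = sprintf("DAPC, K = %d", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot gene diversity by cohort
#'
#' @param object a `bs_diversity` from [diversity_by_cohort()].
#' @param ... unused.
#' @return A ggplot of pi per decade with the bootstrap CI ribbon.
#' @export
autoplot.bs_diversity <- function(object, ...) {
  df <- dplyr::mutate(object, cohort = factor(.data$cohort,
                                              levels = unique(.data$cohort)))
  ggplot2::ggplot(df, ggplot2::aes(as.integer(.data$cohort), .data$pi)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(df)),
                                labels = as.character(df$cohort)) +
    ggplot2::labs(x = "Cohort", y = expression(pi)) +
    ggplot2::theme_minimal()
}

#' Plot allele-frequency trajectories
#'
#' @param object a `bs_traj` from [cohort_frequencies()].
#' @param ... unused.
#' @return A ggplot of reference-allele frequency per cohort, one line per
#'   marker.
#' @export
autoplot.bs_traj <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(as.integer(.data$cohort), .data$freq_ref,
                                       group = .data$marker_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = seq_along(levels(object$cohort)),
                                labels = levels(object$cohort)) +
    ggplot2::labs(x = "Cohort", y = "Reference-allele frequency") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a selection scan
#'
#' @param scan a scan result tibble (from [fdist_scan()], [hier_scan()] or
#'   [bayes_scan()]).
#' @param map marker map tibble.
#' @return A ggplot of per-locus theta along the map, flagged outliers
#'   highlighted.
#' @export
plot_scan <- function(scan, map) {
  fcol <- grep("^flag", names(scan), value = TRUE)[1]
  df <- dplyr::inner_join(scan, map, by = "marker_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_cM, .data$theta,
                                   colour = .data[[fcol]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red")) +
    ggplot2::labs(x = "Position (cM)", y = expression(F[ST]), colour = "Outlier") +
    ggplot2::theme_minimal()
}

#' Q-Q plot data/plot for an association scan
#'
#' @param assoc a `bs_assoc` from [mlm_scan()].
#' @return A ggplot of observed vs expected -log10 p per trait.
#' @export
plot_qq <- function(assoc) {
  df <- dplyr::group_by(assoc, .data$trait) |>
    dplyr::arrange(.data$p_value, .by_group = TRUE) |>
    dplyr::mutate(expected = -log10(stats::ppoints(dplyr::n())),
                  observed = -log10(.data$p_value)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
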