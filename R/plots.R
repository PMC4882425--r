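#' Plot a sliding-window skew profile
#'
#' G-C and A-T per window along the sequence; a deep G-C trough marks the
#' C-rich CTD repeat span.
#'
#' @param object A [skew_windows()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctd_skew_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("G_minus_C", "A_minus_T"),
                              names_to = "statistic", values_to = "value")
  long$statistic <- sub("_minus_", " - ", long$statistic)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start + (.data$end - .data$start) / 2,
                                     y = .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window midpoint (bp)", y = "count difference per window",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a repeat-architecture alignment as a block diagram
#'
#' One row per strain, one tile per unit column; tiles are coloured by
#' best-match unit, SNP-bearing units are outlined, and gaps are blank --
#' the unit-level view of whole-repeat gains and losses.
#'
#' @param alignment A [align_architectures()] result.
#' @return A ggplot object.
#' @export
plot_architecture <- function(alignment) {
  m <- alignment$matches
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m, .name_repair = ~ sprintf("c%02d", seq_along(.x))),
                  strain = alignment$strains),
    -"strain", names_to = "column", values_to = "unit")
  df$column <- as.integer(sub("^c", "", df$column))
  snp_cols <- dplyr::filter(alignment$events, .data$kind == "snp")
  df$has_snp <- paste(df$strain, df$column) %in%
    paste(snp_cols$strain, snp_cols$column)
  df <- dplyr::filter(df, !is.na(.data$unit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column,
                                   y = factor(.data$strain,
                                              levels = rev(alignment$strains)),
                                   fill = .data$unit)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$has_snp),
                       linewidth = 0.4, width = 0.92, height = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey85",
                                            `TRUE` = "orange"),
                                 guide = "none") +
    ggplot2::labs(x = "unit column", y = NULL, fill = "unit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot mutation-rate estimates with confidence intervals
#'
#' @param estimates A list of [estimate_rate()] results (or a single one).
#' @param scale Rate multiplier for display (default `1e6`, so the axis reads
#'   in units of 1e-6 per cell per generation).
#' @return A ggplot object.
#' @export
plot_rate_estimates <- function(estimates, scale = 1e6) {
  if (inherits(estimates, "ld_rate_estimate")) estimates <- list(estimates)
  df <- dplyr::bind_rows(purrr::map(estimates, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$rate * scale)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low * scale,
                                          ymax = .data$ci_high * scale)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL,
                  y = sprintf("rate (x 1e-%d per cell per generation)",
                              round(log10(scale)))) +
    ggplot2::theme_minimal()
}
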