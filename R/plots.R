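# ggplot2 displays for the main result types.

#' Length spectrum of a callset
#'
#' @param records An SV callset tibble.
#' @param bins Number of histogram bins on the log10 length axis.
#' @return A ggplot object: per-svtype log10 length histograms.
#' @export
plot_length_spectrum <- function(records, bins = 60) {
  validate_sv_records(records)
  ggplot2::ggplot(records[!is.na(records$svlen), ],
                  ggplot2::aes(x = .data$svlen, fill = .data$svtype)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8,
                            position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~svtype, scales = "free_y") +
    ggplot2::labs(x = "SV length (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dimorphic-repeat census barplot
#'
#' @param census Output of [repeat_census()].
#' @return A ggplot object: counts per repeat split by DEL/INS.
#' @export
plot_repeat_census <- function(census) {
  key <- intersect(c("repeat_name", "family"), names(census))[1L]
  ggplot2::ggplot(census, ggplot2::aes(x = .data[[key]], y = .data$n,
                                       fill = .data$svtype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "SVs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Intact-element census stacked barplot
#'
#' @param census Output of [intact_census()].
#' @return A ggplot object: per-sample intact elements, deletion side
#'   stacked over insertion side.
#' @export
plot_intact_census <- function(census) {
  long <- tidyr::pivot_longer(census, c("n_del", "n_ins"),
                              names_to = "side", values_to = "n")
  long$side <- ifelse(long$side == "n_del", "deletion", "insertion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$n,
                                     fill = .data$side)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(deletion = "#c0392b",
                                          insertion = "#2980b9")) +
    ggplot2::labs(x = NULL, y = "intact elements", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Selection-scan p-value plot
#'
#' @param x An `sv_scan` object.
#' @return A ggplot object: -log10 p per site and component with the
#'   strict and relaxed thresholds drawn.
#' @export
plot_scan <- function(x) {
  stopifnot(inherits(x, "sv_scan"))
  df <- x$results
  df$idx <- match(df$site, unique(df$site))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx,
                                   y = -log10(.data$p_value),
                                   colour = factor(.data$component))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(x$strict_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(x$relaxed_threshold),
                        linetype = "dotted") +
    ggplot2::labs(x = "site", y = expression(-log[10](p)),
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' Per-population allele-frequency profile of one site
#'
#' @param profiles Output of [allele_frequency_profiles()].
#' @param site Site identifier to display.
#' @return A ggplot object.
#' @export
plot_af_profile <- function(profiles, site) {
  df <- profiles[profiles$site == site, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = .data$alt_freq)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "alternate allele frequency",
                  title = site) +
    ggplot2::theme_minimal()
}
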