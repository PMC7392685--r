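# ggplot2 visualisations for the main result types.

#' Plot the cumulative codon-by-codon substitution profile
#'
#' @param object A profile from [cumulative_dnds_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mhc_dnds_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("cum_syn", "cum_nonsyn"),
                              names_to = "class", values_to = "cumulative")
  long$class <- ifelse(long$class == "cum_syn", "synonymous",
                       "nonsynonymous")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$cumulative,
                                     colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "codon", y = "cumulative mean substitutions",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of top-two read ratios with calling thresholds
#'
#' Shows where individuals fall relative to the homozygote (default 0.10)
#' and heterozygote (default 0.35) bands.
#'
#' @param calls Call tibble from [call_genotypes()].
#' @param homo,het_low Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_read_ratios <- function(calls, homo = 0.10, het_low = 0.35) {
  df <- calls[is.finite(calls$top2_ratio), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$top2_ratio,
                                   fill = .data$status)) +
    ggplot2::geom_histogram(binwidth = 0.01, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(homo, het_low), linetype = 2) +
    ggplot2::facet_wrap(~locus) +
    ggplot2::labs(x = "second / (first + second) read share", y = "individuals",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Allele frequency bar chart per cohort
#'
#' @param freq Allele-frequency tibble from [frequencies()] (`$alleles`).
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = stats::reorder(.data$allele,
                                                        -.data$frequency),
                                     y = .data$frequency,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~locus, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "allele frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
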