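# ggplot2 views of the survey summaries.  Cosmetic layers only; every
# number plotted comes from the corresponding stats function.

#' Bubble chart of intron insertion positions
#'
#' @param survey Survey tibble ([build_survey()]).
#' @return A ggplot object (site on x, phylum on y, bubble size = count,
#'   colour = amino acid).
#' @export
plot_position_matrix <- function(survey) {
  position_matrix(survey) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$site, y = .data$phylum,
                                 size = .data$n,
                                 colour = .data$amino_acid)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(x = "insertion site", y = NULL, size = "introns",
                  colour = "tRNA") +
    ggplot2::theme_minimal()
}

#' Histogram of intron lengths
#'
#' @param survey Survey tibble.
#' @param binwidth,heg_len Passed to [length_histogram()].
#' @return A ggplot object with the HEG-eligibility threshold marked.
#' @export
plot_length_distribution <- function(survey, binwidth = 50L,
                                     heg_len = 500L) {
  tidy(length_histogram(survey, binwidth, heg_len)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin_start + binwidth / 2,
                                 y = .data$count)) +
    ggplot2::geom_col(width = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = heg_len, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "intron length (bp)", y = "introns") +
    ggplot2::theme_minimal()
}

#' Per-phylum retention-rate bars
#'
#' Only phyla passing the `min_genomes` plotting threshold are shown.
#'
#' @param retention Tibble from [retention_rate()].
#' @return A ggplot object.
#' @export
plot_retention <- function(retention) {
  retention |>
    filter(.data$plotted) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$phylum, y = .data$rate,
                                 fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "genomes with introns (fraction)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
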