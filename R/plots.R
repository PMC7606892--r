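# ggplot2 views of the main result types.

#' Plot F1/F0 size-class count ratios of incompletely excised IESs
#'
#' Mirrors the size-class ratio profile: one bar per surviving size class,
#' with the pooled small/large ratios annotated.
#'
#' @param ratio A result from [count_ratio_by_size_class()].
#' @return A ggplot object.
#' @export
plot_size_class_ratio <- function(ratio) {
  df <- ratio$by_class |> filter(.data$kept)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_class, y = .data$ratio,
                                   fill = .data$small_or_large)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "IES size class (bp)", y = "F1 / F0 count ratio",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot median IRS by size class
#'
#' @param med A tibble from [median_irs_by_size_class()] or a named list of
#'   such tibbles (one line per condition).
#' @return A ggplot object.
#' @export
plot_median_irs <- function(med) {
  if (is.data.frame(med)) med <- list(condition = med)
  df <- purrr::imap(med, function(m, nm) mutate(m, condition = nm)) |>
    bind_rows() |>
    filter(.data$kept)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$median_irs,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IES size-class midpoint (bp)", y = "median IRS",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed vs expected epigenetic-class fractions
#'
#' Fraction bars comparing the epi-class fraction among retained IESs with
#' the underlying background expectation, per line.
#'
#' @param enrich A named list (per line) of [epi_enrichment()] results, or a
#'   single result.
#' @return A ggplot object.
#' @export
plot_epi_fraction <- function(enrich) {
  if (is.data.frame(enrich)) enrich <- list(line = enrich)
  df <- purrr::imap(enrich, function(e, nm) mutate(e, line = nm)) |>
    bind_rows() |>
    tidyr::pivot_longer(c("observed_fraction", "expected_fraction"),
                        names_to = "kind", values_to = "fraction") |>
    mutate(kind = ifelse(.data$kind == "observed_fraction", "Observed", "Expected"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line, y = .data$fraction,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of epigenetically controlled IESs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
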