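# ---- ggplot2 views of results ---------------------------------------------

#' Plot evaluation metrics across cutoffs
#'
#' Line plot of a chosen metric against the cutoff percentile, one line per
#' direction, faceted by any available grouping columns (phase, input, label
#' type) — the view in which performance typically declines from the top 5%
#' cutoff towards the 30% cutoffs.
#'
#' @param reports long tibble of evaluation reports with at least `percent`,
#'   `direction` and the metric column.
#' @param metric metric column name (default `"f_measure"`).
#' @return A ggplot object.
#' @export
plot_cutoff_metrics <- function(reports, metric = "f_measure") {
  if (!metric %in% names(reports)) abort(paste0("no column '", metric, "'"))
  p <- ggplot2::ggplot(reports,
    ggplot2::aes(x = .data$percent, y = .data[[metric]],
                 colour = .data$direction, group = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(5, 30, 5)) +
    ggplot2::labs(x = "cutoff percentile (%)", y = metric,
                  colour = "direction") +
    ggplot2::theme_minimal()
  facets <- intersect(c("phase", "input", "label_type"), names(reports))
  facets <- facets[vapply(facets, function(cl)
    length(unique(reports[[cl]])) > 1, logical(1))]
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(facets, collapse = "+"))))
  }
  p
}

#' Plot per-tissue F-measure and accuracy
#'
#' Dot plot comparing tissues on F-measure (and optionally accuracy),
#' coloured by phase when present.
#'
#' @param reports long tibble with `tissue` and `f_measure` (and optionally
#'   `accuracy`, `phase`).
#' @return A ggplot object.
#' @export
plot_tissue_performance <- function(reports) {
  long <- tidyr::pivot_longer(reports,
    dplyr::any_of(c("f_measure", "accuracy")),
    names_to = "metric", values_to = "value")
  aes <- if ("phase" %in% names(long)) {
    ggplot2::aes(x = .data$value, y = .data$tissue, colour = .data$phase)
  } else {
    ggplot2::aes(x = .data$value, y = .data$tissue)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot an NB(k) model
#'
#' Bar chart of the most class-discriminative k-mers: the words with the
#' largest absolute smoothed log-probability difference between the
#' expressed and unexpressed classes.
#'
#' @param object an `nbk_model`.
#' @param top_n number of k-mers to show (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot nbk_model
#' @export
autoplot.nbk_model <- function(object, top_n = 20, ...) {
  td <- tidy(object)
  td <- td[td$order == object$k, , drop = FALSE]
  wide <- tidyr::pivot_wider(td[c("class", "kmer", "log_prob")],
                             names_from = "class", values_from = "log_prob")
  # unseen-in-one-class words fall back to that class's shared smoothed value
  for (cl in c("c0", "c1")) {
    if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
    wide[[cl]][is.na(wide[[cl]])] <- object$tables$num[[cl]]$unseen
  }
  wide$delta <- wide$c1 - wide$c0
  wide <- wide[order(-abs(wide$delta)), , drop = FALSE]
  wide <- head(wide, top_n)
  ggplot2::ggplot(wide, ggplot2::aes(
    x = .data$delta, y = stats::reorder(.data$kmer, .data$delta),
    fill = .data$delta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "log P(kmer | c1) - log P(kmer | c0)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
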