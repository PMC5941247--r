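#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for calibration objects
#'
#' `tidy()` on a calibration returns the per-class interval table; on a
#' range set, the seven labeled intervals. `glance()` on a calibration
#' summarises the control material in one row.
#'
#' @param x a `ct_calibration` or `ct_ranges` object.
#' @param ... unused.
#' @return A tibble.
#' @examples
#' tidy(ct_default_ranges())
#' glance(ct_default_calibration())
#' @export
tidy.ct_calibration <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' @rdname tidy.ct_calibration
#' @export
tidy.ct_ranges <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' @rdname tidy.ct_calibration
#' @export
glance.ct_calibration <- function(x, ...) {
  tibble(
    n_classes = nrow(x),
    n_total = sum(x$n),
    min_confidence_pct = min(x$confidence_pct),
    max_confidence_pct = max(x$confidence_pct)
  )
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("ct_calibration", "ct_ranges",
                                  "ct_metrics", "ct_records"))
  x
}

#' Plot predicted-significance score ranges
#'
#' Draws the seven contiguous ranges as colored bands along the score axis,
#' with the calibration interval endpoints marked.
#'
#' @param object a `ct_ranges` tibble.
#' @param xlim score-axis limits used to render the two unbounded ranges.
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(ct_default_ranges())
#' @export
autoplot.ct_ranges <- function(object, xlim = c(-50, 50), ...) {
  d <- tidy(object)
  d$lower[is.infinite(d$lower)] <- xlim[1]
  d$upper[is.infinite(d$upper)] <- xlim[2]
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$lower, xmax = .data$upper, ymin = 0, ymax = 1,
      fill = .data$label)) +
    ggplot2::geom_vline(xintercept = unique(d$lower[-1]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = "predicted\nsignificance") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "raw score (CTRS)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the raw-score distribution of an annotated record set
#'
#' Histogram of raw scores colored by predicted significance; the usual
#' first look at a batch run or a calibration set.
#'
#' @param object a `ct_metrics` tibble ([ct_annotate()]).
#' @param binwidth histogram bin width in score units.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ct_metrics <- function(object, binwidth = 1, ...) {
  d <- as_tibble(unclass_first(object))
  d$CTPS <- factor(d$CTPS, levels = ct_overall_levels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$CTRS, fill = .data$CTPS)) +
    ggplot2::geom_histogram(binwidth = binwidth) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               na.value = "grey70",
                               name = "predicted\nsignificance") +
    ggplot2::labs(x = "raw score (CTRS)", y = "variants") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
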