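#' Plot a subject or grand-average ERP
#'
#' Waveforms per electrode, negativity plotted upwards as is conventional
#' in the infant ERP literature.
#'
#' @param object a `subject_erp`.
#' @param electrodes channels to show (default: all rows of the ERP).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.subject_erp <- function(object, electrodes = NULL, ...) {
  electrodes <- electrodes %||% rownames(object$data)
  d <- tibble::tibble(
    time = rep(object$time, each = length(electrodes)),
    electrode = rep(electrodes, times = length(object$time)),
    uV = as.vector(object$data[electrodes, , drop = FALSE]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$uV)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line(colour = "#2b6cb0") +
    ggplot2::facet_wrap(~electrode) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV, negative up)",
                  title = sprintf("%s — %s / %s", object$subject_id,
                                  object$phase, object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-bin onset scan
#'
#' Bin means with their significance; the detected onset, if any, is
#' marked by a vertical line.
#'
#' @param object an `onset_result`.
#' @param ... unused.
#' @export
autoplot.onset_result <- function(object, ...) {
  d <- object$bins
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$start + (object$bin / 2),
                                       y = .data$mean,
                                       colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#c53030")) +
    ggplot2::labs(x = "bin centre (ms)", y = "mean difference (µV)",
                  colour = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal()
  if (!is.na(object$onset))
    p <- p + ggplot2::geom_vline(xintercept = object$onset,
                                 linetype = "dashed")
  p
}

#' Plot window amplitudes by quadrant and condition
#'
#' @param object a `window_amplitudes` tibble.
#' @param ... unused.
#' @export
autoplot.window_amplitudes <- function(object, ...) {
  d <- dplyr::filter(object, .data$condition %in% c("familiar", "unfamiliar"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quadrant, y = .data$mean_uV,
                                  fill = .data$condition)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(y = "mean amplitude (µV, negative up)", x = NULL,
                  title = sprintf("window [%g, %g) ms",
                                  attr(object, "window")[1],
                                  attr(object, "window")[2])) +
    ggplot2::theme_minimal()
}

#' Scatter of the left-frontal familiarity effect against word-production LQ
#'
#' @param responders a [classify_responders()] table (carries the basis
#'   amplitude and the polarity split).
#' @param outcomes outcome tibble with `LQ_word`.
#' @return A ggplot object.
#' @export
plot_brain_behavior <- function(responders, outcomes) {
  d <- dplyr::inner_join(responders, outcomes, by = "subject")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$basis_uV, y = .data$LQ_word,
                                  colour = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey30",
                         linewidth = 0.5) +
    ggplot2::labs(x = "left-frontal familiarity effect, 350–450 ms (µV)",
                  y = "word-production LQ at 3 years",
                  colour = "responder") +
    ggplot2::theme_minimal()
}
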