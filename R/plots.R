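# Basic diagnostic plots (ggplot2). Orchestration treats plotting as
# best-effort: a failed device never fails a run.

#' Bland-Altman plot
#'
#' Differences against pair means with the mean-difference line (dotted),
#' the limits of agreement (dashed) and the zero line (red).
#'
#' @param result a \linkS4class{BlandAltmanResult}.
#' @return a ggplot object.
#' @export
plotBlandAltman <- function(result) {
  df <- data.frame(means = result@means, diffs = result@diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$means, y = .data$diffs)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::geom_hline(yintercept = result@meanDiff, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(result@loaLower, result@loaUpper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      title = sprintf("%s: %s (x) vs %s (y)", result@cpgId,
                      result@platformX, result@platformY),
      x = "mean of methods (x + y)/2",
      y = "difference (x - y)") +
    ggplot2::theme_bw()
}

#' Predicted versus chronological age
#'
#' Point predictions against true ages with the identity line (solid
#' grey) and the q10-q90 prediction interval bounds (dashed grey).
#'
#' @param predictions data.frame from [predictAge()].
#' @return a ggplot object.
#' @export
plotPredictions <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$age, y = .data$point)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pi_lower),
                       linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pi_upper),
                       linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted age (years)") +
    ggplot2::theme_bw()
}
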