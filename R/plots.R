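#' Plot an SUVR report
#'
#' Composite SUVR bars with the global value and the positivity cutoff.
#'
#' @param object a `suvr_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot suvr_report
#' @export
autoplot.suvr_report <- function(object, ...) {
  df <- tidy.suvr_report(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$suvr)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed",
                        colour = "indianred") +
    ggplot2::labs(x = NULL, y = "SUVR (pons reference)",
                  title = sprintf("Global SUVR %.3f (%s at cutoff %.2f)",
                                  object$global_suvr,
                                  if (object$classification == 1L) "positive"
                                  else "negative", object$cutoff)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot cross-method ICC estimates
#'
#' Point estimates with 95% bounds per region and method pair, split by ICC
#' form, with the conventional 0.75 reliability guide line.
#'
#' @param object an `agreement_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- object$icc
  df$pair <- paste(df$method_a, "vs", df$method_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$icc,
                                   colour = .data$pair)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::facet_wrap(~form) +
    ggplot2::labs(x = NULL, y = "Intraclass correlation") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
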