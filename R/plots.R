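# ggplot2 visualisations for the main result types.

#' Scatter plot of a harmonized instrument set
#'
#' SNP-outcome effects against SNP-exposure effects with +/- 1 SE bars, the
#' IVW line through the origin and (J >= 3) the MR-Egger line with its
#' intercept — the standard visual check for directional pleiotropy.
#'
#' @param object An `mr_harmonized` set.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  ivw <- mr_ivw(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta, colour = "#2166AC") +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  subtitle = sprintf("IVW slope %.3f", ivw$beta)) +
    ggplot2::theme_minimal()
  if (nrow(object) >= 3) {
    eg <- mr_egger(object)
    p <- p + ggplot2::geom_abline(
      intercept = eg$beta[eg$method == "egger_intercept"],
      slope = eg$beta[eg$method == "egger_slope"],
      colour = "#B2182B", linetype = "dashed"
    )
  }
  p
}

#' Forest plot of tidy MR or meta-analysis estimates
#'
#' @param estimates Tibble with columns `method` (or `label`), `beta`,
#'   `ci_low`, `ci_high`.
#' @param null Reference line position (0 on the log scale).
#' @return A ggplot.
#' @export
plot_forest <- function(estimates, null = 0) {
  lab <- if ("label" %in% names(estimates)) "label" else "method"
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$beta, y = .data[[lab]])) +
    ggplot2::geom_vline(xintercept = null, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "estimate (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pooled meta-analysis
#'
#' Shows each study estimate and the pooled result from an `mr_meta` fit.
#'
#' @param object An `mr_meta` object.
#' @param estimates The study-level tibble (`beta`, `se`, optional `label`)
#'   that produced the fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_meta <- function(object, estimates, ...) {
  z <- z95()
  estimates <- tibble::as_tibble(estimates)
  if (!"label" %in% names(estimates)) {
    estimates$label <- paste0("study ", seq_len(nrow(estimates)))
  }
  rows <- dplyr::bind_rows(
    tibble::tibble(label = estimates$label, beta = estimates$beta,
                   ci_low = estimates$beta - z * estimates$se,
                   ci_high = estimates$beta + z * estimates$se,
                   pooled = FALSE),
    tibble::tibble(label = paste0("pooled (", object$model, ")"),
                   beta = object$pooled$beta,
                   ci_low = object$pooled$ci_low,
                   ci_high = object$pooled$ci_high, pooled = TRUE)
  )
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$label,
                                     colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "log odds ratio", y = NULL) +
    ggplot2::theme_minimal()
}
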