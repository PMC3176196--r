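#' Plot component scores
#'
#' Scatter of the first two (kernel) principal component scores, optionally
#' colored by case-control status.
#'
#' @param object A `component_scores`.
#' @param pheno Optional phenotype tibble (`iid`, `status`) for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.component_scores <- function(object, pheno = NULL, ...) {
  tb <- as_tibble(object)
  nm <- colnames(object$scores)
  if (object$L < 2L) {
    tb$index <- seq_len(nrow(tb))
    p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$index,
                                          y = .data[[nm[1L]]]))
  } else {
    p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data[[nm[1L]]],
                                          y = .data[[nm[2L]]]))
  }
  if (!is.null(pheno)) {
    validate_phenotypes(pheno)
    tb2 <- dplyr::left_join(tb, pheno, by = "iid")
    p <- p %+% tb2 +
      ggplot2::aes(colour = factor(.data$status,
                                   labels = c("control", "case")))
    p <- p + ggplot2::labs(colour = NULL)
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = paste0(toupper(object$method), " scores (L = ",
                                 object$L, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 %+%
NULL

#' Plot a simulation study result
#'
#' Rejection proportions per method and significance level, with the
#' nominal level marked; under the null the bars should sit on the dashed
#' line.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, ...) {
  tb <- object$rates
  tb$alpha_lab <- paste0("alpha = ", tb$alpha)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$method, y = .data$rate,
                                   fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~alpha_lab, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rejection proportion",
                  title = sprintf("RR = %.2f, %d/%d cases/controls",
                                  object$config$relative_risk,
                                  object$config$n_cases,
                                  object$config$n_controls)) +
    ggplot2::theme_minimal()
}

#' Uniform calibration plot of simulated p-values
#'
#' Empirical cumulative distribution of the per-replicate p-values against
#' the uniform diagonal, one line per method. Under the null hypothesis the
#' lines should track the diagonal.
#'
#' @param study A `study_result`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(study) {
  stopifnot(inherits(study, "study_result"))
  tb <- dplyr::filter(study$replicates, !is.na(.data$p_value))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$p_value,
                                   colour = .data$method)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "p-value", y = "empirical CDF", colour = NULL) +
    ggplot2::theme_minimal()
}
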