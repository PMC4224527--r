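#' Plot a Hill-number diversity profile
#'
#' Effective species number against Hill power; an infinite power is drawn
#' at a finite position labelled `Inf`. Flat profiles indicate perfectly
#' even communities; the steeper the drop, the stronger the dominance.
#'
#' @param object A `hill_profile` (see [hill_profile()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  finite <- d$a[is.finite(d$a)]
  inf_pos <- if (any(is.infinite(d$a))) {
    max(finite) + max(diff(range(finite)), 1) * 0.25
  } else NA_real_
  d$a_plot <- ifelse(is.finite(d$a), d$a, inf_pos)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a_plot, y = .data$N)) +
    ggplot2::geom_line(data = d[is.finite(d$a), ]) +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(
      breaks = c(finite, if (!is.na(inf_pos)) inf_pos),
      labels = c(format(finite), if (!is.na(inf_pos)) "Inf")) +
    ggplot2::labs(x = "Hill power a",
                  y = "Effective species number N_a") +
    ggplot2::theme_minimal()
}

#' Biplot of a correlation PCA with importance values
#'
#' Plots plot scores on the first two components with variable loading
#' vectors; each vector is labelled with its importance value under the
#' requested retention rule.
#'
#' @param object A `pca_cor` object.
#' @param retain Retention rule passed to [importance_values()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_cor <- function(object, retain = "kaiser", ...) {
  sc <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE],
                          .name_repair = ~ c("PC1", "PC2"))
  iv <- importance_values(object, retain = retain)
  ld <- tibble::tibble(
    variable = rownames(object$loadings),
    PC1 = object$loadings[, 1], PC2 = object$loadings[, 2]
  )
  ld <- dplyr::left_join(ld, iv, by = "variable")
  sc_r <- max(abs(unlist(sc)))
  ggplot2::ggplot() +
    ggplot2::geom_point(data = sc,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2),
                        colour = "grey60", size = 1) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * sc_r,
                   yend = .data$PC2 * sc_r),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * sc_r * 1.08,
                   y = .data$PC2 * sc_r * 1.08,
                   label = sprintf("%s (%.2f)", .data$variable, .data$IV))) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$variance_explained[2])) +
    ggplot2::theme_minimal()
}

#' Dot plot of standardized path coefficients
#'
#' One point per directed path with a 95% Wald interval; filled points are
#' significant at the given level. For a `multi_path_fit`, panels compare
#' the same paths across diversity indices.
#'
#' @param object A `path_fit` or `multi_path_fit`.
#' @param alpha Significance level for the fill.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.path_fit <- function(object, alpha = 0.05, ...) {
  d <- tidy.path_fit(object)
  d$path <- paste(d$from, "→", d$to)
  d$significant <- d$p_value < alpha
  path_coef_plot(d)
}

#' @rdname autoplot.path_fit
#' @export
autoplot.multi_path_fit <- function(object, alpha = 0.05, ...) {
  d <- object$paths
  d$path <- paste(d$from, "→", d$to)
  d$significant <- d$p_value < alpha
  path_coef_plot(d) + ggplot2::facet_wrap(~index)
}

path_coef_plot <- function(d) {
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$path)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "Standardized path coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
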