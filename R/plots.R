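#' Plot a radial expression layout
#'
#' Scatter of gene points inside the anchor circle, colored by cluster
#' and sized by the largest log10 expression change; anchors are drawn as
#' open circles with their sample labels, mirroring the study's radial
#' clustering figure.
#'
#' @param object A `radial_layout` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot radial_layout
#' @export
autoplot.radial_layout <- function(object, ...) {
  anchors <- attr(object, "anchors")
  circle <- tibble(
    x = cospi(seq(0, 2, length.out = 361)),
    y = sinpi(seq(0, 2, length.out = 361))
  )
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circle, colour = "grey70") +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$size, colour = .data$cluster),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = anchors, shape = 1, size = 4, stroke = 1
    ) +
    ggplot2::geom_text(
      data = anchors, ggplot2::aes(label = .data$sample_id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_size_continuous(range = c(0.3, 4)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      colour = "cluster", size = "max Δlog10",
      title = "Radial-coordinate expression layout"
    )
}

#' Plot transcript-protein decoupling
#'
#' Scatter of protein versus mRNA log10 ratios with the coefficient of
#' determination annotated per comparison.
#'
#' @param object An `omics_pairs` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omics_pairs
#' @export
autoplot.omics_pairs <- function(object, ...) {
  ann <- as_tibble(object) %>%
    group_by(.data$comparison) %>%
    summarise(
      label = sprintf("R² = %.2f", cor(
        .data$mrna_log10_ratio, .data$protein_log10_ratio
      )^2),
      .groups = "drop"
    )
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$mrna_log10_ratio, y = .data$protein_log10_ratio,
    colour = .data$comparison
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::annotate("text",
      x = Inf, y = -Inf, hjust = 1.1, vjust = -0.5,
      label = paste(ann$comparison, ann$label, collapse = "; ")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "mRNA log10 ratio", y = "protein log10 ratio",
      title = "Transcript-protein decoupling"
    )
}

#' @rdname proteome_summary
#' @param x A `protein_quant` tibble.
#' @param ... Passed to [proteome_summary()].
#' @return For `glance()`: the one-row [proteome_summary()] tibble.
#' @method glance protein_quant
#' @export
glance.protein_quant <- function(x, ...) {
  proteome_summary(x, ...)
}

#' @rdname r_squared
#' @param x An `omics_pairs` tibble.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble `n_pairs`, `r_squared`.
#' @method glance omics_pairs
#' @export
glance.omics_pairs <- function(x, ...) {
  tibble(n_pairs = nrow(x), r_squared = r_squared(x))
}
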