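# ggplot2 autoplot methods for the main result types.

#' Plot methods
#'
#' `autoplot()` methods: per-residue alignment distances for a
#' `structural_alignment`, the replicate-cutoff histogram for an
#' `ssea_cutoff`, the probability-vs-score curve for an `ssea_curve`, and
#' grouped membrane distances for a `domex_run`.
#'
#' @param object a domex result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot_domex
NULL

#' @rdname autoplot_domex
#' @method autoplot structural_alignment
#' @export
autoplot.structural_alignment <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$index_a, y = .data$dist)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = paste0("residue index (", object$id_a, ")"),
      y = "Cα pair distance (Å)",
      title = sprintf("%s vs %s: %d pairs, RMSD %.2f Å, TM-score %.2f",
                      object$id_a, object$id_b, object$aligned_length,
                      object$rmsd, object$tm_score)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_domex
#' @method autoplot ssea_cutoff
#' @export
autoplot.ssea_cutoff <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$cutoff)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "per-replicate chosen cutoff", y = "replicates",
                  title = sprintf("Trained SSEA cutoff: %d", object$cutoff)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_domex
#' @method autoplot ssea_curve
#' @export
autoplot.ssea_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "SSEA score bin midpoint",
                  y = "P(structurally similar)",
                  size = "pairs") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_domex
#' @method autoplot domex_run
#' @export
autoplot.domex_run <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$group, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "membrane distance (Å)") +
    ggplot2::theme_minimal()
}
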