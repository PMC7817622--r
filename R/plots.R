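# ggplot2 views of the main result types.

#' Plot a read pattern map
#'
#' Read x CpG tile map of per-molecule methylation calls (the classic
#' amplicon "lollipop" view rendered as tiles): methylated calls dark,
#' unmethylated light, missing grey.
#'
#' @param object a `pattern_map` from [pattern_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pattern_map
#' @export
autoplot.pattern_map <- function(object, ...) {
  m <- calls_matrix(object)
  df <- tibble(
    read = rep(seq_len(nrow(m)), times = ncol(m)),
    cpg = rep(seq_len(ncol(m)), each = nrow(m)),
    call = factor(as.vector(m), levels = c("M", "U", "."))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpg, y = .data$read,
                                   fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(
      values = c(M = "#b2182b", U = "#f7f7c6", . = "grey80"),
      labels = c(M = "methylated", U = "unmethylated", . = "missing"),
      name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "CpG", y = "read",
                  title = attr(object, "amplicon")) +
    ggplot2::theme_minimal()
}

#' Plot PCA sample scores
#'
#' @param object a `meth_pca` from [pca_beta()].
#' @param components length-2 character vector of components to plot.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meth_pca
#' @export
autoplot.meth_pca <- function(object, components = c("PC1", "PC2"), ...) {
  v <- object$variance
  lab <- function(pc) {
    sprintf("%s (%.1f%%)", pc,
            100 * v$prop_variance[match(pc, v$component)])
  }
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[components[1]]],
                               y = .data[[components[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = lab(components[1]), y = lab(components[2])) +
    ggplot2::theme_minimal()
}

#' Plot a group-vs-group methylation comparison
#'
#' Per-probe scatter of the two group means with the delta-threshold
#' hypo/hyper sets highlighted — the correlation-plot view of a
#' differential methylation result.
#'
#' @param object a `meth_diff` from [compare_groups()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meth_diff
#' @export
autoplot.meth_diff <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$mean_reference,
                               y = .data$mean_treatment,
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(none = "grey60", hypo = "#2166ac", hyper = "#b2182b")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("mean beta,", object$reference),
                  y = paste("mean beta,", object$treatment)) +
    ggplot2::theme_minimal()
}

#' Plot per-CpG mean methylation
#'
#' @param object a `meth_summary` from [summarize_methylation()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meth_summary
#' @export
autoplot.meth_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cpg_index,
                                       y = .data$mean_meth_pct)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "CpG", y = "mean methylation (%)") +
    ggplot2::theme_minimal()
}
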