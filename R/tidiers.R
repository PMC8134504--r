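#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for screen results
#'
#' `tidy()` returns the per-unit table (per protein, per sample, per track);
#' `glance()` returns a one-row summary.
#'
#' @param x a fitted/derived mammoquant object.
#' @param ... unused.
#' @name mammoquant-tidiers
NULL

#' @rdname mammoquant-tidiers
#' @export
tidy.mq_differential <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname mammoquant-tidiers
#' @export
glance.mq_differential <- function(x, ...) {
  s <- attr(x, "settings")
  tibble::tibble(
    n_tested = nrow(x),
    n_excluded = s$n_excluded,
    n_significant = sum(x$significant),
    n_unique = sum(!is.na(x$unique_to)),
    alpha = s$alpha, log2_cut = s$log2_cut, q_method = s$q_method
  )
}

#' @rdname mammoquant-tidiers
#' @export
tidy.mq_rf_report <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("p_"),
                      names_to = "class", values_to = "probability",
                      names_prefix = "p_")
}

#' @rdname mammoquant-tidiers
#' @export
glance.mq_rf_report <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_classes = length(x$classes),
                 n_scored = nrow(x$scores), oob_accuracy = x$oob_accuracy,
                 seed = x$seed)
}

#' @rdname mammoquant-tidiers
#' @export
tidy.mq_group_compare <- function(x, ...) {
  if (is.null(x$pairwise)) x$omnibus else x$pairwise
}

#' @rdname mammoquant-tidiers
#' @export
glance.mq_group_compare <- function(x, ...) {
  dplyr::mutate(x$omnibus, design = x$design, .before = 1)
}

#' Volcano plot of a differential-abundance result
#'
#' log2 ratio against -log10 p, with the significance calls highlighted
#' and the +/-10 sentinel ratios (uniquely observed proteins) at the
#' margins.
#'
#' @param object an `mq_differential` from [differential()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mq_differential <- function(object, ...) {
  cmp <- attr(object, "comparison")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2_ratio,
                               y = -log10(pmax(.data$p_value, 1e-16)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("log2 ratio (%s / %s)", cmp["a"], cmp["b"]),
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Protrusion lifetime / length scatter
#'
#' @param object an `mq_tracks` tibble from [track_protrusions()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mq_tracks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lifetime_h,
                                       y = .data$max_length_um)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "protrusion lifetime (h)",
                  y = "max protrusion length (um)") +
    ggplot2::theme_minimal()
}

#' Stage-probability bars for a random-forest report
#'
#' @param object an `mq_rf_report` from [rf_stage_classify()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mq_rf_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample_id, y = .data$probability,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "ensemble vote fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Segmentation overview plot
#'
#' Tree mask with the nipple, detected branch points and (when present)
#' the lymph-node centroid.
#'
#' @param object a [tree_segmentation()].
#' @param record optional `mq_morphometrics` row from [measure_gland()]
#'   whose branch points and boundary are overlaid.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tree_segmentation <- function(object, record = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$tree_mask)),
                           col = seq_len(ncol(object$tree_mask)))
  df$fg <- as.vector(t(object$tree_mask))
  p <- ggplot2::ggplot(df[df$fg, ], ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = "grey25") +
    ggplot2::annotate("point", x = object$nipple_px[2], y = object$nipple_px[1],
                      colour = "dodgerblue", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(object$ln_centroid_px))
    p <- p + ggplot2::annotate("point", x = object$ln_centroid_px[2],
                               y = object$ln_centroid_px[1],
                               colour = "darkorange", size = 3, shape = 17)
  if (!is.null(record)) {
    bp <- attr(record, "branchpoints_px")
    bd <- attr(record, "boundary")$vertices
    p <- p +
      ggplot2::annotate("path", x = c(bd[, 2], bd[1, 2]), y = c(bd[, 1], bd[1, 1]),
                        colour = "firebrick", linewidth = 0.3) +
      ggplot2::annotate("point", x = bp[, 2], y = bp[, 1],
                        colour = "firebrick", size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
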