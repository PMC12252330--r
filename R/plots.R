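#' Plot a trait screen
#'
#' Bar panels of the screening indices per trait -- D/H/E for qualitative
#' traits, CVbar/CV for quantitative -- with the retention gates drawn as
#' dashed lines, in the style of the index bar charts used in germplasm
#' diversity studies.
#'
#' @param object a `trait_screen` from [screen_traits()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trait_screen <- function(object, ...) {
  th <- attr(object, "thresholds") %||% screening_thresholds()
  long <- object |>
    tidyr::pivot_longer(c("D", "H", "E", "cv_within", "cv_among"),
                        names_to = "index", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  gates <- tibble::tibble(
    index = c("D", "H", "E", "cv_within", "cv_among"),
    gate = c(th$d_min, th$h_min, th$e_min, th$cvbar_max, th$cv_min)
  )
  gates <- gates[gates$index %in% unique(long$index), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$value,
                                     fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = gates, ggplot2::aes(yintercept = .data$gate),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "index value", fill = "retained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Scree plot of a trait PCA
#'
#' Eigenvalues per component with the retention threshold and the
#' cumulative variance contribution.
#'
#' @param object a `trait_pca` from [pca_retain()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trait_pca <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$eigenvalues),
    eigenvalue = object$eigenvalues,
    retained = object$retained
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$lambda_min, linetype = "dashed") +
    ggplot2::labs(x = "principal component", y = "eigenvalue",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' Plot a germplasm dendrogram
#'
#' Draws the Ward.D2 merge tree as ggplot segments, leaves labelled by
#' germplasm id, optionally coloured by a partition.
#'
#' @param hc a [cluster_germplasm()] dendrogram.
#' @param partition optional tibble `germplasm_id`, `cluster` used to
#'   colour leaf labels.
#' @return a ggplot.
#' @export
plot_dendrogram <- function(hc, partition = NULL) {
  n <- length(hc$labels)
  leaf_x <- stats::setNames(seq_len(n), hc$labels[hc$order])
  # x position and height of every internal node, bottom-up
  node_x <- node_h <- numeric(length(hc$height))
  pos <- function(id) {
    if (id < 0) c(leaf_x[[hc$labels[-id]]], 0) else c(node_x[id], node_h[id])
  }
  segs <- vector("list", length(hc$height))
  for (i in seq_along(hc$height)) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2]); h <- hc$height[i]
    node_x[i] <- mean(c(a[1], b[1])); node_h[i] <- h
    segs[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], h), yend = c(h, h, h)
    )
  }
  labs <- tibble::tibble(germplasm_id = names(leaf_x), x = unname(leaf_x))
  if (!is.null(partition)) {
    labs <- dplyr::left_join(labs, partition, by = "germplasm_id")
  } else {
    labs$cluster <- "1"
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = dplyr::bind_rows(segs),
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(hc$height),
                                    label = .data$germplasm_id,
                                    colour = .data$cluster),
                       angle = 90, hjust = 1, size = 2.5) +
    ggplot2::scale_y_continuous("merge height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (is.null(partition)) "none" else "right")
}

#' Heatmap of section distribution across clusters
#'
#' @param object a [section_distribution()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_section_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cluster, y = .data$section,
                                       fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "cluster", y = NULL, fill = "% of section") +
    ggplot2::theme_minimal()
}
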