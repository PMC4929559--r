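#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pattern-match result
#'
#' One row per candidate (feature, gene) pair.
#'
#' @param x A `rhizolink_match` from [match_patterns()].
#' @param ... Unused.
#' @return A tibble `feature_id`, `mz`, `rt`, `pattern_key`,
#'   `pattern_length`, `median_intensity`, `gene_id`.
#' @export
tidy.rhizolink_match <- function(x, ...) {
  x$candidates |>
    dplyr::mutate(gene_id = .data$genes) |>
    dplyr::select(-genes, -n_genes) |>
    tidyr::unnest(gene_id)
}

#' @rdname tidy.rhizolink_match
#' @export
glance.rhizolink_match <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_unmatched = nrow(x$unmatched),
    n_multi_gene = sum(x$candidates$n_genes > 1)
  )
}

#' Tidy a pipeline result
#'
#' `tidy()` returns the candidate (feature, gene) pairs; `glance()` the
#' one-row funnel of stage counts.
#'
#' @param x A `rhizolink_result` from [run_pipeline()].
#' @param ... Unused.
#' @export
tidy.rhizolink_result <- function(x, ...) tidy(x$match)

#' @rdname tidy.rhizolink_result
#' @export
glance.rhizolink_result <- function(x, ...) x$funnel

#' Bar chart of candidate features by absence-pattern length
#'
#' @param object A `rhizolink_match`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhizolink_match <- function(object, ...) {
  df <- object$candidates |>
    dplyr::count(.data$pattern_length)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pattern_length),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "absence pattern length (accessions)",
                  y = "candidate features") +
    ggplot2::theme_minimal()
}

#' Absence-pattern heat map
#'
#' Tile plot of feature absence across accessions for features absent in at
#' least one accession.
#'
#' @param patterns Output of [absence_patterns()].
#' @return A ggplot object.
#' @export
plot_absence_map <- function(patterns) {
  pat <- patterns[patterns$pattern_length >= 1, , drop = FALSE]
  df <- pat |>
    dplyr::mutate(absent = lapply(.data$absent, function(x) {
      tibble::tibble(accession = names(x), is_absent = unname(x))
    })) |>
    dplyr::select(feature_id, absent) |>
    tidyr::unnest(absent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accession, y = .data$feature_id,
                                   fill = .data$is_absent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "grey20"),
                               name = "absent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' Dendrogram plot with optional AU support labels
#'
#' Draws an `hclust` tree with ggplot2; when multiscale-bootstrap support
#' is supplied, internal nodes are labelled with their AU values, and an
#' optional correlation threshold is drawn as a cut line at height
#' `1 - threshold`.
#'
#' @param tree An `hclust` object.
#' @param support Optional `support` tibble from
#'   [multiscale_bootstrap_au()].
#' @param threshold Optional correlation threshold for the cut line.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, support = NULL, threshold = NULL) {
  n <- length(tree$labels)
  x_leaf <- numeric(n)
  x_leaf[tree$order] <- seq_len(n)
  node_x <- numeric(n - 1)
  node_y <- tree$height
  seg <- vector("list", n - 1)
  pos <- function(id) if (id < 0) c(x_leaf[-id], 0) else c(node_x[id], node_y[id])
  for (i in seq_len(n - 1)) {
    a <- pos(tree$merge[i, 1])
    b <- pos(tree$merge[i, 2])
    node_x[i] <- mean(c(a[1], b[1]))
    seg[[i]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_y[i]), yend = c(node_y[i], node_y[i], node_y[i])
    )
  }
  segs <- dplyr::bind_rows(seg)
  leaves <- tibble::tibble(x = x_leaf, label = tree$labels)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(node_y),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 2.8) +
    ggplot2::labs(x = NULL, y = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(support)) {
    lab <- tibble::tibble(x = node_x, y = node_y,
                          au = sprintf("%.2f", support$au))
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$au),
                                colour = "red", vjust = -0.4, size = 2.5)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = 1 - threshold,
                                 linetype = "dashed")
  }
  p
}
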