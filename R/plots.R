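# ggplot2 views of the main result types.

#' Plot significance counts per feature
#'
#' Bar chart of the number of subsets in which each feature is significant
#' at the given cutoff (the per-group feature ranking).
#'
#' @param counts tibble from [count_significant()]
#' @param top show only the first `top` features (default 10)
#' @return A ggplot object.
#' @export
plot_significance_counts <- function(counts, top = 10) {
  df <- head(counts, top) %>%
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_significant, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "subsets significant", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the per-feature auROC summary
#'
#' @param summary tibble from [mean_auroc_table()]
#' @return A ggplot object.
#' @export
plot_auroc_summary <- function(summary) {
  df <- summary %>%
    mutate(
      set = stringr::str_extract(.data$feature, "^[A-Z]+"),
      feature = factor(.data$feature, levels = rev(.data$feature))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_auroc, y = .data$feature, fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "mean auROC across subsets", y = NULL, fill = "feature set") +
    ggplot2::theme_minimal()
}

#' Plot metric distributions by number of other bad flags
#'
#' Quartile ribbons of each six-flag metric against how many of the other
#' five flags call the file low quality.
#'
#' @param groups the `groups` tibble from [other_flag_analysis()]
#' @return A ggplot object.
#' @export
plot_flag_groups <- function(groups) {
  ggplot2::ggplot(groups, ggplot2::aes(x = .data$n_bad_other, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "low-quality flags among other metrics", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot a guideline tree
#'
#' Simple node-and-edge rendering of a fitted tree with the standard node
#' annotations; the left branch takes values at or below the threshold.
#'
#' @param object a `qc_tree`
#' @param ... unused
#' @return A ggplot object.
#' @method autoplot qc_tree
#' @export
autoplot.qc_tree <- function(object, ...) {
  nodes <- tidy(object)
  # horizontal position by in-order leaf index, depth on y
  pos <- new.env()
  leaf_x <- 0
  walk <- function(id) {
    r <- nodes[nodes$node == id, ]
    if (r$leaf) {
      leaf_x <<- leaf_x + 1
      assign(as.character(id), leaf_x, envir = pos)
    } else {
      walk(id * 2)
      walk(id * 2 + 1)
      assign(
        as.character(id),
        (get(as.character(id * 2), envir = pos) +
          get(as.character(id * 2 + 1), envir = pos)) / 2,
        envir = pos
      )
    }
  }
  walk(1)
  nodes$x <- vapply(nodes$node, function(i) get(as.character(i), envir = pos), numeric(1))
  nodes$label <- ifelse(nodes$leaf,
    paste0("[", nodes$n_high, ",", nodes$n_low, "]\n", nodes$predicted_class),
    paste0(
      nodes$feature, " <= ", round(nodes$threshold, 3), "\n[",
      nodes$n_high, ",", nodes$n_low, "]"
    )
  )
  edges <- nodes %>%
    filter(!is.na(.data$parent)) %>%
    left_join(nodes[, c("node", "x", "depth")],
      by = c(parent = "node"), suffix = c("", ".p")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x.p, y = -.data$depth.p,
        xend = .data$x, yend = -.data$depth
      )
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = -.data$depth, label = .data$label),
      size = 3
    ) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
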