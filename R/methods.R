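#' @export
print.cbpln_result <- function(x, ...) {
  cat("<cbpln_result>\n")
  cat("  evaluated ordered pairs : ", nrow(x$links), "\n", sep = "")
  cat("  significant links       : ", nrow(x$graph),
    " (FDR ", x$config$fdr_alpha, ", tests: ",
    paste(x$config$tests, collapse = "+"),
    if (x$config$normalize) ", normalized", ")\n",
    sep = ""
  )
  cat("  permutations            : ", x$config$permutations,
    " (seed ", x$config$seed, ")\n",
    sep = ""
  )
  if (nrow(x$graph) > 0L) {
    print(head(x$graph[, intersect(
      c("source", "target", "normalized", "q_geneset", "q_network"),
      names(x$graph)
    )], 10L))
  }
  invisible(x)
}

#' Tidy a contextual linkage result
#'
#' @param x A `cbpln_result` from [compute_cbpln()].
#' @param ... Unused.
#' @return A tibble with one row per evaluated ordered process pair and its
#'   scores, p-values and adjusted p-values (the `contributions` list-column
#'   is dropped; it remains available in `x$links`).
#' @method tidy cbpln_result
#' @export
tidy.cbpln_result <- function(x, ...) {
  cols <- setdiff(names(x$links), "contributions")
  tibble::as_tibble(x$links[, cols, drop = FALSE])
}

#' One-row summary of a contextual linkage result
#'
#' @inheritParams tidy.cbpln_result
#' @return A one-row tibble: numbers of evaluated pairs and significant
#'   links, configured tests, replicates, FDR level and seed.
#' @method glance cbpln_result
#' @export
glance.cbpln_result <- function(x, ...) {
  tibble::tibble(
    n_evaluated = nrow(x$links),
    n_significant = nrow(x$graph),
    tests = paste(x$config$tests, collapse = "+"),
    normalized = x$config$normalize,
    permutations = x$config$permutations,
    fdr_alpha = x$config$fdr_alpha,
    seed = x$config$seed
  )
}

#' Plot the directed process linkage network
#'
#' Draws the significant links as a directed graph on a circular layout:
#' nodes are processes, arrows point from source to target, and arrow color
#' encodes the smallest adjusted p-value supporting the link.
#'
#' @param object A `cbpln_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbpln_result
#' @export
autoplot.cbpln_result <- function(object, ...) {
  graph <- object$graph
  procs <- sort(unique(c(graph$source, graph$target, object$links$source, object$links$target)))
  theta <- seq(0, 2 * pi, length.out = length(procs) + 1L)[seq_along(procs)]
  layout <- tibble::tibble(process = procs, x = cos(theta), y = sin(theta))
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 3, color = "grey30")
  if (nrow(graph) > 0L) {
    qcols <- intersect(c("q_geneset", "q_network"), names(graph))
    qmin <- do.call(pmin, c(unname(as.list(graph[, qcols])), list(na.rm = TRUE)))
    seg <- dplyr::mutate(
      graph,
      x = layout$x[match(.data$source, layout$process)],
      y = layout$y[match(.data$source, layout$process)],
      xend = layout$x[match(.data$target, layout$process)],
      yend = layout$y[match(.data$target, layout$process)],
      q_min = qmin
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        color = .data$q_min
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm"), type = "closed"),
      linewidth = 0.6, alpha = 0.85
    ) +
      ggplot2::scale_color_gradient(
        name = "min adjusted p",
        low = "#b2182b", high = "#2166ac"
      )
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$process),
      nudge_y = 0.08, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Contextual process linkage network")
}

#' Null distribution diagnostic plot
#'
#' Histogram of the permutation replicates with the observed statistic marked,
#' the standard visual check that a link's score sits in (or out of) the bulk
#' of its null.
#'
#' @param null A `null_distribution`.
#' @param observed Observed statistic to mark (optional).
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null, observed = NULL) {
  df <- tibble::tibble(value = null$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", color = "white") +
    ggplot2::labs(
      x = if (null$normalize) "normalized score (null)" else "score (null)",
      y = "replicates",
      title = paste0(null$generator, " randomization null")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, color = "#b2182b", linewidth = 0.8)
  }
  p
}
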