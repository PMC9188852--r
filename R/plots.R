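#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot significance scores per protein and direction
#'
#' Lollipop chart of the group-contrast significance scores, faceted by
#' modulation direction, with the cutoff drawn as a dashed line and
#' significant proteins highlighted.
#'
#' @param object A [score_profile()] result.
#' @param cutoff Reference cutoff line; default 5.
#' @param top Show at most this many proteins per direction; default 20.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tox_significance
#' @export
autoplot.tox_significance <- function(object, cutoff = 5, top = 20, ...) {
  df <- object |>
    dplyr::group_by(.data$direction) |>
    dplyr::slice_max(.data$score, n = top, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      direction = factor(.data$direction, c(1, 2),
                         c("positively modulated", "negatively modulated"))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$protein_id, .data$score),
    colour = .data$significant
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$protein_id, .data$score
    ))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction), scales = "free_y") +
    ggplot2::labs(
      x = "significance score (toxic : non-toxic compound count)",
      y = NULL, colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot pathway enrichment results
#'
#' XD-score against Benjamini-Hochberg q-value (on a -log10 scale), with
#' the XD significance threshold drawn as a dashed line and point size
#' showing the seed overlap.
#'
#' @param object An [enrich()] result.
#' @param xd_threshold Dashed reference line; default 1.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tox_enrichment
#' @export
autoplot.tox_enrichment <- function(object, xd_threshold = 1, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$xd_score, y = -log10(pmax(.data$q_value, 1e-300)),
    size = .data$overlap, colour = .data$significant_xd
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = xd_threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "XD-score (deviation from mean pathway proximity)",
      y = expression(-log[10] ~ "q-value"),
      size = "seed overlap", colour = "XD > threshold"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a protein network with its causal overlay
#'
#' Confidence edges are drawn as segments whose width follows the
#' interaction confidence; causal edges are overlaid as arrows coloured by
#' mode of interaction. Layout is a deterministic Fruchterman-Reingold
#' embedding.
#'
#' @param object A [build_network()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot protein_network
#' @export
autoplot.protein_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(object$edges), directed = FALSE,
    vertices = as.data.frame(object$nodes)
  )
  set.seed(1) # deterministic layout only; no statistical consequence
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    protein_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
  )
  seg <- object$edges |>
    dplyr::left_join(nodes, by = c(protein_a = "protein_id")) |>
    dplyr::left_join(nodes, by = c(protein_b = "protein_id"),
                     suffix = c("", "_b"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b,
                   yend = .data$y_b, linewidth = .data$confidence),
      colour = "grey70"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5))
  if (nrow(object$causal_edges) > 0) {
    ca <- object$causal_edges |>
      dplyr::left_join(nodes, by = c(source_id = "protein_id")) |>
      dplyr::left_join(nodes, by = c(target_id = "protein_id"),
                       suffix = c("", "_b"))
    p <- p + ggplot2::geom_segment(
      data = ca,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b,
                   yend = .data$y_b, colour = factor(.data$moi)),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      linewidth = 0.5
    ) +
      ggplot2::labs(colour = "mode of interaction")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$protein_id),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "confidence")
}
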