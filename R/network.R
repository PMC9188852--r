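#' Build a confidence-weighted protein network
#'
#' Induced subgraph of a STRING-style edge list on a protein set: edges are
#' kept when both endpoints belong to the set and the combined score
#' reaches `min_score`; submitted proteins with no surviving edge remain as
#' isolated nodes. Scores are rescaled to confidence weights in [0, 1]
#' (`combined_score / 1000`). The undirected confidence layer built here
#' and the directed causal layer added by [overlay_causal()] are kept
#' separate: they come from different kinds of evidence and are never
#' merged.
#'
#' @param proteins Character vector (or tibble with `protein_id`) of
#'   proteins to induce on; must be non-empty.
#' @param edges Tibble from [read_string_edges()].
#' @param min_score Minimum combined score in [0, 1000]; default 400,
#'   STRING's conventional medium-confidence threshold.
#' @return An object of class `protein_network`: list with tibbles `nodes`
#'   (`protein_id`), `edges` (`protein_a`, `protein_b`, `confidence`) and
#'   `causal_edges` (`source_id`, `target_id`, `effect`, `moi`; empty until
#'   overlaid).
#' @examples
#' edges <- tibble::tibble(
#'   protein_a = "A", protein_b = "B", combined_score = 900L
#' )
#' build_network(c("A", "B", "C"), edges)
#' @export
build_network <- function(proteins, edges, min_score = 400) {
  if (is.data.frame(proteins)) proteins <- proteins$protein_id
  proteins <- unique(as.character(proteins))
  if (length(proteins) == 0) abort("protein set must be non-empty")
  if (min_score < 0 || min_score > 1000) abort("min_score must lie in [0, 1000]")

  kept <- dplyr::filter(
    edges,
    .data$protein_a %in% proteins,
    .data$protein_b %in% proteins,
    .data$protein_a != .data$protein_b,
    .data$combined_score >= min_score
  )
  kept <- if (nrow(kept) == 0) {
    tibble::tibble(
      protein_a = character(), protein_b = character(), confidence = numeric()
    )
  } else {
    kept |>
      dplyr::mutate(
        # canonical endpoint order makes the undirected layer simple
        a = pmin(.data$protein_a, .data$protein_b),
        b = pmax(.data$protein_a, .data$protein_b)
      ) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
      dplyr::transmute(
        protein_a = .data$a, protein_b = .data$b,
        confidence = .data$combined_score / 1000
      ) |>
      dplyr::arrange(.data$protein_a, .data$protein_b)
  }

  net <- structure(
    list(
      nodes = tibble::tibble(protein_id = sort(proteins)),
      edges = kept,
      causal_edges = tibble::tibble(
        source_id = character(), target_id = character(),
        effect = character(), moi = integer()
      )
    ),
    class = "protein_network"
  )
  ct_inform(
    "built network: %d nodes, %d confidence edges (min_score %d)",
    length(proteins), nrow(kept), as.integer(min_score)
  )
  net
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf(
    "<protein_network: %d nodes, %d confidence edges, %d causal edges>\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$causal_edges)
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x A `protein_network`.
#' @param ... Unused.
#' @method tidy protein_network
#' @export
tidy.protein_network <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$edges,
      from = .data$protein_a, to = .data$protein_b, layer = "confidence",
      weight = .data$confidence, effect = NA_character_, moi = NA_integer_
    ),
    dplyr::transmute(x$causal_edges,
      from = .data$source_id, to = .data$target_id, layer = "causal",
      weight = NA_real_, effect = .data$effect, moi = .data$moi
    )
  )
}

#' @rdname build_network
#' @method glance protein_network
#' @export
glance.protein_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_confidence_edges = nrow(x$edges),
    n_causal_edges = nrow(x$causal_edges)
  )
}

#' Packaged SIGNOR effect to mode-of-interaction mapping
#'
#' @return Tibble with columns `pattern`, `match` (`"prefix"` or
#'   `"exact"`), `category`.
#' @export
signor_effect_mapping <- function() {
  df <- readr::read_tsv(
    ct_resource("mappings", "signor_effects.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  df$category <- as.integer(df$category)
  assert_moa(df$category, allowed = 1:3)
  tibble::as_tibble(df)
}

#' Map a causal effect annotation to a mode-of-interaction category
#'
#' SIGNOR-style free-text effects are grouped into the same categories as
#' drug-target relations: effects starting with "up-regulates" are
#' positive modulation (1), "down-regulates" negative (2), and
#' non-directional effects ("form complex", "unknown") category 3.
#' Matching is case-insensitive; an unmapped effect is an error carrying
#' the term.
#'
#' @param effect Character vector of effect strings.
#' @param mapping Mapping table, default [signor_effect_mapping()].
#' @return Integer vector of categories.
#' @examples
#' map_effect_to_moi("up-regulates quantity by expression")
#' @export
map_effect_to_moi <- function(effect, mapping = signor_effect_mapping()) {
  key <- tolower(trimws(effect))
  out <- rep(NA_integer_, length(key))
  for (j in seq_len(nrow(mapping))) {
    pat <- tolower(mapping$pattern[j])
    hit <- if (mapping$match[j] == "prefix") startsWith(key, pat) else key == pat
    out[is.na(out) & hit] <- mapping$category[j]
  }
  if (anyNA(out)) {
    abort(sprintf(
      "unmapped causal effect term(s): %s",
      paste(sprintf("'%s'", unique(effect[is.na(out)])), collapse = ", ")
    ))
  }
  out
}

#' Overlay directed causal edges on a protein network
#'
#' Filters SIGNOR-format records to protein-protein interactions whose two
#' endpoints are both network nodes, maps each effect to a
#' mode-of-interaction category, and adds the resulting directed edges as
#' the network's causal layer. Duplicate (source, target, effect) records
#' collapse to one edge. No nodes are ever added: records with an endpoint
#' outside the network are dropped and counted.
#'
#' @param network A [build_network()] result.
#' @param records Tibble from [read_signor_tsv()].
#' @param mapping Effect mapping, default [signor_effect_mapping()].
#' @return The network with `causal_edges` populated.
#' @export
overlay_causal <- function(network, records, mapping = signor_effect_mapping()) {
  stopifnot(inherits(network, "protein_network"))
  nodes <- network$nodes$protein_id

  pp <- dplyr::filter(
    records,
    tolower(.data$type_a) == "protein", tolower(.data$type_b) == "protein"
  )
  n_nonprotein <- nrow(records) - nrow(pp)
  in_net <- dplyr::filter(pp, .data$id_a %in% nodes, .data$id_b %in% nodes)
  n_outside <- nrow(pp) - nrow(in_net)

  causal <- in_net |>
    dplyr::distinct(.data$id_a, .data$id_b, .data$effect) |>
    dplyr::transmute(
      source_id = .data$id_a,
      target_id = .data$id_b,
      effect = .data$effect,
      moi = map_effect_to_moi(.data$effect, mapping)
    ) |>
    dplyr::arrange(.data$source_id, .data$target_id, .data$effect)

  ct_inform(
    "causal overlay: %d edges added (%d non-protein rows dropped, %d with endpoints outside the network)",
    nrow(causal), n_nonprotein, n_outside
  )
  network$causal_edges <- causal
  network
}

#' Write a protein network as GraphML (and an edge-list TSV mirror)
#'
#' The GraphML graph is directed so that the causal layer keeps its
#' direction; each undirected confidence edge is written once with edge
#' attribute `layer = "confidence"`, causal edges with `layer = "causal"`
#' plus `effect` and `moi`. Node attribute `gene_name` is attached when a
#' mapping is supplied.
#'
#' @param network A `protein_network`.
#' @param path Output `.graphml` path.
#' @param gene_names Optional tibble `protein_id`, `gene_name`.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, gene_names = NULL) {
  stopifnot(inherits(network, "protein_network"))
  el <- tidy.protein_network(network)
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(el),
    directed = TRUE,
    vertices = as.data.frame(network$nodes)
  )
  if (!is.null(gene_names)) {
    idx <- match(igraph::V(g)$name, gene_names$protein_id)
    igraph::V(g)$gene_name <- ifelse(
      is.na(idx), igraph::V(g)$name, gene_names$gene_name[idx]
    )
  }
  # igraph refuses NA attribute types in graphml; encode absent as sentinel
  igraph::E(g)$weight <- ifelse(is.na(igraph::E(g)$weight), -1, igraph::E(g)$weight)
  igraph::E(g)$effect <- ifelse(is.na(igraph::E(g)$effect), "", igraph::E(g)$effect)
  igraph::E(g)$moi <- ifelse(is.na(igraph::E(g)$moi), -1L, igraph::E(g)$moi)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "protein_network"))
  write_results_tsv(tidy.protein_network(network), path)
}
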