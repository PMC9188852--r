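#' Configuration for topology-based pathway enrichment
#'
#' @param restart_prob Restart probability of the random walk, in (0, 1];
#'   default 0.5. Higher values keep probability mass closer to the seeds.
#' @param tol L1 convergence tolerance of the walk iteration; default 1e-10.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual. Default 1000.
#' @param min_overlap Minimum number of in-network members for a pathway to
#'   be scored; default 1.
#' @param xd_threshold XD-score above which a pathway is flagged
#'   significant; default 1 (the conventional threshold for this score).
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(restart_prob = 0.5, tol = 1e-10,
                              max_iter = 1000, min_overlap = 1,
                              xd_threshold = 1.0) {
  stopifnot(
    restart_prob > 0, restart_prob <= 1, tol > 0,
    max_iter >= 1, min_overlap >= 1
  )
  structure(
    list(
      restart_prob = restart_prob, tol = tol, max_iter = max_iter,
      min_overlap = min_overlap, xd_threshold = xd_threshold
    ),
    class = "enrichment_config"
  )
}

# column-stochastic transition matrix of the confidence layer; dangling
# nodes keep their mass via a self-loop so total probability is conserved
transition_matrix <- function(network) {
  nodes <- network$nodes$protein_id
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges) > 0) {
    ia <- match(network$edges$protein_a, nodes)
    ib <- match(network$edges$protein_b, nodes)
    A[cbind(ia, ib)] <- network$edges$confidence
    A[cbind(ib, ia)] <- network$edges$confidence
  }
  strength <- colSums(A)
  dangling <- strength == 0
  W <- A
  if (any(!dangling)) {
    W[, !dangling] <- sweep(A[, !dangling, drop = FALSE], 2, strength[!dangling], "/")
  }
  W[cbind(which(dangling), which(dangling))] <- 1
  W
}

#' Random walk with restart over the confidence layer
#'
#' Iterates `s <- (1 - r) * W %*% s + r * e` until the L1 change drops
#' below `tol`, where `W` is the degree-normalized (column-stochastic)
#' confidence-weighted adjacency and `e` is uniform over the seed proteins.
#' The converged vector is the stationary visiting probability of each
#' network node relative to the seed set; probabilities sum to 1, and in
#' disconnected graphs all mass stays in the seeds' components.
#'
#' @param network A [build_network()] result.
#' @param seeds Character vector of seed proteins; at least one must be a
#'   network node (seeds outside the network are ignored with a message).
#' @param config An [enrichment_config()].
#' @return Named numeric vector of node scores summing to 1.
#' @examples
#' net <- build_network(
#'   c("A", "B"),
#'   tibble::tibble(protein_a = "A", protein_b = "B", combined_score = 800L)
#' )
#' rwr(net, "A")
#' @export
rwr <- function(network, seeds, config = enrichment_config()) {
  stopifnot(inherits(network, "protein_network"))
  nodes <- network$nodes$protein_id
  seeds_in <- intersect(unique(seeds), nodes)
  if (length(seeds_in) == 0) abort("no seed protein is present in the network")
  if (length(seeds_in) < length(unique(seeds))) {
    ct_inform(
      "%d of %d seed(s) absent from the network and ignored",
      length(unique(seeds)) - length(seeds_in), length(unique(seeds))
    )
  }
  W <- transition_matrix(network)
  r <- config$restart_prob
  e <- setNames(numeric(length(nodes)), nodes)
  e[seeds_in] <- 1 / length(seeds_in)

  s <- e
  for (iter in seq_len(config$max_iter)) {
    s_new <- (1 - r) * drop(W %*% s) + r * e
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < config$tol) return(s)
  }
  abort(sprintf(
    "random walk did not converge in %d iterations (residual %.3g)",
    config$max_iter, delta
  ))
}

#' XD-style pathway deviation scores
#'
#' Node scores are rescaled so their mean over all network nodes is 1; a
#' pathway's raw score is the mean rescaled score over its in-network
#' members, and its XD-score is the deviation of that raw score from the
#' mean raw score across all scored pathways. Pathways with fewer than
#' `min_members` in-network members are skipped (reported via the
#' `scored` column).
#'
#' @param node_scores Named vector from [rwr()].
#' @param pathways Tibble from [read_gmt()].
#' @param min_members Minimum in-network members to score; default 1.
#' @return Tibble `pathway_id`, `name`, `n_in_network`, `raw_score`,
#'   `xd_score`, `scored`.
#' @export
xd_scores <- function(node_scores, pathways, min_members = 1) {
  nodes <- names(node_scores)
  scaled <- node_scores / mean(node_scores)
  members_in <- lapply(pathways$members, intersect, x = nodes)
  n_in <- lengths(members_in)
  scored <- n_in >= min_members
  if (!any(scored)) abort("no pathway has enough members in the network to score")

  raw <- rep(NA_real_, nrow(pathways))
  raw[scored] <- vapply(
    members_in[scored], function(m) mean(scaled[m]), numeric(1)
  )
  xd <- raw - mean(raw[scored])
  if (any(!scored)) {
    ct_inform("%d pathway(s) had no scoreable member in the network", sum(!scored))
  }
  tibble::tibble(
    pathway_id = pathways$pathway_id,
    name = pathways$name,
    n_in_network = n_in,
    raw_score = raw,
    xd_score = xd,
    scored = scored
  )
}

#' One-sided Fisher (hypergeometric) overlap test
#'
#' Exact upper-tail probability of drawing at least the observed overlap
#' between the seed set and a pathway's members when sampling the seed set
#' from the network universe without replacement.
#'
#' @param seeds Character vector of seed proteins.
#' @param pathway_members Character vector of pathway members.
#' @param universe Character vector, the network node set (non-empty;
#'   seeds and members are intersected with it).
#' @return A p-value in [0, 1].
#' @examples
#' fisher_overlap(letters[1:5], letters[2:5], letters[1:20])
#' @export
fisher_overlap <- function(seeds, pathway_members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe must be non-empty")
  seeds <- intersect(unique(seeds), universe)
  memb <- intersect(unique(pathway_members), universe)
  x <- length(intersect(seeds, memb))
  phyper(
    q = x - 1, m = length(memb), n = length(universe) - length(memb),
    k = length(seeds), lower.tail = FALSE
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment across the p-values of one
#' enrichment run; order-equivariant.
#'
#' @param p_values Numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Topology-based pathway enrichment of a seed protein set
#'
#' Composition of the enrichment stages: a random walk with restart from
#' the seed proteins over the network's confidence layer ([rwr()]),
#' XD-style deviation scores per pathway ([xd_scores()]), a one-sided
#' Fisher overlap test per pathway against the network universe
#' ([fisher_overlap()]) and Benjamini-Hochberg correction across all
#' scored pathways ([bh_qvalues()]).
#'
#' @param network A [build_network()] result.
#' @param seeds Character vector of seed proteins.
#' @param pathways Tibble from [read_gmt()].
#' @param config An [enrichment_config()].
#' @return A `tox_enrichment` tibble with columns `pathway_id`, `name`,
#'   `xd_score`, `overlap`, `pathway_size_in_network`, `fisher_p`,
#'   `q_value`, `significant_xd`, sorted by descending XD-score.
#' @export
enrich <- function(network, seeds, pathways, config = enrichment_config()) {
  node_scores <- rwr(network, seeds, config)
  xd <- xd_scores(node_scores, pathways, min_members = config$min_overlap)
  nodes <- names(node_scores)
  seeds_in <- intersect(unique(seeds), nodes)

  res <- xd |>
    dplyr::filter(.data$scored) |>
    dplyr::mutate(
      overlap = vapply(
        pathways$members[match(.data$pathway_id, pathways$pathway_id)],
        function(m) length(intersect(intersect(m, nodes), seeds_in)),
        integer(1)
      ),
      fisher_p = vapply(
        pathways$members[match(.data$pathway_id, pathways$pathway_id)],
        fisher_overlap, numeric(1), seeds = seeds_in, universe = nodes
      )
    ) |>
    dplyr::mutate(
      q_value = bh_qvalues(.data$fisher_p),
      significant_xd = .data$xd_score > config$xd_threshold
    ) |>
    dplyr::select(
      "pathway_id", "name", "xd_score",
      "overlap", pathway_size_in_network = "n_in_network",
      "fisher_p", "q_value", "significant_xd"
    ) |>
    dplyr::arrange(dplyr::desc(.data$xd_score), .data$pathway_id)

  class(res) <- c("tox_enrichment", class(res))
  res
}
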