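#' Scoring configuration for the toxicity group contrast
#'
#' @param ratio_cutoff Minimum toxic:non-toxic compound-count quotient for a
#'   target to be flagged significant when both groups are connected;
#'   default 5 (toxic-group involvement at least five times the non-toxic).
#' @param only_tox_cutoff Minimum raw toxic-group compound count when the
#'   target is connected only to the toxic group; default 5.
#' @param normalize_by_group_size Divide counts by group sizes before taking
#'   the quotient (useful for imbalanced groups); the only-toxic rule still
#'   applies to the raw count. Default off: absolute counts.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(ratio_cutoff = 5, only_tox_cutoff = 5,
                           normalize_by_group_size = FALSE) {
  stopifnot(ratio_cutoff > 0, only_tox_cutoff > 0)
  structure(
    list(
      ratio_cutoff = ratio_cutoff,
      only_tox_cutoff = only_tox_cutoff,
      normalize_by_group_size = isTRUE(normalize_by_group_size)
    ),
    class = "scoring_config"
  )
}

#' Significance score of a target's toxic-group involvement
#'
#' The per-target contrast statistic: with `n_nontox > 0` the score is the
#' plain quotient `n_tox / n_nontox`, significant at `ratio_cutoff`; with
#' `n_nontox = 0` (target connected only to the toxic group) the score is
#' `n_tox` itself, significant at `only_tox_cutoff`. With normalization
#' enabled, counts are first divided by the group sizes, but the
#' only-toxic rule keeps using the raw toxic count.
#'
#' @param n_tox,n_nontox Distinct-compound counts per group (vectorized;
#'   both zero is an error).
#' @param config A [scoring_config()].
#' @param group_sizes Named numeric `c(tox = ..., nontox = ...)`, required
#'   when `normalize_by_group_size` is on.
#' @return Tibble with columns `score`, `significant`.
#' @examples
#' significance_score(16, 1) # quotient 16, significant
#' significance_score(4, 0)  # only-toxic count below cutoff
#' @export
significance_score <- function(n_tox, n_nontox, config = scoring_config(),
                               group_sizes = NULL) {
  stopifnot(length(n_tox) == length(n_nontox))
  if (any(n_tox < 0 | n_nontox < 0)) abort("counts must be non-negative")
  if (any(n_tox + n_nontox == 0)) {
    abort("a target with zero compounds in both groups cannot be scored")
  }
  t <- as.numeric(n_tox)
  u <- as.numeric(n_nontox)
  if (config$normalize_by_group_size) {
    if (is.null(group_sizes) || !all(c("tox", "nontox") %in% names(group_sizes))) {
      abort("group_sizes = c(tox = , nontox = ) is required when normalizing")
    }
    t <- t / group_sizes[["tox"]]
    u <- u / group_sizes[["nontox"]]
  }
  only_tox <- u == 0
  score <- ifelse(only_tox, t, t / u)
  significant <- ifelse(
    only_tox,
    as.numeric(n_tox) >= config$only_tox_cutoff,
    score >= config$ratio_cutoff
  )
  tibble::tibble(score = score, significant = significant)
}

#' Score every target's differential connectivity between compound groups
#'
#' For each (protein, direction) present in either group's resolved causal
#' profile -- direction 1 being positive modulation ("upregulated by"),
#' direction 2 negative ("downregulated by") -- counts the distinct
#' compounds connected per group and applies [significance_score()].
#' Category-3 records (active, direction unknown) never contribute to
#' either direction, and repeated evidence rows for the same compound
#' count once.
#'
#' @param tox,nontox Resolved profiles (tibbles with `compound_id`,
#'   `target_id`, `category`) for the toxic and non-toxic groups.
#' @param config A [scoring_config()].
#' @param group_sizes Optional named counts for normalization; defaults to
#'   the number of distinct compounds in each profile when normalization is
#'   on.
#' @param gene_names Optional tibble `protein_id`, `gene_name` for display
#'   names.
#' @return A `tox_significance` tibble with columns `protein_id`
#'   (+ `gene_name` if mapped), `direction`, `n_tox`, `n_nontox`, `score`,
#'   `significant`, sorted by descending score then protein id.
#' @export
score_profile <- function(tox, nontox, config = scoring_config(),
                          group_sizes = NULL, gene_names = NULL) {
  count_dir <- function(profile, col) {
    profile |>
      dplyr::filter(.data$category %in% c(1L, 2L)) |>
      dplyr::distinct(.data$compound_id, .data$target_id, .data$category) |>
      dplyr::count(.data$target_id, .data$category, name = col)
  }
  counts <- dplyr::full_join(
    count_dir(tox, "n_tox"), count_dir(nontox, "n_nontox"),
    by = c("target_id", "category")
  ) |>
    tidyr::replace_na(list(n_tox = 0L, n_nontox = 0L))

  if (config$normalize_by_group_size && is.null(group_sizes)) {
    group_sizes <- c(
      tox = dplyr::n_distinct(tox$compound_id),
      nontox = dplyr::n_distinct(nontox$compound_id)
    )
  }

  scored <- significance_score(
    counts$n_tox, counts$n_nontox, config = config, group_sizes = group_sizes
  )
  out <- tibble::tibble(
    protein_id = counts$target_id,
    direction = counts$category,
    n_tox = counts$n_tox,
    n_nontox = counts$n_nontox,
    score = scored$score,
    significant = scored$significant
  )
  if (!is.null(gene_names)) {
    out <- dplyr::left_join(out, gene_names, by = "protein_id") |>
      dplyr::relocate("gene_name", .after = "protein_id")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$protein_id)
  ct_inform(
    "scored %d (protein, direction) pairs; %d significant",
    nrow(out), sum(out$significant)
  )
  class(out) <- c("tox_significance", class(out))
  out
}

#' Significant proteins of one modulation direction
#'
#' Convenience accessor over a [score_profile()] table: the significant
#' protein ids for direction 1 (upregulated-by-toxic-group analog) or 2
#' (downregulated).
#'
#' @param scores A `tox_significance` tibble.
#' @param direction 1 or 2.
#' @return Character vector of protein ids.
#' @export
significant_proteins <- function(scores, direction) {
  assert_moa(direction, allowed = 1:2, what = "direction")
  scores$protein_id[scores$significant & scores$direction == direction]
}
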