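#' Resolve the category set observed for one drug-target pair
#'
#' Sub-group semantics of the four-level coding: categories 1 and 2
#' (directional modulation) are each sub-groups of 3 (active, direction
#' unknown), so \{1,3\} and \{2,3\} are not contradictions and resolve to
#' the more specific member. Opposite directions (1 with 2) contradict, and
#' inactive (4) contradicts any active category; contradictory pairs are
#' removed, never adjudicated.
#'
#' @param categories Non-empty vector of categories in 1:4 (duplicates
#'   ignored).
#' @return The resolved category as an integer, or `NA_integer_` when the
#'   set is contradictory and the pair must be removed.
#' @examples
#' resolve_pair(c(1, 3)) # 1: sub-group of 3, kept as the specific label
#' resolve_pair(c(1, 2)) # NA: opposite directions, removed
#' @export
resolve_pair <- function(categories) {
  if (length(categories) == 0) abort("category set must be non-empty")
  cats <- unique(as.integer(categories))
  assert_moa(cats)
  if (1L %in% cats && 2L %in% cats) return(NA_integer_)
  if (4L %in% cats && length(cats) > 1) return(NA_integer_)
  if (1L %in% cats) return(1L)
  if (2L %in% cats) return(2L)
  if (3L %in% cats) return(3L)
  4L
}

#' Remove contradictory annotations from a causal profile
#'
#' Groups the unique (compound, target, category) connections of a profile
#' by drug-target pair, resolves each pair's category set with
#' [resolve_pair()], and removes every connection belonging to a
#' contradictory pair. The bookkeeping counts connections (triples), not
#' pairs: both members of a contradictory \{1,2\} pair count as removed,
#' and all members of an agreeing pair count as retained, which reproduces
#' the unique-connection arithmetic used to report consistency percentages.
#'
#' @param profile Tibble with columns `compound_id`, `target_id`,
#'   `category` (unique triples; extra columns such as `source` are
#'   carried through merged).
#' @return An object of class `consistency_result`: list with
#'   \describe{
#'     \item{profile}{tibble of one row per surviving pair with its
#'       resolved `category`;}
#'     \item{report}{one-row tibble `n_input_unique`, `n_removed`,
#'       `n_retained`, `percent_consistent`.}
#'   }
#'   [generics::tidy()] returns the resolved profile,
#'   [generics::glance()] the report.
#' @examples
#' prof <- tibble::tibble(
#'   compound_id = c("c", "c"), target_id = c("t", "t"), category = c(1L, 3L)
#' )
#' apply_consistency(prof)
#' @export
apply_consistency <- function(profile) {
  need <- c("compound_id", "target_id", "category")
  missing <- setdiff(need, names(profile))
  if (length(missing) > 0) {
    abort(sprintf("profile is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  assert_moa(profile$category)
  uniq <- dplyr::distinct(
    tibble::as_tibble(profile), .data$compound_id, .data$target_id,
    .data$category, .keep_all = TRUE
  )
  has_source <- "source" %in% names(uniq)

  resolved <- uniq |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(
      n_connections = dplyr::n(),
      category = resolve_pair(.data$category),
      source = if (has_source) paste(sort(unique(.data$source)), collapse = ",") else NA_character_,
      .groups = "drop"
    )

  n_input <- nrow(uniq)
  removed_pairs <- dplyr::filter(resolved, is.na(.data$category))
  n_removed <- sum(removed_pairs$n_connections)
  n_retained <- n_input - n_removed

  out_cols <- c("compound_id", "target_id", "category", if (has_source) "source")
  out <- resolved |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::select(dplyr::all_of(out_cols)) |>
    dplyr::arrange(.data$compound_id, .data$target_id)

  report <- tibble::tibble(
    n_input_unique = n_input,
    n_removed = n_removed,
    n_retained = n_retained,
    percent_consistent = if (n_input > 0) 100 * n_retained / n_input else NA_real_
  )
  ct_inform(
    "consistency: %d unique connections, %d retained, %d removed (%.1f%% consistent)",
    n_input, n_retained, n_removed, report$percent_consistent %||% NA_real_
  )
  structure(list(profile = out, report = report), class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<consistency_result: %d unique connections, %d retained, %d removed (%.1f%% consistent)>\n",
    r$n_input_unique, r$n_retained, r$n_removed, r$percent_consistent
  ))
  print(x$profile, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname apply_consistency
#' @param x A `consistency_result`.
#' @param ... Unused.
#' @method tidy consistency_result
#' @export
tidy.consistency_result <- function(x, ...) x$profile

#' @rdname apply_consistency
#' @method glance consistency_result
#' @export
glance.consistency_result <- function(x, ...) x$report
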