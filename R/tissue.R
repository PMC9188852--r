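#' Restrict a causal profile to targets expressed in a tissue
#'
#' Keeps a record iff its target appears in the expression table and the
#' tissue of interest is among that protein's listed tissues
#' (case-insensitive comparison). Expression is presence/absence only: no
#' abundance threshold is applied. Targets missing from the expression
#' table altogether are dropped and counted separately, because absence
#' from the table reflects the repository's coverage (not evidence of
#' non-expression) and deserves scrutiny when a known target disappears.
#'
#' @param profile Tibble with a `target_id` column (e.g. a resolved
#'   profile from [apply_consistency()]).
#' @param expression Long tibble from [read_expression_table()]
#'   (`protein_id`, `tissue`).
#' @param tissue Tissue of interest, e.g. `"liver"`; case-insensitive.
#' @return The retained subset of `profile`, with attribute `tissue_filter`
#'   (one-row tibble: `n_retained`, `n_dropped`, `n_unmeasured_targets`).
#' @examples
#' prof <- tibble::tibble(compound_id = "c", target_id = "P23219", category = 2L)
#' expr <- tibble::tibble(protein_id = "P23219", tissue = "Liver")
#' filter_tissue(prof, expr, "liver")
#' @export
filter_tissue <- function(profile, expression, tissue) {
  if (!is.character(tissue) || length(tissue) != 1 || !nzchar(tissue)) {
    abort("tissue must be a single non-empty string")
  }
  if (!"target_id" %in% names(profile)) abort("profile is missing column: target_id")
  stopifnot(all(c("protein_id", "tissue") %in% names(expression)))

  expressed_here <- unique(
    expression$protein_id[tolower(expression$tissue) == tolower(tissue)]
  )
  if (length(expressed_here) == 0) {
    warn(sprintf("tissue '%s' matches no protein in the expression table", tissue))
  }
  measured <- unique(expression$protein_id)

  keep <- profile$target_id %in% expressed_here
  unmeasured <- unique(profile$target_id[!profile$target_id %in% measured])
  out <- tibble::as_tibble(profile)[keep, ]

  stats <- tibble::tibble(
    n_retained = nrow(out),
    n_dropped = sum(!keep),
    n_unmeasured_targets = length(unmeasured)
  )
  ct_inform(
    "tissue filter '%s': %d records retained, %d dropped (%d target(s) absent from the expression table)",
    tissue, stats$n_retained, stats$n_dropped, stats$n_unmeasured_targets
  )
  attr(out, "tissue_filter") <- stats
  out
}
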