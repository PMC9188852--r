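#' Build a harmonized causal drug-target profile
#'
#' Unions mode-of-action evidence from up to four sources -- curated
#' mechanism records, assay text mining, IUPHAR interactions and a DrugBank
#' skim -- into one table of causal assertions
#' (`compound_id`, `target_id`, `category`), optionally restricted to a
#' compound group. Each source's vocabulary is translated with its mapping
#' table; assay records go through [annotate_assays()] and excluded records
#' are dropped. The result is deduplicated to unique
#' (compound, target, category) triples with source and evidence merged,
#' ready for [apply_consistency()].
#'
#' Targets are expected to be human single proteins; that filtering is the
#' responsibility of the input exports.
#'
#' @param mechanisms Tibble from [read_chembl_mechanisms()], or `NULL`.
#' @param assays Tibble from [read_chembl_assays()], or `NULL`.
#' @param iuphar Tibble from [read_iuphar_interactions()], or `NULL`.
#' @param drugbank Tibble from [read_drugbank_skim()], or `NULL`.
#' @param compounds Optional compound filter: a [read_group_list()] result
#'   or character vector; records for other compounds are dropped.
#' @param rules,active_cutoff Passed to [annotate_assays()].
#' @return Tibble with columns `compound_id`, `target_id`, `category`,
#'   `source` (comma-joined contributing sources) and `evidence`.
#' @examples
#' mech <- tibble::tibble(
#'   compound_id = "CHEMBL25", target_id = "P23219", action_type = "INHIBITOR"
#' )
#' build_profile(mechanisms = mech)
#' @export
build_profile <- function(mechanisms = NULL, assays = NULL, iuphar = NULL,
                          drugbank = NULL, compounds = NULL,
                          rules = assay_keyword_rules(), active_cutoff = 5) {
  if (is.null(mechanisms) && is.null(assays) && is.null(iuphar) && is.null(drugbank)) {
    abort("at least one source collection must be supplied")
  }
  parts <- list()

  if (!is.null(mechanisms) && nrow(mechanisms) > 0) {
    parts$chembl_mechanism <- tibble::tibble(
      compound_id = mechanisms$compound_id,
      target_id = mechanisms$target_id,
      category = map_chembl_action(mechanisms$action_type),
      source = "chembl_mechanism",
      evidence = paste0("action_type=", mechanisms$action_type)
    )
  }
  if (!is.null(iuphar) && nrow(iuphar) > 0) {
    parts$iuphar <- tibble::tibble(
      compound_id = iuphar$compound_id,
      target_id = iuphar$target_id,
      category = map_iuphar_action(iuphar$actions),
      source = "iuphar",
      evidence = paste0("actions=", iuphar$actions)
    )
  }
  if (!is.null(drugbank) && nrow(drugbank) > 0) {
    parts$drugbank <- tibble::tibble(
      compound_id = drugbank$compound_id,
      target_id = drugbank$target_id,
      category = map_drugbank_action(drugbank$action),
      source = "drugbank",
      evidence = paste0("action=", drugbank$action)
    )
  }
  if (!is.null(assays) && nrow(assays) > 0) {
    annotated <- annotate_assays(assays, rules = rules, active_cutoff = active_cutoff)
    kept <- dplyr::filter(annotated, !.data$excluded)
    parts$chembl_assay <- tibble::tibble(
      compound_id = kept$compound_id,
      target_id = kept$target_id,
      category = kept$category,
      source = "chembl_assay",
      evidence = sprintf("pchembl=%s; %s", format(kept$pchembl),
                         substr(kept$assay_description, 1, 80))
    )
  }

  records <- dplyr::bind_rows(parts)
  for (src in names(parts)) {
    ct_inform("source %s contributed %d records", src, nrow(parts[[src]]))
  }

  if (!is.null(compounds)) {
    records <- dplyr::filter(records, .data$compound_id %in% as.character(compounds))
    if (nrow(records) == 0) {
      warn("no records remain after restricting to the compound group")
    }
  }

  records |>
    dplyr::group_by(.data$compound_id, .data$target_id, .data$category) |>
    dplyr::summarise(
      source = paste(sort(unique(.data$source)), collapse = ","),
      evidence = paste(unique(.data$evidence), collapse = " | "),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$compound_id, .data$target_id, .data$category)
}
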