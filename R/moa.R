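#' Packaged mode-of-action vocabulary tables
#'
#' Returns the translation table shipped with the package for one of the
#' source vocabularies: ChEMBL `action_type` terms, IUPHAR `actions` terms
#' or DrugBank action terms, each mapped to a mode-of-action category (see
#' [moa_categories]). The ChEMBL and IUPHAR tables carry the published
#' vocabulary; the DrugBank table is a reconstruction under the same
#' four-category semantics (DrugBank's own action vocabulary is not fixed).
#'
#' @param source One of `"chembl"`, `"iuphar"`, `"drugbank"`.
#' @return Tibble with columns `term`, `category`.
#' @examples
#' moa_mapping("chembl")
#' @export
moa_mapping <- function(source = c("chembl", "iuphar", "drugbank")) {
  source <- match.arg(source)
  file <- switch(source,
    chembl = "chembl_actions.tsv",
    iuphar = "iuphar_actions.tsv",
    drugbank = "drugbank_actions.tsv"
  )
  df <- readr::read_tsv(
    ct_resource("mappings", file),
    show_col_types = FALSE, progress = FALSE
  )
  names(df)[1] <- "term"
  df$category <- as.integer(df$category)
  assert_moa(df$category, allowed = 1:3)
  tibble::as_tibble(df)
}

# shared exact-match mapper: trim + case-fold, error on unmapped terms
map_vocabulary <- function(terms, mapping, source) {
  key <- tolower(trimws(terms))
  idx <- match(key, tolower(trimws(mapping$term)))
  unmapped <- unique(terms[is.na(idx) & !is.na(terms)])
  if (anyNA(terms)) abort(sprintf("%s: missing (NA) action term", source))
  if (length(unmapped) > 0) {
    abort(sprintf(
      "unmapped %s vocabulary term(s): %s",
      source, paste(sprintf("'%s'", unmapped), collapse = ", ")
    ))
  }
  mapping$category[idx]
}

#' Translate source action terms to mode-of-action categories
#'
#' Each source database annotates compound-target pairs in its own
#' vocabulary; these functions translate a term into the common 1/2/3
#' category scheme (positive / negative / unspecified direction). Matching
#' is exact after trimming and case-folding. An unmapped term is an error
#' carrying the term -- it is never silently treated as category 3, so
#' vocabulary drift in an input file surfaces immediately.
#'
#' @param action_type,actions,term Character vector of source terms.
#' @param mapping Translation table (`term`, `category`); defaults to the
#'   packaged table for the source (see [moa_mapping()]).
#' @return Integer vector of categories.
#' @examples
#' map_chembl_action(c("AGONIST", "BLOCKER", "MODULATOR"))
#' map_iuphar_action("Feedback inhibition")
#' map_drugbank_action("inhibitor")
#' @export
map_chembl_action <- function(action_type, mapping = moa_mapping("chembl")) {
  map_vocabulary(action_type, mapping, "ChEMBL action_type")
}

#' @rdname map_chembl_action
#' @export
map_iuphar_action <- function(actions, mapping = moa_mapping("iuphar")) {
  map_vocabulary(actions, mapping, "IUPHAR actions")
}

#' @rdname map_chembl_action
#' @export
map_drugbank_action <- function(term, mapping = moa_mapping("drugbank")) {
  map_vocabulary(term, mapping, "DrugBank action")
}
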