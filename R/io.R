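#' @name io_formats
#' @title File dialects read and written by the pipeline
#'
#' @description
#' The pipeline runs entirely from flat-file exports that mirror the source
#' databases' download formats, one reader per dialect. Every reader
#' validates its required columns (an informative error names any missing
#' column), renames identifier columns to the package-wide canonical names
#' (`compound_id` for ChEMBL-style compound identifiers, `target_id` /
#' `protein_id` for UniProt-style accessions), reports the number of rows
#' parsed, and returns a tibble. The delimiter is taken from the file
#' extension (`.tsv`/`.txt` tab, `.csv` comma), never sniffed.
#'
#' Dialect columns:
#' \describe{
#'   \item{mechanisms}{`molecule_chembl_id`, `accession`, `action_type`}
#'   \item{assays}{`molecule_chembl_id`, `accession`, `assay_description`,
#'     `pchembl_value`, `activity_comment`}
#'   \item{iuphar}{`ligand_chembl_id`, `target_uniprot_id`, `actions`}
#'   \item{drugbank skim}{`compound_chembl_id`, `uniprot_id`, `action`}
#'   \item{expression}{`protein_id`, `tissues` (semicolon-separated)}
#'   \item{string edges}{`protein1`, `protein2`, `combined_score` (0--1000)}
#'   \item{signor}{`typea`, `ida`, `typeb`, `idb`, `effect`}
#' }
NULL

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tsv = "\t", txt = "\t", tab = "\t", csv = ",",
    abort(sprintf("cannot infer delimiter from extension '.%s' of '%s'", ext, path))
  )
}

read_table_file <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(
    path,
    delim = delim_for(path), show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, na = c("", "NA")
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "'%s' is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  df
}

#' Read a compound group list
#'
#' One compound identifier per line; lines starting with `#` and blank lines
#' are ignored. Duplicate identifiers are dropped (order-preserving) with a
#' warning; an empty list is an error.
#'
#' @param path Path to the plain-text list.
#' @param label Group label; defaults to the file name without extension.
#' @return An object of class `compound_group`: a character vector of unique
#'   identifiers with attribute `label`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# toxic set", "CHEMBL25", "CHEMBL521"), f)
#' read_group_list(f, label = "mostTOX")
#' @export
read_group_list <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!nzchar(label)) abort("group label must be non-empty")
  lines <- readLines(path, warn = FALSE)
  ids <- trimws(lines)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0) abort(sprintf("compound group list '%s' is empty", path))
  dup <- duplicated(ids)
  if (any(dup)) {
    warn(sprintf(
      "%d duplicate compound id(s) in '%s' (e.g. %s); keeping first occurrence",
      sum(dup), path, ids[dup][1]
    ))
    ids <- ids[!dup]
  }
  ct_inform("read %d compound ids for group '%s'", length(ids), label)
  structure(ids, label = label, class = c("compound_group", "character"))
}

#' @export
print.compound_group <- function(x, ...) {
  cat(sprintf("<compound_group '%s': %d ids>\n", attr(x, "label"), length(x)))
  print(unclass(head(x, 10)))
  if (length(x) > 10) cat(sprintf("... and %d more\n", length(x) - 10))
  invisible(x)
}

#' Read ChEMBL-style mechanism records
#'
#' @param path TSV/CSV with columns `molecule_chembl_id`, `accession`,
#'   `action_type`.
#' @return Tibble with columns `compound_id`, `target_id`, `action_type`.
#' @export
read_chembl_mechanisms <- function(path) {
  df <- read_table_file(path, c("molecule_chembl_id", "accession", "action_type"))
  out <- tibble::tibble(
    compound_id = as.character(df$molecule_chembl_id),
    target_id = as.character(df$accession),
    action_type = as.character(df$action_type)
  )
  ct_inform("read %d mechanism rows from %s", nrow(out), path)
  out
}

#' Read ChEMBL-style assay bioactivity records
#'
#' @param path TSV/CSV with columns `molecule_chembl_id`, `accession`,
#'   `assay_description`, `pchembl_value`, `activity_comment`.
#' @return Tibble with columns `compound_id`, `target_id`,
#'   `assay_description`, `pchembl` (double, `NA` when unreported) and
#'   `activity_comment` (character, `NA` when absent).
#' @export
read_chembl_assays <- function(path) {
  df <- read_table_file(path, c(
    "molecule_chembl_id", "accession", "assay_description",
    "pchembl_value", "activity_comment"
  ))
  pchembl <- suppressWarnings(as.numeric(df$pchembl_value))
  if (any(pchembl < 0, na.rm = TRUE)) {
    abort(sprintf("'%s' contains negative pchembl_value entries", path))
  }
  out <- tibble::tibble(
    compound_id = as.character(df$molecule_chembl_id),
    target_id = as.character(df$accession),
    assay_description = as.character(df$assay_description),
    pchembl = pchembl,
    activity_comment = as.character(df$activity_comment)
  )
  ct_inform("read %d assay rows from %s", nrow(out), path)
  out
}

#' Read IUPHAR-style interaction records
#'
#' @param path TSV/CSV with columns `ligand_chembl_id`, `target_uniprot_id`,
#'   `actions`.
#' @return Tibble with columns `compound_id`, `target_id`, `actions`.
#' @export
read_iuphar_interactions <- function(path) {
  df <- read_table_file(path, c("ligand_chembl_id", "target_uniprot_id", "actions"))
  out <- tibble::tibble(
    compound_id = as.character(df$ligand_chembl_id),
    target_id = as.character(df$target_uniprot_id),
    actions = as.character(df$actions)
  )
  ct_inform("read %d interaction rows from %s", nrow(out), path)
  out
}

#' Read a DrugBank skim table
#'
#' A minimal per-target action table extracted from DrugBank (compound
#' identifier, UniProt accession, action term).
#'
#' @param path TSV/CSV with columns `compound_chembl_id`, `uniprot_id`,
#'   `action`.
#' @return Tibble with columns `compound_id`, `target_id`, `action`.
#' @export
read_drugbank_skim <- function(path) {
  df <- read_table_file(path, c("compound_chembl_id", "uniprot_id", "action"))
  out <- tibble::tibble(
    compound_id = as.character(df$compound_chembl_id),
    target_id = as.character(df$uniprot_id),
    action = as.character(df$action)
  )
  ct_inform("read %d drugbank rows from %s", nrow(out), path)
  out
}

#' Read a protein-to-tissues expression table
#'
#' Presence/absence expression listing in the style of a proteomics
#' repository export: one row per protein with a semicolon-separated tissue
#' list. Tissue names are stored case-preserved; all downstream comparisons
#' are case-insensitive.
#'
#' @param path TSV/CSV with columns `protein_id`, `tissues`.
#' @return Long tibble with columns `protein_id`, `tissue` (one row per
#'   protein-tissue pair).
#' @export
read_expression_table <- function(path) {
  df <- read_table_file(path, c("protein_id", "tissues"))
  if (any(!nzchar(df$protein_id) | is.na(df$protein_id))) {
    abort(sprintf("'%s' contains empty protein_id entries", path))
  }
  out <- tibble::tibble(
    protein_id = as.character(df$protein_id),
    tissue = strsplit(as.character(df$tissues), ";", fixed = TRUE)
  ) |>
    tidyr::unnest_longer("tissue") |>
    dplyr::mutate(tissue = trimws(.data$tissue)) |>
    dplyr::filter(nzchar(.data$tissue)) |>
    dplyr::distinct()
  ct_inform(
    "read expression for %d proteins (%d protein-tissue pairs) from %s",
    dplyr::n_distinct(out$protein_id), nrow(out), path
  )
  out
}

#' Read STRING-format weighted protein-protein edges
#'
#' @param path TSV/CSV with columns `protein1`, `protein2`,
#'   `combined_score` (integer 0--1000). Self-loops are dropped with a
#'   message; out-of-range scores are an error.
#' @return Tibble with columns `protein_a`, `protein_b`, `combined_score`.
#' @export
read_string_edges <- function(path) {
  df <- read_table_file(path, c("protein1", "protein2", "combined_score"))
  score <- suppressWarnings(as.integer(df$combined_score))
  if (any(is.na(score) & !is.na(df$combined_score)) ||
      any(score < 0 | score > 1000, na.rm = TRUE) || anyNA(score)) {
    abort(sprintf("'%s': combined_score must be an integer in [0, 1000]", path))
  }
  out <- tibble::tibble(
    protein_a = as.character(df$protein1),
    protein_b = as.character(df$protein2),
    combined_score = score
  )
  loops <- out$protein_a == out$protein_b
  if (any(loops)) {
    ct_inform("dropping %d self-loop edge(s) from %s", sum(loops), path)
    out <- out[!loops, ]
  }
  ct_inform("read %d protein-protein edges from %s", nrow(out), path)
  out
}

#' Read SIGNOR-format causal interaction records
#'
#' No filtering happens at read time: rows whose entities are not proteins
#' are retained and removed later by [overlay_causal()].
#'
#' @param path TSV with columns `typea`, `ida`, `typeb`, `idb`, `effect`.
#' @return Tibble with columns `type_a`, `id_a`, `type_b`, `id_b`, `effect`.
#' @export
read_signor_tsv <- function(path) {
  df <- read_table_file(path, c("typea", "ida", "typeb", "idb", "effect"))
  out <- tibble::tibble(
    type_a = as.character(df$typea),
    id_a = as.character(df$ida),
    type_b = as.character(df$typeb),
    id_b = as.character(df$idb),
    effect = as.character(df$effect)
  )
  if (nrow(out) > 0 && any(!nzchar(out$id_a) | !nzchar(out$id_b) |
                           is.na(out$id_a) | is.na(out$id_b))) {
    abort(sprintf("'%s' contains rows with empty entity identifiers", path))
  }
  ct_inform("read %d causal interaction rows from %s", nrow(out), path)
  out
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name`, `description`, members... Members are deduplicated; duplicate
#' pathway identifiers across lines are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with columns `pathway_id`, `name` and list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf(
      "'%s' line %d has %d field(s); GMT requires name, description and >= 1 member",
      path, short[1], length(fields[[short[1]]])
    ))
  }
  out <- tibble::tibble(
    pathway_id = vapply(fields, `[[`, character(1), 1),
    name = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  dup <- duplicated(out$pathway_id)
  if (any(dup)) {
    abort(sprintf(
      "'%s' contains duplicate pathway id(s): %s",
      path, paste(unique(out$pathway_id[dup]), collapse = ", ")
    ))
  }
  ct_inform("read %d pathways from %s", nrow(out), path)
  out
}

#' Write / read a harmonized causal profile as TSV
#'
#' Rows are sorted by compound, target, category and source so repeated runs
#' produce byte-identical, diffable output.
#'
#' @param profile Tibble with columns `compound_id`, `target_id`, `category`
#'   and optionally `source`, `evidence`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly (`read_profile_tsv` returns the tibble).
#' @export
write_profile_tsv <- function(profile, path) {
  need <- c("compound_id", "target_id", "category")
  missing <- setdiff(need, names(profile))
  if (length(missing) > 0) {
    abort(sprintf("profile is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  assert_moa(profile$category)
  keep <- intersect(c(need, "source", "evidence"), names(profile))
  out <- dplyr::arrange(
    profile[, keep],
    .data$compound_id, .data$target_id, .data$category
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read_table_file(path, c("compound_id", "target_id", "category"))
  df$category <- as.integer(df$category)
  assert_moa(df$category)
  ct_inform("read %d profile rows from %s", nrow(df), path)
  tibble::as_tibble(df)
}

#' Write a results table as deterministic TSV
#'
#' Rows are lexicographically sorted over all columns before writing so the
#' output is stable across runs.
#'
#' @param df A data frame.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  ord <- do.call(order, lapply(as.list(df), as.character))
  readr::write_tsv(df[ord, , drop = FALSE], path, progress = FALSE)
  invisible(path)
}
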