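#' Packaged assay-description keyword rules
#'
#' Directional keywords mined from assay descriptions, each carrying a
#' category (1 = positive, 2 = negative) and an optional set of exclusion
#' phrases whose co-occurrence in the same description voids the match
#' (e.g. "activation" is voided by "inactivation"). Matching downstream is
#' case-insensitive substring search, which is equivalent to the
#' leading-letter-dropped wildcard patterns used in graphical workflow
#' tools as a case-insensitivity workaround.
#'
#' @return Tibble with columns `phrase`, `category` and list-column
#'   `exclusions`.
#' @examples
#' assay_keyword_rules()
#' @export
assay_keyword_rules <- function() {
  df <- readr::read_tsv(
    ct_resource("mappings", "assay_keywords.tsv"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      phrase = readr::col_character(),
      category = readr::col_integer(),
      exclusions = readr::col_character()
    )
  )
  assert_moa(df$category, allowed = 1:2)
  if (any(!nzchar(df$phrase))) abort("keyword rules must have non-empty phrases")
  df$exclusions <- lapply(df$exclusions, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  })
  tibble::as_tibble(df)
}

has_phrase <- function(description, phrase) {
  stringr::str_detect(description, stringr::fixed(phrase, ignore_case = TRUE))
}

#' Categorize assay evidence by pChEMBL cutoff and description keywords
#'
#' Applies the assay-level decision procedure to each record:
#' \enumerate{
#'   \item An activity comment contradicting the pChEMBL cutoff excludes the
#'     record: comment implies inactive while `pchembl >= active_cutoff`, or
#'     implies active while `pchembl < active_cutoff`. An "inconclusive"
#'     comment always excludes.
#'   \item A missing pChEMBL excludes (activity cannot be established).
#'   \item `pchembl < active_cutoff` yields category 4 (inactive).
#'   \item Otherwise keyword rules are matched case-insensitively as
#'     substrings of the assay description (a rule is voided when one of its
#'     exclusion phrases also occurs). Agreement on one direction yields
#'     category 1 or 2; matches in both directions exclude the record;
#'     no match yields category 3 (active, direction unknown).
#' }
#' A pChEMBL of 5 corresponds to 10 uM; the cutoff can be made more
#' stringent per analysis.
#'
#' @param assays Tibble as returned by [read_chembl_assays()] (columns
#'   `assay_description`, `pchembl`, `activity_comment`, plus identifiers).
#' @param rules Keyword rule table, default [assay_keyword_rules()].
#' @param active_cutoff pChEMBL at or above which a record counts as
#'   active; default 5 (10 uM).
#' @param inactive_comments,active_comments,inconclusive_comments Comment
#'   vocabularies (case-insensitive) implying inactivity, activity, or an
#'   inconclusive result.
#' @return The input tibble with added columns `category` (integer,
#'   `NA` for excluded records), `excluded` (logical) and `reason`
#'   (character, `NA` for retained records).
#' @examples
#' annotate_assays(tibble::tibble(
#'   compound_id = "CHEMBL25", target_id = "P23219",
#'   assay_description = "Inhibitor of prostaglandin synthase",
#'   pchembl = 6.2, activity_comment = NA_character_
#' ))
#' @export
annotate_assays <- function(assays,
                            rules = assay_keyword_rules(),
                            active_cutoff = 5,
                            inactive_comments = c("not active", "inactive"),
                            active_comments = "active",
                            inconclusive_comments = "inconclusive") {
  stopifnot(is.data.frame(assays), active_cutoff > 0)
  need <- c("assay_description", "pchembl", "activity_comment")
  missing <- setdiff(need, names(assays))
  if (length(missing) > 0) {
    abort(sprintf("assays is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  n <- nrow(assays)
  desc <- as.character(assays$assay_description)
  pchembl <- as.numeric(assays$pchembl)
  comment <- tolower(trimws(as.character(assays$activity_comment)))

  category <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  comment_inactive <- !is.na(comment) & comment %in% tolower(inactive_comments)
  comment_active <- !is.na(comment) & comment %in% tolower(active_comments)
  comment_inconclusive <- !is.na(comment) & comment %in% tolower(inconclusive_comments)

  no_pchembl <- is.na(pchembl)
  active <- !no_pchembl & pchembl >= active_cutoff
  inactive <- !no_pchembl & pchembl < active_cutoff

  reason[comment_inconclusive] <- "inconclusive activity comment"
  reason[is.na(reason) & active & comment_inactive] <-
    "activity comment contradicts pChEMBL >= cutoff"
  reason[is.na(reason) & inactive & comment_active] <-
    "activity comment contradicts pChEMBL < cutoff"
  reason[is.na(reason) & no_pchembl] <- "missing pChEMBL value"

  undecided <- is.na(reason)
  category[undecided & inactive] <- 4L

  # keyword mining only for active, uncontradicted records
  for (i in which(undecided & active)) {
    matched <- vapply(seq_len(nrow(rules)), function(j) {
      has_phrase(desc[i], rules$phrase[j]) &&
        !any(vapply(rules$exclusions[[j]], has_phrase, logical(1),
                    description = desc[i]))
    }, logical(1))
    dirs <- unique(rules$category[matched])
    if (length(dirs) == 0) {
      category[i] <- 3L
    } else if (length(dirs) == 1) {
      category[i] <- dirs
    } else {
      reason[i] <- "keywords of both directions matched"
    }
  }

  out <- tibble::as_tibble(assays)
  out$category <- category
  out$excluded <- is.na(category)
  out$reason <- reason
  n_excl <- sum(out$excluded)
  ct_inform(
    "annotated %d assay records: %d categorized, %d excluded",
    n, n - n_excl, n_excl
  )
  out
}
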