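#' Specification of a synthetic fixture set
#'
#' Parameterizes the planted-signal generator of [generate_fixtures()].
#' The defaults emulate the shape of the liver-toxicity case the package
#' was designed around: 180 toxic and 272 non-toxic compounds, a planted
#' toxic-to-non-toxic connection ratio of 5 (the significance cutoff), and
#' a contradiction rate of 0.05 so roughly 5% of unique connections are
#' removed by the consistency filter.
#'
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param n_tox,n_nontox Compound counts of the toxic and non-toxic groups.
#' @param n_targets Protein panel size.
#' @param n_sig_up,n_sig_down Planted significant proteins per modulation
#'   direction (1 = positive, 2 = negative).
#' @param separation Planted toxic:non-toxic connection ratio for
#'   significant proteins; must be positive.
#' @param contradiction_rate Fraction of used drug-target pairs that
#'   additionally receive a conflicting category (each such pair is removed
#'   by the consistency filter).
#' @param tissue_fraction Fraction of the panel expressed in the focal
#'   tissue (`"Liver"`).
#' @param n_pathways,pathway_size Pathway collection shape: one planted
#'   pathway built from the seed set plus decoys of `pathway_size` random
#'   non-seed members.
#' @param n_decoy_edges Random background edges of the protein network, on
#'   top of a planted high-confidence clique among the significant
#'   negative-direction proteins.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_tox = 180, n_nontox = 272,
                         n_targets = 100, n_sig_up = 4, n_sig_down = 8,
                         separation = 5, contradiction_rate = 0.05,
                         tissue_fraction = 0.8, n_pathways = 12,
                         pathway_size = 6, n_decoy_edges = 150) {
  spec <- list(
    seed = seed, n_tox = n_tox, n_nontox = n_nontox, n_targets = n_targets,
    n_sig_up = n_sig_up, n_sig_down = n_sig_down, separation = separation,
    contradiction_rate = contradiction_rate, tissue_fraction = tissue_fraction,
    n_pathways = n_pathways, pathway_size = pathway_size,
    n_decoy_edges = n_decoy_edges
  )
  counts <- unlist(spec[c("n_tox", "n_nontox", "n_targets", "n_sig_up",
                          "n_sig_down", "n_pathways", "pathway_size",
                          "n_decoy_edges")])
  stopifnot(
    all(counts >= 0), spec$separation > 0,
    spec$contradiction_rate >= 0, spec$contradiction_rate <= 1,
    spec$tissue_fraction >= 0, spec$tissue_fraction <= 1
  )
  if (n_sig_up + n_sig_down > n_targets) {
    abort("more planted significant proteins requested than panel targets")
  }
  structure(spec, class = "fixture_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# vocabulary pools per source and category used when emitting rows
fixture_terms <- list(
  chembl = list(`1` = c("AGONIST", "ACTIVATOR", "POSITIVE MODULATOR"),
                `2` = c("ANTAGONIST", "BLOCKER", "INHIBITOR"),
                `3` = c("MODULATOR", "BINDING AGENT")),
  iuphar = list(`1` = c("Activation", "Full agonist"),
                `2` = c("Inhibition", "Antagonist"),
                `3` = c("Binding", "Neutral")),
  drugbank = list(`1` = c("agonist", "inducer"),
                  `2` = c("inhibitor", "blocker"),
                  `3` = c("binder", "modulator"))
)

assay_description_for <- function(target_id, category) {
  switch(as.character(category),
    `1` = sprintf("Activation of %s in reporter gene assay", target_id),
    `2` = sprintf("Inhibitor potency against human %s", target_id),
    `3` = sprintf("Radioligand binding displacement at %s", target_id),
    `4` = sprintf("Radioligand binding displacement at %s", target_id)
  )
}

#' Generate every input dialect with planted ground truth
#'
#' Writes a complete, mutually consistent set of pipeline inputs to
#' `outdir`: compound group lists, mechanism / assay / IUPHAR / DrugBank
#' tables, an expression table, STRING-format edges, a SIGNOR-format
#' causal TSV, and a GMT pathway collection; plus `truth.json` recording
#' the planted signal. Planted significant proteins receive `separation`
#' times more toxic-group than non-toxic-group compounds (or a toxic-only
#' count at the cutoff); decoy proteins are balanced across groups; the
#' significant negative-direction proteins form a high-confidence clique,
#' are the members of the planted pathway, and carry planted causal edges.
#' Assay rows embed direction keywords in their descriptions with
#' category-consistent pChEMBL values (uniform on [5, 9] for actives,
#' [3, 5) for inactives), so text-mining recovery is exact by construction.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a `fixture_truth` list: `files` (named paths),
#'   `significant` (tibble `protein_id`, `direction`),
#'   `contradictory_pairs`, `tissue_expressed`, `seed_proteins`,
#'   `causal_pairs`, `enriched_pathway`, `expected_consistency`.
#' @examples
#' truth <- generate_fixtures(fixture_spec(seed = 7, n_tox = 12, n_nontox = 15,
#'   n_targets = 20, n_sig_up = 1, n_sig_down = 2, n_pathways = 4,
#'   n_decoy_edges = 20), tempfile())
#' truth$significant
#' @export
generate_fixtures <- function(spec = fixture_spec(), outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(spec$seed, {
    tox_ids <- sprintf("CHEMBL1%05d", seq_len(spec$n_tox))
    nontox_ids <- sprintf("CHEMBL2%05d", seq_len(spec$n_nontox))
    targets <- sprintf("P%05d", seq_len(spec$n_targets))

    sig_up <- if (spec$n_sig_up > 0) targets[seq_len(spec$n_sig_up)] else character(0)
    sig_down <- if (spec$n_sig_down > 0) {
      targets[spec$n_sig_up + seq_len(spec$n_sig_down)]
    } else character(0)
    decoys <- setdiff(targets, c(sig_up, sig_down))

    # --- planted and decoy connections (one category per used pair) -----
    rows <- list()
    add <- function(compound, target, category) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        compound_id = compound, target_id = target, category = as.integer(category)
      )
    }
    n_ratio_tox <- max(1L, ceiling(spec$separation)) # planted ratio numerator
    planted <- tibble::tibble(
      protein_id = c(sig_up, sig_down),
      direction = c(rep(1L, length(sig_up)), rep(2L, length(sig_down)))
    )
    for (i in seq_len(nrow(planted))) {
      p <- planted$protein_id[i]
      d <- planted$direction[i]
      if (i %% 2 == 0 && spec$n_nontox > 0) {
        # ratio-type plant: separation-times more toxic than non-toxic
        add(sample(tox_ids, min(spec$n_tox, n_ratio_tox)), p, d)
        add(sample(nontox_ids, 1), p, d)
      } else {
        # toxic-only plant at the only-toxic cutoff
        add(sample(tox_ids, min(spec$n_tox, max(5L, n_ratio_tox))), p, d)
      }
    }
    for (i in seq_along(decoys)) {
      p <- decoys[i]
      d <- if (i %% 2 == 0) 1L else 2L
      k <- 2L
      if (spec$n_tox >= k) add(sample(tox_ids, k), p, d)
      if (spec$n_nontox >= k) add(sample(nontox_ids, k), p, d)
      # undirected and inactive background evidence on distinct compounds
      if (i %% 3 == 0 && spec$n_tox > 0) add(sample(tox_ids, 1), p, 3L)
      if (i %% 4 == 0 && spec$n_nontox > 0) add(sample(nontox_ids, 1), p, 4L)
    }
    triples <- dplyr::bind_rows(rows) |>
      dplyr::distinct(.data$compound_id, .data$target_id, .keep_all = TRUE)

    # --- planted contradictions on otherwise-unused pairs ---------------
    n_contra <- round(spec$contradiction_rate * nrow(triples))
    contra <- tibble::tibble(compound_id = character(), target_id = character())
    if (n_contra > 0) {
      used <- paste(triples$compound_id, triples$target_id)
      pool_c <- c(tox_ids, nontox_ids)
      picked <- 0
      while (picked < n_contra) {
        cand <- tibble::tibble(
          compound_id = sample(pool_c, 1), target_id = sample(targets, 1)
        )
        key <- paste(cand$compound_id, cand$target_id)
        if (!key %in% used) {
          used <- c(used, key)
          contra <- dplyr::bind_rows(contra, cand)
          picked <- picked + 1
        }
      }
    }

    # --- distribute rows over the four source dialects ------------------
    mech <- list(); assay <- list(); iuph <- list(); db <- list()
    emit <- function(compound, target, category, slot) {
      if (category == 4L) slot <- 1L # only assays can state inactivity
      cat_chr <- as.character(min(category, 3L))
      switch(slot,
        { # assay row with category-consistent pChEMBL and keyworded text
          pchembl <- if (category == 4L) stats::runif(1, 3, 4.99)
                     else stats::runif(1, 5, 9)
          assay[[length(assay) + 1]] <<- tibble::tibble(
            molecule_chembl_id = compound, accession = target,
            assay_description = assay_description_for(target, category),
            pchembl_value = round(pchembl, 2), activity_comment = NA_character_
          )
        },
        mech[[length(mech) + 1]] <<- tibble::tibble(
          molecule_chembl_id = compound, accession = target,
          action_type = sample(fixture_terms$chembl[[cat_chr]], 1)
        ),
        iuph[[length(iuph) + 1]] <<- tibble::tibble(
          ligand_chembl_id = compound, target_uniprot_id = target,
          actions = sample(fixture_terms$iuphar[[cat_chr]], 1)
        ),
        db[[length(db) + 1]] <<- tibble::tibble(
          compound_chembl_id = compound, uniprot_id = target,
          action = sample(fixture_terms$drugbank[[cat_chr]], 1)
        )
      )
    }
    for (i in seq_len(nrow(triples))) {
      emit(triples$compound_id[i], triples$target_id[i], triples$category[i],
           slot = (i %% 4L) + 1L)
    }
    if (nrow(contra) > 0) {
      for (i in seq_len(nrow(contra))) {
        emit(contra$compound_id[i], contra$target_id[i], 1L, slot = 2L)
        emit(contra$compound_id[i], contra$target_id[i], 2L, slot = 3L)
      }
    }

    # --- tissue expression ----------------------------------------------
    n_liver <- round(spec$tissue_fraction * spec$n_targets)
    liver_set <- unique(c(
      sig_up, sig_down,
      sample(decoys, max(0, min(length(decoys), n_liver - length(c(sig_up, sig_down)))))
    ))
    non_liver <- setdiff(targets, liver_set)
    measured_non_liver <- non_liver[seq_along(non_liver) %% 3 != 0]
    expression <- dplyr::bind_rows(
      tibble::tibble(protein_id = liver_set, tissues = "Liver;Kidney"),
      tibble::tibble(protein_id = measured_non_liver, tissues = "Kidney;Brain")
    )

    # --- protein network: planted clique + decoy edges -------------------
    seed_proteins <- if (length(sig_down) > 0) sig_down else sig_up
    clique <- if (length(seed_proteins) >= 2) {
      t(utils::combn(seed_proteins, 2))
    } else matrix(character(0), ncol = 2)
    edges <- tibble::tibble(
      protein1 = clique[, 1], protein2 = clique[, 2],
      combined_score = 900L
    )
    if (spec$n_decoy_edges > 0 && spec$n_targets >= 2) {
      d1 <- sample(targets, spec$n_decoy_edges, replace = TRUE)
      d2 <- sample(targets, spec$n_decoy_edges, replace = TRUE)
      dec <- tibble::tibble(
        protein1 = pmin(d1, d2), protein2 = pmax(d1, d2),
        combined_score = sample(400:900, spec$n_decoy_edges, replace = TRUE)
      ) |>
        dplyr::filter(.data$protein1 != .data$protein2) |>
        dplyr::distinct(.data$protein1, .data$protein2, .keep_all = TRUE) |>
        dplyr::anti_join(edges, by = c("protein1", "protein2"))
      edges <- dplyr::bind_rows(edges, dec)
    }

    # --- causal interactions (one hub up-regulating its clique partners) -
    signor <- tibble::tibble(
      typea = character(), ida = character(),
      typeb = character(), idb = character(), effect = character()
    )
    causal_pairs <- tibble::tibble(source_id = character(), target_id = character())
    if (length(seed_proteins) >= 2) {
      hub <- seed_proteins[1]
      partners <- seed_proteins[-1]
      causal_pairs <- tibble::tibble(source_id = hub, target_id = partners)
      signor <- dplyr::bind_rows(
        tibble::tibble(
          typea = "protein", ida = hub, typeb = "protein", idb = partners,
          effect = "up-regulates quantity by expression"
        ),
        if (length(partners) >= 2) tibble::tibble(
          typea = "protein", ida = partners[1], typeb = "protein",
          idb = partners[2], effect = "down-regulates activity"
        ),
        # non-protein and out-of-network rows exercised by the overlay filter
        tibble::tibble(
          typea = "chemical", ida = "CHEBI:15365", typeb = "protein",
          idb = hub, effect = "down-regulates"
        ),
        tibble::tibble(
          typea = "protein", ida = hub, typeb = "protein",
          idb = "Q99999", effect = "up-regulates"
        )
      )
      if (length(partners) >= 2) {
        causal_pairs <- dplyr::bind_rows(
          causal_pairs,
          tibble::tibble(source_id = partners[1], target_id = partners[2])
        )
      }
    }

    # --- pathways: planted = seed set, decoys from non-seed liver panel --
    gmt_lines <- character(0)
    enriched_pathway <- NA_character_
    if (spec$n_pathways > 0 && length(seed_proteins) > 0) {
      enriched_pathway <- "PW0001"
      gmt_lines <- sprintf(
        "PW0001\tplanted seed-neighborhood pathway\t%s",
        paste(seed_proteins, collapse = "\t")
      )
      decoy_pool <- setdiff(liver_set, seed_proteins)
      for (i in seq_len(spec$n_pathways - 1)) {
        members <- sample(decoy_pool, min(spec$pathway_size, length(decoy_pool)))
        gmt_lines <- c(gmt_lines, sprintf(
          "PW%04d\tdecoy pathway %d\t%s",
          i + 1, i, paste(members, collapse = "\t")
        ))
      }
    }

    # --- expected consistency bookkeeping --------------------------------
    n_input <- nrow(triples) + 2L * nrow(contra)
    n_removed <- 2L * nrow(contra)
    expected_consistency <- tibble::tibble(
      n_input_unique = n_input,
      n_removed = n_removed,
      n_retained = n_input - n_removed,
      percent_consistent = 100 * (n_input - n_removed) / n_input
    )

    # --- write everything -------------------------------------------------
    files <- c(
      tox = file.path(outdir, "compounds_tox.txt"),
      nontox = file.path(outdir, "compounds_nontox.txt"),
      mechanisms = file.path(outdir, "chembl_mechanisms.tsv"),
      assays = file.path(outdir, "chembl_assays.tsv"),
      iuphar = file.path(outdir, "iuphar_interactions.tsv"),
      drugbank = file.path(outdir, "drugbank_skim.tsv"),
      expression = file.path(outdir, "expression.tsv"),
      string = file.path(outdir, "string_edges.tsv"),
      signor = file.path(outdir, "signor.tsv"),
      pathways = file.path(outdir, "pathways.gmt"),
      truth = file.path(outdir, "truth.json")
    )
    writeLines(c("# synthetic toxic compound group", tox_ids), files[["tox"]])
    writeLines(c("# synthetic non-toxic compound group", nontox_ids), files[["nontox"]])
    sort_write <- function(parts, path) {
      df <- dplyr::bind_rows(parts)
      ord <- do.call(order, as.list(df))
      readr::write_tsv(df[ord, ], path, progress = FALSE)
    }
    sort_write(mech, files[["mechanisms"]])
    sort_write(assay, files[["assays"]])
    sort_write(iuph, files[["iuphar"]])
    sort_write(db, files[["drugbank"]])
    sort_write(list(expression), files[["expression"]])
    sort_write(list(edges), files[["string"]])
    sort_write(list(signor), files[["signor"]])
    writeLines(gmt_lines, files[["pathways"]])

    truth <- structure(
      list(
        files = as.list(files),
        spec = unclass(spec),
        significant = planted,
        contradictory_pairs = contra,
        tissue_expressed = sort(liver_set),
        seed_proteins = seed_proteins,
        causal_pairs = causal_pairs,
        enriched_pathway = enriched_pathway,
        expected_consistency = expected_consistency
      ),
      class = "fixture_truth"
    )
    jsonlite::write_json(
      truth[setdiff(names(truth), "files")],
      files[["truth"]],
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    ct_inform(
      "fixtures written to %s: %d triples (%d contradictory pairs), %d targets",
      outdir, n_input, nrow(contra), spec$n_targets
    )
    invisible(truth)
  })
}
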