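#' Assemble a pipeline run configuration
#'
#' Collects input paths and stage parameters into a validated run
#' configuration. Inputs are the flat-file dialects documented in
#' [io_formats]; any missing path is an error naming the path before any
#' stage runs. A YAML document with the same field names can be loaded
#' with [load_run_config()]; explicit arguments override file values.
#'
#' @param inputs Named list of paths: `tox`, `nontox` (compound group
#'   lists), `mechanisms`, `assays`, `iuphar`, `drugbank` (any subset of
#'   these four sources, at least one), `expression`, `string`, `signor`,
#'   `pathways`.
#' @param tissue Tissue of interest; default `"liver"`.
#' @param pchembl_cutoff Active cutoff for assay mining; default 5.
#' @param scoring A [scoring_config()].
#' @param min_score STRING score threshold for [build_network()].
#' @param enrichment An [enrichment_config()].
#' @param seed_direction Modulation direction whose significant proteins
#'   seed the network and enrichment stages; default 2 (proteins
#'   preferentially negatively modulated by the toxic group).
#' @param outdir Output directory for stage artifacts and the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, tissue = "liver", pchembl_cutoff = 5,
                       scoring = scoring_config(), min_score = 400,
                       enrichment = enrichment_config(), seed_direction = 2,
                       outdir = "causaltox_out") {
  need <- c("tox", "nontox", "expression", "string", "signor", "pathways")
  sources <- c("mechanisms", "assays", "iuphar", "drugbank")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0) {
    abort(sprintf("inputs is missing entries: %s", paste(missing, collapse = ", ")))
  }
  if (!any(sources %in% names(inputs))) {
    abort("inputs must name at least one source table (mechanisms, assays, iuphar, drugbank)")
  }
  for (nm in intersect(c(need, sources), names(inputs))) {
    if (!file.exists(inputs[[nm]])) {
      abort(sprintf("input '%s' does not exist: %s", nm, inputs[[nm]]))
    }
  }
  assert_moa(seed_direction, allowed = 1:2, what = "seed_direction")
  structure(
    list(
      inputs = inputs, tissue = tissue, pchembl_cutoff = pchembl_cutoff,
      scoring = scoring, min_score = min_score, enrichment = enrichment,
      seed_direction = as.integer(seed_direction), outdir = outdir
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file with the `run_config()` fields (`inputs` as a
#'   mapping of names to paths; `scoring` and `enrichment` as mappings of
#'   their constructor arguments).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  run_config(
    inputs = y$inputs,
    tissue = y$tissue %||% "liver",
    pchembl_cutoff = y$pchembl_cutoff %||% 5,
    scoring = do.call(scoring_config, y$scoring %||% list()),
    min_score = y$min_score %||% 400,
    enrichment = do.call(enrichment_config, y$enrichment %||% list()),
    seed_direction = y$seed_direction %||% 2,
    outdir = y$outdir %||% "causaltox_out"
  )
}

read_sources <- function(inputs) {
  list(
    mechanisms = if (!is.null(inputs$mechanisms)) read_chembl_mechanisms(inputs$mechanisms),
    assays = if (!is.null(inputs$assays)) read_chembl_assays(inputs$assays),
    iuphar = if (!is.null(inputs$iuphar)) read_iuphar_interactions(inputs$iuphar),
    drugbank = if (!is.null(inputs$drugbank)) read_drugbank_skim(inputs$drugbank)
  )
}

#' Run the full causal profiling pipeline
#'
#' Executes the stages in their canonical order -- profile building per
#' compound group, consistency filtering, tissue filtering, significance
#' scoring, network construction with causal overlay, and pathway
#' enrichment -- writing each stage's artifact plus a manifest to
#' `config$outdir`. Every stage is also an exported function, so any
#' sub-sequence can be run by hand on the same inputs with identical
#' results; `run_pipeline()` adds no hidden processing.
#'
#' The network stage induces the STRING subgraph on the significant
#' seed-direction proteins (the interactome of the toxicity signature);
#' the enrichment stage walks over the network induced on all
#' tissue-expressed profiled targets, so pathway scores are measured
#' against the full profiled universe rather than the signature alone.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [load_run_config()]).
#' @return An object of class `causaltox_run`: list with elements
#'   `profiles` (per group, resolved and tissue-filtered), `consistency`
#'   (per-group and total report), `scores`, `seeds`, `network`,
#'   `enrichment` and `manifest` (tibble of artifact paths and row
#'   counts).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  groups <- stage("inputs", list(
    tox = read_group_list(config$inputs$tox, label = "tox"),
    nontox = read_group_list(config$inputs$nontox, label = "nontox")
  ))
  src <- stage("inputs", read_sources(config$inputs))

  profiles <- stage("profile", lapply(groups, function(g) {
    build_profile(
      mechanisms = src$mechanisms, assays = src$assays,
      iuphar = src$iuphar, drugbank = src$drugbank,
      compounds = g, active_cutoff = config$pchembl_cutoff
    )
  }))

  consist <- stage("consistency", lapply(profiles, apply_consistency))
  resolved <- lapply(consist, tidy)
  report <- dplyr::bind_rows(lapply(consist, glance), .id = "group")
  total <- tibble::tibble(
    group = "total",
    n_input_unique = sum(report$n_input_unique),
    n_removed = sum(report$n_removed),
    n_retained = sum(report$n_retained)
  )
  total$percent_consistent <- 100 * total$n_retained / total$n_input_unique
  report <- dplyr::bind_rows(report, total)

  expression <- stage("tissue", read_expression_table(config$inputs$expression))
  tissue_prof <- stage("tissue", lapply(
    resolved, filter_tissue, expression = expression, tissue = config$tissue
  ))

  scores <- stage("score", score_profile(
    tissue_prof$tox, tissue_prof$nontox, config = config$scoring
  ))
  seeds <- significant_proteins(scores, config$seed_direction)

  string_edges <- stage("network", read_string_edges(config$inputs$string))
  signor <- stage("network", read_signor_tsv(config$inputs$signor))
  network <- if (length(seeds) > 0) {
    stage("network", overlay_causal(
      build_network(seeds, string_edges, min_score = config$min_score), signor
    ))
  } else {
    warn("no significant seed proteins; skipping network and enrichment stages")
    NULL
  }

  pathways <- stage("enrich", read_gmt(config$inputs$pathways))
  enrichment <- if (!is.null(network)) {
    universe <- unique(c(tissue_prof$tox$target_id, tissue_prof$nontox$target_id))
    enr_net <- stage("enrich", build_network(
      universe, string_edges, min_score = config$min_score
    ))
    stage("enrich", enrich(enr_net, seeds, pathways, config = config$enrichment))
  }

  # ---- write artifacts + manifest ----
  out <- function(f) file.path(config$outdir, f)
  write_profile_tsv(resolved$tox, out("profile_tox.tsv"))
  write_profile_tsv(resolved$nontox, out("profile_nontox.tsv"))
  jsonlite::write_json(report, out("consistency_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_profile_tsv(tissue_prof$tox, out("profile_tox_tissue.tsv"))
  write_profile_tsv(tissue_prof$nontox, out("profile_nontox_tissue.tsv"))
  readr::write_tsv(scores, out("significance.tsv"), progress = FALSE)
  if (!is.null(network)) {
    write_network_graphml(network, out("network.graphml"))
    write_network_tsv(network, out("network_edges.tsv"))
  }
  if (!is.null(enrichment)) {
    readr::write_tsv(enrichment, out("enrichment.tsv"), progress = FALSE)
  }
  yaml::write_yaml(
    list(
      inputs = config$inputs, tissue = config$tissue,
      pchembl_cutoff = config$pchembl_cutoff,
      scoring = unclass(config$scoring), min_score = config$min_score,
      enrichment = unclass(config$enrichment),
      seed_direction = config$seed_direction
    ),
    out("run_config.yaml")
  )

  manifest <- tibble::tibble(
    stage = c("profile", "profile", "consistency", "tissue", "tissue",
              "score", "network", "enrich"),
    artifact = c("profile_tox.tsv", "profile_nontox.tsv",
                 "consistency_report.json", "profile_tox_tissue.tsv",
                 "profile_nontox_tissue.tsv", "significance.tsv",
                 "network_edges.tsv", "enrichment.tsv"),
    rows = c(nrow(resolved$tox), nrow(resolved$nontox), nrow(report),
             nrow(tissue_prof$tox), nrow(tissue_prof$nontox), nrow(scores),
             if (is.null(network)) NA_integer_ else nrow(tidy(network)),
             if (is.null(enrichment)) NA_integer_ else nrow(enrichment))
  ) |>
    dplyr::filter(!is.na(.data$rows))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)

  structure(
    list(
      profiles = resolved, tissue_profiles = tissue_prof,
      consistency = report, scores = scores, seeds = seeds,
      network = network, enrichment = enrichment, manifest = manifest,
      outdir = config$outdir
    ),
    class = "causaltox_run"
  )
}

#' @export
print.causaltox_run <- function(x, ...) {
  cat(sprintf(
    "<causaltox_run: %d+%d resolved connections, %d significant seeds, %s>\n",
    nrow(x$profiles$tox), nrow(x$profiles$nontox), length(x$seeds),
    if (is.null(x$enrichment)) "no enrichment" else
      sprintf("%d pathways scored", nrow(x$enrichment))
  ))
  invisible(x)
}
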