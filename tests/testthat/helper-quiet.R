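# keep reader/stage row-count messages out of test output
options(causaltox.quiet = TRUE)

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, n_tox = 40, n_nontox = 60, n_targets = 50,
      n_sig_up = 3, n_sig_down = 5, n_pathways = 10, pathway_size = 6,
      n_decoy_edges = 60
    ),
    list(...)
  )
  do.call(fixture_spec, args)
}

fixture_run_config <- function(truth, outdir = withr::local_tempdir(.local_envir = parent.frame())) {
  run_config(
    inputs = list(
      tox = truth$files$tox, nontox = truth$files$nontox,
      mechanisms = truth$files$mechanisms, assays = truth$files$assays,
      iuphar = truth$files$iuphar, drugbank = truth$files$drugbank,
      expression = truth$files$expression, string = truth$files$string,
      signor = truth$files$signor, pathways = truth$files$pathways
    ),
    outdir = outdir
  )
}
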