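string_fixture <- tibble::tibble(
  protein_a = c("A", "B", "A"),
  protein_b = c("B", "D", "C"),
  combined_score = c(900L, 950L, 350L)
)

test_that("build_network induces on the protein set with score threshold", {
  net <- build_network(c("A", "B", "C"), string_fixture, min_score = 400)
  expect_setequal(net$nodes$protein_id, c("A", "B", "C")) # C stays isolated
  expect_equal(nrow(net$edges), 1)                        # B-D outside, A-C below
  expect_equal(net$edges$confidence, 0.9)
  # lowering the threshold admits the 350-score edge
  net2 <- build_network(c("A", "B", "C"), string_fixture, min_score = 300)
  expect_equal(nrow(net2$edges), 2)
  expect_error(build_network(character(0), string_fixture), "non-empty")
})

test_that("the undirected layer is simple with confidences in [0,1]", {
  doubled <- dplyr::bind_rows(
    string_fixture,
    tibble::tibble(protein_a = "B", protein_b = "A", combined_score = 800L)
  )
  net <- build_network(c("A", "B"), doubled)
  expect_equal(nrow(net$edges), 1) # reciprocal rows collapse, max score kept
  expect_equal(net$edges$confidence, 0.9)
  expect_true(all(net$edges$confidence >= 0 & net$edges$confidence <= 1))
})

test_that("causal effects map to modes of interaction by prefix and term", {
  expect_equal(map_effect_to_moi("up-regulates quantity by expression"), 1L)
  expect_equal(map_effect_to_moi("down-regulates activity"), 2L)
  expect_equal(map_effect_to_moi("form complex"), 3L)
  expect_equal(map_effect_to_moi("unknown"), 3L)
  expect_error(map_effect_to_moi("teleports"), "teleports")
})

signor_fixture <- tibble::tibble(
  type_a = c("protein", "protein", "chemical", "protein", "protein"),
  id_a = c("O60656", "O60656", "CHEBI:1", "O60656", "Z9"),
  type_b = c("protein", "protein", "protein", "protein", "protein"),
  id_b = c("P20823", "P20823", "P20823", "Q99999", "P20823"),
  effect = c(
    "up-regulates quantity by expression",
    "up-regulates quantity by expression", # duplicate row
    "down-regulates", "up-regulates", "down-regulates"
  )
)

test_that("overlay keeps protein-protein records inside the node set", {
  net <- build_network(
    c("O60656", "P20823"),
    tibble::tibble(protein_a = "O60656", protein_b = "P20823",
                   combined_score = 700L)
  )
  net <- overlay_causal(net, signor_fixture)
  # one causal edge survives: duplicates collapsed, chemical row dropped,
  # Q99999 and Z9 endpoints outside the network dropped
  expect_equal(nrow(net$causal_edges), 1)
  expect_equal(net$causal_edges$source_id, "O60656")
  expect_equal(net$causal_edges$target_id, "P20823")
  expect_equal(net$causal_edges$moi, 1L)
  # no nodes added, endpoints within nodes
  expect_setequal(net$nodes$protein_id, c("O60656", "P20823"))
})

test_that("the planted causal hub shape is reproduced from fixtures", {
  truth <- generate_fixtures(small_spec(seed = 31), withr::local_tempdir())
  run <- run_pipeline(fixture_run_config(truth))
  got <- run$network$causal_edges
  expect_setequal(
    paste(got$source_id, got$target_id),
    paste(truth$causal_pairs$source_id, truth$causal_pairs$target_id)
  )
  expect_true(all(got$moi %in% 1:3))
})

test_that("graphml output round-trips both layers through igraph", {
  net <- build_network(
    c("O60656", "P20823", "X1"),
    tibble::tibble(protein_a = "O60656", protein_b = "P20823",
                   combined_score = 700L)
  )
  net <- overlay_causal(net, signor_fixture)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f, gene_names = tibble::tibble(
    protein_id = "O60656", gene_name = "UGT1A9"
  ))
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_setequal(igraph::E(g)$layer, c("confidence", "causal"))
  expect_true("UGT1A9" %in% igraph::V(g)$gene_name)
  conf <- igraph::E(g)[igraph::E(g)$layer == "confidence"]
  expect_equal(conf$weight, 0.7)
})

test_that("tidy and glance expose the two-layer edge table and counts", {
  net <- build_network(c("A", "B"), string_fixture)
  g <- glance(net)
  expect_equal(g$n_nodes, 2)
  expect_equal(g$n_causal_edges, 0)
  td <- tidy(net)
  expect_equal(td$layer, "confidence")
})
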