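# independent oracle: closed-form stationary solution of the restart walk,
# s = r (I - (1-r) W)^{-1} e, with W rebuilt from the edge list by hand
rwr_oracle <- function(net, seeds, r) {
  nodes <- net$nodes$protein_id
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$protein_a[k]; j <- net$edges$protein_b[k]
    A[i, j] <- A[j, i] <- net$edges$confidence[k]
  }
  for (j in seq_len(n)) {
    if (sum(A[, j]) > 0) A[, j] <- A[, j] / sum(A[, j]) else A[j, j] <- 1
  }
  e <- setNames(numeric(n), nodes)
  e[intersect(seeds, nodes)] <- 1 / length(intersect(seeds, nodes))
  drop(r * solve(diag(n) - (1 - r) * A) %*% e)
}

random_network <- function(n, seed) {
  withr::with_seed(seed, {
    nodes <- LETTERS[seq_len(n)]
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.5
    edges <- tibble::tibble(
      protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
      combined_score = sample(400:1000, sum(keep), replace = TRUE)
    )
    build_network(nodes, edges, min_score = 400)
  })
}

test_that("the restart walk matches the dense linear solve on small graphs", {
  for (n in 2:8) {
    for (seed in 1:5) {
      net <- random_network(n, seed = 100 * n + seed)
      seeds <- withr::with_seed(seed, sample(net$nodes$protein_id,
                                             sample(seq_len(n), 1)))
      for (r in c(0.3, 0.5, 0.9)) {
        got <- rwr(net, seeds, enrichment_config(restart_prob = r))
        want <- rwr_oracle(net, seeds, r)
        expect_equal(got, want[names(got)], tolerance = 1e-8)
      }
    }
  }
})

test_that("walk probabilities conserve mass and stay in seed components", {
  for (seed in 1:10) {
    net <- random_network(7, seed = seed)
    seeds <- withr::with_seed(seed, sample(net$nodes$protein_id, 2))
    s <- rwr(net, seeds)
    expect_equal(sum(s), 1, tolerance = 1e-8)
    expect_true(all(s >= 0))
    # nodes with no path from any seed receive no mass
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$protein_id)
    comp <- igraph::components(g)$membership
    reachable <- names(comp)[comp %in% comp[seeds]]
    expect_true(all(s[setdiff(names(s), reachable)] == 0))
  }
})

test_that("degenerate walks have their closed forms", {
  single <- build_network("A", tibble::tibble(
    protein_a = character(), protein_b = character(),
    combined_score = integer()
  ))
  expect_equal(rwr(single, "A"), c(A = 1))
  # restart probability 1 pins all mass uniformly on the seeds
  net <- random_network(5, seed = 3)
  s <- rwr(net, c("A", "B"), enrichment_config(restart_prob = 1))
  expect_equal(s[c("A", "B")], c(A = 0.5, B = 0.5))
  expect_true(all(s[setdiff(names(s), c("A", "B"))] == 0))
  expect_error(rwr(net, "ZZ"), "no seed")
})

path3 <- function() build_network(c("A", "B", "C"), tibble::tibble(
  protein_a = c("A", "B"), protein_b = c("B", "C"),
  combined_score = c(800L, 800L)
))

test_that("a 3-node path with one seed matches the direct solve", {
  net <- path3()
  got <- rwr(net, "A", enrichment_config(restart_prob = 0.5))
  want <- rwr_oracle(net, "A", 0.5)
  expect_equal(got, want[names(got)], tolerance = 1e-9)
  # proximity ordering: seed > neighbour > distal node
  expect_true(got["A"] > got["B"] && got["B"] > got["C"])
})

test_that("XD scores are deviations that sum to zero and rank proximity", {
  net <- path3()
  s <- rwr(net, "A")
  pws <- tibble::tibble(
    pathway_id = c("seeded", "far"),
    name = c("seed pathway", "distal pathway"),
    members = list(c("A", "B"), "C")
  )
  xd <- xd_scores(s, pws)
  expect_equal(sum(xd$xd_score[xd$scored]), 0, tolerance = 1e-12)
  expect_gt(xd$xd_score[xd$pathway_id == "seeded"],
            xd$xd_score[xd$pathway_id == "far"])
  # identical member sets all sit at the common mean: XD = 0
  same <- tibble::tibble(
    pathway_id = c("p1", "p2"), name = c("a", "b"),
    members = list(c("A", "B"), c("A", "B"))
  )
  expect_equal(xd_scores(s, same)$xd_score, c(0, 0), tolerance = 1e-12)
  # pathways without in-network members are skipped, all-skip errors
  none <- tibble::tibble(pathway_id = "x", name = "x", members = list("ZZ"))
  expect_error(xd_scores(s, none), "no pathway")
})

# direct summation of the hypergeometric upper tail
fisher_oracle <- function(x, K, n, N) {
  sum(vapply(x:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

test_that("the overlap test equals hypergeometric enumeration up to N = 50", {
  universe <- sprintf("u%02d", 1:50)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      N <- sample(5:50, 1)
      uni <- universe[1:N]
      seeds <- sample(uni, sample(1:min(8, N), 1))
      pw <- sample(uni, sample(1:min(10, N), 1))
    })
    x <- length(intersect(seeds, pw))
    got <- fisher_overlap(seeds, pw, uni)
    want <- fisher_oracle(x, length(pw), length(seeds), length(uni))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # worked example: universe 20, seeds 5, pathway 4, overlap 4
  expect_equal(
    fisher_overlap(letters[1:5], letters[2:5], letters[1:20]),
    5 / 4845, tolerance = 1e-12
  )
  # degenerate tails
  expect_equal(fisher_overlap(letters[1:4], letters[1:4], letters[1:4]), 1)
  expect_equal(fisher_overlap(letters[1:3], letters[4:6], letters[1:10]),
               fisher_oracle(0, 3, 3, 10))
  expect_error(fisher_overlap("a", "a", character(0)), "universe")
})

test_that("BH q-values follow the step-up construction and input order", {
  expect_equal(bh_qvalues(0.02), 0.02)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand-computed step-up: sorted p (.005,.02,.1,.8) -> q (.02,.04,.1333,.8)
  p <- c(0.1, 0.005, 0.8, 0.02)
  expect_equal(bh_qvalues(p), c(0.4 / 3, 0.02, 0.8, 0.04))
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_qvalues(p[perm]), bh_qvalues(p)[perm])
  expect_error(bh_qvalues(1.2), "0, 1")
})

test_that("enrich composes the stages and flags by the XD threshold", {
  net <- path3()
  pws <- tibble::tibble(
    pathway_id = c("seeded", "far"),
    name = c("seed pathway", "distal pathway"),
    members = list(c("A", "B"), "C")
  )
  res <- enrich(net, "A", pws)
  expect_equal(res$pathway_id[1], "seeded") # sorted by descending XD
  expect_equal(res$overlap[res$pathway_id == "seeded"], 1L)
  expect_true(all(res$q_value >= res$fisher_p))
  expect_equal(res$significant_xd, res$xd_score > 1)
})

test_that("the planted pathway wins on XD and q across generator seeds", {
  wins <- 0L
  n_runs <- 20L
  for (seed in seq_len(n_runs)) {
    truth <- generate_fixtures(small_spec(seed = 1000 + seed),
                               withr::local_tempdir())
    run <- run_pipeline(fixture_run_config(truth))
    enr <- run$enrichment
    top_xd <- enr$pathway_id[which.max(enr$xd_score)]
    min_q <- enr$pathway_id[which.min(enr$q_value)]
    if (identical(top_xd, truth$enriched_pathway) &&
        identical(min_q, truth$enriched_pathway)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 19L)
})
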