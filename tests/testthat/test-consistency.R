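# independent oracle: encode the sub-group semantics directly over an
# explicit category set, without reusing the implementation's control flow
oracle_resolve <- function(set) {
  contradiction <-
    (1 %in% set && 2 %in% set) ||            # opposite directions
    (4 %in% set && any(c(1, 2, 3) %in% set)) # inactive vs any active
  if (contradiction) return(NA_integer_)
  # keep the most specific member: 1/2 are sub-groups of 3
  if (1 %in% set) 1L else if (2 %in% set) 2L else if (3 %in% set) 3L else 4L
}

test_that("resolve_pair agrees with brute-force enumeration of all 15 subsets", {
  subsets <- Filter(length, unlist(
    lapply(1:4, function(k) utils::combn(1:4, k, simplify = FALSE)),
    recursive = FALSE
  ))
  expect_length(subsets, 15)
  for (s in subsets) {
    expect_identical(resolve_pair(s), oracle_resolve(s),
                     label = paste("subset", paste(s, collapse = ",")))
  }
  expect_error(resolve_pair(integer(0)), "non-empty")
})

test_that("sub-group pairs are retained with the specific label", {
  expect_identical(resolve_pair(c(1, 3)), 1L)
  expect_identical(resolve_pair(c(2, 3)), 2L)
  expect_identical(resolve_pair(3), 3L)
  expect_identical(resolve_pair(c(1, 2)), NA_integer_)
  expect_identical(resolve_pair(c(2, 4)), NA_integer_)
})

test_that("apply_consistency resolves, removes and accounts per connection", {
  prof <- tibble::tibble(
    compound_id = c("c", "c", "d", "d", "e"),
    target_id = c("t", "t", "t", "t", "u"),
    category = c(1L, 3L, 1L, 2L, 4L)
  )
  res <- apply_consistency(prof)
  out <- tidy(res)
  # (c,t): {1,3} resolves to 1; (d,t): {1,2} removed; (e,u) untouched
  expect_equal(out$category[out$compound_id == "c"], 1L)
  expect_false("d" %in% out$compound_id)
  expect_equal(out$category[out$compound_id == "e"], 4L)
  rep <- glance(res)
  expect_equal(rep$n_input_unique, 5)
  expect_equal(rep$n_removed, 2)     # both connections of the {1,2} pair
  expect_equal(rep$n_retained, 3)    # agreeing pairs count all members
  expect_equal(rep$percent_consistent, 60)
})

test_that("a profile with no shared pairs passes through unchanged", {
  prof <- tibble::tibble(
    compound_id = c("a", "b"), target_id = c("t1", "t2"), category = c(2L, 3L)
  )
  res <- apply_consistency(prof)
  expect_equal(glance(res)$n_removed, 0)
  expect_equal(tidy(res)[, names(prof)], prof)
})

test_that("consistency filtering is idempotent and conserves counts", {
  for (seed in 1:10) {
    prof <- withr::with_seed(seed, tibble::tibble(
      compound_id = sample(sprintf("c%02d", 1:12), 60, replace = TRUE),
      target_id = sample(sprintf("t%02d", 1:8), 60, replace = TRUE),
      category = sample(1:4, 60, replace = TRUE)
    ))
    res <- apply_consistency(prof)
    rep <- glance(res)
    # conservation on every input
    expect_equal(rep$n_removed + rep$n_retained, rep$n_input_unique)
    # no pair survives with two categories
    pairs <- paste(tidy(res)$compound_id, tidy(res)$target_id)
    expect_false(any(duplicated(pairs)))
    # idempotence
    res2 <- apply_consistency(tidy(res))
    expect_equal(tidy(res2)$category, tidy(res)$category)
    expect_equal(glance(res2)$n_removed, 0)
  }
})

test_that("the printed headline bookkeeping arithmetic is reproduced", {
  # 8637 unique connections of which 451 contradictory: 224 two-category
  # contradictory pairs plus one three-category pair, rest consistent
  singles <- tibble::tibble(
    compound_id = sprintf("s%04d", 1:8186),
    target_id = "t0", category = 3L
  )
  contra2 <- tibble::tibble(
    compound_id = rep(sprintf("x%03d", 1:224), each = 2),
    target_id = "t1", category = rep(c(1L, 2L), 224)
  )
  contra3 <- tibble::tibble(
    compound_id = "y1", target_id = "t1", category = c(1L, 2L, 3L)
  )
  rep <- glance(apply_consistency(dplyr::bind_rows(singles, contra2, contra3)))
  expect_equal(rep$n_input_unique, 8637)
  expect_equal(rep$n_removed, 451)
  expect_equal(rep$n_retained, 8186)
  expect_equal(round(rep$percent_consistent), 95)
})
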