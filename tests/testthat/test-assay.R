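assay_row <- function(desc, pchembl, comment = NA_character_) {
  tibble::tibble(
    compound_id = "CHEMBL1", target_id = "P1",
    assay_description = desc, pchembl = pchembl, activity_comment = comment
  )
}

cat_of <- function(...) annotate_assays(assay_row(...))$category

test_that("keyword mining assigns directions above the active cutoff", {
  expect_equal(cat_of("Inhibitor of CYP3A4 in human liver microsomes", 6.2), 2L)
  expect_equal(cat_of("Channel opening activity at GABA-A receptor", 6.0), 1L)
  expect_equal(cat_of("Compound channel blocking activity in oocytes", 5.5), 2L)
  expect_equal(cat_of("Tested to inhibit 50% of enzyme turnover", 7.1), 2L)
  # keyword matching is case-insensitive substring search
  expect_equal(cat_of("ACTIVATION of PPAR gamma", 6.0), 1L)
  # no keyword: active with unknown direction
  expect_equal(cat_of("Radioligand binding displacement assay", 6.0), 3L)
})

test_that("records below the cutoff become inactive regardless of text", {
  expect_equal(cat_of("Activation of PPAR gamma", 4.2), 4L)
  expect_equal(cat_of("Inhibitor of something", 4.9), 4L)
})

test_that("contradictory or inconclusive activity comments exclude the record", {
  out <- annotate_assays(assay_row("Inhibitor of X", 6.0, "inconclusive"))
  expect_true(out$excluded)
  out <- annotate_assays(assay_row("Inhibitor of X", 6.0, "Not Active"))
  expect_true(out$excluded)
  out <- annotate_assays(assay_row("Some assay", 4.0, "active"))
  expect_true(out$excluded)
  # comment agreeing with the cutoff is fine
  out <- annotate_assays(assay_row("Inhibitor of X", 6.0, "active"))
  expect_equal(out$category, 2L)
  out <- annotate_assays(assay_row("Some assay", 4.0, "inactive"))
  expect_equal(out$category, 4L)
})

test_that("missing pChEMBL excludes: activity cannot be established", {
  out <- annotate_assays(assay_row("Inhibitor of X", NA_real_))
  expect_true(out$excluded)
  expect_match(out$reason, "pChEMBL")
})

test_that("both-direction keyword hits exclude unless an exclusion resolves them", {
  out <- annotate_assays(
    assay_row("Assay measuring Inhibitors and Activators of X", 6.0)
  )
  expect_true(out$excluded)
  expect_match(out$reason, "both directions")

  # an exclusion pair voids one direction and resolves the conflict
  rules <- assay_keyword_rules()
  rules$exclusions[rules$phrase == "activator"] <- list("inhibitors and activators")
  out <- annotate_assays(
    assay_row("Assay measuring Inhibitors and Activators of X", 6.0),
    rules = rules
  )
  expect_equal(out$category, 2L)
})

test_that("exclusion phrases guard against embedded-substring false hits", {
  # 'inactivation' contains 'activation'; packaged exclusion voids the match
  expect_equal(cat_of("Rate of inactivation of enzyme Y", 6.0), 3L)
})

test_that("the cutoff is configurable and boundary behaviour is exact", {
  row <- assay_row("Inhibitor of X", 5.0)
  expect_equal(annotate_assays(row)$category, 2L) # pChEMBL >= 5 is active
  expect_equal(annotate_assays(row, active_cutoff = 6)$category, 4L)
})

test_that("directional categories never cross the pChEMBL cutoff", {
  descs <- c(
    "Inhibitor of X", "Activation of Y", "Binding of Z",
    "channel blocking activity of W", "inactivation kinetics"
  )
  grid <- tidyr::expand_grid(
    assay_description = descs,
    pchembl = c(3, 4.99, 5, 6.5, 9)
  )
  grid$compound_id <- "c"
  grid$target_id <- "t"
  grid$activity_comment <- NA_character_
  out <- annotate_assays(grid)
  below <- out[out$pchembl < 5 & !out$excluded, ]
  above <- out[out$pchembl >= 5 & !out$excluded, ]
  expect_true(all(below$category == 4L))
  expect_true(all(above$category %in% c(1L, 2L, 3L)))
})

test_that("the outcome is invariant to keyword rule order", {
  rules <- assay_keyword_rules()
  rows <- dplyr::bind_rows(
    assay_row("Inhibitor and activation mixed text", 6),
    assay_row("Channel opening activity", 7),
    assay_row("plain descriptive text", 6),
    assay_row("inhibiting enzyme turnover", 5.5)
  )
  base <- annotate_assays(rows, rules = rules)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, rules[sample.int(nrow(rules)), ])
    expect_equal(annotate_assays(rows, rules = perm)$category, base$category)
  }
})
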