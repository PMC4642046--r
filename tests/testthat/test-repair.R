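repair_doc <- function() {
  st_document(
    "d1", "PrA phosphorylates PrB at SerC .",
    entities = tibble::tibble(
      id = c("T1", "T2", "T3"),
      type = c("Protein", "Protein", "Phosphorylation"),
      start = c(0L, 19L, 4L), end = c(3L, 22L, 18L),
      text = c("PrA", "PrB", "phosphorylates"),
      given = c(TRUE, TRUE, FALSE)))
}

test_that("an invalid argument is renamed to the missing required role", {
  # Gene_expression demands exactly one Theme; a lone Cause gets renamed
  d <- repair_doc()
  d$entities$type[3] <- "Gene_expression"
  d$events <- tibble::tibble(
    id = "E1", type = "Gene_expression", trigger = "T3",
    args = list(tibble::tibble(role = "Cause", target = "T2")))
  out <- validate_and_repair(d, demo_scheme())
  expect_equal(out$log$action, "rename_argument")
  expect_equal(out$document$events$args[[1]]$role, "Theme")
  expect_true(st_is_valid(out$document, demo_scheme()))
})

test_that("an argument beyond the role maximum is removed", {
  d <- repair_doc()
  d$events <- tibble::tibble(
    id = "E1", type = "Phosphorylation", trigger = "T3",
    args = list(tibble::tibble(role = c("Theme", "Theme2"),
                               target = c("T1", "T2"))))
  out <- validate_and_repair(d, demo_scheme())
  expect_true("remove_argument" %in% out$log$action)
  expect_equal(nrow(out$document$events$args[[1]]), 1)
  expect_true(st_is_valid(out$document, demo_scheme()))
})

test_that("events referencing removed events are removed recursively", {
  d <- repair_doc()
  d$entities <- dplyr::bind_rows(
    d$entities,
    tibble::tibble(id = "T4", type = "Regulation", start = 26L, end = 30L,
                   text = "SerC", given = FALSE))
  d$events <- tibble::tibble(
    id = c("E1", "E2"),
    type = c("Phosphorylation", "Regulation"),
    trigger = c("T3", "T4"),
    args = list(
      tibble::tibble(role = "Cause", target = "T1"),  # no Theme: unrepairable?
      tibble::tibble(role = "Theme", target = "E1")))
  # E1's Cause renames to Theme (rule 1), so force removal instead: an
  # unknown role plus nothing missing-compatible
  d$events$args[[1]] <- tibble::tibble(role = c("Bogus", "Worse"),
                                       target = c("T1", "T2"))
  out <- validate_and_repair(d, demo_scheme())
  expect_true(all(c("E1", "E2") %in% out$log$event))
  expect_equal(nrow(out$document$events), 0)
  expect_true(st_is_valid(out$document, demo_scheme()))
})

test_that("repair always yields a document that validates cleanly", {
  g <- gen_corpus(8, seed = 51, site_rate = 0.5, nesting_rate = 0.3)
  pert <- perturb_predictions(
    g$st_documents,
    errors = list(retype_event = 3, invalid_role = 3, drop_argument = 3,
                  extra_argument = 3, duplicate_event = 2),
    scheme = g$scheme)
  expect_gt(nrow(pert$applied), 0)
  for (d in pert$documents) {
    out <- validate_and_repair(d, g$scheme)
    expect_true(st_is_valid(out$document, g$scheme))
  }
})

test_that("zero-error perturbation is the identity", {
  g <- gen_corpus(3, seed = 52)
  pert <- perturb_predictions(g$st_documents, errors = list(),
                              scheme = g$scheme)
  expect_equal(nrow(pert$applied), 0)
  for (i in seq_along(g$st_documents)) {
    expect_true(st_documents_equivalent(g$st_documents[[i]],
                                        pert$documents[[i]]))
  }
})

test_that("injected duplicate events are removed by standoff deduplication", {
  g <- gen_corpus(4, seed = 53)
  pert <- perturb_predictions(g$st_documents,
                              errors = list(duplicate_event = 1),
                              scheme = g$scheme)
  i <- match(pert$applied$document[1],
             vapply(pert$documents, function(d) d$id, character(1)))
  d <- pert$documents[[i]]
  back <- roundtrip_st(d, g$parses[[i]], g$scheme)
  # the duplicate disappears on the graph -> standoff conversion
  expect_true(st_documents_equivalent(g$st_documents[[i]], back))
})
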