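nested_regulation_sentence <- function() {
  # a nested chain: regulates -> Regulation -> Theme -> Regulation
  toks <- tibble::tibble(
    id = paste0("t", 1:4),
    text = c("PrA", "regulates", "xreg", "."),
    pos = c("NN", "VBZ", "NN", "."),
    start = c(0L, 4L, 14L, 19L), end = c(3L, 13L, 18L, 20L))
  deps <- tibble::tibble(type = c("nsubj", "dobj", "punct"),
                         governor = c("t2", "t2", "t2"),
                         dependent = c("t1", "t3", "t4"))
  ent <- tibble::tibble(
    id = c("e1", "e2", "e3"),
    type = c("Protein", "Regulation", "Regulation"),
    start = c(0L, 4L, 14L), end = c(3L, 13L, 18L),
    text = c("PrA", "regulates", "xreg"),
    head = c("t1", "t2", "t3"),
    given = c(TRUE, FALSE, FALSE), event = c(FALSE, TRUE, TRUE))
  itr <- tibble::tibble(
    id = "i1", type = "Theme", source = "e2", target = "e3",
    directed = TRUE, event = TRUE, given = FALSE, site_of = NA_character_,
    source_role = NA_character_, target_role = NA_character_,
    cross_sentence = FALSE)
  sentence_graph("d1.s1", "PrA regulates xreg .", tokens = toks,
                 dependencies = deps, entities = complete_layer2(ent),
                 interactions = itr)
}

test_that("dot output contains one node per token and one arc per edge", {
  s <- nested_regulation_sentence()
  dot <- to_dot(s)
  for (tid in s$tokens$id) {
    expect_true(grepl(sprintf('"%s" \\[label=', tid), dot))
  }
  # a nested chain renders two trigger boxes and a trigger-to-trigger arc
  expect_equal(length(gregexpr("shape=box", dot)[[1]]), 3)
  expect_true(grepl('"e2" -> "e3" [label="Theme"', dot, fixed = TRUE))
  # dependency arcs present
  expect_true(grepl('label="nsubj"', dot, fixed = TRUE))
  # rough syntactic sanity: braces balance and every line inside is a
  # node, edge or attribute statement
  expect_equal(sum(strsplit(dot, "")[[1]] == "{"),
               sum(strsplit(dot, "")[[1]] == "}"))
  expect_true(startsWith(dot, "digraph"))
})

test_that("layer toggles hide the corresponding elements", {
  s <- nested_regulation_sentence()
  parse_only <- to_dot(s, render_options(show_annotation = FALSE))
  expect_false(grepl("shape=box", parse_only))
  expect_true(grepl('label="dobj"', parse_only, fixed = TRUE))
  anno_only <- to_dot(s, render_options(show_parse = FALSE))
  expect_false(grepl('label="dobj"', anno_only, fixed = TRUE))
  expect_true(grepl("shape=box", anno_only))
  expect_error(render_options(show_parse = FALSE, show_annotation = FALSE),
               "at least one")
})

test_that("rendering is deterministic and empty sentences get a placeholder", {
  s <- nested_regulation_sentence()
  expect_identical(to_dot(s), to_dot(s))
  empty <- sentence_graph("d1.s1", "")
  dot <- to_dot(empty)
  expect_true(grepl("empty sentence", dot))
  expect_true(startsWith(dot, "digraph"))
})
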