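test_that("head resolution follows the governor-outside-span rule", {
  s <- tiny_sentence()
  # single-token span
  expect_equal(resolve_head_token(4, 18, s), "t2")
  # "protein kinase" with kinase -> protein (nn), kinase governed outside
  toks <- tibble::tibble(id = c("t1", "t2", "t3"),
                         text = c("protein", "kinase", "acts"),
                         pos = c("NN", "NN", "VBZ"),
                         start = c(0L, 8L, 15L), end = c(7L, 14L, 19L))
  deps <- tibble::tibble(type = c("nn", "nsubj"),
                         governor = c("t2", "t3"), dependent = c("t1", "t2"))
  pk <- sentence_graph("s1", "protein kinase acts", tokens = toks,
                       dependencies = deps)
  expect_equal(resolve_head_token(0, 14, pk), "t2")
  # both tokens governed from outside -> rightmost
  deps2 <- tibble::tibble(type = c("amod", "nsubj"),
                          governor = c("t3", "t3"), dependent = c("t1", "t2"))
  pk2 <- sentence_graph("s1", "protein kinase acts", tokens = toks,
                        dependencies = deps2)
  expect_equal(resolve_head_token(0, 14, pk2), "t2")
  # cycle inside span -> rightmost overlapping token
  deps3 <- tibble::tibble(type = c("dep", "dep"),
                          governor = c("t1", "t2"), dependent = c("t2", "t1"))
  pk3 <- sentence_graph("s1", "protein kinase acts", tokens = toks,
                        dependencies = deps3)
  expect_equal(resolve_head_token(0, 14, pk3), "t2")
  # span overlapping zero tokens is an offset error naming the span
  expect_error(resolve_head_token(100, 104, s), "overlaps no token")
})

test_that("head resolution is idempotent for a re-built identical sentence", {
  g <- gen_corpus(2, seed = 3)
  s <- g$corpus$documents[[1]]$sentences[[1]]
  rebuilt <- sentence_graph(s$id, s$text, tokens = s$tokens,
                            dependencies = s$dependencies)
  for (i in seq_len(nrow(s$entities))) {
    expect_equal(resolve_head_token(s$entities$start[i], s$entities$end[i],
                                    rebuilt),
                 s$entities$head[i])
  }
})

test_that("graph validation reports dangling endpoints and siteOf violations", {
  s <- tiny_sentence()
  expect_equal(nrow(validate_graph(s)), 0)
  ent <- tibble::tibble(id = c("e1", "e2"), type = c("Protein", "Phosphorylation"),
                        start = c(0L, 4L), end = c(3L, 18L),
                        text = c("PrA", "phosphorylates"),
                        head = c("t1", "t2"), given = c(TRUE, FALSE),
                        event = c(FALSE, TRUE))
  s$entities <- complete_layer2(ent)
  # dangling target
  s$interactions <- tibble::tibble(
    id = "i1", type = "Theme", source = "e2", target = "missing",
    directed = TRUE, event = TRUE, given = FALSE, site_of = NA_character_,
    source_role = NA_character_, target_role = NA_character_,
    cross_sentence = FALSE)
  v <- validate_graph(s)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "dangling_endpoint")
  # siteOf naming an edge with a different source node
  s$interactions <- tibble::tibble(
    id = c("i1", "i2"), type = c("Theme", "Site"),
    source = c("e2", "e1"), target = c("e1", "e1"),
    directed = TRUE, event = TRUE, given = FALSE,
    site_of = c(NA, "i1"),
    source_role = NA_character_, target_role = NA_character_,
    cross_sentence = FALSE)
  v <- validate_graph(s)
  expect_true(any(v$kind == "site_of"))
})

test_that("every generated corpus validates cleanly (generator contract)", {
  for (seed in c(2, 5)) {
    g <- gen_corpus(6, seed = seed, nesting_rate = 0.3,
                    shared_trigger_rate = 0.3, equiv_rate = 0.3,
                    site_rate = 0.5, cross_sentence_rate = 0.2,
                    sentences_per_document = 3)
    expect_equal(nrow(validate_graph(g$corpus)), 0)
  }
})
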