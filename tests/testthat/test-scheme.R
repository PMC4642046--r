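test_that("argument-count intervals are the observed extremes", {
  # synthetic corpus with events X(Theme:A) and X(Theme:A, Cause:B):
  # X overall [1,2], Theme [1,1], Cause [0,1]
  toks <- tibble::tibble(id = c("t1", "t2", "t3"),
                         text = c("PrB", "xx", "PrA"),
                         pos = c("NN", "VBZ", "NN"),
                         start = c(0L, 4L, 7L), end = c(3L, 6L, 10L))
  mk <- function(sid, with_cause) {
    ent <- tibble::tibble(
      id = paste0(sid, ".e", 1:3),
      type = c("A", "X", "B"), start = c(7L, 4L, 0L), end = c(10L, 6L, 3L),
      text = c("PrA", "xx", "PrB"), head = c("t3", "t2", "t1"),
      given = c(TRUE, FALSE, TRUE), event = c(FALSE, TRUE, FALSE))
    itr <- tibble::tibble(
      id = paste0(sid, ".i", seq_len(1 + with_cause)),
      type = c("Theme", if (with_cause) "Cause"),
      source = paste0(sid, ".e2"),
      target = paste0(sid, c(".e1", if (with_cause) ".e3")),
      directed = TRUE, event = TRUE, given = FALSE,
      site_of = NA_character_, source_role = NA_character_,
      target_role = NA_character_, cross_sentence = FALSE)
    ev <- tibble::tibble(id = paste0(sid, ".ev1"), trigger = paste0(sid, ".e2"),
                         args = list(tibble::tibble(interaction = itr$id,
                                                    target_event = NA_character_)))
    sentence_graph(sid, "PrB xx PrA", tokens = toks, entities = ent,
                   interactions = itr, events = ev)
  }
  doc <- ig_document("d1", "PrB xx PrA PrB xx PrA",
                     list(mk("d1.s1", FALSE)))
  doc$sentences[[1]] <- mk("d1.s1", FALSE)
  s2 <- mk("d1.s2", TRUE); s2$offset <- 11L
  doc$sentences[[2]] <- s2
  sc <- learn_scheme(ig_corpus(list(doc)))
  i <- match("X", sc$events$type)
  expect_equal(sc$events$overall_min[i], 1L)
  expect_equal(sc$events$overall_max[i], 2L)
  cons <- sc$events$arguments[[i]]
  expect_equal(cons$min[cons$role == "Theme"], 1L)
  expect_equal(cons$max[cons$role == "Theme"], 1L)
  expect_equal(cons$min[cons$role == "Cause"], 0L)
  expect_equal(cons$max[cons$role == "Cause"], 1L)
  # entity vs event classification and prediction targets
  expect_setequal(sc$entity_types, c("A", "B"))
  expect_equal(event_types(sc), "X")
  expect_equal(sc$targets$entities, "X")
  expect_setequal(sc$targets$interactions, c("Cause", "Theme"))
})

test_that("an event-flagged node type with no arguments learns overall [0,0]", {
  toks <- tibble::tibble(id = "t1", text = "xglyc", pos = "NN",
                         start = 0L, end = 5L)
  ent <- tibble::tibble(id = "d1.s1.e1", type = "Glycolysis",
                        start = 0L, end = 5L, text = "xglyc", head = "t1",
                        given = FALSE, event = TRUE)
  ev <- tibble::tibble(id = "d1.s1.ev1", trigger = "d1.s1.e1",
                       args = list(tibble::tibble(interaction = character(),
                                                  target_event = character())))
  s <- sentence_graph("d1.s1", "xglyc", tokens = toks, entities = ent,
                      events = ev)
  sc <- learn_scheme(ig_corpus(list(ig_document("d1", "xglyc", list(s)))))
  expect_equal(event_types(sc), "Glycolysis")
  expect_false("Glycolysis" %in% sc$entity_types)
  i <- match("Glycolysis", sc$events$type)
  expect_equal(c(sc$events$overall_min[i], sc$events$overall_max[i]), c(0L, 0L))
})

test_that("edge validity follows the learned definitions", {
  sc <- demo_scheme()
  expect_true(is_valid_edge(sc, "Gene_expression", "Protein", "Theme"))
  expect_false(is_valid_edge(sc, "Protein", "Protein", "Theme"))
  expect_true(is_valid_edge(sc, "Entity", "Protein", "SiteParent"))
  expect_false(is_valid_edge(sc, "Protein", "Entity", "SiteParent"))
  expect_true(is_valid_edge(sc, "Regulation", "Binding", "Theme"))
  expect_false(is_valid_edge(sc, "Gene_expression", "Protein", "Cause"))
  # any query against an empty scheme is false
  empty <- annotation_scheme()
  expect_false(is_valid_edge(empty, "A", "B", "Theme"))
  expect_false(is_valid_edge(empty, "A", "B"))
})

test_that("event-structure validity enforces counts, targets and site primaries", {
  sc <- demo_scheme()
  v <- function(type, roles, targets, prim = rep(NA_character_, length(roles))) {
    is_valid_event_structure(sc, type, tibble::tibble(
      role = roles, target_type = targets, site_primary_role = prim))
  }
  expect_true(v("Phosphorylation", "Theme", "Protein"))
  expect_false(v("Binding", c("Theme", "Theme", "Theme"),
                 rep("Protein", 3)))
  expect_true(v("Binding", c("Theme", "Theme"), rep("Protein", 2)))
  # a Site whose primary is Cause when only Theme is licensed
  expect_false(v("Phosphorylation", c("Theme", "Cause", "Site"),
                 c("Protein", "Protein", "Entity"),
                 c(NA, NA, "Cause")))
  expect_true(v("Phosphorylation", c("Theme", "Cause", "Site"),
                c("Protein", "Protein", "Entity"),
                c(NA, NA, "Theme")))
  # zero arguments only for zero-capable definitions
  expect_false(is_valid_event_structure(sc, "Phosphorylation",
                                        tibble::tibble()))
})

test_that("scheme serialization round-trips losslessly", {
  for (sc in list(demo_scheme(), random_scheme(4), annotation_scheme())) {
    txt <- serialize_scheme(sc)
    back <- parse_scheme(txt)
    expect_identical(serialize_scheme(back), txt)
  }
  # site primary roles survive
  txt <- serialize_scheme(demo_scheme())
  expect_true(grepl("Site \\{Theme\\}", txt))
  expect_identical(serialize_scheme(parse_scheme(txt)), txt)
  # an empty scheme serializes to the header only
  expect_equal(serialize_scheme(annotation_scheme()),
               "# annotation scheme v1\n")
})

test_that("learning is invariant to document order and monotone in data", {
  g <- gen_corpus(8, seed = 71, site_rate = 0.5, nesting_rate = 0.3)
  docs <- g$corpus$documents
  s1 <- learn_scheme(ig_corpus(docs))
  s2 <- learn_scheme(ig_corpus(rev(docs)))
  expect_identical(serialize_scheme(s1), serialize_scheme(s2))
  # adding documents can only widen intervals and grow type sets
  half <- learn_scheme(ig_corpus(docs[1:4]))
  full <- s1
  for (ty in event_types(half)) {
    i <- match(ty, half$events$type); j <- match(ty, full$events$type)
    expect_true(full$events$overall_min[j] <= half$events$overall_min[i])
    expect_true(full$events$overall_max[j] >= half$events$overall_max[i])
  }
  expect_true(all(half$entity_types %in%
                    c(full$entity_types, event_types(full))))
})

test_that("every gold event satisfies the scheme learned from its corpus", {
  g <- gen_corpus(8, seed = 72, site_rate = 0.5, nesting_rate = 0.3,
                  shared_trigger_rate = 0.3)
  sc <- learn_scheme(g$corpus)
  for (d in g$st_documents) {
    expect_true(st_is_valid(d, sc))
  }
})

test_that("saturated corpora recover the generating scheme exactly", {
  for (seed in 1:6) {
    true_scheme <- random_scheme(seed)
    g <- generate_corpus(generator_spec(scheme = true_scheme,
                                        saturate = TRUE, seed = seed + 500))
    learned <- learn_scheme(g$corpus)
    expect_identical(serialize_scheme(learned),
                     serialize_scheme(true_scheme))
  }
})

test_that("an unannotated corpus produces an empty scheme with a warning", {
  toks <- tibble::tibble(id = "t1", text = "x", pos = "NN",
                         start = 0L, end = 1L)
  s <- sentence_graph("d1.s1", "x", tokens = toks)
  expect_warning(sc <- learn_scheme(ig_corpus(list(ig_document("d1", "x", list(s))))),
                 "no annotation")
  expect_equal(length(sc$entity_types) + nrow(sc$events), 0L)
})
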