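test_that("shortest undirected paths are minimal with lexicographic tie-break", {
  s <- tiny_sentence()
  # identical endpoints: empty path
  p <- shortest_undirected_path("t2", "t2", s)
  expect_equal(p$tokens, "t2")
  expect_equal(p$labels, character())
  # chain a -> b -> c: length 2
  p <- shortest_undirected_path("t1", "t3", s)
  expect_equal(length(p$labels), 2)
  expect_equal(p$tokens, c("t1", "t2", "t3"))
  # disconnected tokens
  toks <- tibble::tibble(id = c("t1", "t2"), text = c("a", "b"),
                         pos = c("NN", "NN"), start = c(0L, 2L),
                         end = c(1L, 3L))
  iso <- sentence_graph("s", "a b", tokens = toks)
  expect_null(shortest_undirected_path("t1", "t2", iso))
  # diamond with two length-2 paths: lexicographically smallest label
  # sequence wins (checked against brute-force enumeration)
  toks <- tibble::tibble(id = paste0("t", 1:4),
                         text = c("a", "b", "c", "d"),
                         pos = rep("NN", 4),
                         start = c(0L, 2L, 4L, 6L), end = c(1L, 3L, 5L, 7L))
  deps <- tibble::tibble(type = c("zz", "amod", "bb", "cc"),
                         governor = c("t1", "t1", "t2", "t3"),
                         dependent = c("t2", "t3", "t4", "t4"))
  dia <- sentence_graph("s", "a b c d", tokens = toks, dependencies = deps)
  got <- shortest_undirected_path("t1", "t4", dia)
  all_sp <- bf_all_shortest_paths("t1", "t4", dia)
  keys <- vapply(all_sp, function(p) paste(p$labels, collapse = "\r"),
                 character(1))
  best <- all_sp[[order(keys)[1]]]
  expect_equal(got$labels, best$labels)
  expect_equal(got$tokens, best$tokens)
  expect_equal(got$labels, c("amod", "cc"))
})

test_that("path tie-break agrees with brute force on generated sentences", {
  g <- gen_corpus(6, seed = 81, events_per_sentence = c(2, 3))
  sentences <- gather_sentences(g$corpus)
  checked <- 0
  for (s in sentences) {
    ids <- s$tokens$id
    for (a in ids[1:min(3, length(ids))]) {
      b <- ids[length(ids) - 1]
      got <- shortest_undirected_path(a, b, s)
      oracle <- bf_all_shortest_paths(a, b, s)
      if (is.null(got)) {
        expect_equal(length(oracle), 0)
      } else if (length(got$labels)) {
        keys <- vapply(oracle, function(p) paste(p$labels, collapse = "\r"),
                       character(1))
        expect_equal(got$labels, oracle[[order(keys)[1]]]$labels)
      }
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("entity examples cover non-given tokens with conventionally named features", {
  s <- tiny_sentence()
  ent <- tibble::tibble(
    id = c("e1", "e2"), type = c("Protein", "Phosphorylation"),
    start = c(0L, 4L), end = c(3L, 18L), text = c("PrA", "phosphorylates"),
    head = c("t1", "t2"), given = c(TRUE, FALSE), event = c(FALSE, TRUE))
  s$entities <- complete_layer2(ent)
  ex <- build_entity_examples(s, demo_scheme())
  # 6 tokens minus the one covered by the given Protein
  expect_equal(nrow(ex), 5)
  i <- which(vapply(ex$anchor, function(a) a$token == "t2", logical(1)))
  expect_equal(ex$gold[i], "Phosphorylation")
  f <- ex$features[[i]]
  expect_true("POS_VBZ" %in% f)
  expect_true("txt_phosphorylates" %in% f)
  expect_true(any(startsWith(f, "stem_")))
  expect_true(any(startsWith(f, "dt_")))
  expect_true(any(startsWith(f, "tt_")))
  expect_true("linear_1_txt_PrB" %in% f)
  expect_true("linear_-1_txt_PrA" %in% f)
  expect_true("dist_1_annType_Protein" %in% f)
  expect_true("bow_at" %in% f)
  # all other tokens are negatives
  expect_equal(sort(unique(ex$gold[-i])), "neg")
})

test_that("tokens heading several nodes get a merged gold class", {
  s <- tiny_sentence()
  ent <- tibble::tibble(
    id = c("e1", "e2"), type = c("Phosphorylation", "Regulation"),
    start = c(4L, 4L), end = c(18L, 18L),
    text = c("phosphorylates", "phosphorylates"),
    head = c("t2", "t2"), given = c(FALSE, FALSE), event = c(TRUE, TRUE))
  s$entities <- complete_layer2(ent)
  ex <- build_entity_examples(s, demo_scheme())
  i <- which(vapply(ex$anchor, function(a) a$token == "t2", logical(1)))
  expect_equal(ex$gold[i], "Phosphorylation---Regulation")
})

test_that("edge candidates equal brute-force all-pairs minus invalid pairs", {
  g <- gen_corpus(10, seed = 82, events_per_sentence = c(1, 2),
                  site_rate = 0.5, nesting_rate = 0.3)
  sc <- learn_scheme(g$corpus)
  for (s in gather_sentences(g$corpus)) {
    if (nrow(s$entities) > 8) next
    ex <- build_edge_examples(s, sc)
    got <- sort(vapply(ex$anchor, function(a)
      paste(a$source, a$target), character(1)))
    oracle <- sort(vapply(bf_edge_candidates(s$entities, sc),
                          function(p) paste(p[1], p[2]), character(1)))
    expect_equal(got, oracle)
  }
})

test_that("edge examples carry path features and respect the scheme filter", {
  s <- tiny_sentence()
  ent <- tibble::tibble(
    id = c("e1", "e2", "e3"),
    type = c("Protein", "Phosphorylation", "Protein"),
    start = c(0L, 4L, 19L), end = c(3L, 18L, 22L),
    text = c("PrA", "phosphorylates", "PrB"),
    head = c("t1", "t2", "t3"), given = c(TRUE, FALSE, TRUE),
    event = c(FALSE, TRUE, FALSE))
  s$entities <- complete_layer2(ent)
  ex <- build_edge_examples(s, demo_scheme())
  pairs <- vapply(ex$anchor, function(a) paste(a$source, a$target), character(1))
  # trigger -> protein candidates only; never protein -> protein
  expect_setequal(pairs, c("e2 e1", "e2 e3"))
  f <- ex$features[[1]]
  expect_true(any(startsWith(f, "dep_Reverse_")) ||
                any(startsWith(f, "dep_Forward_")))
  expect_true(any(startsWith(f, "e1_")))
  expect_true(any(startsWith(f, "e2_")))
  expect_true(any(startsWith(f, "tokenPath_")))
  # empty node set: no examples
  s2 <- tiny_sentence()
  expect_equal(nrow(build_edge_examples(s2, demo_scheme())), 0)
})

test_that("unmerging candidates equal brute-force power-set filtering", {
  # spec'd enumeration cases against the demo definitions
  g <- gen_corpus(12, seed = 83, site_rate = 0.5, shared_trigger_rate = 0.4,
                  nesting_rate = 0.3, events_per_sentence = c(1, 2))
  sc <- learn_scheme(g$corpus)
  n_checked <- 0
  for (s in gather_sentences(g$corpus)) {
    triggers <- s$entities$id[s$entities$type %in% event_types(sc)]
    for (nd in triggers) {
      got <- enumerate_event_candidates(s, nd, sc)
      oracle <- bf_unmerging_subsets(s, nd, sc)
      expect_equal(canon_subsets(got), canon_subsets(oracle))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("unmerging enumerates exactly the structurally valid subsets", {
  # Theme[1,1], Cause[0,1], overall [1,2] with edges Theme:A, Theme:B,
  # Cause:C -> candidates {A}, {B}, {A,C}, {B,C}
  sc <- annotation_scheme(
    entity_types = "Protein",
    events = tibble::tibble(
      type = "X", overall_min = 1L, overall_max = 2L,
      arguments = list(dplyr::bind_rows(
        bioevex:::arg_constraint("Cause", 0, 1, "Protein"),
        bioevex:::arg_constraint("Theme", 1, 1, "Protein")))),
    targets = list(entities = "X", interactions = c("Theme", "Cause")))
  toks <- tibble::tibble(id = paste0("t", 1:4),
                         text = c("xx", "PrA", "PrB", "PrC"),
                         pos = c("VBZ", "NN", "NN", "NN"),
                         start = c(0L, 3L, 7L, 11L), end = c(2L, 6L, 10L, 14L))
  ent <- tibble::tibble(
    id = c("e0", "eA", "eB", "eC"),
    type = c("X", "Protein", "Protein", "Protein"),
    start = c(0L, 3L, 7L, 11L), end = c(2L, 6L, 10L, 14L),
    text = c("xx", "PrA", "PrB", "PrC"),
    head = paste0("t", 1:4), given = c(FALSE, TRUE, TRUE, TRUE),
    event = c(TRUE, FALSE, FALSE, FALSE))
  itr <- tibble::tibble(
    id = c("i1", "i2", "i3"), type = c("Theme", "Theme", "Cause"),
    source = "e0", target = c("eA", "eB", "eC"),
    directed = TRUE, event = TRUE, given = FALSE, site_of = NA_character_,
    source_role = NA_character_, target_role = NA_character_,
    cross_sentence = FALSE)
  s <- sentence_graph("s1", "xx PrA PrB PrC", tokens = toks,
                      entities = complete_layer2(ent), interactions = itr)
  got <- enumerate_event_candidates(s, "e0", sc)
  expect_setequal(canon_subsets(got), c("i1", "i2", "i1,i3", "i2,i3"))
  # Binding-style Theme[1,2] with edges to A and B -> {A}, {B}, {A,B}
  sc2 <- annotation_scheme(
    entity_types = "Protein",
    events = tibble::tibble(
      type = "X", overall_min = 1L, overall_max = 2L,
      arguments = list(bioevex:::arg_constraint("Theme", 1, 2, "Protein"))),
    targets = list(entities = "X", interactions = "Theme"))
  s2 <- s
  s2$interactions <- itr[1:2, ]
  got2 <- enumerate_event_candidates(s2, "e0", sc2)
  expect_setequal(canon_subsets(got2), c("i1", "i2", "i1,i2"))
})

test_that("the subset cap trims enumeration with a warning", {
  sc <- annotation_scheme(
    entity_types = "Protein",
    events = tibble::tibble(
      type = "X", overall_min = 1L, overall_max = 12L,
      arguments = list(bioevex:::arg_constraint("Theme", 1, 12, "Protein"))),
    targets = list(entities = "X", interactions = "Theme"))
  n <- 12
  toks <- tibble::tibble(id = paste0("t", 0:n),
                         text = c("xx", paste0("Pr", 1:n)),
                         pos = c("VBZ", rep("NN", n)),
                         start = seq(0L, by = 5L, length.out = n + 1),
                         end = seq(0L, by = 5L, length.out = n + 1) + 3L)
  ent <- tibble::tibble(
    id = c("e0", paste0("e", 1:n)), type = c("X", rep("Protein", n)),
    start = toks$start, end = toks$end, text = toks$text, head = toks$id,
    given = c(FALSE, rep(TRUE, n)), event = c(TRUE, rep(FALSE, n)))
  itr <- tibble::tibble(
    id = sprintf("i%02d", 1:n), type = "Theme", source = "e0",
    target = paste0("e", 1:n), directed = TRUE, event = TRUE, given = FALSE,
    site_of = NA_character_, source_role = NA_character_,
    target_role = NA_character_, cross_sentence = FALSE)
  s <- sentence_graph("s1", paste(toks$text, collapse = " "),
                      tokens = toks, entities = complete_layer2(ent),
                      interactions = itr)
  expect_warning(got <- enumerate_event_candidates(s, "e0", sc,
                                                   max_subsets = 256L),
                 "capping")
  expect_lte(length(got), 256)
})

test_that("unmerging feature names follow the arg/trg conventions", {
  g <- gen_corpus(4, seed = 84, site_rate = 0.6)
  sc <- learn_scheme(g$corpus)
  ex <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                build_unmerging_examples, scheme = sc))
  f <- unique(unlist(ex$features))
  expect_true(any(startsWith(f, "argTheme_dep_")))
  expect_true(any(startsWith(f, "trg_dt_")))
  expect_true(any(startsWith(f, "trg_tt_")))
  expect_true(any(startsWith(f, "bow_")))
  expect_true(any(startsWith(f, "numArgs_")))
})

test_that("modifier examples cover capable triggers with negation cues", {
  g <- gen_corpus(10, seed = 85, negation_rate = 0.5, speculation_rate = 0.3)
  sc <- learn_scheme(g$corpus)
  ex <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                build_modifier_examples, scheme = sc))
  expect_true(any(ex$gold == "negation"))
  i <- which(ex$gold == "negation")[1]
  f <- ex$features[[i]]
  expect_true("t1HOut_neg" %in% f)
  expect_true("t1HOut_neg_RB" %in% f)
  expect_true("dist_1_txt_not" %in% f)
  # a trigger type outside the modifier targets yields no example
  sc2 <- sc
  sc2$modifiers <- list(negation = character(), speculation = character())
  ex2 <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                 build_modifier_examples, scheme = sc2))
  expect_equal(nrow(ex2), 0)
  # speculation word-list matches appear
  expect_true(any(vapply(ex$features, function(f)
    "spec_word_possibly" %in% f, logical(1))))
})

test_that("feature extraction is pure: identical sentences give identical features", {
  g <- gen_corpus(3, seed = 86, site_rate = 0.5)
  sc <- learn_scheme(g$corpus)
  s <- gather_sentences(g$corpus)[[1]]
  for (builder in list(build_entity_examples, build_edge_examples,
                       build_unmerging_examples, build_modifier_examples)) {
    a <- builder(s, sc)
    b <- builder(s, sc)
    expect_identical(a$features, b$features)
  }
})

test_that("the feature space is frozen: unseen names map to no column", {
  ex <- tibble::tibble(id = c("a", "b"), step = "entity",
                       gold = c("X", "neg"),
                       features = list(c("f1", "f2"), c("f2", "f3")),
                       anchor = list(NULL, NULL))
  sp <- feature_space(ex)
  expect_equal(sp$names, c("f1", "f2", "f3"))
  new_ex <- tibble::tibble(id = "c", step = "entity", gold = NA_character_,
                           features = list(c("f2", "brand_new")),
                           anchor = list(NULL))
  m <- examples_to_matrix(new_ex, sp)
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(sum(m), 1)
  expect_equal(unname(m[1, "f2"]), 1)
})

test_that("sparse text export writes one line per example", {
  g <- gen_corpus(2, seed = 87)
  sc <- learn_scheme(g$corpus)
  ex <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                build_entity_examples, scheme = sc))
  sp <- feature_space(ex)
  path <- withr::local_tempfile()
  write_examples_sparse(ex, sp, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(ex))
  expect_true(all(grepl("^\\d+ qid:", lines)))
  fmap <- readLines(paste0(path, ".features"))
  expect_equal(length(fmap), length(sp$names))
})
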