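phospho_parse <- function() {
  list(list(offset = 0L, text = "PrA phosphorylates PrB at SerC .",
            tokens = tiny_sentence()$tokens,
            dependencies = tiny_sentence()$dependencies))
}

test_that("a Site argument yields trigger edges, a SiteParent edge and siteOf", {
  txt <- "PrA phosphorylates PrB at SerC ."
  a1 <- c("T1\tProtein 0 3\tPrA", "T2\tProtein 19 22\tPrB")
  a2 <- c("T3\tPhosphorylation 4 18\tphosphorylates",
          "T4\tEntity 26 30\tSerC",
          "E1\tPhosphorylation:T3 Theme:T2 Site:T4")
  d <- read_st_document(txt, a1, a2, id = "d1")
  doc <- st_to_graph(d, phospho_parse())
  s <- doc$sentences[[1]]
  trig <- s$entities$id[s$entities$type == "Phosphorylation"]
  expect_true(s$entities$event[s$entities$type == "Phosphorylation"])
  out_edges <- s$interactions[s$interactions$source == trig, ]
  expect_setequal(out_edges$type, c("Theme", "Site"))
  sp <- s$interactions[s$interactions$type == "SiteParent", ]
  expect_equal(nrow(sp), 1)
  expect_equal(s$entities$type[match(sp$source, s$entities$id)], "Entity")
  expect_equal(s$entities$type[match(sp$target, s$entities$id)], "Protein")
  site_edge <- s$interactions[s$interactions$type == "Site", ]
  theme_edge <- s$interactions[s$interactions$type == "Theme", ]
  expect_equal(site_edge$site_of, theme_edge$id)
})

test_that("equivalence groups expand into one event copy per member", {
  txt <- "PrA phosphorylates PrB at SerC ."
  a1 <- c("T1\tProtein 0 3\tPrA", "T2\tProtein 19 22\tPrB",
          "T4\tProtein 26 30\tSerC", "*\tEquiv T2 T4")
  a2 <- c("T3\tPhosphorylation 4 18\tphosphorylates",
          "E1\tPhosphorylation:T3 Theme:T2")
  d <- read_st_document(txt, a1, a2, id = "d1")
  doc <- st_to_graph(d, phospho_parse())
  s <- doc$sentences[[1]]
  expect_equal(nrow(s$events), 2)
  expect_equal(sum(s$interactions$type == "Theme"), 2)
  # collapsing on write recovers the same expansion surface
  back <- graph_to_st(doc, demo_scheme())
  expect_true(st_documents_equivalent(d, back))
})

test_that("relations with an event-trigger endpoint are skipped with a warning", {
  txt <- "PrA phosphorylates PrB at SerC ."
  a1 <- c("T1\tProtein 0 3\tPrA", "T2\tProtein 19 22\tPrB")
  a2 <- c("T3\tPhosphorylation 4 18\tphosphorylates",
          "T4\tEntity 26 30\tSerC",
          "E1\tPhosphorylation:T3 Theme:T2",
          "R1\tCoreference Subject:T3 Object:T2")
  d <- read_st_document(txt, a1, a2, id = "d1")
  expect_warning(doc <- st_to_graph(d, phospho_parse()),
                 "event-trigger endpoint")
  s <- doc$sentences[[1]]
  expect_false("Coreference" %in% s$interactions$type)
  expect_equal(sum(grepl("event-trigger", conversion_log(doc))), 1)
})

test_that("cross-sentence arguments are kept but flagged", {
  g <- gen_corpus(8, seed = 31, cross_sentence_rate = 0.8,
                  sentences_per_document = 3)
  expect_gt(g$manifest[["cross_sentence_events"]], 0)
  itr <- dplyr::bind_rows(lapply(gather_sentences(g$corpus),
                                 function(s) s$interactions))
  expect_gt(sum(itr$cross_sentence), 0)
  expect_equal(nrow(validate_graph(g$corpus)), 0)
})

test_that("a second Site reaching an occupied primary argument is discarded", {
  # two sites whose SiteParent both reach the protein of the same primary
  toks <- tibble::tibble(
    id = paste0("t", 1:6),
    text = c("binds", "PrA", "at", "Ser1", "Ser2", "."),
    pos = c("VBZ", "NN", "IN", "NN", "NN", "."),
    start = c(0L, 6L, 10L, 13L, 18L, 23L), end = c(5L, 9L, 12L, 17L, 22L, 24L))
  deps <- tibble::tibble(type = c("dobj", "prep_at", "prep_at", "punct"),
                         governor = c("t1", "t1", "t1", "t1"),
                         dependent = c("t2", "t4", "t5", "t6"))
  ent <- tibble::tibble(
    id = c("e1", "e2", "e3", "e4"),
    type = c("Binding", "Protein", "Entity", "Entity"),
    start = c(0L, 6L, 13L, 18L), end = c(5L, 9L, 17L, 22L),
    text = c("binds", "PrA", "Ser1", "Ser2"),
    head = c("t1", "t2", "t4", "t5"),
    given = c(FALSE, TRUE, FALSE, FALSE),
    event = c(TRUE, FALSE, FALSE, FALSE))
  itr <- tibble::tibble(
    id = c("i1", "i2", "i3", "i4", "i5"),
    type = c("Theme", "Site", "Site", "SiteParent", "SiteParent"),
    source = c("e1", "e1", "e1", "e3", "e4"),
    target = c("e2", "e3", "e4", "e2", "e2"),
    directed = TRUE, event = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    given = FALSE, site_of = NA_character_,
    source_role = c(NA, NA, NA, "Arg1", "Arg1"),
    target_role = c(NA, NA, NA, "Arg2", "Arg2"), cross_sentence = FALSE)
  evs <- tibble::tibble(id = "ev1", trigger = "e1",
                        args = list(tibble::tibble(
                          interaction = c("i1", "i2", "i3"),
                          target_event = NA_character_)))
  s <- sentence_graph("d1.s1", "binds PrA at Ser1 Ser2 .", tokens = toks,
                      dependencies = deps, entities = ent,
                      interactions = itr, events = evs)
  doc <- ig_document("d1", s$text, list(s))
  st <- graph_to_st(doc, demo_scheme())
  args <- st$events$args[[1]]
  expect_equal(sum(role_base(args$role) == "Site"), 1)
  expect_equal(sum(role_base(args$role) == "Theme"), 1)
})

test_that("duplicate events collapse recursively, re-pointing referencing events", {
  # two Phosphorylation events that become identical once their sites are
  # resolved to the same primary, plus a Regulation pointing at one of them
  toks <- tibble::tibble(
    id = paste0("t", 1:4),
    text = c("regulates", "phosphorylates", "PrA", "."),
    pos = c("VBZ", "VBZ", "NN", "."),
    start = c(0L, 10L, 25L, 29L), end = c(9L, 24L, 28L, 30L))
  deps <- tibble::tibble(type = c("dobj", "dobj", "punct"),
                         governor = c("t1", "t2", "t1"),
                         dependent = c("t2", "t3", "t4"))
  ent <- tibble::tibble(
    id = c("e1", "e2", "e3"),
    type = c("Regulation", "Phosphorylation", "Protein"),
    start = c(0L, 10L, 25L), end = c(9L, 24L, 28L),
    text = c("regulates", "phosphorylates", "PrA"),
    head = c("t1", "t2", "t3"),
    given = c(FALSE, FALSE, TRUE), event = c(TRUE, TRUE, FALSE))
  itr <- tibble::tibble(
    id = c("i1", "i2"), type = c("Theme", "Theme"),
    source = c("e1", "e2"), target = c("e2", "e3"),
    directed = TRUE, event = TRUE, given = FALSE, site_of = NA_character_,
    source_role = NA_character_, target_role = NA_character_,
    cross_sentence = FALSE)
  evs <- tibble::tibble(
    id = c("ev1", "ev2", "ev3"), trigger = c("e2", "e2", "e1"),
    args = list(
      tibble::tibble(interaction = "i2", target_event = NA_character_),
      tibble::tibble(interaction = "i2", target_event = NA_character_),
      tibble::tibble(interaction = "i1", target_event = "ev2")))
  s <- sentence_graph("d1.s1", "regulates phosphorylates PrA .",
                      tokens = toks, dependencies = deps, entities = ent,
                      interactions = itr, events = evs)
  doc <- ig_document("d1", s$text, list(s))
  st <- graph_to_st(doc, demo_scheme())
  # ev1/ev2 are identical -> one survivor; the Regulation re-points to it
  expect_equal(sum(st$events$type == "Phosphorylation"), 1)
  reg <- st$events[st$events$type == "Regulation", ]
  expect_equal(nrow(reg), 1)
  surv <- st$events$id[st$events$type == "Phosphorylation"]
  expect_equal(reg$args[[1]]$target, surv)
})

test_that("an empty document converts to an empty a2", {
  d <- st_document("d1", "nothing here .")
  parses <- list(list(offset = 0L, text = "nothing here .",
                      tokens = tibble::tibble(
                        id = c("t1", "t2", "t3"),
                        text = c("nothing", "here", "."),
                        pos = c("NN", "RB", "."),
                        start = c(0L, 8L, 13L), end = c(7L, 12L, 14L)),
                      dependencies = empty_dependencies()))
  doc <- st_to_graph(d, parses)
  back <- graph_to_st(doc, demo_scheme())
  out <- write_st_document(back)
  expect_equal(out$a2, character())
})

test_that("full cycle st -> graph -> st is identity on generated corpora", {
  g <- gen_corpus(15, seed = 41, nesting_rate = 0.35,
                  shared_trigger_rate = 0.3, equiv_rate = 0.3,
                  site_rate = 0.5, negation_rate = 0.2,
                  speculation_rate = 0.15)
  for (i in seq_along(g$st_documents)) {
    back <- roundtrip_st(g$st_documents[[i]], g$parses[[i]], g$scheme)
    expect_true(st_documents_equivalent(g$st_documents[[i]], back))
  }
})
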